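line	viability_regular	viability_ethanol	devtime_regular	devtime_ethanol
line_001	0.5703	0.2311	8.798	9.189
line_002	0.5068	0.0105	10.118	10.307
line_003	0.9091	0.5282	9.829	9.809
line_004	0.5241	0.3536	9.126	10.338
line_005	0.5777	0.2556	9.792	10.258
line_006	0.7498	0.3461	9.469	9.712
line_007	0.6208	0.0326	9.157	9.869
line_008	0.5559	0.2348	8.846	10.402
line_009	0.8741	0.2356	8.75	10.682
line_010	0.5002	0.2846	8.338	9.384
line_011	0.157	0	8.988	9.802
line_012	0.3969	0	8.965	9.379
line_013	0.5169	0.1214	9.058	9.827
line_014	0.4754	0.5192	8.494	9.711
line_015	0.6592	0.2124	9.17	9.389
line_016	1	0.7358	9.926	9.891
line_017	0.3055	0.2873	9.356	9.568
line_018	0.6025	0.5056	10.518	10.886
line_019	0.4294	0.0307	9.309	10.164
line_020	0.3446	0.0741	9.648	9.654
line_021	0.4821	0	9.024	10.36
line_022	0.5323	0.5823	9.556	9.464
line_023	0.7904	0.6601	9.012	9.826
line_024	0.8754	0.3912	8.633	10.006
line_025	0.6093	0.5716	9.141	10.176
line_026	0.2296	0	9.663	10.221
line_027	0.5694	0.2024	8.97	9.975
line_028	0.5787	0.2928	8.421	9.902
line_029	0.8066	0.4298	9.149	9.625
line_030	0.6498	0.4912	9.107	10.289
line_031	0.867	0.4997	9.467	10.79
line_032	0.2968	0.051	8.87	9.851
line_033	0.2736	0	9.276	9.575
line_034	0.5452	0.288	8.912	9.938
line_035	0.4712	0.1623	9.806	10.059
line_036	0.0019	0	8.922	10.57
line_037	0.1228	0	8.813	9.678
line_038	0.9046	0.4168	9.54	9.971
line_039	0.7038	0.5324	9.391	10.268
line_040	0.8624	0.5777	9.454	10.351
line_041	0.6769	0.2576	10.493	10.607
line_042	0.4485	0.3578	9.327	9.611
line_043	0.4956	0.2404	8.693	9.828
line_044	0.3871	0.1634	8.855	9.645
line_045	0.4093	0.4239	9.667	9.713
line_046	0.8284	0.545	8.559	9.561
line_047	0.4173	0.0549	9.721	9.998
line_048	0.5917	0.3191	9.137	9.741
line_049	0.5308	0.3715	9.591	9.303
line_050	0.544	0.3654	9.906	10.393
line_051	0.3281	0	9.226	10.194
line_052	0.1951	0.1029	9.2	9.519
line_053	0.026	0.0749	9.791	10.235
line_054	0.5994	0.2267	8.46	9.551
line_055	0.4558	0.5589	8.246	9.569
line_056	0.9133	0.2141	9.75	10.315
line_057	0.54	0.3912	10.091	10.341
line_058	0.7603	0.3685	9.543	10.16
line_059	0.2524	0	9.478	9.99
line_060	0.494	0	9.419	9.682
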