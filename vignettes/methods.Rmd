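---
title: "Methods: variance partitioning, line-mean association and interaction subnetworks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance partitioning, line-mean association and interaction subnetworks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The design this package analyses

gxenet analyses replicated phenotypes of fully inbred reference panels —
the Drosophila Genetic Reference Panel (DGRP) is the motivating example —
measured under two rearing conditions (here called `regular` and
`ethanol`). Because every line is genetically identical within itself,
replicate vials of the same line estimate an environmental (residual)
variance, differences among line means estimate genetic variance, and the
line-by-treatment interaction estimates genetic variation in *sensitivity*
to the rearing condition (G×E). The package chains four stages:

1. **Variance partitioning** of the replicate-level data under a mixed
   ANOVA model, with broad-sense heritability.
2. **Phenotype derivation**: viability (fraction of adults surviving out of
   the eggs placed), development time (count-weighted mean eclosion day),
   per-line condition means, and sensitivity (ethanol minus regular).
3. **Genome-wide association on line means** against homozygous biallelic
   genotypes, with MAF filtering, nominal thresholds and gene annotation.
4. **Interaction-subnetwork extraction** for the candidate genes under a
   one-bridge recruitment rule, with a randomization test on the size of
   the largest connected cluster.

A synthetic-data generator produces panels with exactly the statistical
structure the stages assume, so the full chain is testable end to end
without any external data.

# Variance partitioning and heritability

The unsexed model is

$$Y = \mu + T + L + L{\times}T + \varepsilon,$$

with treatment $T$ fixed, line $L$ and the interaction $L{\times}T$ random
and mutually independent, and $\varepsilon$ the within-line residual. With
sexes measured, the model extends to
$Y = \mu + T + S + T{\times}S + L + L{\times}S + L{\times}T +
L{\times}T{\times}S + \varepsilon$ (treatment and sex fixed, all line terms
random). Broad-sense heritability is the genetic fraction of phenotypic
variance,

$$H^2 = \frac{\sigma^2_G}{\sigma^2_P}
      = \frac{\sigma^2_L + \sigma^2_{LT}}
             {\sigma^2_L + \sigma^2_{LT} + \sigma^2_\varepsilon},$$

with all line-interaction components joining $\sigma^2_G$ in the sexed
model. Per-condition `reduced` models ($Y = \mu + L + \varepsilon$) give a
within-condition $H^2 = \sigma^2_L / (\sigma^2_L + \sigma^2_\varepsilon)$.

**Estimation.** Components are estimated by REML (`lme4::lmer`). For
exactly balanced designs the package also carries an independent
closed-form solution of the expected-mean-squares (EMS) equations under
the unrestricted-model convention (e.g.
$E[\mathrm{MS}_L] = \sigma^2_\varepsilon + r\,\sigma^2_{LT} +
tr\,\sigma^2_L$ for $r$ replicates and $t$ treatments). On balanced data
the two coincide whenever all estimates are interior, which is what the
test suite asserts; the EMS route exists precisely to be an oracle the
REML path can be checked against, and is exposed via
`ems_variance_components()` / `method = "ems"`.

**Numerical choices.** Negative variance solutions (possible for EMS and
for boundary REML fits) are truncated to zero *before* $H^2$ is formed, so
$H^2 \in [0, 1]$ by construction. Per-term significance comes from the
balanced ANOVA F tests, with each random term tested over the appropriate
narrower mean square (line over line-by-treatment, interactions over the
residual; in the sexed model each interaction over the next narrower
interaction). In the three-way random design no exact F exists for the
line term; the reported line test over $\mathrm{MS}_{LT}$ is the
conventional, slightly conservative choice. Fits require at least two
replicates per design cell.

**Sensitivity.** Per line, `sensitivity = mean(ethanol) − mean(regular)`;
positive values mean a higher trait value under ethanol (slower
development, or better survival). The signed value is retained as the
primary quantity — it is information-preserving — with the magnitude
(`abs_sensitivity`) reported alongside, since survival differences are
often quoted as percentages without sign. Lines with data in only one
condition are flagged excluded with a reason (mirroring panels in which
some lines produce no viable flies under ethanol) and are dropped from
sensitivity and combined-model analyses while remaining available to
per-condition models.

Correlations between per-line quantities (the same trait across
conditions, or two traits' sensitivities) are Pearson correlations with
two-sided parametric p-values, computed over lines present in both tables.

# Association on line means

Association uses the line mean as the unit of analysis — the natural
choice for inbred panels, where replicate variation is environmental. For
each variant the model is ordinary least squares,

$$\bar y_\ell = \beta_0 + \beta_1 g_\ell + \gamma^\top c_\ell +
e_\ell,$$

with $g_\ell \in \{0, 2\}$ the minor-allele count of (fully homozygous)
line $\ell$ and $c_\ell$ optional per-line fixed covariates. The slope,
its standard error, and a two-sided p-value from the t distribution with
$n - k$ degrees of freedom are reported per variant.

Panel-specific association servers additionally adjust for endosymbiont
infection, segregating inversions and polygenic relatedness; those are
panel metadata this package cannot derive, so they are exposed as the
generic covariate matrix — any per-line fixed covariate can be projected
out — rather than re-implemented. A kinship random effect is out of scope.

Filtering and annotation conventions:

* **MAF filter**: variants kept at MAF ≥ threshold (default 0.05,
  boundary inclusive), computed over non-missing lines.
* **Testability guard**: a variant needs at least `min_class` (default 4)
  lines in each genotype class; smaller classes make single-line outliers
  indistinguishable from association. Untestable or constant variants are
  emitted with `p = 1` and a `degenerate` flag rather than dropped, so
  variant accounting stays exact.
* **Thresholds**: nominal and strict (`p < alpha`), with a primary tier
  (default `1e-5`) and a relaxed tier (default `5e-5`) that feeds the
  network stage. No multiplicity correction is applied, matching the
  nominal-threshold convention of panel GWA.
* **Annotation**: a variant is `inside` a gene whose body contains it and
  `near` a gene within `window` bp (default 1000, boundary inclusive;
  distance is the bp offset to the gene-body edge). Gene bodies are
  0-based half-open internally and in BED files, 1-based inclusive in VCF;
  the converters are round-trip tested.

# Subnetwork extraction and the randomization test

Candidate genes (the union, deduplicated by gene id, of annotated genes
across all traits' relaxed-tier hits) are mapped onto a global gene–gene
interaction network. The extracted subnetwork keeps

* every edge joining two candidates, and
* every non-candidate adjacent to **two or more distinct candidates**
  (a "computationally recruited" bridge gene), with its edges to those
  candidates.

The two-neighbour requirement is what makes a bridge a bridge: a
one-bridge path between candidates requires a non-candidate with two
candidate neighbours, whereas a non-candidate touching a single candidate
creates no candidate-to-candidate connection. Bridge–bridge edges are
never retained, and candidates with no retained edge drop out of the
extracted graph.

The statistic is the **node count of the largest connected component**
("largest cluster"). Its significance is assessed by drawing
`n_randomizations` random gene sets of the same (matched) size from the
global network, extracting each one's subnetwork, and counting draws whose
largest cluster **strictly exceeds** the observed size:

$$p = \frac{\#\{b : s_b > s_{\mathrm{obs}}\}}{B}.$$

This literal counting rule can report $p = 0$; the add-one corrected
$(\#+1)/(B+1)$ is always reported alongside. The default null draws nodes
uniformly ("same number of input genes"); a `degree_matched` alternative
samples within global-degree deciles, useful in strongly heterogeneous
networks where hubs inflate null cluster sizes — it is an option, not the
default. Unmatched candidate ids are dropped with a logged count, and the
null uses the matched count so observed and null statistics are
comparable.

Hub ranking orders nodes by extracted-graph degree, descending, ties
broken lexicographically by gene id. The display filter
(`degree_filter()`, default 3) removes low-degree nodes in a **single
pass** — degrees are measured once, before any removal — so a node kept
for having degree ≥ 3 may have lower degree in the filtered graph.

# The synthetic generator

`sim_config()` + `simulate_panel()` generate a panel with the exact
structure the stages assume: balanced phenotypes drawn from the mixed
model above (independent zero-mean normal random effects), strictly
homozygous 0/2 genotypes with per-variant MAF uniform on a configured
interval, non-overlapping gene models, and a Chung–Lu (configuration-model
style) background interaction network with an embedded connected cluster
of configurable size.

Default study conditions (chosen once, as the conditions the pipeline is
meant to emulate):

* 200 lines × 2 treatments × 5 replicates; viability-like scale with
  grand mean 0.36 and treatment effect −0.32 (ethanol minus regular), so
  per-condition means sit near 0.52 / 0.20;
* $\sigma^2_L = 0.030$, $\sigma^2_{LT} = 0.015$,
  $\sigma^2_\varepsilon = 0.038$, giving a combined-condition
  $H^2 = 0.54$ and within-condition $H^2 \approx 0.5$;
* 1000 variants, MAF uniform on [0.05, 0.5]; 3 causal variants of effect
  0.1 per minor allele placed inside embedded-cluster genes. The effect
  size is a power design choice: 0.1 per allele is ~1 line-mean SD
  between homozygote classes at these variance settings, so a causal
  variant clears `p < 1e-5` with high probability at 200 lines; materially
  smaller effects are undetectable at this panel size and would make the
  end-to-end chain untestable by construction.
* 1000 network nodes (one per gene), 1000 background edges with fitness
  exponent −0.3, embedded cluster of 20 genes (random spanning tree plus
  extra random within-cluster edges). The density was calibrated so that
  random candidate sets yield small largest clusters (null mean ≈ 7 nodes
  for 60-gene draws) while the embedded cluster is reliably detected; a
  much denser or more hub-dominated background lets random draws percolate
  and removes the contrast the test needs.

Viability is generated on an *untruncated* normal scale by default: this
keeps the balanced-ANOVA oracle exact, at the cost of occasional values
outside [0, 1]. The error distribution for count-based viability (binomial
out of 50 eggs) is not modelled by default for the same reason; the
derivation functions accept raw counts, so binomially generated counts can
be fed through `derive_viability()` when the latent-scale idealisation
matters.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real panels: linkage disequilibrium (variants are
independent), kinship structure among lines, endosymbiont or inversion
covariates, non-normal and heteroscedastic residuals, unbalanced replicate
counts, and the curation biases of literature-derived interaction networks
(degree heterogeneity is emulated; ascertainment toward well-studied genes
is not).

# Reproducibility and problem sizes

All randomness flows from one integer seed; each generator stage derives
an independent sub-seed (kept below $2^{31}$), so stages are individually
reproducible and insensitive to each other's draw counts. Identical
configurations and seeds give byte-identical run manifests.

The test suite exercises the chain at the panel scale it targets: 100
simulated panels per heritability level (truth 0.30 / 0.46 / 0.54) for
parameter recovery, 1000-variant association scans checked against the
closed-form OLS oracle at $10^{-10}$ relative accuracy plus a 10,000
variant null-uniformity check, exhaustive subnetwork enumeration on all
candidate subsets of random ≤ 8-node graphs, exact-null comparison of the
randomization test on an enumerable 6-node graph, and 20-seed power runs
for the embedded-cluster detection — sizes chosen so the whole suite
completes in a few minutes on one CPU while keeping Monte-Carlo error well
inside the asserted tolerances.

# Known limitations

* REML on severely unbalanced data is supported, but the EMS oracle (and
  the per-term F tests) require exact balance; p-values are `NA` when
  balance fails.
* The association stage is OLS on line means; it does not model
  line-mean variance differences from unequal replicate counts (a
  weighting hook would be the natural extension).
* The randomization test fixes the candidate-set *size*; it does not
  condition on the candidates' degree sequence unless `degree_matched`
  is selected, and that option matches deciles, not exact degrees.
* Reported development-time and viability conventions assume the
  two-condition design; multi-condition panels are out of scope.
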