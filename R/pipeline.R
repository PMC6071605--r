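#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end analysis: input paths (or
#' in-memory objects), model tags, the MAF cutoff, the primary and relaxed
#' association thresholds, the gene-annotation window, the randomization
#' settings and the root seed. Defaults mirror the conventional settings of
#' inbred-panel condition-sensitivity screens: MAF >= 0.05, nominal
#' P < 1e-5 with a relaxed 5e-5 tier feeding the network stage, a 1 kb
#' annotation window and 1000 randomizations.
#'
#' @param phenotypes,genotypes,gene_models,network input file paths
#'   (phenotype TSV, genotype TSV/VCF, BED/GFF3, edge-list TSV) or the
#'   corresponding in-memory objects.
#' @param model variance-partition model tag (see
#'   [fit_variance_components()]).
#' @param maf_threshold minor-allele-frequency cutoff.
#' @param alpha,alpha_relaxed nominal association thresholds; the relaxed
#'   tier defines the candidate genes handed to the network stage.
#' @param window gene annotation window, bp.
#' @param n_randomizations,null_model randomization-test settings.
#' @param min_class minimum lines per genotype class (see [associate()]).
#' @param seed root seed; all stage randomness derives from it.
#' @param out_dir output directory (`NULL` = no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(phenotypes = NULL, genotypes = NULL,
                            gene_models = NULL, network = NULL,
                            model = "full", maf_threshold = 0.05,
                            alpha = 1e-5, alpha_relaxed = 5e-5,
                            window = 1000L, n_randomizations = 1000L,
                            null_model = "uniform_nodes",
                            min_class = 4L, seed = 1L, out_dir = NULL) {
  stopifnot(maf_threshold >= 0, maf_threshold <= 0.5,
            alpha > 0, alpha < 1, alpha_relaxed >= alpha, alpha_relaxed < 1,
            window >= 0, n_randomizations >= 100L)
  structure(list(phenotypes = phenotypes, genotypes = genotypes,
                 gene_models = gene_models, network = network,
                 model = model, maf_threshold = maf_threshold,
                 alpha = alpha, alpha_relaxed = alpha_relaxed,
                 window = as.integer(window),
                 n_randomizations = as.integer(n_randomizations),
                 null_model = null_model, min_class = as.integer(min_class),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Any field of [pipeline_config()] may appear in the file; missing fields
#' take their defaults.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

resolve_input <- function(x, reader, what) {
  if (is.null(x)) stop("pipeline config lacks ", what)
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop(what, " file not found: ", x)
    reader(x)
  } else x
}

#' Run the full analysis pipeline
#'
#' Composes the four stages on one phenotype table: (1) variance
#' partitioning (full model plus per-condition reduced models) and line
#' summaries; (2) MAF filtering and line-mean association for each derived
#' phenotype (each condition mean and the sensitivity) at the primary and
#' relaxed thresholds, with gene annotation; (3) union of the annotated
#' candidate genes across phenotypes at the relaxed threshold
#' (deduplicated by gene id); (4) one-bridge subnetwork extraction and the
#' largest-cluster randomization test. Returns a manifest recording seeds,
#' settings and the counts at every stage; with `out_dir` set, all stage
#' outputs and the manifest JSON are written.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `manifest`, `variance`
#'   (named list of `variance_decomposition`), `summaries`, `associations`
#'   (per phenotype), `hits` (per phenotype and threshold), `candidates`,
#'   `subnetwork`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  pheno <- resolve_input(config$phenotypes, read_phenotypes, "phenotypes")
  geno <- resolve_input(config$genotypes, function(p) {
    if (tolower(tools::file_ext(p)) == "vcf") read_vcf(p)
    else read_genotypes_tsv(p)
  }, "genotypes")
  genes <- resolve_input(config$gene_models, read_gene_models, "gene models")
  net <- resolve_input(config$network, read_interaction_graph, "network")
  stopifnot(inherits(pheno, "replicate_table"),
            inherits(geno, "genotype_matrix"),
            inherits(genes, "gene_model_set"), igraph::is_igraph(net))

  treatments <- unique(pheno$treatment)
  variance <- list(full = fit_variance_components(pheno, model = config$model))
  for (tr in treatments) {
    variance[[paste0("reduced_", tr)]] <-
      fit_variance_components(pheno, model = "reduced", condition = tr)
  }
  summaries <- line_summaries(pheno, treatments = treatments)

  geno_f <- suppressMessages(maf_filter(geno, config$maf_threshold))
  phenos <- c(paste0("mean_", treatments), "sensitivity")
  associations <- list()
  hits <- list()
  candidate_sets <- list()
  for (ph in phenos) {
    rec <- associate(geno_f, summaries, phenotype = ph,
                     min_class = config$min_class)
    rec <- annotate_variants(rec, genes, window = config$window)
    associations[[ph]] <- rec
    hits[[ph]] <- list(
      primary = threshold_hits(rec, config$alpha),
      relaxed = threshold_hits(rec, config$alpha_relaxed))
    candidate_sets[[ph]] <- hit_genes(hits[[ph]]$relaxed)
  }
  candidates <- sort(unique(unlist(candidate_sets)))

  subnetwork <- if (length(candidates) > 0L) {
    suppressMessages(randomization_test(
      net, candidates, n_randomizations = config$n_randomizations,
      null_model = config$null_model,
      seed = stage_seed(config$seed, 9L)))
  } else NULL

  manifest <- list(
    package_version = as.character(utils::packageVersion("gxenet")),
    seed = config$seed,
    settings = list(model = config$model, maf_threshold = config$maf_threshold,
                    alpha = config$alpha, alpha_relaxed = config$alpha_relaxed,
                    window = config$window,
                    n_randomizations = config$n_randomizations,
                    null_model = config$null_model),
    counts = list(
      n_lines = length(unique(pheno$line)),
      n_lines_included = sum(summaries$included),
      n_variants_input = nrow(geno$variants),
      n_variants_tested = nrow(geno_f$variants),
      n_hits_primary = vapply(hits, function(h) nrow(h$primary), integer(1)),
      n_hits_relaxed = vapply(hits, function(h) nrow(h$relaxed), integer(1)),
      n_candidate_genes = length(candidates),
      n_candidates_matched = if (is.null(subnetwork)) 0L else
        length(subnetwork$candidates),
      n_recruited = if (is.null(subnetwork)) 0L else
        length(subnetwork$recruited),
      subnetwork_nodes = if (is.null(subnetwork)) 0L else
        igraph::vcount(subnetwork$graph),
      largest_cluster_size = if (is.null(subnetwork)) 0L else
        subnetwork$largest_cluster_size),
    heritability = lapply(variance, function(v) v$H2),
    permutation_p = if (is.null(subnetwork)) NA else
      subnetwork$permutation$p_value)

  result <- structure(list(manifest = manifest, variance = variance,
                           summaries = summaries, associations = associations,
                           hits = hits, candidates = candidates,
                           subnetwork = subnetwork),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline run\n")
  cat("  H2:", paste(sprintf("%s=%.3f", names(x$manifest$heritability),
                             unlist(x$manifest$heritability)),
                     collapse = ", "), "\n")
  cat("  variants tested:", x$manifest$counts$n_variants_tested,
      "| candidate genes:", x$manifest$counts$n_candidate_genes, "\n")
  if (!is.null(x$subnetwork)) print(x$subnetwork)
  invisible(x)
}

write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_line_summaries(result$summaries, file.path(dir, "line_summaries.tsv"))
  for (ph in names(result$associations)) {
    write_associations(result$associations[[ph]],
                       file.path(dir, paste0("assoc_", ph, ".tsv")))
    write_associations(result$hits[[ph]]$primary,
                       file.path(dir, paste0("hits_primary_", ph, ".tsv")))
    write_associations(result$hits[[ph]]$relaxed,
                       file.path(dir, paste0("hits_relaxed_", ph, ".tsv")))
  }
  writeLines(result$candidates, file.path(dir, "candidate_genes.txt"))
  if (!is.null(result$subnetwork) &&
      igraph::vcount(result$subnetwork$graph) > 0L) {
    write_subnetwork(result$subnetwork, dir)
  }
  vd <- lapply(result$variance, function(v) {
    list(model = v$model, condition = v$condition, H2 = v$H2,
         sigma2 = as.list(v$sigma2), p_values = as.list(v$p_values))
  })
  jsonlite::write_json(vd, file.path(dir, "variance_decomposition.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
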