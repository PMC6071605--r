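#' Simulation configuration for a synthetic inbred panel
#'
#' Collects every tunable of the synthetic generator: the factorial phenotype
#' design (lines x treatments \[x sexes\] x replicates and the variance
#' components of the mixed model Y = mu + T + L + LxT + e, or its sexed
#' extension), the biallelic genotype panel, the gene models, and the global
#' interaction network with an embedded enriched cluster.
#'
#' Defaults emulate an egg-to-adult viability screen on a ~200-line inbred
#' reference panel reared on regular vs ethanol-supplemented medium with five
#' replicate vials per line and condition: grand mean 0.36 on the proportion
#' scale with a treatment effect of -0.32 (ethanol minus regular), so the
#' per-condition means sit near 0.52 and 0.20, and variance components
#' `sigma2_L` = 0.030, `sigma2_LT` = 0.015, `sigma2_eps` = 0.038 giving a
#' combined-condition broad-sense heritability of 0.54.
#'
#' @param n_lines number of inbred lines.
#' @param n_replicates replicates per line x condition (x sex).
#' @param treatments two condition labels; the second receives
#'   `+treatment_effect/2`, the first `-treatment_effect/2`.
#' @param with_sex simulate both sexes with the sexed model terms.
#' @param mu grand mean, phenotype units.
#' @param treatment_effect fixed difference (second minus first treatment).
#' @param sex_effect fixed difference (M minus F), used when `with_sex`.
#' @param sigma2_L,sigma2_LT,sigma2_LS,sigma2_LTS,sigma2_eps variance
#'   components (phenotype units squared), all `>= 0`.
#' @param n_variants,maf_range,n_causal,causal_effect genotype panel: number
#'   of biallelic sites, minor-allele-frequency interval within (0, 0.5],
#'   number of causal sites and their per-minor-allele effect.
#' @param n_genes,genome_length,n_chromosomes gene-model layout.
#' @param network_n_nodes,network_n_edges background interaction network size
#'   (`network_n_nodes` defaults to `n_genes`).
#' @param embedded_cluster_size size of the connected enriched cluster wired
#'   into the background network.
#' @param seed integer seed; every generator draws from it deterministically.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_lines = 200L,
                       n_replicates = 5L,
                       treatments = c("regular", "ethanol"),
                       with_sex = FALSE,
                       mu = 0.36,
                       treatment_effect = -0.32,
                       sex_effect = 0,
                       sigma2_L = 0.030,
                       sigma2_LT = 0.015,
                       sigma2_LS = 0,
                       sigma2_LTS = 0,
                       sigma2_eps = 0.038,
                       n_variants = 1000L,
                       maf_range = c(0.05, 0.5),
                       n_causal = 3L,
                       causal_effect = 0.1,
                       n_genes = 1000L,
                       genome_length = 2e6,
                       n_chromosomes = 2L,
                       network_n_nodes = NULL,
                       network_n_edges = 1000L,
                       embedded_cluster_size = 20L,
                       seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines),
              n_replicates = as.integer(n_replicates),
              treatments = as.character(treatments),
              with_sex = isTRUE(with_sex),
              mu = mu, treatment_effect = treatment_effect,
              sex_effect = sex_effect,
              sigma2_L = sigma2_L, sigma2_LT = sigma2_LT,
              sigma2_LS = sigma2_LS, sigma2_LTS = sigma2_LTS,
              sigma2_eps = sigma2_eps,
              n_variants = as.integer(n_variants),
              maf_range = as.numeric(maf_range),
              n_causal = as.integer(n_causal),
              causal_effect = causal_effect,
              n_genes = as.integer(n_genes),
              genome_length = genome_length,
              n_chromosomes = as.integer(n_chromosomes),
              network_n_nodes = as.integer(network_n_nodes %||% n_genes),
              network_n_edges = as.integer(network_n_edges),
              embedded_cluster_size = as.integer(embedded_cluster_size),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  vars <- c("sigma2_L", "sigma2_LT", "sigma2_LS", "sigma2_LTS", "sigma2_eps")
  for (v in vars) {
    val <- cfg[[v]]
    if (!is.finite(val) || val < 0) {
      stop("configuration error: ", v, " must be finite and >= 0")
    }
  }
  if (length(cfg$treatments) != 2L) stop("exactly two treatment labels required")
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5 ||
      cfg$maf_range[1] > cfg$maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  if (cfg$n_causal > cfg$n_variants) stop("n_causal exceeds n_variants")
  if (cfg$embedded_cluster_size > cfg$network_n_nodes) {
    stop("embedded_cluster_size exceeds network_n_nodes")
  }
  invisible(cfg)
}

# Independent sub-seeds so each generator is reproducible on its own and
# stages do not perturb each other's streams. Kept below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + stage * 1009L) %% 2147483647L
}

#' Simulate a balanced replicate-level phenotype table
#'
#' Draws from the mixed model Y = mu + T + L + LxT + e (or, with sexes,
#' Y = mu + T + S + TxS + L + LxS + LxT + LxTxS + e): the treatment (and sex)
#' effects are fixed, the line and all line interactions are independent
#' zero-mean normals with the configured variances, and the residual is
#' drawn per replicate.
#'
#' @param config a [sim_config()].
#' @param line_effects optional numeric vector of per-line genetic effects to
#'   use instead of drawing from `N(0, sigma2_L)` (used when phenotypes must
#'   track simulated causal variants).
#' @return a [replicate_table()] with `n_lines * 2 [* 2] * n_replicates` rows
#'   and attribute `truth` (the drawn random effects).
#' @export
simulate_phenotypes <- function(config, line_effects = NULL) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, 1L))
  lines <- sprintf("line_%03d", seq_len(config$n_lines))
  sexes <- if (config$with_sex) c("F", "M") else NA_character_

  L <- if (is.null(line_effects)) {
    stats::rnorm(config$n_lines, 0, sqrt(config$sigma2_L))
  } else {
    stopifnot(length(line_effects) == config$n_lines)
    line_effects
  }
  names(L) <- lines
  LT <- matrix(stats::rnorm(config$n_lines * 2L, 0, sqrt(config$sigma2_LT)),
               nrow = config$n_lines, dimnames = list(lines, config$treatments))
  grid <- expand.grid(replicate = seq_len(config$n_replicates),
                      sex = sexes, treatment = config$treatments,
                      line = lines, stringsAsFactors = FALSE)
  t_half <- ifelse(grid$treatment == config$treatments[2L],
                   config$treatment_effect / 2, -config$treatment_effect / 2)
  value <- config$mu + t_half + L[grid$line] +
    LT[cbind(grid$line, grid$treatment)]
  truth <- list(line_effects = L, line_treatment_effects = LT)

  if (config$with_sex) {
    LS <- matrix(stats::rnorm(config$n_lines * 2L, 0, sqrt(config$sigma2_LS)),
                 nrow = config$n_lines, dimnames = list(lines, c("F", "M")))
    LTS <- array(stats::rnorm(config$n_lines * 4L, 0, sqrt(config$sigma2_LTS)),
                 dim = c(config$n_lines, 2L, 2L),
                 dimnames = list(lines, config$treatments, c("F", "M")))
    s_half <- ifelse(grid$sex == "M", config$sex_effect / 2,
                     -config$sex_effect / 2)
    value <- value + s_half + LS[cbind(grid$line, grid$sex)] +
      LTS[cbind(grid$line, grid$treatment, grid$sex)]
    truth$line_sex_effects <- LS
    truth$line_treatment_sex_effects <- LTS
  }
  value <- value + stats::rnorm(nrow(grid), 0, sqrt(config$sigma2_eps))

  out <- replicate_table(
    data.frame(line = grid$line, treatment = grid$treatment, sex = grid$sex,
               replicate = grid$replicate, value = value,
               stringsAsFactors = FALSE),
    phenotype = "simulated", units = "phenotype units")
  attr(out, "truth") <- truth
  out
}

#' Simulate a homozygous biallelic genotype panel
#'
#' Fully inbred lines carry 0 or 2 copies of the minor allele; per-variant
#' minor-allele frequencies are drawn uniformly from `maf_range`. In
#' `"sampling"` mode each line is an independent Bernoulli draw at the
#' variant's frequency; in `"balanced"` mode exactly `round(maf * n_lines)`
#' lines carry the minor allele. Variants get sorted positions on
#' `n_chromosomes` chromosomes spanning `genome_length` bp.
#'
#' @param config a [sim_config()].
#' @param mode `"sampling"` (default) or `"balanced"`.
#' @return a [genotype_matrix()] with attribute `maf_drawn`.
#' @export
simulate_genotypes <- function(config, mode = c("sampling", "balanced")) {
  validate_sim_config(config)
  mode <- match.arg(mode)
  set.seed(stage_seed(config$seed, 2L))
  n_v <- config$n_variants
  n_l <- config$n_lines
  maf <- stats::runif(n_v, config$maf_range[1], config$maf_range[2])

  calls <- matrix(0L, nrow = n_v, ncol = n_l)
  if (mode == "sampling") {
    calls[] <- 2L * stats::rbinom(n_v * n_l, 1L, rep(maf, n_l))
  } else {
    for (i in seq_len(n_v)) {
      k <- round(maf[i] * n_l)
      calls[i, sample.int(n_l, k)] <- 2L
    }
  }
  chrom <- sort(sample.int(config$n_chromosomes, n_v, replace = TRUE))
  pos <- integer(n_v)
  chrom_len <- ceiling(config$genome_length / config$n_chromosomes)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- sort(sample.int(chrom_len, length(idx)))
  }
  variants <- data.frame(
    id = sprintf("var_%05d", seq_len(n_v)),
    chrom = paste0("chr", chrom),
    pos = pos, ref = "A", alt = "T",
    stringsAsFactors = FALSE)
  g <- genotype_matrix(calls, variants, lines = sprintf("line_%03d", seq_len(n_l)))
  attr(g, "maf_drawn") <- maf
  g
}

#' Simulate non-overlapping gene models
#'
#' Lays `n_genes` equal-width, non-overlapping gene bodies across the
#' chromosomes with inter-genic gaps, in 0-based half-open coordinates.
#'
#' @param config a [sim_config()].
#' @return a [gene_model_set()].
#' @export
simulate_gene_models <- function(config) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, 3L))
  n_g <- config$n_genes
  chrom_len <- ceiling(config$genome_length / config$n_chromosomes)
  per_chrom <- diff(round(seq(0, n_g, length.out = config$n_chromosomes + 1L)))
  rows <- list()
  for (ch in seq_len(config$n_chromosomes)) {
    k <- per_chrom[ch]
    if (k == 0L) next
    slot <- floor(chrom_len / k)
    width <- max(1L, floor(slot * 0.6))
    start <- (seq_len(k) - 1L) * slot + floor(slot * 0.2)
    rows[[ch]] <- data.frame(
      gene_id = "", chrom = paste0("chr", ch),
      start = start, end = start + width,
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$gene_id <- sprintf("gene_%04d", seq_len(nrow(out)))
  gene_model_set(out)
}

#' Simulate a global interaction network with an embedded cluster
#'
#' Background edges follow a Chung-Lu configuration-model scheme: nodes get
#' heavy-tailed fitness weights and edges are sampled with probability
#' proportional to the product of endpoint weights, which reproduces the
#' degree heterogeneity of curated gene-gene interaction networks. A
#' connected cluster of `embedded_cluster_size` nodes (a random spanning tree
#' plus extra edges) is then wired in and recorded as truth.
#'
#' @param config a [sim_config()].
#' @param gene_ids node labels; defaults to the ids from
#'   [simulate_gene_models()] so network nodes coincide with genes.
#' @return an igraph graph with attributes `embedded_cluster` (node ids) and
#'   `truth`.
#' @export
simulate_network <- function(config, gene_ids = NULL) {
  validate_sim_config(config)
  set.seed(stage_seed(config$seed, 4L))
  n <- config$network_n_nodes
  if (is.null(gene_ids)) gene_ids <- simulate_gene_models(config)$gene_id
  stopifnot(length(gene_ids) >= n)
  gene_ids <- gene_ids[seq_len(n)]
  max_edges <- n * (n - 1) / 2
  if (config$network_n_edges > max_edges) {
    stop("requested edges exceed simple-graph maximum")
  }
  g <- if (config$network_n_edges == 0L) {
    igraph::make_empty_graph(n, directed = FALSE)
  } else {
    fitness <- (seq_len(n))^(-0.3)  # mildly heavy-tailed expected degrees
    igraph::sample_fitness(config$network_n_edges, fitness[sample.int(n)],
                           loops = FALSE, multiple = FALSE)
  }
  igraph::V(g)$name <- gene_ids

  k <- config$embedded_cluster_size
  cluster_ids <- sample(gene_ids, k)
  if (k >= 2L) {
    ord <- sample(cluster_ids)
    tree <- cbind(ord[-1L], ord[sapply(2:k, function(i) sample.int(i - 1L, 1L))])
    extra_n <- min(k, max_edges)  # densify beyond the spanning tree
    extra <- t(replicate(extra_n, sample(cluster_ids, 2L)))
    g <- igraph::add_edges(g, as.vector(t(rbind(tree, extra))))
    g <- igraph::simplify(g)
  }
  g$embedded_cluster <- cluster_ids
  g
}

#' Simulate a complete synthetic panel
#'
#' Couples the four generators: causal variants are placed inside genes of
#' the embedded network cluster (when possible), per-line genetic values are
#' the causal allele counts times `causal_effect` plus a residual polygenic
#' draw topping total line variance up to `sigma2_L`, and phenotypes are
#' drawn from the mixed model around those line effects.
#'
#' @param config a [sim_config()].
#' @return a list of class `synthetic_panel` with elements `phenotypes`,
#'   `genotypes`, `gene_models`, `network` and `truth`.
#' @export
simulate_panel <- function(config) {
  validate_sim_config(config)
  genotypes <- simulate_genotypes(config)
  gene_models <- simulate_gene_models(config)
  network <- simulate_network(config, gene_ids = gene_models$gene_id)

  set.seed(stage_seed(config$seed, 5L))
  causal_ids <- character(0)
  line_effects <- NULL
  if (config$n_causal > 0L) {
    # prefer variants inside embedded-cluster gene bodies
    cluster_genes <- gene_models[gene_models$gene_id %in% network$embedded_cluster, ]
    in_cluster <- logical(nrow(genotypes$variants))
    for (j in seq_len(nrow(cluster_genes))) {
      in_cluster <- in_cluster |
        (genotypes$variants$chrom == cluster_genes$chrom[j] &
           genotypes$variants$pos > cluster_genes$start[j] &
           genotypes$variants$pos <= cluster_genes$end[j])
    }
    pool <- which(in_cluster)
    if (length(pool) < config$n_causal) {
      pool <- union(pool, sample(setdiff(seq_len(nrow(genotypes$variants)), pool)))
    }
    causal_idx <- pool[seq_len(config$n_causal)]
    causal_ids <- genotypes$variants$id[causal_idx]
    gmat <- genotypes$calls[causal_idx, , drop = FALSE]
    genetic <- drop(crossprod(gmat, rep(config$causal_effect, length(causal_idx))))
    genetic <- genetic - mean(genetic)
    resid_var <- max(0, config$sigma2_L - stats::var(genetic))
    line_effects <- genetic + stats::rnorm(config$n_lines, 0, sqrt(resid_var))
  }
  phenotypes <- simulate_phenotypes(config, line_effects = line_effects)

  truth <- c(attr(phenotypes, "truth"),
             list(causal_variants = causal_ids,
                  embedded_cluster = network$embedded_cluster,
                  config = unclass(config)))
  structure(list(phenotypes = phenotypes, genotypes = genotypes,
                 gene_models = gene_models, network = network, truth = truth),
            class = "synthetic_panel")
}

#' Write a synthetic panel to a directory
#'
#' Emits the pipeline's interchange formats: phenotypes TSV, genotypes as a
#' TSV matrix and a minimal homozygous VCF, gene models BED (0-based
#' half-open), the network edge list TSV, and the simulation truth as JSON.
#'
#' @param panel a [simulate_panel()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "synthetic_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_phenotypes(panel$phenotypes, file.path(dir, "phenotypes.tsv"))
  write_genotypes_tsv(panel$genotypes, file.path(dir, "genotypes.tsv"))
  write_vcf(panel$genotypes, file.path(dir, "genotypes.vcf"))
  write_bed(panel$gene_models, file.path(dir, "gene_models.bed"))
  write_edge_list(panel$network, file.path(dir, "network.tsv"))
  truth <- panel$truth
  truth$line_treatment_effects <- NULL  # matrices/arrays stay in-memory
  truth$line_sex_effects <- NULL
  truth$line_treatment_sex_effects <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
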