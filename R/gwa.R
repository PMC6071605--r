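#' Filter variants by minor allele frequency
#'
#' Retains variants whose MAF among non-missing lines is at least
#' `threshold` (the boundary is inclusive: a variant at exactly the
#' threshold is kept). Variants with no non-missing call are always dropped.
#'
#' @param geno a [genotype_matrix()].
#' @param threshold MAF cutoff in `[0, 0.5]`; default 0.05.
#' @return the filtered [genotype_matrix()], with attribute `maf_filter` =
#'   `list(threshold, n_kept, n_dropped)`.
#' @export
maf_filter <- function(geno, threshold = 0.05) {
  stopifnot(inherits(geno, "genotype_matrix"),
            threshold >= 0, threshold <= 0.5)
  maf <- variant_maf(geno)
  keep <- !is.nan(maf) & maf >= threshold
  out <- subset_variants(geno, keep)
  attr(out, "maf_filter") <- list(threshold = threshold,
                                  n_kept = sum(keep),
                                  n_dropped = sum(!keep))
  message(sprintf("MAF filter >= %g: kept %d, dropped %d variants",
                  threshold, sum(keep), sum(!keep)))
  out
}

#' Single-marker association of line means with genotypes
#'
#' For every variant, regresses the per-line phenotype on the minor-allele
#' count (0/2) with an intercept and optional fixed covariates, by ordinary
#' least squares on line means: `mean ~ 1 + allele_count [+ covariates]`.
#' Reports the allele-count slope, its standard error and the two-sided
#' p-value from the t distribution with `n - k` degrees of freedom. Lines
#' missing the genotype or the phenotype are dropped per variant. Variants
#' that are constant after line matching, or whose smaller genotype class
#' holds fewer than `min_class` lines, are emitted with `p = 1` and a
#' `degenerate` flag rather than silently dropped.
#'
#' The relatedness / infection / inversion adjustments of panel-specific
#' association servers are represented here by the generic covariate matrix:
#' any per-line fixed covariates can be supplied and are projected out.
#'
#' @param geno a [genotype_matrix()] (typically after [maf_filter()]).
#' @param line_means a `line_summary` data.frame (or any data.frame with a
#'   `line` column).
#' @param phenotype column of `line_means` to analyse, e.g. `"sensitivity"`,
#'   `"mean_ethanol"`.
#' @param covariates optional numeric matrix/data.frame of per-line fixed
#'   covariates with rownames (or a `line` column) identifying lines.
#' @param min_class minimum lines per genotype class for a variant to be
#'   testable (default 4).
#' @param min_lines minimum lines shared between genotypes and phenotype.
#' @return data.frame of class `association_table`: `variant_id`, `chrom`,
#'   `pos`, `maf`, `n`, `effect`, `se`, `statistic`, `p`, `degenerate`.
#' @export
associate <- function(geno, line_means, phenotype = "sensitivity",
                      covariates = NULL, min_class = 4L, min_lines = 20L) {
  stopifnot(inherits(geno, "genotype_matrix"),
            is.data.frame(line_means), "line" %in% names(line_means),
            phenotype %in% names(line_means))
  pheno <- stats::setNames(line_means[[phenotype]], line_means$line)
  pheno <- pheno[is.finite(pheno)]
  shared <- intersect(geno$lines, names(pheno))
  if (length(shared) < min_lines) {
    stop("fewer than ", min_lines, " lines shared between genotypes and means")
  }
  y_all <- pheno[shared]
  calls <- geno$calls[, shared, drop = FALSE]

  cov_mat <- NULL
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_lines <- if ("line" %in% names(covariates)) {
      ln <- covariates$line
      covariates$line <- NULL
      ln
    } else rownames(covariates)
    cov_mat <- as.matrix(covariates)
    if (!is.numeric(cov_mat)) stop("covariates must be numeric")
    idx <- match(shared, cov_lines)
    if (anyNA(idx)) stop("covariates missing for some lines")
    cov_mat <- cov_mat[idx, , drop = FALSE]
    if (qr(cbind(1, cov_mat))$rank < ncol(cov_mat) + 1L) {
      stop("rank-deficient covariates")
    }
  }

  n_v <- nrow(calls)
  eff <- se <- tstat <- pval <- rep(NA_real_, n_v)
  nn <- integer(n_v)
  degen <- logical(n_v)
  maf <- variant_maf(geno)
  for (i in seq_len(n_v)) {
    g <- calls[i, ]
    ok <- !is.na(g)
    n <- sum(ok)
    nn[i] <- n
    g_ok <- as.numeric(g[ok])
    y_ok <- y_all[ok]
    class_n <- min(sum(g_ok == 0), sum(g_ok == 2))
    if (n < min_lines || class_n < min_class || stats::var(g_ok) == 0) {
      degen[i] <- TRUE
      pval[i] <- 1
      next
    }
    X <- if (is.null(cov_mat)) cbind(1, g_ok) else {
      cbind(1, g_ok, cov_mat[ok, , drop = FALSE])
    }
    fit <- stats::.lm.fit(X, y_ok)
    k <- ncol(X)
    dfree <- n - k
    rss <- sum(fit$residuals^2)
    # slope variance from (X'X)^{-1}[2,2] via the R factor of the QR
    R <- qr.R(structure(list(qr = fit$qr, rank = fit$rank,
                             qraux = fit$qraux, pivot = fit$pivot),
                        class = "qr"))
    XtX_inv <- chol2inv(R)
    unpiv <- order(fit$pivot)
    sigma2 <- rss / dfree
    eff[i] <- fit$coefficients[which(fit$pivot == 2L)]
    se[i] <- sqrt(sigma2 * XtX_inv[unpiv[2L], unpiv[2L]])
    tstat[i] <- eff[i] / se[i]
    pval[i] <- 2 * stats::pt(abs(tstat[i]), dfree, lower.tail = FALSE)
  }
  out <- data.frame(variant_id = geno$variants$id, chrom = geno$variants$chrom,
                    pos = geno$variants$pos, maf = maf, n = nn,
                    effect = eff, se = se, statistic = tstat, p = pval,
                    degenerate = degen, stringsAsFactors = FALSE)
  attr(out, "phenotype") <- phenotype
  class(out) <- c("association_table", "data.frame")
  out
}

#' Filter association records at a nominal p-value threshold
#'
#' Strict inequality `p < alpha` (a record at exactly the threshold is
#' excluded); degenerate records never pass. Output sorted by ascending p.
#'
#' @param records an `association_table`.
#' @param alpha nominal threshold in (0, 1), e.g. `1e-5` or `5e-5`.
#' @return the filtered, sorted `association_table`.
#' @export
threshold_hits <- function(records, alpha = 1e-5) {
  stopifnot(is.data.frame(records), alpha > 0, alpha < 1)
  keep <- !records$degenerate & is.finite(records$p) & records$p < alpha
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "phenotype") <- attr(records, "phenotype")
  attr(out, "alpha") <- alpha
  ann <- attr(records, "annotation")
  if (!is.null(ann)) {
    ann <- ann[ann$variant_id %in% out$variant_id, , drop = FALSE]
    rownames(ann) <- NULL
    attr(out, "annotation") <- ann
    attr(out, "n_distinct_genes") <- length(unique(ann$gene_id))
  }
  class(out) <- class(records)
  out
}

#' Annotate variants with genes in or near them
#'
#' A variant is `inside` a gene whose body contains its position, and `near`
#' a gene whose body lies within `window` bp of it (boundary inclusive:
#' distance exactly `window` still counts). Variants with no gene within the
#' window are flagged intergenic. Interval arithmetic is delegated to
#' IRanges overlap machinery on gene bodies extended by `window`.
#'
#' @param records an `association_table` (or any data.frame with
#'   `variant_id`, `chrom`, `pos`).
#' @param genes a [gene_model_set()].
#' @param window flank size in bp; default 1000 (the convention of inbred
#'   panel annotation pipelines; the cutoff is configurable and logged).
#' @return `records` with added columns `genes` (comma-separated ids,
#'   `""` if intergenic), `n_genes`, `intergenic`; the long per-pair table
#'   (`variant_id`, `gene_id`, `relation`, `distance`) in attribute
#'   `annotation`, and the distinct annotated gene count in attribute
#'   `n_distinct_genes`.
#' @export
annotate_variants <- function(records, genes, window = 1000L) {
  stopifnot(is.data.frame(records),
            all(c("variant_id", "chrom", "pos") %in% names(records)),
            inherits(genes, "gene_model_set"), window >= 0)
  unknown <- setdiff(unique(records$chrom), unique(genes$chrom))
  if (length(unknown) > 0L && nrow(records) > 0L) {
    warning("chromosomes absent from gene models: ",
            paste(unknown, collapse = ", "), "; variants left unannotated")
  }
  var_gr <- GenomicRanges::GRanges(records$chrom,
                                   IRanges::IRanges(records$pos, records$pos))
  flank_gr <- gene_models_granges(genes, window = window)
  hits <- suppressWarnings(  # seqlevel-mismatch noise; handled above
    GenomicRanges::findOverlaps(var_gr, flank_gr, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  # distance as bp offset to the nearest gene-body edge (0 when inside),
  # so a variant 1 bp upstream has distance 1
  body_start <- genes$start[si] + 1L  # 1-based inclusive
  body_end <- genes$end[si]
  dist <- pmax(0L, body_start - records$pos[qi], records$pos[qi] - body_end)
  annotation <- data.frame(variant_id = records$variant_id[qi],
                           gene_id = genes$gene_id[si],
                           relation = ifelse(dist == 0L, "inside", "near"),
                           distance = as.integer(dist),
                           stringsAsFactors = FALSE)
  per_var <- split(annotation$gene_id, annotation$variant_id)
  records$genes <- vapply(records$variant_id, function(v) {
    paste(sort(per_var[[v]]), collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  records$n_genes <- vapply(records$variant_id, function(v) {
    length(per_var[[v]])
  }, integer(1), USE.NAMES = FALSE)
  records$intergenic <- records$n_genes == 0L
  attr(records, "annotation") <- annotation
  attr(records, "n_distinct_genes") <- length(unique(annotation$gene_id))
  attr(records, "window") <- window
  records
}

#' Distinct gene ids annotated to a set of association hits
#'
#' @param annotated the output of [annotate_variants()].
#' @return character vector of unique gene ids (sorted).
#' @export
hit_genes <- function(annotated) {
  ann <- attr(annotated, "annotation")
  if (is.null(ann)) stop("records have not been annotated")
  sort(unique(ann$gene_id))
}

#' Write an association table as TSV
#'
#' @param records an `association_table`.
#' @param path file path.
#' @export
write_associations <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
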