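#' Homozygous biallelic genotype matrix for inbred lines
#'
#' Calls are minor-allele counts in `{0, 2, NA}` (fully inbred lines carry no
#' heterozygotes), one row per variant, one column per line. Variant records
#' carry id, chromosome, 1-based position and ref/alt labels; positions must
#' be strictly increasing within a chromosome.
#'
#' @param calls integer matrix (variants x lines) with values 0, 2 or `NA`.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param lines character vector of line ids (one per column).
#' @return a list of class `genotype_matrix` with elements `calls`,
#'   `variants`, `lines`.
#' @export
genotype_matrix <- function(calls, variants, lines) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos") %in% names(variants)),
            nrow(calls) == nrow(variants),
            ncol(calls) == length(lines))
  bad <- !(is.na(calls) | calls == 0L | calls == 2L)
  if (any(bad)) stop("genotype calls must be 0, 2 or NA (homozygous-only)")
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  if (!"ref" %in% names(variants)) variants$ref <- "A"
  if (!"alt" %in% names(variants)) variants$alt <- "T"
  dimnames(calls) <- list(variants$id, lines)
  structure(list(calls = calls, variants = variants,
                 lines = as.character(lines)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d variants x %d lines (%d missing calls)\n",
              nrow(x$calls), ncol(x$calls), sum(is.na(x$calls))))
  invisible(x)
}

#' Per-variant minor allele frequency
#'
#' Computed over non-missing lines only. With 0/2 coding, the alternate
#' allele frequency is `mean(calls) / 2`; the minor allele frequency folds it
#' onto `[0, 0.5]`.
#'
#' @param geno a [genotype_matrix()].
#' @return numeric vector, one MAF per variant (`NaN` if all calls missing).
#' @export
variant_maf <- function(geno) {
  stopifnot(inherits(geno, "genotype_matrix"))
  p <- rowMeans(geno$calls, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

subset_variants <- function(geno, keep) {
  genotype_matrix(geno$calls[keep, , drop = FALSE],
                  geno$variants[keep, , drop = FALSE], geno$lines)
}

#' Write / read a genotype matrix as a TSV table
#'
#' Layout: columns `id`, `chrom`, `pos`, `ref`, `alt`, then one column per
#' line with calls 0/2 (`NA` for missing).
#'
#' @param geno a [genotype_matrix()].
#' @param path file path.
#' @export
write_genotypes_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  df <- cbind(geno$variants[, c("id", "chrom", "pos", "ref", "alt")],
              as.data.frame(geno$calls, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = c(id = "character", chrom = "character"))
  meta_cols <- c("id", "chrom", "pos", "ref", "alt")
  genotype_matrix(as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE]),
                  df[, meta_cols], setdiff(names(df), meta_cols))
}

#' Write / read a minimal homozygous-genotype VCF
#'
#' The writer emits VCF 4.2 with GT-only FORMAT and diploid homozygous calls
#' (`0/0`, `1/1`, `./.`), the representation used for fully inbred panels.
#' The reader (via the vcfR package) accepts any VCF whose genotypes are
#' homozygous; heterozygous calls are rejected.
#'
#' @param geno a [genotype_matrix()].
#' @param path file path.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=gxenet",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", geno$lines), collapse = "\t")), con)
  gt <- matrix("./.", nrow = nrow(geno$calls), ncol = ncol(geno$calls))
  gt[!is.na(geno$calls) & geno$calls == 0L] <- "0/0"
  gt[!is.na(geno$calls) & geno$calls == 2L] <- "1/1"
  body <- cbind(geno$variants$chrom, geno$variants$pos, geno$variants$id,
                geno$variants$ref, geno$variants$alt, ".", "PASS", ".", "GT",
                gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  norm <- gsub("\\|", "/", gt)
  calls[norm %in% c("0/0", "0")] <- 0L
  calls[norm %in% c("1/1", "1")] <- 2L
  het <- !is.na(norm) & !(norm %in% c("0/0", "1/1", "0", "1", "./."))
  if (any(het)) stop("heterozygous calls unsupported for inbred panels")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  variants <- data.frame(id = fix$ID, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  genotype_matrix(calls, variants, colnames(gt))
}
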