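#' Gene model set
#'
#' Gene bodies stored in 0-based half-open coordinates (the BED convention),
#' one row per gene: `gene_id`, `chrom`, `start`, `end`, `strand`.
#'
#' @param df data.frame with those columns (`strand` optional, default `"*"`).
#' @return the validated data.frame with class `gene_model_set` prepended.
#' @export
gene_model_set <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("gene_id", "chrom", "start", "end") %in% names(df)))
  if (!"strand" %in% names(df)) df$strand <- "*"
  df <- df[, c("gene_id", "chrom", "start", "end", "strand")]
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  if (any(df$start >= df$end)) stop("gene intervals require start < end")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids")
  rownames(df) <- NULL
  class(df) <- c("gene_model_set", "data.frame")
  df
}

#' Convert gene models to GRanges (1-based inclusive)
#'
#' @param genes a [gene_model_set()].
#' @param window symmetric flank in bp added to each side.
#' @return a `GRanges` named by gene id.
#' @export
gene_models_granges <- function(genes, window = 0L) {
  stopifnot(inherits(genes, "gene_model_set"))
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L - window,
                              end = genes$end + window),
    strand = genes$strand)
  names(gr) <- genes$gene_id
  gr
}

#' Read / write gene models (BED and GFF3)
#'
#' `read_gene_models` dispatches on the file extension: `.bed` via
#' rtracklayer's BED importer, `.gff`/`.gff3` via its GFF importer keeping
#' records of type `gene` (gene id from the `ID` or `Name` attribute).
#' `write_bed` emits BED6 with the gene id in the name column.
#'
#' @param path file path.
#' @export
read_gene_models <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading BED/GFF3 requires the rtracklayer package")
  }
  ext <- tolower(tools::file_ext(path))
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  if (ext %in% c("gff", "gff3")) {
    if ("type" %in% names(md)) gr <- gr[as.character(md$type) == "gene"]
    md <- S4Vectors::mcols(gr)
    ids <- if ("ID" %in% names(md)) as.character(md$ID) else as.character(md$Name)
  } else {
    ids <- as.character(md$name)
  }
  gene_model_set(data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # back to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE))
}

#' @rdname read_gene_models
#' @param genes a [gene_model_set()].
#' @export
write_bed <- function(genes, path) {
  stopifnot(inherits(genes, "gene_model_set"))
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id, 0L,
                    ifelse(genes$strand %in% c("+", "-"), genes$strand, "."))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
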