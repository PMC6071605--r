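#' Replicate-level phenotype table
#'
#' A `replicate_table` is a plain `data.frame` with one row per measured
#' replicate and columns `line`, `treatment`, `sex`, `replicate`, `value`,
#' carrying the phenotype name and units as attributes. It is the common
#' currency between the synthetic generator, the variance-partitioning
#' functions and the line-summary stage.
#'
#' @param df data.frame with columns `line`, `treatment`, `replicate`,
#'   `value`, and optionally `sex` (filled with `NA` when absent).
#' @param phenotype name of the phenotype (e.g. `"viability"`).
#' @param units measurement units (e.g. `"proportion"`, `"days"`).
#' @return the validated data.frame with class `replicate_table` prepended.
#' @export
replicate_table <- function(df, phenotype = "phenotype", units = "") {
  stopifnot(is.data.frame(df))
  required <- c("line", "treatment", "replicate", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("replicate table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  df <- df[, c("line", "treatment", "sex", "replicate", "value")]
  df$line <- as.character(df$line)
  df$treatment <- as.character(df$treatment)
  df$sex <- as.character(df$sex)
  if (!all(is.finite(df$value))) stop("non-finite phenotype values")
  key <- paste(df$line, df$treatment, df$sex, df$replicate, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (line, treatment, sex, replicate) rows")
  attr(df, "phenotype") <- phenotype
  attr(df, "units") <- units
  class(df) <- c("replicate_table", "data.frame")
  df
}

#' @export
print.replicate_table <- function(x, ...) {
  cat(sprintf("replicate_table: %s [%s], %d rows, %d lines, treatments: %s\n",
              attr(x, "phenotype"), attr(x, "units"), nrow(x),
              length(unique(x$line)),
              paste(unique(x$treatment), collapse = ", ")))
  NextMethod()
}

has_sex <- function(table) !all(is.na(table$sex))

#' Write / read a replicate-level phenotype table as TSV
#'
#' Columns `line`, `treatment`, `sex`, `replicate`, `value`; the phenotype
#' name and units travel in a `#phenotype=` / `#units=` header comment so a
#' round trip preserves them.
#'
#' @param table a [replicate_table()].
#' @param path file path.
#' @return `write_phenotypes` returns `path` invisibly; `read_phenotypes`
#'   returns a [replicate_table()].
#' @export
write_phenotypes <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#phenotype=%s", attr(table, "phenotype") %||% "phenotype"), con)
  writeLines(sprintf("#units=%s", attr(table, "units") %||% ""), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  header <- readLines(path, n = 10L)
  meta <- header[startsWith(header, "#")]
  grab <- function(key, default) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (length(hit) == 0L) default else sub(paste0("^#", key, "="), "", hit[1L])
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c(line = "character", sex = "character",
                                         treatment = "character"))
  replicate_table(df, phenotype = grab("phenotype", "phenotype"),
                  units = grab("units", ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
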