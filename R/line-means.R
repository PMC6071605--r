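#' Read a published line-means table
#'
#' Ingests a supplementary-style table of per-line trait means under two
#' rearing conditions (the layout of a DGRP line-means deposit): one line-id
#' column plus one column per trait x condition. Column headers are matched
#' case-insensitively; the trait is taken from substrings (`viability` /
#' `surv`; `devel` / `dt` / `eclosion` for development time) and the
#' condition from substrings (`regular` / `standard` / `control` / `ctrl`
#' vs `ethanol` / `etoh` / `treated`). A `<trait>_sensitivity` column is
#' used when present, otherwise sensitivity is recomputed as ethanol minus
#' regular — the sign convention assumed throughout the package.
#'
#' @param path TSV/CSV file (separator sniffed from the extension and header).
#' @return named list of `line_summary` data.frames, one per detected trait.
#' @export
read_line_means <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  lc <- tolower(names(df))
  line_col <- which(lc %in% c("line", "line_id", "dgrp", "dgrp_line", "ral_id",
                              "id"))[1]
  if (is.na(line_col)) line_col <- 1L
  trait_of <- function(nm) {
    if (grepl("viab|surv", nm)) "viability"
    else if (grepl("devel|dev_|devtime|eclos|\\bdt\\b|^dt|_dt", nm)) "development_time"
    else NA_character_
  }
  cond_of <- function(nm) {
    if (grepl("regular|standard|control|ctrl", nm)) "regular"
    else if (grepl("ethanol|etoh|treated", nm)) "ethanol"
    else if (grepl("sens|diff", nm)) "sensitivity"
    else NA_character_
  }
  traits <- list()
  for (j in setdiff(seq_along(df), line_col)) {
    tr <- trait_of(lc[j]); cd <- cond_of(lc[j])
    if (is.na(tr) || is.na(cd)) next
    traits[[tr]][[cd]] <- suppressWarnings(as.numeric(df[[j]]))
  }
  if (length(traits) == 0L) stop("no recognizable trait/condition columns in ", path)
  out <- lapply(names(traits), function(tr) {
    cols <- traits[[tr]]
    m_reg <- cols$regular %||% rep(NA_real_, nrow(df))
    m_eth <- cols$ethanol %||% rep(NA_real_, nrow(df))
    sens <- cols$sensitivity %||% (m_eth - m_reg)
    included <- is.finite(m_reg) & is.finite(m_eth) | is.finite(sens)
    res <- data.frame(line = as.character(df[[line_col]]),
                      mean_regular = m_reg, mean_ethanol = m_eth,
                      n_regular = NA_integer_, n_ethanol = NA_integer_,
                      sensitivity = sens, abs_sensitivity = abs(sens),
                      included = included,
                      exclusion_reason = ifelse(included, NA_character_,
                                                "missing trait value"),
                      stringsAsFactors = FALSE)
    attr(res, "phenotype") <- tr
    attr(res, "treatments") <- c("regular", "ethanol")
    class(res) <- c("line_summary", "data.frame")
    res
  })
  names(out) <- names(traits)
  out
}

#' Summary statistics of a two-trait line-means panel
#'
#' Recomputes the headline descriptive statistics of a viability /
#' development-time screen from its line means: per-condition means, mean
#' (and mean absolute) sensitivity, the sensitivity range, and the three
#' cross-condition Pearson correlations (each trait across conditions, and
#' the two traits' sensitivities against each other).
#'
#' @param viability,devtime `line_summary` tables (from [line_summaries()]
#'   or [read_line_means()]).
#' @return a list of class `line_means_summary` with elements
#'   `viability` / `devtime` (each: `mean_regular`, `mean_ethanol`,
#'   `mean_sensitivity`, `mean_abs_sensitivity`, `min_sensitivity`,
#'   `max_sensitivity`, `n`), `cor_viability`, `cor_devtime`,
#'   `cor_sensitivity` (each a `correlation_record`).
#' @export
summarize_line_means <- function(viability, devtime) {
  one <- function(s) {
    ok <- s$included & is.finite(s$sensitivity)
    list(mean_regular = mean(s$mean_regular[s$included], na.rm = TRUE),
         mean_ethanol = mean(s$mean_ethanol[s$included], na.rm = TRUE),
         mean_sensitivity = mean(s$sensitivity[ok]),
         mean_abs_sensitivity = mean(s$abs_sensitivity[ok]),
         min_sensitivity = min(s$sensitivity[ok]),
         max_sensitivity = max(s$sensitivity[ok]),
         n = sum(ok))
  }
  structure(list(
    viability = one(viability),
    devtime = one(devtime),
    cor_viability = cross_condition_correlation(
      viability, viability, fields = c("mean_ethanol", "mean_regular")),
    cor_devtime = cross_condition_correlation(
      devtime, devtime, fields = c("mean_ethanol", "mean_regular")),
    cor_sensitivity = cross_condition_correlation(
      viability, devtime, fields = c("sensitivity", "sensitivity"))),
    class = "line_means_summary")
}

#' Write / read a line-summary table as TSV
#'
#' @param summary a `line_summary` data.frame.
#' @param path file path.
#' @export
write_line_summaries <- function(summary, path) {
  utils::write.table(as.data.frame(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
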