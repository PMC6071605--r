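#' Derive viability from egg and adult counts
#'
#' Viability per replicate vial is the fraction of surviving adults out of
#' the eggs placed in the vial (typically 50).
#'
#' @param raw_counts data.frame with columns `line`, `treatment`,
#'   `replicate`, `n_adults`, `n_eggs` (and optionally `sex`).
#' @return a [replicate_table()] with phenotype `"viability"` on the
#'   proportion scale.
#' @export
derive_viability <- function(raw_counts) {
  stopifnot(is.data.frame(raw_counts),
            all(c("line", "treatment", "replicate", "n_adults", "n_eggs")
                %in% names(raw_counts)))
  if (any(raw_counts$n_eggs <= 0)) stop("n_eggs must be positive")
  if (any(raw_counts$n_adults < 0) ||
      any(raw_counts$n_adults > raw_counts$n_eggs)) {
    stop("data error: n_adults must lie in [0, n_eggs]")
  }
  df <- raw_counts[, intersect(c("line", "treatment", "sex", "replicate"),
                               names(raw_counts))]
  df$value <- raw_counts$n_adults / raw_counts$n_eggs
  replicate_table(df, phenotype = "viability", units = "proportion")
}

#' Derive development time (mean eclosion day) from daily eclosion counts
#'
#' The replicate value is the count-weighted mean eclosion day across all
#' flies in the vial, i.e. `sum(day * n_eclosed) / sum(n_eclosed)`.
#' Replicates in which no fly eclosed are dropped with a message and listed
#' in the `dropped` attribute.
#'
#' @param eclosion_counts data.frame with columns `line`, `treatment`,
#'   `replicate`, `day`, `n_eclosed` (and optionally `sex`).
#' @return a [replicate_table()] with phenotype `"development_time"` in days.
#' @export
derive_development_time <- function(eclosion_counts) {
  stopifnot(is.data.frame(eclosion_counts),
            all(c("line", "treatment", "replicate", "day", "n_eclosed")
                %in% names(eclosion_counts)))
  if (any(eclosion_counts$n_eclosed < 0)) stop("negative eclosion counts")
  key_cols <- intersect(c("line", "treatment", "sex", "replicate"),
                        names(eclosion_counts))
  key <- interaction(eclosion_counts[key_cols], drop = TRUE, lex.order = TRUE)
  total <- tapply(eclosion_counts$n_eclosed, key, sum)
  weighted <- tapply(eclosion_counts$day * eclosion_counts$n_eclosed, key, sum)
  first <- !duplicated(key)
  df <- eclosion_counts[first, key_cols, drop = FALSE]
  df$value <- as.numeric(weighted[as.character(key[first])] /
                           total[as.character(key[first])])
  dropped <- df[!is.finite(df$value), key_cols, drop = FALSE]
  if (nrow(dropped) > 0L) {
    message(nrow(dropped), " replicate(s) dropped: zero flies eclosed")
  }
  out <- replicate_table(df[is.finite(df$value), , drop = FALSE],
                         phenotype = "development_time", units = "days")
  attr(out, "dropped") <- dropped
  out
}

#' Partition phenotypic variance and compute broad-sense heritability
#'
#' Fits the mixed ANOVA model for a two-condition inbred-panel design with
#' treatment (and, in the sexed models, sex) as fixed effects and line plus
#' all line interactions as independent random effects:
#'
#' * `full`: Y = mu + T + L + LxT + e, with
#'   H2 = (s2_L + s2_LT) / (s2_L + s2_LT + s2_e);
#' * `reduced`: Y = mu + L + e within one condition,
#'   H2 = s2_L / (s2_L + s2_e);
#' * `sexed_full`: Y = mu + T + S + TxS + L + LxS + LxT + LxTxS + e, with
#'   H2 = (s2_L + s2_LT + s2_LS + s2_LTS) / (that sum + s2_e);
#' * `sexed_reduced`: Y = mu + S + L + LxS + e within one condition.
#'
#' Estimation is by REML (`lme4::lmer`); for exactly balanced designs a
#' closed-form expected-mean-squares solution is available via
#' [ems_variance_components()] (`method = "ems"`), which on balanced data
#' coincides with REML whenever all estimates are interior. Negative EMS
#' solutions are truncated to zero before heritability is formed. Per-term
#' p-values come from the balanced ANOVA F tests (line tested over the
#' line-by-treatment mean square, interactions over the residual).
#'
#' @param table a [replicate_table()]; at least 2 replicates per design cell.
#' @param model one of `"full"`, `"reduced"`, `"sexed_full"`,
#'   `"sexed_reduced"`.
#' @param condition for the reduced models, which treatment level to fit.
#' @param method `"reml"` (default) or `"ems"` (balanced designs only).
#' @return a list of class `variance_decomposition`: `model`, `method`,
#'   `sigma2` (named vector incl. `eps`), `sigma2_G`, `sigma2_P`, `H2`,
#'   `p_values`, `n_lines`, `n_obs`.
#' @export
fit_variance_components <- function(table,
                                    model = c("full", "reduced",
                                              "sexed_full", "sexed_reduced"),
                                    condition = NULL,
                                    method = c("reml", "ems")) {
  stopifnot(inherits(table, "replicate_table"))
  model <- match.arg(model)
  method <- match.arg(method)
  sexed <- startsWith(model, "sexed")
  if (sexed && !has_sex(table)) {
    stop("schema error: sexed model requires a sex column with F/M values")
  }
  if (model %in% c("reduced", "sexed_reduced")) {
    if (is.null(condition)) {
      stop("reduced models fit one condition; supply `condition`")
    }
    if (!condition %in% table$treatment) {
      stop("condition not present in table: ", condition)
    }
    table <- table[table$treatment == condition, , drop = FALSE]
  }
  check_replication(table, sexed)

  df <- data.frame(value = table$value,
                   line = factor(table$line),
                   treatment = factor(table$treatment))
  if (sexed) df$sex <- factor(table$sex)

  terms <- switch(model,
                  full = c("L", "LT"),
                  reduced = "L",
                  sexed_full = c("L", "LT", "LS", "LTS"),
                  sexed_reduced = c("L", "LS"))

  if (method == "ems") {
    sig <- ems_variance_components(table, model = model, condition = condition)
    sigma2 <- sig$sigma2
    p_values <- sig$p_values
  } else {
    formula <- switch(model,
      full = value ~ treatment + (1 | line) + (1 | line:treatment),
      reduced = value ~ (1 | line),
      sexed_full = value ~ treatment * sex + (1 | line) + (1 | line:treatment) +
        (1 | line:sex) + (1 | line:treatment:sex),
      sexed_reduced = value ~ sex + (1 | line) + (1 | line:sex))
    fit <- suppressMessages(suppressWarnings(
      lme4::lmer(formula, data = df, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore",
                                             calc.derivs = FALSE))))
    vc <- as.data.frame(lme4::VarCorr(fit))
    lookup <- c(L = "line", LT = "line:treatment", LS = "line:sex",
                LTS = "line:treatment:sex")
    sigma2 <- vapply(terms, function(tm) {
      vc$vcov[vc$grp == lookup[[tm]]]
    }, numeric(1))
    sigma2 <- c(sigma2, eps = vc$vcov[vc$grp == "Residual"])
    p_values <- tryCatch(
      ems_variance_components(table, model = model,
                              condition = condition)$p_values,
      error = function(e) stats::setNames(rep(NA_real_, length(terms)), terms))
  }

  sigma2 <- pmax(sigma2, 0)  # truncate before H2
  sigma2_G <- sum(sigma2[terms])
  sigma2_P <- sigma2_G + sigma2[["eps"]]
  H2 <- if (sigma2_P > 0) sigma2_G / sigma2_P else 0
  structure(list(model = model, condition = condition, method = method,
                 sigma2 = sigma2, sigma2_G = sigma2_G, sigma2_P = sigma2_P,
                 H2 = H2, p_values = p_values,
                 n_lines = nlevels(df$line), n_obs = nrow(df),
                 phenotype = attr(table, "phenotype")),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("variance decomposition (%s, %s%s): H2 = %.3f\n",
              x$model, x$method,
              if (is.null(x$condition)) "" else paste0(", ", x$condition),
              x$H2))
  print(round(x$sigma2, 6))
  invisible(x)
}

check_replication <- function(table, sexed) {
  cell_cols <- c("line", "treatment", if (sexed) "sex")
  cells <- table(interaction(lapply(cell_cols, function(cl) table[[cl]]),
                             drop = TRUE))
  if (any(cells < 2L)) {
    stop("insufficient replication: every design cell needs >= 2 replicates")
  }
  invisible(TRUE)
}

#' Closed-form variance components for exactly balanced designs
#'
#' Solves the expected-mean-squares equations of the balanced mixed ANOVA
#' (unrestricted-model convention). For the two-factor design with l lines,
#' t treatments and r replicates:
#' `E[MS_L] = s2_e + r*s2_LT + t*r*s2_L`, `E[MS_LT] = s2_e + r*s2_LT`,
#' `E[MS_E] = s2_e`; the sexed design adds the analogous L x S and
#' L x T x S rows. Serves as the independent oracle for the REML fit.
#'
#' @inheritParams fit_variance_components
#' @return list with `sigma2` (untruncated solutions), `p_values` (ANOVA F
#'   tests; random terms tested over the appropriate interaction mean
#'   square) and `mean_squares`.
#' @export
ems_variance_components <- function(table,
                                    model = c("full", "reduced",
                                              "sexed_full", "sexed_reduced"),
                                    condition = NULL) {
  stopifnot(inherits(table, "replicate_table"))
  model <- match.arg(model)
  sexed <- startsWith(model, "sexed")
  if (model %in% c("reduced", "sexed_reduced")) {
    stopifnot(!is.null(condition))
    table <- table[table$treatment == condition, , drop = FALSE]
  }
  df <- data.frame(value = table$value, line = factor(table$line),
                   treatment = factor(table$treatment))
  if (sexed) df$sex <- factor(table$sex)
  cell_cols <- c("line", if (model %in% c("full", "sexed_full")) "treatment",
                 if (sexed) "sex")
  counts <- table(interaction(df[cell_cols], drop = FALSE))
  if (length(unique(as.integer(counts))) != 1L) {
    stop("expected-mean-squares solution requires an exactly balanced design")
  }
  r <- as.integer(counts[1L])
  l <- nlevels(df$line)
  t_lev <- if ("treatment" %in% cell_cols) 2L else 1L
  s_lev <- if (sexed) 2L else 1L

  aov_formula <- switch(model,
    full = value ~ treatment + line + treatment:line,
    reduced = value ~ line,
    sexed_full = value ~ treatment * sex * line,
    sexed_reduced = value ~ sex + line + sex:line)
  ms <- summary(stats::aov(aov_formula, data = df))[[1L]]
  term <- trimws(rownames(ms))
  get_ms <- function(nm) ms[match(nm, term), "Mean Sq"]
  get_df <- function(nm) ms[match(nm, term), "Df"]
  mse <- get_ms("Residuals")
  df_e <- get_df("Residuals")
  f_p <- function(num_ms, den_ms, num_df, den_df) {
    stats::pf(num_ms / den_ms, num_df, den_df, lower.tail = FALSE)
  }

  if (model == "reduced") {
    ms_l <- get_ms("line")
    sigma2 <- c(L = (ms_l - mse) / r, eps = mse)
    p_values <- c(L = f_p(ms_l, mse, get_df("line"), df_e))
  } else if (model == "full") {
    ms_l <- get_ms("line"); ms_lt <- get_ms("treatment:line")
    sigma2 <- c(L = (ms_l - ms_lt) / (t_lev * r),
                LT = (ms_lt - mse) / r, eps = mse)
    p_values <- c(L = f_p(ms_l, ms_lt, get_df("line"), get_df("treatment:line")),
                  LT = f_p(ms_lt, mse, get_df("treatment:line"), df_e))
  } else if (model == "sexed_reduced") {
    ms_l <- get_ms("line"); ms_ls <- get_ms("sex:line")
    sigma2 <- c(L = (ms_l - ms_ls) / (s_lev * r),
                LS = (ms_ls - mse) / r, eps = mse)
    p_values <- c(L = f_p(ms_l, ms_ls, get_df("line"), get_df("sex:line")),
                  LS = f_p(ms_ls, mse, get_df("sex:line"), df_e))
  } else {
    ms_l <- get_ms("line"); ms_lt <- get_ms("treatment:line")
    ms_ls <- get_ms("sex:line"); ms_lts <- get_ms("treatment:sex:line")
    sigma2 <- c(
      L = (ms_l - ms_lt - ms_ls + ms_lts) / (t_lev * s_lev * r),
      LT = (ms_lt - ms_lts) / (s_lev * r),
      LS = (ms_ls - ms_lts) / (t_lev * r),
      LTS = (ms_lts - mse) / r,
      eps = mse)
    # conservative quasi-F for line: test over LT + LS - LTS is non-standard;
    # report line over LT (the dominant interaction) and each interaction
    # over the next narrower mean square.
    p_values <- c(
      L = f_p(ms_l, ms_lt, get_df("line"), get_df("treatment:line")),
      LT = f_p(ms_lt, ms_lts, get_df("treatment:line"),
               get_df("treatment:sex:line")),
      LS = f_p(ms_ls, ms_lts, get_df("sex:line"),
               get_df("treatment:sex:line")),
      LTS = f_p(ms_lts, mse, get_df("treatment:sex:line"), df_e))
  }
  list(sigma2 = sigma2, p_values = p_values, mean_squares = ms)
}

#' Per-line condition means and ethanol sensitivity
#'
#' Averages replicates (and sexes, if present) within line x condition and
#' derives sensitivity as the difference between the two conditions
#' (second treatment minus first; with default labels, ethanol minus
#' regular). Lines lacking data in either condition are flagged excluded
#' with a reason and get `NA` sensitivity.
#'
#' @param table a [replicate_table()] containing both treatments.
#' @param treatments order of the two condition labels; sensitivity is
#'   `mean(treatments[2]) - mean(treatments[1])`. Defaults to the order of
#'   appearance in the table.
#' @return a data.frame of class `line_summary`: `line`, `mean_<t1>`,
#'   `mean_<t2>`, `n_<t1>`, `n_<t2>`, `sensitivity`, `abs_sensitivity`,
#'   `included`, `exclusion_reason`.
#' @export
line_summaries <- function(table, treatments = NULL) {
  stopifnot(inherits(table, "replicate_table"))
  if (is.null(treatments)) treatments <- unique(table$treatment)
  if (length(treatments) != 2L || !all(treatments %in% table$treatment)) {
    stop("table must contain the two requested treatments")
  }
  lines <- sort(unique(table$line))
  cell_mean <- function(tr) {
    m <- tapply(table$value[table$treatment == tr],
                table$line[table$treatment == tr], mean)
    m[lines]
  }
  cell_n <- function(tr) {
    n <- tapply(table$value[table$treatment == tr],
                table$line[table$treatment == tr], length)
    n <- n[lines]
    n[is.na(n)] <- 0L
    as.integer(n)
  }
  m1 <- cell_mean(treatments[1L]); m2 <- cell_mean(treatments[2L])
  n1 <- cell_n(treatments[1L]); n2 <- cell_n(treatments[2L])
  included <- !is.na(m1) & !is.na(m2)
  reason <- rep(NA_character_, length(lines))
  reason[is.na(m1)] <- paste0("no data in ", treatments[1L])
  reason[is.na(m2)] <- paste0("no data in ", treatments[2L])
  sens <- ifelse(included, m2 - m1, NA_real_)
  out <- data.frame(line = lines, m1 = unname(m1), m2 = unname(m2),
                    n1 = n1, n2 = n2,
                    sensitivity = unname(sens),
                    abs_sensitivity = abs(unname(sens)),
                    included = included, exclusion_reason = reason,
                    stringsAsFactors = FALSE)
  names(out)[2:5] <- c(paste0("mean_", treatments), paste0("n_", treatments))
  attr(out, "phenotype") <- attr(table, "phenotype")
  attr(out, "treatments") <- treatments
  class(out) <- c("line_summary", "data.frame")
  out
}

#' Pearson correlation between two per-line quantities
#'
#' Joins two line-summary tables on line id and correlates the chosen
#' fields across lines present (and non-missing) in both.
#'
#' @param summaries_a,summaries_b [line_summaries()] results (may be the
#'   same object).
#' @param fields length-2 character: the column to take from each table,
#'   e.g. `c("sensitivity", "sensitivity")` or
#'   `c("mean_ethanol", "mean_regular")`.
#' @return list of class `correlation_record`: `r`, `p` (two-sided), `n`,
#'   `fields`.
#' @export
cross_condition_correlation <- function(summaries_a, summaries_b,
                                        fields = c("sensitivity",
                                                   "sensitivity")) {
  stopifnot(inherits(summaries_a, "data.frame"),
            inherits(summaries_b, "data.frame"), length(fields) == 2L,
            fields[1L] %in% names(summaries_a),
            fields[2L] %in% names(summaries_b))
  shared <- intersect(summaries_a$line, summaries_b$line)
  x <- summaries_a[[fields[1L]]][match(shared, summaries_a$line)]
  y <- summaries_b[[fields[2L]]][match(shared, summaries_b$line)]
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) stop("need >= 3 lines with both fields present")
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                 fields = fields),
            class = "correlation_record")
}

#' @export
print.correlation_record <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (P = %.3g, n = %d) [%s vs %s]\n",
              x$r, x$p, x$n, x$fields[1L], x$fields[2L]))
  invisible(x)
}
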