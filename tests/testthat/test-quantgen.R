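test_that("viability is the fraction of surviving adults", {
  raw <- data.frame(line = c("A", "A", "B"), treatment = "regular",
                    replicate = 1:3, n_adults = c(25, 0, 50), n_eggs = 50)
  tab <- derive_viability(raw)
  expect_equal(tab$value, c(0.5, 0.0, 1.0))
  expect_equal(attr(tab, "phenotype"), "viability")

  counts <- data.frame(line = sprintf("L%02d", 1:20), treatment = "e",
                       replicate = 1, n_adults = 0:19, n_eggs = 38)
  expect_equal(derive_viability(counts)$value, (0:19) / 38)
  raw$n_adults[1] <- 51
  expect_error(derive_viability(raw), "n_adults")
  raw$n_adults[1] <- 25; raw$n_eggs[2] <- 0
  expect_error(derive_viability(raw), "n_eggs")
})

test_that("development time is the count-weighted mean eclosion day", {
  ec <- data.frame(line = "A", treatment = "regular", replicate = 1,
                   day = c(9, 10, 11), n_eclosed = c(10, 0, 10))
  expect_equal(derive_development_time(ec)$value, 10)
  ec$n_eclosed <- c(20, 0, 0)
  expect_equal(derive_development_time(ec)$value, 9)

  # arbitrary counts equal the brute-force per-fly average
  set.seed(4)
  days <- 8:14
  counts <- rpois(length(days), 3)
  ec2 <- data.frame(line = "B", treatment = "e", replicate = 1,
                    day = days, n_eclosed = counts)
  per_fly <- rep(days, counts)
  expect_equal(derive_development_time(ec2)$value, mean(per_fly))

  # zero-eclosion replicates are dropped with a message
  ec3 <- rbind(ec2,
               data.frame(line = "B", treatment = "e", replicate = 2,
                          day = days, n_eclosed = 0))
  expect_message(out <- derive_development_time(ec3), "dropped")
  expect_equal(nrow(out), 1)
  expect_equal(nrow(attr(out, "dropped")), 1)
})

test_that("REML matches the expected-mean-squares oracle on a balanced toy", {
  # 3 lines x 2 treatments x 2 reps; residuals chosen so cell means and
  # mean squares are simple rationals
  cm <- matrix(c(10, 14, 12,
                 12, 18, 12), nrow = 3,
               dimnames = list(c("l1", "l2", "l3"), c("regular", "ethanol")))
  resid <- rep(c(-1, 1), 6)  # +-1 around every cell mean
  tab <- toy_table(cm, n_reps = 2, resid = resid)

  # independent oracle: mean squares from first principles
  y <- tab$value
  cell <- tapply(y, list(tab$line, tab$treatment), mean)
  line_m <- rowMeans(cell); trt_m <- colMeans(cell); g <- mean(y)
  ms_line <- 2 * 2 * sum((line_m - g)^2) / (3 - 1)
  inter <- sweep(sweep(cell, 1, line_m), 2, trt_m) + g
  ms_lt <- 2 * sum(inter^2) / ((3 - 1) * (2 - 1))
  ms_e <- sum((y - cell[cbind(tab$line, tab$treatment)])^2) / (12 - 6)
  s2_eps <- ms_e
  s2_lt <- (ms_lt - ms_e) / 2
  s2_l <- (ms_line - ms_lt) / 4

  ems <- fit_variance_components(tab, "full", method = "ems")
  expect_equal(unname(ems$sigma2[c("L", "LT", "eps")]),
               pmax(c(s2_l, s2_lt, s2_eps), 0), tolerance = 1e-10)

  reml <- fit_variance_components(tab, "full", method = "reml")
  expect_equal(reml$sigma2, ems$sigma2, tolerance = 1e-6)
  expect_equal(reml$H2, ems$H2, tolerance = 1e-6)
})

test_that("H2 is 1 on noise-free data and invariant under affine transforms", {
  cm <- matrix(c(1, 2, 3, 4, 1.5, 2.5, 3.5, 4.5), nrow = 4,
               dimnames = list(paste0("l", 1:4), c("regular", "ethanol")))
  tab <- toy_table(cm, n_reps = 2, resid = 0)
  expect_equal(fit_variance_components(tab, "full", method = "ems")$H2, 1)

  cfg <- sim_config(n_lines = 50, n_replicates = 3, seed = 8)
  tab2 <- simulate_phenotypes(cfg)
  base <- fit_variance_components(tab2, "full")
  shifted <- tab2
  shifted$value <- 100 + 3.7 * shifted$value
  tr <- fit_variance_components(shifted, "full")
  expect_equal(tr$H2, base$H2, tolerance = 1e-6)
  expect_equal(tr$sigma2[["L"]], 3.7^2 * base$sigma2[["L"]], tolerance = 1e-4)
})

test_that("H2 estimates are near zero when lines do not differ", {
  h2 <- vapply(1:5, function(s) {
    cfg <- sim_config(n_lines = 200, n_replicates = 5, sigma2_L = 0,
                      sigma2_LT = 0, sigma2_eps = 1, seed = s)
    fit_variance_components(simulate_phenotypes(cfg), "full")$H2
  }, numeric(1))
  expect_lte(mean(h2), 0.05)
})

test_that("reduced and sexed models are fitted with matching schemas", {
  cfg <- sim_config(n_lines = 40, n_replicates = 3, with_sex = TRUE,
                    sigma2_LS = 0.02, sigma2_LTS = 0.01, seed = 6)
  tab <- simulate_phenotypes(cfg)
  full <- fit_variance_components(tab, "sexed_full")
  expect_named(full$sigma2, c("L", "LT", "LS", "LTS", "eps"))
  expect_true(full$H2 >= 0 && full$H2 <= 1)
  red <- fit_variance_components(tab, "sexed_reduced", condition = "ethanol")
  expect_named(red$sigma2, c("L", "LS", "eps"))

  # sexed REML agrees with the balanced sexed EMS oracle
  ems <- fit_variance_components(tab, "sexed_full", method = "ems")
  expect_equal(full$sigma2, ems$sigma2, tolerance = 1e-5)

  nosex <- simulate_phenotypes(sim_config(n_lines = 10, seed = 1))
  expect_error(fit_variance_components(nosex, "sexed_full"), "schema")
  expect_error(fit_variance_components(nosex, "reduced"), "condition")
  single <- nosex[nosex$replicate == 1, ]
  class(single) <- class(nosex)
  expect_error(fit_variance_components(single, "full"),
               "insufficient replication")
})

test_that("line summaries equal hand-computed cell means and flag missing lines", {
  cm <- matrix(c(1, 2, 5, 1, 4, 5), nrow = 3,
               dimnames = list(c("a", "b", "c"), c("regular", "ethanol")))
  tab <- toy_table(cm, n_reps = 2, resid = rep(c(-0.5, 0.5), 6))
  tab_drop <- tab[!(tab$line == "c" & tab$treatment == "ethanol"), ]
  class(tab_drop) <- class(tab)
  s <- line_summaries(tab_drop, treatments = c("regular", "ethanol"))
  expect_equal(s$mean_regular, c(1, 2, 5))
  expect_equal(s$mean_ethanol[1:2], c(1, 4))
  expect_equal(s$sensitivity[1:2], c(0, 2))
  expect_equal(s$abs_sensitivity[2], 2)
  expect_false(s$included[3])
  expect_match(s$exclusion_reason[3], "no data in ethanol")
  expect_true(is.na(s$sensitivity[3]))
})

test_that("mean sensitivity tracks the configured treatment effect", {
  cfg <- sim_config(n_lines = 200, n_replicates = 5, treatment_effect = 0.6,
                    mu = 9.6, sigma2_L = 0.1, sigma2_LT = 0.05,
                    sigma2_eps = 0.2, seed = 13)
  s <- line_summaries(simulate_phenotypes(cfg))
  expect_equal(mean(s$sensitivity), 0.6, tolerance = 0.06)
})

test_that("cross-condition correlation matches the textbook Pearson formula", {
  set.seed(21)
  n <- 30
  s1 <- data.frame(line = paste0("l", 1:n), sensitivity = rnorm(n))
  s2 <- data.frame(line = paste0("l", 1:n),
                   sensitivity = 0.5 * s1$sensitivity + rnorm(n))
  rec <- cross_condition_correlation(s1, s2)
  x <- s1$sensitivity; y <- s2$sensitivity
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
  expect_equal(rec$r, r_hand, tolerance = 1e-12)
  expect_equal(rec$p, 2 * pt(abs(t_hand), n - 2, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(rec$n, n)

  self <- cross_condition_correlation(s1, s1)
  expect_equal(self$r, 1)
  expect_error(cross_condition_correlation(s1[1:2, ], s2[1:2, ]), ">= 3")
})

test_that("line-means tables are ingested and summarized", {
  set.seed(31)
  n <- 50
  df <- data.frame(
    line = sprintf("RAL_%03d", 1:n),
    viability_regular = runif(n, 0.3, 0.8),
    viability_ethanol = runif(n, 0.0, 0.5),
    devtime_standard = rnorm(n, 9.3, 0.4),
    devtime_etoh = rnorm(n, 9.9, 0.5))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  lm <- read_line_means(path)
  expect_setequal(names(lm), c("viability", "development_time"))
  expect_equal(lm$viability$mean_regular, df$viability_regular)
  expect_equal(lm$development_time$sensitivity,
               df$devtime_etoh - df$devtime_standard)

  s <- summarize_line_means(lm$viability, lm$development_time)
  expect_equal(s$viability$mean_regular, mean(df$viability_regular))
  expect_equal(s$devtime$mean_sensitivity,
               mean(df$devtime_etoh - df$devtime_standard))
  expect_equal(s$cor_devtime$r,
               cor(df$devtime_etoh, df$devtime_standard))
  expect_equal(s$cor_sensitivity$r,
               cor(df$viability_ethanol - df$viability_regular,
                   df$devtime_etoh - df$devtime_standard))
})
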