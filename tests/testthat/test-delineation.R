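test_that("paired t test handles regular and degenerate inputs", {
  x <- c(1.2, 0.8, 1.5, 1.1)
  res <- paired_t_test(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # constant nonzero difference: unbounded statistic, p collapses to zero
  res2 <- paired_t_test(x + 1, x)
  expect_equal(res2$p_value, 0)
  expect_true(is.infinite(res2$statistic))

  expect_error(paired_t_test(1:3, 1:4), "input error")
  expect_error(paired_t_test(1, 2), "input error")

  # df = n - 1 and two-tailed p from the t distribution
  withr::with_seed(2, {
    a <- rnorm(9); b <- rnorm(9)
  })
  res3 <- paired_t_test(a, b)
  expect_equal(res3$df, 8)
  expect_equal(res3$p_value, 2 * pt(abs(res3$statistic), 8, lower.tail = FALSE))
})

test_that("paired t p-values agree with the exact sign-flip enumeration", {
  signflip_p <- function(d) {
    n <- length(d)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tstat <- function(dd) mean(dd) / (sd(dd) / sqrt(length(dd)))
    t0 <- abs(tstat(d))
    mean(abs(apply(signs * rep(d, each = nrow(signs)), 1, tstat)) >= t0 - 1e-12)
  }
  withr::with_seed(21, {
    deltas <- replicate(120, {
      x <- rnorm(8); y <- rnorm(8)
      abs(paired_t_test(x, y)$p_value - signflip_p(x - y))
    })
  })
  expect_lt(mean(deltas), 0.03)
  expect_lt(max(deltas), 0.2)
})

test_that("Welch test uses Welch-Satterthwaite df and a numeric-tail oracle", {
  x <- c(1, 2, 3, 4)
  res <- welch_t_test(x, x)
  expect_equal(res$p_value, 1)

  # equal variances and equal n collapse the Welch df to 2n - 2
  withr::with_seed(4, {
    a <- rnorm(10); b <- rnorm(10)
  })
  b <- (b - mean(b)) / sd(b) * sd(a) + mean(b)  # force equal variance
  expect_equal(welch_t_test(a, b)$df, 18, tolerance = 1e-10)

  # p-value equals the numerically integrated t tail at the Welch df
  withr::with_seed(5, {
    u <- rnorm(8, sd = 1); v <- rnorm(13, sd = 3.5)
  })
  res2 <- welch_t_test(u, v)
  tail <- stats::integrate(function(z) dt(z, df = res2$df),
                           abs(res2$statistic), Inf, rel.tol = 1e-10)$value
  expect_equal(res2$p_value, 2 * tail, tolerance = 1e-6)

  expect_error(welch_t_test(1, c(2, 3)), "input error")
})

test_that("fold changes reproduce the reference mean ratios", {
  pars <- default_group_parameters()
  g <- function(prep, grp) pars[pars$preparation == prep & pars$group == grp, ]
  expect_equal(signif(fold_change(g("formalin_fixed", "tumor")$rho_b_37_mean,
                                  g("formalin_fixed", "tumor")$rho_b_25_mean), 3),
               4.42)
  expect_equal(signif(fold_change(g("formalin_fixed", "normal")$rho_b_37_mean,
                                  g("formalin_fixed", "normal")$rho_b_25_mean), 3),
               3.47)
  expect_equal(fold_change(7, 7), 1)
  expect_error(fold_change(1, 0), "invalid input")
})

test_that("Fisher combination is exchangeable, monotone, and an identity at m = 1", {
  withr::with_seed(6, {
    for (i in 1:20) {
      p <- runif(sample(2:5, 1))
      expect_equal(fisher_combined(p), fisher_combined(sample(p)),
                   tolerance = 1e-14)
      # decreasing any single input decreases the combination
      j <- sample(length(p), 1)
      p2 <- p; p2[j] <- p2[j] / 2
      expect_lt(fisher_combined(p2), fisher_combined(p))
    }
    for (p1 in runif(10)) {
      expect_equal(fisher_combined(p1), p1, tolerance = 1e-12)
    }
  })
  expect_equal(fisher_combined(c(1, 1, 1)), 1)
  expect_error(fisher_combined(c(0.5, 0)), "invalid probability")
  expect_error(fisher_combined(c(0.5, 1.2)), "invalid probability")
  expect_error(fisher_combined(numeric(0)), "invalid probability")
})

test_that("pairwise regression matches the normal-equations oracle", {
  # exact line
  x <- 1:10
  fit <- pairwise_regression(x, 3 * x - 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 3)
  expect_equal(fit$intercept, -2)

  # independently coded normal equations
  withr::with_seed(8, {
    for (i in 1:10) {
      xx <- rnorm(30); yy <- rnorm(30, sd = 2)
      fit <- pairwise_regression(xx, yy)
      sxx <- sum((xx - mean(xx))^2)
      slope <- sum((xx - mean(xx)) * (yy - mean(yy))) / sxx
      intercept <- mean(yy) - slope * mean(xx)
      resid <- yy - intercept - slope * xx
      r2 <- 1 - sum(resid^2) / sum((yy - mean(yy))^2)
      expect_equal(fit$slope, slope, tolerance = 1e-10)
      expect_equal(fit$intercept, intercept, tolerance = 1e-10)
      expect_equal(fit$r_squared, r2, tolerance = 1e-10)
    }
  })

  # independent y: R^2 near zero at large n
  withr::with_seed(9, {
    xx <- rnorm(2000); yy <- rnorm(2000)
  })
  expect_lt(pairwise_regression(xx, yy)$r_squared, 0.01)

  expect_error(pairwise_regression(rep(1, 5), rnorm(5)), "degenerate fit")
  expect_error(pairwise_regression(1:2, 1:2), "input error")
})

test_that("significance labels follow the reporting cutpoints", {
  expect_equal(significance_label(1.95e-7), "***")
  expect_equal(significance_label(0.04), "*")
  expect_equal(significance_label(0.5), "ns")
  # boundaries fall in the less significant band
  expect_equal(significance_label(c(0.001, 0.01, 0.05)), c("**", "*", "ns"))
  expect_error(significance_label(1.5), "invalid probability")
})

test_that("combination table derives every combined cell from its own singles", {
  pub <- published_single_parameter_pvalues()
  cells <- combine_pvalue_table(pub)
  expect_equal(nrow(cells), 2 * 7 * 4)
  expect_false(anyNA(cells$p_value))

  # audit: each combined cell equals the Fisher combination of the
  # single-parameter cells in the same preparation and contrast
  members <- list("rho_b+rho_s" = c("rho_b", "rho_s"),
                  "rho_b+k" = c("rho_b", "k"),
                  "rho_s+k" = c("rho_s", "k"),
                  "rho_b+rho_s+k" = c("rho_b", "rho_s", "k"))
  for (i in which(cells$parameter_set %in% names(members))) {
    m <- members[[as.character(cells$parameter_set[i])]]
    p_in <- pub$p_value[pub$preparation == cells$preparation[i] &
                          pub$contrast == cells$contrast[i] &
                          pub$parameter %in% m]
    expect_equal(cells$p_value[i], fisher_combined(p_in), tolerance = 1e-14)
  }

  # singleton rows pass through unchanged
  single <- cells[cells$parameter_set == "rho_b", ]
  for (i in seq_len(nrow(single))) {
    expect_equal(single$p_value[i],
                 pub$p_value[pub$parameter == "rho_b" &
                               pub$preparation == single$preparation[i] &
                               pub$contrast == single$contrast[i]])
  }
})

test_that("delineation table has the full contrast grid and honest gaps", {
  cfg <- study_config(seed = 4)
  out <- run_pipeline(cfg)
  delin <- out$delineation
  expect_s3_class(delin, "delineation_table")
  expect_equal(nrow(delin$cells), 56)  # 7 sets x 4 contrasts x 2 preparations
  expect_equal(sum(delin$cells$preparation == "deparaffinized"), 28)
  expect_false(anyNA(delin$cells$p_value))
  expect_equal(nrow(delin$fold_changes), 12)
  expect_equal(nrow(delin$r_squared), 6)
  expect_true(all(delin$r_squared$r_squared >= 0 &
                    delin$r_squared$r_squared <= 1))

  # combined cells equal the Fisher combination of the table's own singles
  all3 <- delin$cells[delin$cells$parameter_set == "rho_b+rho_s+k", ]
  for (i in seq_len(nrow(all3))) {
    p_in <- delin$single_parameter$p_value[
      delin$single_parameter$preparation == all3$preparation[i] &
        delin$single_parameter$contrast == all3$contrast[i]]
    expect_equal(all3$p_value[i], fisher_combined(p_in), tolerance = 1e-14)
  }

  # one group only: between-group cells are flagged, within-group computed
  tum_only <- out$profiles[out$profiles$group == "tumor", ]
  partial <- delineation_table(tum_only)
  tcells <- partial$cells
  expect_true(all(is.na(tcells$p_value[tcells$contrast == "T25_vs_N25"])))
  expect_false(anyNA(tcells$p_value[tcells$contrast == "T37_vs_T25"]))
})

test_that("tumor temperature contrasts dominate normal ones across seeds", {
  hits <- vapply(1:5, function(s) {
    out <- run_pipeline(study_config(seed = s))
    cc <- out$delineation$cells
    all3 <- cc[cc$parameter_set == "rho_b+rho_s+k", ]
    tum <- all3$p_value[all3$contrast == "T37_vs_T25"]
    nor <- all3$p_value[all3$contrast == "N37_vs_N25"]
    between <- all3$p_value[all3$contrast == "T37_vs_N37"]
    all(tum < nor) && all(tum < 0.05) && all(between < 0.05)
  }, logical(1))
  expect_gte(sum(hits), 4)  # majority of seeds
})

test_that("a null cohort rejects at close to the nominal rate", {
  # no group difference, no temperature effect; repeats made independent so
  # the repeat-level pairing assumption of the t tests holds exactly
  rates <- vapply(1:30, function(s) {
    cfg <- study_config(seed = s, preparations = "formalin_fixed",
                        group_parameters = null_group_parameters(),
                        repeat_cv = 10)
    out <- run_pipeline(cfg)
    mean(out$delineation$single_parameter$p_value < 0.05)
  }, numeric(1))
  rate <- mean(rates)  # 30 seeds x 12 single-parameter cells
  expect_gt(rate, 0.01)
  expect_lt(rate, 0.12)
})

test_that("classification calls noiseless endpoint cohorts correctly", {
  pars <- default_group_parameters()
  degen <- pars
  for (col in grep("_spread$", names(degen), value = TRUE)) degen[[col]] <- 0
  cfg <- study_config(noise_cv = 0, repeat_cv = 0,
                      group_parameters = degen)
  for (prep in c("deparaffinized", "formalin_fixed")) {
    for (grp in c("tumor", "normal")) {
      row <- degen[degen$preparation == prep & degen$group == grp, ]
      withr::with_seed(1, sim <- simulate_specimen_profiles(row, cfg))
      expect_equal(classify_sample(sim$profiles)$call, grp,
                   label = paste(prep, grp))
    }
  }
  # evidence carries folds and p-values for both resistivities
  row <- degen[degen$preparation == "formalin_fixed" & degen$group == "tumor", ]
  withr::with_seed(1, sim <- simulate_specimen_profiles(row, cfg))
  ev <- classify_sample(sim$profiles)$evidence
  expect_setequal(ev$parameter, c("rho_b", "rho_s"))
  expect_equal(signif(ev$fold[ev$parameter == "rho_b"], 3), 4.42)

  expect_error(classify_sample(sim$profiles[sim$profiles$sample_id == "S1", ]),
               "cannot classify")
})

test_that("classification separates noisy tumor and normal specimens", {
  # Monte-Carlo operating characteristics at the default threshold; the
  # published fold distributions overlap the threshold, so sensitivity is
  # moderate while specificity stays high
  cfg <- study_config()
  pars <- default_group_parameters()
  mc <- function(prep, grp, n_spec) {
    row <- pars[pars$preparation == prep & pars$group == grp, ]
    calls <- vapply(seq_len(n_spec), function(i) {
      classify_sample(simulate_specimen_profiles(row, cfg)$profiles)$call
    }, character(1))
    mean(calls == "tumor")
  }
  withr::with_seed(77, {
    sens <- mean(c(mc("deparaffinized", "tumor", 120),
                   mc("formalin_fixed", "tumor", 120)))
    fpr <- mean(c(mc("deparaffinized", "normal", 120),
                  mc("formalin_fixed", "normal", 120)))
  })
  expect_gt(sens, 0.45)
  expect_lt(fpr, 0.15)
  expect_gt(sens - fpr, 0.35)  # informative rule: sensitivity >> false-positive rate
})
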