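test_that("2x2 odds ratio matches hand computation and published table rows", {
  e <- odds_ratio_2x2(163, 420, 161, 1416)
  expect_equal(e$or, (163 * 1416) / (420 * 161), tolerance = 1e-12)
  expect_equal(round(e$or, 2), 3.41)
  expect_equal(round(e$ci_low, 2), 2.68, tolerance = 0.01)
  expect_equal(round(e$ci_high, 2), 4.35, tolerance = 0.01)
  # symmetric table
  s <- odds_ratio_2x2(5, 5, 5, 5)
  expect_equal(s$log_or, 0)
  expect_equal(s$or, 1)
  # Haldane correction on a zero cell: hand-computed corrected cells
  h <- odds_ratio_2x2(0, 10, 5, 10)
  expect_true(h$corrected)
  expect_equal(h$or, (0.5 * 10.5) / (10.5 * 5.5), tolerance = 1e-12)
  expect_error(odds_ratio_2x2(0, 0, 5, 5), "untestable")
})

test_that("odds ratio is antisymmetric on the log scale without correction", {
  set.seed(101)
  for (i in 1:25) {
    cells <- sample(1:200, 4)
    a <- odds_ratio_2x2(cells[1], cells[2], cells[3], cells[4],
                        continuity = "none")
    b <- odds_ratio_2x2(cells[3], cells[4], cells[1], cells[2],
                        continuity = "none")
    expect_equal(a$log_or, -b$log_or, tolerance = 1e-12)
    expect_equal(a$se, b$se, tolerance = 1e-12)
  }
})

test_that("fixed-effects pooling follows inverse-variance weight algebra", {
  e1 <- mbcenrich:::effect_estimate(log(2), 0.5)
  e2 <- mbcenrich:::effect_estimate(log(8), 0.5)
  pooled <- fixed_effects_pool(list(e1, e2))
  expect_equal(pooled$or, 4, tolerance = 1e-12)  # log-scale mean
  # single stratum: identity
  one <- fixed_effects_pool(list(e1))
  expect_equal(one$log_or, e1$log_or)
  expect_equal(one$se, e1$se)
  # two identical strata: same estimate, se / sqrt(2)
  twin <- fixed_effects_pool(list(e1, e1))
  expect_equal(twin$log_or, e1$log_or)
  expect_equal(twin$se, e1$se / sqrt(2), tolerance = 1e-12)
})

test_that("pooled fixed-effects estimate stays within the stratum range", {
  set.seed(17)
  for (i in 1:30) {
    k <- sample(2:6, 1)
    ests <- lapply(seq_len(k), function(j) {
      mbcenrich:::effect_estimate(rnorm(1, 0, 1), runif(1, 0.1, 0.8))
    })
    ys <- vapply(ests, `[[`, numeric(1), "log_or")
    pooled <- fixed_effects_pool(ests)$log_or
    expect_gte(pooled, min(ys) - 1e-12)
    expect_lte(pooled, max(ys) + 1e-12)
  }
})

test_that("heterogeneity Q, I2 and REML tau2 match hand and oracle values", {
  e1 <- mbcenrich:::effect_estimate(log(2), 0.5)
  e2 <- mbcenrich:::effect_estimate(log(8), 0.5)
  h <- heterogeneity(list(e1, e2))
  # hand computation: w = 4, ybar = ln4, Q = 4 * 2 * (ln2)^2
  expect_equal(h$q_stat, 8 * log(2)^2, tolerance = 1e-10)
  expect_equal(h$i2, max(0, (h$q_stat - 1) / h$q_stat) * 100,
               tolerance = 1e-10)
  expect_equal(round(h$q_stat, 3), 3.844, tolerance = 1e-3)
  expect_equal(round(h$i2, 1), 74.0, tolerance = 0.1)
  # identical strata: Q = 0, I2 = 0, tau2 = 0
  h0 <- heterogeneity(list(e1, e1, e1))
  expect_equal(h0$q_stat, 0, tolerance = 1e-12)
  expect_equal(h0$i2, 0)
  expect_equal(h0$tau2, 0)
  # fewer than two strata: convention
  h1 <- heterogeneity(list(e1))
  expect_equal(h1$het_p, 1)
  expect_equal(h1$df, 0L)
})

test_that("REML tau2 maximizes the restricted likelihood (grid/optimize oracle)", {
  set.seed(2024)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    y <- rnorm(k, 0.4, 0.7)
    v <- runif(k, 0.02, 0.3)
    t_pkg <- reml_tau2(y, v)
    # independent oracle: coarse grid + optimize refinement of the
    # restricted log-likelihood
    grid <- seq(0, 5, by = 0.01)
    ll <- vapply(grid, reml_loglik, numeric(1), y = y, v = v)
    t0 <- grid[which.max(ll)]
    opt <- stats::optimize(reml_loglik, c(max(0, t0 - 0.02), t0 + 0.02),
                           y = y, v = v, maximum = TRUE, tol = 1e-10)
    t_grid <- if (reml_loglik(0, y, v) >= opt$objective) 0 else opt$maximum
    expect_equal(t_pkg, t_grid, tolerance = 1e-4)
    # tau2 is zero when Q <= df
    expect_gte(t_pkg, 0)
  }
})

test_that("REML tau2 agrees with metafor", {
  skip_if_not_installed("metafor")
  set.seed(7)
  for (i in 1:10) {
    k <- sample(3:6, 1)
    y <- rnorm(k, 0.5, 0.6)
    v <- runif(k, 0.02, 0.3)
    mf <- metafor::rma(yi = y, vi = v, method = "REML")
    expect_equal(reml_tau2(y, v), mf$tau2, tolerance = 1e-4)
    ests <- lapply(seq_len(k), function(j) {
      mbcenrich:::effect_estimate(y[j], sqrt(v[j]))
    })
    expect_equal(random_effects_pool(ests, mf$tau2)$log_or,
                 as.numeric(mf$beta), tolerance = 1e-6)
    expect_equal(fixed_effects_pool(ests)$log_or,
                 as.numeric(metafor::rma(yi = y, vi = v, method = "FE")$beta),
                 tolerance = 1e-8)
  }
})

test_that("random-effects pooling has the right limits", {
  ests <- list(mbcenrich:::effect_estimate(log(2), 0.3),
               mbcenrich:::effect_estimate(log(8), 0.6))
  # tau2 = 0 reduces to fixed effects
  expect_equal(random_effects_pool(ests, 0)$log_or,
               fixed_effects_pool(ests)$log_or, tolerance = 1e-12)
  # tau2 -> infinity approaches the unweighted mean
  big <- random_effects_pool(ests, 1e8)$log_or
  expect_equal(big, mean(c(log(2), log(8))), tolerance = 1e-4)
})

test_that("or_meta pools strata, switches models, and flags untestable input", {
  tab <- data.frame(cohort = c("A", "B"), a = c(30, 25), b = c(70, 75),
                    c = c(10, 12), d = c(90, 88), stringsAsFactors = FALSE)
  fit <- or_meta(tab)
  expect_s3_class(fit, "or_meta")
  expect_equal(fit$k, 2L)
  expect_equal(fit$model, "fixed")
  expect_equal(coef(fit)[["log_or"]], fit$pooled$log_or)
  ci <- confint(fit)
  expect_lt(ci[1], fit$pooled$log_or)
  expect_gt(ci[2], fit$pooled$log_or)
  # single stratum: pooled equals the stratum estimate
  one <- or_meta(tab[1, ])
  crude <- odds_ratio_2x2(30, 70, 10, 90)
  expect_equal(one$pooled$log_or, crude$log_or)
  expect_equal(one$model, "fixed")
  # engineered opposing strata with small se -> random model (raw gate)
  opp <- data.frame(cohort = c("A", "B"), a = c(20, 300), b = c(480, 200),
                    c = c(100, 100), d = c(400, 400),
                    stringsAsFactors = FALSE)
  fit_opp <- or_meta(opp)
  expect_equal(fit_opp$model, "random")
  expect_gt(fit_opp$het$tau2, 0)
  # untestable: all carriers zero
  zero <- data.frame(cohort = "A", a = 0, b = 10, c = 0, d = 10)
  expect_true(or_meta(zero)$untestable)
})

test_that("meta_family applies FDR-gated switching and q >= p", {
  tabs <- list(
    homog = data.frame(cohort = c("A", "B"), a = c(30, 28), b = c(70, 72),
                       c = c(10, 11), d = c(90, 89)),
    heterog = data.frame(cohort = c("A", "B"), a = c(20, 300), b = c(480, 200),
                         c = c(100, 100), d = c(400, 400)),
    null = data.frame(cohort = c("A", "B"), a = c(10, 11), b = c(90, 89),
                      c = c(10, 10), d = c(90, 90))
  )
  fam <- meta_family(tabs)
  expect_equal(fam$feature, names(tabs))
  expect_true(all(fam$q >= fam$p - 1e-12))
  expect_true(all(fam$het_q >= fam$het_p - 1e-12))
  expect_equal(fam$model[fam$feature == "heterog"], "random")
  expect_equal(fam$model[fam$feature == "homog"], "fixed")
  expect_equal(fam$model, unname(vapply(attr(fam, "fits"), `[[`,
                                        character(1), "model")))
})
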