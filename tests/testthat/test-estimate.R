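test_that("closed-form double-reduction estimator recovers generating values", {
  # balanced counts: no double reduction
  expect_equal(est_double_reduction(tc(250, 250, 250, 250))$alpha_hat, 0)
  # exact expected counts at alpha = 0.1, r = 0.2, n = 9000
  e <- tc(3510, 765, 609, 4116)
  expect_equal(est_double_reduction(e)$alpha_hat, 0.1, tolerance = 1e-12)
  d <- est_double_reduction(e, "distal")
  expect_equal(d$beta_hat, 0.169333, tolerance = 1e-5)
  # the distal estimate is the emergent distal coefficient of the model
  expect_equal(d$beta_hat, emergent_dr(0.1, 0.2), tolerance = 1e-9)
  # negative raw estimates are truncated at zero and flagged
  tr <- est_double_reduction(tc(300, 300, 200, 200))
  expect_equal(tr$alpha_hat, 0)
  expect_true(tr$alpha_truncated)
  expect_error(est_double_reduction(tc(0, 0, 0, 0)), "empty")
})

test_that("double-reduction standard error matches the binomial oracle", {
  # pooled groups 600 vs 400, n = 1000: sqrt(16 * 0.6 * 0.4 / 1000)
  r <- est_double_reduction(tc(400, 200, 150, 250))
  expect_equal(r$alpha_se, sqrt(16 * 600 * 400 / 1000^3), tolerance = 1e-12)
  # at expected counts (r = 0) the corrected variance equals (4 - a^2)/n
  for (a in c(0, 0.05, 0.15, 0.4)) {
    n <- 5000
    cnt <- expected_tetrad_counts(a, 0, n)
    se <- est_double_reduction(cnt)$alpha_se
    expect_equal(se^2, (4 - a^2) / n, tolerance = 1e-12)
  }
})

test_that("gamete-count double-reduction estimator matches printed formulas", {
  expect_equal(est_double_reduction_gamete(
    tibble::tibble(n_carrier = 500, n_noncarrier = 500))$alpha_hat, 0)
  g <- est_double_reduction_gamete(
    tibble::tibble(n_carrier = 450, n_noncarrier = 550))
  expect_equal(g$alpha_hat, 0.2, tolerance = 1e-12)
  expect_equal(g$alpha_se, sqrt(15.6816 / 3960), tolerance = 1e-6)
  # printed variance agrees with the simpler (4 - a^2)/n form at expectation
  for (a in c(0, 0.1, 0.3)) {
    n <- 4000
    n1 <- (2 - a) / 4 * n; n2 <- (2 + a) / 4 * n
    g2 <- est_double_reduction_gamete(
      tibble::tibble(n_carrier = n1, n_noncarrier = n2))
    expect_equal(g2$alpha_se^2, (4 - a^2) / n, tolerance = 1e-12)
  }
  expect_error(est_double_reduction_gamete(
    tibble::tibble(n_carrier = 0, n_noncarrier = 0)), "empty")
})

test_that("tetrasomic profile MLE is Fisher-consistent and matches a grid oracle", {
  # all-parental counts: complete linkage
  expect_equal(fit_tetrad_mrf(500, 0, 0, 500)$r$value, 0)
  cases <- list(c(0, 0.2), c(0.1, 0.2), c(0, 0.6), c(0.15, 0.45))
  for (cs in cases) {
    cnt <- expected_tetrad_counts(cs[1], cs[2], 9000)
    fit <- fit_tetrad_mrf(cnt$n_y, cnt$n_g, cnt$n_r, cnt$n_b)
    expect_equal(fit$alpha$value, cs[1], tolerance = 1e-9)
    expect_equal(fit$r$value, cs[2], tolerance = 1e-6)
    # independent dense-grid maximization of the same likelihood
    oracle <- grid_argmax_r(unlist(cnt), fit$alpha$value)
    expect_equal(fit$r$value, oracle, tolerance = 1e-4)
  }
  # spec example counts (rounded expected counts at alpha 0, r 0.2, n 900)
  fit <- fit_tetrad_mrf(366, 84, 58, 392)
  expect_equal(fit$alpha$value, 0)
  expect_equal(fit$r$value, 0.2, tolerance = 5e-4)
})

test_that("joint maximization agrees with the two-step profile", {
  cnt <- expected_tetrad_counts(0.1, 0.3, 20000)
  prof <- fit_tetrad_mrf(cnt$n_y, cnt$n_g, cnt$n_r, cnt$n_b)
  joint <- fit_tetrad_mrf(cnt$n_y, cnt$n_g, cnt$n_r, cnt$n_b, method = "joint")
  expect_equal(joint$r$value, prof$r$value, tolerance = 1e-3)
  expect_equal(joint$alpha$value, prof$alpha$value, tolerance = 1e-3)
})

test_that("disomic estimator is the recombinant-spore fraction capped at 1/2", {
  expect_equal(fit_tetrad_mrf(500, 0, 0, 500, ploidy = "disomic")$r$value, 0)
  f <- fit_tetrad_mrf(450, 50, 50, 450, ploidy = "disomic")
  expect_equal(f$r$value, 0.1)
  expect_equal(f$r$se, sqrt(0.1 * 0.9 / 1000), tolerance = 1e-12)
  # free recombination sits at the boundary
  expect_equal(fit_tetrad_mrf(250, 250, 250, 250, ploidy = "disomic")$r$value, 0.5)
  # clipping beyond 0.5 is flagged
  over <- fit_tetrad_mrf(200, 300, 300, 200, ploidy = "disomic")
  expect_equal(over$r$value, 0.5)
  expect_true(over$r$truncated)
})

test_that("the tetrasomic model admits and recovers r above one half", {
  cnt <- expected_tetrad_counts(0.06, 0.61, 10000)
  fit <- fit_tetrad_mrf(cnt$n_y, cnt$n_g, cnt$n_r, cnt$n_b)
  expect_gt(fit$r$value, 0.5)
  expect_equal(fit$r$value, 0.61, tolerance = 1e-6)
})

test_that("estimators recover parameters from multinomial samples", {
  # mean within 3 MC SEs of truth; empirical SD within 20% of asymptotic SE
  set.seed(42)
  n <- 1000
  n_rep <- 200
  for (cs in list(c(0, 0.05), c(0.05, 0.2), c(0.15, 0.45), c(0, 0.6))) {
    a <- cs[1]; r <- cs[2]
    probs <- unlist(tetrad_class_probs(a, r)[c("f_y", "f_g", "f_r", "f_b")])
    draws <- stats::rmultinom(n_rep, n, probs)
    ests <- apply(draws, 2, function(cn) {
      f <- fit_tetrad_mrf(cn[1], cn[2], cn[3], cn[4])
      c(f$r$value, f$r$se)
    })
    mc_se <- sd(ests[1, ]) / sqrt(n_rep)
    expect_lt(abs(mean(ests[1, ]) - r), 3 * mc_se)
    expect_lt(abs(sd(ests[1, ]) / mean(ests[2, ], na.rm = TRUE) - 1), 0.2)
  }
})

test_that("five-class crossover-probability MLE matches the quadratic closed form", {
  expect_equal(est_co_probability(
    tibble::tibble(n1 = 500, n2 = 500, n3 = 0, n4 = 0, n5 = 0))$p_hat, 0)
  e1 <- est_co_probability(
    tibble::tibble(n1 = 0, n2 = 900, n3 = 0, n4 = 20, n5 = 80))
  expect_equal(e1$p_hat, 0.24, tolerance = 1e-12)
  expect_equal(e1$alpha_hat, 0)
  e2 <- est_co_probability(
    tibble::tibble(n1 = 540, n2 = 550, n3 = 60, n4 = 10, n5 = 40))
  expect_equal(e2$p_hat, 0.2, tolerance = 1e-12)
  expect_equal(e2$root, "minus")
  expect_equal(e2$alpha_hat, 0.5)
})

test_that("the quadratic root equals the numeric likelihood argmax", {
  # random count vectors drawn across the parameter space
  set.seed(7)
  for (i in 1:60) {
    a <- runif(1, 0, 0.8)
    p <- runif(1, 0.02, 0.95)
    n <- sample(200:2000, 1)
    probs <- unlist(co_class_probs(a, p)[paste0("f", 1:5)])
    cnt <- drop(stats::rmultinom(1, n, probs))
    est <- est_co_probability(
      tibble::tibble(n1 = cnt[1], n2 = cnt[2], n3 = cnt[3],
                     n4 = cnt[4], n5 = cnt[5]))$p_hat
    expect_lt(abs(est - grid_argmax_p(cnt)), 1e-4)
  }
})

test_that("crossover-probability recovery from multinomial samples is calibrated", {
  set.seed(11)
  n_rep <- 200
  probs <- unlist(co_class_probs(0.1, 0.3)[paste0("f", 1:5)])
  draws <- stats::rmultinom(n_rep, 1000, probs)
  ests <- apply(draws, 2, function(cn) {
    r <- est_co_probability(tibble::tibble(n1 = cn[1], n2 = cn[2], n3 = cn[3],
                                           n4 = cn[4], n5 = cn[5]))
    c(r$p_hat, r$p_se)
  })
  mc_se <- sd(ests[1, ]) / sqrt(n_rep)
  expect_lt(abs(mean(ests[1, ]) - 0.3), 3 * mc_se)
  expect_lt(abs(sd(ests[1, ]) / mean(ests[2, ]) - 1), 0.2)
})

test_that("expected crossover totals sum interval estimates with quadrature SE", {
  out <- expected_crossovers(
    tibble::tibble(p_hat = c(0.2, 0.24, 0), p_se = c(0.02, 0.01, 0.005)))
  expect_equal(out$co_expected, 0.44)
  expect_equal(out$co_se, sqrt(0.02^2 + 0.01^2 + 0.005^2))
  expect_equal(expected_crossovers(
    tibble::tibble(p_hat = rep(1, 5)))$co_expected, 5)
  expect_error(expected_crossovers(tibble::tibble(p_hat = numeric(0))), "empty")
  byc <- expected_crossovers(
    tibble::tibble(chromosome = c("a", "a", "b"), p_hat = c(0.1, 0.2, 0.3),
                   p_se = c(0.01, 0.01, 0.01)))
  expect_equal(byc$co_expected, c(0.3, 0.3), tolerance = 1e-12)
})

test_that("segregation-neutrality tests behave at and away from the null", {
  perfect <- test_segregation_neutrality(tc(250, 250, 250, 250), "disomic")
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)
  skew <- test_segregation_neutrality(tc(300, 300, 200, 200), "disomic")
  expect_equal(skew$statistic, 40)
  expect_equal(skew$p_value, stats::pchisq(40, 1, lower.tail = FALSE))
  # tetrasomic null is attainable at any alpha in [0, 1/6]
  cnt <- expected_tetrad_counts(0.1, 0.3, 12000)
  tt <- test_segregation_neutrality(cnt, "tetrasomic")
  expect_equal(tt$statistic, 0)
  # strong carrier excess is detected
  hot <- test_segregation_neutrality(tc(4000, 2000, 1000, 3000), "tetrasomic")
  expect_lt(hot$p_value, 1e-6)
})

test_that("map density converts recombination fractions to cM/Mb", {
  expect_equal(cm_per_mb(0.2, 0.05), 400)
  expect_equal(cm_per_mb(0, 1), 0)
  expect_equal(cm_per_mb(0.6143, 0.1), 614.3)
  expect_error(cm_per_mb(0.2, 0), "positive")
})

test_that("tidy and glance methods expose fit results", {
  fit <- fit_tetrad_mrf(3510, 765, 609, 4116)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("alpha", "beta", "r"))
  expect_equal(td$estimate[1], 0.1, tolerance = 1e-9)
  gl <- generics::glance(fit)
  expect_equal(gl$n, 9000)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
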