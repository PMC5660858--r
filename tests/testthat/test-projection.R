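test_that("project_means: in-space, orthogonal, and pseudoinverse oracle", {
  lam <- random_lambda(6, 3, seed = 2)
  cvec <- c(1.5, -0.7, 2.2)
  pr <- project_means(lam %*% cvec, lam)
  expect_equal(unname(pr$kappa), cvec, tolerance = 1e-10)
  expect_equal(max(abs(pr$nu)), 0, tolerance = 1e-10)

  Q <- qr.Q(qr(lam), complete = TRUE)[, 4:6]
  xo <- Q %*% c(1, 2, 3)
  pr2 <- project_means(xo, lam)
  expect_equal(max(abs(pr2$mu_kappa)), 0, tolerance = 1e-10)
  expect_equal(max(abs(pr2$kappa)), 0, tolerance = 1e-10)

  set.seed(9)
  xb <- rnorm(6)
  pr3 <- project_means(xb, lam)
  P_oracle <- lam %*% solve(crossprod(lam)) %*% t(lam)
  expect_equal(pr3$mu_kappa, as.numeric(P_oracle %*% xb), tolerance = 1e-12)
  expect_equal(pr3$nu, as.numeric(xb - P_oracle %*% xb), tolerance = 1e-12)

  lam_bad <- cbind(lam[, 1], lam[, 1] * 2, lam[, 3])
  expect_error(project_means(xb, lam_bad), "rank deficient")
})

test_that("decomposition identity xbar = mu_kappa + nu holds to machine precision", {
  dat <- fixture_moments(seed = 23, invariant = FALSE)
  fit <- fit_mgcfa(dat, fig_model, "metric")
  w <- wald_mean_tests(dat, fit)
  for (j in 1:2)
    expect_equal(w$mu_kappa_hat[[j]] + w$nu_hat[[j]], dat[[j]]$mean,
                 tolerance = 1e-12)
})

test_that("wald_mean_tests: zero under identical means, stated dfs, baseline invariance", {
  lam <- random_lambda(6, 3, seed = 4)
  S <- diag(6) + 0.2
  mu <- setNames(rnorm(6), paste0("v", 1:6))
  g1 <- group_moments("a", 90, mu, S)
  g2 <- group_moments("b", 110, mu, S)
  w0 <- wald_mean_tests(list(g1, g2), lam)
  expect_equal(w0$wald_common$statistic, 0, tolerance = 1e-10)
  expect_equal(w0$wald_specific$statistic, 0, tolerance = 1e-10)
  expect_equal(w0$wald_manifest$statistic, 0, tolerance = 1e-10)
  expect_identical(w0$wald_common$df, 3L)
  expect_identical(w0$wald_specific$df, 3L)
  expect_identical(w0$wald_manifest$df, 6L)

  g2b <- group_moments("b", 110, mu + rnorm(6, 0, 0.4), S * 1.2)
  wa <- wald_mean_tests(list(g1, g2b), lam)
  wb <- wald_mean_tests(list(g2b, g1), lam)
  expect_equal(wa$wald_common$statistic, wb$wald_common$statistic,
               tolerance = 1e-9)
  expect_equal(wa$wald_specific$statistic, wb$wald_specific$statistic,
               tolerance = 1e-9)

  expect_error(wald_mean_tests(list(g1), lam), "2 groups")
  expect_error(wald_mean_tests(list(g1, g2), diag(6)), "undefined")
})

test_that("kappa differences are invariant to the marker scaling of lambda", {
  dat <- fixture_moments(seed = 29)
  lam <- fit_mgcfa(dat, fig_model, "metric")$estimates$groups[[1]]$lambda
  # rescale column 2 (refit with a different marker is equivalent to a
  # column rescale of the loading space; the projection space is unchanged)
  D <- diag(c(1, 1 / lam[4, 2], 1))
  lam2 <- lam %*% D
  wa <- wald_mean_tests(dat, lam)
  wb <- wald_mean_tests(dat, lam2)
  expect_equal(wa$wald_common$statistic, wb$wald_common$statistic,
               tolerance = 1e-9)
  kd_a <- wa$kappa_hat[[2]] - wa$kappa_hat[[1]]
  kd_b <- wb$kappa_hat[[2]] - wb$kappa_hat[[1]]
  expect_equal(unname(kd_a), unname(diag(D) * kd_b), tolerance = 1e-9)
})

test_that("validity index endpoints and direct-formula oracle", {
  lam <- random_lambda(6, 3, seed = 6)
  kd <- c(0.4, -0.2, 0.1)
  expect_equal(validity_index(kd, rep(0, 6), lam), 1)
  expect_equal(validity_index(rep(0, 3), c(0.3, rep(0, 5)), lam), 0)
  expect_message(out <- validity_index(rep(0, 3), rep(0, 6), lam), "undefined")
  expect_true(is.na(out))

  set.seed(12)
  kds <- list(rnorm(3), rnorm(3))
  nds <- list(rnorm(6), rnorm(6))
  mu_d <- c(lam %*% kds[[1]], lam %*% kds[[2]])
  rho_o <- sum(mu_d^2) / (sum(mu_d^2) + sum(unlist(nds)^2))
  expect_equal(validity_index(kds, nds, lam), rho_o, tolerance = 1e-14)
})

test_that("equivalence_mean_tests delegates to the Wald T-size calculus", {
  dat <- fixture_moments(seed = 33)
  w <- wald_mean_tests(dat, fit_mgcfa(dat, fig_model, "metric"))
  et <- equivalence_mean_tests(w)
  expect_named(et, c("fit.mvmean", "fit.common", "fit.specific"))
  direct <- tsize(w$wald_common$statistic, w$wald_common$df, w$n_total, w$m,
                  stat_family = "wald_projection")
  expect_equal(et$fit.common$epsilon_t, direct$epsilon_t, tolerance = 1e-12)
  expect_identical(et$fit.common$label, direct$label)
})

test_that("Wald type-I error is near nominal with estimated loadings (small scale)", {
  # light version of the large-replication calibration in the acceptance
  # suite: estimated lambda per replicate, 60 null datasets
  hits <- 0
  for (r in 1:60) {
    dat <- simulate_groups(sim_design(model = small_model, n = c(250, 250),
                                      seed = 1000 + r), "moments")
    fm <- fit_mgcfa(dat, small_model, "metric")
    w <- wald_mean_tests(dat, fm)
    hits <- hits + (w$wald_common$pvalue < 0.05)
  }
  expect_lte(hits, 9)  # P(X > 9 | Bin(60, .05)) ~ 0.0015
})

test_that("bootstrap tests are deterministic, calibrated under the null, powered under the alternative", {
  d0 <- sim_design(model = small_model, n = c(120, 120), seed = 51)
  raw0 <- simulate_groups(d0, "raw")
  b1 <- bootstrap_mean_tests(raw0, small_model, B = 5, seed = 77)
  b2 <- bootstrap_mean_tests(raw0, small_model, B = 5, seed = 77)
  expect_identical(b1$p_common, b2$p_common)
  expect_identical(b1$p_specific, b2$p_specific)

  # null true: p-values should not be extreme
  b0 <- bootstrap_mean_tests(raw0, small_model, B = 79, seed = 3)
  expect_gt(b0$p_common, 0.01)

  # large latent-mean difference: small bootstrap p
  d1 <- make_violation(sim_design(model = small_model, n = c(200, 200),
                                  seed = 52), "latent_mean_shift", 1.0)
  raw1 <- simulate_groups(d1, "raw")
  b3 <- bootstrap_mean_tests(raw1, small_model, B = 79, seed = 4)
  expect_lt(b3$p_common, 0.05)

  expect_error(bootstrap_mean_tests(fixture_moments(), fig_model),
               "raw data")
})
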