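balanced_data <- function(y_fun, n_per_cell = 2, volumes = 5000) {
  des <- factorial_design(n_per_cell)
  n <- nrow(des)
  count_dataset(y_fun(n), rep_len(volumes, n), des$T, des$H, des$V)
}

test_that("design matrices have the nested column counts and match explicit products", {
  d <- balanced_data(function(n) rep(1L, n))
  X_main <- count_design(d, "main")
  X_two <- count_design(d, "two_way")
  X_three <- count_design(d, "three_way")
  expect_identical(ncol(X_main), 4L)
  expect_identical(ncol(X_two), 7L)
  expect_identical(ncol(X_three), 8L)
  expect_identical(qr(X_three)$rank, 8L)
  # oracle: build the two-way interaction columns as explicit products of
  # indicator columns
  h <- as.integer(d$H == "side")
  v <- as.integer(d$V == "lower")
  t_ <- as.integer(d$T == "flood")
  oracle <- cbind(1, h, v, t_, h * v, h * t_, v * t_)
  expect_identical(unname(X_two[, c("(Intercept)", "Hside", "Vlower",
                                    "Tflood", "Hside:Vlower",
                                    "Hside:Tflood", "Vlower:Tflood")]),
                   matrix(as.numeric(oracle), nrow(d)))
  expect_error(count_dataset(1, 100, "slack", "center", "upper"),
               "unknown level")
})

test_that("Poisson fits reproduce closed-form maximum likelihood estimates", {
  # intercept-only: beta0 = log(ybar / v)
  d0 <- count_dataset(c(1, 2, 3), rep(400, 3), rep("ebb", 3),
                      rep("center", 3), rep("upper", 3))
  f0 <- fit_counts(d0, "main", "poisson")
  expect_equal(unname(coef(f0)), log(2 / 400), tolerance = 1e-8)
  # one binary factor, equal volumes: coefficient = log ratio of means
  d1 <- count_dataset(c(2, 4, 6, 12, 18, 24), rep(1000, 6),
                      c(rep("ebb", 3), rep("flood", 3)),
                      rep("center", 6), rep("upper", 6))
  f1 <- fit_counts(d1, "main", "poisson")
  expect_equal(unname(coef(f1)["Tflood"]), log(18 / 4), tolerance = 1e-8)
  expect_equal(unname(fitted(f1)), rep(c(4, 18), each = 3), tolerance = 1e-6)
})

test_that("an all-zero response is flagged as divergent, not silently fit", {
  dz <- balanced_data(function(n) rep(0L, n))
  fz <- fit_counts(dz, "main", "poisson")
  expect_true("diverged" %in% fz$flags)
  expect_false(fz$converged)
})

test_that("quasi-Poisson shares the Poisson coefficients and uses the Pearson phi", {
  d <- simulate_counts("negbin", c(-7, 1, 0.3, -0.4), theta = 1.5,
                       n_per_cell = 25, volumes = 6000, seed = 301)
  fp <- fit_counts(d, "main", "poisson")
  fq <- fit_counts(d, "main", "quasipoisson")
  expect_identical(coef(fq), coef(fp))
  # oracle: explicit Pearson sum
  phi_oracle <- sum((d$y - fitted(fp))^2 / fitted(fp)) / (nrow(d) - 4)
  expect_equal(fq$phi, phi_oracle, tolerance = 1e-10)
  expect_equal(fq$se, fp$se * sqrt(fq$phi), tolerance = 1e-10)
  expect_true(is.na(fq$aic))
  expect_error(logLik(fq), "quasi-Poisson")
  expect_error(AIC(fq), "quasi-Poisson")
})

test_that("the Pearson dispersion is near 1 for equidispersed counts and is invariant to duplication", {
  d <- simulate_counts("poisson", c(-7, 0.8, 0.2, -0.3), n_per_cell = 63,
                       volumes = 6000, seed = 302)   # n = 504
  fq <- fit_counts(d, "main", "quasipoisson")
  expect_gt(fq$phi, 0.8); expect_lt(fq$phi, 1.2)
  # duplicating every row 4x changes df, not dispersion
  d4 <- count_dataset(rep(d$y, 4), rep(d$volume_m3, 4), rep(d$T, 4),
                      rep(d$H, 4), rep(d$V, 4))
  fq4 <- fit_counts(d4, "main", "quasipoisson")
  phi_oracle <- sum((d4$y - fitted(fq4))^2 / fitted(fq4)) / (nrow(d4) - 4)
  expect_equal(fq4$phi, phi_oracle, tolerance = 1e-10)
  expect_equal(fq4$phi, fq$phi, tolerance = 0.02)
})

test_that("negative binomial fits recover the generating parameters", {
  beta <- c(-7.5, 1.2, -0.5, 0.8)
  d <- simulate_counts("negbin", beta, theta = 0.2, n_per_cell = 250,
                       volumes = 6000, seed = 99)   # n = 2000
  f <- fit_counts(d, "main", "negbin")
  expect_lt(abs(f$theta - 0.2) / 0.2, 0.25)
  expect_true(all(abs(coef(f) - beta) < 3 * f$se))
  # the MLE beats the truth in likelihood (direct evaluation oracle)
  mu_truth <- d$volume_m3 * exp(drop(count_design(d, "main") %*% beta))
  ll_truth <- sum(dnbinom(d$y, size = 0.2, mu = mu_truth, log = TRUE))
  expect_gte(f$loglik, ll_truth - 1e-6)
})

test_that("Poisson-like data drives theta to the cap with a flag", {
  d <- simulate_counts("poisson", c(-7, 0.5, 0, 0), n_per_cell = 100,
                       volumes = 6000, seed = 303)
  f <- fit_counts(d, "main", "negbin")
  expect_gte(f$theta, 100)
  expect_true("theta_capped_poisson_like" %in% f$flags)
})

test_that("zero-inflated fits recover pi and theta and reduce to NB when pi = 0", {
  beta <- c(-7.5, 1.2, -0.5, 0.8)
  d <- simulate_counts("zinb", beta, theta = 0.5, pi = 0.6,
                       n_per_cell = 250, volumes = 6000, seed = 7)
  f <- fit_counts(d, "main", "zinb")
  expect_gt(f$pi, 0.5); expect_lt(f$pi, 0.7)
  expect_lt(abs(f$theta - 0.5) / 0.5, 0.30)
  expect_true(all(abs(coef(f) - beta) < 3.5 * f$se))
  # mixture likelihood at the optimum dominates a grid around the truth
  X <- count_design(d, "main")
  off <- log(d$volume_m3)
  grid_best <- -Inf
  for (g in qlogis(seq(0.4, 0.8, length.out = 20)))
    for (lt in log(seq(0.25, 1.0, length.out = 20))) {
      ll <- -fishpass:::zinb_negll(c(coef(f), lt, g), d$y, X, off)
      grid_best <- max(grid_best, ll)
    }
  expect_gte(f$loglik, grid_best - 1e-6)

  d0 <- simulate_counts("negbin", beta, theta = 0.5, n_per_cell = 250,
                        volumes = 6000, seed = 8)
  f0 <- fit_counts(d0, "main", "zinb")
  fn <- fit_counts(d0, "main", "negbin")
  expect_lt(f0$pi, 0.05)
  expect_lt(abs(f0$loglik - fn$loglik), 0.5)
  dall0 <- balanced_data(function(n) rep(0L, n))
  expect_error(fit_counts(dall0, "main", "zinb"), "all counts are zero")
})

test_that("AIC identity and likelihood nesting hold across families and formulas", {
  d <- simulate_counts("zinb", c(-7, 1.5, -0.3, 0.6), theta = 0.8,
                       pi = 0.4, n_per_cell = 12, volumes = 5500,
                       seed = 42)
  for (fam in c("poisson", "negbin", "zinb")) {
    lls <- vapply(c("main", "two_way", "three_way"), function(lv) {
      f <- fit_counts(d, lv, fam)
      expect_equal(f$aic, 2 * f$k - 2 * f$loglik, tolerance = 1e-10)
      expect_equal(AIC(f), f$aic, tolerance = 1e-10)
      f$loglik
    }, 0)
    expect_true(all(diff(lls) >= -1e-6))  # richer nesting never fits worse
  }
  # k counts all estimated parameters
  expect_identical(fit_counts(d, "main", "poisson")$k, 4L)
  expect_identical(fit_counts(d, "main", "negbin")$k, 5L)
  expect_identical(fit_counts(d, "main", "zinb")$k, 6L)
})

test_that("the NB log-likelihood converges to the Poisson one as theta grows", {
  d <- simulate_counts("poisson", c(-7, 1, 0.5, -0.5), n_per_cell = 25,
                       volumes = 6000, seed = 43)
  f <- fit_counts(d, "main", "poisson")
  mu <- f$count_mu
  ll_pois <- sum(dpois(d$y, mu, log = TRUE))
  ll_nb <- sum(dnbinom(d$y, size = 1e6, mu = mu, log = TRUE))
  expect_lt(abs(ll_nb - ll_pois), 1e-3)
})

test_that("model comparison ranks by AIC, flags near-ties and excludes quasi fits", {
  d <- simulate_counts("zinb", c(-7, 1.5, -0.3, 0.6), theta = 0.8,
                       pi = 0.5, n_per_cell = 7, volumes = 5500, seed = 44)
  fits <- list(fit_counts(d, "main", "poisson"),
               fit_counts(d, "main", "negbin"),
               fit_counts(d, "main", "zinb"),
               fit_counts(d, "main", "quasipoisson"))
  rk <- compare_models(fits)
  expect_identical(nrow(rk), 3L)
  expect_true(all(diff(rk$aic) >= 0))
  expect_identical(rk$delta_aic[1], 0)
  expect_true(rk$negligible[1])
  expect_match(attr(rk, "excluded"), "quasipoisson")
  # near-tie flagging, on the published AIC pattern for the main-effects row
  expect_true((164.5 - 162.8) <= 2)
  # mixed datasets are rejected
  d2 <- simulate_counts("poisson", c(-7, 1, 0, 0), n_per_cell = 7,
                        volumes = 5500, seed = 45)
  expect_error(compare_models(list(fits[[1]],
                                   fit_counts(d2, "main", "poisson"))),
               "same dataset")
})

test_that("the dispersion diagnostic distinguishes linear from quadratic variance", {
  d_pois <- simulate_counts("poisson", c(-6.5, 0.8, 0.4, -0.6),
                            n_per_cell = 250, volumes = 6000, seed = 46)
  f <- fit_counts(d_pois, "main", "poisson")
  dg <- dispersion_diagnostic(f)
  expect_identical(nrow(dg), nrow(d_pois))
  expect_true(all(dg$sq_resid >= 0))
  slope <- coef(lm(sq_resid ~ 0 + mu, data = dg))[[1]]
  expect_gt(slope, 0.7); expect_lt(slope, 1.3)
  # y = mu exactly gives all-zero squared residuals
  dg0 <- dispersion_diagnostic(structure(
    list(fitted = c(1, 2), y = c(1, 2)), class = "count_fit"))
  expect_true(all(dg0$sq_resid == 0))
  # NB data: positive curvature of (y-mu)^2 in mu (direct regression oracle)
  d_nb <- simulate_counts("negbin", c(-6.5, 0.8, 0.4, -0.6), theta = 0.5,
                          n_per_cell = 250, volumes = 6000, seed = 47)
  fnb <- fit_counts(d_nb, "main", "negbin")
  dgn <- dispersion_diagnostic(fnb)
  quad <- coef(lm(sq_resid ~ mu + I(mu^2), data = dgn))[["I(mu^2)"]]
  expect_gt(quad, 0)
})

test_that("Wald tests follow the normal/t reference with inclusive codes", {
  d <- simulate_counts("negbin", c(-7, 1.5, 0, 0), theta = 1,
                       n_per_cell = 50, volumes = 6000, seed = 48)
  f <- fit_counts(d, "main", "negbin")
  w <- wald_tests(f)
  expect_identical(w$term, names(coef(f)))
  # monotonicity: larger |z| gives smaller p
  ord <- order(abs(w$statistic))
  expect_true(all(diff(w$p_value[ord]) <= 1e-12))
  # analytic anchors
  expect_equal(2 * pnorm(-abs(0)), 1.0)
  expect_equal(2 * pnorm(-2.576), 0.009995, tolerance = 1e-3)
  f_fake <- f
  f_fake$coefficients[] <- c(0, 2.576, 1, 1)
  f_fake$se[] <- 1
  w2 <- wald_tests(f_fake)
  expect_equal(w2$p_value[1], 1.0)
  expect_identical(w2$code[1], "")
  expect_identical(w2$code[2], "**")   # p = 0.00995 <= 0.01, inclusive rule
})

test_that("prediction, residuals and simulation are internally consistent", {
  d <- simulate_counts("zinb", c(-7, 1.2, -0.4, 0.3), theta = 0.8, pi = 0.4,
                       n_per_cell = 50, volumes = 6000, seed = 49)
  f <- fit_counts(d, "main", "zinb")
  expect_equal(predict(f), fitted(f), tolerance = 1e-12)
  expect_equal(predict(f, type = "count") * (1 - f$pi), fitted(f),
               tolerance = 1e-12)
  p0 <- predict(f, type = "zero")
  expect_true(all(p0 > f$pi & p0 < 1))
  # average fitted zero probability tracks the empirical zero fraction
  expect_lt(abs(mean(p0) - mean(d$y == 0)), 3 * sd(d$y == 0) / sqrt(nrow(d)))
  r <- residuals(f)
  expect_equal(mean(r^2), 1, tolerance = 0.35)
  sims <- simulate(f, nsim = 3, seed = 50)
  expect_identical(dim(sims), c(nrow(d), 3L))
  expect_identical(simulate(f, nsim = 2, seed = 50),
                   simulate(f, nsim = 2, seed = 50))
  expect_error(simulate(fit_counts(d, "main", "quasipoisson")),
               "no generative model")
})
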