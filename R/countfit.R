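# Factorial count regression with a log-volume offset, implemented from
# scratch: Poisson and negative binomial by Fisher scoring (the NB
# dispersion by profile likelihood), the zero-inflated negative binomial
# by direct maximization of the mixture likelihood, and quasi-Poisson by
# Pearson moment correction of the Poisson fit. Counts, not densities, are
# the response: the offset log(volume) makes the coefficients model
# density.

#' Construct a factorial count dataset
#'
#' One row per trawl sample: the count `y`, the volume filtered (the
#' offset variable) and the three two-level design factors. Reference
#' levels are fixed to ebb / center / upper so that treatment-coded
#' coefficients are the flood, side and lower effects.
#'
#' @param y non-negative integer counts.
#' @param volume_m3 positive volumes (m^3).
#' @param T tide, `"ebb"` or `"flood"`.
#' @param H horizontal position, `"center"` or `"side"`.
#' @param V vertical stratum, `"upper"` or `"lower"`.
#' @param sample_id optional row identifiers.
#' @return data.frame of class `count_dataset`.
#' @export
count_dataset <- function(y, volume_m3, T, H, V, sample_id = NULL) {
  n <- length(y)
  stopifnot(length(volume_m3) == n, length(T) == n, length(H) == n,
            length(V) == n)
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative integers")
  if (any(volume_m3 <= 0)) stop("volumes must be positive")
  chk <- function(x, levels, what) {
    x <- as.character(x)
    bad <- which(!x %in% levels)
    if (length(bad))
      stop(what, " has unknown level(s): ",
           paste(unique(x[bad]), collapse = ", "))
    factor(x, levels = levels)
  }
  df <- data.frame(
    y = as.integer(y), volume_m3 = as.numeric(volume_m3),
    T = chk(T, c("ebb", "flood"), "T"),
    H = chk(H, c("center", "side"), "H"),
    V = chk(V, c("upper", "lower"), "V"))
  if (!is.null(sample_id)) rownames(df) <- as.character(sample_id)
  class(df) <- c("count_dataset", "data.frame")
  df
}

#' Read / write a count dataset as CSV
#'
#' Columns `y, volume_m3, T, H, V` (plus `sample_id` when rownames are
#' set); factor levels round-trip unchanged.
#'
#' @param data a [count_dataset()].
#' @param path CSV file.
#' @return for reading, a `count_dataset`; for writing, `path` invisibly.
#' @export
write_count_dataset <- function(data, path) {
  df <- as.data.frame(data)
  df <- cbind(sample_id = rownames(df), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_dataset
#' @export
read_count_dataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  count_dataset(df$y, df$volume_m3, df$T, df$H, df$V,
                sample_id = df$sample_id)
}

formula_levels <- c("main", "two_way", "three_way")

formula_of <- function(level) {
  switch(level,
         main = ~ H + V + T,
         two_way = ~ (H + V + T)^2,
         three_way = ~ H * V * T,
         stop("formula must be one of: ", paste(formula_levels, collapse = ", ")))
}

#' Design matrix for the factorial model
#'
#' Treatment (reference-level) coding with the intercept first. The three
#' nested formulas give 4 (main effects), 7 (plus all two-way
#' interactions) or 8 (full factorial) columns.
#'
#' @param data a [count_dataset()].
#' @param formula `"main"`, `"two_way"` or `"three_way"`.
#' @return numeric matrix with column names. Columns that are identically
#'   zero (a factor level not present in the data, e.g. a single-tide
#'   subset) are dropped, so degenerate designs reduce gracefully down to
#'   intercept-only.
#' @export
count_design <- function(data, formula = "main") {
  formula <- match.arg(formula, formula_levels)
  X <- model.matrix(formula_of(formula), data = data)
  keep <- colSums(abs(X)) > 0
  X[, keep, drop = FALSE]
}

## ---- family machinery -------------------------------------------------

# Fisher scoring for a log-link count model with offset. `weight_fn(mu)`
# returns the working weights (mu for Poisson, mu/(1+mu/theta) for NB2).
irls_loglink <- function(y, X, off, weight_fn, beta0 = NULL,
                         tol = 1e-10, max_iter = 200L) {
  p <- ncol(X)
  beta <- if (is.null(beta0)) {
    b <- rep(0, p)
    b[1L] <- log(max(mean(y), 1e-3)) - mean(off)
    b
  } else beta0
  diverged <- FALSE
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(off + X %*% beta)
    mu <- exp(eta)
    if (any(!is.finite(mu))) { diverged <- TRUE; break }
    w <- weight_fn(mu)
    z <- (eta - off) + (y - mu) / mu
    XtW <- t(X * w)
    fisher <- XtW %*% X
    beta_new <- tryCatch(drop(solve(fisher, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) {
      diverged <- TRUE; break
    }
    step <- max(abs(beta_new - beta))
    beta <- beta_new
    # log-link likelihood score: X' (w * (y - mu) / mu), i.e. X'(y - mu)
    # for Poisson and X'((y - mu) theta / (theta + mu)) for NB2
    mu <- exp(drop(off + X %*% beta))
    score <- drop(t(X) %*% (weight_fn(mu) * (y - mu) / mu))
    if (max(abs(score)) < 1e-8 || step < tol) { converged <- TRUE; break }
    if (max(abs(beta)) > 40) { diverged <- TRUE; break }
  }
  mu <- exp(drop(off + X %*% beta))
  fisher <- t(X * weight_fn(mu)) %*% X
  list(beta = beta, mu = mu, fisher = fisher,
       converged = converged && !diverged, diverged = diverged)
}

new_count_fit <- function(family, formula, data, X, off, beta, se, mu,
                          statistic, pvalue, stat_type, df_residual,
                          loglik = NA_real_, k = NA_integer_,
                          theta = NULL, phi = NULL, pi = NULL, gamma = NULL,
                          vcov = NULL, flags = character(0),
                          converged = TRUE, fitted = NULL) {
  aic <- if (is.finite(loglik)) 2 * k - 2 * loglik else NA_real_
  structure(list(
    family = family, formula = formula, data = data, X = X, offset = off,
    y = data$y, coefficients = setNames(drop(beta), colnames(X)),
    se = setNames(se, colnames(X)), statistic = statistic, pvalue = pvalue,
    stat_type = stat_type, df_residual = df_residual,
    count_mu = mu, fitted = if (is.null(fitted)) mu else fitted,
    loglik = loglik, k = k, aic = aic, theta = theta, phi = phi, pi = pi,
    gamma = gamma, vcov_matrix = vcov, flags = flags,
    converged = converged), class = "count_fit")
}

fit_poisson_family <- function(data, formula) {
  X <- count_design(data, formula)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  off <- log(data$volume_m3)
  y <- data$y
  fit <- irls_loglink(y, X, off, function(mu) mu)
  flags <- character(0)
  if (all(y == 0)) {
    # the MLE has beta0 -> -Inf; the score criterion is met along the
    # divergent path, so flag explicitly
    flags <- c(flags, "diverged", "all_zero_response")
    fit$converged <- FALSE
  } else if (fit$diverged || !fit$converged) {
    flags <- c(flags, "diverged")
  }
  vc <- tryCatch(solve(fit$fisher), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(pmax(diag(vc), 0))
  z <- fit$beta / se
  ll <- sum(dpois(y, fit$mu, log = TRUE))
  new_count_fit("poisson", formula, data, X, off, fit$beta, se, fit$mu,
                statistic = z, pvalue = 2 * pnorm(-abs(z)),
                stat_type = "z", df_residual = nrow(X) - ncol(X),
                loglik = ll, k = ncol(X), vcov = vc, flags = flags,
                converged = fit$converged)
}

fit_quasipoisson_family <- function(data, formula) {
  base <- fit_poisson_family(data, formula)
  n <- nrow(base$X); p <- ncol(base$X)
  if (n <= p) stop("quasi-Poisson needs n > number of parameters")
  phi <- sum((base$y - base$count_mu)^2 / base$count_mu) / (n - p)
  se <- base$se * sqrt(phi)
  tval <- coef(base) / se
  pv <- 2 * pt(-abs(tval), df = n - p)
  new_count_fit("quasipoisson", formula, data, base$X, base$offset,
                coef(base), se, base$count_mu, statistic = tval,
                pvalue = pv, stat_type = "t", df_residual = n - p,
                loglik = NA_real_, k = NA_integer_, phi = phi,
                vcov = base$vcov_matrix * phi, flags = base$flags,
                converged = base$converged)
}

nb_loglik <- function(y, mu, theta) sum(dnbinom(y, size = theta, mu = mu,
                                                log = TRUE))

THETA_MAX <- 1e6

fit_negbin_family <- function(data, formula) {
  X <- count_design(data, formula)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  off <- log(data$volume_m3)
  y <- data$y
  pois <- irls_loglink(y, X, off, function(mu) mu)
  profile_beta <- function(lgtheta) {
    th <- exp(lgtheta)
    irls_loglink(y, X, off, function(mu) mu / (1 + mu / th),
                 beta0 = pois$beta)
  }
  profile_ll <- function(lgtheta) {
    f <- profile_beta(lgtheta)
    if (f$diverged) return(-1e12)
    nb_loglik(y, f$mu, exp(lgtheta))
  }
  opt <- optimize(profile_ll, interval = c(log(1e-3), log(THETA_MAX)),
                  maximum = TRUE, tol = 1e-8)
  theta <- exp(opt$maximum)
  flags <- character(0)
  if (theta > 1e4) {
    flags <- c(flags, "theta_capped_poisson_like")
    theta <- min(theta, THETA_MAX)
  }
  fit <- profile_beta(log(theta))
  if (fit$diverged || !fit$converged) flags <- c(flags, "diverged")
  vc <- tryCatch(solve(fit$fisher), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  se <- sqrt(pmax(diag(vc), 0))
  z <- fit$beta / se
  ll <- nb_loglik(y, fit$mu, theta)
  new_count_fit("negbin", formula, data, X, off, fit$beta, se, fit$mu,
                statistic = z, pvalue = 2 * pnorm(-abs(z)),
                stat_type = "z", df_residual = nrow(X) - ncol(X),
                loglik = ll, k = ncol(X) + 1L, theta = theta, vcov = vc,
                flags = flags, converged = fit$converged)
}

# ZINB mixture log-likelihood; par = c(beta, log theta, gamma).
zinb_negll <- function(par, y, X, off) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1L])
  gam <- par[p + 2L]
  mu <- exp(drop(off + X %*% beta))
  lp0 <- dnbinom(0L, size = theta, mu = mu, log = TRUE)
  l1mp <- -log1p(exp(gam))          # log(1 - pi)
  lp <- gam + l1mp                  # log(pi)
  ll0 <- ifelse(lp > l1mp + lp0,
                lp + log1p(exp(l1mp + lp0 - lp)),
                l1mp + lp0 + log1p(exp(lp - l1mp - lp0)))
  llpos <- l1mp + dnbinom(y, size = theta, mu = mu, log = TRUE)
  ll <- sum(ifelse(y == 0L, ll0, llpos))
  if (!is.finite(ll)) 1e12 else -ll
}

numeric_grad <- function(fn, par, ..., h = 1e-6) {
  vapply(seq_along(par), function(i) {
    hp <- h * max(1, abs(par[i]))
    pp <- par; pp[i] <- pp[i] + hp
    pm <- par; pm[i] <- pm[i] - hp
    (fn(pp, ...) - fn(pm, ...)) / (2 * hp)
  }, 0)
}

fit_zinb_family <- function(data, formula) {
  X <- count_design(data, formula)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  off <- log(data$volume_m3)
  y <- data$y
  if (all(y == 0)) stop("all counts are zero: the mixture is unidentifiable")
  zero_frac <- mean(y == 0)
  flags <- character(0)
  if (!any(y == 0)) flags <- c(flags, "no_zeros_pi_degenerate")
  nb <- tryCatch(fit_negbin_family(data, formula), error = function(e) NULL)
  p <- ncol(X)
  starts <- list()
  if (!is.null(nb)) {
    nb_p0 <- mean(dnbinom(0L, size = nb$theta, mu = nb$count_mu))
    excess <- min(max(zero_frac - nb_p0, 0.02), 0.9)
    starts[[1L]] <- c(coef(nb), log(min(max(nb$theta, 1e-2), 50)),
                      qlogis(excess))
    starts[[2L]] <- c(coef(nb), log(1), qlogis(min(max(zero_frac / 2, 0.02),
                                                   0.9)))
  }
  b0 <- rep(0, p); b0[1L] <- log(max(mean(y), 1e-3)) - mean(off)
  starts[[length(starts) + 1L]] <- c(b0, 0, qlogis(0.3))
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(optim(st, zinb_negll, y = y, X = X, off = off,
                          method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-14)),
                    error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("zero-inflated fit failed from all starts")
  par <- best$par
  gnorm <- max(abs(numeric_grad(zinb_negll, par, y = y, X = X, off = off)))
  converged <- gnorm < 1e-4 * (1 + abs(best$value))
  if (!converged) flags <- c(flags, "gradient_not_small")
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1L])
  gam <- par[p + 2L]
  pi_hat <- plogis(gam)
  if (pi_hat < 1e-4) flags <- unique(c(flags, "pi_near_zero"))
  mu <- exp(drop(off + X %*% beta))
  hess <- tryCatch(optimHess(par, zinb_negll, y = y, X = X, off = off),
                   error = function(e) NULL)
  vc_full <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  if (is.null(vc_full))
    vc_full <- matrix(NA_real_, p + 2L, p + 2L)
  se <- sqrt(pmax(diag(vc_full)[seq_len(p)], 0))
  z <- beta / se
  ll <- -best$value
  fit <- new_count_fit("zinb", formula, data, X, off, beta, se, mu,
                       statistic = z, pvalue = 2 * pnorm(-abs(z)),
                       stat_type = "z",
                       df_residual = nrow(X) - (p + 2L),
                       loglik = ll, k = p + 2L, theta = theta,
                       pi = pi_hat, gamma = gam,
                       vcov = vc_full[seq_len(p), seq_len(p), drop = FALSE],
                       flags = flags, converged = converged,
                       fitted = (1 - pi_hat) * mu)
  fit$vcov_full <- vc_full
  fit
}

## ---- user-facing fitter ----------------------------------------------

#' Fit a factorial count model with a log-volume offset
#'
#' Fits the expected count `E[y] = volume * exp(x' beta)` (so the
#' coefficients model density) by maximum likelihood for the Poisson,
#' negative binomial (NB2, variance `mu (1 + mu / theta)`) and
#' zero-inflated negative binomial (degenerate-zero mixture with an
#' intercept-only logistic zero model, zero-inflation probability `pi`)
#' families, and by Pearson moment correction of the Poisson fit for the
#' quasi-Poisson (variance `phi * mu`; no likelihood, so no AIC).
#'
#' @param data a [count_dataset()].
#' @param formula nesting level: `"main"` (H+V+T), `"two_way"` (all
#'   two-way interactions) or `"three_way"` (full factorial).
#' @param family `"poisson"`, `"quasipoisson"`, `"negbin"` or `"zinb"`.
#' @return object of class `count_fit`. Key fields: `coefficients`, `se`,
#'   `pvalue`, `theta` (NB/ZINB), `phi` (quasi), `pi` (ZINB), `loglik`,
#'   `k`, `aic`, `fitted` (expected counts), `flags` (e.g. `"diverged"`,
#'   `"theta_capped_poisson_like"`).
#' @seealso [compare_models()], [wald_tests()], [dispersion_diagnostic()],
#'   [simulate_counts()]
#' @examples
#' d <- simulate_counts("negbin", beta = c(-7.5, 1.5, 0, 0), theta = 0.8,
#'                      n_per_cell = 7, seed = 42)
#' fit <- fit_counts(d, "main", "negbin")
#' summary(fit)
#' @export
fit_counts <- function(data, formula = c("main", "two_way", "three_way"),
                       family = c("poisson", "quasipoisson", "negbin",
                                  "zinb")) {
  formula <- match.arg(formula)
  family <- match.arg(family)
  stopifnot(inherits(data, "data.frame"))
  if (!inherits(data, "count_dataset"))
    data <- count_dataset(data$y, data$volume_m3, data$T, data$H, data$V)
  fit <- switch(family,
                poisson = fit_poisson_family(data, formula),
                quasipoisson = fit_quasipoisson_family(data, formula),
                negbin = fit_negbin_family(data, formula),
                zinb = fit_zinb_family(data, formula))
  fit$call <- match.call()
  fit
}

## ---- methods ----------------------------------------------------------

family_label <- function(x) {
  switch(x$family,
         poisson = "Poisson",
         quasipoisson = sprintf("quasi-Poisson (phi = %.2f)", x$phi),
         negbin = sprintf("negative binomial (theta = %.3g, 1/theta = %.3g)",
                          x$theta, 1 / x$theta),
         zinb = sprintf("zero-inflated NB (theta = %.3g, pi = %.3f)",
                        x$theta, x$pi))
}

#' @export
print.count_fit <- function(x, ...) {
  cat("Count model:", family_label(x), "\n")
  cat("Formula level:", x$formula, " (offset: log volume)\n")
  cat("Coefficients:\n")
  print(round(coef(x), 4))
  if (is.finite(x$aic)) cat(sprintf("logLik %.2f  k %d  AIC %.1f\n",
                                    x$loglik, x$k, x$aic))
  else cat("AIC not defined (no likelihood)\n")
  if (length(x$flags)) cat("Flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.count_fit <- function(object, ...) object$coefficients

#' @export
vcov.count_fit <- function(object, ...) object$vcov_matrix

#' @export
logLik.count_fit <- function(object, ...) {
  if (!is.finite(object$loglik))
    stop("no likelihood is defined for quasi-Poisson fits")
  structure(object$loglik, df = object$k, nobs = nrow(object$X),
            class = "logLik")
}

#' @export
fitted.count_fit <- function(object, ...) object$fitted

#' @export
summary.count_fit <- function(object, ...) {
  structure(list(fit = object, wald = wald_tests(object)),
            class = "summary.count_fit")
}

#' @export
print.summary.count_fit <- function(x, ...) {
  f <- x$fit
  cat("Count model:", family_label(f), "-", f$formula, "formula\n\n")
  w <- x$wald
  w$estimate <- round(w$estimate, 4)
  w$se <- round(w$se, 4)
  w$statistic <- round(w$statistic, 3)
  w$p_value <- signif(w$p_value, 3)
  print(w, row.names = FALSE)
  cat("codes: ' p<=0.10  * p<=0.05  ** p<=0.01  (", f$stat_type,
      "statistics )\n")
  if (is.finite(f$aic))
    cat(sprintf("\nlogLik %.3f on k = %d parameters; AIC %.2f\n",
                f$loglik, f$k, f$aic))
  invisible(x)
}

#' Per-coefficient Wald tests with significance codes
#'
#' Two-sided Wald tests (z statistics; t with `n - p` degrees of freedom
#' for quasi-Poisson), with codes `'`, `*`, `**` at the 0.10, 0.05 and
#' 0.01 levels. The boundary rule is inclusive: a p-value exactly at a
#' level receives that level's code.
#'
#' @param fit a [fit_counts()] object.
#' @return data.frame with `term`, `estimate`, `se`, `statistic`,
#'   `p_value`, `code`. Coefficients with zero standard error get `NA`
#'   p-values and the flag code `"(se=0)"`.
#' @export
wald_tests <- function(fit) {
  stopifnot(inherits(fit, "count_fit"))
  est <- coef(fit); se <- fit$se
  stat <- est / se
  pv <- if (fit$stat_type == "t") 2 * pt(-abs(stat), df = fit$df_residual)
        else 2 * pnorm(-abs(stat))
  bad <- !is.finite(se) | se == 0
  pv[bad] <- NA_real_
  code <- ifelse(is.na(pv), "(se=0)",
          ifelse(pv <= 0.01, "**",
          ifelse(pv <= 0.05, "*",
          ifelse(pv <= 0.10, "'", ""))))
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             statistic = unname(stat), p_value = unname(pv), code = code,
             stringsAsFactors = FALSE)
}

#' Predict expected counts (or zero probabilities) from a fit
#'
#' @param object a [fit_counts()] object.
#' @param newdata optional data.frame with `volume_m3`, `T`, `H`, `V`;
#'   defaults to the training data.
#' @param type `"response"` (expected count, zero inflation included),
#'   `"count"` (count-component mean `mu`), `"zero"` (probability of a
#'   zero count) or `"link"` (linear predictor including offset).
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.count_fit <- function(object, newdata = NULL,
                              type = c("response", "count", "zero", "link"),
                              ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X; off <- object$offset
  } else {
    if (!inherits(newdata, "count_dataset"))
      newdata <- count_dataset(
        if (is.null(newdata$y)) rep(0L, nrow(newdata)) else newdata$y,
        newdata$volume_m3, newdata$T, newdata$H, newdata$V)
    X <- count_design(newdata, object$formula)
    off <- log(newdata$volume_m3)
  }
  eta <- drop(off + X %*% coef(object))
  mu <- exp(eta)
  pi <- if (object$family == "zinb") object$pi else 0
  switch(type,
         link = eta,
         count = mu,
         response = (1 - pi) * mu,
         zero = {
           p0 <- switch(object$family,
                        poisson = dpois(0L, mu),
                        quasipoisson = dpois(0L, mu),
                        negbin = dnbinom(0L, size = object$theta, mu = mu),
                        zinb = dnbinom(0L, size = object$theta, mu = mu))
           pi + (1 - pi) * p0
         })
}

#' @export
residuals.count_fit <- function(object,
                                type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  r <- object$y - fitted(object)
  if (type == "response") return(r)
  v <- count_fit_variance(object)
  r / sqrt(v)
}

count_fit_variance <- function(object) {
  mu <- object$count_mu
  switch(object$family,
         poisson = mu,
         quasipoisson = object$phi * mu,
         negbin = mu * (1 + mu / object$theta),
         zinb = {
           pi <- object$pi
           (1 - pi) * (mu + mu^2 / object$theta) + pi * (1 - pi) * mu^2
         })
}

#' Simulate new responses from a fitted count model
#'
#' @param object a [fit_counts()] object (not quasi-Poisson, which has no
#'   generative model).
#' @param nsim number of replicate response vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated counts.
#' @export
simulate.count_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (object$family == "quasipoisson")
    stop("quasi-Poisson has no generative model to simulate from")
  mu <- object$count_mu
  n <- length(mu)
  draw <- function() switch(object$family,
    poisson = rpois(n, mu),
    negbin = rnbinom(n, size = object$theta, mu = mu),
    zinb = {
      z <- rbinom(n, 1L, object$pi)
      ifelse(z == 1L, 0L, rnbinom(n, size = object$theta, mu = mu))
    })
  run <- function() as.data.frame(setNames(
    lapply(seq_len(nsim), function(i) draw()),
    paste0("sim_", seq_len(nsim))))
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Plot the dispersion diagnostic
#'
#' Plots squared residuals `(y - mu)^2` against fitted means `mu` with the
#' Poisson reference (`Var = mu`) and the fitted family's variance
#' function; the standard graphical device for choosing between the
#' linear-variance (quasi-Poisson) and quadratic-variance (negative
#' binomial) families.
#'
#' @param x a [fit_counts()] object.
#' @param ... passed to [plot()].
#' @return the diagnostic data.frame, invisibly.
#' @export
plot.count_fit <- function(x, ...) {
  d <- dispersion_diagnostic(x)
  plot(d$mu, d$sq_resid, xlab = expression(mu),
       ylab = expression((y - mu)^2),
       main = paste("Dispersion diagnostic:", family_label(x)), ...)
  ord <- order(d$mu)
  graphics::lines(d$mu[ord], d$mu[ord], lty = 2)
  graphics::lines(d$mu[ord], count_fit_variance(x)[ord], lty = 1)
  legend("topleft", lty = c(2, 1),
         legend = c("Poisson (Var = mu)", "fitted family"), bty = "n")
  invisible(d)
}

#' Dispersion diagnostic pairs
#'
#' @param fit a [fit_counts()] object.
#' @return data.frame with one row per observation (input order):
#'   `mu` (fitted mean) and `sq_resid` (`(y - mu)^2`).
#' @export
dispersion_diagnostic <- function(fit) {
  stopifnot(inherits(fit, "count_fit"))
  mu <- fitted(fit)
  data.frame(mu = mu, sq_resid = (fit$y - mu)^2)
}

#' Rank likelihood fits by AIC
#'
#' Sorts fits (all on the same data) by AIC and flags fits within 2 units
#' of the best as a negligible difference, under the usual rule of thumb
#' that such pairs are indistinguishable and the simpler model is then
#' preferable. Quasi-Poisson fits carry no likelihood and are excluded
#' from cross-family ranking with a note.
#'
#' @param fits list of [fit_counts()] objects on the same dataset.
#' @return data.frame of class `count_fit_ranking` with columns `family`,
#'   `formula`, `k`, `loglik`, `aic`, `delta_aic`, `negligible`; excluded
#'   quasi-Poisson fits are listed in attribute `"excluded"`.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, TRUE, what = "count_fit")))
  y0 <- fits[[1L]]$y; v0 <- fits[[1L]]$data$volume_m3
  same <- vapply(fits, function(f)
    identical(f$y, y0) && identical(f$data$volume_m3, v0), TRUE)
  if (!all(same)) stop("all fits must be on the same dataset")
  is_quasi <- vapply(fits, function(f) f$family == "quasipoisson", TRUE)
  excluded <- fits[is_quasi]
  fits <- fits[!is_quasi]
  if (!length(fits))
    stop("no likelihood-based fits to rank (quasi-Poisson AIC is of use ",
         "only for comparing quasi-Poisson models with each other)")
  df <- data.frame(
    family = vapply(fits, function(f) f$family, ""),
    formula = vapply(fits, function(f) f$formula, ""),
    k = vapply(fits, function(f) f$k, 0L),
    loglik = vapply(fits, function(f) f$loglik, 0),
    aic = vapply(fits, function(f) f$aic, 0))
  df <- df[order(df$aic), , drop = FALSE]
  df$delta_aic <- df$aic - df$aic[1L]
  df$negligible <- df$delta_aic <= 2
  rownames(df) <- NULL
  attr(df, "excluded") <- vapply(excluded, function(f)
    paste0("quasipoisson/", f$formula), "")
  class(df) <- c("count_fit_ranking", "data.frame")
  df
}

#' @export
print.count_fit_ranking <- function(x, ...) {
  cat("Model ranking by AIC (smallest preferable):\n")
  print.data.frame(x, row.names = FALSE, digits = 5)
  cat("Differences of 2 units or less are negligible;",
      "prefer the simpler model.\n")
  ex <- attr(x, "excluded")
  if (length(ex) && any(nzchar(ex)))
    cat("Excluded (no likelihood, quasi-AIC comparable only within",
        "quasi-Poisson):", paste(ex, collapse = ", "), "\n")
  invisible(x)
}

#' Plain-text model comparison table
#'
#' Formats a family-by-formula grid of AICs, variance functions and
#' significant terms in the layout of a survey report table.
#'
#' @param fits list of [fit_counts()] objects on the same dataset.
#' @return character vector of lines, printed invisibly.
#' @export
format_fit_table <- function(fits) {
  fam_order <- c("poisson", "quasipoisson", "negbin", "zinb")
  fam_head <- c("Po", "Q-Po", "NB", "ZINB")
  lv_label <- c(main = "H+V+T", two_way = "H:V+H:T+V:T (with mains)",
                three_way = "H*V*T")
  lines <- character(0)
  for (lv in formula_levels) {
    sub <- Filter(function(f) f$formula == lv, fits)
    if (!length(sub)) next
    lines <- c(lines, sprintf("Formula: %s", lv_label[[lv]]))
    cells <- vapply(fam_order, function(fam) {
      f <- Filter(function(g) g$family == fam, sub)
      if (!length(f)) return("-")
      f <- f[[1L]]
      if (fam == "quasipoisson") sprintf("AIC NA (phi %.1f)", f$phi)
      else sprintf("AIC %.1f", f$aic)
    }, "")
    lines <- c(lines, paste(sprintf("%-6s %s", fam_head, cells),
                            collapse = " | "))
    var_cells <- vapply(fam_order, function(fam) {
      f <- Filter(function(g) g$family == fam, sub)
      if (!length(f)) return("-")
      f <- f[[1L]]
      switch(fam,
             poisson = "Var mu",
             quasipoisson = sprintf("Var %.1f*mu", f$phi),
             negbin = sprintf("Var mu(1+mu*%.1f)", 1 / f$theta),
             zinb = sprintf("Var mu(1+mu*%.1f), pi=%.2f", 1 / f$theta,
                            f$pi))
    }, "")
    lines <- c(lines, paste(sprintf("%-6s %s", fam_head, var_cells),
                            collapse = " | "))
    sig_cells <- vapply(fam_order, function(fam) {
      f <- Filter(function(g) g$family == fam, sub)
      if (!length(f)) return("-")
      w <- wald_tests(f[[1L]])
      sig <- w$term[!is.na(w$p_value) & w$p_value <= 0.10 &
                      w$term != "(Intercept)"]
      if (length(sig)) paste(sig, collapse = ",") else "none"
    }, "")
    lines <- c(lines, paste(sprintf("%-6s sig: %s", fam_head, sig_cells),
                            collapse = " | "), "")
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
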