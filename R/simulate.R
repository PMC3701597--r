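#' Replicated 2^3 factorial design table
#'
#' @param n_per_cell replicates per treatment combination.
#' @return data.frame with factors `T`, `H`, `V` over all eight cells.
#' @export
factorial_design <- function(n_per_cell = 7L) {
  stopifnot(n_per_cell >= 1L)
  g <- expand.grid(T = c("ebb", "flood"), H = c("center", "side"),
                   V = c("upper", "lower"), stringsAsFactors = FALSE)
  g[rep(seq_len(nrow(g)), each = n_per_cell), , drop = FALSE]
}

#' Simulate factorial count data with known truth
#'
#' Generates a [count_dataset()] from a known density model
#' `mu_i = volume_i * exp(x_i' beta)` under the Poisson, negative binomial
#' or zero-inflated negative binomial family, for parameter-recovery
#' testing of [fit_counts()].
#'
#' @param family `"poisson"`, `"negbin"` or `"zinb"`.
#' @param beta true coefficient vector matching the design columns of
#'   `formula`.
#' @param theta NB2 dispersion (required for `"negbin"` and `"zinb"`).
#' @param pi zero-inflation probability (required for `"zinb"`; `pi = 1`
#'   gives all zeros).
#' @param design data.frame of factors `T`, `H`, `V` (e.g.
#'   [factorial_design()]); alternatively give `n_per_cell`.
#' @param volumes sampled volumes (m^3), recycled over rows; the offset.
#' @param n_per_cell shortcut: replicates per cell of the full factorial.
#' @param formula design nesting level used to build `mu` from `beta`.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @return a [count_dataset()] with attribute `"truth"`.
#' @export
simulate_counts <- function(family = c("poisson", "negbin", "zinb"),
                            beta, theta = NULL, pi = NULL, design = NULL,
                            volumes = 6000, n_per_cell = NULL,
                            formula = "main", seed = 1L) {
  family <- match.arg(family)
  if (family %in% c("negbin", "zinb") &&
      (is.null(theta) || theta <= 0))
    stop("theta > 0 required for family ", family)
  if (family == "zinb" && (is.null(pi) || pi < 0 || pi > 1))
    stop("pi in [0, 1] required for zinb")
  if (is.null(design)) {
    if (is.null(n_per_cell)) stop("give either design or n_per_cell")
    design <- factorial_design(n_per_cell)
  }
  n <- nrow(design)
  volumes <- rep_len(volumes, n)
  d0 <- count_dataset(rep(0L, n), volumes, design$T, design$H, design$V)
  X <- count_design(d0, formula)
  if (length(beta) != ncol(X))
    stop("beta must have length ", ncol(X), " for formula '", formula, "'")
  mu <- volumes * exp(drop(X %*% beta))
  y <- with_seed(seed, {
    base <- switch(family,
                   poisson = rpois(n, mu),
                   negbin = rnbinom(n, size = theta, mu = mu),
                   zinb = rnbinom(n, size = theta, mu = mu))
    if (family == "zinb") {
      z <- rbinom(n, 1L, pi)
      base[z == 1L] <- 0L
    }
    base
  })
  out <- count_dataset(y, volumes, design$T, design$H, design$V)
  attr(out, "truth") <- list(family = family, beta = beta, theta = theta,
                             pi = pi, mu = mu, formula = formula,
                             seed = seed)
  out
}
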