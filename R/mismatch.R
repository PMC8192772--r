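#' Equilibrium (constant-size) mismatch expectation
#'
#' Probability that two sequences drawn from a constant-size population at
#' equilibrium differ at `d` sites: the geometric form
#' \eqn{F(d) = \theta^d / (1+\theta)^{d+1}}.
#'
#' @param d vector of difference classes (`>= 0`).
#' @param theta scaled mutation rate.
#' @return Numeric vector of probabilities.
#' @export
constant_mismatch_probs <- function(d, theta) {
  exp(d * log(theta) - (d + 1) * log1p(theta))
}

#' Sudden-expansion mismatch expectation
#'
#' Closed-form expected mismatch distribution for a population that grew
#' instantaneously from scaled size `theta0` to `theta1` at scaled time
#' `tau` (in units of 1/(2u)) before the present:
#' \deqn{F_d = \hat F_d(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
#'   \sum_{j=0}^{d} \frac{\tau^j}{j!}
#'   \left[\hat F_{d-j}(\theta_0) - \hat F_{d-j}(\theta_1)\right]}
#' where \eqn{\hat F} is [constant_mismatch_probs()]. At `tau = 0` this
#' reduces to the `theta0` equilibrium; for large `theta1` it approaches a
#' Poisson(`tau`) convolved with the `theta0` geometric (the classic
#' infinite-growth limit).
#'
#' @param d_max maximum difference class; the curve is returned for
#'   `0:d_max`.
#' @param theta0,theta1 pre- and post-expansion scaled mutation rates
#'   (`theta0 >= 0`, `theta1 > 0`).
#' @param tau scaled time since the expansion (`>= 0`).
#' @return Numeric vector of length `d_max + 1`.
#' @export
expansion_mismatch_probs <- function(d_max, theta0, theta1, tau) {
  stopifnot(d_max >= 0, theta0 >= 0, theta1 > 0, tau >= 0)
  d <- 0:d_max
  f1 <- constant_mismatch_probs(d, theta1)
  f0 <- if (theta0 > 0) constant_mismatch_probs(d, theta0)
        else c(1, rep(0, d_max))           # theta0 = 0: all pairs identical
  delta <- f0 - f1
  decay <- -tau * (theta1 + 1) / theta1
  log_tau_j <- if (tau > 0) d * log(tau) else c(0, rep(-Inf, d_max))
  w <- exp(decay + log_tau_j - lfactorial(d))   # w[j+1] = e^decay tau^j / j!
  out <- vapply(d, function(i) {
    f1[i + 1] + sum(w[1:(i + 1)] * rev(delta[1:(i + 1)]))
  }, numeric(1))
  pmax(out, 0)
}

#' Observed mismatch distribution with model expectations
#'
#' Histogram of pairwise difference counts over all unordered sequence
#' pairs, together with the constant-size expectation (at `theta = K`,
#' truncated to the observed class range and rescaled to the pair count)
#' and, optionally, the sudden-expansion expectation with `(theta0, theta1,
#' tau)` fitted by a documented deterministic grid search (least squares on
#' relative frequencies, followed by a local refinement of `tau`).
#' Harpending's raggedness index
#' \eqn{r = \sum_i (f_{i+1} - f_i)^2} is computed on the observed relative
#' frequencies (with a closing class of frequency 0 above the largest
#' observed difference).
#'
#' @param aln a [coi_alignment()] with at least 3 sequences.
#' @param fit_expansion fit the sudden-expansion model? (default `TRUE`).
#' @return Object of class `mismatch_distribution`: list with `histogram`
#'   (named counts for classes `0..d_max`), `n_pairs`, `theta` (= `K`),
#'   `expected_constant`, `expected_expansion`, `model_params`
#'   (`theta0`, `theta1`, `tau`) and `raggedness`.
#' @export
mismatch_distribution <- function(aln, fit_expansion = TRUE) {
  stopifnot(inherits(aln, "coi_alignment"))
  N <- n_sequences(aln)
  if (N < 3) stop("mismatch distribution needs at least 3 sequences")
  pd <- pairwise_differences(aln)
  d <- pd$diffs[upper.tri(pd$diffs)]
  n_pairs <- length(d)
  d_max <- max(d)
  hist <- tabulate(d + 1, nbins = d_max + 1)
  names(hist) <- 0:d_max
  theta <- mean(d)
  obs_rel <- hist / n_pairs
  if (theta > 0) {
    ec <- constant_mismatch_probs(0:d_max, theta)
    ec <- ec / sum(ec) * n_pairs
  } else {
    ec <- c(n_pairs, rep(0, d_max))
  }
  fit <- NULL
  ee <- NULL
  if (fit_expansion && d_max >= 1 && theta > 0) {
    fit <- fit_expansion_model(obs_rel, d_max)
    ee <- expansion_mismatch_probs(d_max, fit$theta0, fit$theta1, fit$tau)
    ee <- ee / sum(ee) * n_pairs
  }
  structure(list(histogram = hist, n_pairs = n_pairs, theta = theta,
                 expected_constant = ec, expected_expansion = ee,
                 model_params = fit,
                 raggedness = raggedness(obs_rel)),
            class = "mismatch_distribution")
}

# Deterministic grid search + tau refinement, least squares on relative
# frequencies. Grids are fixed and documented: tau in seq(0, d_max + 5,
# 0.5) refined to 0.05; theta0 in {0, 0.01, 0.1, 0.5, 1, 2, 5, 10};
# theta1 in {10, 100, 1000, 10000}.
fit_expansion_model <- function(obs_rel, d_max) {
  tau_grid <- seq(0, d_max + 5, by = 0.5)
  theta0_grid <- c(0, 0.01, 0.1, 0.5, 1, 2, 5, 10)
  theta1_grid <- c(10, 100, 1000, 10000)
  sse <- function(t0, t1, tau) {
    f <- expansion_mismatch_probs(d_max, t0, t1, tau)
    f <- f / sum(f)
    sum((f - obs_rel)^2)
  }
  best <- list(sse = Inf)
  for (t1 in theta1_grid) for (t0 in theta0_grid) for (tau in tau_grid) {
    s <- sse(t0, t1, tau)
    if (s < best$sse) best <- list(theta0 = t0, theta1 = t1, tau = tau, sse = s)
  }
  for (tau in seq(max(0, best$tau - 0.5), best$tau + 0.5, by = 0.05)) {
    s <- sse(best$theta0, best$theta1, tau)
    if (s < best$sse) { best$tau <- tau; best$sse <- s }
  }
  best
}

#' Harpending's raggedness index
#'
#' \eqn{r = \sum_{i=1}^{d_{max}+1} (f_i - f_{i-1})^2} over relative
#' frequencies `f_0..f_dmax` with `f_{dmax+1} = 0`. Smooth unimodal
#' (expansion-like) distributions give small values; ragged multimodal
#' (stationary-population) distributions give large values.
#'
#' @param rel_freq numeric vector of relative frequencies for classes
#'   `0, 1, 2, ...` (need not include trailing zeros).
#' @return Non-negative scalar.
#' @export
raggedness <- function(rel_freq) {
  f <- c(rel_freq, 0)
  sum(diff(f)^2)
}

#' @export
print.mismatch_distribution <- function(x, ...) {
  cat("<mismatch_distribution> ", x$n_pairs, " pairs, classes 0..",
      length(x$histogram) - 1L, ", theta = ", signif(x$theta, 4),
      ", raggedness = ", signif(x$raggedness, 4), "\n", sep = "")
  if (!is.null(x$model_params))
    cat("  expansion fit: theta0 = ", x$model_params$theta0,
        ", theta1 = ", x$model_params$theta1,
        ", tau = ", x$model_params$tau, "\n", sep = "")
  invisible(x)
}
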