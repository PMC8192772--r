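#' Per-population diversity summary
#'
#' Computes, for each population and for the pooled sample (`Total` row),
#' the standard intraspecific diversity statistics:
#' \itemize{
#'   \item `N` sequences, `N_h` haplotypes, `N_p` private haplotypes
#'     (haplotypes whose members all fall in that population);
#'   \item `h`, Nei's unbiased haplotype diversity
#'     \eqn{h = \frac{N}{N-1}(1 - \sum_i p_i^2)};
#'   \item `pi_raw`, mean over sequence pairs of (differences / compared
#'     sites), and `pi_jc`, the same after applying the Jukes-Cantor
#'     correction \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3} p)} to each
#'     pairwise proportion before averaging;
#'   \item `S`, the number of segregating sites (columns with at least two
#'     observed unambiguous states);
#'   \item `K`, the mean number of pairwise nucleotide differences;
#'   \item Tajima's `D` and Fu's `Fs` (see [tajimas_d()] and [fus_fs()]).
#' }
#' Sites at which either member of a pair carries `N` or `-` are excluded
#' from that pair's comparison. Populations with `N = 1` report `NA`
#' ("not determined") for all pair-based statistics.
#'
#' @param aln a [coi_alignment()].
#' @param pops optional named character vector sample id -> population; when
#'   omitted only the pooled row is returned.
#' @return A data.frame with one row per population plus a `Total` row.
#' @export
diversity_summary <- function(aln, pops = NULL) {
  stopifnot(inherits(aln, "coi_alignment"))
  ht_all <- collapse_haplotypes(aln, pops = pops)
  groups <- list()
  if (!is.null(pops)) {
    pops <- validate_population_map(pops, aln)
    for (p in unique(unname(pops))) groups[[p]] <- aln$ids[pops[aln$ids] == p]
  }
  groups[["Total"]] <- aln$ids
  pd <- pairwise_differences(aln)
  rows <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    sub <- subset_alignment(aln, ids)
    one_population_row(g, sub, pd, match(ids, aln$ids), ht_all, pops)
  })
  do.call(rbind, rows)
}

one_population_row <- function(label, sub, pd, idx, ht_all, pops) {
  N <- length(idx)
  ht <- collapse_haplotypes(sub)
  N_h <- n_haplotypes(ht)
  # private haplotypes: all members of the haplotype fall inside this set
  N_p <- if (label == "Total" || is.null(pops)) {
    NA_integer_
  } else {
    sum(vapply(ht_all$members, function(m) all(pops[m] == label), logical(1)) &
          vapply(ht_all$members, function(m) any(pops[m] == label), logical(1)))
  }
  if (N < 2) {
    return(data.frame(population = label, N = N, N_h = N_h, N_p = N_p,
                      h = NA_real_, pi_raw = NA_real_, pi_jc = NA_real_,
                      S = NA_integer_, K = NA_real_,
                      tajima_D = NA_real_, fu_Fs = NA_real_,
                      stringsAsFactors = FALSE))
  }
  p_i <- ht$count / N
  h <- N / (N - 1) * (1 - sum(p_i^2))
  D2 <- pd$diffs[idx, idx, drop = FALSE]
  C2 <- pd$comparable[idx, idx, drop = FALSE]
  up <- upper.tri(D2)
  d <- D2[up]
  comp <- C2[up]
  p_pair <- ifelse(comp > 0, d / comp, NA_real_)
  pi_raw <- mean(p_pair, na.rm = TRUE)
  pi_jc <- mean(jc_correct(p_pair), na.rm = TRUE)
  K <- mean(d)
  S <- count_segregating_sites(sub)
  td <- tajimas_d(sub)
  fs <- fus_fs(sub)
  data.frame(population = label, N = N, N_h = N_h, N_p = N_p, h = h,
             pi_raw = pi_raw, pi_jc = pi_jc, S = S, K = K,
             tajima_D = td$D, fu_Fs = fs$Fs, stringsAsFactors = FALSE)
}

jc_correct <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p) & p < 0.75
  out[ok] <- -0.75 * log(1 - 4 / 3 * p[ok])
  if (any(!is.na(p) & p >= 0.75))
    warning("pairwise difference proportion >= 0.75; Jukes-Cantor distance undefined")
  out
}

#' Number of segregating sites
#'
#' Columns with two or more distinct unambiguous states (`A/C/G/T`); `N`
#' and `-` are not states.
#'
#' @param aln a [coi_alignment()].
#' @return integer count.
#' @export
count_segregating_sites <- function(aln) {
  M <- aln_matrix(aln)
  sum(apply(M, 2, function(col) length(unique(col[col %in% DNA_STATES])) >= 2))
}

#' Tajima's D
#'
#' Normalized difference between the pairwise-diversity and
#' segregating-sites estimators of the scaled mutation rate:
#' \deqn{D = \frac{K - S/a_1}{\sqrt{e_1 S + e_2 S (S - 1)}}}
#' with the 1989 constants \eqn{a_1 = \sum_{i=1}^{N-1} 1/i},
#' \eqn{a_2 = \sum 1/i^2}, \eqn{b_1 = (N+1)/(3(N-1))},
#' \eqn{b_2 = 2(N^2+N+3)/(9N(N-1))}, \eqn{c_1 = b_1 - 1/a_1},
#' \eqn{c_2 = b_2 - (N+2)/(a_1 N) + a_2/a_1^2}, \eqn{e_1 = c_1/a_1},
#' \eqn{e_2 = c_2/(a_1^2 + a_2)}. Negative values indicate an excess of
#' rare variants, the signature of a recent demographic expansion.
#'
#' Requires `N >= 4` and `S >= 1`; otherwise `D` is `NA` (not determined).
#'
#' @param aln a [coi_alignment()].
#' @return List with `N`, `S`, `K`, the constants, and `D`.
#' @export
tajimas_d <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  N <- n_sequences(aln)
  S <- if (N >= 2) count_segregating_sites(aln) else 0L
  K <- if (N >= 2) {
    pd <- pairwise_differences(aln)
    mean(pd$diffs[upper.tri(pd$diffs)])
  } else NA_real_
  cst <- if (N >= 2) tajima_constants(N) else NULL
  D <- if (N >= 4 && S >= 1)
    (K - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  else NA_real_
  c(list(N = N, S = S, K = K, D = D), cst)
}

tajima_constants <- function(N) {
  i <- seq_len(N - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (N + 1) / (3 * (N - 1))
  b2 <- 2 * (N^2 + N + 3) / (9 * N * (N - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (N + 2) / (a1 * N) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

# Log unsigned Stirling numbers of the first kind, row n:
# log(|s(n, k)|) for k = 1..n, via |s(n+1,k)| = |s(n,k-1)| + n*|s(n,k)|
# evaluated in log space.
stirling1_log_row <- function(n) {
  row <- 0 # log|s(1,1)|
  if (n == 1) return(row)
  for (m in 1:(n - 1)) {
    prev <- c(-Inf, row, -Inf)           # k-1 shifted, pad
    new <- vapply(seq_len(m + 1), function(k) {
      logsumexp(c(prev[k], log(m) + prev[k + 1]))
    }, numeric(1))
    row <- new
  }
  row
}

#' Ewens sampling distribution of the number of alleles
#'
#' Probability of observing `k` distinct alleles in a sample of `n`
#' sequences under neutrality at scaled mutation rate `theta`:
#' \deqn{P(k) = \frac{|s(n,k)| \theta^k}{\theta^{(n)}}}
#' with unsigned Stirling numbers of the first kind and rising factorial
#' \eqn{\theta^{(n)} = \theta(\theta+1)\cdots(\theta+n-1)}, evaluated in
#' log space.
#'
#' @param n sample size (`>= 1`).
#' @param theta scaled mutation rate (`> 0`).
#' @return Numeric vector of length `n`; element `k` is `P(k alleles)`.
#' @export
ewens_allele_probs <- function(n, theta) {
  stopifnot(n >= 1, theta > 0)
  ls <- stirling1_log_row(n)
  log_rise <- sum(log(theta + 0:(n - 1)))
  exp(ls + seq_len(n) * log(theta) - log_rise)
}

#' Fu's Fs
#'
#' Tests for an excess of alleles relative to the neutral expectation at
#' \eqn{\hat\theta = K} (the mean number of pairwise differences). With
#' \eqn{S' = P(k \ge k_{obs})} under the Ewens distribution
#' ([ewens_allele_probs()]),
#' \deqn{F_s = \ln\frac{S'}{1 - S'}.}
#' Strongly negative values indicate many recent alleles, as expected after
#' a demographic expansion.
#'
#' Requires `N >= 2`, `K > 0` and at least two distinct haplotypes;
#' otherwise `Fs` is `NA`.
#'
#' @param aln a [coi_alignment()].
#' @return List with `N`, `k_obs`, `theta`, `S_prime` and `Fs`.
#' @export
fus_fs <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  N <- n_sequences(aln)
  k_obs <- n_haplotypes(collapse_haplotypes(aln))
  if (N < 2) return(list(N = N, k_obs = k_obs, theta = NA_real_,
                         S_prime = NA_real_, Fs = NA_real_))
  pd <- pairwise_differences(aln)
  theta <- mean(pd$diffs[upper.tri(pd$diffs)])
  if (k_obs < 2 || theta <= 0)
    return(list(N = N, k_obs = k_obs, theta = theta,
                S_prime = NA_real_, Fs = NA_real_))
  ls <- stirling1_log_row(N)
  log_rise <- sum(log(theta + 0:(N - 1)))
  logp <- ls + seq_len(N) * log(theta) - log_rise
  log_Sp <- logsumexp(logp[k_obs:N])
  log_1mSp <- if (k_obs > 1) logsumexp(logp[1:(k_obs - 1)]) else -Inf
  Fs <- log_Sp - log_1mSp
  if (!is.finite(Fs))
    warning("Fu's Fs under/overflowed to ", Fs)
  list(N = N, k_obs = k_obs, theta = theta,
       S_prime = exp(log_Sp), Fs = Fs)
}

#' Neutrality statistics (Tajima's D and Fu's Fs) in one call
#'
#' @param aln a [coi_alignment()].
#' @return List combining the results of [tajimas_d()] and [fus_fs()].
#' @export
neutrality_stats <- function(aln) {
  td <- tajimas_d(aln)
  fs <- fus_fs(aln)
  c(td, fs[c("k_obs", "theta", "S_prime", "Fs")])
}
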