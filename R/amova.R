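#' One-level AMOVA with permutation-tested Phi-ST
#'
#' Partitions molecular variance among and within populations from squared
#' inter-individual distances (here, as in Arlequin's haplotype AMOVA, the
#' squared distance between two sequences is their raw pairwise difference
#' count). Sums of squared deviations follow the classic decomposition:
#' \deqn{SSD_{total} = \frac{1}{N}\sum_{i<j} d^2_{ij}, \quad
#'       SSD_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}}
#' with \eqn{SSD_{among} = SSD_{total} - SSD_{within}}. Variance components
#' come from the mean squares with the unequal-sample-size coefficient
#' \eqn{n_0 = (N - \sum_g n_g^2/N)/(P-1)}; negative components are retained
#' (not truncated), so percentages can fall below 0 or exceed 100.
#' \eqn{\Phi_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)}.
#'
#' The p-value is the observed-inclusive proportion of permutations (random
#' reassignment of individuals to populations, sizes fixed) whose
#' \eqn{\Phi_{ST}} is at least the observed one:
#' `p = (1 + #permuted >= observed) / (n_perm + 1)`.
#'
#' At least two populations of size 2 or more are required; populations of
#' size 1 are allowed alongside (they contribute no within-group variance).
#'
#' @param x a [coi_alignment()], or a symmetric matrix of squared distances.
#' @param pops named character vector sample id -> population (or a vector
#'   of labels in row order when `x` is a matrix).
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return Object of class `amova_result`: SSDs, degrees of freedom,
#'   variance components, percentages, `phi_st`, `p_value`, `n_perm`.
#' @export
amova <- function(x, pops, n_perm = 1000, seed = NULL) {
  d2 <- amova_d2(x, pops)
  f <- d2$labels
  tab <- table(f)
  if (length(tab) < 2) stop("AMOVA needs at least 2 populations")
  if (sum(tab >= 2) < 2)
    stop("AMOVA needs at least 2 populations with >= 2 samples")
  obs <- amova_components(d2$d2, f)
  perm_phi <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      amova_components(d2$d2, sample(f))$phi_st, numeric(1))
  })
  p <- (1 + sum(perm_phi >= obs$phi_st, na.rm = TRUE)) / (n_perm + 1)
  structure(c(obs, list(p_value = p, n_perm = n_perm,
                        populations = names(tab), n_per_pop = as.integer(tab))),
            class = "amova_result")
}

amova_d2 <- function(x, pops) {
  if (inherits(x, "coi_alignment")) {
    pops <- validate_population_map(pops, x)
    d2 <- pairwise_differences(x)$diffs
    labels <- unname(pops[x$ids])
  } else {
    d2 <- as.matrix(x)
    if (nrow(d2) != ncol(d2) || max(abs(d2 - t(d2))) > 1e-8)
      stop("squared-distance matrix must be square and symmetric")
    labels <- if (!is.null(names(pops)) && !is.null(rownames(d2)))
      unname(pops[rownames(d2)]) else unname(pops)
    if (length(labels) != nrow(d2) || anyNA(labels))
      stop("population labels do not match the distance matrix")
  }
  list(d2 = d2, labels = labels)
}

amova_components <- function(d2, labels) {
  N <- nrow(d2)
  f <- as.factor(labels)
  P <- nlevels(f)
  ssd_total <- sum(d2) / (2 * N)
  ssd_within <- 0
  n_g <- integer(P)
  for (k in seq_len(P)) {
    idx <- which(f == levels(f)[k])
    n_g[k] <- length(idx)
    ssd_within <- ssd_within + sum(d2[idx, idx]) / (2 * n_g[k])
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- P - 1
  df_within <- N - P
  ms_among <- ssd_among / df_among
  ms_within <- ssd_within / df_within
  n0 <- (N - sum(n_g^2) / N) / (P - 1)
  var_within <- ms_within
  var_among <- (ms_among - ms_within) / n0
  tot <- var_among + var_within
  phi <- if (tot == 0) NA_real_ else var_among / tot
  list(ssd_among = ssd_among, ssd_within = ssd_within, ssd_total = ssd_total,
       df_among = df_among, df_within = df_within,
       variance_among = var_among, variance_within = var_within,
       percent_among = 100 * var_among / tot,
       percent_within = 100 * var_within / tot,
       phi_st = phi)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("<amova_result>\n")
  cat(sprintf("  SSD among/within/total: %.4f / %.4f / %.4f\n",
              x$ssd_among, x$ssd_within, x$ssd_total))
  cat(sprintf("  variance among: %.5f (%.2f%%), within: %.5f (%.2f%%)\n",
              x$variance_among, x$percent_among,
              x$variance_within, x$percent_within))
  cat(sprintf("  Phi_ST = %.5f, p = %.4f (%d permutations)\n",
              x$phi_st, x$p_value, x$n_perm))
  invisible(x)
}

#' Pairwise Phi-ST matrix
#'
#' Runs a two-population [amova()] for every population pair. Pairs that
#' include a population of size 1 are reported as `NA` (not determined).
#'
#' @inheritParams amova
#' @param aln a [coi_alignment()].
#' @return List with symmetric matrices `phi_st` and `p_value`.
#' @export
pairwise_phist <- function(aln, pops, n_perm = 1000, seed = NULL) {
  stopifnot(inherits(aln, "coi_alignment"))
  pops <- validate_population_map(pops, aln)
  d2 <- pairwise_differences(aln)$diffs
  labels <- unname(pops[aln$ids])
  lv <- unique(labels)
  P <- length(lv)
  phi <- p <- matrix(NA_real_, P, P, dimnames = list(lv, lv))
  diag(phi) <- 0
  with_seed(seed, {
    for (a in seq_len(P - 1)) for (b in (a + 1):P) {
      ia <- which(labels == lv[a]); ib <- which(labels == lv[b])
      if (length(ia) < 2 || length(ib) < 2) next
      idx <- c(ia, ib)
      sub <- d2[idx, idx]
      f <- labels[idx]
      obs <- amova_components(sub, f)
      pp <- vapply(seq_len(n_perm), function(i)
        amova_components(sub, sample(f))$phi_st, numeric(1))
      phi[a, b] <- phi[b, a] <- obs$phi_st
      p[a, b] <- p[b, a] <- (1 + sum(pp >= obs$phi_st, na.rm = TRUE)) / (n_perm + 1)
    }
  })
  list(phi_st = phi, p_value = p)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers \eqn{-\frac{1}{2} D^2}, eigendecomposes, and keeps the
#' positive-eigenvalue axes (via [stats::cmdscale()]). Axes are ordered by
#' non-increasing eigenvalue; explained fractions are computed over the
#' positive eigenvalues only.
#'
#' @param distances square symmetric matrix with zero diagonal.
#' @param k maximum number of axes (default: all positive ones).
#' @return Object of class `pcoa_result` with `coordinates` (items x axes),
#'   `eigenvalues` and `explained_fraction`.
#' @export
pcoa <- function(distances, k = NULL) {
  D <- as.matrix(distances)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (max(abs(diag(D))) > 1e-8) stop("distance matrix must have zero diagonal")
  n <- nrow(D)
  if (is.null(k)) k <- n - 1
  # non-Euclidean distances legitimately produce negative eigenvalues,
  # which are dropped; silence cmdscale's note about them
  sc <- suppressWarnings(stats::cmdscale(D, k = k, eig = TRUE))
  eig <- sc$eig
  pos <- eig > max(eig) * 1e-9
  n_axes <- min(k, sum(pos))
  coords <- sc$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- sprintf("Axis%d", seq_len(n_axes))
  structure(list(coordinates = coords,
                 eigenvalues = eig[seq_len(n_axes)],
                 explained_fraction = eig[seq_len(n_axes)] / sum(eig[pos])),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat("<pcoa_result> ", nrow(x$coordinates), " items, ",
      ncol(x$coordinates), " positive axes; first axes explain ",
      paste(sprintf("%.1f%%", 100 * utils::head(x$explained_fraction, 3)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
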