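# Independent oracles, implemented from first principles and sharing no
# code with the package internals they check.

# Tajima's D by literal re-summation of every constant.
oracle_tajima_d <- function(seqs) {
  n <- length(seqs)
  M <- do.call(rbind, strsplit(seqs, ""))
  S <- 0
  for (j in seq_len(ncol(M))) {
    st <- unique(M[, j][M[, j] %in% c("A", "C", "G", "T")])
    if (length(st) >= 2) S <- S + 1
  }
  K <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ok <- M[i, ] %in% c("A", "C", "G", "T") & M[j, ] %in% c("A", "C", "G", "T")
    K <- K + sum(M[i, ok] != M[j, ok]); np <- np + 1
  }
  K <- K / np
  a1 <- 0; a2 <- 0
  for (i in 1:(n - 1)) { a1 <- a1 + 1 / i; a2 <- a2 + 1 / i^2 }
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (K - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Exact small-n Ewens probabilities via integer Stirling numbers.
oracle_stirling_unsigned <- function(n) {
  # returns |s(n, k)| for k = 1..n as exact doubles (small n only)
  row <- 1
  if (n == 1) return(row)
  for (m in 1:(n - 1)) {
    row <- c(0, row, 0)
    row <- sapply(seq_len(m + 1), function(k) row[k] + m * row[k + 1])
  }
  row
}

oracle_fs <- function(n, theta, k_obs) {
  s <- oracle_stirling_unsigned(n)
  p <- s * theta^seq_len(n) / prod(theta + 0:(n - 1))
  Sp <- sum(p[k_obs:n])
  log(Sp / (1 - Sp))
}

# Brute-force pairwise difference count (pairwise deletion of N/-).
oracle_pair_diffs <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  c(diffs = sum(a[ok] != b[ok]), comparable = sum(ok))
}

# Brute-force G4 candidate enumeration: nested loops over all 4-tuples of
# maximal G-runs, no shared code with enumerate_g4.
oracle_g4 <- function(seq, g_min, loop_min, loop_max) {
  chars <- strsplit(seq, "")[[1]]
  runs <- list()
  i <- 1
  while (i <= length(chars)) {
    if (chars[i] == "G") {
      j <- i
      while (j < length(chars) && chars[j + 1] == "G") j <- j + 1
      runs[[length(runs) + 1]] <- c(start = i, len = j - i + 1)
      i <- j + 1
    } else i <- i + 1
  }
  runs <- Filter(function(r) r["len"] >= g_min, runs)
  out <- list()
  nr <- length(runs)
  if (nr >= 4) {
    for (a in 1:(nr - 3)) for (b in (a + 1):(nr - 2))
      for (cc in (b + 1):(nr - 1)) for (d in (cc + 1):nr) {
        idx <- list(runs[[a]], runs[[b]], runs[[cc]], runs[[d]])
        gaps <- sapply(1:3, function(k)
          idx[[k + 1]]["start"] - (idx[[k]]["start"] + idx[[k]]["len"]))
        if (all(gaps >= loop_min & gaps <= loop_max))
          out[[length(out) + 1]] <- c(start = unname(idx[[1]]["start"]),
                                      end = unname(idx[[4]]["start"] +
                                                     idx[[4]]["len"] - 1),
                                      l1 = unname(gaps[1]), l2 = unname(gaps[2]),
                                      l3 = unname(gaps[3]))
      }
  }
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  m[order(m[, "start"], m[, "end"], m[, "l1"], m[, "l2"]), , drop = FALSE]
}

# Random DNA string helper for fuzzing.
random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}
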