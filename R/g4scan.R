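#' Configuration for the G-quadruplex scanner
#'
#' @param g_min minimum G-tract length (default 2, the canonical minimum;
#'   1 is permitted to admit the relaxed single-G "new type" tracts).
#' @param loop_min,loop_max loop-length bounds in bp (defaults 0 and 20;
#'   raise `loop_max` to admit motifs with longer connectors).
#' @param max_passes maximum number of selection passes in
#'   [select_nonoverlapping()] (default 10).
#' @param w_tract,w_loop_mean,w_loop_range weights of the documented
#'   surrogate stability score (see [score_g4()]).
#' @return Object of class `g4_config`.
#' @export
g4_config <- function(g_min = 2, loop_min = 0, loop_max = 20, max_passes = 10,
                      w_tract = 20, w_loop_mean = 1, w_loop_range = 1) {
  stopifnot(g_min >= 1, loop_min >= 0, loop_max >= loop_min, max_passes >= 1)
  structure(list(g_min = as.integer(g_min), loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max),
                 max_passes = as.integer(max_passes),
                 w_tract = w_tract, w_loop_mean = w_loop_mean,
                 w_loop_range = w_loop_range),
            class = "g4_config")
}

#' Surrogate G-quadruplex stability score
#'
#' QGRS-style heuristics reward long G-tracts and short, even loops. The
#' score of a candidate with minimum tract length \eqn{t_{min}} and loops
#' \eqn{(l_1, l_2, l_3)} is
#' \deqn{w_t (t_{min} - 1) - w_m \bar l - w_r (\max l - \min l)}
#' (defaults \eqn{w_t = 20}, \eqn{w_m = w_r = 1}); higher means more
#' stable. The formula is a documented package-defined surrogate, exposed
#' through [g4_config()] so the weights can be tuned.
#'
#' @param min_tract minimum tract length (scalar or vector).
#' @param loop_mean,loop_range mean and range of the three loop lengths.
#' @param cfg a [g4_config()].
#' @return Numeric score(s).
#' @export
score_g4 <- function(min_tract, loop_mean, loop_range, cfg = g4_config()) {
  cfg$w_tract * (min_tract - 1) - cfg$w_loop_mean * loop_mean -
    cfg$w_loop_range * loop_range
}

#' Enumerate G-quadruplex candidates
#'
#' Finds all maximal runs of `G` of length `>= g_min` and emits every
#' ordered choice of four of them whose three inter-tract gaps (loops) lie
#' within `[loop_min, loop_max]`. Loops may themselves contain shorter (or
#' skipped) G-runs. Enumeration is exhaustive and deterministic; output is
#' ordered by start position, then descending score.
#'
#' @param seq a single DNA/RNA string over `A, C, G, T/U` (and `N`/`-`,
#'   which simply never match `G`). `U` is treated as `T`.
#' @param cfg a [g4_config()].
#' @return A data.frame with columns `start`, `end` (1-based inclusive),
#'   `tract_starts`, `tract_lengths`, `loops` (comma-joined specs),
#'   `loop1`, `loop2`, `loop3`, `min_tract`, `score`.
#' @export
enumerate_g4 <- function(seq, cfg = g4_config()) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- chartr("u", "T", toupper(seq))
  s <- gsub("U", "T", s, fixed = TRUE)
  runs <- gregexpr("G+", s)[[1]]
  empty <- data.frame(start = integer(0), end = integer(0),
                      tract_starts = character(0), tract_lengths = character(0),
                      loops = character(0), loop1 = integer(0),
                      loop2 = integer(0), loop3 = integer(0),
                      min_tract = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (runs[1] == -1) return(empty)
  starts <- as.integer(runs)
  lens <- attr(runs, "match.length")
  keep <- lens >= cfg$g_min
  starts <- starts[keep]; lens <- lens[keep]
  nr <- length(starts)
  if (nr < 4) return(empty)
  ends <- starts + lens - 1L
  # successors[[i]]: runs j > i reachable with a loop in range
  succ <- lapply(seq_len(nr), function(i) {
    gap <- starts - ends[i] - 1L
    which(seq_len(nr) > i & gap >= cfg$loop_min & gap <= cfg$loop_max)
  })
  rows <- list()
  for (i1 in seq_len(nr)) for (i2 in succ[[i1]]) for (i3 in succ[[i2]])
    for (i4 in succ[[i3]]) {
      idx <- c(i1, i2, i3, i4)
      loops <- starts[idx[-1]] - ends[idx[-4]] - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        start = starts[i1], end = ends[i4],
        tract_starts = paste(starts[idx], collapse = ","),
        tract_lengths = paste(lens[idx], collapse = ","),
        loops = paste(loops, collapse = ","),
        loop1 = loops[1], loop2 = loops[2], loop3 = loops[3],
        min_tract = min(lens[idx]),
        score = NA_real_, stringsAsFactors = FALSE)
    }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$score <- score_g4(out$min_tract,
                        (out$loop1 + out$loop2 + out$loop3) / 3,
                        pmax(out$loop1, out$loop2, out$loop3) -
                          pmin(out$loop1, out$loop2, out$loop3),
                        cfg)
  out <- out[order(out$start, -out$score, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative greedy selection of non-overlapping candidates
#'
#' Pass `k` repeatedly picks the highest-scoring not-yet-selected candidate
#' (ties: leftmost start, then shortest span), removes every candidate
#' overlapping it from the current pass, and continues until the pass pool
#' is empty; candidates set aside because of an overlap become available
#' again in the next pass. Up to `max_passes` passes are run, so each
#' selected motif carries the index of the pass in which it was chosen and
#' all motifs selected within one pass are pairwise disjoint.
#'
#' @param cands candidate data.frame from [enumerate_g4()].
#' @param cfg a [g4_config()].
#' @return The selected subset with an added integer `pass` column,
#'   ordered by pass then start.
#' @export
select_nonoverlapping <- function(cands, cfg = g4_config()) {
  if (nrow(cands) == 0) {
    cands$pass <- integer(0)
    return(cands)
  }
  pass_of <- rep(NA_integer_, nrow(cands))
  for (k in seq_len(cfg$max_passes)) {
    pool <- which(is.na(pass_of))
    if (!length(pool)) break
    while (length(pool)) {
      o <- pool[order(-cands$score[pool], cands$start[pool],
                      cands$end[pool] - cands$start[pool])]
      pick <- o[1]
      pass_of[pick] <- k
      keep <- cands$end[pool] < cands$start[pick] |
        cands$start[pool] > cands$end[pick]
      pool <- pool[keep]
    }
  }
  out <- cands[!is.na(pass_of), , drop = FALSE]
  out$pass <- pass_of[!is.na(pass_of)]
  out <- out[order(out$pass, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan haplotypes for hotspot-linked G-quadruplex motifs
#'
#' Runs [enumerate_g4()] + [select_nonoverlapping()] on every haplotype
#' sequence (aligned coordinates; `-` and `N` never match `G`) and records,
#' for each selected motif, which key sites fall within its span
#' (`[start, end]`, inclusive).
#'
#' @param ht a `haplotype_table`.
#' @param key_positions 1-based key sites to link against.
#' @param cfg a [g4_config()].
#' @return A data.frame of selected motifs with `hap_id`, the columns of
#'   [enumerate_g4()], `pass` and `linked_sites` (semicolon-joined key
#'   sites inside the span, `""` if none).
#' @export
scan_alignment_hotspots <- function(ht, key_positions, cfg = g4_config()) {
  stopifnot(inherits(ht, "haplotype_table"))
  key_positions <- as.integer(key_positions)
  res <- lapply(seq_along(ht$hap_id), function(i) {
    sel <- select_nonoverlapping(enumerate_g4(ht$sequence[i], cfg), cfg)
    if (nrow(sel) == 0) return(NULL)
    sel$hap_id <- ht$hap_id[i]
    sel$linked_sites <- vapply(seq_len(nrow(sel)), function(r)
      paste(key_positions[key_positions >= sel$start[r] &
                            key_positions <= sel$end[r]], collapse = ";"),
      character(1))
    sel
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    out <- enumerate_g4("A", g4_config())
    out$pass <- integer(0); out$hap_id <- character(0)
    out$linked_sites <- character(0)
    return(out)
  }
  out <- do.call(rbind, res)
  out[, c("hap_id", setdiff(names(out), "hap_id"))]
}

#' Summarize hotspot-linked motifs per group
#'
#' Cross-tabulates, for each hotspot group and key site, how many
#' haplotypes carry the derived/`G`-bearing state at the site and how many
#' carry at least one selected motif spanning it - making visible whether
#' site-linked candidates exist only when the site carries a `G`.
#'
#' @param scan result of [scan_alignment_hotspots()].
#' @param ht the `haplotype_table` that was scanned.
#' @param ga the matching `group_assignment`.
#' @return A data.frame with one row per (group, key site): `group`,
#'   `position`, `n_haplotypes`, `n_with_G`, `n_linked`.
#' @export
hotspot_g4_summary <- function(scan, ht, ga) {
  M <- aln_matrix(hap_alignment(ht))
  rows <- list()
  for (g in names(ga$groups)) {
    haps <- ga$groups[[g]]
    ri <- match(haps, ht$hap_id)
    for (j in seq_along(ga$key_positions)) {
      p <- ga$key_positions[j]
      linked <- vapply(haps, function(h) {
        sub <- scan[scan$hap_id == h, , drop = FALSE]
        any(vapply(strsplit(sub$linked_sites, ";"), function(x)
          as.character(p) %in% x, logical(1)))
      }, logical(1))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, position = p, n_haplotypes = length(haps),
        n_with_G = sum(M[ri, p] == "G"), n_linked = sum(linked),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
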