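#' Classify alignment sites over a haplotype table
#'
#' Per-site state tallies with polymorphism and parsimony-informativeness
#' flags. The default counting unit is one vote per haplotype; individual
#' weighting (each haplotype weighted by its carrier count) is available.
#' `N` and `-` are treated as missing, not as states. A site is polymorphic
#' when it carries at least two observed states and parsimony-informative
#' when at least two states each occur in at least two counting units.
#' Biallelic sites are classed as transition (`A<->G`, `C<->T`) or
#' transversion; sites with more than two states are `multi-state`.
#'
#' @param ht a `haplotype_table` (see [collapse_haplotypes()]).
#' @param weighting `"haplotype"` (default) or `"individual"`.
#' @return A data.frame with one row per site: `position`, state counts
#'   `A/C/G/T`, `n_states`, `is_polymorphic`, `is_parsimony_informative`,
#'   `substitution_class`.
#' @export
classify_sites <- function(ht, weighting = c("haplotype", "individual")) {
  stopifnot(inherits(ht, "haplotype_table"))
  weighting <- match.arg(weighting)
  if (n_haplotypes(ht) < 2) stop("site classification needs >= 2 haplotypes")
  M <- aln_matrix(hap_alignment(ht))
  w <- if (weighting == "haplotype") rep(1L, nrow(M)) else ht$count
  counts <- vapply(DNA_STATES, function(b) colSums((M == b) * w),
                   numeric(ncol(M)))
  # vapply drops to a vector for single-site alignments
  counts <- matrix(counts, ncol = length(DNA_STATES),
                   dimnames = list(NULL, DNA_STATES))
  n_states <- rowSums(counts > 0)
  informative <- rowSums(counts >= 2) >= 2
  sub_class <- rep(NA_character_, ncol(M))
  bi <- n_states == 2
  if (any(bi)) {
    pair <- t(apply(counts[bi, , drop = FALSE], 1,
                    function(r) DNA_STATES[r > 0]))
    sub_class[bi] <- ifelse(is_transition_pair(pair[, 1], pair[, 2]),
                            "transition", "transversion")
  }
  sub_class[n_states > 2] <- "multi-state"
  data.frame(position = seq_len(ncol(M)),
             A = counts[, "A"], C = counts[, "C"],
             G = counts[, "G"], T = counts[, "T"],
             n_states = n_states,
             is_polymorphic = n_states >= 2,
             is_parsimony_informative = informative & n_states >= 2,
             substitution_class = sub_class,
             stringsAsFactors = FALSE)
}

key_strings <- function(ht, key_positions) {
  M <- aln_matrix(hap_alignment(ht))
  apply(M[, key_positions, drop = FALSE], 1, paste, collapse = "-")
}

#' Assign haplotypes to hotspot-key groups
#'
#' Every haplotype is mapped to the state string at the ordered key sites
#' (e.g. `"A-A-G-A"` for sites 207-282-354-420); haplotypes sharing a key
#' string form a group. Within-group haplotype diversity is computed over
#' individuals (Nei's unbiased `h`, weighted by haplotype carrier counts).
#' A warning is raised for key sites that are not biallelic among the
#' haplotypes; monomorphic sites are retained.
#'
#' @param ht a `haplotype_table`.
#' @param key_positions ordered vector of 1-based key sites.
#' @return Object of class `group_assignment`: list with `key_positions`,
#'   `assignments` (hap_id -> key string), `groups` (key string -> hap
#'   ids), `sizes` (haplotype counts), `n_individuals`, and `per_group_h`.
#' @export
assign_groups <- function(ht, key_positions) {
  stopifnot(inherits(ht, "haplotype_table"))
  key_positions <- as.integer(key_positions)
  if (any(key_positions < 1 | key_positions > ht$seq_length))
    stop("key sites outside the alignment: ",
         paste(key_positions[key_positions < 1 | key_positions > ht$seq_length],
               collapse = ", "))
  M <- aln_matrix(hap_alignment(ht))
  for (p in key_positions) {
    states <- unique(M[, p][M[, p] %in% DNA_STATES])
    if (length(states) != 2)
      warning("key site ", p, " is not biallelic (",
              length(states), " state(s) observed); retained")
  }
  ks <- key_strings(ht, key_positions)
  assignments <- setNames(ks, ht$hap_id)
  groups <- split(ht$hap_id, ks)
  sizes <- vapply(groups, length, integer(1))
  n_ind <- vapply(groups, function(h) sum(ht$count[match(h, ht$hap_id)]),
                  integer(1))
  per_h <- vapply(names(groups), function(g) {
    cnt <- ht$count[match(groups[[g]], ht$hap_id)]
    N <- sum(cnt)
    if (N < 2) return(NA_real_)
    N / (N - 1) * (1 - sum((cnt / N)^2))
  }, numeric(1))
  structure(list(key_positions = key_positions, assignments = assignments,
                 groups = groups, sizes = sizes, n_individuals = n_ind,
                 per_group_h = per_h),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat("<group_assignment> key sites ",
      paste(x$key_positions, collapse = ","), "\n", sep = "")
  for (g in names(x$groups))
    cat(sprintf("  %s: %d haplotypes, %d individuals, h = %s\n", g,
                x$sizes[[g]], x$n_individuals[[g]],
                ifelse(is.na(x$per_group_h[[g]]), "nd",
                       sprintf("%.3f", x$per_group_h[[g]]))))
  invisible(x)
}

#' Infer the ancestral-to-derived order of hotspot groups
#'
#' The ancestral group is taken to be the one with the highest within-group
#' haplotype diversity (the rationale being that the oldest group has had
#' the longest time to accumulate variation); an explicit `ancestral`
#' override is available for when external evidence (e.g. outgroup states)
#' is at hand. Remaining groups are ordered by Hamming distance of their
#' key strings from the ancestral key, ties broken by descending
#' within-group diversity and then alphabetically. Per-site polarity is
#' reported as (ancestral base -> derived base), the derived base being the
#' majority alternative at that site. The path is flagged `stepwise` only
#' when every consecutive pair of key strings differs at exactly one site.
#'
#' @param ga a `group_assignment` (see [assign_groups()]).
#' @param ancestral optional key string forcing the ancestral group.
#' @return Object of class `transition_order`: list with `order` (key
#'   strings, ancestral first), `polarity` (data.frame `position`,
#'   `ancestral_base`, `derived_base`), `step_sizes` (Hamming distances
#'   between consecutive key strings) and `stepwise` flag.
#' @export
infer_transition_order <- function(ga, ancestral = NULL) {
  stopifnot(inherits(ga, "group_assignment"))
  keys <- names(ga$groups)
  if (length(keys) < 2) stop("transition order needs >= 2 groups")
  h <- ga$per_group_h
  h[is.na(h)] <- 0
  if (is.null(ancestral)) {
    top <- max(h)
    cand <- keys[h == top]
    if (length(cand) > 1)
      stop("within-group diversity tie for the ancestral group (",
           paste(cand, collapse = ", "),
           "); supply `ancestral` explicitly")
    ancestral <- cand
  } else if (!ancestral %in% keys) {
    stop("ancestral key string '", ancestral, "' is not an observed group")
  }
  anc_states <- strsplit(ancestral, "-", fixed = TRUE)[[1]]
  ham <- vapply(keys, function(k)
    sum(strsplit(k, "-", fixed = TRUE)[[1]] != anc_states), integer(1))
  rest <- setdiff(keys, ancestral)
  ord <- rest[order(ham[rest], -h[rest], rest)]
  path <- c(ancestral, ord)
  # polarity: for each key site, ancestral base -> majority alternative
  split_keys <- do.call(rbind, strsplit(keys, "-", fixed = TRUE))
  polarity <- data.frame(position = ga$key_positions,
                         ancestral_base = anc_states,
                         derived_base = NA_character_,
                         stringsAsFactors = FALSE)
  for (j in seq_along(ga$key_positions)) {
    alt <- split_keys[split_keys[, j] != anc_states[j], j]
    if (length(alt)) {
      tab <- sort(table(alt), decreasing = TRUE)
      polarity$derived_base[j] <- names(tab)[1]
    }
  }
  steps <- vapply(seq_len(length(path) - 1), function(i) {
    a <- strsplit(path[i], "-", fixed = TRUE)[[1]]
    b <- strsplit(path[i + 1], "-", fixed = TRUE)[[1]]
    sum(a != b)
  }, integer(1))
  structure(list(order = path, polarity = polarity, step_sizes = steps,
                 stepwise = all(steps == 1L)),
            class = "transition_order")
}

#' @export
print.transition_order <- function(x, ...) {
  cat("<transition_order> ", paste(x$order, collapse = " -> "),
      if (x$stepwise) "  [stepwise]" else "  [non-stepwise]", "\n", sep = "")
  invisible(x)
}

#' Pairwise positional covariance network
#'
#' For every pair of sites in `sites`, counts the haplotypes whose states
#' at the two sites fall in the same polarity class - both ancestral (or
#' major) or both derived (or minor). Each biallelic site is polarized into
#' (major, minor) by state frequency over haplotypes (ties broken by base
#' order A < C < G < T), or into (ancestral, derived) when a `polarity`
#' table from [infer_transition_order()] is supplied for those sites.
#' Haplotypes with a missing or third state at either site do not count as
#' covariate for that pair.
#'
#' @param ht a `haplotype_table`.
#' @param sites sites to compare; default: all polymorphic biallelic sites.
#'   Requesting a multi-allelic site is an error.
#' @param polarity optional data.frame with columns `position`,
#'   `ancestral_base`, `derived_base` (as produced by
#'   [infer_transition_order()]).
#' @return A data.frame of edges `site_i < site_j` with `covariate_count`
#'   and `frequency_ratio` (= count / number of haplotypes), sorted by
#'   descending count.
#' @export
covariance_network <- function(ht, sites = NULL, polarity = NULL) {
  stopifnot(inherits(ht, "haplotype_table"))
  M <- aln_matrix(hap_alignment(ht))
  n_hap <- nrow(M)
  state_sets <- apply(M, 2, function(col) sort(unique(col[col %in% DNA_STATES])),
                      simplify = FALSE)
  n_states <- lengths(state_sets)
  if (is.null(sites)) {
    sites <- which(n_states == 2)
  } else {
    sites <- as.integer(sites)
    bad <- sites[n_states[sites] > 2]
    if (length(bad))
      stop("multi-allelic site(s) in requested set: ",
           paste(bad, collapse = ", "))
  }
  if (length(sites) < 2) stop("need at least 2 usable sites")
  # polarize each site: class 0 = major/ancestral, 1 = minor/derived, NA else
  cls <- vapply(sites, function(p) {
    col <- M[, p]
    anc <- der <- NA_character_
    if (!is.null(polarity) && p %in% polarity$position) {
      row <- polarity[polarity$position == p, ]
      anc <- row$ancestral_base[1]; der <- row$derived_base[1]
    } else {
      st <- state_sets[[p]]
      if (length(st) == 1) { anc <- st } else {
        cnt <- table(factor(col, levels = st))
        anc <- names(cnt)[which.max(cnt)]      # ties: first in A<C<G<T order
        der <- setdiff(st, anc)[1]
      }
    }
    out <- rep(NA_real_, n_hap)
    out[col == anc] <- 0
    if (!is.na(der)) out[col == der] <- 1
    out
  }, numeric(n_hap))
  colnames(cls) <- as.character(sites)
  pairs <- which(upper.tri(diag(length(sites))), arr.ind = TRUE)
  edges <- data.frame(
    site_i = sites[pairs[, 1]],
    site_j = sites[pairs[, 2]],
    covariate_count = vapply(seq_len(nrow(pairs)), function(r) {
      a <- cls[, pairs[r, 1]]; b <- cls[, pairs[r, 2]]
      sum(!is.na(a) & !is.na(b) & a == b)
    }, numeric(1))
  )
  edges$frequency_ratio <- edges$covariate_count / n_hap
  edges[order(-edges$covariate_count, edges$site_i, edges$site_j), ,
        drop = FALSE]
}

#' Export a covariance network as GraphML
#'
#' @param edges edge data.frame from [covariance_network()].
#' @param path output GraphML path.
#' @return `path`, invisibly.
#' @export
write_covariance_graphml <- function(edges, path) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$site_i),
               to = as.character(edges$site_j),
               weight = edges$covariate_count,
               ratio = edges$frequency_ratio),
    directed = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
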