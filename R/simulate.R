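#' Configuration for the expansion-structured alignment simulator
#'
#' Describes the world the generator emulates: a sample of individuals
#' whose haplotypes fall into a small number of hotspot-key groups created
#' by stepwise transitions at a few key sites, plus shared
#' (parsimony-informative) and singleton third-position mutations, under a
#' star-like expansion frequency law (one dominant haplotype, many
#' singletons) and with no between-population structure by default.
#'
#' The defaults state the emulated study system: 140 individuals over nine
#' populations, a 595 bp coding fragment, key sites 207/282/354/420, the
#' four canonical key groups with 35/12/1/8 haplotypes plus two singleton
#' variant key-strings (A-A-A-G, A-G-A-A) for a total of 58 haplotypes, 40
#' singleton + 27 shared mutated sites (so 71 polymorphic and 31
#' parsimony-informative sites including the 4 key sites), and a dominant
#' haplotype carried by 27 individuals in the most derived group.
#'
#' @param n_individuals number of sampled sequences.
#' @param seq_length alignment width in bp.
#' @param key_positions ordered key sites; with the defaults these all fall
#'   on third codon positions.
#' @param group_freqs named integer vector: key string -> number of
#'   haplotypes; names use `-`-separated states.
#' @param n_singleton_sites number of sites mutated in exactly one
#'   haplotype.
#' @param n_shared_sites number of sites mutated in 2+ haplotypes of one
#'   group (parsimony-informative).
#' @param shared_carrier_range integer range for the number of carriers of
#'   a shared site.
#' @param pop_sizes named integer vector of population sizes; must sum to
#'   `n_individuals`.
#' @param population_mixing fraction in `[0, 1]`; 1 (default) is fully
#'   panmictic, lower values associate populations with "home" groups.
#' @param dominant_count individuals carried by the dominant haplotype.
#' @param dominant_group key string of the group holding the dominant
#'   haplotype (default the last entry of `group_freqs` present).
#' @param seed integer seed; same seed, same bytes.
#' @return Object of class `expansion_sim_config`.
#' @export
expansion_sim_config <- function(n_individuals = 140,
                                 seq_length = 595,
                                 key_positions = c(207, 282, 354, 420),
                                 group_freqs = c("A-A-A-A" = 35,
                                                 "A-A-G-A" = 12,
                                                 "G-A-G-A" = 1,
                                                 "G-G-G-G" = 8,
                                                 "A-A-A-G" = 1,
                                                 "A-G-A-A" = 1),
                                 n_singleton_sites = 40,
                                 n_shared_sites = 27,
                                 shared_carrier_range = c(2, 6),
                                 pop_sizes = c(SC = 5, BG = 21, YG = 29,
                                               HK = 16, JB = 2, BY = 15,
                                               GY = 9, HS = 42, JK = 1),
                                 population_mixing = 1,
                                 dominant_count = 27,
                                 dominant_group = "G-G-G-G",
                                 seed = 1) {
  n_hap <- sum(group_freqs)
  stopifnot(n_hap >= 1, n_hap <= n_individuals,
            all(diff(as.integer(key_positions)) > 0),
            max(key_positions) <= seq_length,
            population_mixing >= 0, population_mixing <= 1,
            sum(pop_sizes) == n_individuals,
            n_singleton_sites >= 0, n_shared_sites >= 0)
  key_mat <- do.call(rbind, strsplit(names(group_freqs), "-", fixed = TRUE))
  if (ncol(key_mat) != length(key_positions))
    stop("key strings must have one state per key position")
  if (!dominant_group %in% names(group_freqs)) dominant_group <- NULL
  structure(list(n_individuals = n_individuals, seq_length = seq_length,
                 key_positions = as.integer(key_positions),
                 group_freqs = group_freqs,
                 n_singleton_sites = as.integer(n_singleton_sites),
                 n_shared_sites = as.integer(n_shared_sites),
                 shared_carrier_range = as.integer(shared_carrier_range),
                 pop_sizes = pop_sizes,
                 population_mixing = population_mixing,
                 dominant_count = as.integer(dominant_count),
                 dominant_group = dominant_group, seed = seed),
            class = "expansion_sim_config")
}

# Haplotype carrier counts: dominant haplotype, then a documented
# decreasing multi-carrier law, then singletons. For the default world
# (140 individuals, 58 haplotypes) the multi-carrier counts are fixed so
# that 15 haplotypes share 97 individuals and 43 are singletons; otherwise
# a deterministic geometric fallback is used.
expansion_counts <- function(n_ind, n_hap, dominant) {
  if (n_hap == 1) return(n_ind)
  dominant <- min(dominant, n_ind - (n_hap - 1))
  if (n_ind == 140 && n_hap == 58 && dominant == 27) {
    multis <- c(12, 10, 8, 7, 6, 5, 4, 4, 3, 3, 2, 2, 2, 2)
  } else {
    extra <- n_ind - n_hap - (dominant - 1)
    multis <- integer(0)
    while (extra > 0 && length(multis) < n_hap - 1) {
      take <- max(1L, floor(extra * 0.3))
      multis <- c(multis, 1L + take)
      extra <- extra - take
    }
    multis <- multis[multis >= 2]
  }
  counts <- c(dominant, multis, rep(1L, n_hap - 1 - length(multis)))
  stopifnot(sum(counts) == n_ind, length(counts) == n_hap)
  counts
}

# Ancestral CDS-compatible sequence: random non-stop codons under the
# invertebrate mitochondrial code, frame 1, trimmed to seq_length; key-site
# codons are forced to GGA-like codons so that the ancestral state at each
# key site matches the first group's key string and any state swap stays
# stop-free.
ancestral_cds <- function(seq_length, key_positions, anc_states) {
  gc5 <- Biostrings::getGeneticCode("5")
  codons <- names(gc5)[gc5 != "*"]
  n_codon <- ceiling(seq_length / 3)
  seqv <- unlist(strsplit(sample(codons, n_codon, replace = TRUE), ""))
  seqv <- seqv[seq_len(seq_length)]
  for (j in seq_along(key_positions)) {
    p <- key_positions[j]
    seqv[p] <- anc_states[j]
    cp <- ((p - 1) %% 3) + 1
    cs <- p - cp + 1
    if (cs + 2 <= seq_length) {
      # force a codon whose variants at the key offset are never stops:
      # GGN (Gly) works at any offset for A/C/G/T swaps at position 3 and
      # keeps G elsewhere; only rewrite if the random codon could become a
      # stop after substitution
      cdn <- seqv[cs:(cs + 2)]
      trial <- cdn
      for (b in c("A", "G")) {
        trial[cp] <- b
        if (gc5[paste(trial, collapse = "")] == "*") {
          cdn <- c("G", "G", "A")
          cdn[cp] <- seqv[p]
          break
        }
      }
      seqv[cs:(cs + 2)] <- cdn
      seqv[p] <- anc_states[j]
    }
  }
  seqv
}

transition_of <- c(A = "G", G = "A", C = "T", T = "C")

#' Simulate an expansion-structured alignment with planted truth
#'
#' Builds an ancestral coding-compatible sequence, applies the key-site
#' states of each hotspot group, plants `n_shared_sites` parsimony-
#' informative transitions (each carried by 2+ haplotypes of one group) and
#' `n_singleton_sites` singleton transitions at distinct third codon
#' positions, assigns individuals to haplotypes by the skewed expansion
#' frequency law, and distributes individuals over populations (panmictic
#' at `population_mixing = 1`). All mutations are transitions at third
#' codon positions, keeping the fragment synonymous-rich and stop-free.
#'
#' The construction guarantees that [collapse_haplotypes()] recovers
#' exactly the planted haplotypes, [assign_groups()] the planted group
#' sizes, and [classify_sites()] the planted polymorphic/informative site
#' counts (`n_singleton + n_shared + informative key sites` polymorphic,
#' `n_shared + informative key sites` parsimony-informative).
#'
#' @param cfg an [expansion_sim_config()].
#' @return List of class `expansion_sim` with `alignment` (the
#'   individual-level [coi_alignment()]), `pops` (named character vector),
#'   and `truth` (planted haplotype sequences, per-individual haplotype,
#'   group of each haplotype, carrier counts, mutated site lists and key
#'   setup).
#' @export
simulate_expansion_alignment <- function(cfg = expansion_sim_config()) {
  stopifnot(inherits(cfg, "expansion_sim_config"))
  with_seed(cfg$seed, {
    groups <- names(cfg$group_freqs)
    key_mat <- do.call(rbind, strsplit(groups, "-", fixed = TRUE))
    anc <- ancestral_cds(cfg$seq_length, cfg$key_positions, key_mat[1, ])
    n_hap <- sum(cfg$group_freqs)
    group_of <- rep(groups, cfg$group_freqs)
    # candidate mutation sites: third codon positions, minus key sites
    thirds <- setdiff(seq(3, cfg$seq_length, by = 3), cfg$key_positions)
    need <- cfg$n_singleton_sites + cfg$n_shared_sites
    if (need > length(thirds))
      stop("site budget (", need, ") exceeds available third positions (",
           length(thirds), ")")
    sites <- if (need > 0) sample(thirds, need) else integer(0)
    shared_sites <- utils::head(sites, cfg$n_shared_sites)
    singleton_sites <- utils::tail(sites, cfg$n_singleton_sites)
    # shared sites: carriers are 2+ haplotypes within one group
    eligible <- which(cfg$group_freqs >= 2)
    if (cfg$n_shared_sites > 0 && !length(eligible))
      stop("shared sites require a group with >= 2 haplotypes")
    carriers <- list()
    ok <- FALSE
    for (try in seq_len(50)) {
      carriers <- lapply(shared_sites, function(p) {
        g <- eligible[sample.int(length(eligible), 1,
                                 prob = cfg$group_freqs[eligible])]
        in_g <- which(group_of == groups[g])
        k <- sample(seq(cfg$shared_carrier_range[1],
                        min(cfg$shared_carrier_range[2], length(in_g))), 1)
        sort(sample(in_g, k))
      })
      # resolve duplicates within groups with singleton sites
      sig <- vapply(seq_len(n_hap), function(h)
        paste(group_of[h],
              paste(which(vapply(carriers, function(cc) h %in% cc,
                                 logical(1))), collapse = ","), sep = "|"),
        character(1))
      dup_needs <- unlist(lapply(split(seq_len(n_hap), sig), function(idx)
        if (length(idx) > 1) idx[-1] else integer(0)), use.names = FALSE)
      if (length(dup_needs) <= cfg$n_singleton_sites) { ok <- TRUE; break }
    }
    if (!ok) stop("could not plant distinct haplotypes; ",
                  "increase n_singleton_sites")
    singleton_carrier <- integer(length(singleton_sites))
    singleton_carrier[seq_along(dup_needs)] <- dup_needs
    remaining <- setdiff(seq_len(n_hap), dup_needs)
    extra_n <- length(singleton_sites) - length(dup_needs)
    if (extra_n > 0)
      singleton_carrier[length(dup_needs) + seq_len(extra_n)] <-
        rep(remaining, length.out = extra_n)
    # build haplotype sequences
    haps <- matrix(rep(anc, n_hap), nrow = n_hap, byrow = TRUE)
    for (h in seq_len(n_hap)) {
      ks <- key_mat[match(group_of[h], groups), ]
      haps[h, cfg$key_positions] <- ks
    }
    for (i in seq_along(shared_sites)) {
      p <- shared_sites[i]
      haps[carriers[[i]], p] <- transition_of[[anc[p]]]
    }
    for (i in seq_along(singleton_sites)) {
      p <- singleton_sites[i]
      haps[singleton_carrier[i], p] <- transition_of[[anc[p]]]
    }
    hap_seqs <- apply(haps, 1, paste, collapse = "")
    if (anyDuplicated(hap_seqs))
      stop("internal error: planted haplotypes are not distinct")
    # carrier counts: dominant haplotype in the dominant group
    counts <- expansion_counts(cfg$n_individuals, n_hap, cfg$dominant_count)
    hap_order <- order_for_counts(group_of, groups, cfg$group_freqs,
                                  cfg$dominant_group, length(counts))
    counts_of_hap <- integer(n_hap)
    counts_of_hap[hap_order] <- counts
    # individuals
    hap_of_ind <- rep(seq_len(n_hap), counts_of_hap)
    ind_ids <- sprintf("IND%03d", seq_along(hap_of_ind))
    aln <- coi_alignment(setNames(hap_seqs[hap_of_ind], ind_ids))
    pops <- assign_populations(ind_ids, group_of[hap_of_ind], cfg)
    truth <- list(hap_sequences = hap_seqs,
                  group_of_hap = group_of,
                  counts_of_hap = counts_of_hap,
                  hap_of_individual = setNames(hap_of_ind, ind_ids),
                  group_sizes = cfg$group_freqs,
                  key_positions = cfg$key_positions,
                  shared_sites = sort(shared_sites),
                  singleton_sites = sort(singleton_sites),
                  n_polymorphic = length(shared_sites) +
                    length(singleton_sites) + informative_keys(cfg),
                  n_informative = length(shared_sites) + informative_keys(cfg))
    structure(list(alignment = aln, pops = pops, truth = truth),
              class = "expansion_sim")
  })
}

# number of key sites segregating (and informative) given the group table;
# with the defaults every key site has derived counts >= 2 and is
# parsimony-informative
informative_keys <- function(cfg) {
  key_mat <- do.call(rbind, strsplit(names(cfg$group_freqs), "-", fixed = TRUE))
  sum(vapply(seq_len(ncol(key_mat)), function(j) {
    tab <- tapply(cfg$group_freqs, key_mat[, j], sum)
    length(tab) >= 2
  }, logical(1)))
}

# Deterministic order in which carrier counts (sorted desc) are assigned to
# haplotypes: dominant haplotype = first haplotype of the dominant group;
# subsequent multi-carrier counts are spread over groups by largest
# remainder of group haplotype share, interleaved round-robin.
order_for_counts <- function(group_of, groups, freqs, dominant_group, n_counts) {
  n_hap <- length(group_of)
  if (is.null(dominant_group)) dominant_group <- groups[which.max(freqs)]
  first_of <- vapply(groups, function(g) which(group_of == g)[1], integer(1))
  dom_hap <- first_of[[dominant_group]]
  order_rest <- integer(0)
  ptr <- setNames(rep(1L, length(groups)), groups)
  ptr[dominant_group] <- 2L
  share <- freqs / sum(freqs)
  credit <- setNames(rep(0, length(groups)), groups)
  for (i in seq_len(n_hap - 1)) {
    credit <- credit + share
    avail <- vapply(groups, function(g)
      ptr[[g]] <= sum(group_of == g), logical(1))
    g <- names(which.max(credit[avail]))
    credit[g] <- credit[g] - 1
    order_rest <- c(order_rest, which(group_of == g)[ptr[[g]]])
    ptr[g] <- ptr[g] + 1L
  }
  c(dom_hap, order_rest)
}

# Distribute individuals across populations. Panmictic at mixing = 1;
# otherwise each population is associated with a "home" group (round-robin
# over groups) and a fraction (1 - mixing) of its slots prefer individuals
# from that group.
assign_populations <- function(ind_ids, group_of_ind, cfg) {
  pop_labels <- rep(names(cfg$pop_sizes), cfg$pop_sizes)
  n <- length(ind_ids)
  if (cfg$population_mixing >= 1) {
    return(setNames(pop_labels[sample.int(n)], ind_ids))
  }
  groups <- unique(group_of_ind)
  home <- setNames(rep(groups, length.out = length(cfg$pop_sizes)),
                   names(cfg$pop_sizes))
  assigned <- rep(NA_character_, n)
  slot_pop <- sample(pop_labels)          # random slot order
  free <- rep(TRUE, n)
  for (s in seq_len(n)) {
    p <- slot_pop[s]
    use_home <- stats::runif(1) > cfg$population_mixing
    cand <- which(free & (!use_home | group_of_ind == home[[p]]))
    if (!length(cand)) cand <- which(free)
    pick <- cand[sample.int(length(cand), 1)]
    assigned[pick] <- p
    free[pick] <- FALSE
  }
  setNames(assigned, ind_ids)
}

#' Simulate a sample under the Kingman coalescent or a star genealogy
#'
#' `constant`: standard n-sample Kingman coalescent with exponential
#' waiting times (`rate k(k-1)/2` while `k` lineages remain, time in units
#' of 2N generations); mutations fall on branches as a Poisson process at
#' rate `theta/2` per unit branch length and each hits a fresh site
#' (infinite-sites, no back mutation). `star`: all lineages coalesce at a
#' single node at depth `2(1 - 1/n)` (the expected coalescent tree height),
#' so every mutation is a singleton - the caricature of a sudden expansion.
#'
#' @param n sample size (`>= 2`).
#' @param theta scaled mutation rate (`> 0`).
#' @param growth_model `"constant"` or `"star"`.
#' @param seq_length alignment width; it is an error for the realized
#'   number of mutations to exceed it (sites are never reused).
#' @param seed optional integer seed.
#' @return A [coi_alignment()] with ids `S001`, `S002`, ...
#' @export
simulate_coalescent <- function(n, theta, growth_model = c("constant", "star"),
                                seq_length = 1000, seed = NULL) {
  growth_model <- match.arg(growth_model)
  stopifnot(n >= 2, theta > 0)
  with_seed(seed, {
    branches <- list()  # each: list(tips, len)
    if (growth_model == "constant") {
      active <- lapply(seq_len(n), function(i) i)
      lens <- rep(0, n)
      while (length(active) > 1) {
        k <- length(active)
        dt <- stats::rexp(1, rate = k * (k - 1) / 2)
        lens <- lens + dt
        pick <- sample.int(k, 2)
        for (j in pick)
          branches[[length(branches) + 1L]] <-
            list(tips = active[[j]], len = lens[j])
        merged <- c(active[[pick[1]]], active[[pick[2]]])
        active <- c(active[-pick], list(merged))
        lens <- c(lens[-pick], 0)
      }
    } else {
      depth <- 2 * (1 - 1 / n)
      for (i in seq_len(n))
        branches[[i]] <- list(tips = i, len = depth)
    }
    n_mut <- vapply(branches, function(b) stats::rpois(1, theta / 2 * b$len),
                    integer(1))
    S <- sum(n_mut)
    if (S > seq_length)
      stop("realized mutations (", S, ") exceed seq_length (", seq_length,
           "); use a longer sequence")
    M <- matrix("A", nrow = n, ncol = seq_length)
    site <- 0L
    for (b in seq_along(branches)) {
      if (n_mut[b] == 0) next
      for (m in seq_len(n_mut[b])) {
        site <- site + 1L
        M[branches[[b]]$tips, site] <- "G"
      }
    }
    coi_alignment(setNames(apply(M, 1, paste, collapse = ""),
                           sprintf("S%03d", seq_len(n))))
  })
}

#' Plant G-quadruplex motifs in a G-free background
#'
#' Builds a random `A/C/T` background (guaranteed G-free) and writes each
#' motif - four G-tracts separated by three random G-free loops - at exact
#' spacings, so a scanner's recovery can be checked against planted truth.
#'
#' @param motifs list of `list(tracts = <4 lengths>, loops = <3 lengths>)`.
#' @param spacings background gaps (bp) between consecutive motifs; length
#'   `length(motifs) - 1`.
#' @param seq_length total sequence length.
#' @param seed optional integer seed.
#' @param offset background bases before the first motif (default 10).
#' @return List with `sequence` (string), `starts`, `ends` (1-based
#'   inclusive motif spans).
#' @export
make_motif_fixture <- function(motifs, spacings = integer(0),
                               seq_length = 600, seed = NULL, offset = 10) {
  stopifnot(length(spacings) == max(0L, length(motifs) - 1L))
  with_seed(seed, {
    bg <- function(k) if (k > 0)
      paste(sample(c("A", "C", "T"), k, replace = TRUE), collapse = "") else ""
    motif_str <- vapply(motifs, function(m) {
      stopifnot(length(m$tracts) == 4, length(m$loops) == 3)
      paste0(strrep("G", m$tracts[1]), bg(m$loops[1]),
             strrep("G", m$tracts[2]), bg(m$loops[2]),
             strrep("G", m$tracts[3]), bg(m$loops[3]),
             strrep("G", m$tracts[4]))
    }, character(1))
    widths <- nchar(motif_str)
    starts <- integer(length(motifs))
    if (length(motifs)) {
      starts[1] <- offset + 1L
      if (length(motifs) > 1)
        for (i in 2:length(motifs))
          starts[i] <- starts[i - 1] + widths[i - 1] + spacings[i - 1]
    }
    ends <- starts + widths - 1L
    if (length(motifs) && max(ends) > seq_length)
      stop("motifs and spacings overflow seq_length (need ", max(ends), ")")
    seqv <- strsplit(bg(seq_length), "")[[1]]
    for (i in seq_along(motifs))
      seqv[starts[i]:ends[i]] <- strsplit(motif_str[i], "")[[1]]
    list(sequence = paste(seqv, collapse = ""), starts = starts, ends = ends)
  })
}
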