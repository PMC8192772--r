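test_that("site classification implements the textbook definitions", {
  # two haplotypes differing at one site: polymorphic, not informative
  ht <- collapse_haplotypes(aln_from(a = "AAAA", b = "AAAT"))
  sc <- classify_sites(ht)
  expect_equal(sum(sc$is_polymorphic), 1)
  expect_equal(sum(sc$is_parsimony_informative), 0)

  # A:2 vs G:2 over four haplotypes: informative transition
  ht2 <- collapse_haplotypes(aln_from(a = "AC", b = "AT", c = "GG", d = "GA"))
  sc2 <- classify_sites(ht2)
  expect_true(sc2$is_parsimony_informative[1])
  expect_equal(sc2$substitution_class[1], "transition")
  expect_equal(sc2$substitution_class[2], "multi-state")
  expect_equal(rowSums(sc2[, c("A", "C", "G", "T")]),
               rep(4, 2), ignore_attr = TRUE)
  # informative implies polymorphic
  expect_true(all(!sc2$is_parsimony_informative | sc2$is_polymorphic))
})

test_that("individual weighting counts carriers instead of haplotypes", {
  aln <- aln_from(a = "A", b = "A", c = "A", d = "G")
  ht <- collapse_haplotypes(aln)
  by_hap <- classify_sites(ht)
  by_ind <- classify_sites(ht, weighting = "individual")
  expect_equal(by_hap$A[1] + by_hap$G[1], 2)
  expect_equal(by_ind$A[1] + by_ind$G[1], 4)
})

test_that("group assignment maps haplotypes to their key strings", {
  aln <- aln_from(h1 = "AAAA", h2 = "AGAA", h3 = "AGAG", h4 = "AGAG")
  ht <- collapse_haplotypes(aln)
  ga <- assign_groups(ht, c(2, 4))
  expect_setequal(names(ga$groups), c("A-A", "G-A", "G-G"))
  expect_equal(ga$sizes[["G-G"]], 1)       # one haplotype (count 2)
  expect_equal(ga$n_individuals[["G-G"]], 2)
  # key strings round-trip against the alignment states
  M <- do.call(rbind, strsplit(ht$sequence, ""))
  expect_equal(unname(ga$assignments),
               paste(M[, 2], M[, 4], sep = "-"))
  # monomorphic key site warns but is retained
  expect_warning(assign_groups(ht, c(1, 2)), "not biallelic")
})

test_that("transition order follows diversity then stepwise Hamming distance", {
  # individual-level fixture whose group diversities are ordered as in the
  # emulated system: A-A-A-A (h = 1) > A-A-G-A > G-G-G-G; G-A-G-A is a
  # lone haplotype
  key <- c(1, 2, 3, 4)
  hap <- function(states, tail_pos = 0) {
    s <- c(strsplit(states, "")[[1]], rep("A", 6))
    if (tail_pos > 0) s[4 + tail_pos] <- "T"
    paste(s, collapse = "")
  }
  seqs <- c(hap("AAAA", 1), hap("AAAA", 2), hap("AAAA", 3),     # h = 1
            hap("AAGA", 1), hap("AAGA", 1), hap("AAGA", 2),     # h = 2/3
            hap("GAGA", 1),                                     # nd
            hap("GGGG", 1), hap("GGGG", 1), hap("GGGG", 1),
            hap("GGGG", 2))                                     # h = 1/2
  names(seqs) <- sprintf("x%02d", seq_along(seqs))
  ht <- collapse_haplotypes(coi_alignment(seqs))
  ga <- assign_groups(ht, key)
  ord <- infer_transition_order(ga)
  expect_equal(ord$order, c("A-A-A-A", "A-A-G-A", "G-A-G-A", "G-G-G-G"))
  # the canonical path changes one site per step except the final
  # two-site step, so the whole path is flagged non-stepwise
  expect_equal(ord$step_sizes, c(1L, 1L, 2L))
  expect_false(ord$stepwise)
  expect_equal(ord$polarity$ancestral_base, rep("A", 4))
  expect_equal(ord$polarity$derived_base, rep("G", 4))
  # invariant to input ordering of sequences
  perm <- rev(seq_along(seqs))
  ht2 <- collapse_haplotypes(coi_alignment(seqs[perm]))
  ord2 <- infer_transition_order(assign_groups(ht2, key))
  expect_equal(ord2$order, ord$order)
  # explicit override
  ord3 <- infer_transition_order(ga, ancestral = "G-G-G-G")
  expect_equal(ord3$order[1], "G-G-G-G")
})

test_that("two groups differing at two key sites are flagged non-stepwise", {
  aln <- aln_from(a = "AAC", b = "AAT", c = "GGC")
  ht <- collapse_haplotypes(aln)
  ga <- assign_groups(ht, c(1, 2))
  ord <- infer_transition_order(ga)
  expect_false(ord$stepwise)
  expect_equal(ord$step_sizes, 2L)
})

test_that("diversity ties for the ancestral group demand an override", {
  aln <- aln_from(a = "AA", b = "AA", c = "GG", d = "GG")
  ht <- collapse_haplotypes(aln)
  ga <- assign_groups(ht, c(1, 2))
  expect_error(infer_transition_order(ga), "tie")
  expect_silent(infer_transition_order(ga, ancestral = "A-A"))
})

test_that("covariance counts same-class haplotypes, checked by brute force", {
  # perfect linkage: every haplotype derived at both or ancestral at both
  aln <- aln_from(h1 = "AATA", h2 = "AATA", h3 = "GATG", h4 = "GCTG",
                  h5 = "GGTG")
  ht <- collapse_haplotypes(aln)
  cv <- covariance_network(ht, sites = c(1, 4))
  expect_equal(cv$covariate_count, n_haplotypes(ht))

  # orthogonal 50/50 states over 20 haplotypes -> covariate count 10
  seqs <- vapply(0:19, function(i) {
    paste0(c("A", "G")[1 + i %% 2], "TT", c("A", "G")[1 + (i %/% 2) %% 2],
           paste(c("A","C","G","T")[1 + (i %/% 4) %% 4], collapse = ""),
           c("A","C","G","T")[1 + (i %/% 8) %% 3])
  }, character(1))
  names(seqs) <- sprintf("o%02d", 1:20)
  ht2 <- collapse_haplotypes(coi_alignment(seqs))
  expect_equal(n_haplotypes(ht2), 20)
  cv2 <- covariance_network(ht2, sites = c(1, 4))
  expect_equal(cv2$covariate_count, 10)

  # brute-force oracle over the default synthetic haplotypes at key sites
  sim <- simulate_expansion_alignment(expansion_sim_config(seed = 13))
  ht3 <- collapse_haplotypes(sim$alignment)
  key <- c(207, 282, 354, 420)
  cv3 <- covariance_network(ht3, sites = key)
  M <- do.call(rbind, strsplit(ht3$sequence, ""))
  for (r in seq_len(nrow(cv3))) {
    i <- cv3$site_i[r]; j <- cv3$site_j[r]
    maj_i <- names(which.max(table(M[, i])))
    maj_j <- names(which.max(table(M[, j])))
    brute <- sum((M[, i] == maj_i) == (M[, j] == maj_j))
    expect_equal(cv3$covariate_count[r], brute)
  }
  expect_equal(cv3$frequency_ratio, cv3$covariate_count / n_haplotypes(ht3))
  # multi-allelic request errors with the site named
  aln4 <- aln_from(a = "AC", b = "CC", c = "GC", d = "TA", e = "TA")
  expect_error(covariance_network(collapse_haplotypes(aln4), sites = c(1, 2)),
               "multi-allelic.*1")
})

test_that("codon annotation finds the frame and classifies synonymy", {
  # frame 1, table 5: GGA <-> GGG third-position swap is synonymous (Gly),
  # TTA <-> ATA first-position swap is nonsynonymous (Leu vs Met)
  aln <- aln_from(h1 = "GGATTACCA", h2 = "GGGTTACCA", h3 = "GGAATACCA")
  ann <- annotate_codon_synonymy(aln)
  expect_equal(attr(ann, "frame"), 1L)
  expect_equal(ann$codon_position, rep(1:3, 3))
  expect_true(ann$is_synonymous[3])     # GGA/GGG
  expect_false(ann$is_synonymous[4])    # TTA/ATA
  # frame shifted by 2 on a realistic coding fragment: stop minimization
  # recovers the true frame (wrong frames of a long CDS contain stops)
  sim <- simulate_expansion_alignment(expansion_sim_config(seed = 4))
  cds <- sim$truth$hap_sequences[1:2]
  shifted <- coi_alignment(setNames(paste0("TT", substr(cds, 1, 591)),
                                    c("h1", "h2")))
  ann2 <- annotate_codon_synonymy(shifted)
  expect_equal(attr(ann2, "frame"), 3L)
  # a sequence with stops in all three frames errors (TAAG repeats put a
  # TAA codon in every phase)
  stops <- aln_from(h1 = strrep("TAAG", 9), h2 = strrep("TAAG", 9))
  expect_error(annotate_codon_synonymy(stops), "stops")
})

test_that("key sites of the emulated fragment are third codon positions", {
  sim <- simulate_expansion_alignment(expansion_sim_config(seed = 2))
  ht <- collapse_haplotypes(sim$alignment)
  ann <- annotate_codon_synonymy(hap_alignment(ht))
  expect_equal(attr(ann, "frame"), 1L)
  expect_equal(ann$codon_position[c(207, 282, 354, 420)], rep(3L, 4))
  # all planted mutations are synonymous third-position transitions
  expect_true(all(ann$is_synonymous[ann$is_polymorphic], na.rm = TRUE))
})
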