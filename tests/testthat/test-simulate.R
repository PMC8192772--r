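test_that("the default synthetic world reproduces its stated structure", {
  sim <- simulate_expansion_alignment(expansion_sim_config(seed = 1))
  expect_equal(n_sequences(sim$alignment), 140)
  ht <- collapse_haplotypes(sim$alignment)
  expect_equal(n_haplotypes(ht), 58)
  # planted partition recovered exactly
  expect_setequal(ht$sequence, sim$truth$hap_sequences)
  expect_equal(sort(ht$count, decreasing = TRUE),
               sort(sim$truth$counts_of_hap, decreasing = TRUE))
  # group sizes land exactly on the planted table
  ga <- assign_groups(ht, sim$truth$key_positions)
  expect_equal(ga$sizes[c("A-A-A-A", "A-A-G-A", "G-A-G-A", "G-G-G-G")],
               c("A-A-A-A" = 35L, "A-A-G-A" = 12L, "G-A-G-A" = 1L,
                 "G-G-G-G" = 8L))
  expect_equal(sum(ga$sizes), 58L)
  # planted site budget recovered: 71 polymorphic, 31 informative
  sc <- classify_sites(ht)
  expect_equal(sum(sc$is_polymorphic), sim$truth$n_polymorphic)
  expect_equal(sum(sc$is_parsimony_informative), sim$truth$n_informative)
  expect_equal(sim$truth$n_polymorphic, 71L)
  expect_equal(sim$truth$n_informative, 31L)
  # ancestral group by diversity is the A-A-A-A group, and the canonical
  # four-group sub-path is stepwise A -> G
  ord <- infer_transition_order(ga)
  expect_equal(ord$order[1], "A-A-A-A")
  canonical <- ord$order[ord$order %in%
                           c("A-A-A-A", "A-A-G-A", "G-A-G-A", "G-G-G-G")]
  expect_equal(canonical, c("A-A-A-A", "A-A-G-A", "G-A-G-A", "G-G-G-G"))
  expect_equal(ord$polarity$ancestral_base, rep("A", 4))
  expect_equal(ord$polarity$derived_base, rep("G", 4))
})

test_that("same seed gives byte-identical simulations, different seeds differ", {
  s1 <- simulate_expansion_alignment(expansion_sim_config(seed = 42))
  s2 <- simulate_expansion_alignment(expansion_sim_config(seed = 42))
  expect_identical(s1, s2)
  s3 <- simulate_expansion_alignment(expansion_sim_config(seed = 43))
  expect_false(identical(s1$alignment$seq, s3$alignment$seq))
})

test_that("degenerate configuration gives a single haplotype", {
  cfg <- expansion_sim_config(n_individuals = 10,
                              group_freqs = c("A-A-A-A" = 1),
                              n_singleton_sites = 0, n_shared_sites = 0,
                              pop_sizes = c(P1 = 10), dominant_count = 10,
                              seed = 3)
  sim <- simulate_expansion_alignment(cfg)
  ht <- collapse_haplotypes(sim$alignment)
  expect_equal(n_haplotypes(ht), 1)
  expect_equal(diversity_summary(sim$alignment)$h, 0)
})

test_that("the planted fragment is a clean CDS under the mito code", {
  sim <- simulate_expansion_alignment(expansion_sim_config(seed = 6))
  gc5 <- Biostrings::getGeneticCode("5")
  for (s in sim$truth$hap_sequences[1:5]) {
    codons <- substring(s, seq(1, 593, 3), seq(3, 595, 3))
    expect_false(any(gc5[codons] == "*"))
  }
})

test_that("coalescent samples behave like their models", {
  # n = 2: S ~ Poisson(theta) across replicates
  theta <- 3
  S <- vapply(1:300, function(i) {
    a <- simulate_coalescent(2, theta, "constant", seq_length = 200,
                             seed = 2000 + i)
    count_segregating_sites(a)
  }, integer(1))
  se <- sqrt(var(S) / length(S))
  expect_lt(abs(mean(S) - theta), 3 * max(se, sqrt(theta / length(S))))

  # star genealogies: every mutation is a singleton
  st <- simulate_coalescent(20, 5, "star", seed = 77)
  M <- do.call(rbind, strsplit(st$seq, ""))
  derived <- colSums(M == "G")
  expect_true(all(derived[derived > 0] == 1))

  # infeasible sequence length errors rather than reusing sites
  expect_error(simulate_coalescent(30, 50, "constant", seq_length = 5,
                                   seed = 1), "seq_length")
})

test_that("motif fixtures are G-free outside the planted motifs", {
  fix <- make_motif_fixture(list(list(tracts = c(2, 2, 2, 2),
                                      loops = c(3, 3, 3))),
                            seq_length = 60, seed = 9)
  chars <- strsplit(fix$sequence, "")[[1]]
  outside <- chars[-(fix$starts[1]:fix$ends[1])]
  expect_false("G" %in% outside)
  # empty motif list: G-free sequence, scanner finds nothing
  none <- make_motif_fixture(list(), seq_length = 50, seed = 9)
  expect_equal(nrow(enumerate_g4(none$sequence, g4_config(g_min = 1))), 0)
  # overflow errors
  expect_error(make_motif_fixture(list(list(tracts = c(2, 2, 2, 2),
                                            loops = c(3, 3, 3))),
                                  seq_length = 20, seed = 1), "overflow")
})
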