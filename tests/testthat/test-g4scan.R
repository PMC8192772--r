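test_that("candidate enumeration handles the canonical single-configuration case", {
  cand <- enumerate_g4("GGTTGGTTGGTTGG")
  expect_equal(nrow(cand), 1)
  expect_equal(cand$start, 1)
  expect_equal(cand$end, 14)
  expect_equal(cand$loops, "2,2,2")
  expect_equal(cand$score, 18)          # 20*(2-1) - 2 - 0

  # G-free sequence: nothing
  expect_equal(nrow(enumerate_g4("ACTACTACTACT")), 0)
  # U is treated as T
  expect_equal(nrow(enumerate_g4("GGUUGGUUGGUUGG")), 1)
})

test_that("the relaxed single-G motif geometry is recovered", {
  # G2-N6-G2-N15-G2-N11-G motif (g_min = 1)
  fix <- make_motif_fixture(list(list(tracts = c(2, 2, 2, 1),
                                      loops = c(6, 15, 11))),
                            seq_length = 70, seed = 17)
  cfg <- g4_config(g_min = 1)
  cand <- enumerate_g4(fix$sequence, cfg)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$loops, "6,15,11")
  expect_equal(cand$start, fix$starts[1])
  expect_equal(cand$end, fix$ends[1])
  # the documented surrogate score of this weak motif
  expect_equal(cand$score, -32 / 3 - 9, tolerance = 1e-9)
})

test_that("scoring is monotone in loop evenness", {
  cfg <- g4_config()
  even <- score_g4(2, mean(c(4, 4, 4)), 0, cfg)
  uneven <- score_g4(2, mean(c(1, 4, 7)), 6, cfg)
  expect_gt(even, uneven)   # same mean loop, same tracts
})

test_that("greedy selection respects scores, passes and disjointness", {
  # two disjoint candidates: both selected in pass 1
  two <- enumerate_g4(paste0("GGTTGGTTGGTTGG", strrep("A", 30),
                             "GGTTGGTTGGTTGG"))
  sel <- select_nonoverlapping(two)
  expect_equal(nrow(sel), 2)
  expect_equal(sel$pass, c(1L, 1L))

  # overlapping candidates: higher score wins pass 1, loser moves to pass 2
  s <- "GGGTGGGTGGGTGGGTGG"   # several overlapping candidates
  cand <- enumerate_g4(s)
  sel2 <- select_nonoverlapping(cand)
  p1 <- sel2[sel2$pass == 1, ]
  expect_equal(max(sel2$score), max(cand$score))
  expect_equal(p1$score[1], max(cand$score))
  # within every pass, selections are pairwise disjoint
  for (k in unique(sel2$pass)) {
    pk <- sel2[sel2$pass == k, ]
    if (nrow(pk) > 1) {
      o <- order(pk$start)
      expect_true(all(pk$start[o][-1] > pk$end[o][-nrow(pk)]))
    }
  }
  # total selected count non-decreasing in max_passes
  n_sel <- vapply(1:4, function(mp)
    nrow(select_nonoverlapping(cand, g4_config(max_passes = mp))),
    integer(1))
  expect_true(all(diff(n_sel) >= 0))

  # determinism: scanning a copy yields identical results
  expect_identical(select_nonoverlapping(enumerate_g4(s)), sel2)
})

test_that("enumeration equals the brute-force oracle on random sequences", {
  set.seed(71)
  for (rep in 1:50) {
    n <- sample(30:100, 1)
    s <- random_dna(n, c("A", "C", "G", "T"))
    cfg <- g4_config(g_min = sample(1:2, 1), loop_max = sample(c(7, 12, 20), 1))
    got <- enumerate_g4(s, cfg)
    want <- oracle_g4(s, cfg$g_min, cfg$loop_min, cfg$loop_max)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      o <- order(got$start, got$end, got$loop1, got$loop2)
      expect_equal(got$start[o], unname(want[, "start"]))
      expect_equal(got$end[o], unname(want[, "end"]))
      expect_equal(got$loop1[o], unname(want[, "l1"]))
      expect_equal(got$loop3[o], unname(want[, "l3"]))
    }
  }
})

test_that("four planted motifs at the studied spacings are recovered exactly", {
  motifs <- list(list(tracts = c(2, 2, 2, 1), loops = c(6, 15, 11)),
                 list(tracts = c(2, 2, 2, 1), loops = c(2, 5, 5)),
                 list(tracts = c(2, 2, 2, 1), loops = c(1, 4, 19)),
                 list(tracts = c(1, 2, 2, 1), loops = c(8, 10, 22)))
  fix <- make_motif_fixture(motifs, spacings = c(57, 39, 65),
                            seq_length = 400, seed = 23)
  cfg <- g4_config(g_min = 1, loop_max = 22)
  sel <- select_nonoverlapping(enumerate_g4(fix$sequence, cfg), cfg)
  p1 <- sel[sel$pass == 1, ]
  expect_equal(nrow(p1), 4)
  expect_equal(p1$start, fix$starts)
  expect_equal(p1$end, fix$ends)
  # spacings preserved: gaps between consecutive recovered motifs
  expect_equal(p1$start[-1] - p1$end[-4] - 1L, c(57L, 39L, 65L))
})

test_that("hotspot linkage ties motifs to key sites per haplotype", {
  # build two 'haplotypes': one with G at a key site inside a motif, one
  # with A there (motif destroyed at the key tract)
  motif <- "GGTTTTGGTTTTGGTTTTGG"
  left <- strrep("A", 30)
  right <- strrep("T", 30)
  hap_g <- paste0(left, motif, right)
  hap_a <- paste0(left, sub("GG$", "AG", motif), right)
  aln <- coi_alignment(c(g = hap_g, a = hap_a, g2 = hap_g, a2 = hap_a,
                         a3 = paste0(left, strrep("C", 20), right)))
  ht <- collapse_haplotypes(aln)
  key <- 49L    # inside the final G-tract of the motif
  scan <- scan_alignment_hotspots(ht, key, g4_config())
  linked <- scan[scan$linked_sites == "49", ]
  hap_of_g <- ht$hap_id[ht$sequence == hap_g]
  expect_true(hap_of_g %in% linked$hap_id)
  hap_of_a <- ht$hap_id[ht$sequence == hap_a]
  expect_false(hap_of_a %in% linked$hap_id)
  # haplotype with no G runs at all: zero candidates
  hap_c <- ht$hap_id[grepl("C", ht$sequence)]
  expect_false(hap_c %in% scan$hap_id)
  # summary table sees the derived-state dependence
  ga <- suppressWarnings(assign_groups(ht, key))  # 3 states at the key site
  summ <- hotspot_g4_summary(scan, ht, ga)
  g_grp <- summ[summ$group == "G", ]
  a_grp <- summ[summ$group == "A", ]
  expect_gt(g_grp$n_linked, 0)
  expect_equal(a_grp$n_linked, 0)
})
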