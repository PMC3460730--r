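test_that("percentile-range sharing splits bins into common and specific sets", {
  a <- make_track(seq(0.1, 1, 0.1) - 0.55)   # ascending R over 10 bins
  # identical tracks: all in-range bins common
  pg <- percentile_group_bins(list(chr1 = a), list(chr1 = a), c(90, 100))
  expect_equal(pg$common$bin, 9)
  expect_equal(nrow(pg$a_specific), 0)
  expect_equal(nrow(pg$b_specific), 0)

  # reversed ranking: top decile disjoint
  b <- make_track(rev(a$R))
  pg2 <- percentile_group_bins(list(chr1 = a), list(chr1 = b), c(90, 100))
  expect_equal(nrow(pg2$common), 0)
  expect_equal(pg2$a_specific$bin, 9)
  expect_equal(pg2$b_specific$bin, 0)

  # a's top bin is 7, b's top bin is 3
  Ra <- c(1:7, 10, 8, 9) / 10; Rb <- Ra[c(4, 2, 3, 8, 5, 6, 7, 1, 9, 10)]
  pg3 <- percentile_group_bins(list(chr1 = make_track(Ra - 0.05)),
                               list(chr1 = make_track(Rb - 0.05)), c(90, 100))
  expect_equal(pg3$a_specific$bin, 7)
  expect_equal(pg3$b_specific$bin, 3)
  # common + a-specific covers all A bins in range
  expect_equal(nrow(pg3$common) + nrow(pg3$a_specific), 1)
  expect_error(percentile_group_bins(list(chr1 = a), list(chr1 = a), c(50, 50)),
               "interval")
})

test_that("pair dynamics cross-tabulates Same/Diff/Minus with rows summing to 1", {
  # condition A: bins 0..7 clustered as {0..3}, {4..7} -> pairs (3,4) Diff, rest Same
  ca <- make_clusters("chr1", 0:7, rep(1:2, each = 4))
  trb_same <- make_track(rep(0.5, 8), d = 1)
  cb_same <- make_clusters("chr1", 0:7, rep(1:2, each = 4))
  pd <- pair_dynamics(ca, cb_same, list(chr1 = trb_same))
  expect_equal(unname(rowSums(pd$fractions)), c(1, 1))
  expect_equal(pd$fractions["Same", "Same"], 1)
  expect_equal(pd$fractions["Diff", "Diff"], 1)

  # all-minus condition B: every pair lands in Minus
  trb_minus <- make_track(rep(-0.5, 8), d = 1)
  cb_empty <- make_clusters(character(), integer(), integer())
  pd2 <- pair_dynamics(ca, cb_empty, list(chr1 = trb_minus))
  expect_equal(unname(pd2$fractions[, "Minus"]), c(1, 1))

  # hand-built mixed case: 4 Diff pairs in A -> 1 Diff, 2 Same, 1 Minus in B
  ca2 <- make_clusters("chr1", 0:7, c(1, 1, 2, 2, 3, 3, 4, 4))
  # Diff pairs in A: (1,2), (3,4), (5,6) -- only 3; extend to 4 with {8,9}
  ca3 <- make_clusters("chr1", 0:9, c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5))
  # B: (1,2) same cluster; (3,4) different; (5,6) one minus; (7,8) same
  st_b <- rep(0.5, 10); st_b[6] <- -0.5
  trb <- make_track(st_b, d = 1)
  cb <- make_clusters("chr1", c(0:5, 7:9),
                      c(1, 1, 1, 2, 3, 3, 9, 9, 9))
  pd3 <- pair_dynamics(ca3, cb, list(chr1 = trb))
  expect_equal(sum(pd3$counts["Diff", ]), 4)
  expect_equal(unname(pd3$counts["Diff", c("Same", "Diff", "Minus")]),
               c(2, 1, 1))
  expect_equal(unname(pd3$fractions["Diff", ]), c(0.5, 0.25, 0.25))
})

test_that("boundary classification splits common from A-specific bins", {
  a <- make_clusters("chr1", c(3:9, 14:18), c(rep(1, 7), rep(2, 5)))
  # A boundaries: {3, 9, 14, 18}
  b_same <- make_clusters("chr1", c(3:9, 14:18), c(rep(5, 7), rep(6, 5)))
  bc <- classify_boundaries(a, b_same)
  expect_equal(sort(bc$bin), c(3, 9, 14, 18))
  expect_true(all(bc$class == "common"))

  b_none <- make_clusters(character(), integer(), integer())
  bc2 <- classify_boundaries(a, b_none)
  expect_true(all(bc2$class == "a_specific"))

  # A boundaries {3,9}, B boundaries {9,14}: common {9}, specific {3}
  a2 <- make_clusters("chr1", 3:9, rep(1, 7))
  b2 <- make_clusters("chr1", 9:14, rep(1, 6))
  bc3 <- classify_boundaries(a2, b2)
  expect_equal(bc3$class[bc3$bin == 9], "common")
  expect_equal(bc3$class[bc3$bin == 3], "a_specific")
  # common + specific = all A boundary bins
  expect_equal(nrow(bc3), sum(a2$bins$label == "boundary"))
})

test_that("cluster Jaccard matches set arithmetic and is symmetric", {
  a <- make_clusters("chr1", 1:3, rep(1, 3))
  b <- make_clusters("chr1", 2:4, rep(7, 3))
  expect_equal(cluster_jaccard("chr1", 2, a, b), 0.5)
  expect_equal(cluster_jaccard("chr1", 2, b, a), 0.5)
  expect_equal(cluster_jaccard("chr1", 2, a, a), 1.0)

  # overlap is only the query bin, |C_a| = |C_b| = 5 -> 1/9
  a5 <- make_clusters("chr1", c(6:10), rep(1, 5))
  b5 <- make_clusters("chr1", c(10, 20:23), rep(2, 5))
  expect_equal(cluster_jaccard("chr1", 10, a5, b5), 1 / 9)
  expect_error(cluster_jaccard("chr1", 99, a, b), "not clustered")
})

test_that("differential-expression association ranks bins by DE proportion", {
  grid <- bin_grid(c(chr1 = 2e6), 1e5)
  tra <- make_track(rep(0.5, 20), d = 1)
  # A: two clusters; B: first cluster identical, second rearranged
  ca <- make_clusters("chr1", 0:19, rep(1:2, each = 10))
  cb <- make_clusters("chr1", 0:19, c(rep(1, 10), rep(2:3, each = 5)))
  genes <- data.frame(gene = paste0("g", 1:20), chrom = "chr1",
                      tss = (0:19) * 1e5 + 50, strand = "+", expr = 1)
  de <- paste0("g", 11:20)   # DE genes sit in the rearranged half
  da <- de_association(ca, cb, list(chr1 = tra), list(chr1 = tra),
                       genes, de, grid, top_frac = 0.25, bottom_frac = 0.25)
  expect_lt(da$mean_j_top, da$mean_j_bottom)
  expect_equal(da$mean_j_bottom, 1)
  expect_equal(da$n_ranked, 20)

  # constant DE proportion: top and bottom draw from the same distribution
  da2 <- de_association(ca, ca, list(chr1 = tra), list(chr1 = tra),
                        genes, character(), grid)
  expect_equal(da2$mean_j_top, da2$mean_j_bottom)
})

test_that("enrichment scores separate common from specific bins on planted data", {
  # housekeeping-like genes concentrated in bins shared by both conditions
  grid <- bin_grid(c(chr1 = 5e6), 1e5)
  common_bins <- data.frame(chrom = "chr1", bin = 0:4)
  hk <- data.frame(gene = paste0("hk", 1:30), chrom = "chr1",
                   tss = c(rep(2e5, 25), rep(4.5e6, 5)), strand = "+", expr = 1)
  sc_common <- gene_set_enrichment_score(common_bins, hk, 50, grid)
  sc_rand <- gene_set_enrichment_score(data.frame(chrom = "chr1", bin = 40:44),
                                       hk, 50, grid)
  expect_gt(sc_common$score, 10)
  expect_lt(sc_rand$score, 2)
})
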