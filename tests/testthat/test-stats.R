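grid10 <- bin_grid(c(chr1 = 1e6), 1e5)

# features placed one per listed bin (positions at bin midpoints)
bins_as_features <- function(bins, chrom = "chr1", bs = 1e5) {
  data.frame(chrom = chrom, pos = bins * bs + bs / 2)
}

test_that("within/across fold is the ratio of mean per-pair counts", {
  # two clusters {0,1} and {3,4}: within pairs (0,1),(3,4); across (0,3),(0,4),(1,3),(1,4)
  cl <- make_clusters("chr1", c(0, 1, 3, 4), c(1, 1, 2, 2))
  m <- contact_map("chr1", 10,
                   c(0, 3, 0, 0, 1, 1), c(1, 4, 3, 4, 3, 4),
                   c(4, 4, 2, 2, 2, 2))
  wf <- within_across_fold(list(chr1 = m), cl)
  expect_equal(wf$fold, 2)
  expect_equal(wf$n_within, 2)
  expect_equal(wf$n_across, 4)
})

test_that("small-sample rank-sum p matches the hand-enumerated tail", {
  # within (3,5), across (1,3): pooled mid-ranks (1, 2.5, 2.5, 4);
  # W_within = 6.5; of the 6 equally likely assignments, 2 reach >= 6.5
  cl <- make_clusters("chr1", c(0, 1, 3, 4), c(1, 1, 2, 2))
  m <- contact_map("chr1", 10,
                   c(0, 3, 0, 0, 1, 1), c(1, 4, 3, 4, 3, 4),
                   c(3, 5, 1, 3, 0, 0))
  # keep only pairs (0,1)=3,(3,4)=5 within and (0,3)=1,(0,4)=3 across:
  # restrict clusters so (1,3),(1,4) do not exist as clustered pairs
  cl2 <- make_clusters("chr1", c(0, 1, 3, 4), c(1, 1, 2, 2))
  pc <- hicratio:::cluster_pair_counts(list(chr1 = m), cl2)
  expect_setequal(pc$within, c(3, 5))
  p <- hicratio:::ranksum_exact_p(c(3, 5), c(1, 3))
  expect_equal(p, 1 / 3)
  # identical distributions give fold 1 and an unremarkable p
  m2 <- contact_map("chr1", 10, c(0, 3, 0, 0, 1, 1), c(1, 4, 3, 4, 3, 4),
                    rep(3, 6))
  wf2 <- within_across_fold(list(chr1 = m2), cl)
  expect_equal(wf2$fold, 1)
  expect_gte(wf2$p_value, 0.3)
})

test_that("null replicates conserve per-distance totals exactly and are seeded", {
  plan <- make_plan(c(chr1 = 200), seed = 8)
  maps <- sample_contacts(plan, sim_params(), seed = 9)
  tracks <- segment_maps(maps)
  cl <- cluster_genome(maps, tracks)
  ne <- simulate_null(maps, cl, n_reps = 5, seed = 3, keep_maps = TRUE)
  obs <- hicratio:::distance_totals(maps$chr1)
  obs <- obs[as.integer(names(obs)) >= 1]
  for (r in 1:5) {
    expect_equal(unname(ne$rep_distance_totals$chr1[r, ]), unname(obs))
    rep_tot <- hicratio:::distance_totals(ne$maps[[r]]$chr1)
    expect_equal(rep_tot[names(obs)], obs)
  }
  ne2 <- simulate_null(maps, cl, n_reps = 5, seed = 3)
  expect_identical(ne$folds, ne2$folds)
})

test_that("boundary enrichment reproduces the density-ratio example", {
  # 5 clusters of 8 consecutive bins: 10 boundary, 30 interior bins;
  # 20 features on boundaries, 30 on interiors -> fold (20/10)/(30/30) = 2
  cl <- make_clusters("chr1", 0:39, rep(1:5, each = 8))
  grid40 <- bin_grid(c(chr1 = 4e6), 1e5)
  bbins <- cl$bins$bin[cl$bins$label == "boundary"]
  ibins <- cl$bins$bin[cl$bins$label == "interior"]
  expect_equal(length(bbins), 10)
  expect_equal(length(ibins), 30)
  feats <- bins_as_features(c(rep(bbins, 2), ibins))
  r <- boundary_enrichment(feats, cl, grid40)
  expect_equal(r$fold, 2)
  expect_equal(r$k_boundary, 20)
  expect_equal(r$k_interior, 30)

  # uniform features over all eligible bins -> fold exactly 1
  r3 <- boundary_enrichment(bins_as_features(0:39), cl, grid40)
  expect_equal(r3$fold, 1)
})

test_that("boundary binomial tail is exact on a 5/5 bin split (56/1024)", {
  # cluster 1 = run {0..3} plus distal {8} (3 boundary, 2 interior);
  # cluster 2 = run {20..24} (2 boundary, 3 interior) -> 5 boundary, 5 interior
  cl <- make_clusters("chr1", c(0:3, 8, 20:24), c(rep(1, 5), rep(2, 5)))
  grid40 <- bin_grid(c(chr1 = 4e6), 1e5)
  expect_equal(sum(cl$bins$label == "boundary"), 5)
  expect_equal(sum(cl$bins$label == "interior"), 5)
  feats <- bins_as_features(c(0, 3, 8, 20, 24, 0, 3, 8, 1, 21))  # k=8, m=2
  r <- boundary_enrichment(feats, cl, grid40)
  expect_equal(r$k_boundary, 8)
  expect_equal(r$k_interior, 2)
  expect_equal(r$p_value, 56 / 1024, tolerance = 1e-12)
})

test_that("gene-set enrichment score is the exact -log10 binomial tail", {
  # n = 20 genes, p0 = 0.25, k = 10 -> p ~ 0.0139, score ~ 1.86
  grid <- bin_grid(c(chr1 = 4e6), 1e5)
  g <- data.frame(gene = paste0("g", 1:20), chrom = "chr1",
                  tss = c(rep(50000, 10), rep(3950000, 10)),
                  strand = "+", expr = 1)
  sc <- gene_set_enrichment_score(data.frame(chrom = "chr1", bin = 0:9),
                                  g, all_bins = 40, grid)
  expect_equal(sc$p0, 0.25)
  expect_equal(sc$k, 10)
  p_exact <- sum(choose(20, 10:20) * 0.25^(10:20) * 0.75^(10:0))
  expect_equal(sc$p_value, p_exact, tolerance = 1e-12)
  expect_equal(sc$score, -log10(p_exact), tolerance = 1e-9)
  # k at the expectation scores near zero
  expect_lt(gene_set_enrichment_score(
    data.frame(chrom = "chr1", bin = 0:9),
    data.frame(gene = paste0("h", 1:8), chrom = "chr1",
               tss = c(rep(50000, 2), rep(3950000, 6)),
               strand = "+", expr = 1),
    all_bins = 40, grid)$score, 0.6)
})

test_that("uniform-feature null keeps the binomial p super-uniform", {
  cl <- make_clusters("chr1", 0:99, rep(1:10, each = 10))
  grid100 <- bin_grid(c(chr1 = 1e7), 1e5)
  set.seed(77)
  hits <- 0
  for (rep in 1:500) {
    feats <- bins_as_features(sample(0:99, 120, replace = TRUE))
    p <- boundary_enrichment(feats, cl, grid100)$p_value
    if (p <= 0.05) hits <- hits + 1
  }
  expect_lte(hits / 500, 0.07)
})

test_that("expression tiers split 25/50/25 and rank boundary placement", {
  cl <- make_clusters("chr1", 0:19, rep(1:2, each = 10))
  grid20 <- bin_grid(c(chr1 = 2e6), 1e5)
  bbins <- cl$bins$bin[cl$bins$label == "boundary"]
  ibins <- cl$bins$bin[cl$bins$label == "interior"]
  # 8 genes, expressions 1..8: top tier = {7, 8}
  g8 <- data.frame(gene = paste0("g", 1:8), chrom = "chr1",
                   tss = c(ibins[1:6], bbins[1:2]) * 1e5 + 10,
                   strand = "+", expr = 1:8)
  res <- expression_tier_enrichment(g8, cl, grid20)
  expect_equal(res$k_boundary[res$feature == "expr_top25"] +
                 res$k_interior[res$feature == "expr_top25"], 2)
  # top genes sit only in boundary bins -> highest fold
  expect_gt(res$fold[res$feature == "expr_top25"],
            max(res$fold[res$feature != "expr_top25"]))
  expect_error(expression_tier_enrichment(g8[1:3, ], cl, grid20), ">= 4 genes")
  g8c <- g8; g8c$expr <- 5
  expect_error(expression_tier_enrichment(g8c, cl, grid20), "constant")
})

test_that("p-value adjustment follows BH and Bonferroni", {
  mk <- function(p) {
    r <- data.frame(feature = paste0("f", seq_along(p)), fold = 1,
                    p_value = p, adj_p = NA_real_, k_boundary = 1,
                    k_interior = 1, n_boundary_bins = 1, n_interior_bins = 1)
    class(r) <- c("enrichment_result", "data.frame")
    r
  }
  one <- adjust_pvalues(mk(0.04))
  expect_equal(one$adj_p, 0.04)
  bh <- adjust_pvalues(mk(c(0.01, 0.02, 0.03)))
  expect_equal(bh$adj_p, c(0.03, 0.03, 0.03))
  bf <- adjust_pvalues(mk(rep(0.02, 35)), method = "bonferroni")
  expect_equal(bf$adj_p, rep(0.7, 35))
  expect_error(adjust_pvalues(mk(1.2)), "outside")
})
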