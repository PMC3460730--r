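#' Within- versus across-cluster interaction fold
#'
#' Compares per-pair interaction counts between bin pairs lying in the same
#' cluster and pairs of clustered bins (same chromosome) in different
#' clusters. All unordered pairs of clustered bins enter, with count 0 for
#' pairs absent from the sparse map. The fold is the ratio of the two means;
#' the p-value is a one-sided rank-sum test (within > across), computed by
#' exact mid-rank enumeration when the pooled sample is small and by
#' `stats::wilcox.test` otherwise.
#'
#' @param maps named list of min-span-filtered [contact_map()].
#' @param clusters a `cluster_set`.
#' @param enum_limit exact enumeration is used when the pooled pair count is
#'   at most this (default 12).
#' @return list with `fold`, `p_value`, `n_within`, `n_across`,
#'   `mean_within`, `mean_across`.
#' @export
within_across_fold <- function(maps, clusters, enum_limit = 12) {
  pc <- cluster_pair_counts(maps, clusters)
  if (!length(pc$across)) stop("no across-cluster pairs")
  if (!length(pc$within)) stop("no within-cluster pairs")
  mw <- mean(pc$within); ma <- mean(pc$across)
  if (ma == 0) stop("across-cluster mean count is zero")
  n <- length(pc$within) + length(pc$across)
  p <- if (n <= enum_limit) {
    ranksum_exact_p(pc$within, pc$across)
  } else {
    suppressWarnings(stats::wilcox.test(pc$within, pc$across,
                                        alternative = "greater")$p.value)
  }
  list(fold = mw / ma, p_value = p,
       n_within = length(pc$within), n_across = length(pc$across),
       mean_within = mw, mean_across = ma)
}

# per-pair counts for all unordered pairs of clustered bins, split by
# whether the two bins share a cluster
cluster_pair_counts <- function(maps, clusters) {
  within <- list(); across <- list()
  for (chrom in names(maps)) {
    cb <- clusters$bins[clusters$bins$chrom == chrom, ]
    if (nrow(cb) < 2) next
    map <- maps[[chrom]]
    bins <- sort(cb$bin)
    cl <- cb$cluster[match(bins, cb$bin)]
    pr <- utils::combn(seq_along(bins), 2)
    b1 <- bins[pr[1, ]]; b2 <- bins[pr[2, ]]
    same <- cl[pr[1, ]] == cl[pr[2, ]]
    key <- pair_keys(b1, b2, map$lc)
    mkey <- pair_keys(map$bin1, map$bin2, map$lc)
    cnt <- map$count[match(key, mkey)]
    cnt[is.na(cnt)] <- 0
    within[[chrom]] <- cnt[same]
    across[[chrom]] <- cnt[!same]
  }
  list(within = unlist(within, use.names = FALSE) %||% numeric(),
       across = unlist(across, use.names = FALSE) %||% numeric())
}

# exact one-sided rank-sum tail by enumeration of all group assignments,
# using mid-ranks so ties are handled exactly
ranksum_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)])
  combs <- utils::combn(length(pooled), length(x))
  stat <- colSums(matrix(r[combs], nrow = length(x)))
  mean(stat >= obs - 1e-12)
}

#' Distance-preserving simulated null for the within/across fold
#'
#' For each replicate and each genomic distance `t` present in the observed
#' (filtered) map, exactly the observed number of interactions at `t` is
#' distributed uniformly at random over the `lc - t` bin pairs at that
#' distance; the within/across fold is then recomputed against the same
#' cluster set. Per-distance totals are conserved exactly in every
#' replicate by construction (multinomial sampling of fixed size).
#'
#' @param maps named list of observed min-span-filtered [contact_map()].
#' @param clusters a `cluster_set`.
#' @param n_reps number of replicates (the full-scale analysis uses 1,000;
#'   desk-scale tests use 200).
#' @param seed integer seed fixing all randomness.
#' @param keep_maps also return each replicate's maps (memory-heavy; for
#'   verification only).
#' @return a `null_ensemble`: list with `observed_fold`, `folds` (length
#'   `n_reps`), `rep_distance_totals` (list per chromosome: `n_reps` x
#'   distances matrix of realized totals), `n_reps`, `seed`, and optionally
#'   `maps` (list of per-replicate map lists).
#' @export
simulate_null <- function(maps, clusters, n_reps = 1000, seed = 1,
                          keep_maps = FALSE) {
  stopifnot(n_reps >= 1)
  set.seed(seed)
  # observed fold and fixed pair partition
  obs <- within_across_fold(maps, clusters)
  # precompute, per chromosome and distance, which of the lc - t pairs are
  # within / across pairs of clustered bins
  setup <- list()
  for (chrom in names(maps)) {
    map <- maps[[chrom]]
    dt <- distance_totals(map)
    dt <- dt[as.integer(names(dt)) >= 1]
    if (!length(dt)) next
    cb <- clusters$bins[clusters$bins$chrom == chrom, ]
    clv <- rep(NA_integer_, map$lc)
    if (nrow(cb)) clv[cb$bin + 1] <- cb$cluster
    per_t <- lapply(as.integer(names(dt)), function(t) {
      m <- 0:(map$lc - 1 - t)
      c1 <- clv[m + 1]; c2 <- clv[m + t + 1]
      both <- !is.na(c1) & !is.na(c2)
      list(t = t, within = which(both & c1 == c2),
           across = which(both & c1 != c2))
    })
    setup[[chrom]] <- list(lc = map$lc, totals = dt, per_t = per_t)
  }
  n_within <- obs$n_within; n_across <- obs$n_across
  folds <- numeric(n_reps)
  rep_totals <- lapply(setup, function(s)
    matrix(0, n_reps, length(s$totals),
           dimnames = list(NULL, names(s$totals))))
  rep_maps <- if (keep_maps) vector("list", n_reps) else NULL
  for (r in seq_len(n_reps)) {
    wsum <- 0; asum <- 0
    if (keep_maps) rep_maps[[r]] <- list()
    for (chrom in names(setup)) {
      s <- setup[[chrom]]
      if (keep_maps) { tb1 <- list(); tb2 <- list(); tcnt <- list() }
      for (k in seq_along(s$per_t)) {
        pt <- s$per_t[[k]]
        npairs <- s$lc - pt$t
        N <- s$totals[[k]]
        cnts <- as.numeric(stats::rmultinom(1, N, rep(1, npairs)))
        wsum <- wsum + sum(cnts[pt$within])
        asum <- asum + sum(cnts[pt$across])
        rep_totals[[chrom]][r, k] <- sum(cnts)
        if (keep_maps) {
          nz <- which(cnts > 0)
          tb1[[k]] <- nz - 1L
          tb2[[k]] <- nz - 1L + pt$t
          tcnt[[k]] <- cnts[nz]
        }
      }
      if (keep_maps)
        rep_maps[[r]][[chrom]] <- contact_map(chrom, s$lc, unlist(tb1),
                                              unlist(tb2), unlist(tcnt))
    }
    folds[r] <- (wsum / n_within) / (asum / n_across)
  }
  structure(list(observed_fold = obs$fold, folds = folds,
                 rep_distance_totals = rep_totals,
                 n_reps = n_reps, seed = seed, maps = rep_maps),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf(paste0("null_ensemble: observed fold %.3f vs simulated mean %.3f",
                     " (%d replicates, empirical percentile %.1f)\n"),
              x$observed_fold, mean(x$folds), x$n_reps,
              100 * mean(x$folds < x$observed_fold)))
  invisible(x)
}

#' Boundary enrichment of a feature set
#'
#' Restricting to eligible clusters (those with at least one interior bin),
#' counts features falling in boundary versus interior bins and tests the
#' boundary share against the bin-share expectation with a one-sided
#' binomial tail: with `k` boundary and `m` interior features, `p = P(X >=
#' k)`, `X ~ Binomial(k + m, n_boundary_bins / (n_boundary_bins +
#' n_interior_bins))`. Features are assigned to the bin containing their
#' midpoint (intervals) or TSS (genes).
#'
#' @param features a `GRanges` of peaks, a gene table data.frame (see
#'   [read_genes()]), or a data.frame with columns `chrom` and `pos`
#'   (0-based bp).
#' @param clusters a labeled `cluster_set`.
#' @param grid a [bin_grid()].
#' @param name feature-set label carried into the result.
#' @return one-row data.frame of class `enrichment_result`: `feature`,
#'   `fold`, `p_value`, `adj_p` (NA until [adjust_pvalues()]),
#'   `k_boundary`, `k_interior`, `n_boundary_bins`, `n_interior_bins`.
#' @export
boundary_enrichment <- function(features, clusters, grid, name = "feature") {
  stopifnot(inherits(clusters, "cluster_set"), !is.null(clusters$clusters))
  elig <- clusters$clusters$cluster[clusters$clusters$eligible]
  if (!length(elig)) stop("no eligible clusters (none has an interior bin)")
  bins <- clusters$bins[clusters$bins$cluster %in% elig, ]
  nb <- sum(bins$label == "boundary")
  ni <- sum(bins$label == "interior")
  fb <- feature_bins(features, grid)
  key <- paste(fb$chrom, fb$bin)
  bkey <- paste(bins$chrom, bins$bin)
  lab <- bins$label[match(key, bkey)]
  k <- sum(lab == "boundary", na.rm = TRUE)
  m <- sum(lab == "interior", na.rm = TRUE)
  if (m == 0 && ni == 0) stop("no interior bins to serve as control")
  p0 <- nb / (nb + ni)
  fold <- if (m == 0) Inf else (k / nb) / (m / ni)
  p <- stats::pbinom(k - 1, k + m, p0, lower.tail = FALSE)
  res <- data.frame(feature = name, fold = fold, p_value = p, adj_p = NA_real_,
                    k_boundary = k, k_interior = m,
                    n_boundary_bins = nb, n_interior_bins = ni,
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", class(res))
  res
}

# map features to (chrom, 0-based bin): interval midpoint or TSS
feature_bins <- function(features, grid) {
  if (inherits(features, "GRanges")) {
    mid <- floor((GenomicRanges::start(features) - 1 +
                    GenomicRanges::end(features)) / 2)
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(features)),
               bin = bin_index(grid, mid))
  } else if (is.data.frame(features) && "tss" %in% names(features)) {
    data.frame(chrom = features$chrom, bin = bin_index(grid, features$tss))
  } else if (is.data.frame(features) && "pos" %in% names(features)) {
    data.frame(chrom = features$chrom, bin = bin_index(grid, features$pos))
  } else stop("unsupported feature container")
}

#' Expression-tier boundary enrichment
#'
#' Ranks genes by expression, splits them into bottom 25% / middle 50% /
#' top 25% tiers, and computes [boundary_enrichment()] of each tier's TSS
#' set.
#'
#' @param genes gene table with an `expr` column (>= 4 genes with
#'   non-missing, non-constant expression).
#' @param clusters a labeled `cluster_set`.
#' @param grid a [bin_grid()].
#' @return stacked `enrichment_result` rows named `expr_top25`,
#'   `expr_mid50`, `expr_bottom25`.
#' @export
expression_tier_enrichment <- function(genes, clusters, grid) {
  g <- genes[!is.na(genes$expr), ]
  if (nrow(g) < 4) stop("need >= 4 genes with expression values")
  if (length(unique(g$expr)) == 1) stop("expression is constant; tiers undefined")
  r <- rank(g$expr, ties.method = "first")
  n <- nrow(g)
  tier <- ifelse(r > 0.75 * n, "expr_top25",
                 ifelse(r <= 0.25 * n, "expr_bottom25", "expr_mid50"))
  out <- lapply(c("expr_top25", "expr_mid50", "expr_bottom25"), function(tn)
    boundary_enrichment(g[tier == tn, ], clusters, grid, name = tn))
  res <- do.call(rbind, out)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Multiple-testing adjustment across an enrichment panel
#'
#' Benjamini-Hochberg by default; Bonferroni optional. Adjusted p-values
#' are written into the `adj_p` column.
#'
#' @param results stacked `enrichment_result` rows.
#' @param method `"BH"` or `"bonferroni"`.
#' @return the results with `adj_p` filled in.
#' @export
adjust_pvalues <- function(results, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  if (nrow(results) < 1) stop("empty result set")
  if (any(results$p_value < 0 | results$p_value > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]")
  results$adj_p <- stats::p.adjust(results$p_value, method = method)
  results
}
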