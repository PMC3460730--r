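#' Percentile-range bin sharing between two conditions
#'
#' Bins are ranked by interaction ratio in each condition separately
#' ([percentile_rank()]); a bin is *common* for a percentile range if its
#' percentile falls in the range in both conditions, and condition-specific
#' if it falls in the range in exactly one.
#'
#' @param tracks_a,tracks_b named lists of `ratio_track` on the same grid.
#' @param range numeric length-2 percentile interval, e.g. `c(90, 100)`;
#'   membership is `pct > lo & pct <= hi` (with `lo = 0` inclusive).
#' @return list of data.frames `common`, `a_specific`, `b_specific`, each
#'   with columns `chrom`, `bin`.
#' @export
percentile_group_bins <- function(tracks_a, tracks_b, range = c(90, 100)) {
  if (length(range) != 2 || range[1] >= range[2])
    stop("range must be a non-empty percentile interval")
  in_range <- function(tracks) {
    p <- percentile_rank(tracks)
    sel <- if (range[1] <= 0) p$pct <= range[2] else
      p$pct > range[1] & p$pct <= range[2]
    p[sel, c("chrom", "bin")]
  }
  a <- in_range(tracks_a); b <- in_range(tracks_b)
  akey <- paste(a$chrom, a$bin); bkey <- paste(b$chrom, b$bin)
  list(common = a[akey %in% bkey, ],
       a_specific = a[!(akey %in% bkey), ],
       b_specific = b[!(bkey %in% akey), ])
}

#' Binomial enrichment score of a gene set in a bin set
#'
#' With `k` of the `n` tested genes having their TSS inside the bin set and
#' `p0` the fraction of non-gap bins the set covers, the score is
#' `-log10 P(X >= k)`, `X ~ Binomial(n, p0)` (computed in log space, so
#' astronomically small tails do not underflow).
#'
#' @param bins data.frame with columns `chrom`, `bin` (0-based).
#' @param genes gene table subset under test (e.g. housekeeping genes).
#' @param all_bins total number of non-gap bins forming the background.
#' @param grid a [bin_grid()].
#' @return list with `score`, `p_value`, `k`, `n`, `p0`.
#' @export
gene_set_enrichment_score <- function(bins, genes, all_bins, grid) {
  if (nrow(bins) == 0) stop("empty bin set")
  if (nrow(genes) == 0) stop("empty gene set")
  fb <- feature_bins(genes, grid)
  k <- sum(paste(fb$chrom, fb$bin) %in% paste(bins$chrom, bins$bin))
  n <- nrow(genes)
  p0 <- nrow(bins) / all_bins
  logp <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = TRUE)
  list(score = -logp / log(10), p_value = exp(logp), k = k, n = n, p0 = p0)
}

# cluster id per bin as a lookup vector (NA = unclustered), per chromosome
cluster_lookup <- function(clusters, chrom, lc) {
  out <- rep(NA_integer_, lc)
  cb <- clusters$bins[clusters$bins$chrom == chrom, ]
  if (nrow(cb)) out[cb$bin + 1] <- cb$cluster
  out
}

boundary_lookup <- function(clusters, chrom, lc) {
  out <- rep(FALSE, lc)
  cb <- clusters$bins[clusters$bins$chrom == chrom &
                        clusters$bins$label == "boundary", ]
  if (nrow(cb)) out[cb$bin + 1] <- TRUE
  out
}

#' Adjacent-bin pair dynamics between two conditions
#'
#' Every pair of adjacent bins that is clustered in condition A is
#' categorized `Same` (one cluster) or `Diff` (different clusters); the
#' table reports, row-normalized, what the pair becomes in condition B:
#' `Same`, `Diff`, or `Minus` (at least one bin minus-state or unclustered
#' in B -- isolated or gap bins count as unclustered).
#'
#' @param clusters_a,clusters_b `cluster_set`s of the two conditions.
#' @param tracks_b condition B's `ratio_track`s (for the minus states).
#' @return list with `fractions` (2 x 3 matrix, rows Same/Diff in A, columns
#'   Same/Diff/Minus in B, rows summing to 1) and `counts` (same shape).
#' @export
pair_dynamics <- function(clusters_a, clusters_b, tracks_b) {
  counts <- matrix(0, 2, 3, dimnames = list(c("Same", "Diff"),
                                            c("Same", "Diff", "Minus")))
  for (chrom in names(tracks_b)) {
    lc <- length(tracks_b[[chrom]]$R)
    ca <- cluster_lookup(clusters_a, chrom, lc)
    cb <- cluster_lookup(clusters_b, chrom, lc)
    minus_b <- tracks_b[[chrom]]$state != "plus"
    i <- seq_len(lc - 1)
    a_ok <- !is.na(ca[i]) & !is.na(ca[i + 1])
    if (!any(a_ok)) next
    a_cat <- ifelse(ca[i][a_ok] == ca[i + 1][a_ok], "Same", "Diff")
    b_minus <- minus_b[i][a_ok] | minus_b[i + 1][a_ok] |
      is.na(cb[i][a_ok]) | is.na(cb[i + 1][a_ok])
    b_cat <- ifelse(b_minus, "Minus",
                    ifelse(cb[i][a_ok] == cb[i + 1][a_ok], "Same", "Diff"))
    tb <- table(factor(a_cat, levels = rownames(counts)),
                factor(b_cat, levels = colnames(counts)))
    counts <- counts + unclass(tb)
  }
  if (sum(counts) == 0) stop("no clustered adjacent pairs in condition A")
  fr <- counts / rowSums(counts)
  fr[rowSums(counts) == 0, ] <- NA
  list(fractions = fr, counts = counts)
}

#' Classify condition-A boundary bins as common or A-specific
#'
#' A boundary bin of A is *common* if it is also a cluster boundary in B and
#' *A-specific* otherwise (interior, minus-state, or unclustered in B).
#'
#' @param clusters_a condition A `cluster_set` (labeled).
#' @param clusters_b condition B `cluster_set` (labeled).
#' @return data.frame `chrom`, `bin`, `class` (`common` / `a_specific`).
#' @export
classify_boundaries <- function(clusters_a, clusters_b) {
  ba <- clusters_a$bins[clusters_a$bins$label == "boundary", c("chrom", "bin")]
  bb <- clusters_b$bins[clusters_b$bins$label == "boundary", c("chrom", "bin")]
  common <- paste(ba$chrom, ba$bin) %in% paste(bb$chrom, bb$bin)
  data.frame(chrom = ba$chrom, bin = ba$bin,
             class = ifelse(common, "common", "a_specific"))
}

#' Jaccard similarity of the clusters containing a bin in two conditions
#'
#' `J = |C_a intersect C_b| / |C_a union C_b|` where `C_a`, `C_b` are the
#' bin sets of the clusters containing `bin` in each condition.
#'
#' @param chrom,bin the bin (0-based), which must be clustered in both.
#' @param clusters_a,clusters_b the two `cluster_set`s.
#' @return Jaccard index in `[0, 1]`.
#' @export
cluster_jaccard <- function(chrom, bin, clusters_a, clusters_b) {
  member_set <- function(cs) {
    cb <- cs$bins[cs$bins$chrom == chrom, ]
    cid <- cb$cluster[cb$bin == bin]
    if (!length(cid)) stop("bin ", bin, " on ", chrom,
                           " is not clustered in both conditions")
    cb$bin[cb$cluster == cid]
  }
  a <- member_set(clusters_a); b <- member_set(clusters_b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Cluster similarity versus differential expression
#'
#' Bins that are plus-state and clustered in both conditions are ranked by
#' their proportion of differentially expressed genes (bins without genes
#' are not rankable); the mean [cluster_jaccard()] over the top and bottom
#' fractions of the ranking is reported.
#'
#' @param clusters_a,clusters_b the two `cluster_set`s.
#' @param tracks_a,tracks_b the two conditions' `ratio_track`s.
#' @param genes gene table (TSS placement).
#' @param de_genes character vector of differentially expressed gene ids
#'   (computed externally).
#' @param grid a [bin_grid()].
#' @param top_frac,bottom_frac fractions of the ranking to average
#'   (default 0.1 each).
#' @return list with `mean_j_top`, `mean_j_bottom`, `difference`, `n_ranked`.
#' @export
de_association <- function(clusters_a, clusters_b, tracks_a, tracks_b,
                           genes, de_genes, grid,
                           top_frac = 0.1, bottom_frac = 0.1) {
  fb <- feature_bins(genes, grid)
  fb$de <- genes$gene %in% de_genes
  rows <- list()
  for (chrom in names(tracks_a)) {
    lc <- length(tracks_a[[chrom]]$R)
    ca <- cluster_lookup(clusters_a, chrom, lc)
    cb <- cluster_lookup(clusters_b, chrom, lc)
    ok <- which(tracks_a[[chrom]]$state == "plus" &
                  tracks_b[[chrom]]$state == "plus" &
                  !is.na(ca) & !is.na(cb)) - 1L
    g <- fb[fb$chrom == chrom & fb$bin %in% ok, ]
    if (!nrow(g)) next
    agg <- stats::aggregate(de ~ bin, data = g,
                            FUN = function(z) c(n = length(z), p = mean(z)))
    rows[[chrom]] <- data.frame(chrom = chrom, bin = agg$bin,
                                de_prop = agg$de[, "p"])
  }
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) < 2) stop("fewer than 2 rankable bins")
  df$J <- mapply(function(ch, b) cluster_jaccard(ch, b, clusters_a, clusters_b),
                 df$chrom, df$bin)
  df <- df[order(-df$de_prop), ]
  n <- nrow(df)
  top <- df[seq_len(max(1, floor(top_frac * n))), ]
  bottom <- df[seq(n - max(1, floor(bottom_frac * n)) + 1, n), ]
  list(mean_j_top = mean(top$J), mean_j_bottom = mean(bottom$J),
       difference = mean(bottom$J) - mean(top$J), n_ranked = n)
}
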