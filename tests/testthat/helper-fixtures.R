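# fixtures built in code: random maps/graphs and hand-made tracks

# random sparse symmetric contact map
rand_map <- function(lc, n_entries = 5 * lc, seed = 1, chrom = "chr1") {
  set.seed(seed)
  b1 <- sample.int(lc, n_entries, replace = TRUE) - 1L
  b2 <- sample.int(lc, n_entries, replace = TRUE) - 1L
  contact_map(chrom, lc, b1, b2, sample(1:10, n_entries, replace = TRUE))
}

# ratio track with prescribed R values (NA = gap)
make_track <- function(R, chrom = "chr1", d = 1) {
  st <- ifelse(is.na(R), "gap", ifelse(R > 0, "plus", "minus"))
  structure(list(chrom = chrom, R = R, d = d, mode = "as_printed",
                 state = factor(st, levels = c("plus", "minus", "gap"))),
            class = "ratio_track")
}

# normalized map built directly from triplets (0-based bins)
make_norm <- function(lc, bin1, bin2, norm, chrom = "chr1") {
  structure(list(chrom = chrom, lc = as.integer(lc),
                 bin1 = as.integer(pmin(bin1, bin2)),
                 bin2 = as.integer(pmax(bin1, bin2)),
                 norm = norm, dist_mean = numeric()),
            class = "normalized_map")
}

# interaction graph from an edge list (0-based node ids)
make_graph <- function(edges, nodes = NULL, chrom = "chr1") {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$u, edges$v)))
  structure(list(chrom = chrom, nodes = as.integer(nodes), edges = edges),
            class = "interaction_graph")
}

# random weighted graph with planted blocks (heavier within-block weights)
rand_block_graph <- function(n, n_blocks = 3, p_in = 0.8, p_out = 0.1,
                             seed = 1) {
  set.seed(seed)
  block <- sort(rep_len(seq_len(n_blocks), n))
  u <- c(); v <- c(); w <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- if (block[i] == block[j]) p_in else p_out
    if (runif(1) < p) {
      u <- c(u, i - 1L); v <- c(v, j - 1L)
      w <- c(w, round(runif(1, 0.5, 2) * if (block[i] == block[j]) 5 else 1, 3))
    }
  }
  make_graph(data.frame(u = u, v = v, w = w), nodes = 0:(n - 1))
}

# cluster set built directly from a bin -> cluster assignment
make_clusters <- function(chrom, bin, cluster) {
  label_boundaries(hicratio:::new_cluster_set(
    data.frame(chrom = chrom, bin = as.integer(bin),
               cluster = as.integer(cluster)),
    NA_real_, TRUE))
}

# canonical partition representation for label-invariant comparison
partition_signature <- function(bins, cluster) {
  groups <- split(sort(bins), cluster[order(bins)])
  sig <- vapply(groups, function(g) paste(sort(g), collapse = ","), character(1))
  paste(sort(sig), collapse = ";")
}
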