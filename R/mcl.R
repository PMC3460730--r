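#' Build the plus-state interaction graph of a chromosome
#'
#' Nodes are the plus-state bins; edge weights are the raw interaction
#' counts between them from a map whose read pairs were already filtered at
#' the minimum-span threshold. Self pairs and zero-weight edges are absent;
#' isolated plus bins remain as nodes.
#'
#' @param map a [contact_map()] (min-span filtered upstream).
#' @param track the chromosome's `ratio_track` with states assigned.
#' @return an `interaction_graph`: list with `chrom`, `nodes` (0-based bins),
#'   `edges` (data.frame u, v, w with u < v).
#' @export
build_graph <- function(map, track) {
  stopifnot(inherits(map, "contact_map"), inherits(track, "ratio_track"),
            map$lc == length(track$R))
  plus <- which(track$state == "plus") - 1L
  in_plus <- map$bin1 %in% plus & map$bin2 %in% plus & map$bin1 != map$bin2
  edges <- data.frame(u = map$bin1[in_plus], v = map$bin2[in_plus],
                      w = map$count[in_plus])
  structure(list(chrom = map$chrom, nodes = plus, edges = edges),
            class = "interaction_graph")
}

#' Deterministic Markov Clustering
#'
#' Column-normalizes the weighted adjacency matrix (with self loops) into a
#' stochastic matrix, then alternates expansion (matrix powering) and
#' inflation (entrywise powering followed by column renormalization, with
#' pruning of small entries) until the matrix change falls below `tol`.
#' Clusters are read from the attractor structure of the converged matrix:
#' nodes with positive diagonal are attractors, attractors connected through
#' non-zero entries form one cluster, and every remaining node joins the
#' cluster of the attractor with the largest entry in its column (ties to
#' the lowest cluster index). The whole procedure involves no randomness.
#'
#' @param graph an `interaction_graph` from [build_graph()].
#' @param inflation Hadamard-power exponent controlling granularity
#'   (default 3.0; must be > 1). Larger values give more, smaller clusters.
#' @param expansion matrix-power exponent (default 2; must be >= 2).
#' @param prune_threshold entries below this are dropped after each
#'   inflation (default 1e-5).
#' @param tol convergence tolerance on the max entrywise change (default 1e-6).
#' @param max_iter iteration cap; hitting it returns best-effort clusters
#'   with `converged = FALSE` and a warning.
#' @param add_loops add a self loop per node weighted by its maximum
#'   incident edge weight (1 for isolated nodes); damps oscillation.
#' @return an unlabeled `cluster_set` (see [label_boundaries()]) with fields
#'   `bins` (chrom, bin, cluster), `inflation`, `converged`.
#' @export
mcl <- function(graph, inflation = 3.0, expansion = 2L, prune_threshold = 1e-5,
                tol = 1e-6, max_iter = 200L, add_loops = TRUE) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2) stop("expansion must be >= 2")
  if (nrow(graph$edges) && any(graph$edges$w < 0))
    stop("negative edge weights are not allowed")
  nodes <- graph$nodes
  nn <- length(nodes)
  if (nn == 0) {
    return(new_cluster_set(data.frame(chrom = character(), bin = integer(),
                                      cluster = integer()),
                           inflation, TRUE))
  }
  idx <- stats::setNames(seq_len(nn), nodes)
  ui <- idx[as.character(graph$edges$u)]
  vi <- idx[as.character(graph$edges$v)]
  M <- Matrix::sparseMatrix(i = c(ui, vi), j = c(vi, ui),
                            x = rep(graph$edges$w, 2), dims = c(nn, nn))
  if (add_loops) {
    mx <- apply_col_max(M)
    mx[mx <= 0] <- 1
    Matrix::diag(M) <- mx
  }
  M <- col_normalize(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mprev <- M
    for (e in seq_len(expansion - 1L)) M <- M %*% M
    M@x <- M@x^inflation
    M <- prune_matrix(M, prune_threshold)
    M <- col_normalize(M)
    if (max(abs(M - Mprev)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations; returning best-effort clusters")
  memb <- mcl_interpret(M)
  # deterministic cluster ids ordered by smallest member bin
  first_bin <- tapply(nodes, memb, min)
  relab <- stats::setNames(rank(first_bin, ties.method = "first"),
                           names(first_bin))
  cluster <- as.integer(relab[as.character(memb)])
  bins <- data.frame(chrom = graph$chrom, bin = nodes, cluster = cluster)
  new_cluster_set(bins[order(bins$cluster, bins$bin), ], inflation, converged)
}

# column maxima of a dgCMatrix (0 for empty columns)
apply_col_max <- function(M) {
  M <- methods::as(M, "CsparseMatrix")
  p <- M@p
  out <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    if (p[j + 1] > p[j]) out[j] <- max(M@x[(p[j] + 1):p[j + 1]])
  }
  out
}

col_normalize <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

prune_matrix <- function(M, threshold) {
  M <- methods::as(M, "CsparseMatrix")
  if (!length(M@x)) return(M)
  keep <- M@x >= threshold
  # never drop a column's maximum entry (keeps every column stochastic)
  p <- M@p
  for (j in seq_len(ncol(M))) {
    if (p[j + 1] > p[j]) {
      rng <- (p[j] + 1):p[j + 1]
      if (!any(keep[rng])) keep[rng[which.max(M@x[rng])]] <- TRUE
    }
  }
  M@x[!keep] <- 0
  Matrix::drop0(M)
}

# read the cluster membership off a converged MCL matrix
mcl_interpret <- function(M) {
  nn <- ncol(M)
  d <- Matrix::diag(M)
  attractors <- which(d > 0)
  if (!length(attractors)) attractors <- seq_len(nn)  # degenerate safeguard
  sub <- M[attractors, attractors, drop = FALSE]
  pat <- (sub + Matrix::t(sub)) > 0
  g <- igraph::graph_from_adjacency_matrix(pat, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership   # cluster id per attractor
  memb <- integer(nn)
  memb[attractors] <- comp
  rest <- setdiff(seq_len(nn), attractors)
  if (length(rest)) {
    Ma <- M[attractors, , drop = FALSE]
    for (j in rest) {
      colv <- Ma[, j]
      if (max(colv) > 0) {
        cand <- comp[colv == max(colv)]
        memb[j] <- min(cand)
      } else {
        memb[j] <- max(memb) + 1L  # unreachable node -> own cluster
      }
    }
  }
  memb
}

new_cluster_set <- function(bins, inflation, converged) {
  structure(list(bins = bins, clusters = NULL, inflation = inflation,
                 converged = converged),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  nc <- length(unique(x$bins$cluster))
  cat(sprintf("cluster_set: %d cluster(s) over %d bins (inflation %.1f)%s\n",
              nc, nrow(x$bins), x$inflation,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  if (!is.null(x$clusters))
    cat(sprintf("  eligible: %d, with distal bins: %d\n",
                sum(x$clusters$eligible), sum(x$clusters$has_distal)))
  invisible(x)
}

#' Label boundary and interior bins of each cluster
#'
#' Within each cluster the member bins are split into maximal contiguous
#' runs; the first and last bin of every run are boundary bins, the rest are
#' interior. A cluster is *eligible* for enrichment analyses iff it has at
#' least one interior bin, and *has_distal* iff its bins form more than one
#' run.
#'
#' @param clusters a `cluster_set` (possibly spanning several chromosomes).
#' @return the `cluster_set` with a `label` column on `bins` and a
#'   `clusters` summary data.frame (cluster, chrom, size, n_runs,
#'   has_distal, eligible).
#' @export
label_boundaries <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  bins <- clusters$bins
  bins$label <- rep("boundary", nrow(bins))
  summ <- list()
  for (cid in unique(bins$cluster)) {
    sel <- which(bins$cluster == cid)
    runs <- split_runs(sort(bins$bin[sel]))
    interior <- unlist(lapply(runs, function(r)
      if (length(r) > 2) r[-c(1, length(r))] else integer()))
    bins$label[sel][bins$bin[sel] %in% interior] <- "interior"
    summ[[length(summ) + 1]] <- data.frame(
      cluster = cid, chrom = bins$chrom[sel[1]], size = length(sel),
      n_runs = length(runs), has_distal = length(runs) > 1,
      eligible = length(interior) > 0)
  }
  clusters$bins <- bins
  clusters$clusters <- if (length(summ)) do.call(rbind, summ) else
    data.frame(cluster = integer(), chrom = character(), size = integer(),
               n_runs = integer(), has_distal = logical(), eligible = logical())
  clusters
}

#' Cluster the plus-state bins of every chromosome
#'
#' Runs [build_graph()] + [mcl()] per chromosome (intra-chromosomal data
#' decomposes the graph, so per-chromosome runs equal a genome-wide run at
#' lower cost), merges the results with globally unique cluster ids, and
#' labels boundaries.
#'
#' @param maps named list of min-span-filtered [contact_map()].
#' @param tracks named list of `ratio_track` on the same grid.
#' @param ... passed to [mcl()].
#' @return a labeled genome-wide `cluster_set`.
#' @export
cluster_genome <- function(maps, tracks, ...) {
  offset <- 0L
  parts <- list()
  converged <- TRUE
  infl <- NULL
  for (chrom in names(maps)) {
    cs <- mcl(build_graph(maps[[chrom]], tracks[[chrom]]), ...)
    infl <- cs$inflation
    converged <- converged && cs$converged
    if (nrow(cs$bins)) {
      cs$bins$cluster <- cs$bins$cluster + offset
      offset <- max(cs$bins$cluster)
      parts[[chrom]] <- cs$bins
    }
  }
  bins <- if (length(parts)) do.call(rbind, parts) else
    data.frame(chrom = character(), bin = integer(), cluster = integer())
  rownames(bins) <- NULL
  label_boundaries(new_cluster_set(bins, infl %||% NA_real_, converged))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sweep the inflation parameter and track boundary stability
#'
#' For each consecutive pair of inflation values, reports the fraction of
#' boundary bins at the smaller inflation that remain boundary bins at the
#' larger -- the stability statistic whose plateau motivates the default
#' inflation of 3.0.
#'
#' @param graph an `interaction_graph` (or named list of maps and tracks via
#'   `maps`/`tracks` in `...` is not supported; sweep one graph at a time).
#' @param inflations ascending numeric vector of inflation values.
#' @param ... passed to [mcl()].
#' @return data.frame with columns `inflation`, `n_clusters`,
#'   `shared_boundary_frac` (NA for the first row).
#' @export
inflation_sweep <- function(graph, inflations, ...) {
  stopifnot(!is.unsorted(inflations))
  prev_bound <- NULL
  rows <- list()
  for (infl in inflations) {
    cs <- label_boundaries(mcl(graph, inflation = infl, ...))
    bound <- cs$bins$bin[cs$bins$label == "boundary"]
    shared <- if (is.null(prev_bound)) NA_real_ else {
      if (length(prev_bound)) mean(prev_bound %in% bound) else NA_real_
    }
    rows[[length(rows) + 1]] <- data.frame(
      inflation = infl, n_clusters = length(unique(cs$bins$cluster)),
      shared_boundary_frac = shared)
    prev_bound <- bound
  }
  do.call(rbind, rows)
}
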