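#' Simulation parameters for the synthetic Hi-C generator
#'
#' Defaults describe the strong-signal study conditions under which the
#' pipeline's recovery properties are stated: power-law distance decay with
#' amplitude `A = 20` reads at distance 1 and exponent `alpha = 1`, a 5x
#' short-range boost inside open blocks within a `w = 10`-bin window, a 4x
#' boost within planted clusters, and a finite contact horizon of
#' `max_range = 30` bins beyond which contacts are absent (emulating the
#' effective sparsity of long-range Hi-C contacts at desk scale).
#'
#' @param A decay amplitude: expected count at distance 1 (before boosts).
#' @param alpha decay exponent (> 0).
#' @param s_open short-range multiplier when both bins are open (>= 1).
#' @param w window (bins) within which `s_open` applies.
#' @param w_in multiplier for pairs in the same planted cluster (>= 1).
#' @param max_range contact horizon in bins; pairs farther apart get rate 0.
#' @param peak_boundary,peak_interior,peak_closed Poisson rates of peaks per
#'   bin by bin class (planted cluster boundary / interior / closed block).
#' @param tss_boundary,tss_interior,tss_closed Poisson rates of gene TSSs
#'   per bin by class.
#' @param expr_meanlog,expr_sdlog log-normal expression parameters.
#' @param expr_boost multiplicative expression boost for genes whose TSS
#'   falls in a planted boundary bin.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(A = 20, alpha = 1, s_open = 5, w = 10, w_in = 4,
                       max_range = 30,
                       peak_boundary = 2, peak_interior = 1, peak_closed = 0.1,
                       tss_boundary = 1.5, tss_interior = 1, tss_closed = 0.2,
                       expr_meanlog = log(10), expr_sdlog = 1,
                       expr_boost = 2) {
  stopifnot(A > 0, alpha > 0, s_open >= 1, w_in >= 1, w >= 1, max_range > 1,
            peak_boundary >= 0, peak_interior >= 0, peak_closed >= 0)
  structure(as.list(environment()), class = "sim_params")
}

#' Plan a synthetic genome with planted states and clusters
#'
#' Tiles each chromosome with alternating open/closed blocks whose lengths
#' are Poisson-distributed around the requested means, then partitions every
#' open block into planted clusters of at least 2 bins. Planted boundary
#' bins are the terminal bins of each planted cluster. Fully reproducible
#' under the seed.
#'
#' @param n_bins named integer vector of chromosome sizes in bins (default a
#'   single 1,000-bin chromosome) -- each >= 10.
#' @param open_frac target fraction of open bins (default 0.4, matching the
#'   roughly 40/60 open/closed split expected of a lymphoblastoid genome).
#' @param mean_open_run mean open block length in bins (default 20).
#' @param mean_cluster mean planted cluster size in bins (default 7, the
#'   field-typical average domain size at 100 kb resolution).
#' @param seed integer seed.
#' @return a `genome_plan`: per chromosome, `open` (logical per bin),
#'   `blocks` (start_bin, end_bin, open), `clusters` (cluster, start_bin,
#'   end_bin), `boundary_bins`.
#' @export
make_plan <- function(n_bins = c(chr1 = 1000), open_frac = 0.4,
                      mean_open_run = 20, mean_cluster = 7, seed = 1) {
  stopifnot(all(n_bins >= 10), open_frac > 0, open_frac < 1,
            mean_open_run >= 2, mean_cluster >= 2)
  if (is.null(names(n_bins)))
    names(n_bins) <- paste0("chr", seq_along(n_bins))
  set.seed(seed)
  mean_closed_run <- mean_open_run * (1 - open_frac) / open_frac
  chroms <- list()
  next_cluster <- 0L
  for (chrom in names(n_bins)) {
    lc <- as.integer(n_bins[[chrom]])
    open <- logical(lc)
    blocks <- list()
    pos <- 0L
    state <- stats::runif(1) < open_frac
    while (pos < lc) {
      mu <- if (state) mean_open_run else mean_closed_run
      len <- min(1L + stats::rpois(1, mu - 1), lc - pos)
      blocks[[length(blocks) + 1]] <- data.frame(start_bin = pos,
                                                 end_bin = pos + len - 1L,
                                                 open = state)
      if (state) open[(pos + 1):(pos + len)] <- TRUE
      pos <- pos + len
      state <- !state
    }
    blocks <- do.call(rbind, blocks)
    cl <- partition_blocks(blocks[blocks$open, , drop = FALSE], mean_cluster,
                           next_cluster)
    next_cluster <- if (nrow(cl)) max(cl$cluster) else next_cluster
    chroms[[chrom]] <- list(
      lc = lc, open = open, blocks = blocks, clusters = cl,
      boundary_bins = sort(unique(c(cl$start_bin, cl$end_bin))))
  }
  structure(list(chroms = chroms, open_frac = open_frac,
                 mean_open_run = mean_open_run, mean_cluster = mean_cluster,
                 seed = seed),
            class = "genome_plan")
}

# split each open block into consecutive planted clusters of size >= 2
partition_blocks <- function(open_blocks, mean_cluster, id0) {
  rows <- list()
  cid <- id0
  for (b in seq_len(nrow(open_blocks))) {
    len <- open_blocks$end_bin[b] - open_blocks$start_bin[b] + 1L
    sizes <- integer()
    left <- len
    while (left > 0) {
      s <- min(2L + stats::rpois(1, mean_cluster - 2), left)
      if (left - s == 1) s <- s + 1L  # never strand a single-bin remainder
      s <- min(s, left)
      sizes <- c(sizes, s)
      left <- left - s
    }
    if (length(sizes) && sizes[length(sizes)] == 1) {
      # merge a trailing singleton into its neighbor (blocks of length 1
      # cannot satisfy the >= 2 rule; keep them as a 1-bin cluster then)
      if (length(sizes) > 1) {
        sizes[length(sizes) - 1] <- sizes[length(sizes) - 1] + 1L
        sizes <- sizes[-length(sizes)]
      }
    }
    pos <- open_blocks$start_bin[b]
    for (s in sizes) {
      cid <- cid + 1L
      rows[[length(rows) + 1]] <- data.frame(cluster = cid, start_bin = pos,
                                             end_bin = pos + s - 1L)
      pos <- pos + s
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), start_bin = integer(), end_bin = integer())
}

#' @export
print.genome_plan <- function(x, ...) {
  lc <- sum(vapply(x$chroms, `[[`, integer(1), "lc"))
  op <- sum(vapply(x$chroms, function(c) sum(c$open), numeric(1)))
  ncl <- sum(vapply(x$chroms, function(c) nrow(c$clusters), numeric(1)))
  cat(sprintf("genome_plan: %d chromosome(s), %d bins (%.0f%% open), %d planted clusters\n",
              length(x$chroms), lc, 100 * op / lc, ncl))
  invisible(x)
}

#' Sample Hi-C-like contact maps from a genome plan
#'
#' For each intra-chromosomal bin pair at distance `t` in `[1, max_range]`
#' the count is Poisson with mean `A * t^-alpha`, multiplied by `s_open`
#' when both bins are open and `t <= w`, and by `w_in` when both bins lie in
#' the same planted cluster. Self pairs are zero.
#'
#' @param plan a `genome_plan`.
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return named list of [contact_map()].
#' @export
sample_contacts <- function(plan, params = sim_params(), seed = 1) {
  stopifnot(inherits(plan, "genome_plan"), inherits(params, "sim_params"))
  set.seed(seed)
  maps <- list()
  for (chrom in names(plan$chroms)) {
    pc <- plan$chroms[[chrom]]
    lc <- pc$lc
    clv <- rep(NA_integer_, lc)
    for (r in seq_len(nrow(pc$clusters)))
      clv[(pc$clusters$start_bin[r]:pc$clusters$end_bin[r]) + 1] <-
        pc$clusters$cluster[r]
    b1 <- integer(); b2 <- integer(); cnt <- numeric()
    for (t in seq_len(min(params$max_range, lc - 1))) {
      m <- 0:(lc - 1 - t)
      mu <- rep(params$A * t^(-params$alpha), length(m))
      both_open <- pc$open[m + 1] & pc$open[m + t + 1]
      if (t <= params$w) mu[both_open] <- mu[both_open] * params$s_open
      same_cl <- !is.na(clv[m + 1]) & !is.na(clv[m + t + 1]) &
        clv[m + 1] == clv[m + t + 1]
      mu[same_cl] <- mu[same_cl] * params$w_in
      if (any(mu > 1e9)) stop("expected counts overflow")
      x <- stats::rpois(length(m), mu)
      nz <- x > 0
      b1 <- c(b1, m[nz]); b2 <- c(b2, m[nz] + t); cnt <- c(cnt, x[nz])
    }
    maps[[chrom]] <- contact_map(chrom, lc, b1, b2, cnt)
  }
  maps
}

#' Sample annotation tracks (peaks and genes) from a genome plan
#'
#' Peak and TSS counts per bin are Poisson with class-specific rates
#' (planted boundary / planted interior / closed); gene expression is
#' log-normal, multiplied by `expr_boost` for genes in boundary bins so that
#' highly expressed genes concentrate there.
#'
#' @param plan a `genome_plan`.
#' @param params a [sim_params()].
#' @param grid a [bin_grid()] matching the plan (for bp coordinates).
#' @param seed integer seed.
#' @return list with `peaks` (`GRanges`) and `genes` (gene table
#'   data.frame).
#' @export
sample_features <- function(plan, params = sim_params(), grid, seed = 1) {
  set.seed(seed)
  bs <- grid$bin_size
  peak_rows <- list(); gene_rows <- list()
  gid <- 0L
  for (chrom in names(plan$chroms)) {
    pc <- plan$chroms[[chrom]]
    cls <- bin_classes(pc)
    lam_peak <- c(boundary = params$peak_boundary,
                  interior = params$peak_interior,
                  closed = params$peak_closed)[cls]
    lam_tss <- c(boundary = params$tss_boundary,
                 interior = params$tss_interior,
                 closed = params$tss_closed)[cls]
    npk <- stats::rpois(pc$lc, lam_peak)
    for (b in which(npk > 0)) {
      s <- floor(stats::runif(npk[b], (b - 1) * bs, b * bs - 200))
      peak_rows[[length(peak_rows) + 1]] <-
        data.frame(chrom = chrom, start = s, end = s + 200)
    }
    ntss <- stats::rpois(pc$lc, lam_tss)
    for (b in which(ntss > 0)) {
      tss <- floor(stats::runif(ntss[b], (b - 1) * bs, b * bs))
      expr <- stats::rlnorm(ntss[b], params$expr_meanlog, params$expr_sdlog)
      if (cls[b] == "boundary") expr <- expr * params$expr_boost
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene = sprintf("g%05d", gid + seq_along(tss)), chrom = chrom,
        tss = tss, strand = sample(c("+", "-"), ntss[b], replace = TRUE),
        expr = expr)
      gid <- gid + ntss[b]
    }
  }
  pk <- do.call(rbind, peak_rows)
  peaks <- if (is.null(pk)) GenomicRanges::GRanges() else
    GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(start = pk$start + 1,
                                                      end = pk$end))
  genes <- do.call(rbind, gene_rows)
  if (is.null(genes))
    genes <- data.frame(gene = character(), chrom = character(),
                        tss = numeric(), strand = character(), expr = numeric())
  rownames(genes) <- NULL
  list(peaks = peaks, genes = genes)
}

# per-bin class: "boundary" / "interior" (planted clusters) / "closed"
bin_classes <- function(pc) {
  cls <- rep("closed", pc$lc)
  for (r in seq_len(nrow(pc$clusters))) {
    span <- pc$clusters$start_bin[r]:pc$clusters$end_bin[r]
    cls[span + 1] <- "interior"
    cls[c(span[1], span[length(span)]) + 1] <- "boundary"
  }
  cls
}

#' Rearrange a genome plan into a second condition
#'
#' Re-draws the planted cluster partition in a stated fraction of the open
#' blocks (and optionally flips those blocks to the closed state);
#' untouched blocks are identical to the first condition.
#'
#' @param plan a `genome_plan`.
#' @param fraction fraction of open blocks to rearrange, in `[0, 1]`.
#' @param seed integer seed.
#' @param flip_states flip the selected blocks to closed instead of
#'   re-partitioning them.
#' @return a new `genome_plan`; attribute `"touched_blocks"` records the
#'   rearranged block rows per chromosome.
#' @export
rearrange <- function(plan, fraction, seed = 1, flip_states = FALSE) {
  stopifnot(fraction >= 0, fraction <= 1)
  set.seed(seed)
  out <- plan
  touched <- list()
  next_cluster <- max(0L, unlist(lapply(plan$chroms,
                                        function(c) c$clusters$cluster)))
  for (chrom in names(plan$chroms)) {
    pc <- plan$chroms[[chrom]]
    open_idx <- which(pc$blocks$open)
    n_sel <- round(fraction * length(open_idx))
    sel <- if (n_sel > 0) sort(sample(open_idx, n_sel)) else integer()
    touched[[chrom]] <- sel
    if (!length(sel)) { out$chroms[[chrom]] <- pc; next }
    sel_blocks <- pc$blocks[sel, , drop = FALSE]
    in_sel <- rep(FALSE, pc$lc)
    for (r in seq_len(nrow(sel_blocks)))
      in_sel[(sel_blocks$start_bin[r]:sel_blocks$end_bin[r]) + 1] <- TRUE
    keep_cl <- pc$clusters[!(pc$clusters$start_bin %in%
                               unlist(mapply(seq, sel_blocks$start_bin,
                                             sel_blocks$end_bin,
                                             SIMPLIFY = FALSE))), ,
                           drop = FALSE]
    if (flip_states) {
      pc$open[in_sel] <- FALSE
      pc$blocks$open[sel] <- FALSE
      pc$clusters <- keep_cl
    } else {
      new_cl <- partition_blocks(sel_blocks, plan$mean_cluster, next_cluster)
      next_cluster <- if (nrow(new_cl)) max(new_cl$cluster) else next_cluster
      pc$clusters <- rbind(keep_cl, new_cl)
      pc$clusters <- pc$clusters[order(pc$clusters$start_bin), ]
    }
    pc$boundary_bins <- sort(unique(c(pc$clusters$start_bin,
                                      pc$clusters$end_bin)))
    out$chroms[[chrom]] <- pc
  }
  attr(out, "touched_blocks") <- touched
  out
}

#' Planted-truth recovery metrics
#'
#' Compares called states and boundary labels against the planted truth of
#' a genome plan: state accuracy over non-gap bins (open vs plus, closed vs
#' minus) and precision/recall/F1 of boundary-bin recovery.
#'
#' @param plan the `genome_plan` used to generate the data.
#' @param tracks segmentation output ([segment_maps()]).
#' @param clusters clustering output ([cluster_genome()]), or NULL to skip
#'   boundary metrics.
#' @return list with `state_accuracy`, and if clusters are given
#'   `boundary_precision`, `boundary_recall`, `boundary_f1`.
#' @export
recovery_metrics <- function(plan, tracks, clusters = NULL) {
  correct <- 0; total <- 0
  for (chrom in names(plan$chroms)) {
    pc <- plan$chroms[[chrom]]
    st <- tracks[[chrom]]$state
    ok <- st != "gap"
    truth <- ifelse(pc$open, "plus", "minus")
    correct <- correct + sum(as.character(st[ok]) == truth[ok])
    total <- total + sum(ok)
  }
  out <- list(state_accuracy = correct / total)
  if (!is.null(clusters)) {
    tp <- 0; fp <- 0; fn <- 0
    for (chrom in names(plan$chroms)) {
      pc <- plan$chroms[[chrom]]
      called <- clusters$bins$bin[clusters$bins$chrom == chrom &
                                    clusters$bins$label == "boundary"]
      truth <- pc$boundary_bins
      tp <- tp + length(intersect(called, truth))
      fp <- fp + length(setdiff(called, truth))
      fn <- fn + length(setdiff(truth, called))
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    out$boundary_precision <- prec
    out$boundary_recall <- rec
    out$boundary_f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
      2 * prec * rec / (prec + rec) else 0
  }
  out
}
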