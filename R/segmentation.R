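#' Distance-decay normalization of a contact map
#'
#' Divides every interaction value by the chromosome-wide mean interaction
#' value at the same bin distance, where the number of bin pairs at distance
#' `t` is `lc - t`. After normalization the mean over all pairs at any
#' distance with signal equals 1, removing the power-law distance decay that
#' otherwise dominates raw Hi-C counts. Distances with zero total signal
#' normalize to zero.
#'
#' @param map a [contact_map()].
#' @return a `normalized_map`: same sparse layout with field `norm` in place
#'   of `count`, plus the per-distance means used (`dist_mean`).
#' @export
normalize_by_distance <- function(map) {
  stopifnot(inherits(map, "contact_map"))
  if (map$lc < 2) stop("normalization needs lc >= 2")
  t <- map$bin2 - map$bin1
  norm <- numeric(length(t))
  dist_mean <- numeric()
  if (length(t)) {
    tot <- rowsum(map$count, t)
    tvals <- as.integer(rownames(tot))
    means <- as.numeric(tot) / (map$lc - tvals)
    dist_mean <- stats::setNames(means, tvals)
    norm <- map$count / means[match(t, tvals)]
  }
  structure(list(chrom = map$chrom, lc = map$lc, bin1 = map$bin1,
                 bin2 = map$bin2, norm = norm, dist_mean = dist_mean),
            class = "normalized_map")
}

#' Per-bin short/long-range interaction ratio
#'
#' For each bin `i` the ratio is the natural log of the summed normalized
#' interaction values within `d` bins of `i` (both sides, self pairs
#' excluded, window clipped at the chromosome ends) over the summed
#' normalized values with bins beyond `i + d`. In mode `"symmetric"` the
#' long-range sum additionally includes bins below `i - d`. The ratio is
#' undefined (state `gap`) wherever either sum is zero -- in particular the
#' trailing bins of a chromosome under `"as_printed"`, whose rightward
#' long-range window is empty.
#'
#' @param norm a `normalized_map` from [normalize_by_distance()].
#' @param d short-range window half-width in bins (default 10, i.e. 1 Mb at
#'   100 kb resolution).
#' @param mode `"as_printed"` (one-sided long-range sum, the default) or
#'   `"symmetric"`.
#' @param include_self include the self pair (distance 0) in the short-range
#'   sum; off by default because distance-0 counts are dominated by
#'   self-ligation artifacts.
#' @return a `ratio_track` with fields `chrom`, `R` (NA where undefined),
#'   `state` (factor plus/minus/gap, from [assign_states()] with no gap
#'   annotation), `d`, `mode`.
#' @export
interaction_ratio <- function(norm, d = 10, mode = c("as_printed", "symmetric"),
                              include_self = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(norm, "normalized_map"))
  lc <- norm$lc
  if (d < 1 || d >= lc) stop("d must satisfy 1 <= d < lc")
  S <- numeric(lc); L <- numeric(lc)
  t <- norm$bin2 - norm$bin1
  x <- norm$norm
  m <- norm$bin1 + 1L; n <- norm$bin2 + 1L  # 1-based for accumulation
  short <- t >= 1 & t <= d
  if (include_self) short <- short | t == 0
  # each stored pair contributes to both member bins' short sums
  if (any(short)) {
    S <- S + tab_add(m[short], x[short], lc) + tab_add(n[short], x[short], lc)
    if (include_self && any(t == 0)) {
      sel <- t == 0  # self pairs were double-added above; correct to single
      S <- S - tab_add(m[sel], x[sel], lc)
    }
  }
  long <- t > d
  if (any(long)) {
    # pair (m, n), n - m > d: partner n lies beyond m + d -> long sum of m
    L <- L + tab_add(m[long], x[long], lc)
    if (mode == "symmetric") L <- L + tab_add(n[long], x[long], lc)
  }
  R <- ifelse(S > 0 & L > 0, log(S / L), NA_real_)
  tr <- structure(list(chrom = norm$chrom, R = R, d = d, mode = mode,
                       S = S, L = L,
                       state = factor(rep("gap", lc),
                                      levels = c("plus", "minus", "gap"))),
                  class = "ratio_track")
  tr$state <- state_from_R(R)
  tr
}

# sum values into a length-lc accumulator by 1-based index
tab_add <- function(idx, val, lc) {
  out <- numeric(lc)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- as.numeric(s)
  out
}

state_from_R <- function(R) {
  st <- ifelse(is.na(R), "gap", ifelse(R > 0, "plus", "minus"))
  factor(st, levels = c("plus", "minus", "gap"))
}

#' @export
print.ratio_track <- function(x, ...) {
  tb <- table(x$state)
  cat(sprintf("ratio_track: %s, %d bins (%d plus / %d minus / %d gap), d=%d, mode=%s\n",
              x$chrom, length(x$R), tb[["plus"]], tb[["minus"]], tb[["gap"]],
              x$d, x$mode))
  invisible(x)
}

#' Assign plus/minus/gap states and extract maximal same-state regions
#'
#' The sign of the interaction ratio decides the state (`R > 0` plus,
#' `R <= 0` minus); bins with undefined ratio are gaps. Bins overlapping a
#' supplied assembly-gap annotation are forced to gap regardless of their
#' ratio. When no annotation is given and a raw map is supplied, bins with
#' zero total raw signal are gaps (the observable proxy for unassembled
#' sequence).
#'
#' @param track a `ratio_track`.
#' @param grid a [bin_grid()] (needed to place gap intervals; may be NULL if
#'   `gaps` is NULL).
#' @param gaps optional `GRanges` of assembly gaps.
#' @param map optional raw [contact_map()] used for zero-signal gap masking
#'   when `gaps` is NULL.
#' @return the track with updated `state` and a `regions` data.frame
#'   (chrom, start_bin, end_bin, state) of maximal same-state runs.
#' @export
assign_states <- function(track, grid = NULL, gaps = NULL, map = NULL) {
  stopifnot(inherits(track, "ratio_track"))
  lc <- length(track$R)
  st <- state_from_R(track$R)
  if (!is.null(gaps)) {
    stopifnot(inherits(grid, "bin_grid"))
    g <- gaps[as.character(GenomeInfoDb::seqnames(gaps)) == track$chrom]
    if (length(g)) {
      bins_gr <- GenomicRanges::GRanges(track$chrom,
        IRanges::IRanges(start = (seq_len(lc) - 1) * grid$bin_size + 1,
                         width = grid$bin_size))
      hit <- unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(bins_gr, g)))
      st[hit] <- "gap"
    }
  } else if (!is.null(map)) {
    tot <- tab_add(c(map$bin1 + 1L, map$bin2 + 1L), rep(map$count, 2), lc)
    st[tot == 0] <- "gap"
  }
  track$state <- st
  r <- rle(as.character(st))
  ends <- cumsum(r$lengths)
  track$regions <- data.frame(chrom = track$chrom,
                              start_bin = ends - r$lengths,
                              end_bin = ends - 1L,
                              state = r$values)
  track
}

#' Sign concordance between a ratio track and a reference signal
#'
#' Fraction (in percent) of bins whose ratio sign matches the sign of an
#' external per-bin reference (e.g. the first principal component of the
#' interaction correlation matrix). Only bins that are non-gap in the track
#' and have a defined, non-zero reference value are compared.
#'
#' @param track a `ratio_track`.
#' @param ref numeric vector of per-bin reference values (NA allowed).
#' @return percent concordance in `[0, 100]`.
#' @export
sign_concordance <- function(track, ref) {
  stopifnot(length(ref) == length(track$R))
  ok <- track$state != "gap" & !is.na(ref) & ref != 0
  if (!any(ok)) stop("no comparable bins")
  a_sign <- ifelse(track$state[ok] == "plus", 1, -1)
  100 * mean(a_sign == sign(ref[ok]))
}

#' Percentile rank of interaction ratios
#'
#' Ranks all non-gap bins (across all supplied chromosomes) by ascending
#' ratio and reports each bin's percentile in `(0, 100]`; ties share the
#' mean rank.
#'
#' @param tracks a `ratio_track` or named list of them.
#' @return data.frame with columns `chrom`, `bin` (0-based), `R`, `pct`.
#' @export
percentile_rank <- function(tracks) {
  if (inherits(tracks, "ratio_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    ok <- tr$state != "gap"
    data.frame(chrom = tr$chrom, bin = which(ok) - 1L, R = tr$R[ok])
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || nrow(df) == 0) stop("no non-gap bins")
  df$pct <- 100 * rank(df$R, ties.method = "average") / nrow(df)
  rownames(df) <- NULL
  df
}

#' Segment a set of contact maps
#'
#' Convenience wrapper: distance normalization, interaction ratio, and state
#' assignment for every chromosome.
#'
#' @param maps named list of [contact_map()].
#' @param d,mode,include_self see [interaction_ratio()].
#' @param grid,gaps see [assign_states()].
#' @return named list of `ratio_track`.
#' @export
segment_maps <- function(maps, d = 10, mode = "as_printed", grid = NULL,
                         gaps = NULL, include_self = FALSE) {
  out <- lapply(maps, function(m) {
    tr <- interaction_ratio(normalize_by_distance(m), d = d, mode = mode,
                            include_self = include_self)
    assign_states(tr, grid = grid, gaps = gaps, map = m)
  })
  names(out) <- vapply(maps, function(m) m$chrom, character(1))
  out
}
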