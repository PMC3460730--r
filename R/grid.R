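#' Genomic bin grid
#'
#' A bin grid divides each chromosome into fixed-size, non-overlapping bins.
#' Bin `i` (0-based) covers the half-open interval
#' `[i * bin_size, (i + 1) * bin_size)` in 0-based genomic coordinates; the
#' last bin of a chromosome may be truncated by the chromosome end.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp (default 100 kb, the working resolution of
#'   the method).
#' @return an object of class `bin_grid`.
#' @export
#' @examples
#' g <- bin_grid(c(chr1 = 1e6), bin_size = 1e5)
#' n_bins(g, "chr1")
bin_grid <- function(chrom_sizes, bin_size = 1e5) {
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("bin_size must be a single positive number")
  if (length(chrom_sizes) == 0 || is.null(names(chrom_sizes)) ||
      any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector of chromosome lengths")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  structure(list(bin_size = as.numeric(bin_size),
                 chrom_sizes = chrom_sizes),
            class = "bin_grid")
}

#' Number of bins of a chromosome
#'
#' @param grid a [bin_grid()].
#' @param chrom chromosome name.
#' @return integer bin count `ceiling(length / bin_size)`.
#' @export
n_bins <- function(grid, chrom) {
  stopifnot(inherits(grid, "bin_grid"))
  if (!chrom %in% names(grid$chrom_sizes))
    stop("unknown chromosome: ", chrom)
  as.integer(ceiling(grid$chrom_sizes[[chrom]] / grid$bin_size))
}

# 0-based bin index of a 0-based position
bin_index <- function(grid, pos0) as.integer(floor(pos0 / grid$bin_size))

# 0-based start/end (half-open) of bins, end clamped to chromosome length
bin_coords <- function(grid, chrom, bins) {
  data.frame(start = bins * grid$bin_size,
             end = pmin((bins + 1) * grid$bin_size, grid$chrom_sizes[[chrom]]))
}

#' @export
print.bin_grid <- function(x, ...) {
  cat("bin_grid:", length(x$chrom_sizes), "chromosome(s), bin size",
      format(x$bin_size, big.mark = ","), "bp\n")
  invisible(x)
}

#' Construct a grid sized to a set of contact maps
#'
#' Useful when maps were generated directly in bin space (e.g. by
#' [sample_contacts()]): each chromosome is given a length of
#' `lc * bin_size` bp.
#'
#' @param maps named list of [contact_map()] objects.
#' @param bin_size bin width in bp.
#' @return a [bin_grid()].
#' @export
grid_from_maps <- function(maps, bin_size = 1e5) {
  sizes <- vapply(maps, function(m) m$lc * bin_size, numeric(1))
  names(sizes) <- vapply(maps, function(m) m$chrom, character(1))
  bin_grid(sizes, bin_size)
}
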