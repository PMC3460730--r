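#' Sparse symmetric intra-chromosomal contact map
#'
#' Stores the absolute interaction value (IV) -- the number of read pairs
#' joining two bins -- for one chromosome. Only the upper triangle
#' (`bin1 <= bin2`) is stored; the map is symmetric by construction.
#' Bin indices are 0-based.
#'
#' @param chrom chromosome name.
#' @param lc total number of bins on the chromosome.
#' @param bin1,bin2 integer vectors of 0-based bin indices.
#' @param count non-negative interaction values; entries with identical
#'   (unordered) bin pairs are summed, zero entries are dropped.
#' @return an object of class `contact_map` with fields `chrom`, `lc`,
#'   `bin1`, `bin2` (with `bin1 <= bin2`), `count`.
#' @export
contact_map <- function(chrom, lc, bin1 = integer(), bin2 = integer(),
                        count = numeric()) {
  lc <- as.integer(lc)
  stopifnot(length(chrom) == 1, lc >= 1,
            length(bin1) == length(bin2), length(bin1) == length(count))
  bin1 <- as.integer(bin1); bin2 <- as.integer(bin2)
  if (any(count < 0)) stop("interaction counts must be non-negative")
  if (length(bin1) && (min(bin1, bin2) < 0 || max(bin1, bin2) >= lc))
    stop("bin indices must lie in [0, lc)")
  m <- pmin(bin1, bin2); n <- pmax(bin1, bin2)
  keep <- count > 0
  m <- m[keep]; n <- n[keep]; count <- count[keep]
  if (length(m)) {
    key <- m * as.double(lc) + n
    o <- order(key)
    m <- m[o]; n <- n[o]; count <- count[o]; key <- key[o]
    if (anyDuplicated(key)) {
      g <- cumsum(!duplicated(key))
      count <- as.numeric(rowsum(count, g))
      first <- !duplicated(key)
      m <- m[first]; n <- n[first]
    }
  }
  structure(list(chrom = chrom, lc = lc, bin1 = m, bin2 = n,
                 count = as.numeric(count)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %s, %d bins, %d non-zero pairs, total IV %.0f\n",
              x$chrom, x$lc, length(x$count), sum(x$count)))
  invisible(x)
}

#' Total interaction count of a map
#' @param map a [contact_map()].
#' @export
total_iv <- function(map) sum(map$count)

# per-distance totals: named numeric, names are distances t = bin2 - bin1
distance_totals <- function(map) {
  t <- map$bin2 - map$bin1
  if (!length(t)) return(numeric())
  s <- rowsum(map$count, t)
  out <- as.numeric(s)
  names(out) <- rownames(s)
  out
}

# fast lookup structure: environment-free named vector keyed "m:n"
pair_keys <- function(bin1, bin2, lc) bin1 * as.double(lc) + bin2

#' Multiply all counts of a map by a constant
#' @param map a [contact_map()].
#' @param k positive scale factor.
#' @export
scale_map <- function(map, k) {
  stopifnot(k > 0)
  contact_map(map$chrom, map$lc, map$bin1, map$bin2, map$count * k)
}
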