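#' Parse mapped Hi-C read pairs from a tab-delimited text file
#'
#' Reads a text export of mapped paired-end reads. The default column mapping
#' targets a seven-column layout (read id, chrom1, pos1, strand1, chrom2,
#' pos2, strand2); `columns` remaps it for other dialects. Strand columns are
#' never used. Positions are 1-based as in the source file.
#'
#' @param path path to the pairs file.
#' @param grid a [bin_grid()]; chromosomes absent from the grid are skipped
#'   (counted as dropped, with one warning).
#' @param intra_only drop inter-chromosomal pairs (default TRUE).
#' @param min_span drop intra-chromosomal pairs whose ends are closer than
#'   this many bp (default 0; the clustering step of the pipeline uses
#'   20,000 bp to suppress random-ligation noise).
#' @param columns named integer vector giving the 1-based column indices of
#'   `chrom1`, `pos1`, `chrom2`, `pos2`.
#' @return a `data.table` with columns `chrom1, pos1, chrom2, pos2` of the
#'   retained pairs; attribute `"pair_counts"` holds the bookkeeping
#'   (total, kept, dropped_inter, dropped_span, dropped_unknown_chrom).
#' @export
parse_pairs <- function(path, grid, intra_only = TRUE, min_span = 0,
                        columns = c(chrom1 = 2, pos1 = 3, chrom2 = 5, pos2 = 6)) {
  stopifnot(file.exists(path), inherits(grid, "bin_grid"))
  need <- c("chrom1", "pos1", "chrom2", "pos2")
  if (!all(need %in% names(columns))) stop("columns must name ", paste(need, collapse = ", "))
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = "character", fill = TRUE)
  total <- nrow(dt)
  if (total == 0) {
    out <- data.table::data.table(chrom1 = character(), pos1 = numeric(),
                                  chrom2 = character(), pos2 = numeric())
    attr(out, "pair_counts") <- c(total = 0, kept = 0, dropped_inter = 0,
                                  dropped_span = 0, dropped_unknown_chrom = 0)
    return(out)
  }
  if (ncol(dt) < max(columns))
    stop("malformed line 1: expected at least ", max(columns), " columns, found ", ncol(dt))
  short <- which(!nzchar(dt[[columns[["pos2"]]]]))
  if (length(short))
    stop("malformed line ", short[1], ": fewer fields than the column mapping requires")
  pos1 <- suppressWarnings(as.numeric(dt[[columns[["pos1"]]]]))
  pos2 <- suppressWarnings(as.numeric(dt[[columns[["pos2"]]]]))
  bad <- which(is.na(pos1) | is.na(pos2) | pos1 < 1 | pos2 < 1)
  if (length(bad))
    stop("malformed line ", bad[1], ": non-numeric or non-positive position")
  out <- data.table::data.table(chrom1 = dt[[columns[["chrom1"]]]], pos1 = pos1,
                                chrom2 = dt[[columns[["chrom2"]]]], pos2 = pos2)
  known <- names(grid$chrom_sizes)
  unk <- !(out$chrom1 %in% known & out$chrom2 %in% known)
  dropped_unknown <- sum(unk)
  if (dropped_unknown > 0)
    warning(dropped_unknown, " pair(s) on chromosomes absent from the grid were skipped")
  out <- out[!unk]
  inter <- out$chrom1 != out$chrom2
  dropped_inter <- 0L
  if (intra_only) {
    dropped_inter <- sum(inter)
    out <- out[!inter]
  }
  shortspan <- out$chrom1 == out$chrom2 & abs(out$pos1 - out$pos2) < min_span
  dropped_span <- sum(shortspan)
  out <- out[!shortspan]
  attr(out, "pair_counts") <- c(total = total, kept = nrow(out),
                                dropped_inter = dropped_inter,
                                dropped_span = dropped_span,
                                dropped_unknown_chrom = dropped_unknown)
  out
}

#' Bin intra-chromosomal read pairs into per-chromosome contact maps
#'
#' A read end falls in the bin containing its starting position. Positions
#' beyond the chromosome end are clamped to the last bin (with a warning).
#'
#' @param pairs output of [parse_pairs()] (intra-chromosomal rows only).
#' @param grid a [bin_grid()].
#' @return named list of [contact_map()], one per chromosome present.
#' @export
bin_pairs <- function(pairs, grid) {
  stopifnot(inherits(grid, "bin_grid"))
  if (nrow(pairs) && any(pairs$chrom1 != pairs$chrom2))
    stop("bin_pairs expects intra-chromosomal pairs")
  maps <- list()
  clamped <- 0L
  for (chrom in unique(pairs$chrom1)) {
    p <- pairs[pairs$chrom1 == chrom, ]
    lc <- n_bins(grid, chrom)
    b1 <- bin_index(grid, p$pos1 - 1)  # 1-based file position -> 0-based coord
    b2 <- bin_index(grid, p$pos2 - 1)
    over <- b1 >= lc | b2 >= lc
    clamped <- clamped + sum(over)
    b1 <- pmin(b1, lc - 1L); b2 <- pmin(b2, lc - 1L)
    maps[[chrom]] <- contact_map(chrom, lc, b1, b2, rep(1, length(b1)))
  }
  if (clamped > 0)
    warning(clamped, " read end(s) beyond the chromosome length were clamped to the last bin")
  maps
}

#' Read pre-binned contact triplets
#'
#' Four-column tab-delimited text: chrom, bin1, bin2, count (bins 0-based).
#'
#' @param path triplet file.
#' @param grid a [bin_grid()] giving `lc` per chromosome.
#' @return named list of [contact_map()].
#' @export
read_triplets <- function(path, grid) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "bin1", "bin2", "count"))
  maps <- list()
  for (chrom in unique(dt$chrom)) {
    d <- dt[dt$chrom == chrom, ]
    maps[[chrom]] <- contact_map(chrom, n_bins(grid, chrom),
                                 d$bin1, d$bin2, d$count)
  }
  maps
}

#' Write contact maps as triplets
#' @param maps named list of [contact_map()].
#' @param path output file.
#' @export
write_triplets <- function(maps, path) {
  dt <- data.table::rbindlist(lapply(maps, function(m)
    data.table::data.table(chrom = m$chrom, bin1 = m$bin1, bin2 = m$bin2,
                           count = m$count)))
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a GRanges
#'
#' Accepts 3+ column BED (0-based half-open). Records with `start >= end`
#' are rejected with a message and dropped.
#'
#' @param path BED file.
#' @return a `GRanges` with optional `name` and `score` metadata columns.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  dt <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(dt) < 3) stop("BED file must have at least 3 columns: ", path)
  start <- as.numeric(dt[[2]]); end <- as.numeric(dt[[3]])
  bad <- which(start >= end)
  if (length(bad)) {
    message("rejected ", length(bad), " BED record(s) with start >= end (first at line ",
            bad[1], ")")
    dt <- dt[-bad, , drop = FALSE]
    start <- start[-bad]; end <- end[-bad]
  }
  gr <- GenomicRanges::GRanges(dt[[1]],
                               IRanges::IRanges(start = start + 1, end = end))
  if (ncol(dt) >= 4) gr$name <- as.character(dt[[4]])
  if (ncol(dt) >= 5) gr$score <- suppressWarnings(as.numeric(dt[[5]]))
  gr
}

#' Read a gene table
#'
#' Tab-delimited columns: gene id, chrom, TSS position (0-based bp), strand,
#' expression (real; NA allowed). A header line is detected and skipped.
#'
#' @param path gene table file.
#' @return a data.frame with columns `gene`, `chrom`, `tss`, `strand`, `expr`.
#' @export
read_genes <- function(path) {
  stopifnot(file.exists(path))
  first <- readLines(path, n = 1)
  hdr <- grepl("^gene\t", first)
  dt <- utils::read.table(path, sep = "\t", header = hdr,
                          stringsAsFactors = FALSE,
                          col.names = c("gene", "chrom", "tss", "strand", "expr"))
  if (any(dt$tss < 0)) stop("TSS positions must be >= 0")
  dt
}

#' Write a gene table in the format read by [read_genes()]
#' @param genes data.frame with columns `gene`, `chrom`, `tss`, `strand`, `expr`.
#' @param path output file.
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes[, c("gene", "chrom", "tss", "strand", "expr")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signal track (wig or bedGraph) and average it into grid bins
#'
#' Values are averaged with coverage weighting: a bin's value is the mean of
#' the covering records' values weighted by the width each record covers
#' inside the bin; uncovered stretches do not contribute. Bins with no
#' coverage are `NA`.
#'
#' @param path wig or bedGraph file (format inferred from the extension by
#'   `rtracklayer`).
#' @param grid a [bin_grid()].
#' @return named list (per chromosome) of numeric vectors of length `lc`.
#' @export
read_track <- function(path, grid) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path)
  out <- list()
  for (chrom in names(grid$chrom_sizes)) {
    lc <- n_bins(grid, chrom)
    vals <- rep(NA_real_, lc)
    g <- gr[as.character(GenomeInfoDb::seqnames(gr)) == chrom]
    if (length(g)) {
      bs <- grid$bin_size
      s0 <- GenomicRanges::start(g) - 1  # 0-based
      e0 <- GenomicRanges::end(g)        # half-open end
      sc <- as.numeric(g$score)
      wsum <- rep(0, lc); vsum <- rep(0, lc)
      first_bin <- pmax(floor(s0 / bs), 0)
      last_bin <- pmin(ceiling(e0 / bs) - 1, lc - 1)
      for (i in seq_along(g)) {
        if (last_bin[i] < first_bin[i]) next
        for (b in first_bin[i]:last_bin[i]) {
          w <- min(e0[i], (b + 1) * bs) - max(s0[i], b * bs)
          if (w > 0) {
            wsum[b + 1] <- wsum[b + 1] + w
            vsum[b + 1] <- vsum[b + 1] + w * sc[i]
          }
        }
      }
      cov <- wsum > 0
      vals[cov] <- vsum[cov] / wsum[cov]
    }
    out[[chrom]] <- vals
  }
  out
}

#' Write the interaction-ratio wiggle file
#'
#' Fixed-step wiggle (1-based starts, step = bin size); gap bins are skipped,
#' breaking the track into multiple fixedStep blocks.
#'
#' @param tracks named list of ratio tracks (see [interaction_ratio()]).
#' @param grid a [bin_grid()].
#' @param path output path.
#' @export
write_ratio_wig <- function(tracks, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=wiggle_0 name=\"interaction_ratio\"", con)
  bs <- format(grid$bin_size, scientific = FALSE)
  for (tr in tracks) {
    ok <- tr$state != "gap"
    if (!any(ok)) next
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (r in which(runs$values)) {
      i0 <- starts[r] - 1  # 0-based first bin of the run
      writeLines(sprintf("fixedStep chrom=%s start=%s step=%s span=%s",
                         tr$chrom,
                         format(i0 * grid$bin_size + 1, scientific = FALSE),
                         bs, bs), con)
      writeLines(sprintf("%.10g", tr$R[starts[r]:ends[r]]), con)
    }
  }
  invisible(path)
}

#' Write the per-bin state/cluster BED file
#'
#' Six tab-separated columns: chrom, start, end, state (`+`, `-`, `gap`),
#' cluster id (`.` if unclustered), bin label (`boundary`, `interior`, `.`).
#'
#' @param tracks named list of ratio tracks.
#' @param clusters a `cluster_set` or NULL.
#' @param grid a [bin_grid()].
#' @param path output path.
#' @export
write_state_bed <- function(tracks, clusters, grid, path) {
  rows <- list()
  cl_bins <- if (!is.null(clusters)) clusters$bins else NULL
  for (tr in tracks) {
    lc <- length(tr$state)
    co <- bin_coords(grid, tr$chrom, seq_len(lc) - 1L)
    cid <- rep(".", lc); lab <- rep(".", lc)
    if (!is.null(cl_bins)) {
      cb <- cl_bins[cl_bins$chrom == tr$chrom, ]
      if (nrow(cb)) {
        cid[cb$bin + 1] <- as.character(cb$cluster)
        lab[cb$bin + 1] <- cb$label
      }
    }
    state_sym <- c(plus = "+", minus = "-", gap = "gap")[as.character(tr$state)]
    rows[[tr$chrom]] <- data.frame(chrom = tr$chrom,
                                   start = format(co$start, scientific = FALSE, trim = TRUE),
                                   end = format(co$end, scientific = FALSE, trim = TRUE),
                                   state = state_sym, cluster = cid, label = lab)
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read back a state/cluster BED written by [write_state_bed()]
#'
#' @param path BED file.
#' @param grid a [bin_grid()].
#' @return list with `states` (named list of per-bin state factors) and
#'   `bins` (data.frame chrom, bin, cluster, label for clustered bins).
#' @export
read_state_bed <- function(path, grid) {
  dt <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "state",
                                        "cluster", "label"))
  states <- list()
  for (chrom in unique(dt$chrom)) {
    d <- dt[dt$chrom == chrom, ]
    bin <- bin_index(grid, d$start)
    st <- rep("gap", n_bins(grid, chrom))
    st[bin + 1] <- c(`+` = "plus", `-` = "minus", gap = "gap")[d$state]
    states[[chrom]] <- factor(st, levels = c("plus", "minus", "gap"))
  }
  cl <- dt[dt$cluster != ".", ]
  bins <- data.frame(chrom = cl$chrom, bin = bin_index(grid, cl$start),
                     cluster = as.integer(cl$cluster), label = cl$label)
  list(states = states, bins = bins)
}

#' Write the cluster file
#'
#' One cluster per line: id, then comma-separated `chrom:start-end` spans of
#' its contiguous bin runs (0-based half-open genomic coordinates).
#'
#' @param clusters a `cluster_set`.
#' @param grid a [bin_grid()].
#' @param path output path.
#' @export
write_cluster_file <- function(clusters, grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bins <- clusters$bins
  for (cid in sort(unique(bins$cluster))) {
    b <- bins[bins$cluster == cid, ]
    chrom <- b$chrom[1]
    runs <- split_runs(sort(b$bin))
    spans <- vapply(runs, function(r) {
      co <- bin_coords(grid, chrom, r)
      sprintf("%s:%s-%s", chrom,
              format(min(co$start), scientific = FALSE),
              format(max(co$end), scientific = FALSE))
    }, character(1))
    writeLines(paste0(cid, "\t", paste(spans, collapse = ",")), con)
  }
  invisible(path)
}

#' Read back a cluster file written by [write_cluster_file()]
#' @param path cluster file.
#' @param grid a [bin_grid()].
#' @return data.frame with columns chrom, bin, cluster.
#' @export
read_cluster_file <- function(path, grid) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    cid <- as.integer(parts[1])
    spans <- strsplit(parts[2], ",")[[1]]
    for (sp in spans) {
      m <- regmatches(sp, regexec("^(.+):([0-9]+)-([0-9]+)$", sp))[[1]]
      chrom <- m[2]
      b0 <- bin_index(grid, as.numeric(m[3]))
      b1 <- bin_index(grid, as.numeric(m[4]) - 1)
      out[[length(out) + 1]] <- data.frame(chrom = chrom, bin = b0:b1,
                                           cluster = cid)
    }
  }
  do.call(rbind, out)
}

#' Write the three standard output files
#'
#' Produces `<prefix>.wig` (interaction ratios), `<prefix>.bed` (per-bin
#' state, cluster id and boundary/interior label) and `<prefix>.cluster`
#' (one cluster per line with its genomic spans).
#'
#' @param tracks named list of ratio tracks.
#' @param clusters a `cluster_set` or NULL (then no cluster file is written
#'   and the BED cluster columns are `.`).
#' @param grid a [bin_grid()].
#' @param prefix output path prefix.
#' @return character vector of the files written.
#' @export
write_outputs <- function(tracks, clusters, grid, prefix) {
  files <- c(wig = paste0(prefix, ".wig"), bed = paste0(prefix, ".bed"))
  write_ratio_wig(tracks, grid, files[["wig"]])
  write_state_bed(tracks, clusters, grid, files[["bed"]])
  if (!is.null(clusters)) {
    files[["cluster"]] <- paste0(prefix, ".cluster")
    write_cluster_file(clusters, grid, files[["cluster"]])
  }
  files
}

# split a sorted integer vector into maximal consecutive runs
split_runs <- function(x) {
  if (!length(x)) return(list())
  brk <- cumsum(c(1, diff(x) != 1))
  unname(split(x, brk))
}
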