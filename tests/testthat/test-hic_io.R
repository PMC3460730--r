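grid1 <- bin_grid(c(chr1 = 1e6, chr2 = 5e5), bin_size = 1e5)
cols4 <- c(chrom1 = 1, pos1 = 2, chrom2 = 3, pos2 = 4)

write_pairs <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("pair parsing applies the span and chromosome filters with full bookkeeping", {
  f <- write_pairs(c("chr1\t500\tchr1\t30500",     # span 30,000 -> kept
                     "chr1\t500\tchr2\t900",        # inter -> dropped
                     "chr1\t1000\tchr1\t16000",     # span 15,000
                     "chr9\t100\tchr9\t50000"))     # unknown chromosome
  expect_warning(
    parse_pairs(f, grid1, intra_only = TRUE, min_span = 20000, columns = cols4),
    "absent from the grid")
  p <- suppressWarnings(
    parse_pairs(f, grid1, intra_only = TRUE, min_span = 20000, columns = cols4))
  expect_equal(nrow(p), 1)
  expect_equal(abs(p$pos2 - p$pos1), 30000)
  ct <- attr(p, "pair_counts")
  expect_equal(unname(ct[c("total", "kept", "dropped_inter", "dropped_span",
                           "dropped_unknown_chrom")]),
               c(4, 1, 1, 1, 1))
  expect_equal(sum(ct[-1]), ct[["total"]])

  # ten short-span pairs -> none kept
  f2 <- write_pairs(rep("chr1\t100\tchr1\t15100", 10))
  p2 <- parse_pairs(f2, grid1, min_span = 20000, columns = cols4)
  expect_equal(nrow(p2), 0)
  expect_equal(attr(p2, "pair_counts")[["dropped_span"]], 10)
})

test_that("malformed pair lines are reported by line number", {
  f <- write_pairs(c("chr1\t500\tchr1\t30500", "chr1\tabc\tchr1\t900"))
  expect_error(parse_pairs(f, grid1, columns = cols4), "line 2")
})

test_that("binning counts pairs into symmetric maps and conserves mass", {
  lines <- c(rep("chr1\t250000\tchr1\t750000", 3),   # bins 2 and 7
             "chr1\t450000\tchr1\t460000")           # both ends in bin 4
  p <- parse_pairs(write_pairs(lines), grid1, columns = cols4)
  maps <- bin_pairs(p, grid1)
  m <- maps$chr1
  expect_equal(m$count[m$bin1 == 2 & m$bin2 == 7], 3)
  expect_equal(m$count[m$bin1 == 4 & m$bin2 == 4], 1)
  expect_equal(total_iv(m), 4)

  # 1,000 random pairs conserve total mass
  set.seed(42)
  rnd <- sprintf("chr1\t%d\tchr1\t%d", sample.int(1e6, 1000),
                 sample.int(1e6, 1000))
  maps2 <- bin_pairs(parse_pairs(write_pairs(rnd), grid1, columns = cols4),
                     grid1)
  expect_equal(total_iv(maps2$chr1), 1000)
})

test_that("positions beyond the chromosome length clamp to the last bin", {
  p <- parse_pairs(write_pairs("chr2\t100\tchr2\t600000"), grid1,
                   columns = cols4)
  expect_warning(bin_pairs(p, grid1), "clamped")
  maps <- suppressWarnings(bin_pairs(p, grid1))
  expect_equal(maps$chr2$bin2, n_bins(grid1, "chr2") - 1L)
})

test_that("BED reading validates coordinates and keeps names", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tpeakA", "chr1\t300\t300\tbad"), f)
  expect_message(read_bed(f), "rejected 1")
  gr <- suppressMessages(read_bed(f))
  expect_equal(length(gr), 1)
  expect_equal(GenomicRanges::width(gr), 100)
  expect_equal(gr$name, "peakA")
})

test_that("bedGraph values average into bins with coverage weighting", {
  f <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t100000\t1.5",           # whole bin 0 at 1.5
               "chr1\t100000\t150000\t1",         # half of bin 1 at 1
               "chr1\t150000\t200000\t3"),        # other half at 3
             f)
  vals <- read_track(f, grid1)
  expect_equal(vals$chr1[1], 1.5)
  expect_equal(vals$chr1[2], 2)       # coverage-weighted mean of 1 and 3
  expect_true(is.na(vals$chr1[3]))
})

test_that("output triple round-trips at bin resolution", {
  tr <- make_track(c(0.5, -0.2, NA, 0.1, 0.4, -0.3, 0.2, 0.9, -0.1, 0.3))
  cl <- make_clusters("chr1", c(3, 4, 6, 7, 9), c(1, 1, 2, 2, 2))
  dir <- withr::local_tempdir()
  files <- write_outputs(list(chr1 = tr), cl, grid1, file.path(dir, "run"))

  # wiggle: one value per non-gap bin
  wig <- readLines(files[["wig"]])
  expect_equal(sum(grepl("^[-0-9.]+$", wig)), 9)
  wvals <- read_track(files[["wig"]], grid1)$chr1
  expect_equal(wvals[-3], tr$R[-3], tolerance = 1e-6)
  expect_true(is.na(wvals[3]))

  # BED: states and clusters reproduce exactly
  sb <- read_state_bed(files[["bed"]], grid1)
  expect_identical(as.character(sb$states$chr1), as.character(tr$state))
  expect_equal(sb$bins[, c("chrom", "bin", "cluster")],
               cl$bins[, c("chrom", "bin", "cluster")],
               ignore_attr = TRUE)

  # cluster file: coordinate arithmetic and lossless bins
  cf <- readLines(files[["cluster"]])
  expect_match(cf[1], "chr1:300000-500000", fixed = TRUE)
  back <- read_cluster_file(files[["cluster"]], grid1)
  expect_equal(back[order(back$bin), c("bin", "cluster")],
               cl$bins[order(cl$bins$bin), c("bin", "cluster")],
               ignore_attr = TRUE)
})

test_that("a single cluster of bins 10-12 spans chr1:1,000,000-1,300,000", {
  cl <- make_clusters("chr1", 10:12, c(1, 1, 1))
  grid <- bin_grid(c(chr1 = 5e6), 1e5)
  f <- withr::local_tempfile(fileext = ".cluster")
  write_cluster_file(cl, grid, f)
  expect_equal(readLines(f), "1\tchr1:1000000-1300000")
})

test_that("triplet files round-trip contact maps", {
  m <- rand_map(10, 30, seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_triplets(list(chr1 = m), f)
  back <- read_triplets(f, grid1)$chr1
  expect_equal(back$bin1, m$bin1)
  expect_equal(back$bin2, m$bin2)
  expect_equal(back$count, m$count)
})
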