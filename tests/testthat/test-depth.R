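test_that("bin counting uses half-open bins and conserves reads", {
  expect_equal(as.integer(bin_counts(c(0, 999, 1000), 2000, 1000)),
               c(2L, 1L))
  empty <- bin_counts(numeric(0), 5500, 1000)
  expect_equal(as.integer(empty), rep(0L, 6))
  expect_true(attr(empty, "partial"))
  expect_error(bin_counts(c(10, 2000), 2000, 1000), "outside")
  set.seed(12)
  pos <- floor(runif(1e5) * 97531)
  got <- bin_counts(pos, 97531, 1000)
  want <- as.integer(table(cut(pos, breaks = seq(0, 98000, by = 1000),
                               right = FALSE)))
  expect_equal(as.integer(got), want[seq_along(got)])
  expect_equal(sum(got), length(pos))
})

test_that("BED reads load as 0-based starts, skipping unknown chroms", {
  bed <- write_bed_reads(c(5, 100, 2500))
  reads <- load_reads(bed, c(chr1 = 10000))
  expect_equal(reads$chr1, c(5, 100, 2500))
  bed2 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t5\t6", "chrUn\t10\t11"), bed2)
  expect_warning(reads2 <- load_reads(bed2, c(chr1 = 10000)),
                 "undeclared")
  expect_equal(reads2$chr1, 5)
  bed3 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t5\t6", "chr1\t7\t7"), bed3)
  expect_message(reads3 <- load_reads(bed3, c(chr1 = 10000)),
                 "zero-length")
  expect_equal(reads3$chr1, 5)
})

test_that("SAM reads drop unmapped records with a note", {
  set.seed(3)
  pos <- sort(sample(0:9000, 100))
  sam <- write_sam(pos, chrom_length = 10000, n_unmapped = 5)
  expect_message(reads <- load_reads(sam, c(chr1 = 10000)), "unmapped")
  expect_equal(length(reads$chr1), 100L)
  expect_equal(reads$chr1, pos)
})

test_that("track loading averages length-weighted and masks uncovered", {
  bg <- write_bedgraph("chr1", c(0, 1000, 2000), c(1000, 2000, 3000),
                       c(1, 1, 1))
  tr <- load_track(bg, c(chr1 = 3000), 1000)
  expect_equal(tr$chr1$values, c(1, 1, 1))
  expect_false(any(tr$chr1$mask))
  # interval covering half a bin at 1.0, rest uncovered
  bg2 <- write_bedgraph("chr1", 0, 500, 1)
  tr2 <- load_track(bg2, c(chr1 = 2000), 1000)
  expect_equal(tr2$chr1$values, c(0.5, 0))
  expect_equal(tr2$chr1$mask, c(FALSE, TRUE))
  expect_error(load_track(write_bedgraph("chr1", 0, 10, 1.5),
                          c(chr1 = 100), 10), "outside")
})

test_that("piecewise track matches a per-base expansion oracle", {
  set.seed(8)
  edges <- sort(sample(1:9999, 30))
  starts <- c(0, edges)
  ends <- c(edges, 10000)
  vals <- round(runif(31), 3)
  keep <- rbinom(31, 1, 0.8) == 1   # leave some gaps uncovered
  bg <- write_bedgraph("chr1", starts[keep], ends[keep], vals[keep])
  tr <- load_track(bg, c(chr1 = 10000), 250)
  base <- numeric(10000)
  for (i in which(keep)) base[(starts[i] + 1):ends[i]] <- vals[i]
  want <- colMeans(matrix(base, nrow = 250))
  expect_equal(tr$chr1$values, want, tolerance = 1e-12)
})

test_that("methylation reports validate and summarize", {
  df <- data.frame(chrom = "chr1", pos = c(10, 25), strand = "+",
                   n_methylated = c(3, 0), n_total = c(4, 2))
  meth <- load_methylation(write_methylation(df))
  expect_s3_class(meth, "methylation_map")
  expect_equal(nrow(meth), 2L)
  expect_error(load_methylation(write_methylation(rbind(df, df[1, ]))),
               "duplicate")
  bad <- df; bad$n_methylated[1] <- 9
  expect_error(load_methylation(write_methylation(bad)), "n_methylated")
  # genome-wide fraction recovered from a generated map
  set.seed(21)
  tot <- sample(5:30, 500, replace = TRUE)
  m <- rbinom(500, tot, 0.7)
  big <- data.frame(chrom = "chr1", pos = seq(0, by = 7, length.out = 500),
                    strand = "+", n_methylated = m, n_total = tot)
  expect_equal(methylation_mean(load_methylation(write_methylation(big))),
               sum(m) / sum(tot))
})

test_that("segment tables round-trip and reject overlap", {
  seg1 <- data.frame(chrom = "chr1", start = 0, end = 50000,
                     n_bins = 50L, mean_depth = 100.5,
                     copy_number = 2.01,
                     call = factor("neutral", c("loss", "neutral", "gain")))
  path <- tempfile(fileext = ".seg")
  write_segments(seg1, path)
  expect_length(readLines(path), 2L)  # header + one row
  set.seed(77)
  bounds <- sort(sample(seq(1000, 1e6, by = 1000), 51))
  segs <- data.frame(chrom = "chr1", start = bounds[-51], end = bounds[-1],
                     n_bins = sample(2:50, 50, replace = TRUE),
                     mean_depth = round(runif(50, 50, 400), 6),
                     copy_number = round(runif(50, 0.5, 4), 6),
                     call = factor(sample(c("loss", "neutral", "gain"), 50,
                                          replace = TRUE),
                                   c("loss", "neutral", "gain")))
  write_segments(segs, path)
  back <- read_segments(path)
  expect_equal(back$start, segs$start)
  expect_equal(back$end, segs$end)
  expect_equal(back$mean_depth, segs$mean_depth)
  expect_equal(as.character(back$call), as.character(segs$call))
  # adjacent rows share their boundary exactly (half-open tiling)
  expect_equal(back$start[-1], back$end[-nrow(back)])
  bad <- segs; bad$start[2] <- bad$start[2] - 1500
  expect_error(write_segments(bad, path), "overlap")
})
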