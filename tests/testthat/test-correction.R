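test_that("mapability correction scales by the inverse and masks low bins", {
  tr <- make_track(counts = c(10, 10, 10, 10),
                   mapability = c(0.5, 1, 0.2, 0.8))
  out <- mapability_correct(tr)
  expect_equal(out$counts[1], 20)
  expect_equal(out$counts[2], 10)
  expect_true(out$mask[3])          # below the 25% floor
  expect_equal(out$counts[4], 12.5)
  expect_true(all(out$counts >= tr$counts))   # mapability <= 1
  # already-masked bins stay masked and untouched
  tr2 <- make_track(counts = c(10, 10), mapability = c(0.5, 0.5),
                    mask = c(TRUE, FALSE))
  out2 <- mapability_correct(tr2)
  expect_true(out2$mask[1])
  expect_equal(out2$counts, c(10, 20))
})

test_that("GC correction is the identity when depth is GC-independent", {
  set.seed(5)
  gc <- runif(1000, 0.3, 0.7)
  tr <- make_track(counts = rep(200, 1000), gc = gc)
  out <- gc_correct(tr)
  expect_equal(out$counts, tr$counts, tolerance = 1e-6)
})

test_that("GC correction conserves unmasked depth and removes the bias", {
  set.seed(42)
  n <- 5000
  gc <- runif(n, 0.3, 0.9)
  bias <- 1 + 2 * (gc - 0.3)^2
  mu <- 400 * bias
  counts <- rnbinom(n, mu = mu, size = mu / 2)   # vmr 3
  mask <- rep(FALSE, n); mask[sample(n, 100)] <- TRUE
  tr <- make_track(counts, gc = gc, mask = mask)
  out <- gc_correct(tr)
  expect_equal(sum(out$counts[!mask]), sum(counts[!mask]),
               tolerance = 1e-9)
  expect_equal(out$counts[mask], counts[mask])   # masked untouched
  slope_before <- coef(lm(counts[!mask] ~ gc[!mask]))[2]
  slope_after <- coef(lm(out$counts[!mask] ~ gc[!mask]))[2]
  expect_lt(abs(slope_after), abs(slope_before) / 10)
})

test_that("GC correction degrades to identity on insufficient data", {
  tr <- make_track(counts = rpois(50, 100), gc = runif(50, 0.4, 0.6))
  expect_warning(out <- gc_correct(tr), "identity")
  expect_equal(out$counts, tr$counts)
  tr2 <- make_track(counts = rpois(500, 100), gc = rep(0.5, 500))
  expect_warning(out2 <- gc_correct(tr2), "identity")  # 1 GC group
})

test_that("effective GC reflects methylation protection of cytosines", {
  comp <- data.frame(chrom = "chr1", bin = 0L, n_mappable = 1000,
                     n_c = 200, n_g = 300)
  mk_meth <- function(frac) {
    df <- data.frame(chrom = "chr1", pos = seq(0, by = 5, length.out = 200),
                     strand = "+", n_methylated = round(frac * 10),
                     n_total = 10)
    class(df) <- c("methylation_map", "data.frame")
    df
  }
  # fully methylated: all cytosines protected, standard GC
  expect_equal(effective_gc(comp, mk_meth(1), 5000), 0.5)
  # fully unmethylated: every C converted, only G remains
  expect_equal(effective_gc(comp, mk_meth(0), 5000), 0.3)
  # half methylated: (300 + 200*0.5)/1000
  expect_equal(effective_gc(comp, mk_meth(0.5), 5000), 0.4)
})

test_that("effective GC imputes unmapped cytosines at the genome mean", {
  comp <- data.frame(chrom = "chr1", bin = c(0L, 1L),
                     n_mappable = c(1000, 1000), n_c = c(200, 100),
                     n_g = c(300, 100))
  # map covers only 50 of bin 0's cytosines, at fraction 0.8
  df <- data.frame(chrom = "chr1", pos = seq(0, by = 2, length.out = 50),
                   strand = "+", n_methylated = 8, n_total = 10)
  class(df) <- c("methylation_map", "data.frame")
  egc <- effective_gc(comp, df, 1000)
  expect_equal(egc[1], (300 + 50 * 0.8 + 150 * 0.8) / 1000)
  expect_equal(egc[2], (100 + 100 * 0.8) / 1000)
})

test_that("effective GC is bounded and monotone in methylation", {
  set.seed(9)
  comp <- data.frame(chrom = "chr1", bin = 0:9, n_mappable = 1000,
                     n_c = sample(100:300, 10), n_g = sample(100:300, 10))
  pos <- sort(sample(0:9999, 400))
  fr <- runif(400)
  mk <- function(f) {
    df <- data.frame(chrom = "chr1", pos = pos, strand = "+",
                     n_methylated = round(f * 100), n_total = 100)
    class(df) <- c("methylation_map", "data.frame")
    df
  }
  e0 <- effective_gc(comp, mk(fr), 1000)
  expect_true(all(e0 >= 0 & e0 <= 1))
  fr2 <- pmin(fr + 0.2, 1)
  e1 <- effective_gc(comp, mk(fr2), 1000)
  expect_true(all(e1 >= e0 - 1e-12))
  # zero mappable bases: missing value (map describes other bins)
  comp0 <- data.frame(chrom = "chr1", bin = 99L, n_mappable = 0,
                      n_c = 0, n_g = 0)
  expect_true(is.na(effective_gc(comp0, mk(fr), 1000)))
})

test_that("base composition from sequence feeds effective GC", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste(
    c(rep("A", 250), rep("C", 200), rep("G", 300), rep("T", 250),
      rep("N", 20), rep("G", 100), rep("C", 100), rep("A", 300)),
    collapse = "")))
  comp <- bin_composition(seqs, 1000)
  expect_equal(nrow(comp), 2L)
  expect_equal(comp$n_mappable, c(1000, 500))
  expect_equal(comp$n_c, c(200, 100))
  expect_equal(comp$n_g, c(300, 100))
  expect_equal(comp$gc, c(0.5, 0.4))
  # fully methylated map reproduces the standard GC exactly
  cpos <- c(which(strsplit(as.character(seqs[[1]]), "")[[1]] == "C")) - 1
  meth <- data.frame(chrom = "chr1", pos = cpos, strand = "+",
                     n_methylated = 5, n_total = 5)
  class(meth) <- c("methylation_map", "data.frame")
  expect_equal(effective_gc(comp, meth, 1000), comp$gc)
})
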