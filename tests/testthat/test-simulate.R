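# a spec whose selected-model lambda is overridden to a known value, so
# moment checks have an exact target
flat_spec <- function(n_bins = 1e5, lam = 100, vmr = 3, bin_size = 1000) {
  L <- n_bins * bin_size
  n_reads <- lam * L / bin_size
  th <- optimize_thresholds(lam, vmr)
  params <- model_params(n_reads = n_reads, genome_size = L,
                         bin_size = bin_size, lam = lam, vmr = vmr,
                         fdr_target = 0.01, t_loss = th$t_loss,
                         t_gain = th$t_gain, fdr_achieved = th$fdr)
  spec <- trial_spec(coverage = n_reads * 76 / L, cna_size = 0,
                     chrom_length = L, vmr = vmr)
  list(spec = spec, params = params)
}

test_that("simulated diploid counts match the model's moments", {
  fs <- flat_spec()
  sim <- simulate_counts(fs$spec, seed = 401, params = fs$params)
  x <- sim$track$counts
  expect_length(x, 1e5)
  expect_gte(mean(x), 99); expect_lte(mean(x), 101)
  vmr_hat <- var(x) / mean(x)
  expect_gte(vmr_hat, 2.9); expect_lte(vmr_hat, 3.1)
})

test_that("a copy-neutral 'alteration' is indistinguishable from none", {
  fs <- flat_spec(n_bins = 1000)
  spec2 <- trial_spec(coverage = fs$spec$coverage, cna_size = 2e5,
                      cna_cn = 2, chrom_length = fs$spec$chrom_length)
  a <- simulate_counts(fs$spec, seed = 7, params = fs$params)
  b <- simulate_counts(spec2, seed = 7, params = fs$params)
  expect_identical(a$track$counts, b$track$counts)
})

test_that("a low-coverage lane configuration reports its model", {
  # single 76 bp lane at 0.5x coverage of a chromosome-1-sized territory
  spec <- trial_spec(coverage = 0.5, cna_size = 2e6, read_length = 76)
  params <- simulate_counts(spec, seed = 1)$params
  expect_equal(params$lam,
               params$n_reads * params$bin_size / params$genome_size)
  expect_gt(params$bin_size, 0)
  expect_lte(params$fdr_achieved, 0.01)
})

test_that("sub-bin alterations warn as undetectable", {
  spec <- trial_spec(coverage = 5, cna_size = 1000, chrom_length = 8e6)
  expect_warning(simulate_counts(spec, seed = 3), "smaller than one bin")
})

test_that("trial scoring applies the both-edges definitions", {
  truth <- list(start = 1e6, end = 3e6, copy_number = 3)
  seg <- function(s, e, call = "gain")
    data.frame(chrom = "chr1", start = s, end = e, n_bins = 10L,
               mean_depth = 600, copy_number = 3,
               call = factor(call, c("loss", "neutral", "gain")))
  exact <- score_trial(seg(1e6, 3e6), truth, 25000)
  expect_true(exact$detected)
  expect_equal(exact$n_false_positives, 0L)
  off <- score_trial(seg(1e6 + 5e4, 3e6 + 5e4), truth, 25000)
  expect_false(off$detected)
  expect_equal(off$n_false_positives, 1L)
  three <- score_trial(rbind(seg(1e6, 3e6), seg(4e6, 5e6),
                             seg(6e6, 6.5e6)), truth, 25000)
  expect_true(three$detected)
  expect_equal(three$n_false_positives, 2L)
  # neutral rows are not calls
  none <- score_trial(seg(1e6, 3e6, call = "neutral"), truth, 25000)
  expect_false(none$detected)
  expect_equal(none$n_false_positives, 0L)
})

test_that("an idealized caller returning the truth has specificity one", {
  truth <- list(start = 2e6, end = 4e6, copy_number = 3)
  ideal <- data.frame(chrom = "chr1", start = truth$start,
                      end = truth$end, n_bins = 80L, mean_depth = 600,
                      copy_number = 3,
                      call = factor("gain", c("loss", "neutral", "gain")))
  sc <- score_trial(ideal, truth, 25000)
  expect_true(sc$detected)
  expect_equal(sc$n_false_positives, 0L)
})

test_that("trial batteries are seeded and degenerate cases score zero", {
  spec0 <- trial_spec(coverage = 5, cna_size = 0, chrom_length = 2e6)
  res <- run_trials(spec0, 3, seed = 5)
  expect_equal(res$sensitivity, 0)
  spec <- trial_spec(coverage = 5, cna_size = 1e6, chrom_length = 4e6)
  a <- run_trials(spec, 3, seed = 11)
  b <- run_trials(spec, 3, seed = 11)
  expect_identical(a$trials, b$trials)
  expect_identical(a$sensitivity, b$sensitivity)
})

test_that("with no alteration, threshold crossings match the null model", {
  fs <- flat_spec(n_bins = 1e5)
  sim <- simulate_counts(fs$spec, seed = 88, params = fs$params)
  p <- fs$params
  cross <- mean(sim$track$counts < p$t_loss | sim$track$counts > p$t_gain)
  # independent expectation for diploid bins, straight from the cdf
  mu <- p$lam; size <- mu / (p$vmr - 1)
  expected <- pnbinom(p$t_loss - 1, mu = mu, size = size) +
    (1 - pnbinom(p$t_gain, mu = mu, size = size))
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_lt(abs(cross - expected), 3 * se)
})

test_that("the read-level emitter reproduces its bin counts", {
  spec <- trial_spec(coverage = 5, cna_size = 1e6, chrom_length = 4e6)
  sim <- simulate_reads(spec, seed = 19)
  pos <- sim$reads$chr1
  expect_true(all(pos >= 0 & pos < spec$chrom_length))
  counts <- bin_counts(pos, spec$chrom_length, sim$params$bin_size)
  expect_equal(sum(counts), length(pos))
  # CNA region should be visibly amplified
  inside <- counts[(sim$truth$start / sim$params$bin_size + 1):
                     (sim$truth$end / sim$params$bin_size)]
  outside <- counts[1:(sim$truth$start / sim$params$bin_size)]
  expect_gt(mean(inside) / mean(outside), 1.3)
})
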