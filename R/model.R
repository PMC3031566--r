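#' @useDynLib depthCNA, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dnbinom pnbinom qnbinom rnbinom dpois ppois qpois rpois
#'   median loess predict
NULL

# mean of the class-c distribution: c * lam / 2 (diploid bins average lam)
.class_mu <- function(copy_number, lam) copy_number * lam / 2

.nb_cdf <- function(q, copy_number, lam, vmr) {
  mu <- .class_mu(copy_number, lam)
  if (vmr == 1) ppois(q, mu) else pnbinom(q, mu = mu, size = mu / (vmr - 1))
}

.nb_logpmf <- function(x, copy_number, lam, vmr) {
  mu <- .class_mu(copy_number, lam)
  if (vmr == 1) dpois(x, mu, log = TRUE)
  else dnbinom(x, mu = mu, size = mu / (vmr - 1), log = TRUE)
}

.nb_quantile <- function(p, copy_number, lam, vmr) {
  mu <- .class_mu(copy_number, lam)
  if (vmr == 1) qpois(p, mu) else qnbinom(p, mu = mu, size = mu / (vmr - 1))
}

.check_vmr <- function(vmr) {
  if (!is.numeric(vmr) || length(vmr) != 1L || is.na(vmr) || vmr < 1)
    stop("`vmr` must be a single number >= 1 (1 is the Poisson limit)",
         call. = FALSE)
}

#' Expected reads per bin
#'
#' Mean number of reads falling in a bin of `bin_size` bases when `n_reads`
#' uniquely mapping reads are spread over a genome of `genome_size` bases:
#' `n * b / g`.
#'
#' @param n_reads number of uniquely mapping reads.
#' @param bin_size bin width in bases.
#' @param genome_size genome (or mappable genome) size in bases.
#' @return expected reads per diploid bin (lambda).
#' @examples
#' expected_reads_per_bin(1000, 100, 100000) # 1
#' @export
expected_reads_per_bin <- function(n_reads, bin_size, genome_size) {
  if (!is.numeric(genome_size) || length(genome_size) != 1L ||
      is.na(genome_size) || genome_size <= 0)
    stop("`genome_size` must be a positive number", call. = FALSE)
  if (n_reads < 0 || bin_size < 0)
    stop("`n_reads` and `bin_size` must be non-negative", call. = FALSE)
  n_reads * bin_size / genome_size
}

#' Copy-class negative binomial probability mass
#'
#' Probability of observing `count` reads in a bin of copy number
#' `copy_number`, under the overdispersed model: negative binomial with mean
#' `mu = copy_number * lam / 2` and size `mu / (vmr - 1)`, so that the
#' variance is `vmr * mu`.  At `vmr = 1` the Poisson limit is used.
#'
#' @param count non-negative integer count (vectorized).
#' @param copy_number copy number class, one of 1, 2, 3.
#' @param lam expected reads per diploid bin.
#' @param vmr variance/mean ratio (>= 1).
#' @return probability mass at `count`.
#' @export
nbinom_pmf_class <- function(count, copy_number, lam, vmr) {
  .check_vmr(vmr)
  if (lam <= 0) stop("`lam` must be positive", call. = FALSE)
  if (!copy_number %in% c(1, 2, 3))
    stop("`copy_number` must be 1, 2 or 3", call. = FALSE)
  exp(.nb_logpmf(count, copy_number, lam, vmr))
}

#' Copy-class distributions
#'
#' The three read-count distributions (copy number 1, 2, 3) sharing a
#' variance/mean ratio, with the support cutoff used for exact mass sums.
#'
#' @inheritParams nbinom_pmf_class
#' @param p_tail upper-tail mass excluded by `support_max`.
#' @return list with `means`, `vmr` and `support_max`.
#' @export
class_distributions <- function(lam, vmr, p_tail = 1e-9) {
  .check_vmr(vmr)
  if (lam <= 0) stop("`lam` must be positive", call. = FALSE)
  list(means = .class_mu(c(1, 2, 3), lam), vmr = vmr,
       support_max = max(vapply(c(1, 2, 3), function(cn)
         .nb_quantile(1 - p_tail, cn, lam, vmr), numeric(1))))
}

# misclassification mass of the loss cut at t (count < t called loss):
# CN1 bins not called loss + CN2 bins called loss
.loss_cut_mass <- function(t, lam, vmr)
  (1 - .nb_cdf(t - 1, 1, lam, vmr)) + .nb_cdf(t - 1, 2, lam, vmr)

# misclassification mass of the gain cut at t (count > t called gain):
# CN2 bins called gain + CN3 bins not called gain
.gain_cut_mass <- function(t, lam, vmr)
  (1 - .nb_cdf(t, 2, lam, vmr)) + .nb_cdf(t, 3, lam, vmr)

# first integer t in [lo, hi] with f(t) >= 0, f monotone non-decreasing
.first_nonneg <- function(f, lo, hi) {
  while (lo < hi) {
    mid <- floor((lo + hi) / 2)
    if (f(mid) >= 0) hi <- mid else lo <- mid + 1
  }
  lo
}

#' Optimal gain/loss thresholds
#'
#' Finds the integer read-count cuts separating the copy-number 1/2 and 2/3
#' distributions that minimize the total misclassification mass, and the
#' false-discovery rate those cuts achieve.  A bin with `count < t_loss` is
#' called a loss, `count > t_gain` a gain, anything else neutral.  The FDR is
#' the summed misclassification probability of the three class
#' distributions under those cuts (expected misclassified bins per bin drawn
#' from each class).
#'
#' Because the three distributions share the negative binomial probability
#' parameter, their likelihood ratios are monotone in the count, so each
#' cut's misclassification mass is unimodal and the minimizer is located by
#' bisection on the sign of the pmf difference; a local exact scan then
#' resolves ties.  Ties are broken toward the threshold pair whose midpoint
#' is closest to `lam`, then toward smaller thresholds.
#'
#' @inheritParams nbinom_pmf_class
#' @return list with integer `t_loss`, `t_gain` and achieved `fdr`.
#' @export
optimize_thresholds <- function(lam, vmr) {
  .check_vmr(vmr)
  if (lam <= 0) stop("`lam` must be positive", call. = FALSE)
  hi <- .nb_quantile(1 - 1e-12, 3, lam, vmr) + 1
  # loss cut: mass difference A(t+1) - A(t) = p2(t) - p1(t), monotone sign
  ta <- .first_nonneg(function(t)
    .nb_logpmf(t, 2, lam, vmr) - .nb_logpmf(t, 1, lam, vmr), 0, hi)
  # gain cut: B(t+1) - B(t) = p3(t+1) - p2(t+1)
  tb <- .first_nonneg(function(t)
    .nb_logpmf(t + 1, 3, lam, vmr) - .nb_logpmf(t + 1, 2, lam, vmr), 0, hi)
  ties <- function(tc, mass_fun) {
    w <- max(0, tc - 50):(tc + 50)
    v <- mass_fun(w, lam, vmr)
    w[v == min(v)]
  }
  ia <- ties(ta, .loss_cut_mass)
  ib <- ties(tb, .gain_cut_mass)
  cand <- expand.grid(t_loss = ia, t_gain = ib)
  cand <- cand[cand$t_gain > cand$t_loss, , drop = FALSE]
  if (nrow(cand) == 0L) cand <- data.frame(t_loss = min(ia),
                                           t_gain = min(ia) + 1)
  o <- order(abs((cand$t_loss + cand$t_gain) / 2 - lam),
             cand$t_loss, cand$t_gain)
  tl <- cand$t_loss[o[1]]
  tg <- cand$t_gain[o[1]]
  list(t_loss = as.integer(tl), t_gain = as.integer(tg),
       fdr = .loss_cut_mass(tl, lam, vmr) + .gain_cut_mass(tg, lam, vmr))
}

#' Classify bin counts against model thresholds
#'
#' @param counts numeric vector of (corrected) bin counts.
#' @param t_loss,t_gain integer thresholds; counts strictly below `t_loss`
#'   are losses, strictly above `t_gain` gains, boundary counts neutral.
#' @return factor with levels loss/neutral/gain.
#' @export
classify_counts <- function(counts, t_loss, t_gain) {
  out <- rep("neutral", length(counts))
  out[counts < t_loss] <- "loss"
  out[counts > t_gain] <- "gain"
  factor(out, levels = c("loss", "neutral", "gain"))
}

#' Draw bin counts from a copy-number class
#'
#' Seeded sampling mode of the model, used for Monte-Carlo calibration of
#' the exact misclassification masses.
#'
#' @param n number of draws.
#' @inheritParams nbinom_pmf_class
#' @export
sample_class_counts <- function(n, copy_number, lam, vmr) {
  .check_vmr(vmr)
  mu <- .class_mu(copy_number, lam)
  if (vmr == 1) rpois(n, mu) else rnbinom(n, mu = mu, size = mu / (vmr - 1))
}

#' Select the smallest bin size meeting an FDR target
#'
#' Searches the bin-size grid (multiples of `grid_step` up to `max_bin`) for
#' the smallest bin size whose optimal thresholds achieve
#' `fdr <= fdr_target`.  The achieved FDR is non-increasing in bin size
#' (larger bins separate the copy-number classes better), so the search
#' bisects the grid.
#'
#' @param n_reads number of uniquely mapping reads.
#' @param genome_size genome (or mappable genome) size in bases.
#' @param vmr variance/mean ratio of bin counts (default 3).
#' @param fdr_target maximum tolerated misclassification rate, in (0, 1).
#' @param grid_step,max_bin bin-size search grid: multiples of `grid_step`
#'   bases up to `max_bin`.
#' @return a `model_params` object (see [model_params()]).
#' @export
select_bin_size <- function(n_reads, genome_size, vmr = 3, fdr_target = 0.01,
                            grid_step = 100, max_bin = 1e7) {
  .check_vmr(vmr)
  if (!is.numeric(fdr_target) || fdr_target <= 0 || fdr_target >= 1)
    stop("`fdr_target` must lie in (0, 1)", call. = FALSE)
  if (n_reads <= 0) stop("`n_reads` must be positive", call. = FALSE)
  fdr_at <- function(b)
    optimize_thresholds(expected_reads_per_bin(n_reads, b, genome_size),
                        vmr)$fdr
  hi <- as.integer(max_bin / grid_step)
  best <- fdr_at(hi * grid_step)
  if (best > fdr_target)
    stop(sprintf(paste0("no bin size up to %g bp meets the FDR target %g; ",
                        "best achievable FDR is %.4g"),
                 hi * grid_step, fdr_target, best), call. = FALSE)
  lo <- 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (fdr_at(mid * grid_step) <= fdr_target) hi <- mid else lo <- mid + 1L
  }
  bin_size <- lo * grid_step
  lam <- expected_reads_per_bin(n_reads, bin_size, genome_size)
  th <- optimize_thresholds(lam, vmr)
  model_params(n_reads = n_reads, genome_size = genome_size,
               bin_size = bin_size, lam = lam, vmr = vmr,
               fdr_target = fdr_target, t_loss = th$t_loss,
               t_gain = th$t_gain, fdr_achieved = th$fdr)
}

#' Model parameter bundle
#'
#' Read-depth model parameters: input sizes, selected bin size, expected
#' reads per diploid bin, overdispersion, and the thresholds/FDR achieved.
#'
#' @param n_reads,genome_size,bin_size,lam,vmr,fdr_target,t_loss,t_gain,fdr_achieved
#'   see [select_bin_size()].
#' @return object of class `model_params`.
#' @export
model_params <- function(n_reads, genome_size, bin_size, lam, vmr,
                         fdr_target, t_loss, t_gain, fdr_achieved) {
  stopifnot(isTRUE(all.equal(lam, n_reads * bin_size / genome_size)))
  structure(list(n_reads = n_reads, genome_size = genome_size,
                 bin_size = bin_size, lam = lam, vmr = vmr,
                 fdr_target = fdr_target, t_loss = as.integer(t_loss),
                 t_gain = as.integer(t_gain), fdr_achieved = fdr_achieved),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("read-depth model parameters\n")
  cat(sprintf("  reads:        %g\n", x$n_reads))
  cat(sprintf("  genome size:  %g bp\n", x$genome_size))
  cat(sprintf("  bin size:     %g bp\n", x$bin_size))
  cat(sprintf("  lambda:       %.3f reads/bin (VMR %.2f)\n", x$lam, x$vmr))
  cat(sprintf("  thresholds:   loss < %d, gain > %d\n", x$t_loss, x$t_gain))
  cat(sprintf("  FDR:          %.4g (target %.4g)\n",
              x$fdr_achieved, x$fdr_target))
  invisible(x)
}

#' Serialize model parameters as key=value text
#'
#' @param params a `model_params` object.
#' @param path output file (`params.txt` convention).
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "model_params"))
  writeLines(sprintf("%s=%.15g", names(params),
                     vapply(params, as.numeric, numeric(1))), path)
  invisible(path)
}

#' Read serialized model parameters
#'
#' @param path file written by [write_params()].
#' @export
read_params <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- as.numeric(vapply(kv, `[`, character(1), 2))
  names(vals) <- vapply(kv, `[`, character(1), 1)
  do.call(model_params, as.list(vals))
}
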