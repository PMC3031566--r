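#' Specification of one simulated trial
#'
#' Describes a simulated chromosome carrying a single seeded copy-number
#' alteration: diploid background counts follow the negative binomial model
#' at the coverage-implied rate, and the seeded interval is drawn at the
#' alternative copy number.
#'
#' @param coverage fold sequence coverage.
#' @param cna_size alteration size in bases.
#' @param cna_start alteration start in bases (default: centered).
#' @param cna_cn alteration copy number (the validation protocol uses 1 or 3).
#' @param chrom_length chromosome length in bases (default 247 Mbp, a
#'   chromosome-1-sized territory).
#' @param read_length read length in bases (default 76).
#' @param vmr variance/mean ratio (default 3).
#' @param fdr_target FDR target for bin-size selection (default 0.01).
#' @param snap if TRUE (default) the seeded edges are snapped to bin
#'   boundaries; FALSE leaves them off-grid (for refinement studies).
#' @param chrom chromosome name.
#' @return object of class `trial_spec`.
#' @export
trial_spec <- function(coverage, cna_size, cna_start = NULL, cna_cn = 3,
                       chrom_length = 247e6, read_length = 76, vmr = 3,
                       fdr_target = 0.01, snap = TRUE, chrom = "chr1") {
  if (is.null(cna_start)) cna_start <- round((chrom_length - cna_size) / 2)
  if (cna_size < 0 || cna_start < 0 ||
      cna_start + cna_size > chrom_length)
    stop("seeded alteration must lie inside the chromosome", call. = FALSE)
  structure(list(coverage = coverage, cna_size = cna_size,
                 cna_start = cna_start, cna_cn = cna_cn,
                 chrom_length = chrom_length, read_length = read_length,
                 vmr = vmr, fdr_target = fdr_target, snap = snap,
                 chrom = chrom),
            class = "trial_spec")
}

.spec_params <- function(spec) {
  n_reads <- spec$coverage * spec$chrom_length / spec$read_length
  select_bin_size(n_reads, spec$chrom_length, vmr = spec$vmr,
                  fdr_target = spec$fdr_target)
}

.spec_truth <- function(spec, bin_size) {
  if (spec$cna_size == 0)
    return(list(start = NA_real_, end = NA_real_, copy_number = spec$cna_cn,
                bins = integer(0)))
  s <- spec$cna_start; e <- spec$cna_start + spec$cna_size
  if (spec$snap) {
    s <- round(s / bin_size) * bin_size
    e <- round(e / bin_size) * bin_size
  }
  n_bins <- ceiling(spec$chrom_length / bin_size)
  mid <- (seq_len(n_bins) - 0.5) * bin_size
  list(start = s, end = e, copy_number = spec$cna_cn,
       bins = which(mid >= s & mid < e))
}

#' Simulate a binned read-depth track with a seeded alteration
#'
#' Selects the bin size from the trial's implied read count, then draws
#' per-bin counts from the class distributions: copy number 2 outside the
#' seeded interval, the seeded copy number inside.  Mapability defaults to
#' 1 and GC to flat (no bias); a mapability profile, per-bin GC and a GC
#' bias multiplier can be injected to exercise the correction path.
#'
#' @param spec a [trial_spec()].
#' @param seed optional integer seed.
#' @param params optionally, precomputed `model_params` for this spec
#'   (avoids re-running bin-size selection across trials).
#' @param mapability optional per-bin mapable fractions; expected counts are
#'   thinned accordingly (reads lost in poorly mappable bins).
#' @param gc optional per-bin GC fractions.
#' @param gc_bias optional function mapping GC fraction to a depth
#'   multiplier (the injected bias curve).
#' @return list with `track` ([bin_track()]), `truth` (seeded start/end/
#'   copy_number and member bins) and `params`.
#' @export
simulate_counts <- function(spec, seed = NULL, params = NULL,
                            mapability = NULL, gc = NULL, gc_bias = NULL) {
  stopifnot(inherits(spec, "trial_spec"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(params)) params <- .spec_params(spec)
  b <- params$bin_size
  n_bins <- as.integer(ceiling(spec$chrom_length / b))
  truth <- .spec_truth(spec, b)
  if (spec$cna_size > 0 && spec$cna_size < b)
    warning("seeded alteration smaller than one bin; undetectable by ",
            "construction", call. = FALSE)
  cn <- rep(2, n_bins)
  cn[truth$bins] <- spec$cna_cn
  mu <- cn * params$lam / 2
  if (!is.null(mapability)) mu <- mu * mapability
  if (!is.null(gc_bias) && !is.null(gc)) mu <- mu * gc_bias(gc)
  counts <- if (spec$vmr == 1) rpois(n_bins, mu)
            else rnbinom(n_bins, mu = mu, size = mu / (spec$vmr - 1))
  track <- bin_track(spec$chrom, spec$chrom_length, b, counts,
                     mapability = mapability, gc = gc)
  list(track = track, truth = truth, params = params)
}

#' Simulate read start positions (read-level emitter)
#'
#' Feeds the full I/O path: per-bin counts are drawn as in
#' [simulate_counts()] and each read is placed uniformly within its bin.
#'
#' @inheritParams simulate_counts
#' @return list with `reads` (named list of sorted 0-based positions),
#'   `truth` and `params`.
#' @export
simulate_reads <- function(spec, seed = NULL, params = NULL) {
  sim <- simulate_counts(spec, seed = seed, params = params)
  b <- sim$params$bin_size
  counts <- sim$track$counts
  offsets <- rep((seq_along(counts) - 1) * b, counts)
  width <- pmin(rep(b, length(counts)),
                spec$chrom_length - (seq_along(counts) - 1) * b)
  pos <- sort(offsets + floor(stats::runif(sum(counts)) *
                                rep(width, counts)))
  reads <- stats::setNames(list(pos), spec$chrom)
  list(reads = reads, truth = sim$truth, params = sim$params)
}

#' Score one trial against the seeded truth
#'
#' A trial is detected when some gain/loss call matches both edges of the
#' seeded alteration within one bin size; every call failing that both-ends
#' test is a false positive.
#'
#' @param calls data.frame of called segments (rows with call != neutral
#'   are considered; a fully neutral table yields no calls).
#' @param truth seeded alteration (`start`, `end`) from
#'   [simulate_counts()]; NULL or NA edges mean no seeded alteration.
#' @param bin_size edge-match tolerance in bases.
#' @return list with `detected`, `n_false_positives`, `called_edges`.
#' @export
score_trial <- function(calls, truth, bin_size) {
  if (!is.null(calls) && nrow(calls))
    calls <- calls[calls$call != "neutral", , drop = FALSE]
  if (is.null(calls) || !nrow(calls))
    return(list(detected = FALSE, n_false_positives = 0L,
                called_edges = numeric(0)))
  if (is.null(truth) || is.na(truth$start)) {
    return(list(detected = FALSE, n_false_positives = nrow(calls),
                called_edges = c(rbind(calls$start, calls$end))))
  }
  match_both <- abs(calls$start - truth$start) <= bin_size &
    abs(calls$end - truth$end) <= bin_size
  list(detected = any(match_both),
       n_false_positives = sum(!match_both),
       called_edges = c(rbind(calls$start, calls$end)))
}

#' Run a battery of seeded-alteration trials
#'
#' For each trial, simulates a track, runs the calling pipeline
#' ([call_cna_track()]) and scores the result.  Sensitivity is the fraction
#' of trials whose seeded alteration was detected (both edges within one
#' bin size); specificity is one minus the fraction of trials with at least
#' one false positive call.  Per-trial seeds derive deterministically from
#' the master seed.
#'
#' @param spec a [trial_spec()].
#' @param n_trials number of trials.
#' @param seed master seed.
#' @param alpha,n_perm,min_width segmentation settings (see
#'   [call_cna_track()]).
#' @return list with `sensitivity`, `specificity`, per-trial `trials`
#'   data.frame, and the `params` shared by all trials.
#' @export
run_trials <- function(spec, n_trials, seed, alpha = 0.01, n_perm = 1000,
                       min_width = NULL) {
  stopifnot(n_trials >= 1)
  params <- .spec_params(spec)
  set.seed(seed)
  trial_seeds <- sample.int(2^31 - 2, n_trials)
  rows <- lapply(seq_len(n_trials), function(i) {
    sim <- simulate_counts(spec, seed = trial_seeds[i], params = params)
    segs <- call_cna_track(sim$track, params, alpha = alpha,
                           n_perm = n_perm, min_width = min_width)
    sc <- score_trial(segs, sim$truth, params$bin_size)
    data.frame(trial = i, seed = trial_seeds[i],
               detected = sc$detected,
               n_false_positives = sc$n_false_positives)
  })
  trials <- do.call(rbind, rows)
  list(sensitivity = mean(trials$detected),
       specificity = 1 - mean(trials$n_false_positives >= 1),
       trials = trials, params = params)
}
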