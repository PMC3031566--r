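#' Circular binary segmentation of a depth vector
#'
#' Recursively splits the vector at the arc `(i, j]` maximizing the circular
#' two-sample t statistic, accepting a split when its permutation p-value is
#' below `alpha` and every resulting segment spans at least `min_width`
#' bins.  The statistic is computed on `log2(depth / median)` (zeros
#' replaced by half the smallest positive depth), which stabilizes the
#' variance across copy-number levels.  Masked bins are removed before
#' segmentation and coordinates re-expanded afterwards.  Results are
#' deterministic given `seed`.
#'
#' @param depth numeric vector of corrected bin depths for one chromosome.
#' @param mask logical vector; masked bins are excluded.
#' @param alpha significance level for accepting a split (default 0.01).
#' @param min_width minimum number of (unmasked) bins per segment.
#' @param n_perm permutations per split test (default 1000).
#' @param seed optional integer seed.
#' @return sorted integer vector of breakpoints: value `k` means a segment
#'   boundary between original bins `k` and `k + 1` (1-based).
#' @export
cbs_segment <- function(depth, mask = NULL, alpha = 0.01, min_width = 2,
                        n_perm = 1000, seed = NULL) {
  stopifnot(min_width >= 2, n_perm >= 1, alpha > 0, alpha < 1)
  if (is.null(mask)) mask <- rep(FALSE, length(depth))
  if (!is.null(seed)) set.seed(seed)
  unm <- which(!mask)
  if (length(unm) < 2 * min_width) return(integer(0))
  y <- depth[unm]
  if (any(y == 0)) {
    pos <- y[y > 0]
    y[y == 0] <- if (length(pos)) min(pos) / 2 else 1
  }
  x <- log2(y / stats::median(y))
  cuts <- .cbs_recurse(x, 1L, length(x), alpha, min_width, n_perm)
  sort(unm[cuts])
}

# recursion over the compacted vector; returns compacted cut positions
.cbs_recurse <- function(x, lo, hi, alpha, min_width, n_perm) {
  m <- hi - lo + 1L
  if (m < 2 * min_width) return(integer(0))
  seg <- x[lo:hi]
  res <- .cbs_max_t(seg, as.integer(min_width))
  t2 <- res[1]; i <- as.integer(res[2]); j <- as.integer(res[3])
  if (t2 <= 0 || (i == 0L && j == m)) return(integer(0))
  # stop permuting once the exceedance count already implies p >= alpha
  stop_at <- ceiling(alpha * (n_perm + 1) - 1)
  ex <- .cbs_perm_exceed(seg, t2, as.integer(n_perm),
                         as.integer(max(1, stop_at)),
                         as.integer(min_width))[1]
  if ((ex + 1) / (n_perm + 1) >= alpha) return(integer(0))
  cuts <- integer(0)
  if (i > 0L) cuts <- c(cuts, lo - 1L + i)
  if (j < m) cuts <- c(cuts, lo - 1L + j)
  bounds <- c(lo - 1L, cuts, hi)
  kids <- lapply(seq_len(length(bounds) - 1L), function(k)
    .cbs_recurse(x, bounds[k] + 1L, bounds[k + 1L], alpha, min_width,
                 n_perm))
  sort(c(cuts, unlist(kids)))
}

#' Segment one chromosome's track
#'
#' Runs [cbs_segment()] on a track and converts the breakpoints into
#' genomic segments.  Segments tile the track's unmasked extent: the first
#' starts at the first unmasked bin, the last ends at the last unmasked bin
#' (capped at the chromosome length); interior masked gaps stay inside the
#' enclosing segment's interval.
#'
#' @param track a [bin_track()] with corrected counts.
#' @inheritParams cbs_segment
#' @return data.frame with chrom, start, end (0-based half-open), n_bins
#'   (unmasked bins) and mean_depth.
#' @export
segment_track <- function(track, alpha = 0.01, min_width = 2,
                          n_perm = 1000, seed = NULL) {
  stopifnot(inherits(track, "bin_track"))
  unm <- which(!track$mask)
  if (!length(unm))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), n_bins = integer(0),
                      mean_depth = numeric(0)))
  cuts <- cbs_segment(track$counts, track$mask, alpha = alpha,
                      min_width = min_width, n_perm = n_perm, seed = seed)
  b <- track$bin_size
  edges <- c(unm[1] - 1L, cuts, unm[length(unm)])
  out <- lapply(seq_len(length(edges) - 1L), function(k) {
    members <- unm[unm > edges[k] & unm <= edges[k + 1L]]
    data.frame(chrom = track$chrom,
               start = if (k == 1L) (unm[1] - 1) * b else edges[k] * b,
               end = if (k == length(edges) - 1L)
                 min(unm[length(unm)] * b, track$chrom_length)
               else edges[k + 1L] * b,
               n_bins = length(members),
               mean_depth = mean(track$counts[members]))
  })
  do.call(rbind, out)
}

#' Diploid anchor depth
#'
#' Median corrected depth over all unmasked bins, the depth level assigned
#' copy number 2.
#'
#' @param x a [bin_track()] or list of them.
#' @export
diploid_anchor <- function(x) {
  tracks <- .gather_tracks(x)
  stats::median(unlist(lapply(tracks, function(t) t$counts[!t$mask])))
}

#' Assign copy numbers and gain/loss calls to segments
#'
#' Copy number is `2 * mean_depth / lam_diploid`; a segment is flagged a
#' gain when its mean depth exceeds the model's per-bin gain threshold, a
#' loss when below the loss threshold, neutral otherwise.  Applying the
#' bin-level thresholds to segment means is conservative.
#'
#' @param segments data.frame from [segment_track()] (rows from several
#'   chromosomes may be combined).
#' @param params a `model_params` object with `t_loss` and `t_gain`.
#' @param lam_diploid depth level corresponding to copy number 2; defaults
#'   to the model's expected reads per bin.  Use [diploid_anchor()] for the
#'   genome-median anchor.
#' @return `segments` with `copy_number` and `call` columns.
#' @export
call_segments <- function(segments, params, lam_diploid = params$lam) {
  stopifnot(inherits(params, "model_params"))
  if (is.null(lam_diploid) || is.na(lam_diploid) || lam_diploid == 0)
    stop("diploid anchor depth is zero or undefined", call. = FALSE)
  segments$copy_number <- 2 * segments$mean_depth / lam_diploid
  segments$call <- classify_counts(segments$mean_depth,
                                   params$t_loss, params$t_gain)
  segments
}
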