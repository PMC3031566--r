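#' Mapability correction
#'
#' Scales each bin's count by the inverse of its mapable fraction, so that
#' a bin in which only half the positions accept a uniquely mapping read is
#' counted as if fully mappable.  Bins whose mapability falls below
#' `min_map` are masked instead of corrected, to prevent overcorrection.
#'
#' @param track a [bin_track()] with its `mapability` vector set.
#' @param min_map mapability below which a bin is masked (default 0.25).
#' @return the corrected `bin_track`.
#' @export
mapability_correct <- function(track, min_map = 0.25) {
  stopifnot(inherits(track, "bin_track"))
  low <- track$mapability < min_map
  ok <- !track$mask & !low
  track$counts[ok] <- track$counts[ok] / track$mapability[ok]
  track$mask <- track$mask | low
  track
}

.gather_tracks <- function(x) {
  if (inherits(x, "bin_track")) list(x)
  else { stopifnot(all(vapply(x, inherits, logical(1), "bin_track"))); x }
}

#' GC-bias curve
#'
#' Groups unmasked bins by GC fraction in increments of `gc_step` (0.1% by
#' default), averages their depth, and fits a locally weighted regression
#' (degree 2, span `span`, weighted by group occupancy) through the group
#' means.
#'
#' @param x a [bin_track()] or list of them (the fit pools chromosomes).
#' @param gc_step GC grouping increment (fraction; 0.001 = 0.1%).
#' @param span loess span.
#' @return data.frame with `gc`, `mean_depth`, `n`, `fitted`, or NULL when
#'   the data cannot support a fit.
#' @export
gc_curve <- function(x, gc_step = 0.001, span = 0.3) {
  tracks <- .gather_tracks(x)
  depth <- unlist(lapply(tracks, function(t) t$counts[!t$mask]))
  gc <- unlist(lapply(tracks, function(t) t$gc[!t$mask]))
  keep <- !is.na(gc)
  depth <- depth[keep]
  gc <- round(gc[keep] / gc_step) * gc_step
  if (!length(gc)) return(NULL)
  grp <- stats::aggregate(depth, by = list(gc = gc), FUN = mean)
  grp$n <- as.vector(table(gc)[as.character(grp$gc)])
  names(grp)[2] <- "mean_depth"
  if (nrow(grp) < 2) return(NULL)
  fit <- stats::loess(mean_depth ~ gc, data = grp, weights = grp$n,
                      span = span, degree = 2,
                      control = stats::loess.control(surface = "direct"))
  grp$fitted <- stats::predict(fit, newdata = grp)
  grp
}

#' GC-content correction
#'
#' Removes the dependence of read depth on bin GC content.  Bins are grouped
#' by GC in `gc_step` increments, the group-mean depths are smoothed by
#' locally weighted regression, and each bin receives the additive
#' correction `median(depth) - fitted(gc)`.  Corrected depths below zero are
#' floored at zero, and all adjusted depths are rescaled multiplicatively so
#' the correction is neutral with respect to the total number of reads.
#' Masked bins, and bins with unknown GC, are untouched.
#'
#' Requires at least `min_groups` occupied GC groups and `min_bins` unmasked
#' bins; otherwise the identity correction is applied with a warning.
#'
#' @inheritParams gc_curve
#' @param min_groups,min_bins minimum data for a trustworthy fit.
#' @return object of the same shape as `x`, corrected; the fitted curve is
#'   attached as `attr(, "gc_curve")`.
#' @export
gc_correct <- function(x, gc_step = 0.001, span = 0.3,
                       min_groups = 10, min_bins = 200) {
  single <- inherits(x, "bin_track")
  tracks <- .gather_tracks(x)
  if (any(vapply(tracks, function(t) is.null(t$gc), logical(1))))
    stop("gc vector missing from track", call. = FALSE)
  usable <- lapply(tracks, function(t) !t$mask & !is.na(t$gc))
  n_usable <- sum(vapply(usable, sum, numeric(1)))
  curve <- gc_curve(tracks, gc_step = gc_step, span = span)
  if (is.null(curve) || nrow(curve) < min_groups || n_usable < min_bins) {
    warning("too little data for a GC fit (",
            if (is.null(curve)) 0 else nrow(curve), " GC groups, ",
            n_usable, " bins); identity correction applied", call. = FALSE)
    return(x)
  }
  med <- stats::median(unlist(lapply(seq_along(tracks), function(i)
    tracks[[i]]$counts[usable[[i]]])))
  before <- sum(unlist(lapply(seq_along(tracks), function(i)
    tracks[[i]]$counts[usable[[i]]])))
  for (i in seq_along(tracks)) {
    u <- usable[[i]]
    if (!any(u)) next
    snapped <- round(tracks[[i]]$gc[u] / gc_step) * gc_step
    fitted <- curve$fitted[match(snapped, curve$gc)]
    adj <- tracks[[i]]$counts[u] + (med - fitted)
    tracks[[i]]$counts[u] <- pmax(adj, 0)
  }
  after <- sum(unlist(lapply(seq_along(tracks), function(i)
    tracks[[i]]$counts[usable[[i]]])))
  if (after > 0) {
    f <- before / after
    for (i in seq_along(tracks)) {
      u <- usable[[i]]
      tracks[[i]]$counts[u] <- tracks[[i]]$counts[u] * f
    }
  }
  out <- if (single) tracks[[1]] else tracks
  attr(out, "gc_curve") <- curve
  out
}

#' Per-bin base composition from a reference sequence
#'
#' Tallies A/C/G/T (mappable, i.e. non-ambiguous) bases per fixed-size bin
#' of each reference sequence, the input needed for bisulfite-aware
#' effective GC.
#'
#' @param seqs a `Biostrings::DNAStringSet`, or path to a FASTA file.
#' @param bin_size bin width in bases.
#' @return data.frame with `chrom`, `bin` (0-based index), `n_mappable`,
#'   `n_c`, `n_g` and the standard `gc` fraction (NA where no mappable
#'   base).
#' @export
bin_composition <- function(seqs, bin_size) {
  if (is.character(seqs)) seqs <- Biostrings::readDNAStringSet(seqs)
  out <- lapply(seq_along(seqs), function(i) {
    len <- Biostrings::width(seqs)[i]
    starts <- seq(1, len, by = bin_size)
    ends <- pmin(starts + bin_size - 1, len)
    v <- Biostrings::Views(seqs[[i]], start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    n_map <- rowSums(freq)
    data.frame(chrom = names(seqs)[i], bin = seq_along(starts) - 1L,
               n_mappable = n_map, n_c = freq[, "C"], n_g = freq[, "G"],
               gc = ifelse(n_map > 0, (freq[, "C"] + freq[, "G"]) / n_map,
                           NA_real_))
  })
  do.call(rbind, out)
}

#' Methylation-aware effective GC content
#'
#' Bisulfite treatment converts unmethylated cytosines to uracil (read as
#' thymine) while methylated cytosines are protected, so the base
#' composition the sequencer observes depends on the methylation state.
#' Each reference cytosine therefore contributes its methylation fraction
#' `n_methylated / n_total` to the G+C tally (the protected fraction stays a
#' C, the converted fraction reads as T); guanines, which are not altered on
#' the read strand, count fully.  Cytosines absent from the map contribute
#' the map's genome-wide mean methylation fraction.
#'
#' @param composition per-bin base counts from [bin_composition()].
#' @param meth a `methylation_map` ([load_methylation()]); plus-strand
#'   records describe the reference cytosines.
#' @param bin_size bin width used for `composition`.
#' @return numeric vector of effective GC fractions aligned with
#'   `composition` rows; NA (to be masked) where a bin has no mappable base.
#' @export
effective_gc <- function(composition, meth, bin_size) {
  stopifnot(inherits(meth, "methylation_map"))
  m_mean <- methylation_mean(meth)
  if (is.na(m_mean)) m_mean <- 0
  plus <- meth[meth$strand == "+", , drop = FALSE]
  key <- paste(composition$chrom, composition$bin)
  frac_sum <- n_present <- numeric(nrow(composition))
  if (nrow(plus)) {
    mkey <- paste(plus$chrom, floor(plus$pos / bin_size))
    frac <- ifelse(plus$n_total > 0, plus$n_methylated / plus$n_total,
                   m_mean)
    rs <- rowsum(frac, mkey)
    frac_sum <- rs[match(key, rownames(rs)), 1]
    frac_sum[is.na(frac_sum)] <- 0
    tab <- table(mkey)
    n_present <- as.vector(tab[key])
    n_present[is.na(n_present)] <- 0
  }
  if (any(n_present > composition$n_c))
    stop("methylation map lists more cytosines in a bin than the ",
         "composition contains", call. = FALSE)
  n_absent <- composition$n_c - n_present
  egc <- (composition$n_g + frac_sum + n_absent * m_mean) /
    composition$n_mappable
  egc[composition$n_mappable == 0] <- NA_real_
  unname(egc)
}
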