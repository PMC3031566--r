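#' Load paired-end breakpoint calls
#'
#' Accepts BED (single-base intervals; the 0-based start is the breakpoint
#' position) or a 2-column TSV `chrom<TAB>pos`.  An optional numeric third
#' TSV column (or BED score) is kept as `support`.
#'
#' @param path input file.
#' @return data.frame with `chrom`, `pos` and optional `support`, sorted.
#' @export
load_breakpoints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (tolower(tools::file_ext(path)) == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     pos = GenomicRanges::start(gr) - 1)
    sc <- S4Vectors::mcols(gr)$score
    if (!is.null(sc)) df$support <- sc
  } else {
    raw <- utils::read.delim(path, header = FALSE,
                             stringsAsFactors = FALSE)
    if (ncol(raw) < 2) stop("breakpoint TSV needs chrom and pos columns",
                            call. = FALSE)
    df <- data.frame(chrom = as.character(raw[[1]]),
                     pos = as.numeric(raw[[2]]))
    if (ncol(raw) >= 3) df$support <- as.numeric(raw[[3]])
  }
  df[order(df$chrom, df$pos), , drop = FALSE]
}

#' Refine segment boundaries with paired-end breakpoints
#'
#' Bin-level segmentation localizes a copy-number boundary only to within a
#' bin; junction coordinates from discordant read pairs are far more
#' precise.  For each boundary between a called (gain or loss) segment and
#' its neighbor, if exactly one breakpoint lies strictly within half a bin
#' size of the boundary, the boundary is moved to that breakpoint (both
#' adjacent segments are updated).  Boundaries with zero or two or more
#' candidate breakpoints in the window are ambiguous and left unchanged, as
#' is any move that would invert a segment.
#'
#' @param segments called segments ([call_segments()]).
#' @param breakpoints data.frame with `chrom` and `pos`
#'   ([load_breakpoints()]).
#' @param bin_size bin width in bases (the refinement window is
#'   `bin_size / 2`, open).
#' @return list with `segments` (refined), `n_refined` (boundaries moved)
#'   and `mean_residual` (mean absolute distance moved; NA if none).
#' @export
refine_boundaries <- function(segments, breakpoints, bin_size) {
  .check_segments(segments)
  half <- bin_size / 2
  segments <- segments[order(segments$chrom, segments$start), , drop = FALSE]
  moved <- numeric(0)
  for (ch in unique(segments$chrom)) {
    idx <- which(segments$chrom == ch)
    if (length(idx) < 2) next
    bp <- breakpoints$pos[breakpoints$chrom == ch]
    for (k in idx[-length(idx)]) {
      left <- k; right <- k + 1
      if (segments$call[left] == "neutral" &&
          segments$call[right] == "neutral") next
      bound <- segments$end[left]
      cand <- bp[abs(bp - bound) < half]
      if (length(cand) != 1L) next
      if (cand <= segments$start[left] || cand >= segments$end[right]) {
        warning(sprintf("refinement at %s:%g would invert a segment; %s",
                        ch, bound, "skipped"), call. = FALSE)
        next
      }
      if (cand != bound) {
        moved <- c(moved, abs(cand - bound))
        segments$end[left] <- cand
        segments$start[right] <- cand
      }
    }
  }
  list(segments = segments, n_refined = length(moved),
       mean_residual = if (length(moved)) mean(moved) else NA_real_)
}
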