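#' Per-chromosome binned track
#'
#' Container for one chromosome's fixed-size bins: raw or corrected read
#' counts, per-bin mapability and GC fractions, and a mask of bins excluded
#' from downstream statistics.  All vectors have length
#' `ceiling(chrom_length / bin_size)`; the trailing bin may be partial and is
#' flagged via `attr(, "partial")`.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bases.
#' @param bin_size bin width in bases.
#' @param counts numeric vector of bin counts (raw counts are integers;
#'   corrected counts are reals).
#' @param mapability per-bin mapable fraction in \[0, 1\] (default 1).
#' @param gc per-bin GC fraction in \[0, 1\], or NULL if unknown.
#' @param mask logical; TRUE marks bins excluded from statistics.
#' @return object of class `bin_track`.
#' @export
bin_track <- function(chrom, chrom_length, bin_size, counts,
                      mapability = NULL, gc = NULL, mask = NULL) {
  n_bins <- as.integer(ceiling(chrom_length / bin_size))
  if (length(counts) != n_bins)
    stop(sprintf("counts length %d != ceiling(%g / %g) = %d",
                 length(counts), chrom_length, bin_size, n_bins),
         call. = FALSE)
  if (any(counts < 0, na.rm = TRUE)) stop("negative bin count", call. = FALSE)
  if (is.null(mapability)) mapability <- rep(1, n_bins)
  if (is.null(mask)) mask <- rep(FALSE, n_bins)
  if (!is.null(gc) && any(gc < 0 | gc > 1, na.rm = TRUE))
    stop("gc values must lie in [0, 1]", call. = FALSE)
  if (any(mapability < 0 | mapability > 1, na.rm = TRUE))
    stop("mapability values must lie in [0, 1]", call. = FALSE)
  stopifnot(length(mapability) == n_bins, length(mask) == n_bins,
            is.null(gc) || length(gc) == n_bins)
  structure(list(chrom = as.character(chrom),
                 chrom_length = as.numeric(chrom_length),
                 bin_size = as.numeric(bin_size),
                 counts = as.numeric(counts),
                 mapability = as.numeric(mapability), gc = gc,
                 mask = as.logical(mask)),
            class = "bin_track",
            partial = (chrom_length %% bin_size) != 0)
}

#' @export
print.bin_track <- function(x, ...) {
  cat(sprintf("bin_track %s: %d bins of %g bp (%d masked)\n", x$chrom,
              length(x$counts), x$bin_size, sum(x$mask)))
  invisible(x)
}

#' Count read starts into fixed-size bins
#'
#' Each read is assigned to bin `floor(start / bin_size)`; bins are 0-based
#' half-open.  The trailing partial bin (if `chrom_length` is not a multiple
#' of `bin_size`) is kept and flagged on the result.
#'
#' @param positions 0-based read start positions on one chromosome.
#' @param chrom_length chromosome length in bases.
#' @param bin_size bin width in bases.
#' @return integer vector of length `ceiling(chrom_length / bin_size)`.
#' @export
bin_counts <- function(positions, chrom_length, bin_size) {
  n_bins <- as.integer(ceiling(chrom_length / bin_size))
  if (length(positions)) {
    bad <- which(positions < 0 | positions >= chrom_length)
    if (length(bad))
      stop(sprintf("read start %g outside [0, %g) (record %d)",
                   positions[bad[1]], chrom_length, bad[1]), call. = FALSE)
  }
  out <- tabulate(floor(positions / bin_size) + 1L, nbins = n_bins)
  attr(out, "partial") <- (chrom_length %% bin_size) != 0
  out
}

#' Load aligned read start positions
#'
#' Reads BED (read start = interval start) or SAM/BAM (leftmost aligned
#' position of mapped records) into per-chromosome sorted 0-based start
#' vectors.  Unmapped and zero-length records are dropped with a message;
#' records on chromosomes absent from `chrom_lengths` are skipped with a
#' warning.
#'
#' @param path input file.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param format "auto" (by extension), "bed", "sam" or "bam".
#' @return named list of sorted numeric position vectors, one per declared
#'   chromosome.
#' @export
load_reads <- function(path, chrom_lengths,
                       format = c("auto", "bed", "sam", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     bed = "bed", sam = "sam", bam = "bam",
                     stop("cannot infer read format from extension: ", path,
                          call. = FALSE))
  if (format == "bed") {
    gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                   error = function(e)
                     stop("BED parse error in ", path, ": ",
                          conditionMessage(e), call. = FALSE))
    chroms <- as.character(GenomicRanges::seqnames(gr))
    starts <- GenomicRanges::start(gr) - 1 # to 0-based
    widths <- GenomicRanges::width(gr)
    drop <- widths == 0
    if (any(drop)) {
      message(sum(drop), " zero-length record(s) dropped")
      chroms <- chroms[!drop]; starts <- starts[!drop]
    }
  } else {
    bam <- path
    if (format == "sam")
      bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                              indexDestination = FALSE)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, what = c("rname", "pos"))
    res <- Rsamtools::scanBam(bam, param = param)[[1]]
    n_total <- Rsamtools::countBam(bam)$records
    n_dropped <- n_total - length(res$pos)
    if (n_dropped > 0) message(n_dropped, " unmapped record(s) dropped")
    chroms <- as.character(res$rname)
    starts <- res$pos - 1
  }
  known <- chroms %in% names(chrom_lengths)
  if (any(!known)) {
    warning(sum(!known), " record(s) on undeclared chromosome(s) skipped: ",
            paste(unique(chroms[!known]), collapse = ", "), call. = FALSE)
    chroms <- chroms[known]; starts <- starts[known]
  }
  out <- lapply(names(chrom_lengths), function(ch)
    sort(starts[chroms == ch]))
  names(out) <- names(chrom_lengths)
  out
}

#' Bin reads into per-chromosome tracks
#'
#' @param reads named list of 0-based position vectors ([load_reads()]).
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param bin_size bin width in bases.
#' @return named list of [bin_track()] objects.
#' @export
bin_reads <- function(reads, chrom_lengths, bin_size) {
  out <- lapply(names(chrom_lengths), function(ch)
    bin_track(ch, chrom_lengths[[ch]], bin_size,
              bin_counts(reads[[ch]] %||% numeric(0),
                         chrom_lengths[[ch]], bin_size)))
  names(out) <- names(chrom_lengths)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an annotation track into per-bin averages
#'
#' Reads a bedGraph or fixed-step wiggle track whose values lie in \[0, 1\]
#' (mapability or GC fractions) and averages it, length-weighted, into bins.
#' Bases not covered by any interval contribute value 0; bins with no
#' covered base are additionally masked.
#'
#' @param path bedGraph or wiggle file.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @param bin_size bin width in bases.
#' @return named list (per chromosome) of `list(values, mask)`.
#' @export
load_track <- function(path, chrom_lengths, bin_size) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e)
                   stop("track parse error in ", path, ": ",
                        conditionMessage(e), call. = FALSE))
  sc <- S4Vectors::mcols(gr)$score
  if (is.null(sc)) stop("track has no score column: ", path, call. = FALSE)
  if (any(sc < 0 | sc > 1))
    stop("track value outside [0, 1] in ", path, call. = FALSE)
  keep <- as.character(GenomicRanges::seqnames(gr)) %in% names(chrom_lengths)
  if (any(!keep))
    warning(sum(!keep), " track interval(s) on undeclared chromosome(s) ",
            "skipped", call. = FALSE)
  gr <- gr[keep]
  if (sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr)))) <
      sum(as.numeric(GenomicRanges::width(gr))))
    stop("track intervals overlap in ", path, call. = FALSE)
  gr <- GenomeInfoDb::keepSeqlevels(gr, names(chrom_lengths),
                                    pruning.mode = "coarse")
  GenomeInfoDb::seqlengths(gr) <- chrom_lengths[
    GenomeInfoDb::seqlevels(gr)]
  bins <- GenomicRanges::tileGenome(GenomeInfoDb::seqinfo(gr),
                                    tilewidth = bin_size,
                                    cut.last.tile.in.chrom = TRUE)
  val <- GenomicRanges::binnedAverage(bins,
                                      GenomicRanges::coverage(gr,
                                                              weight = sc),
                                      "value")
  cov <- GenomicRanges::binnedAverage(bins, GenomicRanges::coverage(gr),
                                      "covered")
  out <- lapply(names(chrom_lengths), function(ch) {
    sel <- as.character(GenomicRanges::seqnames(val)) == ch
    list(values = S4Vectors::mcols(val)$value[sel],
         mask = S4Vectors::mcols(cov)$covered[sel] == 0)
  })
  names(out) <- names(chrom_lengths)
  out
}

#' Load a per-cytosine methylation report
#'
#' Tab-separated report with columns `chrom`, `pos` (0-based), `strand`,
#' `n_methylated`, `n_total`: for each cytosine, how often methylation was
#' observed among `n_total` informative reads.
#'
#' @param path TSV file with a header row.
#' @return data.frame of class `methylation_map`.
#' @export
load_methylation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "strand", "n_methylated", "n_total")
  if (!all(need %in% names(df)))
    stop("methylation report must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df[c("chrom", "pos")]))
    stop("duplicate cytosine position in methylation report", call. = FALSE)
  if (any(df$n_methylated < 0 | df$n_total < 0 |
          df$n_methylated > df$n_total))
    stop("methylation report requires 0 <= n_methylated <= n_total",
         call. = FALSE)
  class(df) <- c("methylation_map", "data.frame")
  df
}

#' Genome-wide mean methylation fraction of a map
#'
#' @param meth a `methylation_map` ([load_methylation()]).
#' @export
methylation_mean <- function(meth) {
  tot <- sum(meth$n_total)
  if (tot == 0) return(NA_real_)
  sum(meth$n_methylated) / tot
}

.check_segments <- function(segments) {
  need <- c("chrom", "start", "end", "n_bins", "mean_depth",
            "copy_number", "call")
  if (!all(need %in% names(segments)))
    stop("segments need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(segments$end <= segments$start))
    stop("segment with end <= start", call. = FALSE)
  for (ch in unique(segments$chrom)) {
    s <- segments[segments$chrom == ch, ]
    s <- s[order(s$start), ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping segments on ", ch, call. = FALSE)
  }
  invisible(segments)
}

#' Write copy-number segments as SEG-style TSV
#'
#' Columns: chrom, start, end (0-based half-open), n_bins, mean_depth,
#' copy_number, call.  Overlapping segments on one chromosome are rejected.
#'
#' @param segments data.frame of segments ([call_segments()]).
#' @param path output path.
#' @export
write_segments <- function(segments, path) {
  .check_segments(segments)
  utils::write.table(
    segments[c("chrom", "start", "end", "n_bins", "mean_depth",
               "copy_number", "call")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SEG-style TSV written by [write_segments()]
#'
#' @param path input path.
#' @export
read_segments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$call <- factor(df$call, levels = c("loss", "neutral", "gain"))
  .check_segments(df)
  df
}
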