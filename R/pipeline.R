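#' Run configuration
#'
#' Bundles paths and tuning parameters for a full calling run.  Defaults
#' follow the method's standard operating point: FDR target 0.01, VMR 3,
#' mapability floor 0.25, segmentation alpha 0.01 with 1000 permutations.
#'
#' @param reads path to aligned reads (BED/SAM/BAM).
#' @param genome named numeric vector of chromosome lengths, or path to a
#'   2-column TSV `chrom<TAB>length`.
#' @param outdir output directory (created if missing).
#' @param mapability optional bedGraph/wiggle mapability track (use a
#'   bisulfite mapability track in bisulfite mode).
#' @param gc_track optional bedGraph/wiggle of per-bin GC fractions.
#' @param fasta optional reference FASTA (GC computed from sequence;
#'   required for bisulfite mode).
#' @param methylation optional per-cytosine methylation report
#'   ([load_methylation()]); required for bisulfite mode.
#' @param breakpoints optional paired-end breakpoint calls
#'   ([load_breakpoints()]).
#' @param fdr_target,vmr,min_map,alpha,n_perm model and segmentation
#'   parameters.
#' @param min_width "auto" (2 when lambda < 100, else 4), or an integer.
#' @param workers parallel workers for per-chromosome stages; results are
#'   independent of the worker count.
#' @param seed master seed.
#' @param bisulfite logical; switches GC correction to the
#'   methylation-aware effective GC.
#' @return object of class `run_config`.
#' @export
run_config <- function(reads = NULL, genome = NULL, outdir = NULL,
                       mapability = NULL, gc_track = NULL, fasta = NULL,
                       methylation = NULL, breakpoints = NULL,
                       fdr_target = 0.01, vmr = 3, min_map = 0.25,
                       alpha = 0.01, n_perm = 1000, min_width = "auto",
                       workers = 1, seed = 1, bisulfite = FALSE) {
  if (!identical(min_width, "auto") &&
      (!is.numeric(min_width) || min_width < 2))
    stop("`min_width` must be \"auto\" or an integer >= 2", call. = FALSE)
  structure(list(reads = reads, genome = genome, outdir = outdir,
                 mapability = mapability, gc_track = gc_track,
                 fasta = fasta, methylation = methylation,
                 breakpoints = breakpoints, fdr_target = fdr_target,
                 vmr = vmr, min_map = min_map, alpha = alpha,
                 n_perm = n_perm, min_width = min_width,
                 workers = workers, seed = seed, bisulfite = bisulfite),
            class = "run_config")
}

.load_genome <- function(genome) {
  if (is.numeric(genome)) {
    if (is.null(names(genome))) stop("`genome` vector must be named",
                                     call. = FALSE)
    return(genome)
  }
  df <- utils::read.delim(genome, header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

# mappable genome size: declared length minus bases whose mapability is
# below the floor (uncovered track territory counts as unmappable)
.mappable_size <- function(chrom_lengths, mapability_path, min_map) {
  if (is.null(mapability_path)) return(sum(chrom_lengths))
  gr <- rtracklayer::import(mapability_path)
  keep <- as.character(GenomicRanges::seqnames(gr)) %in%
    names(chrom_lengths)
  gr <- gr[keep]
  sc <- S4Vectors::mcols(gr)$score
  sum(as.numeric(GenomicRanges::width(gr))[sc >= min_map])
}

.auto_min_width <- function(min_width, params) {
  if (!identical(min_width, "auto")) return(as.integer(min_width))
  if (params$lam < 100) 2L else 4L
}

#' Correct and call one chromosome track
#'
#' The per-chromosome calling core shared by [rd_run()] and the simulation
#' harness: mapability correction, optional GC correction (when the track
#' carries a GC vector), circular binary segmentation, and copy-number
#' calling against the model thresholds.  The diploid anchor is the track's
#' median unmasked depth; when more than half of the bins end up inside
#' called segments the anchor falls back to the model's expected depth.
#'
#' @param track a [bin_track()] with raw counts.
#' @param params `model_params` for the run.
#' @param alpha,n_perm segmentation settings.
#' @param min_width integer, or NULL for the automatic choice (2 when
#'   lambda < 100, else 4).
#' @param min_map mapability floor.
#' @param seed optional seed for the permutation stream.
#' @return called segments data.frame.
#' @export
call_cna_track <- function(track, params, alpha = 0.01, n_perm = 1000,
                           min_width = NULL, min_map = 0.25, seed = NULL) {
  if (is.null(min_width)) min_width <- .auto_min_width("auto", params)
  track <- mapability_correct(track, min_map)
  if (!is.null(track$gc)) track <- gc_correct(track)
  segs <- segment_track(track, alpha = alpha, min_width = min_width,
                        n_perm = n_perm, seed = seed)
  if (!nrow(segs)) return(cbind(segs, copy_number = numeric(0),
                                call = factor(character(0),
                                              c("loss", "neutral",
                                                "gain"))))
  anchor <- diploid_anchor(track)
  called <- call_segments(segs, params, lam_diploid = anchor)
  altered <- sum(called$n_bins[called$call != "neutral"])
  if (altered > sum(called$n_bins) / 2)
    called <- call_segments(segs, params, lam_diploid = params$lam)
  called
}

#' Model stage: bin size, thresholds and achieved FDR
#'
#' Runs only the model: counts the reads, determines the mappable genome
#' size, selects the smallest bin size meeting the FDR target and reports
#' the thresholds.  No binning or segmentation is performed.
#'
#' @param config a [run_config()]; alternatively pass `n_reads` and
#'   `genome_size` directly and leave `config` NULL.
#' @param n_reads,genome_size direct inputs, bypassing file I/O.
#' @return a `model_params` object (serialized to `params.txt` under
#'   `outdir` when configured).
#' @export
rd_model <- function(config = NULL, n_reads = NULL, genome_size = NULL) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "run_config"))
    if (is.null(n_reads)) {
      chrom_lengths <- .load_genome(config$genome)
      reads <- load_reads(config$reads, chrom_lengths)
      n_reads <- sum(lengths(reads))
      genome_size <- .mappable_size(chrom_lengths, config$mapability,
                                    config$min_map)
    }
    params <- select_bin_size(n_reads, genome_size, vmr = config$vmr,
                              fdr_target = config$fdr_target)
    if (!is.null(config$outdir)) {
      dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
      write_params(params, file.path(config$outdir, "params.txt"))
    }
  } else {
    params <- select_bin_size(n_reads, genome_size)
  }
  print(params)
  invisible(params)
}

.provenance <- function(config, params, extra = list()) {
  paths <- Filter(function(p) is.character(p) && length(p) == 1 &&
                    file.exists(p),
                  config[c("reads", "mapability", "gc_track", "fasta",
                           "methylation", "breakpoints")])
  digests <- lapply(paths, function(p) unname(tools::md5sum(p)))
  c(list(config = config[!vapply(config, is.null, logical(1))],
         params = unclass(params), input_md5 = digests,
         timestamp = format(Sys.time(), tz = "UTC")),
    extra)
}

#' Full copy-number calling run
#'
#' End-to-end pipeline: read loading, model-driven bin-size selection,
#' binning, mapability correction, (effective-)GC correction, circular
#' binary segmentation, copy-number calling, optional breakpoint
#' refinement, and output.  Writes `segments.seg`, `calls.bed` (gain/loss
#' segments only), `params.txt` and `provenance.json` under
#' `config$outdir`.  Chromosomes are processed in parallel across
#' `config$workers`; per-chromosome permutation streams are seeded from the
#' master seed, so the output is byte-identical for any worker count.
#'
#' @param config a [run_config()].
#' @return the called (and possibly refined) segments, invisibly.
#' @export
rd_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (need in c("reads", "genome", "outdir"))
    if (is.null(config[[need]]))
      stop("run_config is missing `", need, "`", call. = FALSE)
  if (config$bisulfite && (is.null(config$fasta) ||
                           is.null(config$methylation)))
    stop("bisulfite mode needs `fasta` and `methylation`", call. = FALSE)
  chrom_lengths <- .load_genome(config$genome)
  message("loading reads from ", config$reads)
  reads <- load_reads(config$reads, chrom_lengths)
  n_reads <- sum(lengths(reads))
  g_eff <- .mappable_size(chrom_lengths, config$mapability, config$min_map)
  params <- select_bin_size(n_reads, g_eff, vmr = config$vmr,
                            fdr_target = config$fdr_target)
  message(sprintf("selected bin size %g bp (lambda %.1f, FDR %.3g)",
                  params$bin_size, params$lam, params$fdr_achieved))
  tracks <- bin_reads(reads, chrom_lengths, params$bin_size)

  if (!is.null(config$mapability)) {
    mt <- load_track(config$mapability, chrom_lengths, params$bin_size)
    for (ch in names(tracks)) {
      tracks[[ch]]$mapability <- mt[[ch]]$values
      tracks[[ch]]$mask <- tracks[[ch]]$mask | mt[[ch]]$mask
    }
  }
  tracks <- lapply(tracks, mapability_correct, min_map = config$min_map)

  if (config$bisulfite) {
    comp <- bin_composition(config$fasta, params$bin_size)
    meth <- load_methylation(config$methylation)
    egc <- effective_gc(comp, meth, params$bin_size)
    for (ch in names(tracks)) {
      sel <- comp$chrom == ch
      v <- egc[sel][order(comp$bin[sel])]
      tracks[[ch]]$gc <- v
      tracks[[ch]]$mask <- tracks[[ch]]$mask | is.na(v)
    }
  } else if (!is.null(config$gc_track)) {
    gt <- load_track(config$gc_track, chrom_lengths, params$bin_size)
    for (ch in names(tracks)) {
      tracks[[ch]]$gc <- gt[[ch]]$values
      tracks[[ch]]$mask <- tracks[[ch]]$mask | gt[[ch]]$mask
    }
  } else if (!is.null(config$fasta)) {
    comp <- bin_composition(config$fasta, params$bin_size)
    for (ch in names(tracks)) {
      sel <- comp$chrom == ch
      v <- comp$gc[sel][order(comp$bin[sel])]
      tracks[[ch]]$gc <- v
      tracks[[ch]]$mask <- tracks[[ch]]$mask | is.na(v)
    }
  }
  has_gc <- !all(vapply(tracks, function(t) is.null(t$gc), logical(1)))
  if (has_gc) tracks <- gc_correct(tracks)

  min_width <- .auto_min_width(config$min_width, params)
  set.seed(config$seed)
  chrom_seeds <- sample.int(2^31 - 2, length(tracks))
  seg_one <- function(i) segment_track(tracks[[i]], alpha = config$alpha,
                                       min_width = min_width,
                                       n_perm = config$n_perm,
                                       seed = chrom_seeds[i])
  seg_list <- if (config$workers > 1)
    parallel::mclapply(seq_along(tracks), seg_one,
                       mc.cores = config$workers)
  else lapply(seq_along(tracks), seg_one)
  segments <- do.call(rbind, seg_list)

  anchor <- diploid_anchor(tracks)
  called <- call_segments(segments, params, lam_diploid = anchor)
  altered <- sum(called$n_bins[called$call != "neutral"])
  if (altered > sum(called$n_bins) / 2) {
    message("more than half the genome called altered; ",
            "anchoring diploid depth at the modeled lambda")
    called <- call_segments(segments, params, lam_diploid = params$lam)
  }

  refined <- NULL
  if (!is.null(config$breakpoints)) {
    bps <- load_breakpoints(config$breakpoints)
    refined <- refine_boundaries(called, bps, params$bin_size)
    called <- refined$segments
    message(refined$n_refined, " boundary(ies) refined")
  }

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_segments(called, file.path(config$outdir, "segments.seg"))
  write_params(params, file.path(config$outdir, "params.txt"))
  calls <- called[called$call != "neutral", , drop = FALSE]
  if (nrow(calls))
    utils::write.table(
      data.frame(calls$chrom, format(calls$start, scientific = FALSE,
                                     trim = TRUE),
                 format(calls$end, scientific = FALSE, trim = TRUE),
                 calls$call),
      file.path(config$outdir, "calls.bed"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  prov <- .provenance(config, params,
                      list(n_reads = n_reads, chrom_seeds = chrom_seeds,
                           n_refined = if (is.null(refined)) 0L
                                       else refined$n_refined))
  jsonlite::write_json(prov, file.path(config$outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(called)
}

#' Sensitivity/specificity over a grid of trial specifications
#'
#' Front-end to [run_trials()]: runs each specification's trial battery and
#' tabulates sensitivity and specificity.
#'
#' @param specs list of [trial_spec()] objects (must be non-empty).
#' @param n_trials trials per specification.
#' @param seed master seed (each spec's battery derives its own seeds).
#' @param outdir optional directory for `simulation.tsv`.
#' @param alpha,n_perm,min_width forwarded to [run_trials()].
#' @return data.frame with one row per specification.
#' @export
rd_simulate <- function(specs, n_trials, seed, outdir = NULL,
                        alpha = 0.01, n_perm = 1000, min_width = NULL) {
  if (!length(specs)) stop("empty trial grid", call. = FALSE)
  if (inherits(specs, "trial_spec")) specs <- list(specs)
  rows <- lapply(seq_along(specs), function(i) {
    res <- run_trials(specs[[i]], n_trials, seed = seed + i - 1,
                      alpha = alpha, n_perm = n_perm,
                      min_width = min_width)
    data.frame(coverage = specs[[i]]$coverage,
               cna_size = specs[[i]]$cna_size,
               cna_cn = specs[[i]]$cna_cn, vmr = specs[[i]]$vmr,
               bin_size = res$params$bin_size, lambda = res$params$lam,
               n_trials = n_trials, sensitivity = res$sensitivity,
               specificity = res$specificity)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(outdir, "simulation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab
}
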