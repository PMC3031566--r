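# Fixture builders shared across test files.  Everything is generated in
# code at test time; nothing binary is stored.

make_track <- function(counts, bin_size = 1000, chrom = "chr1",
                       chrom_length = length(counts) * bin_size, ...) {
  bin_track(chrom, chrom_length, bin_size, counts, ...)
}

write_bed_reads <- function(positions, chrom = "chr1",
                            path = tempfile(fileext = ".bed"),
                            width = 1) {
  writeLines(sprintf("%s\t%d\t%d", chrom, as.integer(positions),
                     as.integer(positions) + width), path)
  path
}

write_bedgraph <- function(chrom, start, end, value,
                           path = tempfile(fileext = ".bedGraph")) {
  writeLines(sprintf("%s\t%d\t%d\t%g", chrom, as.integer(start),
                     as.integer(end), value), path)
  path
}

# minimal SAM: n_mapped single-end records at given 0-based positions plus
# n_unmapped placeholder records
write_sam <- function(positions, chrom = "chr1", chrom_length = 100000,
                      n_unmapped = 0, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(chrom_length)))
  mapped <- sprintf("r%d\t0\t%s\t%d\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
                    seq_along(positions), chrom,
                    as.integer(positions) + 1L)
  unmapped <- if (n_unmapped > 0)
    sprintf("u%d\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTAC\t*",
            seq_len(n_unmapped)) else character(0)
  writeLines(c(hdr, mapped, unmapped), path)
  path
}

write_methylation <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# exhaustive integer-threshold search: the independent oracle for
# optimize_thresholds, built from raw pmf sums over the truncated support
oracle_thresholds <- function(lam, vmr, p_tail = 1e-12) {
  mu <- c(1, 2, 3) * lam / 2
  pmf <- function(x, i) {
    if (vmr == 1) dpois(x, mu[i])
    else dnbinom(x, mu = mu[i], size = mu[i] / (vmr - 1))
  }
  smax <- max(vapply(1:3, function(i) {
    if (vmr == 1) qpois(1 - p_tail, mu[i])
    else qnbinom(1 - p_tail, mu = mu[i], size = mu[i] / (vmr - 1))
  }, numeric(1))) + 2L
  x <- 0:smax
  p1 <- pmf(x, 1); p2 <- pmf(x, 2); p3 <- pmf(x, 3)
  # A[t+1] = misclassification of the loss cut at t, t = 0..smax
  A <- (1 - c(0, cumsum(p1))) + c(0, cumsum(p2))
  B <- (1 - cumsum(p2)) + cumsum(p3)       # gain cut at t = 0..smax
  tot <- outer(A[1:(smax + 1)], B[1:(smax + 1)], "+")
  valid <- outer(0:smax, 0:smax, "<")      # t_loss < t_gain
  tot[!valid] <- Inf
  best <- min(tot)
  hits <- which(tot <= best + 1e-13, arr.ind = TRUE)
  tl <- hits[, 1] - 1L; tg <- hits[, 2] - 1L
  o <- order(abs((tl + tg) / 2 - lam), tl, tg)
  list(t_loss = tl[o[1]], t_gain = tg[o[1]], fdr = best)
}

# small end-to-end fixture: BED reads + genome TSV for rd_run
make_run_fixture <- function(dir, seed = 101, coverage = 5,
                             chrom_length = 4e6, cna_size = 1e6,
                             extra_chrom = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- trial_spec(coverage = coverage, cna_size = cna_size,
                     chrom_length = chrom_length)
  sim <- simulate_reads(spec, seed = seed)
  reads <- sim$reads
  if (extra_chrom) {
    null_spec <- trial_spec(coverage = coverage, cna_size = 0,
                            chrom_length = chrom_length / 2,
                            chrom = "chr2")
    sim2 <- simulate_reads(null_spec, seed = seed + 1,
                           params = sim$params)
    reads$chr2 <- sim2$reads$chr2
  }
  bed <- file.path(dir, "reads.bed")
  lines <- unlist(lapply(names(reads), function(ch)
    sprintf("%s\t%d\t%d", ch, as.integer(reads[[ch]]),
            as.integer(reads[[ch]]) + 1L)))
  writeLines(lines, bed)
  genome <- file.path(dir, "genome.tsv")
  lens <- c(chr1 = chrom_length,
            if (extra_chrom) c(chr2 = chrom_length / 2))
  writeLines(sprintf("%s\t%d", names(lens), as.integer(lens)), genome)
  list(reads = bed, genome = genome, truth = sim$truth,
       params = sim$params, chrom_lengths = lens)
}
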