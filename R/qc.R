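# ChIP-seq library quality metrics computed on mapped-read interval
# tables (chrom/start/end/strand).  Location identity for the complexity
# metrics includes strand, the usual ENCODE duplicate definition.

read_location_key <- function(reads) {
  strand <- if ("strand" %in% names(reads)) reads$strand else "+"
  paste(reads$chrom, reads$start, reads$end, strand, sep = "\r")
}

#' Non-redundant fraction (NRF)
#'
#' Distinct (chrom, start, end, strand) locations divided by the total
#' number of reads.
#'
#' @param reads Read data frame with chrom/start/end and optional strand.
#' @return Fraction in (0, 1].
#' @export
nrf <- function(reads) {
  validate_intervals(reads, "reads")
  if (nrow(reads) == 0) stop("nrf: empty read list")
  length(unique(read_location_key(reads))) / nrow(reads)
}

#' PCR bottleneck coefficients PBC1 and PBC2
#'
#' `pbc1` is the fraction of read-bearing genomic locations carrying
#' exactly one read; `pbc2` is the ratio of one-read locations to two-read
#' locations (`Inf` when no location has exactly two reads).
#'
#' @param reads Read data frame.
#' @return Named list with `pbc1` and `pbc2`.
#' @export
pbc1_pbc2 <- function(reads) {
  validate_intervals(reads, "reads")
  if (nrow(reads) == 0) stop("pbc1_pbc2: empty read list")
  counts <- table(read_location_key(reads))
  n1 <- sum(counts == 1); n2 <- sum(counts == 2)
  list(pbc1 = n1 / length(counts),
       pbc2 = if (n2 == 0) Inf else n1 / n2)
}

#' Fraction of reads in peaks (FRiP)
#'
#' A read is in peaks when it overlaps any peak interval by >= 1 bp.
#'
#' @param reads Read data frame.
#' @param peaks Peak interval data frame (pre-merged).
#' @return Fraction in \[0, 1\]; 0 when there are no peaks.
#' @export
frip <- function(reads, peaks) {
  validate_intervals(reads, "reads")
  if (nrow(reads) == 0) stop("frip: empty read list")
  if (nrow(peaks) == 0) return(0)
  mean(overlap_any(reads, peaks))
}

bin_read_starts <- function(reads, bin_size) {
  key <- paste(reads$chrom, reads$start %/% bin_size, sep = "\r")
  table(key)
}

#' Jensen-Shannon distance between two read libraries
#'
#' Bins read starts into fixed non-overlapping windows, normalizes each
#' library's bin counts to a probability vector over all bins carrying at
#' least one read in either library, and returns the square root of the
#' Jensen-Shannon divergence (log base 2, so the distance lies in
#' \[0, 1\]).
#'
#' @param chip_reads,input_reads Read data frames on the same genome.
#' @param bin_size Window width in bp (default 500).
#' @return Jensen-Shannon distance in \[0, 1\].
#' @export
jsd <- function(chip_reads, input_reads, bin_size = 500) {
  validate_intervals(chip_reads, "chip_reads")
  validate_intervals(input_reads, "input_reads")
  if (nrow(chip_reads) == 0 || nrow(input_reads) == 0)
    stop("jsd: both libraries must be non-empty")
  c1 <- bin_read_starts(chip_reads, bin_size)
  c2 <- bin_read_starts(input_reads, bin_size)
  bins <- union(names(c1), names(c2))
  p <- as.numeric(c1[bins]); p[is.na(p)] <- 0; p <- p / sum(p)
  q <- as.numeric(c2[bins]); q[is.na(q)] <- 0; q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a) sum(ifelse(a > 0, a * log2(a / m), 0))
  d <- 0.5 * kl(p) + 0.5 * kl(q)
  sqrt(min(max(d, 0), 1))
}

#' Full QC report for a ChIP library
#'
#' Computes NRF, PBC1/PBC2, FRiP and the Jensen-Shannon distance to the
#' input library, with ENCODE-style qualitative flags: NRF and PBC1 in
#' 0.5-0.8 are "acceptable"/"moderate bottlenecking", PBC2 in 3-10 is
#' "mild bottlenecking" (values above each range are better).
#'
#' @param chip_reads ChIP read data frame.
#' @param input_reads Input (control) read data frame.
#' @param peaks Peak interval data frame.
#' @param bin_size JSD bin width in bp.
#' @return List with `nrf`, `pbc1`, `pbc2`, `frip`, `jsd` and a named
#'   logical vector `thresholds_passed`.
#' @export
qc_report <- function(chip_reads, input_reads, peaks, bin_size = 500) {
  v_nrf <- nrf(chip_reads)
  pbc <- pbc1_pbc2(chip_reads)
  v_frip <- frip(chip_reads, peaks)
  v_jsd <- jsd(chip_reads, input_reads, bin_size)
  list(nrf = v_nrf, pbc1 = pbc$pbc1, pbc2 = pbc$pbc2, frip = v_frip,
       jsd = v_jsd,
       thresholds_passed = c(
         nrf_at_least_acceptable = v_nrf >= 0.5,
         pbc1_at_least_moderate = pbc$pbc1 >= 0.5,
         pbc2_at_least_mild = pbc$pbc2 >= 3))
}
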