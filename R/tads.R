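# TAD prediction from CTCF peaks: FIMO-style log-odds motif scanning with
# an exact dynamic-programming p-value threshold, one oriented site per
# peak, convergent loop pairing, and merging of nested/overlapping loops.

#' Log-odds scoring matrix from a probability PWM
#'
#' Adds a pseudocount to every cell, renormalizes each row, and scores
#' against the uniform background: `log2(p'/0.25)` in bits.
#'
#' @param pwm Probability matrix (rows = positions, columns A,C,G,T).
#' @param pseudocount Pseudocount added to each probability.
#' @return Log-odds matrix of the same shape, in bits.
#' @export
pwm_log_odds <- function(pwm, pseudocount = 1e-3) {
  stopifnot(ncol(pwm) == 4)
  q <- pwm + pseudocount
  q <- q / rowSums(q)
  log2(q / 0.25)
}

#' Score threshold for a PWM p-value under the uniform null
#'
#' Enumerates the exact distribution of the log-odds score of a random
#' uniform-background sequence by dynamic programming over scores
#' discretized at `granularity` bits, and returns the smallest score whose
#' upper-tail probability is at most `pvalue`.
#'
#' @param pwm Probability PWM.
#' @param pvalue Target p-value in (0, 1).
#' @param pseudocount Pseudocount for [pwm_log_odds()].
#' @param granularity Score discretization step in bits.
#' @return List with integer threshold `int` (units of `granularity`),
#'   `score` in bits, and the inputs.
#' @export
pwm_score_threshold <- function(pwm, pvalue = 1e-4, pseudocount = 1e-3,
                                granularity = 1e-3) {
  stopifnot(pvalue > 0, pvalue < 1)
  lom <- pwm_log_odds(pwm, pseudocount)
  ints <- round(lom / granularity)
  dist <- 1; off <- 0
  for (j in seq_len(nrow(ints))) {
    r <- ints[j, ]
    nd <- numeric(length(dist) + diff(range(r)))
    for (b in 1:4) {
      sh <- r[b] - min(r)
      idx <- (1 + sh):(sh + length(dist))
      nd[idx] <- nd[idx] + dist * 0.25
    }
    dist <- nd; off <- off + min(r)
  }
  tail_p <- rev(cumsum(rev(dist)))
  k <- which(tail_p <= pvalue)[1]
  thr_int <- if (is.na(k)) off + length(dist) else off + k - 1
  list(int = thr_int, score = thr_int * granularity,
       granularity = granularity, pvalue = pvalue)
}

encode_dna <- function(s) {
  chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  if (any(is.na(code) & chars != "N"))
    stop("sequence contains characters outside ACGTN")
  code
}

scan_one_strand <- function(code, lom_int) {
  w <- nrow(lom_int); L <- length(code) - w + 1
  if (L < 1) return(integer(0))
  sc <- numeric(L)
  for (j in seq_len(w)) {
    row <- lom_int[j, ]
    sc <- sc + row[code[j:(j + L - 1)]]
  }
  sc
}

#' Scan sequences for PWM hits above a p-value threshold
#'
#' Scores every position on both strands with the pseudocounted log-odds
#' of [pwm_log_odds()]; positions are reported as hits when their
#' discretized score reaches the exact-DP threshold of
#' [pwm_score_threshold()].  `N` positions never match.
#'
#' @param seqs Named character vector or `DNAStringSet`; names become
#'   chromosome labels.
#' @param pwm Probability PWM.
#' @param pvalue_threshold Hit p-value threshold (default 1e-4).
#' @param pseudocount,granularity Passed to the scoring helpers.
#' @return Data frame of hits: chrom, start, end (0-based half-open, width
#'   = PWM width), strand, score (bits), sorted by position.
#' @export
scan_pwm <- function(seqs, pwm, pvalue_threshold = 1e-4,
                     pseudocount = 1e-3, granularity = 1e-3) {
  if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  stopifnot(!is.null(names(seqs)))
  lom <- pwm_log_odds(pwm, pseudocount)
  lom_int <- round(lom / granularity)
  thr <- pwm_score_threshold(pwm, pvalue_threshold, pseudocount,
                             granularity)
  w <- nrow(pwm)
  # reverse strand: reverse positions and complement columns
  rlom_int <- lom_int[w:1, 4:1, drop = FALSE]
  out <- list()
  for (chrom in names(seqs)) {
    code <- encode_dna(seqs[[chrom]])
    for (strand in c("+", "-")) {
      m <- if (strand == "+") lom_int else rlom_int
      sc <- scan_one_strand(code, m)
      hit <- which(!is.na(sc) & sc >= thr$int)
      if (length(hit) == 0) next
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = hit - 1, end = hit - 1 + w, strand = strand,
        score = sc[hit] * granularity, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$strand), , drop = FALSE]
}

#' Assign one oriented CTCF site to each motif-bearing peak
#'
#' Each peak keeps its single best-scoring hit lying fully inside the peak
#' (ties broken by smaller start, then `+` strand); peaks without any hit
#' are discarded.  The site position is the hit midpoint.
#'
#' @param peaks Peak interval data frame; a `peak_id` column is added when
#'   absent.
#' @param hits Motif hits from [scan_pwm()] in the same coordinate system.
#' @return Oriented-site data frame: chrom, position, orientation
#'   (`forward`/`reverse`), source_peak, score.
#' @export
orient_peaks <- function(peaks, hits) {
  validate_intervals(peaks, "peaks")
  if (!"peak_id" %in% names(peaks))
    peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  if (nrow(hits) == 0 || nrow(peaks) == 0)
    return(data.frame(chrom = character(), position = numeric(),
                      orientation = character(), source_peak = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  w <- hits$end[1] - hits$start[1]
  j <- overlap_join(hits, peaks)
  j <- j[j$bp == w, , drop = FALSE]  # hit fully inside peak
  if (nrow(j) == 0)
    return(data.frame(chrom = character(), position = numeric(),
                      orientation = character(), source_peak = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  cand <- data.frame(peak = j$subject, hit = j$query)
  ord <- order(cand$peak, -hits$score[cand$hit], hits$start[cand$hit],
               hits$strand[cand$hit])
  cand <- cand[ord, , drop = FALSE]
  best <- cand[!duplicated(cand$peak), , drop = FALSE]
  h <- hits[best$hit, , drop = FALSE]
  out <- data.frame(
    chrom = h$chrom, position = h$start + w %/% 2,
    orientation = ifelse(h$strand == "+", "forward", "reverse"),
    source_peak = peaks$peak_id[best$peak], score = h$score,
    stringsAsFactors = FALSE)
  out[order(out$chrom, out$position), , drop = FALSE]
}

#' Pair convergent CTCF sites into loops
#'
#' Each forward site is paired with the nearest reverse site downstream of
#' it within `max_span`; forward sites without such a partner emit no
#' loop.
#'
#' @param sites Oriented-site data frame from [orient_peaks()].
#' @param max_span Maximum loop span in bp (default 1 Mb).
#' @return Loop interval data frame (chrom, start, end).
#' @export
pair_loops <- function(sites, max_span = 1e6) {
  out <- list()
  for (chrom in unique(sites$chrom)) {
    s <- sites[sites$chrom == chrom, , drop = FALSE]
    s <- s[order(s$position), , drop = FALSE]
    fw <- s$position[s$orientation == "forward"]
    rv <- s$position[s$orientation == "reverse"]
    if (length(fw) == 0 || length(rv) == 0) next
    # nearest reverse site strictly downstream of each forward site
    k <- findInterval(fw, rv) + 1
    ok <- k <= length(rv)
    partner <- rep(NA_real_, length(fw))
    partner[ok] <- rv[k[ok]]
    ok <- ok & !is.na(partner) & (partner - fw) <= max_span & partner > fw
    if (!any(ok)) next
    out[[length(out) + 1]] <- data.frame(
      chrom = chrom, start = fw[ok], end = partner[ok],
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  sort_intervals(do.call(rbind, out))
}

#' Merge nested and overlapping loops into TADs
#'
#' Transitive union of overlapping or nested loops; abutting loops are
#' kept separate (bookended merging off).
#'
#' @param loops Loop interval data frame.
#' @return Sorted disjoint TAD data frame with a `tad_id` column.
#' @export
merge_loops <- function(loops) {
  tads <- merge_intervals(loops, bookended = FALSE)
  if (nrow(tads) > 0)
    tads$tad_id <- sprintf("TAD%04d", seq_len(nrow(tads)))
  tads
}

#' Fraction of the genome covered by TADs
#'
#' @param tads TAD interval data frame.
#' @param genome_size Total genome size in bp.
#' @return Coverage fraction in \[0, 1\].
#' @export
tad_coverage <- function(tads, genome_size) {
  if (nrow(tads) == 0) return(0)
  sum(tads$end - tads$start) / genome_size
}

#' Predict TADs from CTCF peaks, a genome and a motif
#'
#' Runs the full chain: extract peak sequences, scan them for the motif,
#' orient each peak by its best hit, pair convergent sites into loops, and
#' merge loops into TADs.
#'
#' @param genome Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param peaks CTCF peak interval data frame (pooled across tissues).
#' @param pwm Probability PWM of the CTCF motif.
#' @param pvalue_threshold Motif hit p-value threshold.
#' @param max_span Maximum loop span in bp.
#' @return List with `tads`, `sites`, and `hits`.
#' @export
predict_tads <- function(genome, peaks, pwm, pvalue_threshold = 1e-4,
                         max_span = 1e6) {
  if (is(genome, "DNAStringSet")) genome <- as.character(genome)
  validate_intervals(peaks, "peaks")
  if (!"peak_id" %in% names(peaks))
    peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  seqs <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks)))
    seqs[i] <- substr(genome[[peaks$chrom[i]]], peaks$start[i] + 1,
                      peaks$end[i])
  names(seqs) <- sprintf("pk%d", seq_len(nrow(peaks)))
  hits <- scan_pwm(seqs, pwm, pvalue_threshold)
  if (nrow(hits) > 0) {
    i <- as.integer(sub("^pk", "", hits$chrom))
    hits$start <- hits$start + peaks$start[i]
    hits$end <- hits$end + peaks$start[i]
    hits$chrom <- peaks$chrom[i]
  }
  sites <- orient_peaks(peaks, hits)
  loops <- pair_loops(sites, max_span)
  list(tads = merge_loops(loops), sites = sites, hits = hits)
}
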