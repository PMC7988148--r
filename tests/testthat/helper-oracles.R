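# Independent brute-force oracles used to validate the sweep/IRanges-based
# implementations.  All of these work on per-base logical masks or O(n*m)
# scans and deliberately share no code with the package internals.

# logical occupancy mask of one chromosome
mask_from_intervals <- function(iv, chrom, chrom_len) {
  m <- logical(chrom_len)
  r <- iv[iv$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(r))) m[(r$start[i] + 1):r$end[i]] <- TRUE
  m
}

# intervals (sorted, disjoint) back from a mask: run-length encoding
intervals_from_mask <- function(mask, chrom) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e5,
                             max_len = 500) {
  start <- floor(runif(n) * (max_pos - max_len))
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + 1 + floor(runif(n) * max_len),
             stringsAsFactors = FALSE)
}

# step-up BH definition, straight from the formula
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  pmin(q, 1)
}

# two-sided Fisher p by direct enumeration with choose(), no dhyper
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  support <- max(0, k - m2):min(k, m1)
  prob <- function(x) choose(m1, x) * choose(m2, k - x) / choose(n, k)
  probs <- vapply(support, prob, 0)
  p_obs <- prob(a)
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

# per-base interval mapping through an alignment-block map
map_oracle <- function(iv, map) {
  pos <- iv$start:(iv$end - 1)
  tgt_chrom <- character(0); tgt_pos <- numeric(0)
  for (i in seq_len(nrow(map))) {
    b <- map[i, ]
    if (b$src_chrom != iv$chrom) next
    inb <- pos >= b$src_start & pos < b$src_end
    if (!any(inb)) next
    p <- pos[inb]
    t <- if (b$tgt_strand == "+") b$tgt_start + (p - b$src_start)
         else b$tgt_end - 1 - (p - b$src_start)
    tgt_chrom <- c(tgt_chrom, rep(b$tgt_chrom, length(p)))
    tgt_pos <- c(tgt_pos, t)
  }
  if (length(tgt_pos) == 0) return(NULL)
  cnt <- table(tgt_chrom)
  best <- sort(names(cnt)[cnt == max(cnt)])[1]
  keep <- tgt_pos[tgt_chrom == best]
  list(chrom = best, start = min(keep), end = max(keep) + 1,
       aligned_bases = length(tgt_pos))
}

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, chrom_len = 1e6, n_genes = 60, n_res = 120,
             n_tads = 8, n_decoy_peaks = 10, ...)
}
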