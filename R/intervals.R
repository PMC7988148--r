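# Genomic intervals are plain data frames with columns chrom/start/end in
# 0-based half-open coordinates.  IRanges backs the set operations; the
# +1 shift to 1-based closed coordinates happens only inside these helpers.

#' Construct a genomic-interval data frame
#'
#' @param chrom Chromosome names (character).
#' @param start 0-based inclusive start positions.
#' @param end Exclusive end positions; must satisfy `0 <= start < end`.
#' @param ... Further columns recycled alongside the coordinates.
#' @return A `data.frame` with columns `chrom`, `start`, `end` and any
#'   extras, validated.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), ..., stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' Validate a genomic-interval data frame
#'
#' Checks the presence of `chrom`, `start`, `end` columns and the invariant
#' `0 <= start < end` for every row.
#'
#' @param x Candidate interval data frame.
#' @param what Label used in error messages.
#' @return `x`, invisibly; errors on the first offending row.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, ": expected a data frame with chrom/start/end columns")
  if (nrow(x) == 0) return(invisible(x))
  bad <- which(!(x$start >= 0 & x$start < x$end) | is.na(x$start) |
                 is.na(x$end))
  if (length(bad) > 0)
    stop(sprintf("%s: invalid interval at row %d (start=%s, end=%s)",
                 what, bad[1], format(x$start[bad[1]], scientific = FALSE),
                 format(x$end[bad[1]], scientific = FALSE)))
  invisible(x)
}

# internal: data frame <-> GRanges (1-based closed)
as_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1,
             end = BiocGenerics::end(gr),
             stringsAsFactors = FALSE)
}

sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Merge intervals into a minimal disjoint set
#'
#' Computes the union of the input intervals as a sorted list of disjoint
#' intervals.  With `bookended = TRUE` (the BEDTools merge default)
#' abutting intervals (`a$end == b$start`) are also merged.
#'
#' @param x Interval data frame.
#' @param bookended Merge abutting intervals as well as overlapping ones.
#' @return Sorted disjoint interval data frame covering exactly the union
#'   of the input.
#' @export
merge_intervals <- function(x, bookended = TRUE) {
  validate_intervals(x)
  if (nrow(x) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::reduce(as_gr(x),
                              min.gapwidth = if (bookended) 1L else 0L)
  sort_intervals(gr_to_df(gr))
}

#' Base pairs of overlap between two intervals
#'
#' Vectorized over rows; intervals on different chromosomes overlap by 0.
#'
#' @param a,b Interval data frames (recycled elementwise like vectors).
#' @return Integer vector of overlapping base counts.
#' @export
overlap_bp <- function(a, b) {
  validate_intervals(a, "a"); validate_intervals(b, "b")
  ov <- pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  ifelse(a$chrom == b$chrom, ov, 0)
}

#' All overlapping pairs between two interval sets
#'
#' @param query,subject Interval data frames.
#' @return Data frame with columns `query`, `subject` (row indices) and
#'   `bp` (bases of overlap, always >= 1).
#' @export
overlap_join <- function(query, subject) {
  validate_intervals(query, "query"); validate_intervals(subject, "subject")
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(data.frame(query = integer(), subject = integer(),
                      bp = numeric()))
  hits <- GenomicRanges::findOverlaps(as_gr(query), as_gr(subject))
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  bp <- pmin(query$end[qi], subject$end[si]) -
    pmax(query$start[qi], subject$start[si])
  data.frame(query = qi, subject = si, bp = bp)
}

#' Flag query intervals overlapping any subject interval by >= 1 bp
#'
#' @param query,subject Interval data frames.
#' @return Logical vector along the rows of `query`.
#' @export
overlap_any <- function(query, subject) {
  validate_intervals(query, "query"); validate_intervals(subject, "subject")
  if (nrow(query) == 0) return(logical(0))
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(as_gr(query), as_gr(subject))
}

#' Total bases covered by an interval set (union size)
#'
#' @param x Interval data frame.
#' @return Number of distinct bases covered.
#' @export
covered_bp <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}
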