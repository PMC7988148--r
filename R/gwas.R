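# GWAS-SNP overlap with the RE catalog: in/out flags, p-value density
# contrasts, and per-category Fisher enrichment against uncategorized
# SNPs.

#' Flag SNPs lying inside regulatory elements
#'
#' Half-open containment: a SNP at `pos` is inside an RE `[start, end)`
#' when `start <= pos < end`.
#'
#' @param snps SNP data frame with `chrom` and `pos` (0-based).
#' @param catalog RE interval data frame.
#' @return Logical vector along the rows of `snps`.
#' @export
flag_in_re <- function(snps, catalog) {
  validate_intervals(catalog, "catalog")
  if (nrow(snps) == 0) return(logical(0))
  pts <- data.frame(chrom = snps$chrom, start = snps$pos,
                    end = snps$pos + 1)
  overlap_any(pts, catalog)
}

#' Normalized p-value histograms for SNPs inside and outside REs
#'
#' @param snps SNP data frame with a `pvalue` column.
#' @param in_re Logical flags from [flag_in_re()].
#' @param bins Number of equal-width bins on \[0, 1\] (default 50).
#' @return Data frame: `bin_lo`, `bin_hi`, `in_re`, `out_re`; each density
#'   column sums to 1 (all-zero when its group is empty).
#' @export
pvalue_density <- function(snps, in_re, bins = 50) {
  stopifnot(length(in_re) == nrow(snps))
  breaks <- seq(0, 1, length.out = bins + 1)
  cut_counts <- function(p) {
    if (length(p) == 0) return(rep(0, bins))
    idx <- pmin(pmax(ceiling(p * bins), 1), bins)  # p in (0,1]
    tabulate(idx, nbins = bins)
  }
  a <- cut_counts(snps$pvalue[in_re]); b <- cut_counts(snps$pvalue[!in_re])
  data.frame(bin_lo = breaks[-(bins + 1)], bin_hi = breaks[-1],
             in_re = if (sum(a) > 0) a / sum(a) else a,
             out_re = if (sum(b) > 0) b / sum(b) else b)
}

#' Fisher's exact test for a 2x2 table
#'
#' Sample odds ratio `(a*d)/(b*c)` (with `Inf`/`NaN` sentinels for zero
#' cells) and the two-sided p-value summing the hypergeometric
#' probabilities of all tables with the same margins whose probability is
#' at most that of the observed table (ties recognized with a small
#' relative tolerance, so symmetric tables contribute both tails).
#'
#' @param table 2x2 matrix or `[[a,b],[c,d]]`-style list of non-negative
#'   integers.
#' @return List with `odds_ratio` and `pvalue`.
#' @export
fisher_exact_2x2 <- function(table) {
  if (is.list(table)) table <- rbind(unlist(table[[1]]), unlist(table[[2]]))
  stopifnot(identical(dim(table), c(2L, 2L)))
  if (any(table < 0)) stop("fisher_exact_2x2: negative entries")
  a <- table[1, 1]; b <- table[1, 2]; cc <- table[2, 1]; d <- table[2, 2]
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  m1 <- a + b; m2 <- cc + d; k <- a + cc
  if (m1 + m2 == 0) return(list(odds_ratio = or, pvalue = 1))
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  # relative tolerance for ties: an absolute epsilon would absorb every
  # table whose probability is below it once p_obs itself is tiny
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, pvalue = min(p, 1))
}

#' Per-category enrichment of SNPs inside REs
#'
#' For each category c, builds the 2x2 table of (category vs
#' uncategorized) x (in-RE vs out-of-RE) and runs [fisher_exact_2x2()].
#' The comparison group is SNPs belonging to no category; multi-category
#' SNPs are counted in each of their categories.  Categories with zero
#' SNPs are skipped with a message.
#'
#' @param snps SNP data frame with `categories` list-column.
#' @param in_re Logical flags from [flag_in_re()].
#' @return Data frame: `category`, `n`, `frac_in_re`,
#'   `frac_uncategorized_in_re`, `ratio_vs_other`, `odds_ratio`,
#'   `fisher_p`.
#' @export
category_enrichment <- function(snps, in_re) {
  stopifnot(length(in_re) == nrow(snps))
  cats <- sort(unique(unlist(snps$categories)))
  uncat <- lengths(snps$categories) == 0
  cu <- sum(uncat & in_re); du <- sum(uncat & !in_re)
  rows <- list()
  for (cat in cats) {
    inc <- vapply(snps$categories, function(x) cat %in% x, TRUE)
    a <- sum(inc & in_re); b <- sum(inc & !in_re)
    if (a + b == 0) {
      message("category_enrichment: skipping empty category ", cat)
      next
    }
    ft <- fisher_exact_2x2(rbind(c(a, b), c(cu, du)))
    frac <- a / (a + b)
    frac_u <- if (cu + du > 0) cu / (cu + du) else NA_real_
    rows[[cat]] <- data.frame(
      category = cat, n = a + b, frac_in_re = frac,
      frac_uncategorized_in_re = frac_u,
      ratio_vs_other = if (!is.na(frac_u) && frac_u > 0) frac / frac_u
                       else NA_real_,
      odds_ratio = ft$odds_ratio, fisher_p = ft$pvalue,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(category = character(), n = integer(),
                      frac_in_re = numeric(),
                      frac_uncategorized_in_re = numeric(),
                      ratio_vs_other = numeric(), odds_ratio = numeric(),
                      fisher_p = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
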