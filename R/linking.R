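# Enhancer-to-gene linking: TMM normalization to counts per million,
# expression/variance prefilters, TAD membership, Spearman correlation of
# RE signal with gene expression, and genome-wide BH FDR control.

#' Trimmed-mean-of-M-values (TMM) scale factors
#'
#' Between-sample normalization factors for a count matrix.  The reference
#' sample is the one whose upper-quartile of counts/library-size (over
#' rows with any positive count) is closest to the mean upper quartile.
#' For each sample versus the reference, M (log2 ratio) and A (average
#' log2 abundance) values over rows positive in both are trimmed (30% of
#' M from each tail, 5% of A) and the surviving M values averaged with
#' inverse asymptotic-binomial-variance weights.  Factors are finally
#' scaled so their geometric mean is 1.
#'
#' @param counts Non-negative count matrix (rows = features, columns =
#'   samples, >= 2 columns).
#' @param lib_sizes Optional per-sample library sizes (default column
#'   sums); zeros are an error.
#' @param logratio_trim,sum_trim Trim fractions for M and A.
#' @param do_weighting Use precision weights for the trimmed mean.
#' @return Named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        logratio_trim = 0.3, sum_trim = 0.05,
                        do_weighting = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("tmm_factors: need at least 2 samples")
  if (any(lib_sizes <= 0)) stop("tmm_factors: sample with zero library size")
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  f75 <- vapply(seq_len(ncol(counts)), function(k)
    quantile(counts[, k] / lib_sizes[k], 0.75, names = FALSE), 0)
  ref <- which.min(abs(f75 - mean(f75)))
  one <- function(k) {
    if (k == ref) return(1)
    obs <- counts[, k]; refc <- counts[, ref]
    nO <- lib_sizes[k]; nR <- lib_sizes[ref]
    pos <- obs > 0 & refc > 0
    if (!any(pos)) return(1)
    o <- obs[pos] / nO; r <- refc[pos] / nR
    M <- log2(o / r); A <- 0.5 * log2(o * r)
    w <- (nO - obs[pos]) / (nO * obs[pos]) + (nR - refc[pos]) / (nR * refc[pos])
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (length(M) == 0 || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    if (!any(keep)) return(1)
    mn <- if (do_weighting) sum(M[keep] / w[keep]) / sum(1 / w[keep])
          else mean(M[keep])
    if (!is.finite(mn)) mn <- 0
    2^mn
  }
  f <- vapply(seq_len(ncol(counts)), one, 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

#' TMM-normalize a count matrix to counts per million
#'
#' @param counts Count matrix (features x samples).
#' @param lib_sizes Optional library sizes (default column sums).
#' @return Object of class `tmm_matrix`: list with `counts`, `lib_sizes`,
#'   `tmm_factors` and the derived `cpm` matrix
#'   (`counts / (lib_sizes * factors) * 1e6`).
#' @export
normalize_counts <- function(counts, lib_sizes = colSums(counts)) {
  counts <- as.matrix(counts)
  f <- tmm_factors(counts, lib_sizes)
  cpm <- sweep(counts, 2, lib_sizes * f, "/") * 1e6
  structure(list(counts = counts, lib_sizes = lib_sizes, tmm_factors = f,
                 cpm = cpm), class = "tmm_matrix")
}

as_cpm <- function(x) {
  if (inherits(x, "tmm_matrix")) x$cpm else as.matrix(x)
}

#' Expressed and tissue-specific flags per gene
#'
#' Tissue-level CPM is the mean over that tissue's replicates.  A gene is
#' expressed when its maximum tissue CPM is >= `expressed_min` (default
#' 1), and tissue-specific when some tissue's CPM is at least `fold` times
#' (default 4) higher than in every other tissue (a zero elsewhere counts
#' as satisfied provided the top tissue is positive).
#'
#' @param x `tmm_matrix` or CPM matrix.
#' @param tissue_map Character/factor vector along the columns giving each
#'   sample's tissue.
#' @param expressed_min Expression threshold on tissue CPM.
#' @param fold Fold-change threshold for tissue specificity.
#' @return Data frame: `gene_id`, `expressed`, `tissue_specific`,
#'   `top_tissue`.
#' @export
expressed_and_specific <- function(x, tissue_map, expressed_min = 1,
                                   fold = 4) {
  cpm <- as_cpm(x)
  stopifnot(length(tissue_map) == ncol(cpm))
  tis <- unique(as.character(tissue_map))
  m <- vapply(tis, function(t)
    rowMeans(cpm[, tissue_map == t, drop = FALSE]), numeric(nrow(cpm)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1, dimnames = list(rownames(cpm), tis))
  top <- apply(m, 1, max)
  second <- apply(m, 1, function(v) sort(v, decreasing = TRUE)[2])
  data.frame(gene_id = rownames(cpm), expressed = top >= expressed_min,
             tissue_specific = top > 0 & top >= fold * second,
             top_tissue = tis[apply(m, 1, which.max)],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Max/min-ratio variance filter
#'
#' Retains a row when the ratio of its maximum to its minimum value
#' across samples exceeds `threshold`.  Rows with minimum 0 but a positive
#' maximum are retained (infinite ratio); all-zero rows are dropped.
#'
#' @param x `tmm_matrix` or value matrix (CPM scale).
#' @param threshold Ratio threshold (default 6, strict inequality).
#' @return Character vector of retained row identifiers.
#' @export
variance_filter <- function(x, threshold = 6) {
  v <- as_cpm(x)
  mx <- apply(v, 1, max); mn <- apply(v, 1, min)
  keep <- (mn == 0 & mx > 0) | (mn > 0 & mx / mn > threshold)
  rownames(v)[keep]
}

gene_tss_5p <- function(genes) {
  vapply(seq_len(nrow(genes)), function(j) {
    t <- genes$tss[[j]]
    if (genes$strand[j] == "+") min(t) else max(t)
  }, 0)
}

#' Assign REs and genes to TADs
#'
#' An RE belongs to a TAD when its midpoint lies inside the TAD interval
#' (half-open); a gene belongs when its 5'-most TSS does.  Elements
#' outside every TAD get `NA` and form no candidate pairs.
#'
#' @param res RE catalog data frame.
#' @param genes Gene-model data frame.
#' @param tads TAD data frame (disjoint); a `tad_id` column is added when
#'   absent.
#' @return List with `re_tad` and `gene_tad` (named character vectors of
#'   TAD ids, `NA` outside all TADs) and the `tads` used.
#' @export
assign_to_tads <- function(res, genes, tads) {
  validate_intervals(tads, "tads")
  if (!"tad_id" %in% names(tads))
    tads$tad_id <- sprintf("TAD%04d", seq_len(nrow(tads)))
  point_tad <- function(chrom, pos) {
    out <- rep(NA_character_, length(pos))
    for (cn in unique(chrom)) {
      tc <- tads[tads$chrom == cn, , drop = FALSE]
      if (nrow(tc) == 0) next
      tc <- tc[order(tc$start), , drop = FALSE]
      i <- which(chrom == cn)
      k <- findInterval(pos[i], tc$start)
      inside <- k >= 1 & pos[i] < tc$end[pmax(k, 1)]
      out[i[inside]] <- tc$tad_id[k[inside]]
    }
    out
  }
  re_mid <- floor((res$start + res$end) / 2)
  re_tad <- setNames(point_tad(res$chrom, re_mid), res$re_id)
  gene_tad <- setNames(point_tad(genes$chrom, gene_tss_5p(genes)),
                       genes$gene_id)
  list(re_tad = re_tad, gene_tad = gene_tad, tads = tads)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Average ranks for ties; rho is the Pearson correlation of the rank
#' vectors; the two-sided p-value uses `t = rho * sqrt((n-2)/(1-rho^2))`
#' on n-2 degrees of freedom, with p = 0 when |rho| = 1.  Zero variance in
#' either vector yields `NA` for both values.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return List with `rho` and `pvalue`.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 4)
  if (sd(x) == 0 || sd(y) == 0) return(list(rho = NA_real_, pvalue = NA_real_))
  rho <- cor(rank(x), rank(y))
  list(rho = rho, pvalue = spearman_pvalue(rho, n))
}

spearman_pvalue <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ex <- !is.na(rho) & (1 - abs(rho)) < 1e-12
  p[ex] <- 0
  ok <- !is.na(rho) & !ex
  t <- rho[ok] * sqrt((n - 2) / (1 - rho[ok]^2))
  p[ok] <- 2 * pt(-abs(t), n - 2)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_(j>=i) m * p_(j) / j`, capped at
#' 1, returned in the original order.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Adjusted p-values (q-values).
#' @export
bh_adjust <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Naive RE-gene pairs by overlap or proximity
#'
#' Genic REs pair with every protein-coding gene whose body they overlap;
#' intergenic REs pair with the gene carrying the nearest TSS (ties broken
#' by lexicographically smaller gene id).  Requires a `re_class` column.
#'
#' @param res RE catalog with `re_class`.
#' @param genes Gene-model data frame.
#' @return Data frame of `re_id`, `gene_id` pairs.
#' @export
naive_pairs <- function(res, genes) {
  stopifnot("re_class" %in% names(res))
  out <- list()
  coding <- genes[genes$biotype == "protein_coding", , drop = FALSE]
  genic <- res[res$re_class == "genic", , drop = FALSE]
  if (nrow(genic) > 0 && nrow(coding) > 0) {
    j <- overlap_join(genic, coding)
    if (nrow(j) > 0)
      out[["genic"]] <- data.frame(re_id = genic$re_id[j$query],
                                   gene_id = coding$gene_id[j$subject],
                                   stringsAsFactors = FALSE)
  }
  inter <- res[res$re_class == "intergenic", , drop = FALSE]
  tp <- tss_points(genes, coding_only = FALSE)
  if (nrow(inter) > 0 && nrow(tp) > 0) {
    ids <- character(nrow(inter))
    for (i in seq_len(nrow(inter))) {
      cand <- tp[tp$chrom == inter$chrom[i], , drop = FALSE]
      if (nrow(cand) == 0) { ids[i] <- NA_character_; next }
      d <- pmax(inter$start[i] - cand$pos, cand$pos - (inter$end[i] - 1), 0)
      best <- cand$gene_id[d == min(d)]
      ids[i] <- sort(unique(best))[1]
    }
    keep <- !is.na(ids)
    if (any(keep))
      out[["intergenic"]] <- data.frame(re_id = inter$re_id[keep],
                                        gene_id = ids[keep],
                                        stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(re_id = character(), gene_id = character(),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, out))
}

#' Predict RE-target-gene links within TADs
#'
#' Tests every (RE, gene) pair sharing a TAD by Spearman correlation of
#' the RE's signal CPM with the gene's expression CPM across all samples,
#' applies one genome-wide BH adjustment, and retains pairs with q-value
#' below `alpha` (and positive rho by default, since the signal is an
#' activating mark).  Rows with zero variance are skipped and counted.
#'
#' @param signal `tmm_matrix` (or CPM matrix) over REs.
#' @param expr `tmm_matrix` (or CPM matrix) over genes; columns must match
#'   `signal` exactly.
#' @param res RE catalog data frame (rownames of `signal` must be re_ids).
#' @param genes Gene-model data frame.
#' @param tads TAD data frame.
#' @param alpha BH q-value threshold (default 0.05).
#' @param positive_only Keep only positively correlated pairs.
#' @param tissue_map Optional tissue of each sample column; when
#'   `by_tissue_mean = TRUE`, correlations use tissue means instead of
#'   individual samples.
#' @param by_tissue_mean Correlate tissue means rather than samples.
#' @return List: `links` data frame (re_id, gene_id, tad_id, rho, pvalue,
#'   qvalue, is_naive_pair), `tests` data frame of all tested pairs,
#'   `n_tests`, `skipped_zero_variance`, and `summary`.
#' @export
predict_links <- function(signal, expr, res, genes, tads, alpha = 0.05,
                          positive_only = TRUE, tissue_map = NULL,
                          by_tissue_mean = FALSE) {
  sig <- as_cpm(signal); ex <- as_cpm(expr)
  if (!identical(colnames(sig), colnames(ex)))
    stop("predict_links: signal and expression sample columns differ")
  if (by_tissue_mean) {
    stopifnot(!is.null(tissue_map))
    collapse <- function(m) {
      tis <- unique(as.character(tissue_map))
      out <- vapply(tis, function(t)
        rowMeans(m[, tissue_map == t, drop = FALSE]), numeric(nrow(m)))
      rownames(out) <- rownames(m)
      out
    }
    sig <- collapse(sig); ex <- collapse(ex)
  }
  n <- ncol(sig)
  if (n < 4) stop("predict_links: need at least 4 sample columns")
  memb <- assign_to_tads(res, genes, tads)
  skipped <- 0
  tests <- list()
  for (tid in unique(stats::na.omit(memb$re_tad))) {
    rids <- intersect(names(memb$re_tad)[!is.na(memb$re_tad) &
                                           memb$re_tad == tid],
                      rownames(sig))
    gids <- intersect(names(memb$gene_tad)[!is.na(memb$gene_tad) &
                                             memb$gene_tad == tid],
                      rownames(ex))
    if (length(rids) == 0 || length(gids) == 0) next
    rs <- sig[rids, , drop = FALSE]; gs <- ex[gids, , drop = FALSE]
    r_ok <- apply(rs, 1, function(v) length(unique(v)) > 1)
    g_ok <- apply(gs, 1, function(v) length(unique(v)) > 1)
    skipped <- skipped + sum(!r_ok) * length(gids) +
      sum(r_ok) * sum(!g_ok)
    rs <- rs[r_ok, , drop = FALSE]; gs <- gs[g_ok, , drop = FALSE]
    if (nrow(rs) == 0 || nrow(gs) == 0) next
    rr <- t(apply(rs, 1, rank)); gr <- t(apply(gs, 1, rank))
    rho <- cor(t(rr), t(gr))
    tests[[length(tests) + 1]] <- data.frame(
      re_id = rep(rownames(rs), times = nrow(gs)),
      gene_id = rep(rownames(gs), each = nrow(rs)),
      tad_id = tid, rho = as.vector(rho), stringsAsFactors = FALSE)
  }
  if (length(tests) == 0) {
    empty <- data.frame(re_id = character(), gene_id = character(),
                        tad_id = character(), rho = numeric(),
                        pvalue = numeric(), qvalue = numeric(),
                        is_naive_pair = logical(), stringsAsFactors = FALSE)
    return(list(links = empty, tests = empty, n_tests = 0,
                skipped_zero_variance = skipped, summary = NULL))
  }
  tests <- do.call(rbind, tests)
  tests$pvalue <- spearman_pvalue(tests$rho, n)
  tests$qvalue <- bh_adjust(tests$pvalue)
  keep <- tests$qvalue < alpha
  if (positive_only) keep <- keep & tests$rho > 0
  links <- tests[keep, , drop = FALSE]
  np <- if ("re_class" %in% names(res)) naive_pairs(res, genes) else NULL
  if (!is.null(np)) {
    key <- function(d) paste(d$re_id, d$gene_id, sep = "\r")
    links$is_naive_pair <- key(links) %in% key(np)
  } else links$is_naive_pair <- rep(NA, nrow(links))
  rownames(links) <- NULL
  list(links = links, tests = tests, n_tests = nrow(tests),
       skipped_zero_variance = skipped,
       summary = link_summary(links, res, np))
}

link_summary <- function(links, res, np) {
  gpr <- table(links$re_id); rpg <- table(links$gene_id)
  s <- list(n_pairs = nrow(links),
            n_res = length(unique(links$re_id)),
            n_genes = length(unique(links$gene_id)),
            mean_genes_per_re = if (length(gpr)) mean(gpr) else 0,
            median_genes_per_re = if (length(gpr)) median(gpr) else 0,
            mean_res_per_gene = if (length(rpg)) mean(rpg) else 0,
            median_res_per_gene = if (length(rpg)) median(rpg) else 0)
  if (!is.null(np) && "re_class" %in% names(res)) {
    key <- function(d) paste(d$re_id, d$gene_id, sep = "\r")
    frac_naive <- function(cls) {
      ids <- res$re_id[res$re_class == cls]
      with_target <- intersect(ids, unique(links$re_id))
      if (length(with_target) == 0) return(NA_real_)
      np_cls <- np[np$re_id %in% with_target, , drop = FALSE]
      hit <- unique(np_cls$re_id[key(np_cls) %in% key(links)])
      length(hit) / length(with_target)
    }
    s$frac_genic_targeting_overlapped <- frac_naive("genic")
    s$frac_intergenic_targeting_nearest <- frac_naive("intergenic")
  }
  s
}
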