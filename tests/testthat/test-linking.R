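test_that("TMM factors are 1 for identical or depth-scaled columns", {
  set.seed(51)
  m <- matrix(rpois(400, 60), 100, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  same <- cbind(a = m[, 1], b = m[, 1], c = m[, 1])
  expect_equal(unname(tmm_factors(same)), rep(1, 3), tolerance = 1e-12)
  doubled <- cbind(a = m[, 1], b = 2 * m[, 1])
  expect_equal(unname(tmm_factors(doubled)), c(1, 1), tolerance = 1e-12)
  f <- tmm_factors(m)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  expect_error(tmm_factors(m, lib_sizes = c(0, 1, 1, 1)), "zero library")
})

test_that("TMM matches edgeR::calcNormFactors on random count matrices", {
  skip_if_not_installed("edgeR")
  set.seed(52)
  for (i in 1:3) {
    m <- matrix(rnbinom(600 * 6, mu = exp(runif(600 * 6, 2, 6)), size = 5),
                600, 6, dimnames = list(NULL, paste0("s", 1:6)))
    ours <- unname(tmm_factors(m))
    ref <- unname(edgeR::calcNormFactors(m, method = "TMM"))
    expect_equal(ours, ref, tolerance = 1e-8)
  }
})

test_that("TMM absorbs composition bias and recenters unperturbed rows", {
  set.seed(53)
  base <- rpois(600, 100) + 1
  biased <- base
  hot <- sample(600, 60)
  biased[hot] <- biased[hot] * 8
  m <- cbind(ref = base, biased = biased)
  nm <- normalize_counts(m)
  lr <- log2(nm$cpm[-hot, "biased"] / nm$cpm[-hot, "ref"])
  expect_lt(abs(median(lr)), 0.05)
  # without normalization the same rows are visibly shifted
  raw <- sweep(m, 2, colSums(m), "/")
  expect_gt(abs(median(log2(raw[-hot, 2] / raw[-hot, 1]))), 0.1)
})

test_that("TMM factors are equivariant under sample permutation", {
  set.seed(54)
  m <- matrix(rnbinom(500 * 5, mu = 80, size = 5), 500, 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  f <- tmm_factors(m)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(unname(tmm_factors(m[, perm])), unname(f[perm]),
               tolerance = 1e-12)
})

test_that("expressed/tissue-specific flags follow the CPM rules", {
  cpm <- rbind(a = c(40, 40, 5, 5, 5, 5),    # ratios 8x -> specific
               b = c(16, 16, 5, 5, 4, 4),    # 16/5 = 3.2 < 4 -> not
               c = c(0.9, 0.9, 0.2, 0.2, 0.1, 0.1),  # below 1 CPM
               d = c(3, 3, 0, 0, 0, 0))      # zero elsewhere counts
  tm <- rep(c("liver", "lung", "spleen"), each = 2)
  fl <- expressed_and_specific(cpm, tm)
  expect_equal(fl$expressed, c(TRUE, TRUE, FALSE, TRUE))
  # specificity is independent of the expressed flag (row c: 0.9/0.2 >= 4)
  expect_equal(fl$tissue_specific, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(fl$top_tissue[1], "liver")
})

test_that("variance filter retains max/min ratio > threshold and zero-min rows", {
  v <- rbind(r1 = c(1, 7), r2 = c(2, 10), r3 = c(0, 3), r4 = c(0, 0),
             r5 = c(1, 6))
  expect_equal(variance_filter(v), c("r1", "r3"))
})

test_that("TAD membership matches a brute-force point-in-interval scan", {
  tads <- genomic_intervals("chr1", c(1000, 5000), c(2000, 8000))
  res <- data.frame(chrom = "chr1", start = c(990, 1990, 4990),
                    end = c(1010, 2010, 5010),
                    re_id = c("a", "b", "c"))
  genes <- data.frame(gene_id = c("g1", "g2"), biotype = "protein_coding",
                      chrom = "chr1", start = c(1000, 7999),
                      end = c(1500, 9000), strand = c("+", "+"))
  genes$tss <- I(list(1000, 7999))
  memb <- assign_to_tads(res, genes, tads)
  # midpoints: 1000 (on start boundary -> member), 2000 (past end), 5000
  expect_equal(unname(memb$re_tad), c("TAD0001", NA, "TAD0002"))
  expect_equal(unname(memb$gene_tad), c("TAD0001", "TAD0002"))
  set.seed(61)
  tr <- merge_intervals(random_intervals(20, chroms = "chr1",
                                         max_pos = 5e4, max_len = 3000),
                        bookended = FALSE)
  tr$tad_id <- sprintf("TAD%04d", seq_len(nrow(tr)))
  rr <- random_intervals(200, chroms = "chr1", max_pos = 5e4)
  rr$re_id <- sprintf("re%d", seq_len(nrow(rr)))
  mb <- assign_to_tads(rr, genes, tr)
  mid <- floor((rr$start + rr$end) / 2)
  oracle <- vapply(mid, function(p) {
    k <- which(tr$start <= p & p < tr$end)
    if (length(k)) tr$tad_id[k] else NA_character_
  }, "")
  expect_equal(unname(mb$re_tad), oracle)
})

test_that("spearman_test matches hand computations and cor.test", {
  expect_equal(spearman_test(1:4, c(10, 20, 30, 40))$rho, 1)
  expect_equal(spearman_test(1:4, c(10, 20, 30, 40))$pvalue, 0)
  expect_equal(spearman_test(1:4, c(40, 30, 20, 10))$rho, -1)
  # tied data, hand-computed with average ranks
  st <- spearman_test(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(st$rho, 4.5 / sqrt(22.5), tolerance = 1e-12)
  expect_true(is.na(spearman_test(rep(2, 5), 1:5)$rho))
  set.seed(71)
  for (i in 1:20) {
    n <- sample(5:50, 1)
    x <- sample(1:8, n, replace = TRUE)   # heavy ties
    y <- x * sample(c(1, -1), 1) + rnorm(n, 0, 2)
    st <- spearman_test(x, y)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    expect_equal(st$rho, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(st$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    if (abs(st$rho) < 1 - 1e-12)
      expect_equal(st$pvalue, ct$p.value, tolerance = 1e-9)
  }
})

test_that("bh_adjust equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(81)
  for (i in 1:10) {
    p <- runif(sample(c(3, 50, 1000), 1))^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(q >= 0 & q <= 1))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-14))  # monotone in p-rank
  }
})

test_that("naive_pairs handles overlaps, nearest TSS and ties", {
  genes <- data.frame(gene_id = c("gB", "gA", "gC"),
                      biotype = "protein_coding", chrom = "chr1",
                      start = c(100, 150, 5000), end = c(1000, 900, 6000),
                      strand = "+")
  genes$tss <- I(list(100, 150, 5000))
  res <- data.frame(chrom = "chr1", start = c(200, 2550), end = c(300, 2650),
                    re_id = c("reG", "reI"),
                    re_class = c("genic", "intergenic"))
  np <- naive_pairs(res, genes)
  # genic RE inside two overlapping genes -> two pairs
  expect_setequal(np$gene_id[np$re_id == "reG"], c("gA", "gB"))
  # intergenic RE equidistant (2450 bp) from gA's TSS? no: distances to
  # TSSs 100/150/5000 are 2450/2400/2350 -> gC
  expect_equal(np$gene_id[np$re_id == "reI"], "gC")
  # exact tie broken lexicographically
  res2 <- data.frame(chrom = "chr1", start = 2575, end = 2576,
                     re_id = "mid", re_class = "intergenic")
  genes2 <- genes[c(2, 3), ]; genes2$tss <- I(list(150, 5000))
  expect_equal(naive_pairs(res2, genes2)$gene_id, "gA")
})

test_that("predict_links recovers a single planted deterministic pair", {
  tads <- genomic_intervals("chr1", 0, 1e5)
  res <- data.frame(chrom = "chr1", start = c(1000, 3000, 8000),
                    end = c(1500, 3500, 8500),
                    re_id = c("re1", "re2", "re3"))
  genes <- data.frame(gene_id = c("g1", "g2"), biotype = "protein_coding",
                      chrom = "chr1", start = c(20000, 40000),
                      end = c(25000, 45000), strand = "+")
  genes$tss <- I(list(20000, 40000))
  x <- seq_len(8)
  sig <- rbind(re1 = 10 * x, re2 = rep(5, 8), re3 = rep(7, 8))
  ex <- rbind(g1 = 3 * x + 100, g2 = rep(4, 8))
  colnames(sig) <- colnames(ex) <- paste0("s", 1:8)
  out <- predict_links(sig, ex, res, genes, tads, alpha = 0.05)
  expect_equal(out$links$re_id, "re1")
  expect_equal(out$links$gene_id, "g1")
  expect_equal(out$links$rho, 1)
  expect_equal(out$n_tests, 1)            # constant rows are skipped
  expect_equal(out$skipped_zero_variance, 5)
  expect_true(all(out$links$qvalue < 0.05))
  expect_error(predict_links(sig, ex[, 8:1], res, genes, tads),
               "columns differ")
})

test_that("retained links are a subset of tests with q below alpha", {
  cfg <- small_cfg(seed = 19)
  truth <- simulate_truth(cfg)
  exs <- simulate_expression_and_signal(cfg, truth)
  out <- predict_links(normalize_counts(exs$re_counts),
                       normalize_counts(exs$gene_counts),
                       truth$res, truth$genes, truth$tads)
  key <- function(d) paste(d$re_id, d$gene_id)
  expect_true(all(key(out$links) %in% key(out$tests)))
  expect_true(all(out$links$qvalue < 0.05))
  expect_true(all(out$links$rho > 0))
})
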