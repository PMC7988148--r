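seg_df <- function(chrom, start, end, state) {
  data.frame(chrom = chrom, start = start, end = end, state = state,
             stringsAsFactors = FALSE)
}

test_that("consolidate_active merges adjacent active states only", {
  seg <- seg_df("chr1", c(100, 300, 500), c(300, 500, 900), c(2, 4, 14))
  act <- consolidate_active(list(liver = seg))
  expect_equal(act$liver, data.frame(chrom = "chr1", start = 100, end = 500))
  seg <- seg_df("chr1", c(0, 100), c(100, 200), c(14, 12))
  expect_equal(nrow(consolidate_active(list(liver = seg))$liver), 0)
  bad <- seg_df("chr1", c(0, 50), c(100, 150), c(1, 2))
  expect_error(consolidate_active(list(liver = bad)), "overlapping")
})

test_that("consolidation matches the per-base active-state oracle", {
  set.seed(21)
  for (rep in 1:5) {
    # random tiling of a 50 kb chromosome
    cuts <- sort(sample(1:49999, 200))
    bounds <- c(0, cuts, 50000)
    seg <- seg_df("chr1", bounds[-length(bounds)], bounds[-1],
                  sample(1:14, length(bounds) - 1, replace = TRUE))
    act <- consolidate_active(list(x = seg))$x
    mask <- logical(50000)
    on <- seg[seg$state %in% ACTIVE_STATES, ]
    for (i in seq_len(nrow(on))) mask[(on$start[i] + 1):on$end[i]] <- TRUE
    expect_equal(act, intervals_from_mask(mask, "chr1"), ignore_attr = TRUE)
  }
})

test_that("combine_tissues unions intervals and assigns contributing tissues", {
  act <- list(liver = genomic_intervals("chr1", 100, 300),
              lung = genomic_intervals("chr1", 250, 400))
  cat <- combine_tissues(act)
  expect_equal(nrow(cat), 1)
  expect_equal(cat$start, 100); expect_equal(cat$end, 400)
  expect_equal(cat$active_tissues[[1]], c("liver", "lung"))
  expect_false(cat$tissue_specific)
  solo <- combine_tissues(list(liver = genomic_intervals("chr1", 5, 50)))
  expect_true(solo$tissue_specific)
})

test_that("tissue sets match the per-base contributor oracle on random tracks", {
  set.seed(31)
  tissues <- paste0("t", 1:8)
  act <- lapply(setNames(tissues, tissues), function(t)
    merge_intervals(random_intervals(40, chroms = "chr1", max_pos = 2e4,
                                     max_len = 800)))
  cat <- combine_tissues(act)
  # catalog intervals are pairwise disjoint
  expect_true(all(cat$start[-1] >= cat$end[-nrow(cat)]))
  masks <- lapply(act, mask_from_intervals, chrom = "chr1", chrom_len = 2e4)
  expect_equal(covered_bp(cat), sum(Reduce(`|`, masks)))
  for (i in seq_len(nrow(cat))) {
    span <- (cat$start[i] + 1):cat$end[i]
    oracle <- tissues[vapply(masks, function(m) any(m[span]), TRUE)]
    expect_equal(cat$active_tissues[[i]], oracle)
  }
})

mk_genes <- function(chrom, start, end, strand, biotype, tss = NULL) {
  g <- data.frame(gene_id = sprintf("g%d", seq_along(start)), biotype = biotype,
                  chrom = chrom, start = start, end = end, strand = strand,
                  stringsAsFactors = FALSE)
  g$tss <- I(if (is.null(tss))
    lapply(seq_along(start), function(i)
      if (strand[i] == "+") start[i] else end[i] - 1)
    else tss)
  g
}

test_that("classify_re applies the precedence rules", {
  genes <- mk_genes("chr1", c(10000, 40000), c(30000, 80000), c("+", "+"),
                    c("protein_coding", "protein_coding"))
  res <- data.frame(chrom = "chr1",
                    start = c(8500, 50000, 200000, 300000),
                    end = c(9200, 50400, 200400, 300400),
                    re_id = paste0("re", 1:4))
  extra <- data.frame(chrom = "chr1", pos = 202399)  # 1999 bp from re3 end
  cls <- classify_re(res, genes, extra)
  expect_equal(as.character(cls),
               c("tss_proximal", "genic", "excluded", "intergenic"))
  # inclusive 2 kb boundary: RE starting exactly tss + 2000 is proximal
  re_edge <- data.frame(chrom = "chr1", start = 12000, end = 12100)
  expect_equal(as.character(classify_re(re_edge, genes)), "tss_proximal")
  re_out <- data.frame(chrom = "chr1", start = 82001, end = 82100)
  expect_equal(as.character(classify_re(re_out, genes)), "intergenic")
  # coding proximity beats the exclusion rule
  both <- data.frame(chrom = "chr1", start = 9500, end = 9600)
  expect_equal(as.character(classify_re(both, genes,
                                        data.frame(chrom = "chr1", pos = 9550))),
               "tss_proximal")
})

test_that("classify_re is total and matches a brute-force distance oracle", {
  set.seed(41)
  truth <- simulate_truth(small_cfg(seed = 41))
  res <- truth$res; genes <- truth$genes
  extra <- data.frame(chrom = "chr1",
                      pos = sample(1e6, 30))
  cls <- classify_re(res, genes, extra)
  expect_false(any(is.na(cls)))
  pc <- genes[genes$biotype == "protein_coding", ]
  for (i in sample(nrow(res), 60)) {
    dist_to <- function(pos_set, chroms) {
      same <- chroms == res$chrom[i]
      if (!any(same)) return(Inf)
      p <- pos_set[same]
      min(pmax(res$start[i] - p, p - (res$end[i] - 1), 0))
    }
    tpc <- do.call(rbind, lapply(seq_len(nrow(pc)), function(j)
      data.frame(pos = pc$tss[[j]], chrom = pc$chrom[j])))
    d_cod <- dist_to(tpc$pos, tpc$chrom)
    d_ex <- dist_to(extra$pos, extra$chrom)
    ov <- any(overlap_bp(res[rep(i, nrow(pc)), ], pc) > 0)
    want <- if (d_cod <= 2000) "tss_proximal"
            else if (d_ex <= 2000) "excluded"
            else if (ov) "genic" else "intergenic"
    expect_equal(as.character(cls[i]), want)
  }
})

test_that("open-chromatin support is tissue-matched", {
  res <- data.frame(chrom = "chr1", start = c(100, 500), end = c(200, 600),
                    re_id = c("a", "b"))
  res$active_tissues <- I(list("liver", "liver"))
  peaks <- list(liver = genomic_intervals("chr1", 150, 160),
                lung = genomic_intervals("chr1", 550, 560))
  sup <- open_chromatin_support(res, peaks)
  expect_equal(sup$supported, c(TRUE, FALSE))  # lung peak does not count
  expect_equal(sup$fraction, 0.5)
})

test_that("state enrichment matches closed forms and the null case", {
  feat <- genomic_intervals("chr1", 0, 1000)
  seg <- seg_df("chr1", 0, 1000, 3)
  e <- state_feature_enrichment(seg, feat, genome_size = 10000)
  expect_equal(e$enrichment[3], 10000 / 1000)    # state == features
  # state fully inside features occupying 20% of the genome -> 5x
  seg2 <- seg_df("chr1", c(0, 5000), c(500, 5500), c(7, 7))
  feat2 <- genomic_intervals("chr1", c(0, 5000), c(1000, 6000))
  e2 <- state_feature_enrichment(seg2, feat2, genome_size = 10000)
  expect_equal(e2$enrichment[7], 5)
  expect_true(is.na(e2$enrichment[1]))           # absent state sentinel
  # state uniform over the whole genome -> enrichment 1
  seg3 <- seg_df("chr1", 0, 10000, 9)
  e3 <- state_feature_enrichment(seg3, feat2, genome_size = 10000)
  expect_equal(e3$enrichment[9], 1)
})
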