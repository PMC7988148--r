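test_that("the generator is deterministic under a fixed seed", {
  cfg <- small_cfg(seed = 4)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth$res, s2$truth$res)
  expect_identical(s1$segmentations, s2$segmentations)
  expect_identical(s1$expression$gene_counts, s2$expression$gene_counts)
  expect_identical(as.character(s1$ctcf$genome), as.character(s2$ctcf$genome))
  expect_identical(s1$alignment$map, s2$alignment$map)
  expect_identical(s1$snps$pos, s2$snps$pos)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  # different seeds diverge
  expect_false(identical(simulate_truth(small_cfg(seed = 5))$res$start,
                         s1$truth$res$start))
})

test_that("segmentations tile every chromosome without gaps and plant the REs", {
  cfg <- small_cfg(seed = 6)
  truth <- simulate_truth(cfg)
  segs <- simulate_segmentations(cfg, truth)
  expect_named(segs, cfg$tissues, ignore.order = TRUE)
  for (t in cfg$tissues) {
    seg <- segs[[t]]
    for (cn in names(truth$chroms)) {
      s <- seg[seg$chrom == cn, ]
      s <- s[order(s$start), ]
      expect_equal(s$start[1], 0)
      expect_equal(s$end[nrow(s)], unname(truth$chroms[[cn]]))
      expect_true(all(s$start[-1] == s$end[-nrow(s)]))  # gapless tiling
    }
    expect_true(all(seg$state %in% 1:14))
  }
  # an RE active only in one tissue is active exactly there
  solo <- which(lengths(truth$res$active_tissues) == 1)[1]
  re <- truth$res[solo, ]
  tis <- re$active_tissues[[1]]
  for (t in cfg$tissues) {
    seg <- segs[[t]]
    inside <- seg$chrom == re$chrom & seg$start < re$end & seg$end > re$start
    active <- seg$state[inside] %in% ACTIVE_STATES
    if (t == tis) expect_true(all(active))
    else expect_false(any(active))
  }
})

test_that("consolidating emitted segmentations recovers >= 99% of planted RE bases", {
  cfg <- small_cfg(seed = 8)
  truth <- simulate_truth(cfg)
  catalog <- combine_tissues(consolidate_active(simulate_segmentations(cfg, truth)))
  inter <- overlap_join(truth$res, catalog)
  frac <- sum(inter$bp) / sum(truth$res$end - truth$res$start)
  expect_gte(frac, 0.99)
  # recovered activity sets equal the planted ones
  expect_equal(nrow(catalog), nrow(truth$res))
  expect_equal(lapply(catalog$active_tissues, as.character),
               lapply(truth$res$active_tissues, as.character),
               ignore_attr = TRUE)
})

test_that("noise-free limit gives Spearman 1 for true pairs", {
  cfg <- small_cfg(seed = 10, link_rho = 1, nb_dispersion = 0)
  truth <- simulate_truth(cfg)
  exs <- simulate_expression_and_signal(cfg, truth)
  for (i in seq_len(min(10, nrow(truth$links)))) {
    x <- exs$re_counts[truth$links$re_id[i], ]
    y <- exs$gene_counts[truth$links$gene_id[i], ]
    expect_equal(spearman_test(x, y)$rho, 1)
  }
})

test_that("null pairs show no systematic association", {
  cfg <- small_cfg(seed = 12, link_rho = 0)
  truth <- simulate_truth(cfg)
  exs <- simulate_expression_and_signal(cfg, truth)
  set.seed(1)
  n <- ncol(exs$re_counts)
  rhos <- replicate(1000, {
    r <- exs$re_counts[sample(nrow(exs$re_counts), 1), ]
    g <- exs$gene_counts[sample(nrow(exs$gene_counts), 1), ]
    spearman_test(r, g)$rho
  })
  mc_se <- sd(abs(rhos)) / sqrt(length(rhos))
  expect_lte(mean(abs(rhos)), 2 / sqrt(n - 1) + 3 * mc_se)
})

test_that("doubling one sample's depth leaves its post-TMM CPM unchanged", {
  base <- small_cfg(seed = 14, nb_dispersion = 0,
                    depth_factors = rep(1, 16))
  boosted <- small_cfg(seed = 14, nb_dispersion = 0,
                       depth_factors = c(2, rep(1, 15)))
  e1 <- simulate_expression_and_signal(base)
  e2 <- simulate_expression_and_signal(boosted)
  cpm1 <- normalize_counts(e1$gene_counts)$cpm
  cpm2 <- normalize_counts(e2$gene_counts)$cpm
  expect_equal(cpm2, cpm1, tolerance = 0.01)
})

test_that("library sizes span a > 3-fold range by default", {
  exs <- simulate_expression_and_signal(small_cfg(seed = 16))
  lib <- colSums(exs$gene_counts)
  expect_gt(max(lib) / min(lib), 3 * 0.8)   # depth design ratio ~3.3
  expect_gt(max(exs$depth_factors) / min(exs$depth_factors), 3)
})

test_that("CTCF architecture embeds the consensus at planted boundaries", {
  cfg <- small_cfg(seed = 18)
  truth <- simulate_truth(cfg)
  ctcf <- simulate_ctcf_architecture(cfg, truth)
  cons <- "TGGCCACCAGGGGGCGCTA"
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(cons, "")[[1]]),
                                     collapse = ""))
  w <- nchar(cons); half <- w %/% 2
  g <- as.character(ctcf$genome)
  for (j in sample(nrow(truth$tads), 5)) {
    td <- truth$tads[j, ]
    fs <- td$start - half; rs <- td$end - half
    expect_equal(substr(g[[td$chrom]], fs + 1, fs + w), cons)
    expect_equal(substr(g[[td$chrom]], rs + 1, rs + w), rc)
  }
  # every planted motif lies inside a peak; decoys carry no hits
  pred <- predict_tads(ctcf$genome, ctcf$peaks, ctcf$pwm)
  expect_equal(nrow(pred$sites), 2 * nrow(truth$tads))
})

test_that("alignment maps plant conservation at the configured rate", {
  cfg <- sim_config(seed = 20, n_res = 400)
  truth <- simulate_truth(cfg)
  al <- simulate_alignment_map(cfg, truth)
  validate_alignment_map(al$map)
  cc <- call_conservation(map_intervals(truth$res, al$map), al$target_res)
  expect_equal(cc$mapping_rate, mean(truth$res$truth_mapped))
  expect_equal(cc$conservation_rate,
               sum(truth$res$truth_conserved) / sum(truth$res$truth_mapped))
  # identity-map limit: everything mapped, everything conserved
  cfg1 <- small_cfg(seed = 22, map_frac = 1, frac_conserved_re = 1)
  truth1 <- simulate_truth(cfg1)
  al1 <- simulate_alignment_map(cfg1, truth1)
  cc1 <- call_conservation(map_intervals(truth1$res, al1$map),
                           al1$target_res)
  expect_equal(cc1$mapping_rate, 1)
  expect_equal(cc1$conservation_rate, 1)
})

test_that("ground-truth invariants hold: links live inside their TAD", {
  truth <- simulate_truth(small_cfg(seed = 24))
  memb <- assign_to_tads(truth$res, truth$genes, truth$tads)
  expect_equal(unname(memb$re_tad[truth$links$re_id]), truth$links$tad_id)
  expect_equal(unname(memb$gene_tad[truth$links$gene_id]),
               truth$links$tad_id)
  expect_true(all(lengths(truth$res$active_tissues) >= 1))
  expect_equal(truth$res$tissue_specific,
               lengths(truth$res$active_tissues) == 1)
})
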