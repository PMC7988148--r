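# Seeded generator for every input the pipeline consumes, with planted
# ground truth: tissue-structured chromatin-state tracks containing known
# REs, negative-binomial expression/signal counts with planted monotone
# RE-gene relationships inside planted TADs, convergent CTCF motif
# placements delimiting those TADs, alignment-block maps with planted
# conserved REs, and SNP sets enriched inside REs at a known odds ratio.
#
# Each component reseeds the RNG from the config seed plus a fixed
# offset, so any subset of components can be generated reproducibly and
# independently of call order.

STUDY_TISSUES <- c("liver", "lung", "spleen", "muscle", "adipose",
                   "cerebellum", "cortex", "hypothalamus")

#' Simulation configuration
#'
#' Defaults describe the reference study design: a 2 x 10 Mb genome, 300
#' genes and 600 REs inside 40 planted TADs, eight tissues with two
#' replicates each (16 samples), 10% of in-TAD RE-gene pairs planted as
#' true links with latent correlation 0.9, and SNP categories enriched in
#' REs at odds 2.5.
#'
#' @param seed RNG seed (integer).
#' @param n_chroms,chrom_len Genome shape.
#' @param n_genes,n_res,n_tads Feature counts (all placed inside TADs).
#' @param n_tissues,n_reps Sample layout (default 8 x 2).
#' @param frac_true_links Fraction of in-TAD RE-gene pairs planted as true
#'   links (each RE drives at most one gene).
#' @param link_rho Latent Gaussian correlation of a true link's tissue
#'   activities, in (0, 1].
#' @param nb_dispersion Negative-binomial dispersion of the counts; 0
#'   switches to the noise-free limit where expected counts are emitted.
#' @param activity_sd Standard deviation of the per-tissue log-activity.
#' @param depth_factors Optional per-sample depth multipliers (length
#'   `n_tissues * n_reps`); the default spans a > 3-fold range to exercise
#'   TMM.
#' @param n_decoy_peaks Motif-free CTCF peaks added per genome.
#' @param tad_max_span Maximum planted TAD span in bp.
#' @param map_frac Probability that an RE lies in an aligned region.
#' @param frac_conserved_re Probability that a mapped RE has a planted
#'   ortholog in the target catalog.
#' @param snp_re_odds Planted odds ratio of categorized vs uncategorized
#'   SNPs lying in REs.
#' @param n_snps_per_group SNPs per category group (and uncategorized).
#' @param snp_categories Category labels to simulate.
#' @param prob_extra_tissue Per-tissue probability of an RE being active
#'   in each additional tissue beyond its first.
#' @param tissue_share Fraction of latent log-activity variance that is
#'   tissue-consistent (shared between replicates); the rest is
#'   sample-specific.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chroms = 2L, chrom_len = 1e7,
                       n_genes = 300L, n_res = 600L, n_tads = 40L,
                       n_tissues = 8L, n_reps = 2L,
                       frac_true_links = 0.1, link_rho = 0.9,
                       nb_dispersion = 0.05, activity_sd = 1.2,
                       depth_factors = NULL,
                       n_decoy_peaks = 60L, tad_max_span = 1e6,
                       map_frac = 0.8, frac_conserved_re = 0.5,
                       snp_re_odds = 2.5, n_snps_per_group = 5000L,
                       snp_categories = c("geQTL", "mQTL"),
                       prob_extra_tissue = 0.18, tissue_share = 0.3) {
  stopifnot(n_chroms >= 1, chrom_len >= 1e5, n_genes >= 1, n_res >= 1,
            n_tads >= 1, n_tissues >= 2, n_tissues <= length(STUDY_TISSUES),
            n_reps >= 1, link_rho >= 0, link_rho <= 1,
            frac_true_links >= 0, frac_true_links <= 1,
            nb_dispersion >= 0, map_frac >= 0, map_frac <= 1,
            frac_conserved_re >= 0, frac_conserved_re <= 1,
            snp_re_odds > 0, tissue_share >= 0, tissue_share <= 1)
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_len = chrom_len, n_genes = as.integer(n_genes),
              n_res = as.integer(n_res), n_tads = as.integer(n_tads),
              n_tissues = as.integer(n_tissues), n_reps = as.integer(n_reps),
              tissues = STUDY_TISSUES[seq_len(n_tissues)],
              frac_true_links = frac_true_links, link_rho = link_rho,
              nb_dispersion = nb_dispersion, activity_sd = activity_sd,
              depth_factors = depth_factors,
              n_decoy_peaks = as.integer(n_decoy_peaks),
              tad_max_span = tad_max_span, map_frac = map_frac,
              frac_conserved_re = frac_conserved_re,
              snp_re_odds = snp_re_odds,
              n_snps_per_group = as.integer(n_snps_per_group),
              snp_categories = snp_categories,
              prob_extra_tissue = prob_extra_tissue,
              tissue_share = tissue_share)
  structure(cfg, class = "sim_config")
}

sim_seed <- function(cfg, offset) {
  set.seed((cfg$seed %% 2000000L) * 1000L + offset)
}

#' Simulate the genome layout and ground truth
#'
#' Places disjoint TADs on each chromosome, then genes and REs in
#' non-overlapping slots inside each TAD, assigns each RE a non-empty
#' tissue-activity set, draws per-RE mapped/conserved flags, and plants
#' true RE-gene links (each RE drives at most one gene in its own TAD).
#'
#' @param cfg A [sim_config()].
#' @return Object of class `sim_truth`: list with `cfg`, `chroms`, `tads`,
#'   `genes`, `res`, `links`, `motif_width`.
#' @export
simulate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sim_seed(cfg, 0L)
  w <- nrow(ctcf_pwm())
  chroms <- setNames(rep(cfg$chrom_len, cfg$n_chroms),
                     paste0("chr", seq_len(cfg$n_chroms)))
  # --- TADs: one per regular slot, jittered, capped at tad_max_span -----
  per_chrom <- diff(round(seq(0, cfg$n_tads, length.out = cfg$n_chroms + 1)))
  tad_rows <- list()
  for (ci in seq_len(cfg$n_chroms)) {
    nt <- per_chrom[ci]
    if (nt == 0) next
    slot <- cfg$chrom_len / nt
    for (k in seq_len(nt)) {
      span <- min(runif(1, 0.35, 0.65) * slot, cfg$tad_max_span)
      lo <- (k - 1) * slot + 0.12 * slot
      start <- round(lo + runif(1, 0, 0.15 * slot))
      tad_rows[[length(tad_rows) + 1]] <- data.frame(
        chrom = names(chroms)[ci], start = start,
        end = round(start + span), stringsAsFactors = FALSE)
    }
  }
  tads <- sort_intervals(do.call(rbind, tad_rows))
  tads$tad_id <- sprintf("TAD%04d", seq_len(nrow(tads)))
  # --- genes and REs in interleaved slots inside each TAD --------------
  n_tads <- nrow(tads)
  genes_per <- diff(round(seq(0, cfg$n_genes, length.out = n_tads + 1)))
  res_per <- diff(round(seq(0, cfg$n_res, length.out = n_tads + 1)))
  gene_rows <- list(); re_rows <- list()
  for (ti in seq_len(n_tads)) {
    ng <- genes_per[ti]; nr <- res_per[ti]
    n_items <- ng + nr
    if (n_items == 0) next
    span <- tads$end[ti] - tads$start[ti]
    slot <- span / n_items
    if (slot < 400)
      stop("RE/gene density exceeds TAD capacity; enlarge the genome")
    kind <- sample(c(rep("gene", ng), rep("re", nr)))
    # genes first: one per gene slot, with a leading margin left free so
    # promoter REs can sit upstream of the TSS without slot collisions
    local_genes <- list()
    for (k in which(kind == "gene")) {
      lo <- tads$start[ti] + (k - 1) * slot
      len <- round(min(runif(1, 2000, 8000), 0.55 * slot))
      start <- round(lo + runif(1, 0.25, 0.35) * slot)
      start <- min(start, tads$end[ti] - len - 10)
      local_genes[[length(local_genes) + 1]] <- list(
        start = start, end = start + len,
        strand = sample(c("+", "-"), 1), used_prom = FALSE,
        used_genic = FALSE)
    }
    # REs: a mix of intergenic, promoter-attached and gene-body elements;
    # candidates needing gene context fall back to their own slot when
    # clearance (>= 30 bp from every placed RE, inside the TAD) fails
    placed <- list()
    clear <- function(s, e) {
      if (s < tads$start[ti] + 10 || e > tads$end[ti] - 10) return(FALSE)
      for (p in placed) if (s < p$end + 30 && p$start < e + 30) return(FALSE)
      TRUE
    }
    for (k in which(kind == "re")) {
      lo <- tads$start[ti] + (k - 1) * slot
      type <- sample(c("intergenic", "promoter", "genic"), 1,
                     prob = c(0.55, 0.25, 0.2))
      start <- NA
      if (type == "promoter") {
        avail <- which(!vapply(local_genes, `[[`, TRUE, "used_prom"))
        if (length(avail) > 0) {
          gi <- if (length(avail) == 1) avail else sample(avail, 1)
          g <- local_genes[[gi]]
          # total reach <= 0.2 * slot keeps the element inside the gene's
          # own slot at any simulation scale
          len <- round(min(runif(1, 500, 1500), 0.12 * slot))
          gap <- round(min(runif(1, 50, 1200), 0.08 * slot))
          s <- if (g$strand == "+") g$start - gap - len else g$end + gap
          if (clear(s, s + len)) {
            start <- s
            local_genes[[gi]]$used_prom <- TRUE
          }
        }
      } else if (type == "genic") {
        ok <- vapply(local_genes, function(g)
          !g$used_genic && (g$end - g$start) >= 4800, TRUE)
        if (any(ok)) {
          gi <- if (sum(ok) == 1) which(ok) else sample(which(ok), 1)
          g <- local_genes[[gi]]
          len <- round(runif(1, 400, 900))
          s <- if (g$strand == "+") g$start + 2200 + round(runif(1, 0, 200))
               else g$end - 2200 - len - round(runif(1, 0, 200))
          if (s > g$start && s + len < g$end && clear(s, s + len)) {
            start <- s
            local_genes[[gi]]$used_genic <- TRUE
          }
        }
      }
      if (is.na(start)) {
        type <- "intergenic"
        len <- round(min(runif(1, 500, 2000), 0.5 * slot))
        start <- round(lo + runif(1, 0.3, 0.45) * slot)
        start <- min(start, tads$end[ti] - len - 10)
      }
      placed[[length(placed) + 1]] <- list(start = start, end = start + len)
      re_rows[[length(re_rows) + 1]] <- data.frame(
        chrom = tads$chrom[ti], start = start, end = start + len,
        tad_id = tads$tad_id[ti], planted_context = type,
        stringsAsFactors = FALSE)
    }
    for (g in local_genes)
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        chrom = tads$chrom[ti], start = g$start, end = g$end,
        strand = g$strand, tad_id = tads$tad_id[ti],
        stringsAsFactors = FALSE)
  }
  genes <- sort_intervals(do.call(rbind, gene_rows))
  genes$gene_id <- sprintf("G%05d", seq_len(nrow(genes)))
  genes$biotype <- sample(c("protein_coding", "non_coding"), nrow(genes),
                          replace = TRUE, prob = c(0.9, 0.1))
  tss <- vector("list", nrow(genes))
  for (j in seq_len(nrow(genes))) {
    n_tx <- sample(1:2, 1)
    len <- genes$end[j] - genes$start[j]
    off <- c(0, round(runif(n_tx - 1, 0.05, 0.3) * len))
    tss[[j]] <- sort(if (genes$strand[j] == "+") genes$start[j] + off
                     else genes$end[j] - 1 - off)
  }
  genes$tss <- I(tss)
  res <- sort_intervals(do.call(rbind, re_rows))
  res$re_id <- sprintf("RE%05d", seq_len(nrow(res)))
  # --- tissue activity sets (non-empty) ---------------------------------
  act <- vector("list", nrow(res))
  for (j in seq_len(nrow(res))) {
    first <- sample(cfg$tissues, 1)
    extra <- cfg$tissues[runif(cfg$n_tissues) < cfg$prob_extra_tissue]
    act[[j]] <- sort(unique(c(first, extra)))
  }
  res$active_tissues <- I(act)
  res$tissue_specific <- lengths(act) == 1
  # --- conservation flags ----------------------------------------------
  res$truth_mapped <- runif(nrow(res)) < cfg$map_frac
  res$truth_conserved <- res$truth_mapped &
    (runif(nrow(res)) < cfg$frac_conserved_re)
  # --- true links: sample in-TAD pairs, one gene per RE -----------------
  pair_list <- list()
  for (tid in tads$tad_id) {
    r <- res$re_id[res$tad_id == tid]
    g <- genes$gene_id[genes$tad_id == tid]
    if (length(r) == 0 || length(g) == 0) next
    pair_list[[tid]] <- expand.grid(re_id = r, gene_id = g,
                                    KEEP.OUT.ATTRS = FALSE,
                                    stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pair_list)
  n_true <- round(cfg$frac_true_links * nrow(pairs))
  pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
  pairs <- pairs[!duplicated(pairs$re_id), , drop = FALSE]
  links <- head(pairs, n_true)
  links$tad_id <- res$tad_id[match(links$re_id, res$re_id)]
  links <- links[order(links$re_id), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(cfg = cfg, chroms = chroms, tads = tads, genes = genes,
                 res = res, links = links, motif_width = w),
            class = "sim_truth")
}

#' Simulate per-tissue chromatin-state segmentations
#'
#' Each planted RE is written as a run of active states (from 1-6, 8, 9,
#' 11) in every tissue of its activity set; the background tiles the rest
#' of each chromosome with low-signal state 14 interleaved with repressed
#' states 12-13.  Per-tissue records tile each chromosome without gaps.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_truth()] (regenerated when omitted).
#' @return Named list (per tissue) of segmentation data frames
#'   (chrom/start/end/state).
#' @export
simulate_segmentations <- function(cfg, truth = simulate_truth(cfg)) {
  sim_seed(cfg, 101L)
  active_pool <- ACTIVE_STATES
  bg_pool <- c(12L, 13L, 14L)
  segs <- list()
  for (t in cfg$tissues) {
    rows <- list()
    active_here <- vapply(truth$res$active_tissues, function(s) t %in% s,
                          TRUE)
    for (cn in names(truth$chroms)) {
      r <- truth$res[active_here & truth$res$chrom == cn, , drop = FALSE]
      r <- r[order(r$start), , drop = FALSE]
      pos <- 0
      emit_bg <- function(from, to) {
        if (to <= from) return(NULL)
        n_seg <- if (to - from > 5000) sample(1:3, 1) else 1L
        cuts <- sort(c(from, to,
                       if (n_seg > 1) round(runif(n_seg - 1, from + 1, to - 1))))
        cuts <- unique(cuts)
        data.frame(chrom = cn, start = cuts[-length(cuts)], end = cuts[-1],
                   state = sample(bg_pool, length(cuts) - 1, replace = TRUE,
                                  prob = c(0.08, 0.07, 0.85)),
                   stringsAsFactors = FALSE)
      }
      for (j in seq_len(nrow(r))) {
        rows[[length(rows) + 1]] <- emit_bg(pos, r$start[j])
        n_seg <- if (r$end[j] - r$start[j] > 800) sample(1:2, 1) else 1L
        cuts <- unique(sort(c(r$start[j], r$end[j],
                              if (n_seg > 1)
                                round(runif(1, r$start[j] + 1, r$end[j] - 1)))))
        rows[[length(rows) + 1]] <- data.frame(
          chrom = cn, start = cuts[-length(cuts)], end = cuts[-1],
          state = sample(active_pool, length(cuts) - 1, replace = TRUE),
          stringsAsFactors = FALSE)
        pos <- r$end[j]
      }
      rows[[length(rows) + 1]] <- emit_bg(pos, truth$chroms[[cn]])
    }
    segs[[t]] <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  }
  segs
}

nb_draw <- function(mu, dispersion) {
  if (dispersion <= 0) return(mu)
  matrix(rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
         nrow = nrow(mu), dimnames = dimnames(mu))
}

#' Simulate gene-expression and RE-signal count matrices
#'
#' A per-gene, per-tissue latent activity drives the gene's
#' negative-binomial mean; each truly linked RE shares that latent with
#' correlation `link_rho` (unlinked REs get independent latents), so true
#' pairs show a monotone association across the `n_tissues * n_reps`
#' samples while null pairs are independent.  Per-sample depth factors
#' span a > 3-fold range so TMM normalization has real work to do.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @return List: `gene_counts` (genes x samples), `re_counts` (REs x
#'   samples), `samples` data frame (sample_id, tissue, rep),
#'   `depth_factors`.
#' @export
simulate_expression_and_signal <- function(cfg, truth = simulate_truth(cfg)) {
  sim_seed(cfg, 202L)
  n_s <- cfg$n_tissues * cfg$n_reps
  samples <- data.frame(
    sample_id = paste(rep(cfg$tissues, each = cfg$n_reps),
                      rep(seq_len(cfg$n_reps), cfg$n_tissues), sep = "_"),
    tissue = rep(cfg$tissues, each = cfg$n_reps),
    rep = rep(seq_len(cfg$n_reps), cfg$n_tissues),
    stringsAsFactors = FALSE)
  depth <- cfg$depth_factors
  if (is.null(depth))
    depth <- sample(exp(seq(log(0.55), log(1.8), length.out = n_s)))
  stopifnot(length(depth) == n_s)
  ng <- nrow(truth$genes); nr <- nrow(truth$res)
  tis_idx <- match(samples$tissue, cfg$tissues)
  # Per-sample latent activity with a tissue-consistent component:
  # replicates are different animals, so most activity variation is
  # sample-specific; gene expression and RE signal of a true link are
  # measured in the same sample and share the per-sample latent with
  # correlation link_rho.
  ts <- cfg$tissue_share
  structured <- function(n, ids) {
    b <- matrix(rnorm(n * cfg$n_tissues), n)[, tis_idx, drop = FALSE]
    e <- matrix(rnorm(n * n_s), n)
    m <- sqrt(ts) * b + sqrt(1 - ts) * e
    dimnames(m) <- list(ids, samples$sample_id)
    m
  }
  u <- structured(ng, truth$genes$gene_id)
  z <- structured(nr, truth$res$re_id)
  v <- z
  li <- match(truth$links$re_id, truth$res$re_id)
  gi <- match(truth$links$gene_id, truth$genes$gene_id)
  rho <- cfg$link_rho
  v[li, ] <- rho * u[gi, , drop = FALSE] +
    sqrt(1 - rho^2) * z[li, , drop = FALSE]
  gene_base <- exp(rnorm(ng, log(150), 0.7))
  re_base <- exp(rnorm(nr, log(80), 0.7))
  gene_mu <- (gene_base * exp(cfg$activity_sd * u)) %*% diag(depth)
  re_mu <- (re_base * exp(cfg$activity_sd * v)) %*% diag(depth)
  dimnames(gene_mu) <- list(truth$genes$gene_id, samples$sample_id)
  dimnames(re_mu) <- list(truth$res$re_id, samples$sample_id)
  list(gene_counts = nb_draw(gene_mu, cfg$nb_dispersion),
       re_counts = nb_draw(re_mu, cfg$nb_dispersion),
       samples = samples, depth_factors = depth)
}

#' Reference CTCF-like position-weight matrix
#'
#' A 19-bp informative motif (consensus probability 0.88 per position)
#' used by the simulator; any PWM of the same shape can replace it in the
#' prediction functions.
#'
#' @return Probability matrix (19 x 4, columns A,C,G,T).
#' @export
ctcf_pwm <- function() {
  consensus <- strsplit("TGGCCACCAGGGGGCGCTA", "")[[1]]
  pwm <- matrix(0.04, nrow = length(consensus), ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (j in seq_along(consensus)) pwm[j, consensus[j]] <- 0.88
  pwm
}

revcomp_chars <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Simulate the CTCF architecture: genome, peaks, motif
#'
#' Generates a random genome and embeds the motif consensus forward at
#' each planted TAD start and its reverse complement at each TAD end, so
#' the motif midpoints coincide exactly with the TAD boundaries.  Each
#' embedded motif sits inside a CTCF peak; decoy peaks guaranteed free of
#' motif hits at the scan threshold are added elsewhere.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @param pvalue_threshold Scan threshold the decoys are sanitized
#'   against (keep in sync with the prediction call).
#' @return List: `genome` (`DNAStringSet`), `peaks` (data frame with
#'   peak_id), `pwm`, `tads` (planted truth).
#' @export
simulate_ctcf_architecture <- function(cfg, truth = simulate_truth(cfg),
                                       pvalue_threshold = 1e-4) {
  sim_seed(cfg, 303L)
  pwm <- ctcf_pwm()
  w <- nrow(pwm)
  half <- w %/% 2
  consensus <- "TGGCCACCAGGGGGCGCTA"
  flank <- 150L
  genome <- list()
  for (cn in names(truth$chroms)) {
    len <- truth$chroms[[cn]]
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    td <- truth$tads[truth$tads$chrom == cn, , drop = FALSE]
    for (j in seq_len(nrow(td))) {
      fs <- td$start[j] - half          # forward motif start (0-based)
      rs <- td$end[j] - half            # reverse motif start
      bases[(fs + 1):(fs + w)] <- strsplit(consensus, "")[[1]]
      bases[(rs + 1):(rs + w)] <- strsplit(revcomp_chars(consensus), "")[[1]]
    }
    genome[[cn]] <- bases
  }
  boundary <- do.call(rbind, lapply(seq_len(nrow(truth$tads)), function(j) {
    td <- truth$tads[j, ]
    data.frame(chrom = td$chrom,
               start = c(td$start - half - flank, td$end - half - flank),
               end = c(td$start - half + w + flank, td$end - half + w + flank),
               stringsAsFactors = FALSE)
  }))
  # decoy peaks: uniform placement away from boundary peaks, sanitized so
  # that no position reaches the scan threshold
  thr <- pwm_score_threshold(pwm, pvalue_threshold)
  lom_int <- round(pwm_log_odds(pwm) / thr$granularity)
  rlom_int <- lom_int[w:1, 4:1, drop = FALSE]
  decoys <- list()
  tries <- 0
  while (length(decoys) < cfg$n_decoy_peaks && tries < cfg$n_decoy_peaks * 20) {
    tries <- tries + 1
    cn <- sample(names(truth$chroms), 1)
    start <- round(runif(1, 0, truth$chroms[[cn]] - 400))
    cand <- data.frame(chrom = cn, start = start, end = start + 300)
    near <- boundary[boundary$chrom == cn, , drop = FALSE]
    if (any(pmax(0, pmin(cand$end + 50, near$end) -
                   pmax(cand$start - 50, near$start)) > 0)) next
    if (length(decoys) > 0) {
      prev <- do.call(rbind, decoys)
      prev <- prev[prev$chrom == cn, , drop = FALSE]
      if (nrow(prev) > 0 &&
          any(pmax(0, pmin(cand$end, prev$end) -
                     pmax(cand$start, prev$start)) > 0)) next
    }
    for (k in 1:50) {
      code <- match(genome[[cn]][(cand$start + 1):cand$end],
                    c("A", "C", "G", "T"))
      hit <- any(scan_one_strand(code, lom_int) >= thr$int) ||
        any(scan_one_strand(code, rlom_int) >= thr$int)
      if (!hit) break
      genome[[cn]][(cand$start + 1):cand$end] <-
        sample(c("A", "C", "G", "T"), 300, replace = TRUE)
    }
    decoys[[length(decoys) + 1]] <- cand
  }
  peaks <- rbind(boundary, do.call(rbind, decoys))
  peaks <- sort_intervals(peaks)
  peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  gseq <- vapply(genome, paste, "", collapse = "")
  list(genome = Biostrings::DNAStringSet(gseq), peaks = peaks, pwm = pwm,
       tads = truth$tads)
}

#' Simulate an alignment-block map and target-species catalog
#'
#' Builds co-linear gapless blocks covering the source genome except for
#' holes punched at REs planted as unmapped; block breakpoints avoid RE
#' bodies so every mapped RE lies inside a single block.  Target
#' coordinates accumulate random inter-block gaps.  For each planted
#' conserved RE the target catalog contains its exact mapped span; mapped
#' non-conserved REs map into target regions without any catalog entry.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @return List: `map` (alignment-block data frame), `target_res`
#'   (target catalog with `src_re_id`), and the per-RE truth flags.
#' @export
simulate_alignment_map <- function(cfg, truth = simulate_truth(cfg)) {
  sim_seed(cfg, 404L)
  res <- truth$res
  holes <- res[!res$truth_mapped, c("chrom", "start", "end")]
  if (nrow(holes) > 0) {
    holes$start <- pmax(0, holes$start - 20)
    holes$end <- holes$end + 20
  }
  blocks <- list(); tgt_rows <- list()
  for (cn in names(truth$chroms)) {
    len <- truth$chroms[[cn]]
    keep <- data.frame(chrom = cn, start = 0, end = len)
    h <- merge_intervals(holes[holes$chrom == cn, , drop = FALSE])
    if (nrow(h) > 0) {
      bounds <- c(0, as.vector(rbind(h$start, h$end)), len)
      keep <- data.frame(chrom = cn,
                         start = bounds[seq(1, length(bounds), 2)],
                         end = bounds[seq(2, length(bounds), 2)])
      keep <- keep[keep$end > keep$start, , drop = FALSE]
    }
    # split long kept stretches at ~50 kb breakpoints that avoid RE bodies
    rr <- res[res$chrom == cn, , drop = FALSE]
    pieces <- list()
    for (j in seq_len(nrow(keep))) {
      s <- keep$start[j]; e <- keep$end[j]
      cand <- if (e - s > 5e4 + 1) seq(s + 5e4, e - 1, by = 5e4)
              else numeric(0)
      if (length(cand) > 0) {
        inside_re <- vapply(cand, function(p)
          any(rr$start - 10 <= p & p <= rr$end + 10), TRUE)
        cand <- cand[!inside_re]
      }
      cuts <- c(s, cand, e)
      pieces[[j]] <- data.frame(chrom = cn, start = cuts[-length(cuts)],
                                end = cuts[-1])
    }
    pieces <- do.call(rbind, pieces)
    tpos <- 0
    tname <- sub("^chr", "tchr", cn)
    for (j in seq_len(nrow(pieces))) {
      tpos <- tpos + sample(0:5000, 1)
      blk_len <- pieces$end[j] - pieces$start[j]
      blocks[[length(blocks) + 1]] <- data.frame(
        src_chrom = cn, src_start = pieces$start[j], src_end = pieces$end[j],
        tgt_chrom = tname, tgt_start = tpos, tgt_end = tpos + blk_len,
        tgt_strand = "+", stringsAsFactors = FALSE)
      tpos <- tpos + blk_len
    }
  }
  map <- do.call(rbind, blocks)
  # target catalog: the exact mapped span of each conserved RE
  cons <- res[res$truth_conserved, , drop = FALSE]
  for (j in seq_len(nrow(cons))) {
    b <- map[map$src_chrom == cons$chrom[j] &
               map$src_start <= cons$start[j] &
               map$src_end >= cons$end[j], , drop = FALSE]
    if (nrow(b) == 0)
      stop("internal: conserved RE not contained in a single block")
    b <- b[1, ]
    ts <- b$tgt_start + (cons$start[j] - b$src_start)
    tgt_rows[[length(tgt_rows) + 1]] <- data.frame(
      chrom = b$tgt_chrom, start = ts,
      end = ts + (cons$end[j] - cons$start[j]),
      src_re_id = cons$re_id[j], stringsAsFactors = FALSE)
  }
  target_res <- if (length(tgt_rows) > 0) sort_intervals(do.call(rbind, tgt_rows))
                else data.frame(chrom = character(), start = numeric(),
                                end = numeric(), src_re_id = character())
  list(map = map, target_res = target_res,
       truth = res[, c("re_id", "truth_mapped", "truth_conserved")])
}

#' Simulate SNP tables with planted in-RE enrichment
#'
#' Each category group and the uncategorized group contain
#' `n_snps_per_group` SNPs.  Categorized SNPs fall inside REs with odds
#' `snp_re_odds` relative to the uncategorized baseline; in-RE SNPs draw
#' p-values skewed toward small values (Beta(0.4, 3)), out-of-RE SNPs
#' from Uniform(0, 1).  A small fraction of categorized SNPs carries a
#' second category label.
#'
#' @param cfg A [sim_config()].
#' @param truth Output of [simulate_truth()].
#' @param base_in_re_prob Baseline probability that an uncategorized SNP
#'   lies inside an RE.
#' @return SNP data frame (chrom, pos, pvalue, categories list-column,
#'   truth_in_re).
#' @export
simulate_snps <- function(cfg, truth = simulate_truth(cfg),
                          base_in_re_prob = 0.12) {
  sim_seed(cfg, 505L)
  res <- truth$res
  re_len <- res$end - res$start
  genome_bp <- sum(truth$chroms)
  odds0 <- base_in_re_prob / (1 - base_in_re_prob)
  p_cat <- cfg$snp_re_odds * odds0 / (1 + cfg$snp_re_odds * odds0)
  draw_group <- function(n, p_in, labels) {
    in_re <- runif(n) < p_in
    chrom <- character(n); pos <- numeric(n)
    k_in <- sum(in_re)
    if (k_in > 0) {
      ri <- sample(nrow(res), k_in, replace = TRUE, prob = re_len)
      chrom[in_re] <- res$chrom[ri]
      pos[in_re] <- res$start[ri] + floor(runif(k_in) * re_len[ri])
    }
    k_out <- n - k_in
    if (k_out > 0) {
      got <- 0; oc <- character(0); op <- numeric(0)
      while (got < k_out) {
        m <- (k_out - got) * 2 + 10
        ci <- sample(length(truth$chroms), m, replace = TRUE)
        pp <- floor(runif(m) * truth$chroms[ci])
        cand <- data.frame(chrom = names(truth$chroms)[ci], pos = pp)
        ok <- !flag_in_re(cand, res)
        oc <- c(oc, cand$chrom[ok]); op <- c(op, cand$pos[ok])
        got <- length(oc)
      }
      chrom[!in_re] <- oc[seq_len(k_out)]
      pos[!in_re] <- op[seq_len(k_out)]
    }
    pv <- numeric(n)
    pv[in_re] <- pmax(rbeta(k_in, 0.4, 3), 1e-300)
    pv[!in_re] <- pmax(runif(k_out), 1e-300)
    data.frame(chrom = chrom, pos = pos, pvalue = pv,
               primary = labels, truth_in_re = in_re,
               stringsAsFactors = FALSE)
  }
  groups <- list(draw_group(cfg$n_snps_per_group, base_in_re_prob, ""))
  for (cat in cfg$snp_categories)
    groups[[length(groups) + 1]] <-
      draw_group(cfg$n_snps_per_group, p_cat, cat)
  snps <- do.call(rbind, groups)
  cats <- lapply(snps$primary, function(x) if (nzchar(x)) x else character(0))
  if (length(cfg$snp_categories) > 1) {
    categorized <- which(snps$primary != "")
    extra <- categorized[runif(length(categorized)) < 0.05]
    for (i in extra) {
      other <- setdiff(cfg$snp_categories, snps$primary[i])
      cats[[i]] <- sort(c(cats[[i]], sample(other, 1)))
    }
  }
  snps$primary <- NULL
  snps$categories <- I(cats)
  snps
}

#' Run the full simulator
#'
#' Generates every pipeline input and the ground truth under one seed.
#'
#' @param cfg A [sim_config()].
#' @param include_sequence Also generate the genome sequence and CTCF
#'   architecture (the slowest component).
#' @return Object of class `sim_study`: list with `truth`,
#'   `segmentations`, `expression` (see
#'   [simulate_expression_and_signal()]), `ctcf` (or NULL), `alignment`,
#'   `snps`.
#' @export
simulate_study <- function(cfg, include_sequence = TRUE) {
  truth <- simulate_truth(cfg)
  structure(list(
    cfg = cfg, truth = truth,
    segmentations = simulate_segmentations(cfg, truth),
    expression = simulate_expression_and_signal(cfg, truth),
    ctcf = if (include_sequence) simulate_ctcf_architecture(cfg, truth)
           else NULL,
    alignment = simulate_alignment_map(cfg, truth),
    snps = simulate_snps(cfg, truth)), class = "sim_study")
}

#' Write a simulated study to disk
#'
#' Emits every input file the pipeline consumes plus the ground-truth
#' tables: per-tissue dense-segmentation BEDs, genes GFF3, gene/RE count
#' TSVs, genome FASTA, CTCF peak BED and MEME motif, alignment-block TSV,
#' target-species RE BED, SNP TSV, and truth TSV/BEDs.
#'
#' @param study Output of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  truth <- study$truth
  for (t in names(study$segmentations)) {
    seg <- study$segmentations[[t]]
    writeLines(paste(seg$chrom, fmt_int(seg$start), fmt_int(seg$end),
                     seg$state, sep = "\t"),
               fp(sprintf("segmentation_%s.bed", t)))
  }
  write_gff3_genes(truth$genes, fp("genes.gff3"))
  write_counts_matrix(study$expression$gene_counts, fp("gene_counts.tsv"),
                      "gene_id")
  write_counts_matrix(study$expression$re_counts, fp("re_counts.tsv"),
                      "re_id")
  if (!is.null(study$ctcf)) {
    writeXStringSet(study$ctcf$genome, fp("genome.fa"))
    write_bed(study$ctcf$peaks[, c("chrom", "start", "end", "peak_id")]
              |> setNames(c("chrom", "start", "end", "name")),
              fp("ctcf_peaks.bed"))
    write_meme(study$ctcf$pwm, fp("ctcf_motif.meme"), "CTCF_SIM")
  }
  write_alignment_map(study$alignment$map, fp("alignment_map.tsv"))
  write_bed(study$alignment$target_res[, c("chrom", "start", "end",
                                           "src_re_id")]
            |> setNames(c("chrom", "start", "end", "name")),
            fp("target_res.bed"))
  write_snps(study$snps, fp("snps.tsv"))
  # ground truth
  tr <- truth$res
  writeLines(paste(tr$chrom, fmt_int(tr$start), fmt_int(tr$end), tr$re_id,
                   vapply(tr$active_tissues, paste, "", collapse = ","),
                   tr$tad_id, as.integer(tr$truth_mapped),
                   as.integer(tr$truth_conserved), sep = "\t"),
             fp("truth_res.bed"))
  write_bed(truth$tads[, c("chrom", "start", "end", "tad_id")]
            |> setNames(c("chrom", "start", "end", "name")),
            fp("truth_tads.bed"))
  write.table(truth$links, fp("truth_links.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}
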