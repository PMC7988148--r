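# Consolidation of per-tissue chromatin-state segmentations into a
# species-level regulatory-element catalog.  States 1-6, 8, 9 and 11 of
# the 14-state vocabulary are treated as "active" by default; state 14 is
# the low-signal background and 12-13 are repressed.

#' Default set of active chromatin states
#' @export
ACTIVE_STATES <- c(1:6, 8L, 9L, 11L)

#' Merge active chromatin-state runs within each tissue
#'
#' For each tissue, consecutive or abutting segmentation records whose
#' state belongs to `active_states` are merged into maximal active runs.
#' Records within one tissue must be non-overlapping.
#'
#' @param segmentations Named list (one element per tissue) of
#'   segmentation data frames with columns chrom/start/end/state.
#' @param active_states Integer states considered active.
#' @return Named list of merged active interval data frames.
#' @export
consolidate_active <- function(segmentations, active_states = ACTIVE_STATES) {
  stopifnot(is.list(segmentations), length(names(segmentations)) > 0)
  lapply(segmentations, function(seg) {
    validate_intervals(seg, "segmentation")
    if (!all(seg$state %in% 1:14))
      stop("segmentation states must lie in 1..14")
    seg <- sort_intervals(seg)
    by_chrom <- split(seg, seg$chrom)
    for (s in by_chrom) {
      if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
        stop("overlapping segmentation records within one tissue")
    }
    merge_intervals(seg[seg$state %in% active_states, , drop = FALSE],
                    bookended = TRUE)
  })
}

#' Combine per-tissue active intervals into a regulatory-element catalog
#'
#' Union-merges active intervals across tissues (bookended merge) and
#' annotates each combined element with the set of tissues contributing at
#' least 1 bp to it.  Elements active in exactly one tissue are flagged
#' tissue-specific.
#'
#' @param active_by_tissue Named list of per-tissue interval data frames
#'   (each internally disjoint), as returned by [consolidate_active()].
#' @return RE catalog data frame: `re_id`, `chrom`, `start`, `end`,
#'   list-column `active_tissues`, logical `tissue_specific`.
#' @export
combine_tissues <- function(active_by_tissue) {
  tissues <- names(active_by_tissue)
  stopifnot(length(tissues) > 0)
  all_iv <- do.call(rbind, lapply(tissues, function(t) {
    x <- active_by_tissue[[t]]
    if (nrow(x) == 0) return(NULL)
    data.frame(chrom = x$chrom, start = x$start, end = x$end, tissue = t,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_iv) || nrow(all_iv) == 0)
    return(data.frame(re_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      tissue_specific = logical()))
  merged <- merge_intervals(all_iv, bookended = TRUE)
  hits <- overlap_join(merged, all_iv)
  sets <- rep(list(character(0)), nrow(merged))
  contrib <- split(all_iv$tissue[hits$subject], hits$query)
  for (k in names(contrib))
    sets[[as.integer(k)]] <- sort(unique(contrib[[k]]))
  out <- data.frame(re_id = sprintf("RE%05d", seq_len(nrow(merged))),
                    chrom = merged$chrom, start = merged$start,
                    end = merged$end, stringsAsFactors = FALSE)
  out$active_tissues <- I(sets)
  out$tissue_specific <- lengths(sets) == 1
  out
}

tss_points <- function(genes, coding_only = TRUE) {
  keep <- if (coding_only) genes$biotype == "protein_coding"
          else rep(TRUE, nrow(genes))
  g <- genes[keep, , drop = FALSE]
  if (nrow(g) == 0)
    return(data.frame(chrom = character(), pos = numeric(),
                      gene_id = character()))
  n <- lengths(g$tss)
  data.frame(chrom = rep(g$chrom, n), pos = unlist(g$tss),
             gene_id = rep(g$gene_id, n), stringsAsFactors = FALSE)
}

tss_windows <- function(points, window) {
  if (nrow(points) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  data.frame(chrom = points$chrom, start = pmax(0, points$pos - window),
             end = points$pos + window + 1, stringsAsFactors = FALSE)
}

#' Classify regulatory elements relative to annotated genes
#'
#' Precedence: (1) `tss_proximal` when the element comes within
#' `tss_window` bp (inclusive, measured edge-to-point) of any
#' protein-coding TSS; else (2) `excluded` when within the same distance
#' of any extra TSS (non-coding or unannotated); else (3) `genic` when
#' overlapping any protein-coding gene body by >= 1 bp; else (4)
#' `intergenic`.
#'
#' @param res RE catalog data frame.
#' @param genes Gene-model data frame (see [read_gff3_genes()]).
#' @param extra_tss Optional data frame of non-coding/unannotated TSS
#'   positions with columns chrom/pos.
#' @param tss_window Proximity window in bp (default 2000, inclusive).
#' @return Factor of classes along the rows of `res`, levels
#'   `tss_proximal`, `excluded`, `genic`, `intergenic`.
#' @export
classify_re <- function(res, genes, extra_tss = NULL, tss_window = 2000) {
  validate_intervals(res, "res")
  coding <- tss_windows(tss_points(genes, coding_only = TRUE), tss_window)
  prox <- overlap_any(res, coding)
  if (!is.null(extra_tss) && nrow(extra_tss) > 0) {
    ex_win <- tss_windows(data.frame(chrom = extra_tss$chrom,
                                     pos = extra_tss$pos), tss_window)
    excl <- overlap_any(res, ex_win)
  } else excl <- rep(FALSE, nrow(res))
  bodies <- genes[genes$biotype == "protein_coding", c("chrom", "start", "end")]
  genic <- overlap_any(res, bodies)
  cls <- ifelse(prox, "tss_proximal",
                ifelse(excl, "excluded",
                       ifelse(genic, "genic", "intergenic")))
  factor(cls, levels = c("tss_proximal", "excluded", "genic", "intergenic"))
}

#' Open-chromatin support of regulatory elements
#'
#' An element is supported when it overlaps (>= 1 bp) an accessibility
#' peak in at least one tissue of its own active set.
#'
#' @param res RE catalog data frame with `active_tissues` list-column.
#' @param peaks_by_tissue Named list of per-tissue peak interval data
#'   frames.
#' @return List with logical vector `supported` and scalar `fraction`.
#' @export
open_chromatin_support <- function(res, peaks_by_tissue) {
  validate_intervals(res, "res")
  supported <- rep(FALSE, nrow(res))
  for (t in names(peaks_by_tissue)) {
    pk <- peaks_by_tissue[[t]]
    if (nrow(pk) == 0) next
    active_here <- vapply(res$active_tissues, function(s) t %in% s, TRUE)
    if (!any(active_here)) next
    supported <- supported | (active_here & overlap_any(res, pk))
  }
  list(supported = supported, fraction = mean(supported))
}

#' Fold enrichment of chromatin states at a feature set
#'
#' For each state s, computes (bp of s overlapping the features / total bp
#' of s) divided by (feature bp / genome size).  States occupying zero bp
#' get `NA`.
#'
#' @param segmentation Segmentation data frame with a `state` column.
#' @param features Feature interval data frame.
#' @param genome_size Total genome size in bp.
#' @return Data frame with `state`, `state_bp`, `overlap_bp`,
#'   `enrichment` for states 1-14.
#' @export
state_feature_enrichment <- function(segmentation, features, genome_size) {
  validate_intervals(segmentation, "segmentation")
  fm <- merge_intervals(features)
  feat_bp <- sum(fm$end - fm$start)
  out <- data.frame(state = 1:14, state_bp = 0, overlap_bp = 0,
                    enrichment = NA_real_)
  for (s in 1:14) {
    sub <- segmentation[segmentation$state == s, , drop = FALSE]
    if (nrow(sub) == 0) next
    out$state_bp[s] <- sum(sub$end - sub$start)
    hits <- overlap_join(sub, fm)
    out$overlap_bp[s] <- sum(hits$bp)
    out$enrichment[s] <- (out$overlap_bp[s] / out$state_bp[s]) /
      (feat_bp / genome_size)
  }
  out
}
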