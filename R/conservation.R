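# Cross-species conservation of regulatory elements: coordinate mapping
# over gapless alignment blocks, conservation calls by >= 1 bp overlap
# with the target-species catalog, and lineage-set intersections.

#' Map one interval through an alignment-block map
#'
#' Collects the target positions of every aligned base of the interval.
#' If none are aligned the interval is unmapped.  Otherwise positions are
#' restricted to the target chromosome receiving the most aligned bases
#' (ties: lexicographically smallest name) and the span
#' `[min, max + 1)` of those positions is returned.  Positions inside
#' minus-strand blocks are mirrored within the block.
#'
#' @param iv Single-row interval data frame (or list with chrom, start,
#'   end).
#' @param map Alignment-block data frame (see [read_alignment_map()]).
#' @param min_mapped_frac Minimum fraction of the interval's bases that
#'   must be aligned for it to count as mapped (default 0: >= 1 base).
#' @return `NULL` when unmapped, else a list with `chrom`, `start`, `end`,
#'   `aligned_bases`.
#' @export
map_interval <- function(iv, map, min_mapped_frac = 0) {
  hit <- map$src_chrom == iv$chrom & map$src_start < iv$end &
    map$src_end > iv$start
  if (!any(hit)) return(NULL)
  b <- map[hit, , drop = FALSE]
  os <- pmax(iv$start, b$src_start); oe <- pmin(iv$end, b$src_end)
  plus <- b$tgt_strand == "+"
  ts <- ifelse(plus, b$tgt_start + (os - b$src_start),
               b$tgt_end - (oe - b$src_start))
  te <- ifelse(plus, b$tgt_start + (oe - b$src_start),
               b$tgt_end - (os - b$src_start))
  seg <- data.frame(chrom = b$tgt_chrom, start = ts, end = te,
                    bases = oe - os, stringsAsFactors = FALSE)
  aligned <- sum(seg$bases)
  if (aligned < min_mapped_frac * (iv$end - iv$start) || aligned == 0)
    return(NULL)
  per_chrom <- tapply(seg$bases, seg$chrom, sum)
  best <- names(per_chrom)[per_chrom == max(per_chrom)]
  chosen <- sort(best)[1]
  seg <- seg[seg$chrom == chosen, , drop = FALSE]
  list(chrom = chosen, start = min(seg$start), end = max(seg$end),
       aligned_bases = aligned)
}

#' Map an RE catalog through an alignment-block map
#'
#' @param res RE catalog data frame (needs `re_id`).
#' @param map Alignment-block data frame.
#' @param min_mapped_frac Passed to [map_interval()].
#' @return Data frame: `re_id`, `mapped`, `tgt_chrom`, `tgt_start`,
#'   `tgt_end`, `aligned_bases` (NA where unmapped).
#' @export
map_intervals <- function(res, map, min_mapped_frac = 0) {
  validate_intervals(res, "res")
  validate_alignment_map(map)
  out <- data.frame(re_id = res$re_id, mapped = FALSE,
                    tgt_chrom = NA_character_, tgt_start = NA_real_,
                    tgt_end = NA_real_, aligned_bases = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(res))) {
    m <- map_interval(res[i, ], map, min_mapped_frac)
    if (is.null(m)) next
    out$mapped[i] <- TRUE
    out$tgt_chrom[i] <- m$chrom
    out$tgt_start[i] <- m$start
    out$tgt_end[i] <- m$end
    out$aligned_bases[i] <- m$aligned_bases
  }
  out
}

#' Call conservation of mapped REs against a target catalog
#'
#' A mapped element is conserved when its mapped span overlaps any
#' target-species RE by at least 1 bp.
#'
#' @param mapping Result of [map_intervals()].
#' @param target_res Target-species RE interval data frame.
#' @return List: `results` (per-RE data frame with `conserved` flag),
#'   `mapping_rate` (mapped / total) and `conservation_rate`
#'   (conserved / mapped).
#' @export
call_conservation <- function(mapping, target_res) {
  validate_intervals(target_res, "target_res")
  res <- mapping
  res$conserved <- FALSE
  mp <- which(res$mapped)
  if (length(mp) > 0 && nrow(target_res) > 0) {
    spans <- data.frame(chrom = res$tgt_chrom[mp], start = res$tgt_start[mp],
                        end = res$tgt_end[mp], stringsAsFactors = FALSE)
    res$conserved[mp] <- overlap_any(spans, target_res)
  }
  list(results = res,
       mapping_rate = mean(res$mapped),
       conservation_rate = if (sum(res$mapped) == 0) NA_real_
                           else sum(res$conserved) / sum(res$mapped))
}

#' REs conserved across every species of a lineage set
#'
#' @param results_by_target Named list of [call_conservation()] `results`
#'   data frames, one per target species, sharing a source catalog.
#' @param species_set Target species whose conservation flags must all be
#'   set.
#' @return Character vector of source RE ids conserved in every listed
#'   species.
#' @export
lineage_conserved <- function(results_by_target, species_set) {
  stopifnot(all(species_set %in% names(results_by_target)))
  sets <- lapply(species_set, function(sp) {
    r <- results_by_target[[sp]]
    r$re_id[r$conserved]
  })
  Reduce(intersect, sets)
}
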