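# Readers and writers for the plain-text formats the pipeline touches.
# All readers validate coordinates and report the offending line number;
# every reader/writer pair round-trips canonical records exactly.

fmt_int <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a BED3/BED6 file
#'
#' Tab-separated; 0-based half-open coordinates are kept as-is.  Lines
#' beginning with `#`, `track` or `browser` are skipped.  Malformed lines
#' (fewer than 3 fields, non-numeric or negative coordinates,
#' `start >= end`) raise an error naming the line.
#'
#' @param path File path.
#' @return Interval data frame; with >= 6 fields also `name`, `score`,
#'   `strand` columns.
#' @export
read_bed <- function(path) {
  ln <- readLines(path)
  keep <- nzchar(ln) & !grepl("^(#|track\\b|browser\\b)", ln)
  idx <- which(keep)
  fields <- strsplit(ln[idx], "\t", fixed = TRUE)
  out <- vector("list", length(idx))
  n_col <- if (length(idx)) min(vapply(fields, length, 1L)) else 3L
  for (i in seq_along(idx)) {
    f <- fields[[i]]
    if (length(f) < 3)
      stop(sprintf("%s line %d: expected >= 3 tab-separated fields", path,
                   idx[i]))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || s >= e)
      stop(sprintf("%s line %d: invalid coordinates '%s'-'%s'", path,
                   idx[i], f[2], f[3]))
    out[[i]] <- f
  }
  if (length(idx) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  df <- data.frame(
    chrom = vapply(out, `[`, "", 1),
    start = as.numeric(vapply(out, `[`, "", 2)),
    end = as.numeric(vapply(out, `[`, "", 3)),
    stringsAsFactors = FALSE)
  if (n_col >= 6) {
    df$name <- vapply(out, `[`, "", 4)
    df$score <- suppressWarnings(as.numeric(vapply(out, `[`, "", 5)))
    df$strand <- vapply(out, `[`, "", 6)
  } else if (n_col >= 4) {
    df$name <- vapply(out, `[`, "", 4)
  }
  df
}

#' Write intervals as BED
#'
#' Writes BED3, or BED6 when `name`, `score` and `strand` columns are all
#' present (a lone `name` column gives BED4).
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- list(x$chrom, fmt_int(x$start), fmt_int(x$end))
  if (all(c("name", "score", "strand") %in% names(x))) {
    cols <- c(cols, list(x$name, fmt_int(x$score), x$strand))
  } else if ("name" %in% names(x)) {
    cols <- c(cols, list(x$name))
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]*)"), attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `mRNA`/`transcript` features.  GFF3 1-based inclusive
#' coordinates are converted to 0-based half-open; the TSS of a `+`-strand
#' transcript is its start, of a `-`-strand transcript its last base.
#' Genes without any transcript feature contribute their own body as a
#' single transcript.  A transcript whose `Parent` is not a parsed gene is
#' an error, as are invalid coordinates (reported with line numbers).
#'
#' @param path File path.
#' @return Gene-model data frame: `gene_id`, `biotype`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, and list-column `tss` of sorted
#'   0-based TSS positions.
#' @export
read_gff3_genes <- function(path) {
  ln <- readLines(path)
  idx <- which(nzchar(ln) & !startsWith(ln, "#"))
  fields <- strsplit(ln[idx], "\t", fixed = TRUE)
  rec <- list()
  for (i in seq_along(idx)) {
    f <- fields[[i]]
    if (length(f) != 9)
      stop(sprintf("%s line %d: expected 9 tab-separated fields", path, idx[i]))
    type <- f[3]
    if (!type %in% c("gene", "mRNA", "transcript")) next
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || s < 1 || e < s)
      stop(sprintf("%s line %d: invalid 1-based coordinates '%s'-'%s'",
                   path, idx[i], f[4], f[5]))
    if (!f[7] %in% c("+", "-"))
      stop(sprintf("%s line %d: strand must be + or -", path, idx[i]))
    rec[[length(rec) + 1]] <- list(type = type, chrom = f[1], start = s,
                                   end = e, strand = f[7], attrs = f[9],
                                   line = idx[i])
  }
  is_gene <- vapply(rec, function(r) r$type == "gene", TRUE)
  g <- rec[is_gene]; tx <- rec[!is_gene]
  gene_id <- vapply(g, function(r) gff_attr(r$attrs, "ID"), "")
  if (anyNA(gene_id)) stop(path, ": gene feature without ID attribute")
  biotype <- vapply(g, function(r) {
    b <- gff_attr(r$attrs, "biotype")
    if (is.na(b)) b <- gff_attr(r$attrs, "gene_biotype")
    if (is.na(b)) "protein_coding" else b
  }, "")
  genes <- data.frame(
    gene_id = gene_id, biotype = biotype,
    chrom = vapply(g, `[[`, "", "chrom"),
    start = vapply(g, function(r) r$start - 1, 0),
    end = vapply(g, function(r) r$end, 0),
    strand = vapply(g, `[[`, "", "strand"),
    stringsAsFactors = FALSE)
  tss <- rep(list(numeric(0)), nrow(genes))
  for (r in tx) {
    parent <- gff_attr(r$attrs, "Parent")
    j <- match(parent, gene_id)
    if (is.na(j))
      stop(sprintf("%s line %d: transcript with unknown Parent '%s'",
                   path, r$line, parent))
    pos <- if (r$strand == "+") r$start - 1 else r$end - 1
    tss[[j]] <- c(tss[[j]], pos)
  }
  for (j in seq_len(nrow(genes))) {
    if (length(tss[[j]]) == 0)
      tss[[j]] <- if (genes$strand[j] == "+") genes$start[j] else genes$end[j] - 1
    tss[[j]] <- sort(tss[[j]])
    if (any(tss[[j]] < genes$start[j] | tss[[j]] >= genes$end[j]))
      stop(path, ": TSS outside gene body for ", genes$gene_id[j])
  }
  genes$tss <- I(tss)
  genes
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gff3_genes()]: one `gene` feature per row plus one
#' `transcript` feature per TSS (transcript span runs from the TSS to the
#' far end of the gene body).
#'
#' @param genes Gene-model data frame (see [read_gff3_genes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3_genes <- function(genes, path) {
  out <- "##gff-version 3"
  for (j in seq_len(nrow(genes))) {
    g <- genes[j, ]
    out <- c(out, paste(g$chrom, "recatalog", "gene", fmt_int(g$start + 1),
                        fmt_int(g$end), ".", g$strand, ".",
                        sprintf("ID=%s;biotype=%s", g$gene_id, g$biotype),
                        sep = "\t"))
    tss <- genes$tss[[j]]
    for (k in seq_along(tss)) {
      if (g$strand == "+") { s <- tss[k] + 1; e <- g$end }
      else { s <- g$start + 1; e <- tss[k] + 1 }
      out <- c(out, paste(g$chrom, "recatalog", "transcript", fmt_int(s),
                          fmt_int(e), ".", g$strand, ".",
                          sprintf("ID=%s.t%d;Parent=%s", g$gene_id, k,
                                  g$gene_id),
                          sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a position-weight matrix in MEME minimal motif format
#'
#' Reads the first motif of the file.  Rows of the letter-probability
#' matrix must each sum to 1 within 1e-9.
#'
#' @param path File path.
#' @return Numeric matrix, one row per motif position, columns `A`, `C`,
#'   `G`, `T`.
#' @export
read_meme <- function(path) {
  ln <- readLines(path)
  i <- grep("^letter-probability matrix", ln)
  if (length(i) == 0) stop(path, ": no letter-probability matrix found")
  i <- i[1]
  w <- as.integer(sub(".*\\bw=\\s*([0-9]+).*", "\\1", ln[i]))
  rows <- ln[(i + 1):(i + w)]
  pwm <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
  colnames(pwm) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(pwm) - 1) > 1e-9) || any(pwm < 0))
    stop(path, ": PWM rows must be non-negative and sum to 1")
  pwm
}

#' Write a position-weight matrix in MEME minimal motif format
#'
#' @param pwm Matrix of per-position base probabilities (columns A,C,G,T).
#' @param path Output path.
#' @param name Motif name.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, path, name = "MOTIF_1") {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
           "Background letter frequencies",
           "A 0.25000 C 0.25000 G 0.25000 T 0.25000", "",
           paste("MOTIF", name),
           sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                   nrow(pwm)),
           apply(pwm, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")))
  writeLines(out, path)
  invisible(path)
}

#' Read a feature-by-sample count matrix from TSV
#'
#' First column holds feature identifiers, header row holds sample
#' identifiers.  Values must be non-negative and finite; duplicated row or
#' column identifiers are an error.
#'
#' @param path File path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_counts_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(ids)) stop(path, ": duplicate feature identifiers")
  if (anyDuplicated(colnames(m))) stop(path, ": duplicate sample identifiers")
  if (any(!is.finite(m)) || any(m < 0))
    stop(path, ": values must be non-negative and finite")
  m
}

#' Write a feature-by-sample matrix as TSV
#'
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param id_col Name of the identifier column.
#' @return `path`, invisibly.
#' @export
write_counts_matrix <- function(m, path, id_col = "feature_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an alignment-block map
#'
#' TSV with columns `src_chrom`, `src_start`, `src_end`, `tgt_chrom`,
#' `tgt_start`, `tgt_end`, `tgt_strand`.  Blocks are gapless: source and
#' target spans must have identical lengths, and source blocks must be
#' pairwise disjoint.
#'
#' @param path File path.
#' @return Alignment-block data frame.
#' @export
read_alignment_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("src_chrom", "src_start", "src_end", "tgt_chrom", "tgt_start",
            "tgt_end", "tgt_strand")
  if (!all(need %in% names(df)))
    stop(path, ": missing alignment-map columns")
  validate_alignment_map(df)
  df
}

#' Validate an alignment-block map
#'
#' @param map Alignment-block data frame.
#' @return `map`, invisibly; errors on gapful blocks or overlapping source
#'   spans.
#' @export
validate_alignment_map <- function(map) {
  src <- data.frame(chrom = map$src_chrom, start = map$src_start,
                    end = map$src_end)
  tgt <- data.frame(chrom = map$tgt_chrom, start = map$tgt_start,
                    end = map$tgt_end)
  validate_intervals(src, "alignment map (source)")
  validate_intervals(tgt, "alignment map (target)")
  if (any((src$end - src$start) != (tgt$end - tgt$start)))
    stop("alignment map: blocks must be gapless (equal src/tgt lengths)")
  if (!all(map$tgt_strand %in% c("+", "-")))
    stop("alignment map: tgt_strand must be + or -")
  if (covered_bp(src) != sum(src$end - src$start))
    stop("alignment map: source blocks must be pairwise disjoint")
  invisible(map)
}

#' Write an alignment-block map as TSV
#'
#' @param map Alignment-block data frame (see [read_alignment_map()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_map <- function(map, path) {
  write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP table
#'
#' TSV with columns `chrom`, `pos` (0-based), `pvalue`, `categories`
#' (semicolon-joined labels; empty string = uncategorized).
#'
#' @param path File path.
#' @return SNP data frame with `categories` as a list-column of character
#'   vectors.
#' @export
read_snps <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(categories = "character"))
  if (any(df$pos < 0)) {
    bad <- which(df$pos < 0)[1]
    stop(sprintf("%s line %d: negative position", path, bad + 1))
  }
  if (any(df$pvalue <= 0 | df$pvalue > 1))
    stop(path, ": p-values must lie in (0, 1]")
  df$categories <- I(lapply(strsplit(df$categories, ";", fixed = TRUE),
                            function(x) x[nzchar(x)]))
  df
}

#' Write a SNP table as TSV
#'
#' @param snps SNP data frame (see [read_snps()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snps <- function(snps, path) {
  out <- data.frame(chrom = snps$chrom, pos = snps$pos,
                    pvalue = snps$pvalue,
                    categories = vapply(snps$categories, paste, "",
                                        collapse = ";"),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an RE catalog as BED6+2
#'
#' Columns: chrom, start, end, RE id, score 0, strand `.`, class,
#' comma-joined active tissues.
#'
#' @param catalog RE catalog data frame (see [combine_tissues()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  cls <- if ("re_class" %in% names(catalog)) as.character(catalog$re_class)
         else rep(".", nrow(catalog))
  lines <- paste(catalog$chrom, fmt_int(catalog$start),
                 fmt_int(catalog$end), catalog$re_id, 0, ".", cls,
                 vapply(catalog$active_tissues, paste, "", collapse = ","),
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read an RE catalog written by [write_catalog()]
#'
#' @param path File path.
#' @return RE catalog data frame.
#' @export
read_catalog <- function(path) {
  f <- strsplit(readLines(path), "\t", fixed = TRUE)
  df <- data.frame(
    chrom = vapply(f, `[`, "", 1),
    start = as.numeric(vapply(f, `[`, "", 2)),
    end = as.numeric(vapply(f, `[`, "", 3)),
    re_id = vapply(f, `[`, "", 4),
    re_class = vapply(f, `[`, "", 7),
    stringsAsFactors = FALSE)
  validate_intervals(df, path)
  df$active_tissues <- I(strsplit(vapply(f, `[`, "", 8), ",", fixed = TRUE))
  df$tissue_specific <- lengths(df$active_tissues) == 1
  df
}
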