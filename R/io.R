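# Readers and writers for the plain-text formats the pipeline consumes:
# BED3/BED5 for elements and region sets, BEDPE for contacts and
# translocation partners, headered TSV for variants, expression, LD pairs and
# methylation.  All readers accept gzip transparently (base connections).
# Coordinates are 0-based half-open on disk and in memory; a `one_based`
# flag converts 1-based inclusive inputs at the boundary.

norm_chrom <- function(chrom, add_chr_prefix = TRUE) {
  chrom <- as.character(chrom)
  if (add_chr_prefix) {
    no_pref <- !startsWith(chrom, "chr")
    chrom[no_pref] <- paste0("chr", chrom[no_pref])
  }
  chrom
}

#' Read a BED file of intervals or regulatory elements
#'
#' Parses BED3 (intervals) or BED5 (named, scored elements).  With
#' `with_score = TRUE`, column 4 becomes the element `id` and column 5 the
#' per-element signal stored under `mark`.
#'
#' @param path file path (may be gzipped).
#' @param with_score if TRUE expect >= 5 columns and attach the score column
#'   as signal.
#' @param mark name under which the score column is stored (e.g.
#'   `"H3K27me3"`).
#' @param one_based set TRUE for 1-based inclusive input coordinates; they
#'   are converted to 0-based half-open.
#' @param add_chr_prefix prepend `"chr"` to chromosome names lacking it.
#' @return data.frame with columns `chrom`, `start`, `end` and, for scored
#'   input, `id` and the mark column.
#' @export
read_bed <- function(path, with_score = FALSE, mark = "score",
                     one_based = FALSE, add_chr_prefix = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE, quote = ""),
    error = function(e) stop("malformed BED file ", path, ": ",
                             conditionMessage(e))
  )
  if (ncol(x) < 3) stop("BED file ", path, " has fewer than 3 columns")
  out <- data.frame(chrom = norm_chrom(x[[1]], add_chr_prefix),
                    start = x[[2]], end = x[[3]],
                    stringsAsFactors = FALSE)
  if (!is.numeric(out$start) || !is.numeric(out$end)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x[[2]]))) |
                 is.na(suppressWarnings(as.numeric(x[[3]]))))
    stop("BED file ", path, ": non-integer coordinates at line ",
         if (length(bad)) bad[1] else "?")
  }
  if (one_based) out$start <- out$start - 1L
  bad <- which(!(out$start >= 0 & out$start < out$end))
  if (length(bad))
    stop("BED file ", path, ": start >= end at line ", bad[1])
  if (with_score) {
    if (ncol(x) < 5)
      stop("BED file ", path, ": with_score requires >= 5 columns")
    out$id <- as.character(x[[4]])
    out[[mark]] <- as.numeric(x[[5]])
    if (any(is.na(out[[mark]])) || any(out[[mark]] < 0))
      stop("BED file ", path, ": signal column must be non-negative numeric")
    out <- out[, c("id", "chrom", "start", "end", mark)]
  } else if (ncol(x) >= 4) {
    out$name <- as.character(x[[4]])
  }
  out
}

#' Write intervals or elements as BED
#'
#' @param x interval data.frame; if `name_col`/`score_col` are given a BED5
#'   line is written, else BED3 (plus `name_col` alone for BED4).
#' @param path output path.
#' @param name_col,score_col optional column names for BED columns 4 and 5.
#' @export
write_bed <- function(x, path, name_col = NULL, score_col = NULL) {
  cols <- data.frame(chrom = x$chrom, start = format(x$start, scientific = FALSE, trim = TRUE),
                     end = format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(name_col)) cols$name <- x[[name_col]]
  if (!is.null(score_col)) {
    if (is.null(name_col)) cols$name <- "."
    cols$score <- x[[score_col]]
  }
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read chromatin contacts from BEDPE
#'
#' Expects six coordinate columns (anchor1, anchor2); an optional seventh
#' column is kept as `name`.  Anchors must be intra-chromosomal.
#'
#' @param path BEDPE path.
#' @param add_chr_prefix prepend `"chr"` where missing.
#' @return data.frame with `chrom`, `start1`, `end1`, `start2`, `end2`.
#' @export
read_bedpe <- function(path, add_chr_prefix = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE, quote = "")
  if (ncol(x) < 6) stop("BEDPE file ", path, " has fewer than 6 columns")
  out <- data.frame(chrom = norm_chrom(x[[1]], add_chr_prefix),
                    start1 = x[[2]], end1 = x[[3]],
                    chrom2 = norm_chrom(x[[4]], add_chr_prefix),
                    start2 = x[[5]], end2 = x[[6]],
                    stringsAsFactors = FALSE)
  bad <- which(out$chrom != out$chrom2)
  if (length(bad))
    stop("BEDPE file ", path, ": inter-chromosomal contact at line ", bad[1],
         " (contacts must be intra-chromosomal)")
  out$chrom2 <- NULL
  out
}

#' @rdname read_bedpe
#' @param x contact data.frame as returned by [read_bedpe()].
#' @export
write_bedpe <- function(x, path) {
  cols <- data.frame(x$chrom, x$start1, x$end1, x$chrom, x$start2, x$end2)
  write.table(cols, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a variant table
#'
#' Headered TSV with columns `chrom`, `pos` (0-based), `vtype` (SNV, SNP or
#' TLBP), `categories`, `samples`, `studies` (comma-separated sets; may be
#' empty) and, for TLBP records, optional partner coordinates
#' `chrom2`/`pos2`.
#'
#' @param path TSV path.
#' @param add_chr_prefix prepend `"chr"` where missing.
#' @return data.frame, one row per variant record.
#' @export
read_variants <- function(path, add_chr_prefix = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  quote = "", na.strings = "NA")
  need <- c("chrom", "pos", "vtype")
  if (!all(need %in% names(x)))
    stop("variant table ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  x$chrom <- norm_chrom(x$chrom, add_chr_prefix)
  if (!all(x$vtype %in% c("SNV", "SNP", "TLBP")))
    stop("variant table ", path, ": vtype must be SNV, SNP or TLBP")
  for (col in c("categories", "samples", "studies"))
    if (is.null(x[[col]])) x[[col]] <- "" else x[[col]][is.na(x[[col]])] <- ""
  if (is.null(x$id)) x$id <- paste0("v", seq_len(nrow(x)))
  x
}

#' @rdname read_variants
#' @param x variant data.frame.
#' @export
write_variants <- function(x, path) {
  cols <- c("id", "chrom", "pos", "vtype", "categories", "samples", "studies")
  cols <- c(cols, intersect(c("chrom2", "pos2"), names(x)))
  write.table(x[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Split a comma-separated set column into a list of character vectors.
split_set_col <- function(v) {
  out <- strsplit(as.character(v), ",", fixed = TRUE)
  lapply(out, function(s) s[nzchar(s)])
}

#' Read an LD pair table
#'
#' Headered TSV with columns `snp_a`, `snp_b`, `r2`.
#'
#' @param path TSV path.
#' @return data.frame with those three columns.
#' @export
read_ld_pairs <- function(path) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("snp_a", "snp_b", "r2")
  if (!all(need %in% names(x)))
    stop("LD table ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  x
}

#' Read a gene model / expression table
#'
#' Headered TSV with columns `gene_id`, `chrom`, `tss` (0-based position),
#' `strand`, followed by one numeric expression column per cell type.
#'
#' @param path TSV path.
#' @param add_chr_prefix prepend `"chr"` where missing.
#' @return data.frame; expression cell types are every column after `strand`.
#' @export
read_genes <- function(path, add_chr_prefix = TRUE) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(x)))
    stop("gene table ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  x$chrom <- norm_chrom(x$chrom, add_chr_prefix)
  x
}

#' Read a CpG methylation table
#'
#' Headered TSV with columns `chrom`, `pos` (0-based site position) and
#' `beta` in \[0, 1\]; out-of-range betas are rejected at load.
#'
#' @param path TSV path.
#' @param add_chr_prefix prepend `"chr"` where missing.
#' @return data.frame of per-site beta values.
#' @export
read_methylation <- function(path, add_chr_prefix = TRUE) {
  x <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "beta")
  if (!all(need %in% names(x)))
    stop("methylation table ", path, " lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  if (any(x$beta < 0 | x$beta > 1))
    stop("methylation table ", path, ": beta values must be in [0, 1]")
  x$chrom <- norm_chrom(x$chrom, add_chr_prefix)
  x
}

#' Load a TAD set
#'
#' Validates that TADs do not overlap within a chromosome (violations are
#' rejected) and derives the sorted boundary positions (both endpoints of
#' each TAD; adjacent TADs sharing an endpoint contribute one boundary).
#'
#' @param tads interval data.frame of TADs, or a BED path.
#' @return object of class `tad_set`: list with `tads` and per-chromosome
#'   sorted `boundaries`.
#' @export
load_tads <- function(tads) {
  if (is.character(tads)) tads <- read_bed(tads)
  validate_intervals(tads, "TADs")
  tads <- tads[order(tads$chrom, tads$start), , drop = FALSE]
  for (chr in unique(tads$chrom)) {
    t <- tads[tads$chrom == chr, ]
    if (nrow(t) > 1 && any(t$start[-1] < t$end[-nrow(t)]))
      stop("TADs overlap on ", chr, "; overlapping TADs are rejected")
  }
  boundaries <- lapply(split(tads, tads$chrom),
                       function(t) sort(unique(c(t$start, t$end))))
  structure(list(tads = tads, boundaries = boundaries), class = "tad_set")
}
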