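# Genomic-interval algebra.  Intervals are data.frames with columns
# chrom/start/end, 0-based half-open throughout the package (BED native).
# Overlap joins and merging are delegated to IRanges/GenomicRanges; the
# helpers here adapt the data.frame representation.

#' Validate an interval data frame
#'
#' Checks the package-wide interval invariants: `chrom` non-empty,
#' integer-like coordinates, `0 <= start < end`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param what label used in error messages.
#' @return `x`, invisibly, with coordinates coerced to numeric.
#' @export
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)))
    stop(what, " must be a data.frame with columns chrom, start, end")
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom))))
    stop(what, ": chrom must be non-empty")
  if (any(is.na(x$start)) || any(is.na(x$end)))
    stop(what, ": coordinates must not be NA")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  if (length(bad))
    stop(what, ": invalid interval (need 0 <= start < end) at row ",
         bad[1], ": ", x$chrom[bad[1]], ":", x$start[bad[1]], "-",
         x$end[bad[1]])
  invisible(x)
}

# data.frame -> GRanges (internal; shifts to 1-based closed as GRanges wants)
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

# GRanges -> data.frame in package convention
gr_to_df <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

interval_width <- function(x) x$end - x$start

interval_midpoint <- function(x) (x$start + x$end) / 2

#' Base-pair overlap between two intervals
#'
#' Vectorised; arguments are recycled to a common length.  Returns
#' `max(0, min(end) - max(start))` when the chromosomes match, else 0.
#'
#' @param a,b interval data.frames (columns `chrom`, `start`, `end`).
#' @return integer vector of overlap widths in bp.
#' @export
overlap_bp <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(0, pmin(a$end[idx_a], b$end[idx_b]) -
                pmax(a$start[idx_a], b$start[idx_b]))
  ov[as.character(a$chrom[idx_a]) != as.character(b$chrom[idx_b])] <- 0
  as.integer(ov)
}

# For each interval in `query`, the maximum single-interval overlap (bp) with
# any interval in `subject`.  0 when nothing overlaps.
max_overlap_bp <- function(query, subject) {
  if (nrow(query) == 0) return(integer(0))
  if (is.null(subject) || nrow(subject) == 0) return(rep(0L, nrow(query)))
  # suppressed: GenomeInfoDb warns when the two sides share no seqlevels,
  # but disjoint chromosomes are a documented zero-overlap case here
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_gr(query), as_gr(subject)))
  out <- rep(0L, nrow(query))
  if (length(hits)) {
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    w <- pmin(query$end[qi], subject$end[si]) -
      pmax(query$start[qi], subject$start[si])
    agg <- tapply(w, qi, max)
    out[as.integer(names(agg))] <- as.integer(agg)
  }
  out
}

#' Fraction of elements overlapping a second interval set
#'
#' The fraction of `set_a` members whose maximum single-interval overlap with
#' `set_b` is at least `min_bp`.
#'
#' @param set_a interval data.frame (the elements being classified).
#' @param set_b interval data.frame (the reference set).
#' @param min_bp minimum overlap in bp (>= 1).
#' @return real in \[0, 1\].
#' @export
fraction_overlapping <- function(set_a, set_b, min_bp = 1L) {
  if (min_bp < 1) stop("min_bp must be >= 1")
  if (nrow(set_a) == 0) stop("fraction_overlapping is undefined for empty set_a")
  if (is.null(set_b) || nrow(set_b) == 0) return(0)
  mean(max_overlap_bp(set_a, set_b) >= min_bp)
}

#' Merge overlapping or bookended intervals
#'
#' Collapses an interval set to its union (per chromosome), so that counts and
#' lengths over the set never double-count shared bases.
#'
#' @param x interval data.frame.
#' @return merged interval data.frame, sorted by chrom then start.
#' @export
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(x[, c("chrom", "start", "end")])
  gr_to_df(GenomicRanges::reduce(as_gr(x)))
}

# Total merged length in bp of an interval set.
merged_length_bp <- function(x) {
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# Positions (data.frame chrom/pos, 0-based) falling inside an interval set.
# Returns a logical vector along positions.
positions_in_intervals <- function(pos, intervals) {
  if (nrow(pos) == 0) return(logical(0))
  if (is.null(intervals) || nrow(intervals) == 0)
    return(rep(FALSE, nrow(pos)))
  pgr <- GenomicRanges::GRanges(as.character(pos$chrom),
                                IRanges::IRanges(pos$pos + 1L, pos$pos + 1L))
  suppressWarnings(IRanges::overlapsAny(pgr, as_gr(intervals)))
}
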