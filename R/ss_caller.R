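# Super-silencer / super-enhancer calling: stitch elements, rank stitched
# regions by aggregate mark signal, and cut the unit-square-scaled rank curve
# at its geometric elbow (the rank farthest below the diagonal), the discrete
# analogue of the classical slope-1 tangent rule used for super-enhancer
# detection.

#' Stitch elements on one chromosome into candidate regions
#'
#' Elements whose end-to-start distance is at most `gap_bp` are merged
#' transitively; each region spans the leftmost start to the rightmost end of
#' its constituents.  Every element belongs to exactly one region.
#'
#' @param elements element data.frame (columns `id`, `chrom`, `start`,
#'   `end`), all on a single chromosome.
#' @param gap_bp maximum stitching gap in bp (>= 0); the classical
#'   convention is 12,500 bp.
#' @return data.frame with one row per region: `chrom`, `start`, `end`,
#'   `n_constituents`, and a list-column `constituent_ids` ordered by
#'   position.
#' @export
stitch <- function(elements, gap_bp = 12500L) {
  if (gap_bp < 0) stop("gap_bp must be >= 0")
  if (length(unique(elements$chrom)) > 1)
    stop("stitch() takes elements from a single chromosome; got: ",
         paste(unique(elements$chrom), collapse = ", "))
  o <- order(elements$start, elements$end)
  el <- elements[o, , drop = FALSE]
  n <- nrow(el)
  # transitive merge: new region when the gap to the running end exceeds gap_bp
  grp <- integer(n)
  grp[1] <- 1L
  run_end <- el$end[1]
  for (i in seq_len(n)[-1]) {
    if (el$start[i] - run_end > gap_bp) {
      grp[i] <- grp[i - 1] + 1L
      run_end <- el$end[i]
    } else {
      grp[i] <- grp[i - 1]
      run_end <- max(run_end, el$end[i])
    }
  }
  regs <- data.frame(
    chrom = el$chrom[!duplicated(grp)],
    start = tapply(el$start, grp, min)[as.character(unique(grp))],
    end = tapply(el$end, grp, max)[as.character(unique(grp))],
    n_constituents = as.integer(table(grp)[as.character(unique(grp))]),
    stringsAsFactors = FALSE
  )
  regs$constituent_ids <- unname(split(el$id, grp))
  rownames(regs) <- NULL
  regs
}

# Stitch across chromosomes (internal wrapper).
stitch_all <- function(elements, gap_bp = 12500L) {
  parts <- lapply(split(elements, elements$chrom), stitch, gap_bp = gap_bp)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Aggregate a mark signal over a region's constituents
#'
#' Default aggregation is the sum of constituent signals; when a
#' `background` column is present on the elements it is subtracted
#' per-element and floored at 0 before summing.
#'
#' @param region one row of a stitched region data.frame (with
#'   `constituent_ids`).
#' @param elements element data.frame carrying the mark column.
#' @param mark signal column name (e.g. `"H3K27me3"`).
#' @param background optional name of a per-element background column to
#'   subtract.
#' @return total signal (non-negative real).
#' @export
aggregate_signal <- function(region, elements, mark, background = NULL) {
  ids <- region$constituent_ids[[1]]
  idx <- match(ids, elements$id)
  sig <- elements[[mark]][idx]
  if (any(is.na(sig)))
    stop("element ", ids[which(is.na(sig))[1]], " lacks mark ", mark)
  if (!is.null(background) && background %in% names(elements))
    sig <- pmax(0, sig - elements[[background]][idx])
  sum(sig)
}

#' Build the unit-square rank curve from region totals
#'
#' Totals are sorted ascending; ranks and totals are linearly mapped to
#' \[0, 1\].
#'
#' @param totals numeric vector of region total signals.
#' @return object of class `rank_curve`: list with `sorted_totals`,
#'   `x_scaled`, `y_scaled` and the ordering permutation `order`.
#' @export
rank_curve <- function(totals) {
  o <- order(totals)
  st <- totals[o]
  n <- length(st)
  x <- if (n > 1) (seq_len(n) - 1) / (n - 1) else rep(0, n)
  rng <- st[n] - st[1]
  y <- if (rng > 0) (st - st[1]) / rng else rep(0, n)
  structure(list(sorted_totals = st, x_scaled = x, y_scaled = y, order = o),
            class = "rank_curve")
}

#' Find the elbow cutoff on a rank curve
#'
#' Returns the ascending rank at which the scaled curve lies farthest below
#' the diagonal, i.e. `argmax(x_scaled - y_scaled)`; ties are broken toward
#' the higher rank (fewer supers).  Regions with total signal strictly
#' greater than the total at that rank are super.  A degenerate curve (all
#' totals equal) yields `NA` (no supers).
#'
#' @param curve a `rank_curve` object.
#' @return integer rank index into `sorted_totals`, or `NA_integer_` for a
#'   degenerate curve.
#' @export
find_cutoff <- function(curve) {
  stopifnot(inherits(curve, "rank_curve"))
  n <- length(curve$sorted_totals)
  if (n < 3) return(NA_integer_)
  if (curve$sorted_totals[n] <= curve$sorted_totals[1]) return(NA_integer_)
  gap <- curve$x_scaled - curve$y_scaled
  # ties toward the higher rank
  max(which(gap == max(gap)))
}

#' Call super regions from regulatory elements
#'
#' The package's central fitting function.  Elements are stitched within
#' `gap_bp`, each stitched region's total mark signal is aggregated, regions
#' are rank-ordered, and the rank curve is cut at its geometric elbow;
#' regions above the cutoff total are super, their constituents are the
#' super components, and all remaining elements are typical.  Applied to
#' silencers with H3K27me3 this yields super-silencers (SS); to enhancers
#' with H3K27ac, super-enhancers (SE) — the algorithm is identical.
#'
#' @param elements element data.frame with columns `id`, `chrom`, `start`,
#'   `end` and the mark signal column; ids must be unique.
#' @param mark signal column to rank on (default `"H3K27me3"`).
#' @param gap_bp stitching gap in bp (default 12,500).
#' @param background optional per-element background column, subtracted
#'   floored at 0.
#' @return object of class `super_call`: list with `regions` (stitched
#'   regions with `total_signal`, `rank`, `is_super`), `elements` (input
#'   augmented with `region_id` and `status` = component/typical), `curve`
#'   (the `rank_curve`), `cutoff` (rank index), `threshold` (total at the
#'   cutoff), `mark`, `gap_bp`.
#' @seealso [components()], [typicals()], [plot.super_call()]
#' @examples
#' el <- data.frame(id = paste0("e", 1:6), chrom = "chr1",
#'                  start = c(0, 2000, 50000, 52000, 54000, 500000),
#'                  end = c(1000, 3000, 51000, 53000, 55000, 501000),
#'                  H3K27me3 = c(1, 1, 40, 55, 60, 2))
#' fit <- call_super_regions(el)
#' summary(fit)
#' @export
call_super_regions <- function(elements, mark = "H3K27me3", gap_bp = 12500L,
                               background = NULL) {
  if (nrow(elements) == 0) stop("no elements supplied")
  if (is.null(elements$id)) elements$id <- paste0(
    elements$chrom, ":", elements$start, "-", elements$end)
  if (anyDuplicated(elements$id))
    stop("element ids must be unique")
  validate_intervals(elements, "elements")
  if (is.null(elements[[mark]]))
    stop("elements lack signal column '", mark, "'")
  regions <- stitch_all(elements, gap_bp)
  regions$total_signal <- vapply(seq_len(nrow(regions)), function(i)
    aggregate_signal(regions[i, ], elements, mark, background), numeric(1))
  curve <- rank_curve(regions$total_signal)
  cutoff <- find_cutoff(curve)
  regions$rank <- match(seq_len(nrow(regions)), curve$order)
  if (is.na(cutoff)) {
    threshold <- Inf
    regions$is_super <- FALSE
  } else {
    threshold <- curve$sorted_totals[cutoff]
    regions$is_super <- regions$total_signal > threshold
  }
  regions$region_id <- paste0("R", sprintf("%05d", seq_len(nrow(regions))))
  comp_ids <- unlist(regions$constituent_ids[regions$is_super])
  el <- elements
  reg_of <- rep(regions$region_id, lengths(regions$constituent_ids))
  el$region_id <- reg_of[match(el$id, unlist(regions$constituent_ids))]
  el$status <- ifelse(el$id %in% comp_ids, "component", "typical")
  structure(list(regions = regions, elements = el, curve = curve,
                 cutoff = cutoff, threshold = threshold, mark = mark,
                 gap_bp = gap_bp, call = match.call()),
            class = "super_call")
}

#' Extract super-region components or typical elements
#'
#' @param x a `super_call` object.
#' @return data.frame of elements (components of super regions, or all
#'   other, typical elements).
#' @export
components <- function(x) {
  stopifnot(inherits(x, "super_call"))
  x$elements[x$elements$status == "component", , drop = FALSE]
}

#' @rdname components
#' @export
typicals <- function(x) {
  stopifnot(inherits(x, "super_call"))
  x$elements[x$elements$status == "typical", , drop = FALSE]
}

#' @export
print.super_call <- function(x, ...) {
  cat("Super-region call (mark:", x$mark, ", gap:", x$gap_bp, "bp)\n")
  cat("  regions:   ", nrow(x$regions), " (", sum(x$regions$is_super),
      " super)\n", sep = "")
  cat("  elements:  ", nrow(x$elements), " (",
      sum(x$elements$status == "component"), " components, ",
      sum(x$elements$status == "typical"), " typical)\n", sep = "")
  if (is.finite(x$threshold))
    cat("  cutoff total signal: ", signif(x$threshold, 4), "\n", sep = "")
  else cat("  degenerate rank curve: no super regions called\n")
  invisible(x)
}

#' @export
summary.super_call <- function(object, ...) {
  sup <- object$regions[object$regions$is_super, ]
  out <- list(
    n_regions = nrow(object$regions),
    n_super = nrow(sup),
    n_components = sum(object$elements$status == "component"),
    n_typical = sum(object$elements$status == "typical"),
    super_fraction = nrow(sup) / nrow(object$regions),
    mean_super_width = if (nrow(sup)) mean(sup$end - sup$start) else NA_real_,
    mean_constituents = if (nrow(sup)) mean(sup$n_constituents) else NA_real_,
    threshold = object$threshold, mark = object$mark
  )
  class(out) <- "summary.super_call"
  out
}

#' @export
print.summary.super_call <- function(x, ...) {
  cat("Super-region call summary (", x$mark, ")\n", sep = "")
  cat(sprintf("  %d regions, %d super (%.2f%%)\n", x$n_regions, x$n_super,
              100 * x$super_fraction))
  cat(sprintf("  %d components, %d typical elements\n", x$n_components,
              x$n_typical))
  if (x$n_super > 0)
    cat(sprintf("  mean super width %.0f bp, mean %.2f constituents\n",
                x$mean_super_width, x$mean_constituents))
  invisible(x)
}

#' Plot the signal rank curve of a super-region call
#'
#' The classical hockey-stick: regions ordered by increasing total signal,
#' with the elbow cutoff marked; regions right of the cutoff are super.
#'
#' @param x a `super_call` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.super_call <- function(x, ...) {
  st <- x$curve$sorted_totals
  graphics::plot(seq_along(st), st, type = "l",
                 xlab = "regions ranked by total signal",
                 ylab = paste("total", x$mark, "signal"), ...)
  if (!is.na(x$cutoff)) {
    graphics::abline(v = x$cutoff, lty = 2, col = "red")
    graphics::abline(h = x$threshold, lty = 3, col = "grey40")
  }
  invisible(x)
}

#' Export a super-region call as BED files
#'
#' Writes regions (BED5, score = total signal, name encodes super status),
#' components and typical elements.
#'
#' @param x a `super_call` object.
#' @param prefix output path prefix; files `<prefix>_regions.bed`,
#'   `<prefix>_components.bed`, `<prefix>_typicals.bed` are written.
#' @export
write_super_call <- function(x, prefix) {
  stopifnot(inherits(x, "super_call"))
  regs <- x$regions
  regs$name <- paste0(regs$region_id, "_",
                      ifelse(regs$is_super, "super", "typical"))
  write_bed(regs, paste0(prefix, "_regions.bed"),
            name_col = "name", score_col = "total_signal")
  write_bed(components(x), paste0(prefix, "_components.bed"), name_col = "id")
  write_bed(typicals(x), paste0(prefix, "_typicals.bed"), name_col = "id")
  invisible(prefix)
}
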