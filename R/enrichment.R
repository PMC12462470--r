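# Variant-density and fraction-based enrichment statistics over element
# sets, GWAS LD expansion, replicated/recurrent fractions, and
# cross-cell-type element-set Jaccard.  Tests are two-sided binomial tests
# without multiple-testing adjustment.

#' Variant density per kilobase of an element set
#'
#' Elements are merged first so overlapping bases are never counted twice;
#' the density is the number of variant positions inside the merged set per
#' kb of merged length.
#'
#' @param variants variant data.frame (`chrom`, `pos`).
#' @param elements interval data.frame (non-empty).
#' @return variants per kb.
#' @export
density_per_kb <- function(variants, elements) {
  if (nrow(elements) == 0) stop("element set is empty")
  m <- merge_intervals(elements)
  len <- sum(m$end - m$start)
  if (len == 0) stop("element set has zero total length")
  n_in <- sum(positions_in_intervals(variants[, c("chrom", "pos")], m))
  n_in / (len / 1000)
}

#' Fraction of variants carrying a category tag
#'
#' @param variants variant data.frame with a comma-separated `categories`
#'   column (non-empty table).
#' @param category tag to count (e.g. `"b_cell_cancer"`).
#' @return real in \[0, 1\].
#' @export
category_fraction <- function(variants, category) {
  if (nrow(variants) == 0)
    stop("category_fraction is undefined for an empty variant set")
  cats <- split_set_col(variants$categories)
  mean(vapply(cats, function(s) category %in% s, logical(1)))
}

#' Enrichment fold and binomial test against a reference fraction
#'
#' `fold = set_fraction / reference_fraction`; the p-value is a two-sided
#' exact binomial test of `k = round(set_fraction * n_in_set)` successes in
#' `n_in_set` trials at probability `reference_fraction`.
#'
#' @param set_fraction observed fraction in the element set.
#' @param reference_fraction reference (e.g. whole-genome) fraction, in
#'   (0, 1).
#' @param n_in_set number of observations behind `set_fraction` (>= 1).
#' @return list with `fold` and `p_value`.
#' @export
enrichment_fold <- function(set_fraction, reference_fraction, n_in_set) {
  if (reference_fraction <= 0 || reference_fraction >= 1)
    stop("reference_fraction must be in (0, 1)")
  if (n_in_set < 1) stop("n_in_set must be >= 1")
  k <- round(set_fraction * n_in_set)
  p <- binom.test(k, n_in_set, p = reference_fraction,
                  alternative = "two.sided")$p.value
  list(fold = set_fraction / reference_fraction, p_value = p)
}

#' Expand GWAS seed SNPs through strong LD
#'
#' Adds the partner of every LD pair with one end in the seed set and
#' `r2 > threshold` (strict).  A single expansion pass: partners of seeds
#' only, no transitive closure.
#'
#' @param seed_snps character vector of seed SNP ids.
#' @param ld_pairs data.frame with `snp_a`, `snp_b`, `r2`.
#' @param threshold LD threshold (default 0.8, strict `>`).
#' @return character vector: the expanded SNP id set (superset of seeds).
#' @export
ld_expand <- function(seed_snps, ld_pairs, threshold = 0.8) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (is.null(ld_pairs) || nrow(ld_pairs) == 0) return(unique(seed_snps))
  strong <- ld_pairs[ld_pairs$r2 > threshold, , drop = FALSE]
  add <- c(strong$snp_b[strong$snp_a %in% seed_snps],
           strong$snp_a[strong$snp_b %in% seed_snps])
  unique(c(seed_snps, add))
}

#' Fraction of SNPs replicated across independent studies
#'
#' A SNP is replicated when reported by at least two distinct studies for
#' the trait class.
#'
#' @param variants variant data.frame with comma-separated `studies` and
#'   `categories` columns.
#' @param trait_filter optional category tag; only SNPs carrying it are
#'   considered.
#' @return real in \[0, 1\].
#' @export
replicated_fraction <- function(variants, trait_filter = NULL) {
  x <- variants
  if (!is.null(trait_filter)) {
    keep <- vapply(split_set_col(x$categories),
                   function(s) trait_filter %in% s, logical(1))
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) == 0)
    stop("replicated_fraction is undefined: no SNPs after filtering")
  mean(lengths(lapply(split_set_col(x$studies), unique)) >= 2)
}

#' Fraction of SNVs recurrent across cancer samples
#'
#' An SNV is recurrent when detected in at least two distinct samples.
#'
#' @param variants variant data.frame with a comma-separated `samples`
#'   column (non-empty).
#' @return real in \[0, 1\].
#' @export
recurrent_fraction <- function(variants) {
  if (nrow(variants) == 0)
    stop("recurrent_fraction is undefined for an empty variant set")
  mean(lengths(lapply(split_set_col(variants$samples), unique)) >= 2)
}

#' Jaccard index between two element sets
#'
#' An element of one set is matched when it overlaps any element of the
#' other set by at least `min_bp` (each element counted once); the index is
#' `matched / (|a| + |b| - matched)` with matches counted from set `a`.
#'
#' @param set_a,set_b interval data.frames (both non-empty).
#' @param min_bp minimum overlap in bp.
#' @return real in \[0, 1\].
#' @export
elementset_jaccard <- function(set_a, set_b, min_bp = 1L) {
  if (nrow(set_a) == 0 && nrow(set_b) == 0)
    stop("elementset_jaccard is undefined for two empty sets")
  if (nrow(set_a) == 0 || nrow(set_b) == 0) return(0)
  m <- sum(max_overlap_bp(set_a, set_b) >= min_bp)
  m / (nrow(set_a) + nrow(set_b) - m)
}

#' Flanking regions of an element set
#'
#' The `+/- flank_bp` neighbourhood around each element, with the merged
#' element set itself excluded; used as the local background for density
#' comparisons.
#'
#' @param elements interval data.frame.
#' @param flank_bp flank width each side (default 50 kb).
#' @return merged interval data.frame of the flanks.
#' @export
flanking_regions <- function(elements, flank_bp = 50000L) {
  fl <- data.frame(chrom = elements$chrom,
                   start = pmax(0, elements$start - flank_bp),
                   end = elements$end + flank_bp,
                   stringsAsFactors = FALSE)
  fl <- merge_intervals(fl)
  el <- merge_intervals(elements)
  gr <- GenomicRanges::setdiff(as_gr(fl), as_gr(el))
  gr_to_df(gr)
}

#' Variant enrichment table over element sets
#'
#' For each named element set, counts the variants inside (merged),
#' computes density per kb and the fraction carrying `category`, and the
#' fold and binomial p-value of that fraction against the fraction among
#' all supplied variants (the reference).
#'
#' @param variants variant data.frame.
#' @param sets named list of interval data.frames.
#' @param category category tag tested for enrichment.
#' @return data.frame, one row per set: `set_name`, `count`,
#'   `density_per_kb`, `category_fraction`, `fold_vs_reference`, `p_value`.
#' @export
variant_enrichment <- function(variants, sets, category = "b_cell_cancer") {
  ref_frac <- category_fraction(variants, category)
  rows <- lapply(names(sets), function(nm) {
    el <- sets[[nm]]
    m <- merge_intervals(el)
    inside <- positions_in_intervals(variants[, c("chrom", "pos")], m)
    v_in <- variants[inside, , drop = FALSE]
    n <- nrow(v_in)
    dens <- n / (sum(m$end - m$start) / 1000)
    frac <- if (n > 0) category_fraction(v_in, category) else NA_real_
    if (n > 0 && ref_frac > 0 && ref_frac < 1) {
      ef <- enrichment_fold(frac, ref_frac, n)
      fold <- ef$fold; p <- ef$p_value
    } else {
      fold <- NA_real_; p <- NA_real_
    }
    data.frame(set_name = nm, count = n, density_per_kb = dens,
               category_fraction = frac, fold_vs_reference = fold,
               p_value = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify translocation partner breakpoints by element neighbourhood
#'
#' Each partner breakpoint is assigned to the first element group (by the
#' precedence super silencer > super enhancer > typical silencer > typical
#' enhancer, i.e. super before typical and silencer before enhancer on
#' ties) whose regions or their `+/- flank_bp` proximity contain it; ties
#' are logged via message.  Unassigned breakpoints get `"none"`.
#'
#' @param partners data.frame with `chrom`, `pos` of partner breakpoints.
#' @param groups named list of interval data.frames in precedence order
#'   (e.g. `list(SS = ..., SE = ..., TS = ..., TE = ...)`).
#' @param flank_bp proximity width (default 50 kb).
#' @return character vector of group names (or `"none"`).
#' @export
classify_tl_partner <- function(partners, groups, flank_bp = 50000L) {
  out <- rep("none", nrow(partners))
  assigned <- rep(FALSE, nrow(partners))
  n_multi <- 0L
  hit_mat <- sapply(groups, function(g) {
    wide <- data.frame(chrom = g$chrom,
                       start = pmax(0, g$start - flank_bp),
                       end = g$end + flank_bp)
    positions_in_intervals(partners[, c("chrom", "pos")], wide)
  })
  if (is.null(dim(hit_mat))) hit_mat <- matrix(hit_mat, nrow = nrow(partners))
  n_multi <- sum(rowSums(hit_mat) > 1)
  for (j in seq_along(groups)) {
    take <- hit_mat[, j] & !assigned
    out[take] <- names(groups)[j]
    assigned <- assigned | hit_mat[, j]
  }
  if (n_multi > 0)
    message(n_multi, " partner breakpoint(s) matched multiple groups; ",
            "precedence applied")
  out
}
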