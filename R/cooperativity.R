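# Cooperativity among components of the same super region: synchronized
# ternary activity across cell types (cosine similarity) and TF-binding
# similarity (Jaccard), compared against distance-matched and random
# backgrounds.

#' Ternary activity of elements in one cell type
#'
#' An element overlapping (by >= 1 bp) an H3K27ac peak only is active (1),
#' an H3K27me3 peak only is repressed (-1), both marks is uncertain (0), and
#' neither mark is 0 (no evidence contributes no sign).
#'
#' @param elements interval data.frame.
#' @param ac_peaks H3K27ac peak intervals for the cell type.
#' @param me3_peaks H3K27me3 peak intervals for the cell type.
#' @return integer vector in \{-1, 0, 1\} along `elements`.
#' @export
ternary_activity <- function(elements, ac_peaks, me3_peaks) {
  has_ac <- max_overlap_bp(elements, ac_peaks) >= 1
  has_me3 <- max_overlap_bp(elements, me3_peaks) >= 1
  out <- integer(nrow(elements))
  out[has_ac & !has_me3] <- 1L
  out[has_me3 & !has_ac] <- -1L
  out
}

#' Build an element-by-cell-type ternary activity matrix
#'
#' @param elements element data.frame with `id`.
#' @param peaks_by_cell_type named list; each entry a list with interval
#'   data.frames `ac` and `me3` for that cell type.
#' @return integer matrix (rows = element ids, columns = cell types) with
#'   entries in \{-1, 0, 1\}.
#' @export
build_activity_matrix <- function(elements, peaks_by_cell_type) {
  cols <- lapply(peaks_by_cell_type, function(p)
    ternary_activity(elements, p$ac, p$me3))
  m <- do.call(cbind, cols)
  rownames(m) <- elements$id
  colnames(m) <- names(peaks_by_cell_type)
  m
}

#' Cooperativity score between two activity vectors
#'
#' Cosine similarity of ternary activity over the tested cell types:
#' `sum(a_i * a_j) / (sqrt(sum(a_i^2)) * sqrt(sum(a_j^2)))`.  A zero vector
#' makes the score undefined and returns `NA` (callers exclude and log such
#' pairs).
#'
#' @param a_i,a_j integer vectors in \{-1, 0, 1\}, equal length >= 1.
#' @return real in \[-1, 1\], or `NA` if either vector is all zero.
#' @export
cooperativity_score <- function(a_i, a_j) {
  if (length(a_i) != length(a_j)) stop("activity vectors differ in length")
  ni <- sum(a_i^2); nj <- sum(a_j^2)
  if (ni == 0 || nj == 0) return(NA_real_)
  # clamp to the documented range against floating-point drift
  max(-1, min(1, sum(a_i * a_j) / (sqrt(ni) * sqrt(nj))))
}

#' TF-binding similarity between two binary occupancy vectors
#'
#' Jaccard similarity over the TF set:
#' `sum(t_i * t_j) / sum(t_i + t_j - t_i * t_j)`; two empty profiles give 0.
#'
#' @param t_i,t_j binary vectors in \{0, 1\}, equal length.
#' @return real in \[0, 1\].
#' @export
tfbs_similarity <- function(t_i, t_j) {
  if (length(t_i) != length(t_j)) stop("TFBS vectors differ in length")
  denom <- sum(t_i + t_j - t_i * t_j)
  if (denom == 0) return(0)
  sum(t_i * t_j) / denom
}

#' Fraction of TFs bound in at least two components of a region
#'
#' @param tfbs binary matrix, rows = the region's constituents (>= 2),
#'   columns = TFs.
#' @return real in \[0, 1\]: (number of TFs with >= 2 bound constituents) /
#'   number of TFs.
#' @export
shared_tf_fraction <- function(tfbs) {
  if (nrow(tfbs) < 2)
    stop("shared_tf_fraction is undefined for regions with < 2 constituents")
  mean(colSums(tfbs) >= 2)
}

#' Sample background element pairs matching a distance distribution
#'
#' Draws pairs of distinct elements from a pool (typically the typical
#' elements) so that the midpoint-distance histogram of the sampled pairs, at
#' `bin_width_bp` resolution, matches the target histogram's proportions.
#' Only intra-chromosomal pairs are considered.  Candidate pairs are drawn by
#' randomized search; sampling within bins is without replacement.  Demand
#' falling in bins with no candidates is redistributed over the remaining
#' bins (with a warning).
#'
#' @param target_distances bp distances to match (e.g. within-region
#'   component pair distances).
#' @param pool element data.frame to sample pairs from.
#' @param n_pairs number of pairs to return.
#' @param bin_width_bp histogram bin width (default 10 kb).
#' @param seed RNG seed; the same seed gives identical output.
#' @return data.frame with columns `id1`, `id2`, `distance_bp`, `group` =
#'   `"matched_background"`.
#' @export
matched_background_pairs <- function(target_distances, pool, n_pairs,
                                     bin_width_bp = 10000L, seed = 1L) {
  if (nrow(pool) < 2) stop("pool must contain at least two elements")
  if (length(target_distances) == 0) stop("no target distances supplied")
  with_local_seed(seed, {
    # enumerate every same-chromosome candidate pair whose midpoint distance
    # could fall in an occupied target bin (sliding window over the sorted
    # pool), so that short within-region distances have dense candidates
    maxd <- (floor(max(target_distances) / bin_width_bp) + 1) * bin_width_bp
    o <- order(pool$chrom, interval_midpoint(pool))
    ps <- pool[o, , drop = FALSE]
    mid <- interval_midpoint(ps)
    ci <- integer(0); cj <- integer(0)
    for (chr in unique(ps$chrom)) {
      sel <- which(ps$chrom == chr)
      m <- mid[sel]
      for (a in seq_along(sel)) {
        b <- a + 1L
        while (b <= length(sel) && m[b] - m[a] <= maxd) {
          ci <- c(ci, sel[a]); cj <- c(cj, sel[b]); b <- b + 1L
        }
      }
    }
    if (length(ci) == 0) stop("pool has no candidate pairs within the ",
                              "target distance range")
    d <- mid[cj] - mid[ci]
    tbin <- floor(target_distances / bin_width_bp)
    cbin <- floor(d / bin_width_bp)
    tt <- table(tbin)
    demand <- setNames(round(as.vector(tt) / sum(tt) * n_pairs), names(tt))
    avail <- split(seq_along(d), as.character(cbin))
    picked <- integer(0)
    deficit <- 0L
    for (b in names(demand)) {
      want <- demand[[b]]
      have <- avail[[b]] %||% integer(0)
      if (length(have) == 0 && want > 0) {
        warning("no candidate pairs in distance bin ", b,
                "; demand redistributed")
        deficit <- deficit + want
        next
      }
      if (want >= length(have)) {
        take <- have
        deficit <- deficit + want - length(have)
      } else {
        # within the bin, match the sampled target distances to the nearest
        # unused candidates so the within-bin shape follows the target
        tgt <- sample(target_distances[tbin == as.integer(b)], want,
                      replace = TRUE)
        take <- integer(0)
        left <- have
        for (t in tgt) {
          k <- left[which.min(abs(d[left] - t))]
          take <- c(take, k)
          left <- setdiff(left, k)
        }
      }
      picked <- c(picked, take)
      avail[[b]] <- setdiff(have, take)
    }
    # redistribute any deficit over remaining candidates, nearest-bin first
    if (deficit > 0) {
      rest <- setdiff(unlist(avail), picked)
      if (length(rest)) {
        take <- rest[sample.int(length(rest), min(deficit, length(rest)))]
        picked <- c(picked, take)
      }
    }
    if (length(picked) > n_pairs)
      picked <- picked[sample.int(length(picked), n_pairs)]
    data.frame(id1 = ps$id[ci[picked]], id2 = ps$id[cj[picked]],
               distance_bp = d[picked], group = "matched_background",
               stringsAsFactors = FALSE)
  })
}

# All within-region component pairs of the super regions of a call.
within_region_pairs <- function(fit, max_pairs_per_region = 50L) {
  regs <- fit$regions[fit$regions$is_super & fit$regions$n_constituents >= 2, ]
  if (nrow(regs) == 0)
    return(data.frame(id1 = character(0), id2 = character(0),
                      distance_bp = numeric(0), group = character(0)))
  el <- fit$elements
  mid <- setNames(interval_midpoint(el), el$id)
  out <- lapply(regs$constituent_ids, function(ids) {
    cmb <- utils::combn(ids, 2)
    if (ncol(cmb) > max_pairs_per_region)
      cmb <- cmb[, seq_len(max_pairs_per_region), drop = FALSE]
    data.frame(id1 = cmb[1, ], id2 = cmb[2, ],
               distance_bp = abs(mid[cmb[1, ]] - mid[cmb[2, ]]),
               group = "within_region", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Random pairs from the pool (no distance matching).
random_pairs <- function(pool, n_pairs, seed = 1L) {
  with_local_seed(seed, {
    mid <- interval_midpoint(pool)
    i <- sample.int(nrow(pool), 4L * n_pairs, replace = TRUE)
    j <- sample.int(nrow(pool), 4L * n_pairs, replace = TRUE)
    keep <- which(i != j & pool$chrom[i] == pool$chrom[j])[seq_len(n_pairs)]
    keep <- keep[!is.na(keep)]
    data.frame(id1 = pool$id[i[keep]], id2 = pool$id[j[keep]],
               distance_bp = abs(mid[i[keep]] - mid[j[keep]]),
               group = "random_background", stringsAsFactors = FALSE)
  })
}

#' Cooperativity analysis of a super-region call
#'
#' Scores all within-region component pairs with the activity cooperativity
#' (cosine) and TFBS similarity (Jaccard), builds distance-matched and random
#' background pairs from the typical elements, and tests group separation
#' with one-sided Wilcoxon rank-sum tests (no multiple-testing adjustment).
#' Pairs with an all-zero activity vector are excluded from the cosine and
#' counted in the returned diagnostics.
#'
#' @param fit a `super_call` object.
#' @param activity ternary activity matrix from [build_activity_matrix()].
#' @param tfbs optional binary TFBS matrix (rows = element ids).
#' @param n_background number of background pairs per group.
#' @param bin_width_bp distance-histogram bin width for matching.
#' @param seed RNG seed.
#' @return list with `pairs` (per-pair table: ids, group, distance,
#'   cooperativity, tfbs_similarity), `summary` (group medians),
#'   `tests` (Wilcoxon p-values within vs each background) and
#'   `n_excluded_zero_vector`.
#' @export
cooperativity_analysis <- function(fit, activity, tfbs = NULL,
                                   n_background = 500L,
                                   bin_width_bp = 10000L, seed = 1L) {
  win <- within_region_pairs(fit)
  if (nrow(win) == 0) stop("no super regions with >= 2 constituents")
  pool <- typicals(fit)
  mb <- matched_background_pairs(win$distance_bp, pool,
                                 n_pairs = min(n_background, nrow(win) * 4L),
                                 bin_width_bp = bin_width_bp, seed = seed)
  rb <- random_pairs(pool, n_pairs = min(n_background, nrow(win) * 4L),
                     seed = seed + 1L)
  pairs <- rbind(win, mb, rb)
  score1 <- function(id1, id2) cooperativity_score(activity[id1, ],
                                                   activity[id2, ])
  pairs$cooperativity <- mapply(score1, pairs$id1, pairs$id2)
  n_excl <- sum(is.na(pairs$cooperativity))
  if (!is.null(tfbs)) {
    pairs$tfbs_similarity <- mapply(function(a, b)
      tfbs_similarity(tfbs[a, ], tfbs[b, ]), pairs$id1, pairs$id2)
  }
  med <- aggregate(cooperativity ~ group, pairs, median, na.action = stats::na.omit)
  w_of <- function(g) {
    a <- pairs$cooperativity[pairs$group == "within_region"]
    b <- pairs$cooperativity[pairs$group == g]
    wilcox.test(a, b, alternative = "greater")$p.value
  }
  tests <- c(vs_matched = w_of("matched_background"),
             vs_random = w_of("random_background"))
  list(pairs = pairs, summary = med, tests = tests,
       n_excluded_zero_vector = n_excl)
}
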