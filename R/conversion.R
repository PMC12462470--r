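# Functional conversion of normal-cell elements into cancer super-elements
# across patient samples (e.g. SS components falling inside DLBCL
# super-enhancer regions), recurrence over samples, and chromatin-contact
# retention between conditions.

#' Detect element conversions across cancer samples
#'
#' An element is converted when it overlaps a cancer region (e.g. a
#' patient's SE set) by at least `min_bp` in at least one sample.  With
#' `containment = TRUE`, the element must lie fully inside a cancer region
#' instead.
#'
#' @param elements element data.frame with `id`.
#' @param cancer_regions_by_sample named list: sample id -> interval
#'   data.frame.
#' @param min_bp minimum overlap in bp (default 1).
#' @param direction label recorded on the output (e.g. `"SS_to_SE"`).
#' @param containment require full containment instead of overlap.
#' @return data.frame of conversion records (converted elements only):
#'   `element_id`, `direction`, `samples_hit` (comma-joined),
#'   `n_samples_hit`, `n_samples_total`, `recurrent_over_half`
#'   (strictly more than half of the samples).
#' @export
detect_conversions <- function(elements, cancer_regions_by_sample,
                               min_bp = 1L, direction = "SS_to_SE",
                               containment = FALSE) {
  if (length(cancer_regions_by_sample) == 0)
    stop("no cancer samples supplied")
  if (min_bp < 1) stop("min_bp must be >= 1")
  n_tot <- length(cancer_regions_by_sample)
  samples <- sort(names(cancer_regions_by_sample))
  hit <- sapply(samples, function(s) {
    regs <- cancer_regions_by_sample[[s]]
    if (is.null(regs) || nrow(regs) == 0) return(rep(FALSE, nrow(elements)))
    if (containment) {
      ov <- max_overlap_bp(elements, regs)
      ov >= (elements$end - elements$start)
    } else {
      max_overlap_bp(elements, regs) >= min_bp
    }
  })
  if (is.null(dim(hit))) hit <- matrix(hit, nrow = nrow(elements))
  n_hit <- rowSums(hit)
  conv <- which(n_hit >= 1)
  if (length(conv) == 0)
    return(data.frame(element_id = character(0), direction = character(0),
                      samples_hit = character(0), n_samples_hit = integer(0),
                      n_samples_total = integer(0),
                      recurrent_over_half = logical(0)))
  data.frame(
    element_id = elements$id[conv],
    direction = direction,
    samples_hit = vapply(conv, function(k)
      paste(samples[hit[k, ]], collapse = ","), character(1)),
    n_samples_hit = n_hit[conv],
    n_samples_total = n_tot,
    recurrent_over_half = n_hit[conv] > n_tot / 2,
    stringsAsFactors = FALSE
  )
}

#' Conversion recurrence summary
#'
#' @param records conversion records from [detect_conversions()].
#' @param universe_size number of elements tested (>= number of records).
#' @return list with `converted_fraction` (records / universe) and
#'   `recurrent_over_half_fraction` (among converted records only; `NA`
#'   when there are no conversions).
#' @export
recurrence_summary <- function(records, universe_size) {
  if (universe_size <= 0) stop("universe_size must be positive")
  if (nrow(records) > universe_size)
    stop("universe_size smaller than the number of conversion records")
  conv_frac <- nrow(records) / universe_size
  rec_frac <- if (nrow(records) > 0) mean(records$recurrent_over_half)
              else NA_real_
  list(converted_fraction = conv_frac,
       recurrent_over_half_fraction = rec_frac)
}

# Re-bin contact anchors to bin_size and return a canonical key per contact
# (chrom + ordered bin starts).
contact_keys <- function(contacts, bin_size) {
  b1 <- floor(contacts$start1 / bin_size) * bin_size
  b2 <- floor(contacts$start2 / bin_size) * bin_size
  paste(contacts$chrom, pmin(b1, b2), pmax(b1, b2))
}

#' Chromatin-contact retention between two conditions
#'
#' Among contacts in condition `a` with at least one anchor overlapping the
#' element set, the fraction that persist in condition `b` with both anchor
#' bins identical (same chromosome, same bin starts) after re-binning both
#' sets to `bin_size`.
#'
#' @param contacts_a,contacts_b contact data.frames ([read_bedpe()]
#'   layout).
#' @param elements interval data.frame defining the anchored set.
#' @param bin_size anchor bin size in bp (default 10 kb).
#' @return real in \[0, 1\]; `NA` (with a warning) when no contact in `a`
#'   qualifies.
#' @export
contact_retention <- function(contacts_a, contacts_b, elements,
                              bin_size = 10000L) {
  a1 <- data.frame(chrom = contacts_a$chrom, start = contacts_a$start1,
                   end = contacts_a$end1)
  a2 <- data.frame(chrom = contacts_a$chrom, start = contacts_a$start2,
                   end = contacts_a$end2)
  qual <- max_overlap_bp(a1, elements) >= 1 | max_overlap_bp(a2, elements) >= 1
  if (!any(qual)) {
    warning("no contacts in condition a touch the element set")
    return(NA_real_)
  }
  if (nrow(contacts_b) == 0) return(0)
  keys_a <- contact_keys(contacts_a[qual, , drop = FALSE], bin_size)
  keys_b <- contact_keys(contacts_b, bin_size)
  mean(keys_a %in% keys_b)
}

#' Expected contact retention by chance
#'
#' Permutation null for [contact_retention()]: element labels are shuffled
#' over a matched pool (elements plus pool members), and retention is
#' recomputed for each permuted label set.
#'
#' @param contacts_a,contacts_b contact data.frames.
#' @param elements interval data.frame (the labelled set).
#' @param pool interval data.frame of exchangeable candidate elements.
#' @param n_perm number of permutations (default 1000).
#' @param bin_size anchor bin size in bp.
#' @param seed RNG seed.
#' @return list with `expected` (mean permuted retention) and `perm`
#'   (vector of permuted retentions).
#' @export
expected_retention <- function(contacts_a, contacts_b, elements, pool,
                               n_perm = 1000L, bin_size = 10000L, seed = 1L) {
  all_el <- rbind(elements[, c("chrom", "start", "end")],
                  pool[, c("chrom", "start", "end")])
  n_lab <- nrow(elements)
  with_local_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(nrow(all_el), n_lab)
      suppressWarnings(contact_retention(contacts_a, contacts_b,
                                         all_el[idx, , drop = FALSE],
                                         bin_size))
    }, numeric(1))
    list(expected = mean(perm, na.rm = TRUE), perm = perm)
  })
}
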