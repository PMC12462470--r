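# Element annotation: CpG-island status, TAD geometry, gene linkage by
# proximity and by chromatin contacts, tissue-specificity (tau) and CpG
# methylation summaries.

#' CpG-island classification of elements
#'
#' An element is `CGI` when its maximum single-CGI overlap strictly exceeds
#' `min_bp` (default 200 bp), else `non_CGI`.
#'
#' @param elements interval data.frame.
#' @param cgis CGI interval data.frame.
#' @param min_bp strict overlap threshold in bp.
#' @return character vector `"CGI"`/`"non_CGI"` along elements.
#' @export
cgi_class <- function(elements, cgis, min_bp = 200L) {
  ifelse(max_overlap_bp(elements, cgis) > min_bp, "CGI", "non_CGI")
}

#' TAD-section classification of elements
#'
#' Distance `d` from the element midpoint to the nearest TAD boundary
#' labels the element: `d <= boundary_bp` (20 kb) is `boundary`,
#' `boundary_bp < d <= shore_bp` (50 kb) is `shore`, beyond is `center`.
#' Elements on chromosomes without TADs are labelled `NA` (logged via
#' warning).
#'
#' @param elements interval data.frame.
#' @param tads a `tad_set` from [load_tads()] (or a TAD data.frame/path).
#' @param boundary_bp,shore_bp band limits in bp.
#' @return data.frame with `label` (boundary/shore/center), `distance_bp`
#'   and `side` (`"left"`/`"right"`: which side of the nearest boundary the
#'   midpoint lies on; left = upstream of the boundary).
#' @export
tad_section <- function(elements, tads, boundary_bp = 20000L,
                        shore_bp = 50000L) {
  if (!inherits(tads, "tad_set")) tads <- load_tads(tads)
  mid <- interval_midpoint(elements)
  n <- nrow(elements)
  label <- rep(NA_character_, n)
  dist <- rep(NA_real_, n)
  side <- rep(NA_character_, n)
  for (chr in unique(elements$chrom)) {
    b <- tads$boundaries[[chr]]
    sel <- which(elements$chrom == chr)
    if (is.null(b) || length(b) == 0) next
    nb_idx <- vapply(mid[sel], function(m) which.min(abs(b - m)), integer(1))
    d <- abs(b[nb_idx] - mid[sel])
    dist[sel] <- d
    side[sel] <- ifelse(mid[sel] < b[nb_idx], "left", "right")
    label[sel] <- ifelse(d <= boundary_bp, "boundary",
                         ifelse(d <= shore_bp, "shore", "center"))
  }
  if (anyNA(label))
    warning(sum(is.na(label)), " element(s) on chromosomes without TADs ",
            "left unassigned")
  data.frame(label = label, distance_bp = dist, side = side,
             stringsAsFactors = FALSE)
}

#' Counterpart TAD shore of a boundary
#'
#' Given a TAD boundary and the side a query shore lies on, returns the
#' 20-50 kb band on the opposite side of the boundary.  Bands extending past
#' the chromosome start are truncated at 0 (with a warning).
#'
#' @param boundary_pos boundary base position.
#' @param query_side `"left"` or `"right"`: the side of the query shore.
#' @param boundary_bp,shore_bp band limits in bp (20 kb / 50 kb).
#' @param chrom chromosome name attached to the returned interval.
#' @return one-row interval data.frame for the counterpart shore.
#' @export
counterpart_shore <- function(boundary_pos, query_side = c("left", "right"),
                              boundary_bp = 20000L, shore_bp = 50000L,
                              chrom = "chr1") {
  query_side <- match.arg(query_side)
  if (query_side == "right") {
    start <- boundary_pos - shore_bp
    end <- boundary_pos - boundary_bp
  } else {
    start <- boundary_pos + boundary_bp
    end <- boundary_pos + shore_bp
  }
  if (start < 0) {
    warning("counterpart shore truncated at chromosome start")
    start <- 0
    end <- max(end, 0)
  }
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Nearest gene by TSS distance
#'
#' For each element, the gene on the same chromosome whose TSS is closest to
#' the element midpoint; ties go to the lexicographically smaller `gene_id`
#' (logged via message).  Elements on chromosomes without genes get `NA`.
#'
#' @param elements interval data.frame.
#' @param genes gene data.frame (columns `gene_id`, `chrom`, `tss`).
#' @return character vector of gene ids along elements.
#' @export
nearest_gene <- function(elements, genes) {
  mid <- interval_midpoint(elements)
  out <- rep(NA_character_, nrow(elements))
  n_ties <- 0L
  for (chr in unique(elements$chrom)) {
    g <- genes[genes$chrom == chr, ]
    sel <- which(elements$chrom == chr)
    if (nrow(g) == 0) next
    g <- g[order(g$gene_id), ]  # tie-break by id: first minimum wins
    for (k in sel) {
      d <- abs(g$tss - mid[k])
      w <- which(d == min(d))
      if (length(w) > 1) n_ties <- n_ties + 1L
      out[k] <- g$gene_id[w[1]]
    }
  }
  if (n_ties > 0)
    message(n_ties, " nearest-gene tie(s) broken lexicographically")
  out
}

#' Genes contacting elements through chromatin loops
#'
#' A gene is linked to an element when some contact has one anchor
#' overlapping the gene promoter and the other anchor overlapping the
#' element (>= 1 bp each).
#'
#' @param elements interval data.frame.
#' @param contacts contact data.frame ([read_bedpe()] layout).
#' @param genes gene data.frame with `gene_id`, `chrom`, `tss`.
#' @param promoter_halfwidth promoter half-width around the TSS (default
#'   2 kb).
#' @return list (along elements) of character vectors of gene ids.
#' @export
contact_genes <- function(elements, contacts, genes,
                          promoter_halfwidth = 2000L) {
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss - promoter_halfwidth),
                     end = genes$tss + promoter_halfwidth,
                     stringsAsFactors = FALSE)
  a1 <- data.frame(chrom = contacts$chrom, start = contacts$start1,
                   end = contacts$end1)
  a2 <- data.frame(chrom = contacts$chrom, start = contacts$start2,
                   end = contacts$end2)
  ov <- function(q, s) {  # list of subject hits per query
    hits <- GenomicRanges::findOverlaps(as_gr(q), as_gr(s))
    split(S4Vectors::subjectHits(hits), factor(S4Vectors::queryHits(hits),
                                               levels = seq_len(nrow(q))))
  }
  el_a1 <- ov(elements, a1); el_a2 <- ov(elements, a2)
  pr_a1 <- ov(prom, a1); pr_a2 <- ov(prom, a2)
  # invert promoter hits: contact index -> gene ids
  inv <- function(l) {
    ci <- unlist(l, use.names = FALSE)
    gi <- rep(genes$gene_id, lengths(l))
    split(gi, ci)
  }
  g_by_a1 <- inv(pr_a1); g_by_a2 <- inv(pr_a2)
  lapply(seq_len(nrow(elements)), function(k) {
    # element on anchor1 -> genes on anchor2, and vice versa
    g <- c(unlist(g_by_a2[as.character(el_a1[[k]])], use.names = FALSE),
           unlist(g_by_a1[as.character(el_a2[[k]])], use.names = FALSE))
    sort(unique(as.character(g %||% character(0))))
  })
}

#' Tissue-specificity index tau
#'
#' `tau = sum(1 - x / max(x)) / (N - 1)` over `N >= 2` tissues; 0 for
#' uniform expression, 1 for single-tissue expression.  All-zero profiles
#' are undefined (`NA`).
#'
#' @param expr non-negative expression vector over tissues, or a matrix
#'   (genes x tissues) scored row-wise.
#' @return tau in \[0, 1\] (vector for matrix input).
#' @export
tau <- function(expr) {
  if (is.matrix(expr)) return(apply(expr, 1, tau))
  if (length(expr) < 2) stop("tau requires >= 2 tissues")
  if (any(expr < 0)) stop("tau requires non-negative expression")
  m <- max(expr)
  if (m == 0) return(NA_real_)
  sum(1 - expr / m) / (length(expr) - 1)
}

#' Mean CpG methylation of elements
#'
#' Arithmetic mean of beta values at CpG sites inside each element; `NA`
#' when an element contains no site.
#'
#' @param elements interval data.frame.
#' @param meth per-site methylation data.frame (`chrom`, `pos`, `beta`),
#'   e.g. from [read_methylation()].
#' @return numeric vector of mean betas along elements.
#' @export
mean_methylation <- function(elements, meth) {
  if (any(meth$beta < 0 | meth$beta > 1))
    stop("beta values must be in [0, 1]")
  out <- rep(NA_real_, nrow(elements))
  if (nrow(meth) == 0 || nrow(elements) == 0) return(out)
  sgr <- GenomicRanges::GRanges(as.character(meth$chrom),
                                IRanges::IRanges(meth$pos + 1L, meth$pos + 1L))
  hits <- GenomicRanges::findOverlaps(as_gr(elements), sgr)
  if (length(hits)) {
    agg <- tapply(meth$beta[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), mean)
    out[as.integer(names(agg))] <- as.vector(agg)
  }
  out
}

#' Annotate elements with CGI status, TAD section, genes and methylation
#'
#' One row per element, mirroring the per-element annotation table of the
#' pipeline: `cgi_class`, `tad_section`, `nearest_gene`, `contact_genes`
#' (comma-joined), `mean_methylation`.
#'
#' @param elements element data.frame with `id`.
#' @param cgis CGI intervals (or NULL to skip).
#' @param tads `tad_set` or TAD intervals (or NULL to skip).
#' @param contacts contact data.frame (or NULL to skip).
#' @param genes gene data.frame (or NULL to skip).
#' @param meth methylation table (or NULL to skip).
#' @param promoter_halfwidth promoter half-width for contact linkage.
#' @return annotation data.frame, one row per element.
#' @export
annotate_elements <- function(elements, cgis = NULL, tads = NULL,
                              contacts = NULL, genes = NULL, meth = NULL,
                              promoter_halfwidth = 2000L) {
  out <- data.frame(id = elements$id, stringsAsFactors = FALSE)
  if (!is.null(cgis)) out$cgi_class <- cgi_class(elements, cgis)
  if (!is.null(tads)) {
    ts <- tad_section(elements, tads)
    out$tad_section <- ts$label
    out$tad_distance_bp <- ts$distance_bp
  }
  if (!is.null(genes)) {
    out$nearest_gene <- nearest_gene(elements, genes)
    if (!is.null(contacts)) {
      cg <- contact_genes(elements, contacts, genes, promoter_halfwidth)
      out$contact_genes <- vapply(cg, paste, character(1), collapse = ",")
    }
  }
  if (!is.null(meth)) out$mean_methylation <- mean_methylation(elements, meth)
  out
}
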