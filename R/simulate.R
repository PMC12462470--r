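# Synthetic-data generator: builds a complete, internally consistent dataset
# (elements with heavy-right-tailed signal, ternary activity with planted
# within-region correlation, TFBS occupancy, CGIs, methylation, TADs, genes
# with expression, chromatin contacts, variants with planted enrichment
# folds, LD pairs, per-sample cancer super-element sets with planted
# conversion recurrence) together with a ground-truth manifest, so every
# pipeline stage is testable without external downloads.

#' Default configuration of the synthetic dataset
#'
#' Returns the full parameter list of [simulate_ss_dataset()]; override any
#' entry through `...`.  The defaults define the study conditions the
#' generator emulates: a small three-chromosome genome, element counts and
#' sizes in the range of real silencer/enhancer calls, a log-normal signal
#' body with a planted Pareto tail concentrated in clusters (so the rank
#' curve has a genuine elbow), within-region activity correlation rho,
#' variant enrichment folds per element class, and cancer-sample SE sets
#' with a controlled conversion fraction and recurrence.
#'
#' @param ... named overrides of any default.
#' @return named list of parameters (class `ss_sim_config`).
#' @export
ss_sim_config <- function(...) {
  cfg <- list(
    chroms = c("chr1", "chr2", "chr3"),
    chrom_length = 1e7,
    # elements
    n_silencers = 1000, n_enhancers = 1000,
    n_ss_clusters = 40, n_se_clusters = 30,
    cluster_size_range = c(5L, 8L),
    cluster_element_length = c(2000, 5000),
    cluster_gap_range = c(500, 8000),
    cluster_margin = 13000,          # isolation beyond the stitching gap
    bg_element_length = c(800, 2500),
    # signal model: log-normal body + Pareto tail on planted clusters
    signal_meanlog = 1, signal_sdlog = 0.5,
    tail_shape = 1.5, tail_scale = 15, tail_truncation = 10,
    offmark_meanlog = -1, offmark_sdlog = 0.5,
    # activity model
    n_cell_types = 20L,
    rho = 0.6,
    activity_marginal = c(neg = 0.4, zero = 0.2, pos = 0.4),
    # TFBS model
    n_tfs = 168L, tf_bg_prob = 0.05, tf_region_tfs = 15L,
    tf_region_prob = 0.4,
    # CGI / methylation
    p_cgi = c(ss_component = 0.27, ts = 0.17, se_component = 0.17,
              te = 0.17),
    cgi_overlap_range = c(250, 1200),
    n_random_cgis = 150L, cgi_length = c(300, 1500),
    meth_sites_per_element = 3L,
    meth_beta_shapes = list(ss_component = c(1.5, 8), ts = c(2, 6),
                            se_component = c(3, 5), te = c(3, 5)),
    n_bg_meth_sites = 500L, bg_meth_shape = c(5, 2),
    # TADs, genes, contacts
    tad_length_range = c(4e5, 1.2e6),
    n_genes_per_chrom = 200L, promoter_halfwidth = 2000L,
    stem_expr_meanlog = 3, broad_expr_meanlog = 1, broad_expr_sdlog = 0.4,
    contact_bin = 10000L, contacts_per_component = 2L,
    contact_min_dist = 80000, contact_decay_bp = 300000,
    n_random_contacts = 1000L,
    retention_component = 0.09, retention_other = 0.12,
    n_cancer_new_contacts = 400L,
    # variants
    bcell_snv_rate_per_kb = 2000 / 30000,
    other_snv_rate_per_kb = 4000 / 30000,
    snv_fold = c(ss_component = 3.0, se_component = 3.0, ts = 1, te = 1),
    recurrent_prob = c(component = 0.035, elsewhere = 0.015),
    n_icgc_samples = 50L,
    n_gwas_snps = 400L, gwas_in_element_frac = 0.3,
    trait_probs = c(immune = 0.3, b_cell_cancer_trait = 0.1,
                    other_trait = 0.6),
    replicated_prob = c(component = 0.30, elsewhere = 0.15),
    n_ld_pairs = 150L,
    n_tlbp = 300L, tlbp_in_component_frac = 0.15,
    tlbp_bcell_prob = 0.3, tlbp_partner_se_prob = 0.26,
    # cancer samples and conversions
    n_cancer_samples = 10L,
    conversion_fraction = 0.13, conversion_recurrent_fraction = 0.25,
    se_to_ss_fraction = 0.048, se_to_ss_recurrent_fraction = 0.074,
    n_decoy_regions = 30L, decoy_length = c(5000, 20000)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "ss_sim_config")
}

# Truncated Pareto draws (x_m * U^(-1/shape), capped at trunc * x_m).
# Truncation keeps the tail heavy but bounded, as ChIP-seq intensities are:
# an unbounded draw can make one region dwarf every other planted cluster
# and push the rank-curve elbow above them.
rpareto <- function(n, shape, scale, trunc = Inf) {
  pmin(scale * runif(n)^(-1 / shape), scale * trunc)
}

# Lay out items (cluster layouts and background elements) along one
# chromosome with exchangeable random gaps; returns element rows.
place_chrom <- function(chrom, clusters, n_bg_sil, n_bg_enh, cfg) {
  lens_bg_s <- round(runif(n_bg_sil, cfg$bg_element_length[1],
                           cfg$bg_element_length[2]))
  lens_bg_e <- round(runif(n_bg_enh, cfg$bg_element_length[1],
                           cfg$bg_element_length[2]))
  # each cluster: element lengths + internal gaps + isolation margins
  cl_layout <- lapply(clusters, function(cl) {
    k <- cl$k
    el_len <- round(runif(k, cfg$cluster_element_length[1],
                          cfg$cluster_element_length[2]))
    gaps <- round(runif(k - 1, cfg$cluster_gap_range[1],
                        cfg$cluster_gap_range[2]))
    list(el_len = el_len, gaps = gaps,
         span = sum(el_len) + sum(gaps) + 2 * cfg$cluster_margin,
         class = cl$class, cluster_id = cl$cluster_id)
  })
  items <- c(
    lapply(cl_layout, function(x) c(x, list(type = "cluster"))),
    lapply(lens_bg_s, function(L) list(type = "bg", class = "silencer",
                                       span = L)),
    lapply(lens_bg_e, function(L) list(type = "bg", class = "enhancer",
                                       span = L))
  )
  items <- items[sample.int(length(items))]
  occupied <- sum(vapply(items, `[[`, numeric(1), "span"))
  free <- cfg$chrom_length - occupied
  if (free <= 0)
    stop("infeasible config: planted items exceed chromosome space on ",
         chrom)
  e <- stats::rexp(length(items) + 1)
  gaps <- floor(free * e / sum(e))
  pos <- 0
  rows <- vector("list", length(items))
  for (ii in seq_along(items)) {
    pos <- pos + gaps[ii]
    it <- items[[ii]]
    if (it$type == "bg") {
      rows[[ii]] <- data.frame(chrom = chrom, start = pos,
                               end = pos + it$span,
                               element_class = it$class,
                               cluster_id = NA_character_,
                               stringsAsFactors = FALSE)
      pos <- pos + it$span
    } else {
      p <- pos + cfg$cluster_margin
      starts <- p + cumsum(c(0, it$el_len[-length(it$el_len)] + it$gaps))
      rows[[ii]] <- data.frame(chrom = chrom, start = starts,
                               end = starts + it$el_len,
                               element_class = it$class,
                               cluster_id = it$cluster_id,
                               stringsAsFactors = FALSE)
      pos <- pos + it$span
    }
  }
  do.call(rbind, rows)
}

# Draw a ternary activity value set from the configured marginal.
r_ternary <- function(n, marg) {
  sample(c(-1L, 0L, 1L), n, replace = TRUE,
         prob = c(marg["neg"], marg["zero"], marg["pos"]))
}

#' Generate a synthetic super-silencer dataset
#'
#' Builds the complete input bundle for the pipeline under the study
#' conditions in `config`, deterministically from `(config, seed)`.  When
#' `out_dir` is given the bundle is also written to disk in the standard
#' formats (BED/BEDPE/TSV; see [write_ss_dataset()]).
#'
#' @param config parameter list from [ss_sim_config()].
#' @param seed integer RNG seed; the same `(config, seed)` always yields an
#'   identical bundle.
#' @param out_dir optional output directory.
#' @return list of class `ss_dataset` with entries `elements`,
#'   `peaks_by_cell_type`, `activity` (the generating ternary matrix),
#'   `tfbs`, `cgis`, `methylation`, `tads`, `genes`, `contacts_normal`,
#'   `contacts_cancer`, `variants`, `ld_pairs`, `cancer_se_by_sample`,
#'   `cancer_ss_by_sample` and `manifest` (the ground truth: planted
#'   parameters and planted element id sets).
#' @export
simulate_ss_dataset <- function(config = ss_sim_config(), seed = 1L,
                                out_dir = NULL) {
  cfg <- config
  with_local_seed(seed, {
    ## ---- elements -------------------------------------------------------
    n_chr <- length(cfg$chroms)
    mk_clusters <- function(n, class, prefix) {
      if (n == 0) return(list())
      lapply(seq_len(n), function(i)
        list(k = sample(cfg$cluster_size_range[1]:cfg$cluster_size_range[2],
                        1),
             class = class, cluster_id = paste0(prefix, i)))
    }
    cl_sil <- mk_clusters(cfg$n_ss_clusters, "silencer", "SSC")
    cl_enh <- mk_clusters(cfg$n_se_clusters, "enhancer", "SEC")
    # round-robin clusters over chromosomes
    chr_of <- function(cl) split(cl, rep_len(seq_len(n_chr), length(cl)))
    cl_by_chr <- lapply(seq_len(n_chr), function(i)
      c(chr_of(cl_sil)[[as.character(i)]] %||% list(),
        chr_of(cl_enh)[[as.character(i)]] %||% list()))
    n_planted_sil <- sum(vapply(cl_sil, `[[`, numeric(1), "k"))
    n_planted_enh <- sum(vapply(cl_enh, `[[`, numeric(1), "k"))
    if (n_planted_sil > cfg$n_silencers || n_planted_enh > cfg$n_enhancers)
      stop("infeasible config: planted cluster elements exceed element count")
    n_bg_sil <- cfg$n_silencers - n_planted_sil
    n_bg_enh <- cfg$n_enhancers - n_planted_enh
    bg_s_chr <- diff(floor(seq(0, n_bg_sil, length.out = n_chr + 1)))
    bg_e_chr <- diff(floor(seq(0, n_bg_enh, length.out = n_chr + 1)))
    elements <- do.call(rbind, lapply(seq_len(n_chr), function(i)
      place_chrom(cfg$chroms[i], cl_by_chr[[i]], bg_s_chr[i], bg_e_chr[i],
                  cfg)))
    elements <- elements[order(elements$chrom, elements$start), ]
    rownames(elements) <- NULL
    elements$id <- paste0(ifelse(elements$element_class == "silencer",
                                 "sil", "enh"),
                          sprintf("%05d", seq_len(nrow(elements))))
    ## signals: log-normal body, Pareto tail on planted cluster elements
    n_el <- nrow(elements)
    planted <- !is.na(elements$cluster_id)
    body <- rlnorm(n_el, cfg$signal_meanlog, cfg$signal_sdlog)
    tail_draw <- rpareto(n_el, cfg$tail_shape, cfg$tail_scale,
                         cfg$tail_truncation)
    own <- ifelse(planted, tail_draw, body)
    off <- rlnorm(n_el, cfg$offmark_meanlog, cfg$offmark_sdlog)
    is_sil <- elements$element_class == "silencer"
    elements$H3K27me3 <- ifelse(is_sil, own, off)
    elements$H3K27ac <- ifelse(is_sil, off, own)

    ## ---- activity (ternary, planted correlation rho) --------------------
    K <- cfg$n_cell_types
    cts <- sprintf("ct%02d", seq_len(K))
    act <- matrix(0L, n_el, K, dimnames = list(elements$id, cts))
    flip_p <- (1 - cfg$rho) / 2
    for (cl in unique(elements$cluster_id[planted])) {
      idx <- which(elements$cluster_id %in% cl)
      program <- r_ternary(K, cfg$activity_marginal)
      for (i in idx) {
        flips <- ifelse(runif(K) < flip_p, -1L, 1L)
        act[i, ] <- program * flips
      }
    }
    act[!planted, ] <- r_ternary(sum(!planted) * K, cfg$activity_marginal)
    # peaks realising the activity: me3 peak where a = -1, ac peak where +1
    peaks_by_cell_type <- lapply(seq_len(K), function(k) {
      list(ac = elements[act[, k] == 1L, c("chrom", "start", "end")],
           me3 = elements[act[, k] == -1L, c("chrom", "start", "end")])
    })
    names(peaks_by_cell_type) <- cts

    ## ---- TFBS matrix ----------------------------------------------------
    G <- cfg$n_tfs
    tfs <- sprintf("TF%03d", seq_len(G))
    tfbs <- matrix(rbinom(n_el * G, 1, cfg$tf_bg_prob), n_el, G,
                   dimnames = list(elements$id, tfs))
    for (cl in unique(elements$cluster_id[planted])) {
      idx <- which(elements$cluster_id %in% cl)
      region_tfs <- sample.int(G, cfg$tf_region_tfs)
      add <- matrix(rbinom(length(idx) * length(region_tfs), 1,
                           cfg$tf_region_prob),
                    length(idx), length(region_tfs))
      tfbs[idx, region_tfs] <- pmax(tfbs[idx, region_tfs], add)
    }

    ## ---- CGIs and methylation ------------------------------------------
    el_group <- ifelse(is_sil,
                       ifelse(planted, "ss_component", "ts"),
                       ifelse(planted, "se_component", "te"))
    has_cgi <- which(runif(n_el) < cfg$p_cgi[el_group])
    ov <- pmin(round(runif(length(has_cgi), cfg$cgi_overlap_range[1],
                           cfg$cgi_overlap_range[2])),
               elements$end[has_cgi] - elements$start[has_cgi])
    slack <- pmax(0, elements$end[has_cgi] - elements$start[has_cgi] - ov)
    cgi_s <- elements$start[has_cgi] + round(runif(length(has_cgi), 0, slack))
    rnd_len <- round(runif(cfg$n_random_cgis, cfg$cgi_length[1],
                           cfg$cgi_length[2]))
    rnd_start <- round(runif(cfg$n_random_cgis, 0,
                             cfg$chrom_length - max(rnd_len)))
    cgis <- rbind(
      data.frame(chrom = elements$chrom[has_cgi], start = cgi_s,
                 end = cgi_s + ov),
      data.frame(chrom = sample(cfg$chroms, cfg$n_random_cgis,
                                replace = TRUE),
                 start = rnd_start, end = rnd_start + rnd_len))
    cgis <- cgis[order(cgis$chrom, cgis$start), ]
    rownames(cgis) <- NULL
    # per-element CpG sites with class-dependent beta
    ns <- cfg$meth_sites_per_element
    site_el <- rep(seq_len(n_el), each = ns)
    shapes <- do.call(rbind, cfg$meth_beta_shapes[el_group[site_el]])
    el_sites <- data.frame(
      chrom = elements$chrom[site_el],
      pos = round(runif(length(site_el), elements$start[site_el],
                        elements$end[site_el] - 1)),
      beta = rbeta(length(site_el), shapes[, 1], shapes[, 2]))
    bg_sites <- data.frame(
      chrom = sample(cfg$chroms, cfg$n_bg_meth_sites, replace = TRUE),
      pos = round(runif(cfg$n_bg_meth_sites, 0, cfg$chrom_length - 1)),
      beta = rbeta(cfg$n_bg_meth_sites, cfg$bg_meth_shape[1],
                   cfg$bg_meth_shape[2]))
    methylation <- rbind(el_sites, bg_sites)

    ## ---- TADs -----------------------------------------------------------
    tad_rows <- lapply(cfg$chroms, function(chr) {
      pos <- 0; s <- numeric(0); e <- numeric(0)
      while (pos < cfg$chrom_length) {
        L <- round(runif(1, cfg$tad_length_range[1], cfg$tad_length_range[2]))
        if (pos + L > cfg$chrom_length) L <- cfg$chrom_length - pos
        if (L < 5e4) break
        s <- c(s, pos); e <- c(e, pos + L); pos <- pos + L
      }
      data.frame(chrom = chr, start = s, end = e)
    })
    tads <- do.call(rbind, tad_rows)

    ## ---- genes and expression ------------------------------------------
    sil_clusters <- unique(elements$cluster_id[planted & is_sil])
    target_rows <- lapply(sil_clusters, function(cl) {
      idx <- which(elements$cluster_id %in% cl)
      edge <- max(elements$end[idx])
      data.frame(chrom = elements$chrom[idx[1]],
                 tss = edge + round(runif(1, 5000, 30000)),
                 target_of = cl, stringsAsFactors = FALSE)
    })
    targets <- do.call(rbind, target_rows)
    if (is.null(targets))
      targets <- data.frame(chrom = character(0), tss = numeric(0),
                            target_of = character(0))
    n_other <- cfg$n_genes_per_chrom * n_chr - nrow(targets)
    others <- data.frame(
      chrom = sample(cfg$chroms, n_other, replace = TRUE),
      tss = round(runif(n_other, 0, cfg$chrom_length - 1)),
      target_of = NA_character_, stringsAsFactors = FALSE)
    genes <- rbind(targets, others)
    genes <- genes[order(genes$chrom, genes$tss), ]
    rownames(genes) <- NULL
    genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    expr <- matrix(rlnorm(nrow(genes) * K, cfg$broad_expr_meanlog,
                          cfg$broad_expr_sdlog),
                   nrow(genes), K, dimnames = list(genes$gene_id, cts))
    is_target <- !is.na(genes$target_of)
    for (i in which(is_target)) {
      # repressed in the differentiated reference type (ct01), high in a
      # couple of stem-like types: low expression near the SS, high tau
      prof <- rep(0.05, K)
      stem <- sample(2:K, 2)
      prof[stem] <- rlnorm(2, cfg$stem_expr_meanlog, 0.3)
      expr[i, ] <- prof
    }
    genes <- cbind(genes[, c("gene_id", "chrom", "tss", "strand",
                             "target_of")], expr)

    ## ---- chromatin contacts --------------------------------------------
    bin <- cfg$contact_bin
    bin_of <- function(p) floor(p / bin) * bin
    mk_contact <- function(chrom, p1, p2) {
      b1 <- bin_of(p1); b2 <- bin_of(p2)
      data.frame(chrom = chrom, start1 = pmin(b1, b2),
                 end1 = pmin(b1, b2) + bin, start2 = pmax(b1, b2),
                 end2 = pmax(b1, b2) + bin, stringsAsFactors = FALSE)
    }
    comp_idx <- rep(which(planted), cfg$contacts_per_component)
    cm <- (elements$start[comp_idx] + elements$end[comp_idx]) / 2
    cd <- cfg$contact_min_dist +
      stats::rexp(length(comp_idx), 1 / cfg$contact_decay_bp)
    cp2 <- pmin(pmax(cm + ifelse(runif(length(comp_idx)) < 0.5, -cd, cd),
                     0), cfg$chrom_length - bin)
    anchor_rows <- list(mk_contact(elements$chrom[comp_idx], cm, cp2))
    anchor_src <- elements$id[comp_idx]
    # promoter contacts from each SS target gene to one of its components
    prom_rows <- lapply(which(is_target), function(gi) {
      cl <- genes$target_of[gi]
      idx <- which(elements$cluster_id %in% cl)
      i <- idx[sample.int(length(idx), 1)]
      mk_contact(genes$chrom[gi], genes$tss[gi],
                 (elements$start[i] + elements$end[i]) / 2)
    })
    rnd_chr <- sample(cfg$chroms, cfg$n_random_contacts, replace = TRUE)
    p1 <- runif(cfg$n_random_contacts, 0, cfg$chrom_length - bin)
    d <- cfg$contact_min_dist +
      stats::rexp(cfg$n_random_contacts, 1 / cfg$contact_decay_bp)
    p2 <- pmin(pmax(p1 + ifelse(runif(cfg$n_random_contacts) < 0.5, -d, d),
                    0), cfg$chrom_length - bin)
    rnd_rows <- mk_contact(rnd_chr, p1, p2)
    contacts_normal <- rbind(do.call(rbind, anchor_rows),
                             do.call(rbind, prom_rows), rnd_rows)
    rownames(contacts_normal) <- NULL
    # cancer condition: planted retention of normal contacts + new contacts
    is_comp_contact <- seq_len(nrow(contacts_normal)) <=
      length(anchor_src)
    keep_p <- ifelse(is_comp_contact, cfg$retention_component,
                     cfg$retention_other)
    kept <- contacts_normal[runif(nrow(contacts_normal)) < keep_p, ]
    new_chr <- sample(cfg$chroms, cfg$n_cancer_new_contacts, replace = TRUE)
    q1 <- runif(cfg$n_cancer_new_contacts, 0, cfg$chrom_length - bin)
    d2 <- cfg$contact_min_dist +
      stats::rexp(cfg$n_cancer_new_contacts, 1 / cfg$contact_decay_bp)
    q2 <- pmin(pmax(q1 + ifelse(runif(cfg$n_cancer_new_contacts) < 0.5,
                                -d2, d2), 0), cfg$chrom_length - bin)
    contacts_cancer <- rbind(kept, mk_contact(new_chr, q1, q2))
    rownames(contacts_cancer) <- NULL

    ## ---- variants -------------------------------------------------------
    genome_kb <- n_chr * cfg$chrom_length / 1000
    unif_pos <- function(n) data.frame(
      chrom = sample(cfg$chroms, n, replace = TRUE),
      pos = round(runif(n, 0, cfg$chrom_length - 1)))
    pos_in_set <- function(n, set) {
      m <- merge_intervals(set)
      w <- m$end - m$start
      pick <- sample.int(nrow(m), n, replace = TRUE, prob = w)
      data.frame(chrom = m$chrom[pick],
                 pos = floor(runif(n, m$start[pick], m$end[pick])))
    }
    sets_by_group <- split(elements[, c("chrom", "start", "end")], el_group)
    # background B-cell SNVs genome-wide, plus planted extras per class so
    # that density(set) / density(genome) equals the configured fold
    n_bg_b <- rpois(1, cfg$bcell_snv_rate_per_kb * genome_kb)
    bcell <- unif_pos(n_bg_b)
    extra_rows <- list()
    for (g in names(cfg$snv_fold)) {
      fold <- cfg$snv_fold[[g]]
      if (fold <= 1 || is.null(sets_by_group[[g]])) next
      set <- sets_by_group[[g]]
      f <- merged_length_bp(set) / (genome_kb * 1000)
      xr <- cfg$bcell_snv_rate_per_kb * (fold - 1) / (1 - fold * f)
      n_x <- rpois(1, xr * merged_length_bp(set) / 1000)
      if (n_x > 0) extra_rows[[g]] <- pos_in_set(n_x, set)
    }
    bcell <- rbind(bcell, do.call(rbind, extra_rows))
    n_other <- rpois(1, cfg$other_snv_rate_per_kb * genome_kb)
    otherv <- unif_pos(n_other)
    snv <- rbind(
      data.frame(bcell, vtype = "SNV", categories = "b_cell_cancer"),
      data.frame(otherv, vtype = "SNV", categories = "other_cancer"))
    # recurrence: more recurrent inside components
    comp_set <- rbind(sets_by_group[["ss_component"]],
                      sets_by_group[["se_component"]])
    in_comp <- positions_in_intervals(snv[, c("chrom", "pos")], comp_set)
    p_rec <- ifelse(in_comp, cfg$recurrent_prob["component"],
                    cfg$recurrent_prob["elsewhere"])
    icgc <- sprintf("icgc_s%02d", seq_len(cfg$n_icgc_samples))
    snv$samples <- vapply(p_rec, function(p) {
      k <- if (runif(1) < p) sample(2:4, 1) else 1L
      paste(sample(icgc, k), collapse = ",")
    }, character(1))
    snv$studies <- ""
    # GWAS SNPs
    n_g <- cfg$n_gwas_snps
    n_in <- round(n_g * cfg$gwas_in_element_frac)
    gw_pos <- rbind(pos_in_set(n_in, elements), unif_pos(n_g - n_in))
    gwas <- data.frame(gw_pos, vtype = "SNP",
                       categories = sample(names(cfg$trait_probs), n_g,
                                           replace = TRUE,
                                           prob = cfg$trait_probs))
    gw_in_comp <- positions_in_intervals(gwas[, c("chrom", "pos")], comp_set)
    p_rep <- ifelse(gw_in_comp, cfg$replicated_prob["component"],
                    cfg$replicated_prob["elsewhere"])
    studies <- sprintf("study%02d", 1:12)
    gwas$studies <- vapply(p_rep, function(p) {
      k <- if (runif(1) < p) sample(2:4, 1) else 1L
      paste(sample(studies, k), collapse = ",")
    }, character(1))
    gwas$samples <- ""
    # TLBPs with partner breakpoints
    n_t <- cfg$n_tlbp
    ss_set <- sets_by_group[["ss_component"]]
    se_set <- sets_by_group[["se_component"]]
    n_tc <- if (is.null(ss_set)) 0L
            else round(n_t * cfg$tlbp_in_component_frac)
    tl_pos <- rbind(if (n_tc > 0) pos_in_set(n_tc, ss_set),
                    unif_pos(n_t - n_tc))
    partner_in_se <- !is.null(se_set) &
      runif(n_t) < cfg$tlbp_partner_se_prob
    tl_partner <- unif_pos(n_t)
    if (any(partner_in_se)) {
      pin <- pos_in_set(sum(partner_in_se), se_set)
      tl_partner[partner_in_se, ] <- pin
    }
    tlbp <- data.frame(tl_pos, vtype = "TLBP",
                       categories = ifelse(runif(n_t) < cfg$tlbp_bcell_prob,
                                           "b_cell_cancer", "other_cancer"),
                       samples = sample(icgc, n_t, replace = TRUE),
                       studies = "")
    tlbp$chrom2 <- tl_partner$chrom
    tlbp$pos2 <- tl_partner$pos
    snv$chrom2 <- NA_character_; snv$pos2 <- NA_real_
    gwas$chrom2 <- NA_character_; gwas$pos2 <- NA_real_
    variants <- rbind(snv, gwas, tlbp)
    variants$id <- paste0("v", sprintf("%06d", seq_len(nrow(variants))))
    rownames(variants) <- NULL
    # LD pairs among GWAS SNP ids
    gwas_ids <- variants$id[variants$vtype == "SNP"]
    ld_a <- sample(gwas_ids, cfg$n_ld_pairs, replace = TRUE)
    ld_b <- sample(gwas_ids, cfg$n_ld_pairs, replace = TRUE)
    ok <- ld_a != ld_b
    ld_pairs <- data.frame(snp_a = ld_a[ok], snp_b = ld_b[ok],
                           r2 = round(runif(sum(ok), 0.4, 0.999), 3))

    ## ---- cancer sample SE/SS sets with planted conversions -------------
    n_smp <- cfg$n_cancer_samples
    smp <- sprintf("sample%02d", seq_len(n_smp))
    plant_conversions <- function(source_idx, frac, rec_frac) {
      n_src <- length(source_idx)
      n_conv <- round(frac * n_src)
      conv <- sample(source_idx, n_conv)
      n_rec <- round(rec_frac * n_conv)
      rec <- if (n_rec > 0) conv[seq_len(n_rec)] else integer(0)
      hits <- lapply(conv, function(i) {
        k <- if (i %in% rec) sample((floor(n_smp / 2) + 1):n_smp, 1)
             else sample.int(floor(n_smp / 2), 1)
        sample(smp, k)
      })
      list(conv = conv, rec = rec, hits = hits)
    }
    mk_sample_sets <- function(plan, avoid) {
      av_m <- merge_intervals(avoid)
      # decoy pool: random regions rejected against every element, so that
      # accidental overlaps never inflate the planted conversion counts
      n_pool <- cfg$n_decoy_regions * n_smp * 2L
      L <- round(runif(n_pool, cfg$decoy_length[1], cfg$decoy_length[2]))
      st <- round(runif(n_pool, 0, cfg$chrom_length - L))
      cand <- data.frame(chrom = sample(cfg$chroms, n_pool, replace = TRUE),
                         start = st, end = st + L)
      cand <- cand[max_overlap_bp(cand, av_m) == 0, , drop = FALSE]
      sets <- lapply(smp, function(s) {
        hit_el <- plan$conv[vapply(plan$hits, function(h) s %in% h,
                                   logical(1))]
        rows <- data.frame(chrom = elements$chrom[hit_el],
                           start = pmax(0, elements$start[hit_el] - 500),
                           end = elements$end[hit_el] + 500)
        dec <- cand[sample.int(nrow(cand),
                               min(cfg$n_decoy_regions, nrow(cand))), ]
        out <- rbind(rows, dec)
        out <- out[order(out$chrom, out$start), , drop = FALSE]
        rownames(out) <- NULL
        out
      })
      names(sets) <- smp
      sets
    }
    all_el <- elements[, c("chrom", "start", "end")]
    plan_se <- plant_conversions(which(planted & is_sil),
                                 cfg$conversion_fraction,
                                 cfg$conversion_recurrent_fraction)
    cancer_se_by_sample <- mk_sample_sets(plan_se, all_el)
    plan_ss <- plant_conversions(which(planted & !is_sil),
                                 cfg$se_to_ss_fraction,
                                 cfg$se_to_ss_recurrent_fraction)
    cancer_ss_by_sample <- mk_sample_sets(plan_ss, all_el)

    ## ---- manifest -------------------------------------------------------
    manifest <- list(
      seed = seed,
      config = unclass(cfg),
      n_elements = n_el,
      n_planted_ss_clusters = cfg$n_ss_clusters,
      n_planted_se_clusters = cfg$n_se_clusters,
      planted_ss_components = elements$id[planted & is_sil],
      planted_se_components = elements$id[planted & !is_sil],
      planted_rho = cfg$rho,
      planted_snv_fold = cfg$snv_fold,
      planted_conversion_fraction = cfg$conversion_fraction,
      planted_conversion_recurrent_fraction =
        cfg$conversion_recurrent_fraction,
      planted_converted_ids = elements$id[plan_se$conv],
      planted_recurrent_ids = elements$id[plan_se$rec],
      planted_retention_component = cfg$retention_component,
      planted_retention_other = cfg$retention_other,
      n_cancer_samples = n_smp
    )
    bundle <- structure(list(
      elements = elements, peaks_by_cell_type = peaks_by_cell_type,
      activity = act, tfbs = tfbs, cgis = cgis, methylation = methylation,
      tads = tads, genes = genes, contacts_normal = contacts_normal,
      contacts_cancer = contacts_cancer, variants = variants,
      ld_pairs = ld_pairs, cancer_se_by_sample = cancer_se_by_sample,
      cancer_ss_by_sample = cancer_ss_by_sample, manifest = manifest),
      class = "ss_dataset")
    if (!is.null(out_dir)) write_ss_dataset(bundle, out_dir)
    bundle
  })
}

#' @export
print.ss_dataset <- function(x, ...) {
  m <- x$manifest
  cat("Synthetic super-silencer dataset (seed ", m$seed, ")\n", sep = "")
  cat("  elements: ", nrow(x$elements), " (",
      length(m$planted_ss_components), " planted SS components, ",
      length(m$planted_se_components), " planted SE components)\n", sep = "")
  cat("  cell types: ", ncol(x$activity), "; TFs: ", ncol(x$tfbs), "\n",
      sep = "")
  cat("  variants: ", nrow(x$variants), "; cancer samples: ",
      m$n_cancer_samples, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits the bundle in the standard formats the pipeline readers consume:
#' scored BED for elements, per-cell-type peak BEDs, TSV matrices, BED for
#' CGIs/TADs, BEDPE for contacts, TSV for variants/LD/genes/methylation,
#' one BED per cancer sample, and a JSON manifest (when jsonlite is
#' available).
#'
#' @param bundle an `ss_dataset` from [simulate_ss_dataset()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_ss_dataset <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  el <- bundle$elements
  sil <- el[el$element_class == "silencer", ]
  enh <- el[el$element_class == "enhancer", ]
  write_bed(sil, p("silencers.bed"), name_col = "id", score_col = "H3K27me3")
  write_bed(enh, p("enhancers.bed"), name_col = "id", score_col = "H3K27ac")
  dir.create(p("peaks"), showWarnings = FALSE)
  for (ct in names(bundle$peaks_by_cell_type)) {
    write_bed(bundle$peaks_by_cell_type[[ct]]$ac, p("peaks",
              paste0(ct, "_H3K27ac.bed")))
    write_bed(bundle$peaks_by_cell_type[[ct]]$me3, p("peaks",
              paste0(ct, "_H3K27me3.bed")))
  }
  write.table(data.frame(id = rownames(bundle$tfbs), bundle$tfbs,
                         check.names = FALSE),
              p("tfbs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed(bundle$cgis, p("cgi.bed"))
  write.table(bundle$methylation, p("methylation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_bed(bundle$tads, p("tads.bed"))
  write.table(bundle$genes, p("genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_bedpe(bundle$contacts_normal, p("contacts_normal.bedpe"))
  write_bedpe(bundle$contacts_cancer, p("contacts_cancer.bedpe"))
  write_variants(bundle$variants, p("variants.tsv"))
  write.table(bundle$ld_pairs, p("ld_pairs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (cond in c("cancer_se_by_sample", "cancer_ss_by_sample")) {
    d <- sub("_by_sample", "", cond)
    dir.create(p(d), showWarnings = FALSE)
    for (s in names(bundle[[cond]]))
      write_bed(bundle[[cond]][[s]], p(d, paste0(s, ".bed")))
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(bundle$manifest, p("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out_dir)
}

#' Compare planted parameters against recovered pipeline results
#'
#' Builds the parameter-recovery table: planted value, recovered value,
#' tolerance, pass/fail, for the quantities the ground-truth manifest pins
#' down (number of super regions, cooperativity separation, variant
#' enrichment fold, conversion fraction and recurrence).
#'
#' @param manifest the `manifest` of an `ss_dataset`.
#' @param results pipeline results from [run_ss_pipeline()] on the same
#'   bundle.
#' @param tolerances named list of tolerances: `super_rel` (relative, on
#'   the super-region count), `fold_rel` (relative, on the SNV fold),
#'   `conversion_abs`, `recurrence_abs` (absolute).
#' @return data.frame with columns `quantity`, `planted`, `recovered`,
#'   `tolerance`, `pass`.
#' @export
plant_report <- function(manifest, results,
                         tolerances = list(super_rel = 0.5, fold_rel = 0.2,
                                           conversion_abs = 0.02,
                                           recurrence_abs = 0.05)) {
  if (!identical(manifest$seed, results$seed))
    stop("manifest/seed mismatch: manifest seed ", manifest$seed,
         ", results seed ", results$seed)
  rows <- list()
  add <- function(q, planted, recovered, tol, pass)
    rows[[length(rows) + 1]] <<- data.frame(
      quantity = q, planted = planted, recovered = recovered,
      tolerance = tol, pass = pass, stringsAsFactors = FALSE)
  n_sup <- results$ss_summary$n_super
  add("n_super_regions", manifest$n_planted_ss_clusters, n_sup,
      tolerances$super_rel,
      abs(n_sup - manifest$n_planted_ss_clusters) <=
        tolerances$super_rel * manifest$n_planted_ss_clusters)
  sep <- results$cooperativity_within_median -
    results$cooperativity_matched_median
  add("cooperativity_separation", manifest$planted_rho^2, sep, NA,
      if (manifest$planted_rho > 0) sep > 0 && results$cooperativity_p < 0.01
      else TRUE)
  fold <- results$snv_fold_component
  planted_fold <- manifest$planted_snv_fold[["ss_component"]]
  add("snv_fold_component", planted_fold, fold, tolerances$fold_rel,
      abs(fold - planted_fold) <= tolerances$fold_rel * planted_fold)
  cf <- results$conversion$converted_fraction
  add("conversion_fraction", manifest$planted_conversion_fraction, cf,
      tolerances$conversion_abs,
      abs(cf - manifest$planted_conversion_fraction) <=
        tolerances$conversion_abs)
  rf <- results$conversion$recurrent_over_half_fraction
  add("recurrence_fraction",
      manifest$planted_conversion_recurrent_fraction, rf,
      tolerances$recurrence_abs,
      abs(rf - manifest$planted_conversion_recurrent_fraction) <=
        tolerances$recurrence_abs)
  do.call(rbind, rows)
}
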