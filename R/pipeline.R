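# End-to-end driver: super-region calling on both element classes,
# cooperativity, annotation, variant enrichment, conversion detection, and
# the aggregated report tables.

#' Run the full super-silencer analysis pipeline
#'
#' Executes every stage on a dataset bundle (typically from
#' [simulate_ss_dataset()] or [read_ss_dataset()]): SS and SE calling,
#' cooperativity of SS components against distance-matched and random
#' backgrounds, element annotation (CGI status, TAD section, gene linkage,
#' methylation), variant density/fraction enrichment with GWAS LD
#' expansion, SS-to-SE (and SE-to-SS) conversion detection with recurrence,
#' and chromatin-contact retention.  Missing bundle entries degrade
#' gracefully: the corresponding tables are omitted with a warning.
#'
#' @param bundle `ss_dataset`-style list; required entries `elements`; all
#'   other entries optional.
#' @param seed RNG seed for background sampling and permutations.
#' @param out_dir optional directory; report tables are written as TSV.
#' @param gap_bp stitching gap (default 12,500 bp).
#' @param n_background background pairs per group for cooperativity.
#' @param n_perm permutations for expected contact retention.
#' @return list of results and report tables (see Details), of class
#'   `ss_report`.
#' @details The returned list contains: `fit_ss`, `fit_se` (super_call
#'   objects), `ss_summary`, `se_summary`, `cooperativity` (+ group
#'   medians/p under `cooperativity_*`), `annotation`, `element_counts`,
#'   `cgi_table`, `tad_table`, `expression_table`, `snv_table`,
#'   `gwas_table`, `tlbp_table`, `snv_fold_component`, `conversion` and
#'   `conversion_records`, `contact_retention`, `expected_retention`,
#'   `seed`.
#' @export
run_ss_pipeline <- function(bundle, seed = 1L, out_dir = NULL,
                            gap_bp = 12500L, n_background = 500L,
                            n_perm = 200L) {
  el <- bundle$elements
  if (is.null(el)) stop("stage call: bundle lacks 'elements'")
  res <- list(seed = seed)
  sil <- el[el$element_class == "silencer", ]
  enh <- el[el$element_class == "enhancer", ]

  ## stage: call
  res$fit_ss <- call_super_regions(sil, mark = "H3K27me3", gap_bp = gap_bp)
  res$fit_se <- call_super_regions(enh, mark = "H3K27ac", gap_bp = gap_bp)
  res$ss_summary <- summary(res$fit_ss)
  res$se_summary <- summary(res$fit_se)
  groups <- list(ss_component = components(res$fit_ss),
                 ts = typicals(res$fit_ss),
                 se_component = components(res$fit_se),
                 te = typicals(res$fit_se))
  res$element_counts <- data.frame(
    group = names(groups),
    n = vapply(groups, nrow, integer(1)),
    mean_width_bp = vapply(groups, function(g)
      mean(g$end - g$start), numeric(1)), row.names = NULL)

  ## stage: cooccur
  if (!is.null(bundle$activity) || !is.null(bundle$peaks_by_cell_type)) {
    act <- bundle$activity %||%
      build_activity_matrix(el, bundle$peaks_by_cell_type)
    coop <- tryCatch(
      cooperativity_analysis(res$fit_ss, act, tfbs = bundle$tfbs,
                             n_background = n_background, seed = seed),
      error = function(e) { warning("stage cooccur skipped: ",
                                    conditionMessage(e)); NULL })
    if (!is.null(coop)) {
      res$cooperativity <- coop
      meds <- setNames(coop$summary$cooperativity, coop$summary$group)
      res$cooperativity_within_median <- unname(meds["within_region"])
      res$cooperativity_matched_median <- unname(meds["matched_background"])
      res$cooperativity_p <- unname(coop$tests["vs_matched"])
    }
  } else warning("stage cooccur skipped: no activity data in bundle")

  ## stage: annotate
  ann_el <- rbind(cbind(groups$ss_component, group = "ss_component"),
                  cbind(groups$ts, group = "ts"),
                  cbind(groups$se_component, group = "se_component"),
                  cbind(groups$te, group = "te"))
  tads <- if (!is.null(bundle$tads)) load_tads(bundle$tads) else NULL
  res$annotation <- annotate_elements(
    ann_el, cgis = bundle$cgis, tads = tads, contacts =
      bundle$contacts_normal, genes = bundle$genes,
    meth = bundle$methylation)
  res$annotation$group <- ann_el$group
  if (!is.null(bundle$cgis)) {
    res$cgi_table <- aggregate(cgi_class ~ group, res$annotation,
                               function(x) mean(x == "CGI"))
    names(res$cgi_table) <- c("group", "cgi_fraction")
  }
  if (!is.null(tads)) {
    tt <- table(res$annotation$group, res$annotation$tad_section)
    res$tad_table <- as.data.frame.matrix(prop.table(tt, 1))
    res$tad_table <- cbind(group = rownames(res$tad_table), res$tad_table,
                           row.names = NULL)
  } else warning("TAD table omitted: no TADs in bundle")
  if (!is.null(bundle$genes)) {
    cts <- setdiff(names(bundle$genes),
                   c("gene_id", "chrom", "tss", "strand", "target_of"))
    expr <- as.matrix(bundle$genes[, cts])
    rownames(expr) <- bundle$genes$gene_id
    gene_tau <- tau(expr)
    ref_ct <- cts[1]
    ng <- res$annotation$nearest_gene
    res$expression_table <- do.call(rbind, lapply(
      split(ng, res$annotation$group), function(g) {
        g <- g[!is.na(g)]
        data.frame(n_genes = length(unique(g)),
                   median_expression = median(expr[unique(g), ref_ct]),
                   median_tau = median(gene_tau[unique(g)]))
      }))
    res$expression_table <- cbind(group = rownames(res$expression_table),
                                  res$expression_table, row.names = NULL)
    res$gene_tau <- gene_tau
  }

  ## stage: enrich
  if (!is.null(bundle$variants)) {
    v <- bundle$variants
    snv <- v[v$vtype == "SNV", ]
    genome_kb <- if (!is.null(bundle$manifest))
      length(bundle$manifest$config$chroms) *
        bundle$manifest$config$chrom_length / 1000
    else NULL
    bcell_snv <- snv[grepl("b_cell_cancer", snv$categories), ]
    res$snv_table <- variant_enrichment(snv, groups,
                                        category = "b_cell_cancer")
    flank_dens <- density_per_kb(bcell_snv,
                                 flanking_regions(groups$ss_component))
    res$snv_table$flank_density_ss <- c(flank_dens,
                                        rep(NA, nrow(res$snv_table) - 1))
    if (!is.null(genome_kb)) {
      genome_density <- nrow(bcell_snv) / genome_kb
      res$snv_fold_component <-
        density_per_kb(bcell_snv, groups$ss_component) / genome_density
      res$snv_fold_by_group <- vapply(groups, function(g)
        density_per_kb(bcell_snv, g) / genome_density, numeric(1))
    }
    res$snv_recurrent <- vapply(groups, function(g) {
      inside <- positions_in_intervals(snv[, c("chrom", "pos")],
                                       merge_intervals(g))
      if (!any(inside)) return(NA_real_)
      recurrent_fraction(snv[inside, ])
    }, numeric(1))
    # GWAS SNPs: LD expansion then replicated fraction per group
    gw <- v[v$vtype == "SNP", ]
    if (nrow(gw) > 0) {
      expanded <- ld_expand(gw$id, bundle$ld_pairs %||%
                              data.frame(snp_a = character(0),
                                         snp_b = character(0),
                                         r2 = numeric(0)))
      res$gwas_table <- do.call(rbind, lapply(names(groups), function(nm) {
        inside <- positions_in_intervals(gw[, c("chrom", "pos")],
                                         merge_intervals(groups[[nm]]))
        g_in <- gw[inside, , drop = FALSE]
        data.frame(group = nm, n_snps = nrow(g_in),
                   density_per_kb = density_per_kb(g_in, groups[[nm]]),
                   replicated_fraction = if (nrow(g_in) > 0)
                     tryCatch(replicated_fraction(g_in),
                              error = function(e) NA_real_) else NA_real_)
      }))
      res$n_ld_expanded <- length(expanded)
    }
    # TLBPs: fractions in and by (+/- 50 kb) each group; partner classes
    tl <- v[v$vtype == "TLBP", ]
    if (nrow(tl) > 0) {
      res$tlbp_table <- do.call(rbind, lapply(names(groups), function(nm) {
        m <- merge_intervals(groups[[nm]])
        in_set <- positions_in_intervals(tl[, c("chrom", "pos")], m)
        fl <- flanking_regions(groups[[nm]])
        by_set <- positions_in_intervals(tl[, c("chrom", "pos")], fl)
        frac_of <- function(sel) {
          t_in <- tl[sel, , drop = FALSE]
          if (nrow(t_in) == 0) return(NA_real_)
          category_fraction(t_in, "b_cell_cancer")
        }
        data.frame(group = nm, n_in = sum(in_set),
                   bcell_fraction_in = frac_of(in_set),
                   bcell_fraction_by = frac_of(by_set))
      }))
      partners <- data.frame(chrom = tl$chrom2, pos = tl$pos2)
      ok <- complete.cases(partners)
      if (any(ok)) {
        cls <- classify_tl_partner(partners[ok, , drop = FALSE], groups)
        res$tl_partner_table <- as.data.frame(table(partner_class = cls))
      }
    }
  } else warning("stage enrich skipped: no variants in bundle")

  ## stage: convert
  if (!is.null(bundle$cancer_se_by_sample)) {
    comp <- groups$ss_component
    if (nrow(comp) > 0) {
      res$conversion_records <- detect_conversions(
        comp, bundle$cancer_se_by_sample, direction = "SS_to_SE")
      res$conversion <- recurrence_summary(res$conversion_records,
                                           nrow(comp))
      ts_rec <- detect_conversions(groups$ts, bundle$cancer_se_by_sample,
                                   direction = "TS_to_SE")
      res$ts_conversion <- recurrence_summary(ts_rec, nrow(groups$ts))
    }
    if (!is.null(bundle$cancer_ss_by_sample) &&
        nrow(groups$se_component) > 0) {
      rec <- detect_conversions(groups$se_component,
                                bundle$cancer_ss_by_sample,
                                direction = "SE_to_SS")
      res$se_to_ss <- recurrence_summary(rec, nrow(groups$se_component))
    }
    if (!is.null(bundle$contacts_normal) &&
        !is.null(bundle$contacts_cancer) && nrow(comp) > 0) {
      res$contact_retention <- contact_retention(
        bundle$contacts_normal, bundle$contacts_cancer, comp)
      res$expected_retention <- expected_retention(
        bundle$contacts_normal, bundle$contacts_cancer, comp,
        pool = groups$ts, n_perm = n_perm, seed = seed)$expected
    }
  } else warning("stage convert skipped: no cancer sample sets in bundle")

  class(res) <- "ss_report"
  if (!is.null(out_dir)) write_ss_report(res, out_dir)
  res
}

#' @export
print.ss_report <- function(x, ...) {
  cat("Super-silencer pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  SS: %d regions (%d super), %d components\n",
              x$ss_summary$n_regions, x$ss_summary$n_super,
              x$ss_summary$n_components))
  cat(sprintf("  SE: %d regions (%d super), %d components\n",
              x$se_summary$n_regions, x$se_summary$n_super,
              x$se_summary$n_components))
  if (!is.null(x$cooperativity_within_median))
    cat(sprintf("  cooperativity median within %.3f vs matched %.3f (p = %.3g)\n",
                x$cooperativity_within_median,
                x$cooperativity_matched_median, x$cooperativity_p))
  if (!is.null(x$snv_fold_component))
    cat(sprintf("  B-cell SNV fold in SS components vs genome: %.2f\n",
                x$snv_fold_component))
  if (!is.null(x$conversion))
    cat(sprintf("  SS-to-SE: %.1f%% converted, %.1f%% recurrent over half\n",
                100 * x$conversion$converted_fraction,
                100 * x$conversion$recurrent_over_half_fraction))
  if (!is.null(x$contact_retention))
    cat(sprintf("  contact retention %.3f (expected by chance %.3f)\n",
                x$contact_retention, x$expected_retention))
  invisible(x)
}

#' Write the pipeline report tables as TSV
#'
#' @param res `ss_report` from [run_ss_pipeline()].
#' @param out_dir output directory.
#' @export
write_ss_report <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(tbl, name) {
    if (!is.null(tbl))
      write.table(tbl, file.path(out_dir, paste0(name, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(res$element_counts, "element_counts")
  wr(res$cgi_table, "cgi_fractions")
  wr(res$tad_table, "tad_sections")
  wr(res$expression_table, "expression_tau")
  wr(res$snv_table, "snv_enrichment")
  wr(res$gwas_table, "gwas_enrichment")
  wr(res$tlbp_table, "tlbp_fractions")
  wr(res$tl_partner_table, "tl_partner_classes")
  wr(res$conversion_records, "conversion_records")
  if (!is.null(res$cooperativity)) {
    wr(res$cooperativity$pairs, "cooperativity_pairs")
    wr(res$cooperativity$summary, "cooperativity_summary")
  }
  summary_lines <- c(
    sprintf("ss_regions\t%d", res$ss_summary$n_regions),
    sprintf("ss_super\t%d", res$ss_summary$n_super),
    sprintf("ss_components\t%d", res$ss_summary$n_components),
    sprintf("se_super\t%d", res$se_summary$n_super),
    if (!is.null(res$snv_fold_component))
      sprintf("snv_fold_component\t%.4f", res$snv_fold_component),
    if (!is.null(res$conversion)) c(
      sprintf("conversion_fraction\t%.4f",
              res$conversion$converted_fraction),
      sprintf("recurrent_over_half_fraction\t%.4f",
              res$conversion$recurrent_over_half_fraction)),
    if (!is.null(res$contact_retention)) c(
      sprintf("contact_retention\t%.4f", res$contact_retention),
      sprintf("expected_retention\t%.4f", res$expected_retention)))
  writeLines(summary_lines, file.path(out_dir, "summary.tsv"))
  invisible(out_dir)
}

#' Read a written synthetic dataset back into a bundle
#'
#' Counterpart of [write_ss_dataset()]: reloads every file through the
#' package readers into the in-memory bundle layout the pipeline consumes.
#'
#' @param dir dataset directory.
#' @return `ss_dataset`-style list (without the manifest unless
#'   `manifest.json` is present and jsonlite is installed).
#' @export
read_ss_dataset <- function(dir) {
  p <- function(...) file.path(dir, ...)
  sil <- read_bed(p("silencers.bed"), with_score = TRUE, mark = "H3K27me3")
  enh <- read_bed(p("enhancers.bed"), with_score = TRUE, mark = "H3K27ac")
  sil$element_class <- "silencer"; sil$H3K27ac <- 0
  enh$element_class <- "enhancer"; enh$H3K27me3 <- 0
  elements <- rbind(sil[, c("id", "chrom", "start", "end", "element_class",
                            "H3K27me3", "H3K27ac")],
                    enh[, c("id", "chrom", "start", "end", "element_class",
                            "H3K27me3", "H3K27ac")])
  pk_files <- list.files(p("peaks"), pattern = "_H3K27ac\\.bed$")
  cts <- sub("_H3K27ac\\.bed$", "", pk_files)
  peaks <- lapply(cts, function(ct) list(
    ac = read_bed(p("peaks", paste0(ct, "_H3K27ac.bed"))),
    me3 = read_bed(p("peaks", paste0(ct, "_H3K27me3.bed")))))
  names(peaks) <- cts
  tf <- read.table(p("tfbs.tsv"), sep = "\t", header = TRUE,
                   check.names = FALSE)
  tfbs <- as.matrix(tf[, -1]); rownames(tfbs) <- tf$id
  read_samples <- function(d) {
    fs <- list.files(p(d), pattern = "\\.bed$")
    out <- lapply(fs, function(f) read_bed(p(d, f)))
    names(out) <- sub("\\.bed$", "", fs)
    out
  }
  list(elements = elements, peaks_by_cell_type = peaks, tfbs = tfbs,
       cgis = read_bed(p("cgi.bed")),
       methylation = read_methylation(p("methylation.tsv")),
       tads = read_bed(p("tads.bed")),
       genes = read_genes(p("genes.tsv")),
       contacts_normal = read_bedpe(p("contacts_normal.bedpe")),
       contacts_cancer = read_bedpe(p("contacts_cancer.bedpe")),
       variants = read_variants(p("variants.tsv")),
       ld_pairs = read_ld_pairs(p("ld_pairs.tsv")),
       cancer_se_by_sample = read_samples("cancer_se"),
       cancer_ss_by_sample = read_samples("cancer_ss"))
}
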