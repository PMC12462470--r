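# CGI classification, TAD geometry, gene linkage, tau and methylation.

test_that("CGI status requires strictly more than 200 bp of overlap", {
  cgis <- iv("chr1", 1000, 2000)
  el <- iv("chr1", c(799, 800, 3000), c(1201, 1200, 4000))
  expect_equal(cgi_class(el, cgis), c("CGI", "non_CGI", "non_CGI"))
})

test_that("TAD sections follow the 20/50 kb bands from the nearest
          boundary", {
  tads <- load_tads(iv("chr1", 0, 1e6))
  el <- iv("chr1", c(9500, 29500, 99500), c(10500, 30500, 100500))
  ts <- tad_section(el, tads)
  expect_equal(ts$label, c("boundary", "shore", "center"))
  expect_equal(ts$distance_bp, c(10000, 30000, 100000))
})

test_that("TAD-section labels partition all labelled elements", {
  b <- small_sim(seed = 41)
  el <- b$elements
  ts <- tad_section(el, load_tads(b$tads))
  expect_false(anyNA(ts$label))
  expect_equal(sum(table(ts$label)), nrow(el))
  expect_true(all(ts$label %in% c("boundary", "shore", "center")))
})

test_that("counterpart shore mirrors the band across the boundary and is
          an involution on sides", {
  r <- counterpart_shore(1e6, "right")
  expect_equal(c(r$start, r$end), c(950000, 980000))
  l <- counterpart_shore(1e6, "left")
  expect_equal(c(l$start, l$end), c(1020000, 1050000))
  expect_warning(tr <- counterpart_shore(30000, "right"), "truncated")
  expect_equal(c(tr$start, tr$end), c(0, 10000))
  # counterpart of the counterpart's side is the original band
  orig <- iv("chr1", 1e6 + 20000, 1e6 + 50000)  # a right-side shore
  cp <- counterpart_shore(1e6, "right")          # left band
  back <- counterpart_shore(1e6, "left")
  expect_equal(back$start, orig$start)
  expect_equal(back$end, orig$end)
})

test_that("nearest gene minimises TSS distance with lexicographic ties", {
  genes <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                      tss = c(50000, 10000))
  el <- iv("chr1", 4000, 6000)  # midpoint 5000
  expect_equal(nearest_gene(el, genes), "gA")
  tie <- data.frame(gene_id = c("gB", "gA"), chrom = "chr1",
                    tss = c(6000, 4000))
  expect_message(g <- nearest_gene(el, tie), "tie")
  expect_equal(g, "gA")
})

test_that("nearest gene matches an exhaustive scan on random fixtures", {
  set.seed(42)
  el <- random_intervals(100)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:80),
                      chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
                      tss = round(runif(80, 0, 1e6)))
  got <- nearest_gene(el, genes)
  mid <- (el$start + el$end) / 2
  for (i in 1:100) {
    g <- genes[genes$chrom == el$chrom[i], ]
    g <- g[order(g$gene_id), ]
    expect_equal(got[i], g$gene_id[which.min(abs(g$tss - mid[i]))])
  }
})

test_that("contact genes equal a brute-force double loop", {
  set.seed(43)
  el <- random_intervals(30, chroms = "chr1")
  genes <- data.frame(gene_id = sprintf("g%02d", 1:25), chrom = "chr1",
                      tss = round(runif(25, 0, 1e6)))
  ct <- data.frame(chrom = "chr1",
                   start1 = round(runif(60, 0, 1e6)), end1 = 0,
                   start2 = round(runif(60, 0, 1e6)), end2 = 0)
  ct$end1 <- ct$start1 + 10000; ct$end2 <- ct$start2 + 10000
  got <- contact_genes(el, ct, genes, promoter_halfwidth = 2000)
  for (i in seq_len(nrow(el))) {
    want <- character(0)
    for (k in seq_len(nrow(ct))) {
      e_a1 <- bf_overlap(el[i, ], iv(ct$chrom[k], ct$start1[k], ct$end1[k])) > 0
      e_a2 <- bf_overlap(el[i, ], iv(ct$chrom[k], ct$start2[k], ct$end2[k])) > 0
      for (j in seq_len(nrow(genes))) {
        pr <- iv(genes$chrom[j], genes$tss[j] - 2000, genes$tss[j] + 2000)
        p_a1 <- bf_overlap(pr, iv(ct$chrom[k], ct$start1[k], ct$end1[k])) > 0
        p_a2 <- bf_overlap(pr, iv(ct$chrom[k], ct$start2[k], ct$end2[k])) > 0
        if ((e_a1 && p_a2) || (e_a2 && p_a1))
          want <- c(want, genes$gene_id[j])
      }
    }
    expect_setequal(got[[i]], unique(want))
  }
})

test_that("tau spans uniform to single-tissue expression and is
          scale-invariant", {
  expect_equal(tau(c(1, 1, 1)), 0)
  expect_equal(tau(c(1, 0, 0)), 1)
  expect_equal(tau(c(2, 1, 1)), 0.5)
  expect_true(is.na(tau(c(0, 0, 0))))
  set.seed(44)
  for (i in 1:20) {
    x <- rlnorm(sample(3:12, 1))
    expect_equal(tau(3.7 * x), tau(x))
    expect_gte(tau(x), 0); expect_lte(tau(x), 1)
  }
})

test_that("mean methylation averages sites inside the element", {
  meth <- data.frame(chrom = "chr1", pos = c(100, 200, 5000),
                     beta = c(0.2, 0.8, 0.9))
  el <- iv("chr1", c(0, 6000), c(1000, 7000))
  expect_equal(mean_methylation(el, meth), c(0.5, NA))
  expect_error(mean_methylation(el, data.frame(chrom = "chr1", pos = 1,
                                               beta = 1.2)), "beta")
})

test_that("mean methylation equals direct per-element averaging", {
  set.seed(45)
  el <- random_intervals(50)
  meth <- data.frame(chrom = sample(c("chr1", "chr2"), 400, replace = TRUE),
                     pos = round(runif(400, 0, 1e6)),
                     beta = runif(400))
  got <- mean_methylation(el, meth)
  for (i in 1:50) {
    sel <- meth$chrom == el$chrom[i] & meth$pos >= el$start[i] &
      meth$pos < el$end[i]
    want <- if (any(sel)) mean(meth$beta[sel]) else NA_real_
    expect_equal(got[i], want)
  }
})

test_that("annotate_elements produces one consistent row per element", {
  b <- small_sim(seed = 46)
  el <- head(b$elements, 50)
  ann <- annotate_elements(el, cgis = b$cgis, tads = load_tads(b$tads),
                           contacts = b$contacts_normal, genes = b$genes,
                           meth = b$methylation)
  expect_equal(nrow(ann), 50)
  expect_true(all(c("cgi_class", "tad_section", "nearest_gene",
                    "contact_genes", "mean_methylation") %in% names(ann)))
})
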