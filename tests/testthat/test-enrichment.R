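# Variant density, enrichment folds, LD expansion, replicated/recurrent
# fractions and element-set Jaccard.

vdf <- function(chrom, pos, categories = "", samples = "", studies = "") {
  data.frame(chrom = chrom, pos = pos, vtype = "SNV",
             categories = categories, samples = samples, studies = studies,
             stringsAsFactors = FALSE)
}

test_that("density_per_kb counts positions over merged length", {
  el <- iv("chr1", 0, 10000)
  v <- vdf("chr1", c(1, 2, 3, 4, 5))
  expect_equal(density_per_kb(v, el), 0.5)
  expect_equal(density_per_kb(v[0, ], el), 0)
  expect_error(density_per_kb(v, el[0, ]), "empty")
})

test_that("density is invariant to splitting elements into adjacent
          pieces and double-counted bases are merged", {
  set.seed(51)
  v <- vdf("chr1", round(runif(300, 0, 1e5)))
  whole <- iv("chr1", 20000, 60000)
  split3 <- iv("chr1", c(20000, 30000, 45000), c(30000, 45000, 60000))
  overlapping <- iv("chr1", c(20000, 25000, 40000), c(45000, 60000, 50000))
  expect_equal(density_per_kb(v, split3), density_per_kb(v, whole))
  expect_equal(density_per_kb(v, overlapping), density_per_kb(v, whole))
  # brute force merge-then-scan oracle
  inside <- v$pos >= 20000 & v$pos < 60000
  expect_equal(density_per_kb(v, whole), sum(inside) / 40)
})

test_that("category_fraction counts tags exactly", {
  v <- vdf("chr1", 1:100,
           categories = c(rep("b_cell_cancer", 8), rep("other", 92)))
  expect_equal(category_fraction(v, "b_cell_cancer"), 0.08)
  expect_equal(category_fraction(v, "other"), 0.92)
  expect_equal(category_fraction(v[1:8, ], "b_cell_cancer"), 1)
  expect_error(category_fraction(v[0, ], "x"), "empty")
})

test_that("enrichment_fold matches an exact binomial tail summation", {
  ef <- enrichment_fold(0.10, 0.05, 100)
  expect_equal(ef$fold, 2)
  null <- enrichment_fold(0.05, 0.05, 100)
  expect_equal(null$fold, 1)
  expect_gt(null$p_value, 0.99)
  ef2 <- enrichment_fold(0.08, 0.02, 100)
  expect_equal(ef2$p_value, bf_binom_p(8, 100, 0.02), tolerance = 1e-8)
  set.seed(52)
  for (i in 1:20) {
    n <- sample(10:2000, 1)
    k <- rbinom(1, n, 0.1)
    p0 <- runif(1, 0.01, 0.5)
    got <- enrichment_fold(k / n, p0, n)$p_value
    expect_equal(got, bf_binom_p(k, n, p0), tolerance = 1e-6)
  }
  expect_error(enrichment_fold(0.1, 0, 10), "reference_fraction")
})

test_that("LD expansion is single-pass with a strict threshold", {
  ld <- data.frame(snp_a = c("s1", "s1", "x"), snp_b = c("x", "y", "z"),
                   r2 = c(0.9, 0.8, 0.95))
  expect_setequal(ld_expand("s1", ld[1, ]), c("s1", "x"))
  expect_setequal(ld_expand("s1", ld[2, ]), "s1")       # r2 == 0.8 excluded
  expect_setequal(ld_expand("s1", ld), c("s1", "x"))    # no closure via x-z
  expect_setequal(ld_expand("s1", ld[0, ]), "s1")
  # superset of seeds, idempotent without qualifying pairs
  expect_true(all(c("s1") %in% ld_expand("s1", ld)))
  weak <- data.frame(snp_a = "s1", snp_b = "q", r2 = 0.5)
  expect_identical(ld_expand(ld_expand("s1", weak), weak), "s1")
})

test_that("replicated and recurrent fractions count distinct sets", {
  v <- vdf("chr1", 1:4, categories = "trait",
           studies = c("a,b", "a", "a,a", "b,c"))
  expect_equal(replicated_fraction(v, "trait"), 0.5)  # a,a is one study
  v2 <- vdf("chr1", 1:100, samples = c(rep("s1,s2", 3), rep("s1", 97)))
  expect_equal(recurrent_fraction(v2), 0.03)
  expect_equal(recurrent_fraction(vdf("chr1", 1:5, samples = "s1")), 0)
  set.seed(53)
  n <- 200
  ks <- sample(1:4, n, replace = TRUE)
  v3 <- vdf("chr1", 1:n, samples = vapply(ks, function(k)
    paste(sample(letters, k), collapse = ","), character(1)))
  expect_equal(recurrent_fraction(v3), mean(ks >= 2))
})

test_that("element-set Jaccard matches the constructed fixture", {
  a <- iv("chr1", seq(0, 9e4, 1e4), seq(0, 9e4, 1e4) + 1000)
  b <- a; b$start <- b$start + 500; b$end <- b$end + 500
  expect_equal(elementset_jaccard(a, a, 1), 1)
  far <- a; far$start <- far$start + 5000; far$end <- far$end + 5000
  expect_equal(elementset_jaccard(a, far, 1), 0)
  # 10 vs 10 with exactly 4 matched
  b4 <- rbind(b[1:4, ], far[5:10, ])
  expect_equal(elementset_jaccard(a, b4, 1), 4 / 16)
})

test_that("flanking regions exclude the element set itself", {
  el <- iv("chr1", 100000, 110000)
  fl <- flanking_regions(el, 50000)
  expect_equal(fl, iv("chr1", c(50000, 110000), c(100000, 160000)))
})

test_that("translocation partners classify by precedence", {
  groups <- list(SS = iv("chr1", 0, 1000), SE = iv("chr1", 40000, 41000),
                 TS = iv("chr2", 0, 1000), TE = iv("chr3", 0, 1000))
  partners <- data.frame(chrom = c("chr1", "chr2", "chr4"),
                         pos = c(500, 30000, 5))
  expect_message(
    cls <- classify_tl_partner(partners, groups, flank_bp = 50000),
    "precedence")
  # chr1:500 is inside SS and within 50 kb of SE: SS wins by precedence
  expect_equal(cls, c("SS", "TS", "none"))
})

test_that("variant enrichment table recovers a planted fold", {
  b <- small_sim(seed = 54)
  sil <- b$elements[b$elements$element_class == "silencer", ]
  fit <- call_super_regions(sil)
  snv <- b$variants[b$variants$vtype == "SNV", ]
  tbl <- variant_enrichment(snv, list(ss_component = components(fit),
                                      ts = typicals(fit)))
  expect_equal(nrow(tbl), 2)
  # planted B-cell enrichment makes the component fraction exceed the
  # typical-silencer fraction
  expect_gt(tbl$category_fraction[1], tbl$category_fraction[2])
  expect_gt(tbl$fold_vs_reference[1], 1)
})
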