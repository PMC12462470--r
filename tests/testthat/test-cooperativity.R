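# Ternary activity coding, cosine/Jaccard similarity, distance-matched
# background sampling and shared-TF counting.

test_that("ternary activity codes H3K27ac-only as 1, H3K27me3-only as -1,
          both or neither as 0", {
  el <- iv("chr1", c(0, 2000, 4000, 6000), c(1000, 3000, 5000, 7000))
  ac <- iv("chr1", c(0, 4000), c(500, 4500))
  me3 <- iv("chr1", c(2000, 4600), c(2500, 5000))
  a <- ternary_activity(el, ac, me3)
  expect_identical(a, c(1L, -1L, 0L, 0L))
})

test_that("cooperativity score reproduces the fixed examples", {
  expect_equal(cooperativity_score(c(1, -1, 0), c(1, -1, 0)), 1)
  expect_equal(cooperativity_score(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cooperativity_score(c(1, 0, 1), c(1, 1, 0)), 0.5)
  expect_true(is.na(cooperativity_score(c(0, 0, 0), c(1, 0, 0))))
})

test_that("tfbs similarity reproduces the fixed examples", {
  # {A,B} vs {B,C} over G = {A,B,C,D}
  expect_equal(tfbs_similarity(c(1, 1, 0, 0), c(0, 1, 1, 0)), 1 / 3)
  expect_equal(tfbs_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tfbs_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  expect_equal(tfbs_similarity(c(0, 0), c(0, 0)), 0)
})

test_that("cosine and Jaccard obey their algebraic laws on random vectors", {
  set.seed(31)
  for (i in 1:300) {
    K <- sample(3:30, 1)
    a <- sample(c(-1L, 0L, 1L), K, replace = TRUE)
    b <- sample(c(-1L, 0L, 1L), K, replace = TRUE)
    ca <- cooperativity_score(a, b)
    expect_equal(ca, cooperativity_score(b, a))
    if (!is.na(ca)) {
      expect_gte(ca, -1); expect_lte(ca, 1)
      expect_equal(cooperativity_score(-a, -b), ca)  # joint sign flip
    }
    if (any(a != 0)) expect_equal(cooperativity_score(a, a), 1)
    ti <- sample(0:1, K, replace = TRUE)
    tj <- sample(0:1, K, replace = TRUE)
    ja <- tfbs_similarity(ti, tj)
    expect_equal(ja, tfbs_similarity(tj, ti))
    expect_gte(ja, 0); expect_lte(ja, 1)
    # set-algebra equivalence
    si <- which(ti == 1); sj <- which(tj == 1)
    uni <- length(union(si, sj))
    expect_equal(ja, if (uni == 0) 0 else
      length(intersect(si, sj)) / uni)
  }
})

test_that("shared_tf_fraction equals an exhaustive column scan", {
  m <- matrix(0L, 3, 168)
  m[1, 5] <- 1L; m[2, 5] <- 1L  # exactly one TF shared by two constituents
  expect_equal(shared_tf_fraction(m), 1 / 168)
  expect_equal(shared_tf_fraction(matrix(0L, 4, 10)), 0)
  set.seed(32)
  r <- matrix(rbinom(200, 1, 0.3), 10, 20)
  cnt <- 0L
  for (g in 1:20) if (sum(r[, g]) >= 2) cnt <- cnt + 1L
  expect_equal(shared_tf_fraction(r), cnt / 20)
  expect_error(shared_tf_fraction(r[1, , drop = FALSE]), "undefined")
})

test_that("matched background sampling is deterministic and matches the
          target distance distribution", {
  # dense pool: 400 elements spaced a few kb apart on one chromosome, so
  # every target bin has candidate pairs
  set.seed(33)
  starts <- cumsum(round(runif(400, 3000, 9000)))
  pool <- data.frame(id = paste0("t", 1:400), chrom = "chr1",
                     start = starts, end = starts + 1500)
  target <- round(runif(600, 4000, 45000))
  p1 <- matched_background_pairs(target, pool, 200, seed = 5)
  p2 <- matched_background_pairs(target, pool, 200, seed = 5)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 200)
  expect_true(all(p1$id1 != p1$id2))
  expect_lt(bf_ks(target, p1$distance_bp), 0.1)
  # degenerate case: all targets in one bin
  p3 <- matched_background_pairs(rep(3000, 50), pool, 50, seed = 6)
  expect_true(all(floor(p3$distance_bp / 10000) == 0))
  # sparse pool: demand in bins without candidates is redistributed with a
  # warning
  sparse <- pool[seq(1, 400, by = 40), ]
  expect_warning(matched_background_pairs(c(rep(5000, 10), rep(250000, 10)),
                                          sparse, 10, seed = 7),
                 "redistributed")
})

test_that("cooperativity analysis separates planted within-region pairs
          from both backgrounds", {
  b <- small_sim(seed = 34)
  sil <- b$elements[b$elements$element_class == "silencer", ]
  fit <- call_super_regions(sil)
  coop <- cooperativity_analysis(fit, b$activity, tfbs = b$tfbs, seed = 3)
  med <- setNames(coop$summary$cooperativity, coop$summary$group)
  expect_gt(med["within_region"], med["matched_background"])
  expect_lt(coop$tests["vs_matched"], 0.01)
  jac <- aggregate(tfbs_similarity ~ group, coop$pairs, median)
  jm <- setNames(jac$tfbs_similarity, jac$group)
  expect_gt(jm["within_region"], jm["random_background"])
})
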