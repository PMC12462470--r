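# Conversion detection across cancer samples, recurrence and contact
# retention.

test_that("conversion detection counts samples hit and strict majority
          recurrence", {
  el <- data.frame(id = c("a", "b"), chrom = "chr1",
                   start = c(0, 50000), end = c(1000, 51000))
  se <- iv("chr1", 0, 2000)
  samples <- list(s1 = se, s2 = se, s3 = se, s4 = iv("chr1", 9e5, 9.1e5),
                  s5 = iv("chr1", 9e5, 9.1e5))
  rec <- detect_conversions(el, samples)
  expect_equal(rec$element_id, "a")
  expect_equal(rec$n_samples_hit, 3)
  expect_true(rec$recurrent_over_half)  # 3 > 5/2
  expect_equal(rec$samples_hit, "s1,s2,s3")
  # exactly half is not "more than half"
  samples6 <- c(samples, list(s6 = iv("chr1", 9e5, 9.1e5)))
  rec6 <- detect_conversions(el, samples6)
  expect_false(rec6$recurrent_over_half)  # 3 of 6
  expect_error(detect_conversions(el, list()), "no cancer samples")
})

test_that("detection is invariant to sample and element order", {
  b <- small_sim(seed = 61)
  sil <- b$elements[b$elements$element_class == "silencer", ]
  fit <- call_super_regions(sil)
  comp <- components(fit)
  r1 <- detect_conversions(comp, b$cancer_se_by_sample)
  set.seed(62)
  r2 <- detect_conversions(comp[sample.int(nrow(comp)), ],
                           rev(b$cancer_se_by_sample))
  o1 <- r1[order(r1$element_id), ]
  o2 <- r2[order(r2$element_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("containment mode is stricter than overlap mode", {
  el <- data.frame(id = "a", chrom = "chr1", start = 0, end = 1000)
  half <- list(s1 = iv("chr1", 500, 2000))
  expect_equal(nrow(detect_conversions(el, half)), 1)
  expect_equal(nrow(detect_conversions(el, half, containment = TRUE)), 0)
  full <- list(s1 = iv("chr1", 0, 2000))
  expect_equal(nrow(detect_conversions(el, full, containment = TRUE)), 1)
})

test_that("recurrence summary divides records by the universe", {
  rec <- data.frame(element_id = paste0("e", 1:13),
                    recurrent_over_half = c(rep(TRUE, 3), rep(FALSE, 10)))
  s <- recurrence_summary(rec, 100)
  expect_equal(s$converted_fraction, 0.13)
  expect_equal(s$recurrent_over_half_fraction, 3 / 13)
  s0 <- recurrence_summary(rec[0, ], 100)
  expect_equal(s0$converted_fraction, 0)
  expect_true(is.na(s0$recurrent_over_half_fraction))
  expect_error(recurrence_summary(rec, 0), "positive")
  expect_error(recurrence_summary(rec, 5), "smaller")
})

test_that("recurrent fraction cannot grow as the sample universe grows", {
  el <- data.frame(id = "a", chrom = "chr1", start = 0, end = 1000)
  se <- iv("chr1", 0, 2000)
  empty <- iv("chr1", 9e5, 9.1e5)
  fr <- function(n_tot) {
    samples <- c(rep(list(se), 3), rep(list(empty), n_tot - 3))
    names(samples) <- paste0("s", seq_len(n_tot))
    detect_conversions(el, samples)$recurrent_over_half
  }
  expect_true(fr(5)); expect_false(fr(6)); expect_false(fr(9))
})

test_that("contact retention matches brute-force bin matching", {
  ca <- data.frame(chrom = "chr1",
                   start1 = c(0, 20000, 40000, 500000) ,
                   end1 = c(10000, 30000, 50000, 510000),
                   start2 = c(100000, 120000, 140000, 700000),
                   end2 = c(110000, 130000, 150000, 710000))
  cb <- ca[c(1, 3), ]
  el <- iv("chr1", c(2000, 22000, 42000), c(3000, 23000, 43000))
  # qualifying: first three contacts; retained: 1 and 3
  expect_equal(contact_retention(ca, cb, el), 2 / 3)
  expect_equal(contact_retention(ca, cb[0, ], el), 0)
  expect_warning(r <- contact_retention(ca, cb, iv("chr2", 0, 1000)),
                 "no contacts")
  expect_true(is.na(r))
  # brute-force double loop on a random binned fixture
  set.seed(63)
  mk <- function(n) {
    s1 <- sample(seq(0, 9e5, 1e4), n, replace = TRUE)
    s2 <- sample(seq(0, 9e5, 1e4), n, replace = TRUE)
    data.frame(chrom = "chr1", start1 = s1, end1 = s1 + 1e4,
               start2 = s2, end2 = s2 + 1e4)
  }
  A <- mk(40); B <- mk(40)
  el2 <- iv("chr1", seq(0, 9e5, 5e4) + 100, seq(0, 9e5, 5e4) + 200)
  got <- contact_retention(A, B, el2)
  qual <- logical(40); ret <- logical(40)
  for (i in 1:40) {
    q1 <- any(el2$start < A$end1[i] & el2$end > A$start1[i])
    q2 <- any(el2$start < A$end2[i] & el2$end > A$start2[i])
    qual[i] <- q1 || q2
    for (j in 1:40) {
      same <- setequal(c(A$start1[i], A$start2[i]),
                       c(B$start1[j], B$start2[j]))
      if (same) ret[i] <- TRUE
    }
  }
  expect_equal(got, mean(ret[qual]))
})

test_that("planted conversion and recurrence are recovered on the small
          bundle", {
  b <- small_sim(seed = 64)
  sil <- b$elements[b$elements$element_class == "silencer", ]
  fit <- call_super_regions(sil)
  comp <- components(fit)
  rec <- detect_conversions(comp, b$cancer_se_by_sample)
  s <- recurrence_summary(rec, nrow(comp))
  expect_equal(s$converted_fraction,
               b$manifest$planted_conversion_fraction, tolerance = 0.25)
  # every planted converted element is detected
  expect_true(all(b$manifest$planted_converted_ids %in% rec$element_id))
})
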