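# Stitching, rank-curve elbow detection and super-region calling.

el1 <- function(starts, ends, signal, chrom = "chr1") {
  data.frame(id = paste0("e", seq_along(starts)), chrom = chrom,
             start = starts, end = ends, H3K27me3 = signal,
             stringsAsFactors = FALSE)
}

test_that("stitch merges within the gap and splits beyond it", {
  a <- el1(c(0, 5000), c(1000, 6000), c(1, 1))
  r <- stitch(a, gap_bp = 12500)
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(0, 6000))
  expect_equal(r$constituent_ids[[1]], c("e1", "e2"))

  b <- el1(c(0, 20000), c(1000, 21000), c(1, 1))
  expect_equal(nrow(stitch(b, gap_bp = 12500)), 2)

  ov <- el1(c(0, 500), c(1000, 1500), c(1, 1))
  r3 <- stitch(ov, gap_bp = 0)
  expect_equal(nrow(r3), 1)
  expect_equal(c(r3$start, r3$end), c(0, 1500))
})

test_that("stitch refuses mixed chromosomes and conserves elements", {
  a <- el1(c(0, 5000), c(1000, 6000), c(1, 1))
  a$chrom <- c("chr1", "chr2")
  expect_error(stitch(a), "single chromosome")
  set.seed(21)
  e <- random_elements(120, chroms = "chr1", max_pos = 3e6)
  e$H3K27me3 <- runif(120)
  r <- stitch(e, gap_bp = 8000)
  expect_equal(sort(unlist(r$constituent_ids)), sort(e$id))
  expect_equal(sum(r$n_constituents), nrow(e))
})

test_that("aggregate_signal sums constituents and names missing marks", {
  e <- el1(c(0, 5000), c(1000, 6000), c(2, 3))
  r <- stitch(e)
  expect_equal(aggregate_signal(r[1, ], e, "H3K27me3"), 5)
  single <- el1(0, 1000, 7.5)
  expect_equal(aggregate_signal(stitch(single)[1, ], single, "H3K27me3"),
               7.5)
  e2 <- e; e2$H3K27me3[2] <- NA
  expect_error(aggregate_signal(r[1, ], e2, "H3K27me3"), "e2")
})

test_that("aggregate_signal equals independent per-region re-summation", {
  set.seed(22)
  e <- random_elements(200, chroms = "chr1", max_pos = 5e6)
  e$H3K27me3 <- rlnorm(200)
  regs <- stitch(e, gap_bp = 10000)
  for (i in seq_len(nrow(regs))) {
    ids <- regs$constituent_ids[[i]]
    expect_equal(aggregate_signal(regs[i, ], e, "H3K27me3"),
                 sum(e$H3K27me3[match(ids, e$id)]))
  }
})

test_that("background column is subtracted floored at zero", {
  e <- el1(c(0, 5000), c(1000, 6000), c(2, 3))
  e$input <- c(5, 1)  # first element over-subtracts to 0
  r <- stitch(e)
  expect_equal(aggregate_signal(r[1, ], e, "H3K27me3", background = "input"),
               2)
})

test_that("find_cutoff matches the exhaustive unit-square elbow on the
          spec fixtures", {
  c1 <- rank_curve(c(1, 2, 3, 4, 100))
  expect_equal(find_cutoff(c1), bf_elbow(c(1, 2, 3, 4, 100)))
  expect_equal(find_cutoff(c1), 4L)
  expect_true(all(c1$x_scaled >= 0 & c1$x_scaled <= 1))
  expect_equal(c1$y_scaled[1], 0); expect_equal(c1$y_scaled[5], 1)

  t2 <- c(rep(1, 8), 50, 60)
  c2 <- rank_curve(t2)
  k <- find_cutoff(c2)
  expect_equal(k, bf_elbow(t2))
  expect_equal(sum(c2$sorted_totals > c2$sorted_totals[k]), 2)

  expect_true(is.na(find_cutoff(rank_curve(rep(5, 10)))))
})

test_that("calling separates planted clusters into components", {
  b <- small_sim(seed = 7)
  sil <- b$elements[b$elements$element_class == "silencer", ]
  fit <- call_super_regions(sil)
  planted <- b$manifest$planted_ss_components
  expect_gte(mean(planted %in% components(fit)$id), 0.95)
  n_sup <- sum(fit$regions$is_super)
  n_cl <- b$manifest$n_planted_ss_clusters
  expect_lte(abs(n_sup - n_cl) / n_cl, 0.5)
})

test_that("components and typicals partition the input", {
  b <- small_sim(seed = 8)
  sil <- b$elements[b$elements$element_class == "silencer", ]
  fit <- call_super_regions(sil)
  expect_equal(nrow(components(fit)) + nrow(typicals(fit)), nrow(sil))
  expect_length(intersect(components(fit)$id, typicals(fit)$id), 0)
  expect_setequal(c(components(fit)$id, typicals(fit)$id), sil$id)
})

test_that("a single element yields one region and no supers", {
  e <- el1(0, 1000, 5)
  fit <- call_super_regions(e)
  expect_equal(nrow(fit$regions), 1)
  expect_false(any(fit$regions$is_super))
  expect_equal(fit$elements$status, "typical")
})

test_that("the identical algorithm calls super-enhancers on H3K27ac", {
  b <- small_sim(seed = 9)
  enh <- b$elements[b$elements$element_class == "enhancer", ]
  fit <- call_super_regions(enh, mark = "H3K27ac")
  planted <- b$manifest$planted_se_components
  expect_gte(mean(planted %in% components(fit)$id), 0.95)
})

test_that("calling is invariant to input order and uniform signal scaling", {
  b <- small_sim(seed = 10)
  sil <- b$elements[b$elements$element_class == "silencer", ]
  fit <- call_super_regions(sil)
  set.seed(101)
  perm <- sil[sample.int(nrow(sil)), ]
  fit_perm <- call_super_regions(perm)
  expect_setequal(components(fit_perm)$id, components(fit)$id)
  scaled <- sil; scaled$H3K27me3 <- scaled$H3K27me3 * 17.3
  fit_sc <- call_super_regions(scaled)
  expect_setequal(components(fit_sc)$id, components(fit)$id)
})

test_that("super_call print, summary and BED export are consistent", {
  b <- small_sim(seed = 11)
  sil <- b$elements[b$elements$element_class == "silencer", ]
  fit <- call_super_regions(sil)
  s <- summary(fit)
  expect_equal(s$n_components + s$n_typical, nrow(sil))
  expect_output(print(fit), "Super-region call")
  d <- withr::local_tempdir()
  write_super_call(fit, file.path(d, "run1"))
  regs <- read_bed(file.path(d, "run1_regions.bed"), with_score = TRUE,
                   mark = "total")
  expect_equal(nrow(regs), s$n_regions)
  expect_equal(sum(grepl("super", regs$id)), s$n_super)
  comp <- read_bed(file.path(d, "run1_components.bed"))
  expect_equal(nrow(comp), s$n_components)
})
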