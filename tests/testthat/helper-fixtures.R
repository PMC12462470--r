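# Fixture builders and independent brute-force oracles shared across tests.

iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e6,
                             len_range = c(100, 5000)) {
  L <- round(runif(n, len_range[1], len_range[2]))
  s <- round(runif(n, 0, max_pos - max(len_range)))
  iv(sample(chroms, n, replace = TRUE), s, s + L)
}

random_elements <- function(n, ...) {
  x <- random_intervals(n, ...)
  x$id <- paste0("e", seq_len(n))
  x
}

# Brute-force single-pair overlap, no interval machinery.
bf_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  as.integer(max(0, min(a$end, b$end) - max(a$start, b$start)))
}

# Brute-force maximum overlap of each query with any subject.
bf_max_overlap <- function(query, subject) {
  vapply(seq_len(nrow(query)), function(i) {
    best <- 0L
    for (j in seq_len(nrow(subject)))
      best <- max(best, bf_overlap(query[i, ], subject[j, ]))
    best
  }, integer(1))
}

# Exhaustive elbow search: scale ranks and totals to the unit square and
# scan every rank for the largest drop below the diagonal (ties -> higher
# rank).  Independent of the package's rank_curve/find_cutoff path.
bf_elbow <- function(totals) {
  st <- sort(totals)
  n <- length(st)
  if (n < 3 || max(st) <= min(st)) return(NA_integer_)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (st - min(st)) / (max(st) - min(st))
  best <- -Inf; best_i <- NA_integer_
  for (i in seq_len(n)) {
    if (x[i] - y[i] >= best) { best <- x[i] - y[i]; best_i <- i }
  }
  best_i
}

# Two-sample KS statistic by direct empirical-CDF comparison.
bf_ks <- function(a, b) {
  g <- sort(unique(c(a, b)))
  Fa <- vapply(g, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(g, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}

# Exact two-sided binomial p-value by pmf tail summation.
bf_binom_p <- function(k, n, p0) {
  pk <- dbinom(k, n, p0)
  sum(dbinom(0:n, n, p0)[dbinom(0:n, n, p0) <= pk * (1 + 1e-7)])
}

small_sim <- function(seed = 7, ...) {
  simulate_ss_dataset(ss_sim_config(
    n_silencers = 300, n_enhancers = 300, n_ss_clusters = 12,
    n_se_clusters = 8, n_random_contacts = 300, n_gwas_snps = 150,
    n_tlbp = 120, n_bg_meth_sites = 200, n_random_cgis = 60, ...),
    seed = seed)
}
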