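# Independent oracles used by unit and acceptance tests. These deliberately
# recompute quantities by the most literal route available (dense matrices,
# explicit convolutions, per-pair loops) so they share no code path with the
# package implementations they check.

# Exact conditional NB two-sided p by explicit convolution of per-replicate
# NB pmfs (unit size factors), enumerating outcomes up to max_count.
oracle_nb_p <- function(ka, kb, dispersion, max_count = 2000) {
  K <- sum(ka) + sum(kb)
  stopifnot(K <= max_count)
  q0 <- K / (length(ka) + length(kb))
  size <- 1 / dispersion
  pmf1 <- stats::dnbinom(0:max_count, mu = q0, size = size)
  convolve_trunc <- function(p, q) {
    n <- length(p)
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- sum(p[1:i] * q[i:1])
    out
  }
  pmf_sum <- function(n_rep) {
    out <- pmf1
    if (n_rep > 1) for (r in 2:n_rep) out <- convolve_trunc(out, pmf1)
    out
  }
  pa <- pmf_sum(length(ka))
  pb <- pmf_sum(length(kb))
  a <- 0:K
  w <- pa[a + 1] * pb[K - a + 1]
  w_obs <- w[sum(ka) + 1]
  sum(w[w <= w_obs * (1 + 1e-7)]) / sum(w)
}

# Brute-force interaction caller: dense matrices and explicit per-pair loops.
oracle_interactions <- function(map, n_bins, alpha = 0.05, z_min = 2,
                                min_distance_bins = 2L, smooth_above = 20L) {
  M <- matrix(0, n_bins, n_bins)
  for (k in seq_len(nrow(map))) {
    i <- map$bin_i[k] + 1L
    j <- map$bin_j[k] + 1L
    M[i, j] <- M[i, j] + map$count[k]
    if (i != j) M[j, i] <- M[j, i] + map$count[k]
  }
  cov <- rowSums(M)
  covered <- cov > 0
  cfac <- cov / mean(cov[covered])

  grp_of <- function(d) if (d <= smooth_above) d else smooth_above + floor(log2(d) * 4)
  gsum <- list()
  gcnt <- list()
  for (i in 1:(n_bins - 1)) {
    for (j in (i + 1):n_bins) {
      if (!covered[i] || !covered[j]) next
      g <- as.character(grp_of(j - i))
      gsum[[g]] <- (gsum[[g]] %||% 0) + M[i, j]
      gcnt[[g]] <- (gcnt[[g]] %||% 0) + 1
    }
  }
  gmean <- function(d) {
    g <- as.character(grp_of(d))
    gsum[[g]] / gcnt[[g]]
  }

  rows <- list()
  for (k in seq_len(nrow(map))) {
    i <- map$bin_i[k]
    j <- map$bin_j[k]
    d <- j - i
    if (d < min_distance_bins) next
    if (!covered[i + 1] || !covered[j + 1]) next
    e <- gmean(d) * cfac[i + 1] * cfac[j + 1]
    obs <- map$count[k]
    z <- (obs - e) / sqrt(e)
    p <- stats::ppois(obs - 1, e, lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      bin_i = i, bin_j = j, observed = obs, expected = e, z = z, pvalue = p,
      significant = p <= alpha & z >= z_min
    )
  }
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random sparse single-chromosome map for oracle-equivalence tests.
random_map <- function(seed, n_bins) {
  set.seed(seed)
  pairs <- expand.grid(bin_i = 0:(n_bins - 1), bin_j = 0:(n_bins - 1))
  pairs <- pairs[pairs$bin_j >= pairs$bin_i, ]
  d <- pairs$bin_j - pairs$bin_i
  lambda <- 30 / pmax(d, 1)
  cnt <- stats::rpois(nrow(pairs), lambda)
  keep <- cnt > 0 & stats::runif(nrow(pairs)) < 0.9  # leave holes
  contact_map(
    tibble::tibble(chrom = "chrT", bin_i = pairs$bin_i[keep],
                   bin_j = pairs$bin_j[keep], count = cnt[keep]),
    bin_size = 10000L
  )
}

# Shared small DE pipeline used by several suites: simulate, normalize per
# read class, test both classes, call regulation.
run_de_pipeline <- function(cfg) {
  cnt <- simulate_counts(cfg)
  s <- cnt$samples
  cols <- function(bg, cond, rc) {
    s$sample[s$background == bg & s$condition == cond & s$read_class == rc]
  }
  sf <- c()
  for (rc in c("total", "intronic")) {
    cc <- s$sample[s$read_class == rc]
    nrm <- compute_size_factors(cnt$counts[, c("gene_id", cc)],
                                reference_sample = cols(cfg$backgrounds[1], "resting", rc)[1])
    sf <- c(sf, stats::setNames(nrm$factors$size_factor, nrm$factors$sample))
  }
  de <- list()
  for (bg in cfg$backgrounds) {
    de[[bg]] <- list(
      total = test_induction(cnt$counts, cols(bg, "resting", "total"),
                             cols(bg, "TPA", "total"), sf),
      intronic = test_induction(cnt$counts, cols(bg, "resting", "intronic"),
                                cols(bg, "TPA", "intronic"), sf)
    )
  }
  reg <- call_regulated(de[[cfg$backgrounds[1]]]$total,
                        de[[cfg$backgrounds[1]]]$intronic)
  list(counts = cnt$counts, truth = cnt$truth, samples = s, sf = sf,
       de = de, regulation = reg)
}

precision_recall <- function(pred, truth) {
  tp <- length(intersect(pred, truth))
  c(precision = if (length(pred)) tp / length(pred) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}
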