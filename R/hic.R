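#' Distance- and coverage-aware expected contact model
#'
#' Fits the background expectation used for significant-interaction calling:
#' a per-distance mean contact count (raw up to `smooth_above` bins, pooled
#' over quarter-octave log-spaced distance groups beyond it) multiplied by
#' per-bin coverage factors `c_i = (bin total) / (mean bin total)`. Bins with
#' zero coverage are masked and contribute to neither the distance means nor
#' downstream calls.
#'
#' @param map A [contact_map()] for a single chromosome.
#' @param n_bins Number of bins in the chromosome; defaults to the largest
#'   occupied bin index + 1.
#' @param smooth_above Distance (in bins) beyond which distance means are
#'   pooled in log-spaced groups (default 20).
#' @return An `expected_model` list: `distance_mean` (smoothed, indexed by
#'   distance in bins), `raw_distance_mean`, `pair_count` (covered pairs per
#'   distance), `coverage_factor`, `covered`, `n_bins`, `chrom`, `bin_size`.
#' @export
fit_expected <- function(map, n_bins = NULL, smooth_above = 20L) {
  stopifnot(inherits(map, "contact_map"))
  chroms <- unique(map$chrom)
  if (length(chroms) != 1) abort("fit_expected expects a single-chromosome map")
  if (is.null(n_bins)) n_bins <- max(map$bin_j) + 1L
  n_bins <- as.integer(n_bins)

  cov <- numeric(n_bins)
  idx_i <- map$bin_i + 1L
  idx_j <- map$bin_j + 1L
  t1 <- tapply(map$count, idx_i, sum)
  cov[as.integer(names(t1))] <- cov[as.integer(names(t1))] + t1
  off <- idx_j != idx_i
  if (any(off)) {
    t2 <- tapply(map$count[off], idx_j[off], sum)
    cov[as.integer(names(t2))] <- cov[as.integer(names(t2))] + t2
  }
  covered <- cov > 0
  if (sum(covered) < 2) abort("fewer than 2 covered bins")
  cfac <- cov / mean(cov[covered])

  # covered-pair counts and count sums per distance
  v <- as.numeric(covered)
  dmax <- n_bins - 1L
  pair_count <- vapply(seq_len(dmax), function(d) {
    sum(v[seq_len(n_bins - d)] * v[seq_len(n_bins - d) + d])
  }, numeric(1))
  d_of <- map$bin_j - map$bin_i
  keep <- d_of >= 1 & covered[idx_i] & covered[idx_j]
  sums <- numeric(dmax)
  tab <- tapply(map$count[keep], d_of[keep], sum)
  sums[as.integer(names(tab))] <- tab
  raw_mean <- ifelse(pair_count > 0, sums / pair_count, NA_real_)

  # smoothing: raw means below the cutoff, pooled log-spaced groups above
  d <- seq_len(dmax)
  grp <- ifelse(d <= smooth_above, d, smooth_above + floor(log2(d) * 4))
  gsum <- tapply(sums, grp, sum)
  gcnt <- tapply(pair_count, grp, sum)
  gmean <- ifelse(gcnt > 0, gsum / gcnt, NA_real_)
  smooth_mean <- as.numeric(gmean[as.character(grp)])

  structure(
    list(distance_mean = smooth_mean, raw_distance_mean = raw_mean,
         pair_count = pair_count, coverage_factor = cfac, covered = covered,
         n_bins = n_bins, chrom = chroms, bin_size = map_bin_size(map),
         smooth_above = as.integer(smooth_above)),
    class = "expected_model"
  )
}

#' @export
print.expected_model <- function(x, ...) {
  cat(sprintf(
    "Expected contact model: %s, %d bins (%d covered), smoothing above %d bins\n",
    x$chrom, x$n_bins, sum(x$covered), x$smooth_above
  ))
  invisible(x)
}

#' Expected contact count for bin pairs under a fitted model
#'
#' @param model An `expected_model`.
#' @param bin_i,bin_j Bin index vectors.
#' @return Expected counts `distance_mean(|i - j|) * c_i * c_j` (NA for
#'   masked bins or unseen distances).
#' @export
expected_contacts <- function(model, bin_i, bin_j) {
  d <- abs(bin_j - bin_i)
  out <- rep(NA_real_, length(d))
  ok <- d >= 1 & model$covered[bin_i + 1L] & model$covered[bin_j + 1L]
  out[ok] <- model$distance_mean[d[ok]] *
    model$coverage_factor[bin_i[ok] + 1L] *
    model$coverage_factor[bin_j[ok] + 1L]
  out
}

#' Call significant interactions from a contact map
#'
#' Evaluates every stored bin pair at distance >= `min_distance_bins` against
#' the expected model: `Z = (obs - exp) / sqrt(exp)` and an upper-tail
#' Poisson p value at mean `exp`. A pair is significant when `p <= alpha`
#' and `Z >= z_min`. Pairs involving masked bins are skipped; unstored
#' (zero-count) pairs are never significant under an upper-tail test and are
#' not emitted.
#'
#' @param map A [contact_map()].
#' @param model The [fit_expected()] model for the same map.
#' @param alpha p-value threshold (default 0.05).
#' @param z_min Z-score threshold (default 2).
#' @param min_distance_bins Minimum pair distance in bins (default 2;
#'   excludes self- and adjacent-bin pairs dominated by self-ligation).
#' @return A tibble of interaction calls: `chrom`, `bin_i`, `bin_j`,
#'   `observed`, `expected`, `z`, `pvalue`, `significant`.
#' @export
call_interactions <- function(map, model, alpha = 0.05, z_min = 2,
                              min_distance_bins = 2L) {
  d <- map$bin_j - map$bin_i
  keep <- d >= min_distance_bins &
    model$covered[map$bin_i + 1L] & model$covered[map$bin_j + 1L]
  x <- map[keep, , drop = FALSE]
  expd <- expected_contacts(model, x$bin_i, x$bin_j)
  z <- (x$count - expd) / sqrt(expd)
  p <- ppois(x$count - 1, lambda = expd, lower.tail = FALSE)
  tibble(
    chrom = x$chrom, bin_i = x$bin_i, bin_j = x$bin_j,
    observed = x$count, expected = expd, z = z, pvalue = p,
    significant = p <= alpha & z >= z_min
  )
}

#' A/B compartment assignment by PCA of the contact correlation matrix
#'
#' Forms the observed/expected matrix over covered bins, takes its Pearson
#' correlation matrix, and extracts the first principal component. The sign
#' is oriented so that the score correlates positively with
#' `orientation_track` (a per-bin activity proxy such as gene or active-TSS
#' density: the gene-rich compartment is A by convention), and scores are
#' scaled so the 95th percentile of |score| is 1,000 — making the `> 100`
#' assignment threshold a 10%-of-typical-amplitude rule. Bins score A when
#' above `threshold`, B when below `-threshold`, otherwise unassigned.
#'
#' @param map A [contact_map()].
#' @param model The matching [fit_expected()] model.
#' @param orientation_track Numeric per-bin track of length `n_bins`.
#' @param threshold Assignment threshold on the scaled score (default 100).
#' @return A tibble: `bin`, `score`, `label` in `{A, B, unassigned}` (masked
#'   bins have `NA` score and `unassigned` label).
#' @export
compartment_pca <- function(map, model, orientation_track, threshold = 100) {
  nb <- model$n_bins
  stopifnot(length(orientation_track) == nb)
  if (sum(model$covered) < 50) abort("compartment_pca needs >= 50 covered bins")

  obs <- matrix(0, nb, nb)
  idx <- cbind(map$bin_i + 1L, map$bin_j + 1L)
  obs[idx] <- map$count
  obs[idx[, c(2, 1)]] <- map$count
  expd <- outer(model$coverage_factor, model$coverage_factor) *
    matrix(c(NA, model$distance_mean)[abs(outer(seq_len(nb), seq_len(nb), "-")) + 1L],
           nb, nb)
  oe <- obs / expd
  cov_idx <- which(model$covered)
  oe <- oe[cov_idx, cov_idx, drop = FALSE]
  oe[!is.finite(oe)] <- NA

  cmat <- suppressWarnings(cor(oe, use = "pairwise.complete.obs"))
  cmat[!is.finite(cmat)] <- 0
  pc1 <- eigen(cmat, symmetric = TRUE)$vectors[, 1]

  ori <- orientation_track[cov_idx]
  al <- suppressWarnings(cor(pc1, ori))
  if (is.finite(al) && al < 0) pc1 <- -pc1

  sc95 <- quantile(abs(pc1), 0.95, names = FALSE)
  if (sc95 > 0) pc1 <- pc1 * (1000 / sc95)

  score <- rep(NA_real_, nb)
  score[cov_idx] <- pc1
  tibble(
    bin = 0:(nb - 1L),
    score = score,
    label = dplyr::case_when(
      is.na(score) ~ "unassigned",
      score > threshold ~ "A",
      score < -threshold ~ "B",
      .default = "unassigned"
    )
  )
}

#' Link TSSs to binding-site bins through significant interactions
#'
#' A TSS is linked to a site when the bin holding the TSS base and the bin
#' holding the site summit form a significant interaction call.
#'
#' @param tss Interval tibble of TSS annotations (`name` identifies the
#'   gene); the TSS base follows [tss_position()] conventions.
#' @param sites Interval tibble of retained binding sites ([peak_summit()]
#'   conventions).
#' @param calls Interaction calls from [call_interactions()].
#' @param bin_size Bin width in bp.
#' @return A tibble, one row per TSS: `name`, `chrom`, `tss`, `tss_bin`,
#'   `linked` (any significant link to a site-bearing bin), `linked_bins`
#'   (list column of linked site bins).
#' @export
link_tss <- function(tss, sites, calls, bin_size = 10000L) {
  tss_bin <- bin_of(tss_position(tss), bin_size)
  site_bins <- unique(tibble(chrom = sites$chrom,
                             bin = bin_of(peak_summit(sites), bin_size)))
  sig <- filter(calls, .data$significant)
  sig_key <- c(paste(sig$chrom, sig$bin_i, sig$bin_j),
               paste(sig$chrom, sig$bin_j, sig$bin_i))

  linked_bins <- purrr::map2(tss$chrom, tss_bin, function(ch, tb) {
    cand <- site_bins$bin[site_bins$chrom == ch]
    cand[paste(ch, tb, cand) %in% sig_key]
  })
  tibble(
    name = if ("name" %in% names(tss)) tss$name else as.character(seq_len(nrow(tss))),
    chrom = tss$chrom,
    tss = tss_position(tss),
    tss_bin = tss_bin,
    linked = lengths(linked_bins) > 0,
    linked_bins = linked_bins
  )
}
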