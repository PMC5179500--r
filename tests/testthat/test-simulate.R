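test_that("generators are pure functions of the configuration", {
  cfg <- sim_config(seed = 3, n_genes = 200L, n_induced = 40L, n_down = 20L,
                    n_bins = 60L, n_loops = 3L)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  ca <- simulate_contacts(cfg)
  cb <- simulate_contacts(cfg)
  expect_identical(tibble::as_tibble(ca$map), tibble::as_tibble(cb$map))
  tp <- simulate_true_peaks(cfg, 10)
  expect_identical(simulate_peak_replicates(cfg, tp, 3),
                   simulate_peak_replicates(cfg, tp, 3))
})

test_that("planted labels partition genes at the configured fractions", {
  cfg <- sim_config(seed = 1, n_genes = 2000L, n_induced = 400L,
                    frac_dependent = 0.6)
  tr <- simulate_counts(cfg)$truth
  expect_equal(sum(tr$label == "induced-dependent"), 240L)
  expect_equal(sum(tr$label == "induced-independent"), 160L)
  expect_equal(sum(tr$label == "down-regulated"), cfg$n_down)
  expect_equal(nrow(tr), 2000L)
  expect_setequal(unique(tr$label),
                  c("invariant", "induced-dependent", "induced-independent",
                    "down-regulated"))
})

test_that("marginal count means match size factor x baseline x fold change", {
  cfg <- sim_config(seed = 5, n_genes = 1000L, n_induced = 200L, n_down = 0L,
                    size_factors = c(1, 1.3, 1, 1.3),
                    backgrounds = "WT", n_reps = 2L,
                    dispersion = 0.05)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  # TPA replicate 2 library: size factor 1.3, induced genes at 2^lfc
  mu_expected <- 1.3 * tr$base_mean * 2^tr$lfc_wt
  obs <- sim$counts$WT_TPA_2_total
  rel <- sum(obs) / sum(mu_expected)
  expect_lt(abs(rel - 1), 0.05)
  # per-gene agreement over the well-measured mid-range (the raw sum ratio is
  # dominated by a handful of huge log-normal baselines)
  mid <- mu_expected >= 100 & mu_expected <= 1000
  expect_lt(abs(mean(obs[mid] / mu_expected[mid]) - 1), 0.05)
  # intronic counts are a thinned copy of the latent signal
  frac <- sum(sim$counts$WT_TPA_2_intronic) / sum(obs)
  expect_lt(abs(frac - cfg$intronic_fraction), 0.01)
  expect_true(all(sim$counts$WT_TPA_2_intronic <= obs))
})

test_that("attenuation multiplies dependent genes' induction in the knockout", {
  cfg <- sim_config(seed = 9, n_genes = 1500L, n_induced = 300L, n_down = 0L,
                    attenuation = 0.15, dispersion = 0.01,
                    size_factors = 1)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  dep <- tr$label == "induced-dependent"
  ind <- tr$label == "induced-independent"
  lfc_ko <- log2((rowMeans(cbind(sim$counts$TKO_TPA_1_total,
                                 sim$counts$TKO_TPA_2_total)) + 0.5) /
                 (rowMeans(cbind(sim$counts$TKO_resting_1_total,
                                 sim$counts$TKO_resting_2_total)) + 0.5))
  fit_dep <- sum(lfc_ko[dep] * tr$lfc_wt[dep]) / sum(tr$lfc_wt[dep]^2)
  fit_ind <- sum(lfc_ko[ind] * tr$lfc_wt[ind]) / sum(tr$lfc_wt[ind]^2)
  expect_lt(abs(fit_dep - 0.15), 0.05)
  expect_lt(abs(fit_ind - 1), 0.05)
})

test_that("null attenuation makes dependent and independent genes indistinguishable", {
  cfg <- sim_config(seed = 2, n_genes = 600L, n_induced = 120L, n_down = 0L,
                    attenuation = 1.0, size_factors = 1)
  sim <- simulate_counts(cfg)
  tr <- sim$truth
  lfc_ko <- log2((sim$counts$TKO_TPA_1_total + 0.5) /
                 (sim$counts$TKO_resting_1_total + 0.5))
  dep <- tr$label == "induced-dependent"
  ind <- tr$label == "induced-independent"
  expect_gt(stats::t.test(lfc_ko[dep] - tr$lfc_wt[dep],
                          lfc_ko[ind] - tr$lfc_wt[ind])$p.value, 0.01)
})

test_that("planted loops enrich contacts by the configured fold", {
  cfg <- sim_config(seed = 11, n_bins = 80L, compartment_strength = 0,
                    loop_enrichment = 10, contact_scale = 50)
  loops <- tibble::tibble(bin_i = 10L, bin_j = 60L)
  obs_loop <- numeric(200)
  bg50 <- numeric(200)
  for (r in 1:200) {
    cfg_r <- sim_config(seed = 11 + r, n_bins = 80L, compartment_strength = 0,
                        loop_enrichment = 10, contact_scale = 50)
    m <- simulate_contacts(cfg_r, loops = loops)$map
    d <- m$bin_j - m$bin_i
    at <- m$count[m$bin_i == 10 & m$bin_j == 60]
    obs_loop[r] <- if (length(at)) at else 0
    bg <- m$count[d == 50 & !(m$bin_i == 10 & m$bin_j == 60)]
    bg50[r] <- sum(bg) / (80 - 50 - 1)   # zero entries are unstored
  }
  expect_lt(abs(mean(obs_loop) / mean(bg50) - 10), 1.5)
})

test_that("alternating compartment blocks imprint a checkerboard correlation", {
  cfg <- sim_config(seed = 4, n_bins = 200L, compartment_block_size = 20L,
                    n_loops = 0L)
  sim <- simulate_contacts(cfg)
  model <- fit_expected(sim$map, n_bins = cfg$n_bins)
  nb <- cfg$n_bins
  obs <- matrix(0, nb, nb)
  idx <- cbind(sim$map$bin_i + 1L, sim$map$bin_j + 1L)
  obs[idx] <- sim$map$count
  obs[idx[, c(2, 1)]] <- sim$map$count
  oe <- obs / outer(model$coverage_factor, model$coverage_factor)
  dmat <- abs(outer(1:nb, 1:nb, "-"))
  oe <- oe / matrix(c(NA, model$distance_mean)[dmat + 1], nb, nb)
  cmat <- suppressWarnings(stats::cor(oe, use = "pairwise.complete.obs"))
  comp <- sim$truth$compartments
  same <- outer(comp, comp, "==")
  off_diag <- dmat > 0
  agree <- sign(cmat[off_diag]) == ifelse(same[off_diag], 1, -1)
  expect_gt(mean(agree, na.rm = TRUE), 0.9)
})

test_that("peak pseudo-replicates honour the reproducibility probability", {
  cfg1 <- sim_config(seed = 6, peak_reproducibility = 1)
  tp <- simulate_true_peaks(cfg1, 50)
  reps <- simulate_peak_replicates(cfg1, tp, 4)
  for (r in reps) {
    expect_equal(sum(grepl("^peak", r$name)), 50L)
  }
  cfg0 <- sim_config(seed = 6, peak_reproducibility = 0)
  reps0 <- simulate_peak_replicates(cfg0, tp, 4)
  expect_true(all(grepl("^decoy", unlist(lapply(reps0, function(r) r$name)))))
  # decoys live in exactly one replicate each
  dec <- table(unlist(lapply(reps0, function(r) unique(r$name))))
  expect_true(all(dec == 1))
})

test_that("pseudo-replicate jitter stays within 50 bp and scores above threshold", {
  cfg <- sim_config(seed = 8, peak_reproducibility = 1)
  tp <- simulate_true_peaks(cfg, 30)
  reps <- simulate_peak_replicates(cfg, tp, 3)
  for (r in reps) {
    called <- r[grepl("^peak", r$name), ]
    m <- match(called$name, tp$name)
    expect_true(all(abs(called$start - tp$start[m]) <= 50))
    expect_true(all(called$score > 4))
  }
})
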