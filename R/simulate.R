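#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with the defaults used
#' throughout the test-bed: a 2,000-gene transcriptome in which 400 genes are
#' phorbol-ester (TPA) inducible, 60% of induction is TCF-dependent and is
#' attenuated to 15% of its wild-type magnitude in the knockout background,
#' plus a single 5-Mb chromosome of 500 10-kb bins for the contact-map
#' generator.
#'
#' @param seed Integer seed; every generator is a pure function of
#'   `(config, seed)`.
#' @param n_genes Number of genes.
#' @param n_induced Number of TPA-induced genes.
#' @param n_down Number of TPA-downregulated genes (planted symmetrically to
#'   the induced set, with negative log2 fold changes).
#' @param frac_dependent Fraction of induced genes whose induction is planted
#'   TCF-dependent.
#' @param induction_lfc_range Log2 fold-change interval for induced genes in
#'   the wild-type background.
#' @param attenuation Multiplicative factor (log2 scale) applied to dependent
#'   genes' induction in the knockout background; 1 means no dependence.
#' @param dispersion Negative-binomial dispersion of the counts.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of per-gene
#'   baseline mean counts.
#' @param intronic_fraction Binomial thinning fraction producing intronic from
#'   latent transcript counts.
#' @param size_factors Optional vector of true per-library scale factors
#'   (recycled/checked against the number of libraries); when `NULL`, factors
#'   are drawn log-normally with `size_factor_sdlog`.
#' @param size_factor_sdlog Spread of the drawn size factors on the log scale.
#' @param n_reps Replicate libraries per background x condition.
#' @param backgrounds Genetic backgrounds to simulate; the first is the
#'   reference (full induction), all others attenuate dependent genes.
#' @param rescue_background Optional name of a background in which a planted
#'   subset of dependent genes regains full wild-type induction.
#' @param rescue_fraction Fraction of dependent genes rescued in
#'   `rescue_background`.
#' @param n_bins Bins per simulated chromosome.
#' @param bin_size Bin width in bp.
#' @param compartment_block_size Width, in bins, of alternating A/B blocks.
#' @param compartment_strength Within-compartment contact enrichment; pairs in
#'   the same compartment are multiplied by `1 + s`, cross-compartment pairs
#'   divided by `1 + s`. Zero gives a compartment-free map.
#' @param contact_scale Expected contact count at distance one bin.
#' @param contact_decay Power-law exponent of the distance decay.
#' @param loop_enrichment Fold enrichment over the local expectation at
#'   planted loop anchors.
#' @param n_loops Number of random planted loops when none are supplied.
#' @param peak_reproducibility Probability that a true peak is called in any
#'   one pseudo-replicate.
#' @param peak_width True peak width in bp.
#' @param peak_score_range Range of -log10(p) scores drawn for called peaks
#'   (above the 1e-4 caller threshold).
#' @param n_decoys Number of single-replicate decoy peaks; default half the
#'   number of true peaks.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 2000L,
                       n_induced = 400L,
                       n_down = 200L,
                       frac_dependent = 0.6,
                       induction_lfc_range = c(1, 3),
                       attenuation = 0.15,
                       dispersion = 0.02,
                       baseline_meanlog = log(400),
                       baseline_sdlog = 0.8,
                       intronic_fraction = 0.2,
                       size_factors = NULL,
                       size_factor_sdlog = 0.15,
                       n_reps = 2L,
                       backgrounds = c("WT", "TKO"),
                       rescue_background = NULL,
                       rescue_fraction = 0.5,
                       n_bins = 500L,
                       bin_size = 10000L,
                       compartment_block_size = 20L,
                       compartment_strength = 0.5,
                       contact_scale = 200,
                       contact_decay = 1.0,
                       loop_enrichment = 10,
                       n_loops = 10L,
                       peak_reproducibility = 0.9,
                       peak_width = 200L,
                       peak_score_range = c(4.5, 9),
                       n_decoys = NULL) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_genes >= 1, n_induced + n_down <= n_genes,
    frac_dependent >= 0, frac_dependent <= 1,
    dispersion > 0,
    intronic_fraction > 0, intronic_fraction <= 1,
    is.null(size_factors) || all(size_factors > 0),
    n_reps >= 1, length(backgrounds) >= 1,
    n_bins >= 2, bin_size > 0, compartment_block_size >= 1,
    compartment_strength >= 0, contact_scale > 0,
    loop_enrichment > 0,
    peak_reproducibility >= 0, peak_reproducibility <= 1
  )
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

# Gene truth labels shared by simulate_counts and simulate_study.
sim_gene_truth <- function(config) {
  n <- config$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  label <- rep("invariant", n)
  n_dep <- round(config$n_induced * config$frac_dependent)
  if (config$n_induced > 0) {
    label[seq_len(config$n_induced)] <-
      c(rep("induced-dependent", n_dep),
        rep("induced-independent", config$n_induced - n_dep))
  }
  if (config$n_down > 0) {
    label[config$n_induced + seq_len(config$n_down)] <- "down-regulated"
  }
  base_mean <- rlnorm(n, config$baseline_meanlog, config$baseline_sdlog)
  lfc_wt <- numeric(n)
  induced <- label %in% c("induced-dependent", "induced-independent")
  lfc_wt[induced] <- runif(sum(induced),
                           config$induction_lfc_range[1],
                           config$induction_lfc_range[2])
  down <- label == "down-regulated"
  lfc_wt[down] <- -runif(sum(down),
                         config$induction_lfc_range[1],
                         config$induction_lfc_range[2])
  rescued <- rep(FALSE, n)
  dep_idx <- which(label == "induced-dependent")
  if (!is.null(config$rescue_background) && length(dep_idx) > 0) {
    n_resc <- round(length(dep_idx) * config$rescue_fraction)
    rescued[sample(dep_idx, n_resc)] <- TRUE
  }
  tibble(gene_id = gene_id, label = label, base_mean = base_mean,
         lfc_wt = lfc_wt, rescued = rescued)
}

#' Simulate total and intronic RNA-seq count tables with planted truth
#'
#' Draws negative-binomial latent transcript counts per library and obtains
#' intronic counts by binomial thinning of the same latent signal, so both
#' read classes share the planted fold-change structure. Induced genes carry
#' their log2 fold change in the reference (first) background under TPA;
#' dependent genes have it multiplied by `attenuation` in every other
#' background, except rescued genes in `rescue_background`, which regain the
#' full wild-type fold change.
#'
#' @param config A [sim_config()].
#' @return A list with `counts` (wide tibble, `gene_id` + one column per
#'   sample named `background_condition_rep_readclass`), `samples` (descriptor
#'   tibble), and `truth` (gene labels, baseline means, wild-type log2 fold
#'   changes, rescue flags, and the per-library true size factors as the
#'   `size_factors` attribute of the list).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- sim_gene_truth(config)

  libs <- tidyr::expand_grid(
    background = config$backgrounds,
    condition = c("resting", "TPA"),
    replicate = seq_len(config$n_reps)
  )
  n_lib <- nrow(libs)
  sf <- config$size_factors
  if (is.null(sf)) {
    sf <- rlnorm(n_lib, 0, config$size_factor_sdlog)
  } else {
    if (length(sf) == 1L) sf <- rep(sf, n_lib)
    stopifnot(length(sf) == n_lib)
  }
  libs$size_factor <- sf

  dep <- truth$label == "induced-dependent"
  n <- config$n_genes
  cols_total <- vector("list", n_lib)
  cols_intr <- vector("list", n_lib)
  for (k in seq_len(n_lib)) {
    lfc <- numeric(n)
    if (libs$condition[k] == "TPA") {
      lfc <- truth$lfc_wt
      bg <- libs$background[k]
      if (bg != config$backgrounds[1]) {
        att <- ifelse(dep, config$attenuation, 1)
        if (!is.null(config$rescue_background) && bg == config$rescue_background) {
          att[dep & truth$rescued] <- 1
        }
        lfc <- lfc * att
      }
    }
    mu <- libs$size_factor[k] * truth$base_mean * 2^lfc
    latent <- rnbinom(n, mu = mu, size = 1 / config$dispersion)
    cols_total[[k]] <- latent
    cols_intr[[k]] <- rbinom(n, latent, config$intronic_fraction)
  }
  lib_id <- sprintf("%s_%s_%d", libs$background, libs$condition, libs$replicate)
  counts <- tibble(gene_id = truth$gene_id)
  for (k in seq_len(n_lib)) counts[[paste0(lib_id[k], "_total")]] <- cols_total[[k]]
  for (k in seq_len(n_lib)) counts[[paste0(lib_id[k], "_intronic")]] <- cols_intr[[k]]

  samples <- parse_samples(names(counts)[-1]) |>
    left_join(mutate(libs, lib = lib_id), by = c("background", "condition", "replicate")) |>
    select(-"lib")

  list(counts = counts, samples = samples, truth = truth)
}

# Compartment labels for a simulated chromosome.
sim_compartments <- function(config) {
  if (config$compartment_strength == 0) {
    return(rep("A", config$n_bins))
  }
  blocks <- ceiling(config$n_bins / config$compartment_block_size)
  rep(rep(c("A", "B"), length.out = blocks),
      each = config$compartment_block_size)[seq_len(config$n_bins)]
}

# Analytic expected contact count for bin pairs at distance d >= 1.
sim_expected_contact <- function(config, d, same_compartment, is_loop) {
  base <- config$contact_scale * d^(-config$contact_decay)
  if (config$compartment_strength > 0) {
    base <- base * ifelse(same_compartment,
                          1 + config$compartment_strength,
                          1 / (1 + config$compartment_strength))
  }
  base * ifelse(is_loop, config$loop_enrichment, 1)
}

#' Simulate an intra-chromosomal Hi-C contact map with planted structure
#'
#' The expected count for a bin pair at distance d bins is a power law
#' `contact_scale * d^-contact_decay`, multiplied by the compartment factor
#' (same-compartment pairs enriched, cross-compartment depressed) and by
#' `loop_enrichment` at planted loop anchors; observed counts are Poisson.
#'
#' @param config A [sim_config()].
#' @param loops Optional tibble with columns `bin_i`, `bin_j` giving planted
#'   loop anchors; when `NULL`, `config$n_loops` random pairs at distances
#'   between 20 bins and half the chromosome are planted.
#' @param chrom Chromosome name for the emitted map.
#' @return A list with `map` (a [contact_map()]) and `truth` (per-bin
#'   compartment labels and the planted loop list).
#' @export
simulate_contacts <- function(config, loops = NULL, chrom = "chr1") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1000L)
  nb <- config$n_bins
  comp <- sim_compartments(config)

  if (is.null(loops)) {
    if (config$n_loops > 0) {
      dmin <- min(20L, nb %/% 4L)
      a <- sample.int(nb, config$n_loops, replace = TRUE) - 1L
      gap <- sample(seq(dmin, max(dmin + 1L, nb %/% 2L)), config$n_loops, replace = TRUE)
      b <- pmin(a + gap, nb - 1L)
      loops <- tibble(bin_i = pmin(a, b), bin_j = pmax(a, b)) |>
        filter(.data$bin_j > .data$bin_i) |>
        distinct()
    } else {
      loops <- tibble(bin_i = integer(), bin_j = integer())
    }
  }
  stopifnot(all(loops$bin_i >= 0), all(loops$bin_j < nb))

  pairs <- tidyr::expand_grid(bin_i = 0:(nb - 1L), bin_j = 0:(nb - 1L)) |>
    filter(.data$bin_j > .data$bin_i)
  d <- pairs$bin_j - pairs$bin_i
  same <- comp[pairs$bin_i + 1L] == comp[pairs$bin_j + 1L]
  key <- paste(pairs$bin_i, pairs$bin_j)
  is_loop <- key %in% paste(loops$bin_i, loops$bin_j)
  lambda <- sim_expected_contact(config, d, same, is_loop)
  cnt <- rpois(nrow(pairs), lambda)

  map <- contact_map(
    tibble(chrom = chrom, bin_i = pairs$bin_i, bin_j = pairs$bin_j, count = cnt),
    bin_size = config$bin_size
  )
  list(map = map,
       truth = list(compartments = comp, loops = loops,
                    expected = function(i, j) {
                      sim_expected_contact(
                        config, abs(j - i),
                        comp[i + 1L] == comp[j + 1L],
                        paste(pmin(i, j), pmax(i, j)) %in%
                          paste(loops$bin_i, loops$bin_j)
                      )
                    }))
}

#' Simulate non-overlapping true binding sites
#'
#' Places `n_peaks` peaks of width `config$peak_width` on a uniform grid over
#' the simulated chromosome so that no two peaks are closer than 500 bp
#' (single-linkage consensus clustering then never merges distinct sites).
#'
#' @param config A [sim_config()].
#' @param n_peaks Number of true peaks.
#' @param chrom Chromosome name.
#' @return Interval tibble of true peaks with `name` and `score` columns.
#' @export
simulate_true_peaks <- function(config, n_peaks, chrom = "chr1") {
  set.seed(config$seed + 2000L)
  genome <- config$n_bins * config$bin_size
  pitch <- config$peak_width + 600L
  slots <- seq(0L, genome - config$peak_width - 1L, by = pitch)
  stopifnot(n_peaks <= length(slots))
  start <- sort(sample(slots, n_peaks))
  tibble(
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(start + config$peak_width),
    name = sprintf("peak%04d", seq_len(n_peaks)),
    score = runif(n_peaks, config$peak_score_range[1], config$peak_score_range[2]),
    strand = "."
  )
}

#' Simulate pseudo-replicate peak calls around a set of true peaks
#'
#' Each true peak is called in each pseudo-replicate independently with
#' probability `peak_reproducibility`, with its position jittered by at most
#' 50 bp and a fresh -log10(p) score drawn above the caller threshold. Decoy
#' peaks, emulating irreproducible caller noise, each appear in exactly one
#' pseudo-replicate.
#'
#' @param config A [sim_config()].
#' @param true_peaks Interval tibble of true peaks (see
#'   [simulate_true_peaks()]).
#' @param n_pseudo Number of pseudo-replicates (>= 1).
#' @return A list of `n_pseudo` interval tibbles.
#' @export
simulate_peak_replicates <- function(config, true_peaks, n_pseudo) {
  stopifnot(inherits(config, "sim_config"), n_pseudo >= 1)
  set.seed(config$seed + 3000L)
  n_true <- nrow(true_peaks)
  n_dec <- config$n_decoys
  if (is.null(n_dec)) n_dec <- n_true %/% 2L
  genome <- config$n_bins * config$bin_size

  reps <- vector("list", n_pseudo)
  for (r in seq_len(n_pseudo)) {
    present <- runif(n_true) < config$peak_reproducibility
    jit <- as.integer(round(runif(sum(present), -50, 50)))
    called <- true_peaks[present, , drop = FALSE]
    called$start <- pmax(0L, called$start + jit)
    called$end <- called$start + config$peak_width
    called$score <- runif(nrow(called),
                          config$peak_score_range[1], config$peak_score_range[2])
    reps[[r]] <- called
  }
  if (n_dec > 0) {
    dstart <- as.integer(runif(n_dec, 0, genome - config$peak_width))
    home <- sample.int(n_pseudo, n_dec, replace = TRUE)
    for (r in seq_len(n_pseudo)) {
      idx <- which(home == r)
      if (length(idx) == 0) next
      dec <- tibble(
        chrom = true_peaks$chrom[1],
        start = dstart[idx],
        end = dstart[idx] + config$peak_width,
        name = sprintf("decoy%04d", idx),
        score = runif(length(idx),
                      config$peak_score_range[1], config$peak_score_range[2]),
        strand = "."
      )
      reps[[r]] <- bind_rows(reps[[r]], dec) |> arrange(.data$start)
    }
  }
  reps
}
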