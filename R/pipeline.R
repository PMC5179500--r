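#' Simulate a coordinated multi-assay study with planted target classes
#'
#' Generates, from one configuration, every input of the integrated pipeline
#' on a single synthetic chromosome: total/intronic count tables for all
#' backgrounds, TSS annotations for every gene, true SRF binding sites in two
#' clusters, pseudo-replicate peak calls, Elk-1 sites (some SRF-coincident,
#' some solo), and a contact map carrying planted TSS-site loops. Dependent
#' genes are placed so their planted class is unambiguous:
#'
#' * *Direct-proximal*: TSS within 5 kb of a site;
#' * *Direct-remote*: TSS > 100 kb from every site, with a planted loop to a
#'   site-bearing bin;
#' * *Indirect*: TSS > 100 kb from every site, unlooped;
#' * the remaining dependent genes sit in the 30-80 kb evidence gap
#'   (planted Unassigned).
#'
#' Non-dependent genes are placed uniformly. The contact map is generated
#' without compartment blocks by default because the interaction caller's
#' expected model is deliberately compartment-blind; compartment recovery is
#' exercised on dedicated block maps ([simulate_contacts()]).
#'
#' @param config A [sim_config()].
#' @param n_direct_proximal,n_direct_remote,n_indirect Numbers of dependent
#'   genes planted in each class (the rest fall in the evidence gap).
#' @param n_pseudo Pseudo-replicates for the peak generator.
#' @param n_decoy_loops Random loops between non-site bins (links to
#'   non-site bins must never drive classification).
#' @param flat_compartments Generate the map with `compartment_strength = 0`
#'   (default).
#' @return A list: `counts`, `samples`, `truth` (gene tibble with
#'   `planted_class`), `tss`, `srf_sites`, `elk_sites`, `peak_reps`, `map`,
#'   `loops`, `config`.
#' @export
simulate_study <- function(config,
                           n_direct_proximal = 50L,
                           n_direct_remote = 40L,
                           n_indirect = 100L,
                           n_pseudo = 4L,
                           n_decoy_loops = 15L,
                           flat_compartments = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cnt <- simulate_counts(config)
  truth <- cnt$truth
  nb <- config$n_bins
  bs <- config$bin_size
  genome <- nb * bs

  set.seed(config$seed + 4000L)
  site_bins <- as.integer(round(nb * c(0.12, 0.72)))
  offsets <- c(1500L, 4800L, 8100L)
  srf_sites <- tidyr::expand_grid(bin = site_bins, off = offsets) |>
    mutate(
      chrom = "chr1",
      start = .data$bin * bs + .data$off,
      end = .data$start + config$peak_width,
      name = sprintf("srf%02d", row_number()),
      score = 8,
      strand = "."
    ) |>
    select("chrom", "start", "end", "name", "score", "strand")
  site_summits <- peak_summit(srf_sites)

  dep_genes <- sample(truth$gene_id[truth$label == "induced-dependent"])
  need <- n_direct_proximal + n_direct_remote + n_indirect
  if (length(dep_genes) < need) {
    abort("not enough dependent genes for the requested planted classes")
  }
  g_prox <- dep_genes[seq_len(n_direct_proximal)]
  g_remote <- dep_genes[n_direct_proximal + seq_len(n_direct_remote)]
  g_indirect <- dep_genes[n_direct_proximal + n_direct_remote + seq_len(n_indirect)]
  g_gap <- setdiff(dep_genes, c(g_prox, g_remote, g_indirect))

  # bins far (> 100 kb, with margin) from both site clusters
  far_bins <- setdiff(2:(nb - 3L),
                      unlist(lapply(site_bins, function(s) (s - 12L):(s + 12L))))
  picked <- sample(far_bins, n_direct_remote + n_indirect)
  remote_bins <- picked[seq_len(n_direct_remote)]
  indirect_bins <- picked[n_direct_remote + seq_len(n_indirect)]

  pos_of <- function(bins) bins * bs + 5000L
  prox_site <- rep(seq_len(nrow(srf_sites)), length.out = n_direct_proximal)
  prox_off <- rep(c(-4000L, -2000L, 2000L, 4000L), length.out = n_direct_proximal)
  gap_cluster <- rep(site_bins, length.out = length(g_gap))
  gap_off <- (sample(c(-1L, 1L), length(g_gap), replace = TRUE) *
                as.integer(runif(length(g_gap), 30000, 80000)))

  placed <- bind_rows(
    tibble(gene_id = g_prox,
           pos = pmax(0L, site_summits[prox_site] + prox_off),
           planted_class = "Direct"),
    tibble(gene_id = g_remote, pos = pos_of(remote_bins),
           planted_class = "Direct"),
    tibble(gene_id = g_indirect, pos = pos_of(indirect_bins),
           planted_class = "Indirect"),
    tibble(gene_id = g_gap,
           pos = pmin(genome - 2000L,
                      pmax(0L, gap_cluster * bs + 5000L + gap_off)),
           planted_class = "Unassigned")
  )
  others <- setdiff(truth$gene_id, placed$gene_id)
  placed <- bind_rows(
    placed,
    tibble(gene_id = others,
           pos = as.integer(runif(length(others), 0, genome - 2000L)),
           planted_class = "none")
  )
  placed <- placed[match(truth$gene_id, placed$gene_id), ]
  truth$planted_class <- placed$planted_class
  truth$tss <- placed$pos

  tss <- tibble(
    chrom = "chr1",
    start = placed$pos,
    end = placed$pos + 1000L,
    name = placed$gene_id,
    score = NA_real_,
    strand = "+"
  )

  remote_sites <- rep(site_bins, length.out = n_direct_remote)
  loops <- tibble(bin_i = pmin(remote_bins, remote_sites),
                  bin_j = pmax(remote_bins, remote_sites))
  if (n_decoy_loops > 0) {
    da <- sample(far_bins, n_decoy_loops)
    db <- sample(far_bins, n_decoy_loops)
    dec <- tibble(bin_i = pmin(da, db), bin_j = pmax(da, db)) |>
      filter(.data$bin_j - .data$bin_i >= 20L)
    loops <- bind_rows(loops, dec) |> distinct()
  }

  map_cfg <- config
  if (flat_compartments) map_cfg$compartment_strength <- 0
  contacts <- simulate_contacts(map_cfg, loops = loops)

  peak_reps <- simulate_peak_replicates(config, srf_sites, n_pseudo = n_pseudo)

  set.seed(config$seed + 5000L)
  elk_assoc <- srf_sites[sample(nrow(srf_sites), 4L), ] |>
    mutate(name = sprintf("elk%02d", row_number()))
  solo_pos <- as.integer(sample(far_bins, 2L) * bs + 2500L)
  elk_solo <- tibble(chrom = "chr1", start = solo_pos,
                     end = solo_pos + config$peak_width,
                     name = c("elk_solo1", "elk_solo2"),
                     score = 8, strand = ".")
  elk_sites <- bind_rows(elk_assoc, elk_solo)

  list(counts = cnt$counts, samples = cnt$samples, truth = truth, tss = tss,
       srf_sites = srf_sites, elk_sites = elk_sites, peak_reps = peak_reps,
       map = contacts$map, loops = loops, config = config)
}

# Per-read-class sample columns for a background/condition.
study_cols <- function(samples, background, condition, read_class) {
  samples$sample[samples$background == background &
                   samples$condition == condition &
                   samples$read_class == read_class]
}

#' Run the integrated pipeline on a simulated study
#'
#' Executes the full chain - invariant-gene normalization, NB induction
#' testing on both read classes in both backgrounds, regulation calls,
#' iterative dependence partition, pseudo-replicate peak consensus,
#' interaction calling, TSS linkage, Direct/Indirect classification, Elk-1
#' coincidence, and the summary report - and scores recovery against the
#' planted truth.
#'
#' @param study Output of [simulate_study()].
#' @param tau,delta_min Partition parameters (see [iterate_partition()]).
#' @param alpha,min_change Regulation-call thresholds
#'   (see [call_regulated()]).
#' @return A list with every intermediate (`norm_factors`, `de`,
#'   `regulation`, `partition`, `consensus_peaks`, `interactions`, `links`,
#'   `classification`, `coincidence`, `summary`) plus `metrics`: precision
#'   and recall of dependent labels and of the planted Direct and Indirect
#'   classes, and the fitted attenuation slope.
#' @export
run_study <- function(study, tau = 0.5, delta_min = 0.2,
                      alpha = 0.01, min_change = 0.10) {
  cfg <- study$config
  samples <- study$samples
  counts <- study$counts
  bgs <- cfg$backgrounds
  stopifnot(length(bgs) >= 2)

  # size factors per read class, reference = first resting library of the
  # reference background
  sf <- c()
  norms <- list()
  for (rc in c("total", "intronic")) {
    cols <- samples$sample[samples$read_class == rc]
    ref <- study_cols(samples, bgs[1], "resting", rc)[1]
    nrm <- compute_size_factors(counts[, c("gene_id", cols)], reference_sample = ref)
    sf <- c(sf, setNames(nrm$factors$size_factor, nrm$factors$sample))
    norms[[rc]] <- nrm
  }

  de <- list()
  for (bg in bgs) {
    for (rc in c("total", "intronic")) {
      de[[bg]][[rc]] <- test_induction(
        counts,
        study_cols(samples, bg, "resting", rc),
        study_cols(samples, bg, "TPA", rc),
        sf
      )
    }
  }

  regulation <- call_regulated(de[[bgs[1]]]$total, de[[bgs[1]]]$intronic,
                               alpha = alpha, min_change = min_change)
  induced_genes <- regulation$gene_id[regulation$call == "induced"]

  pairs <- induction_ratios(de[[bgs[1]]], de[[bgs[2]]], induced_genes)
  part <- iterate_partition(pairs, tau = tau, delta_min = delta_min)
  dep_calls <- tidy(part)

  cons <- consensus(study$peak_reps, p_threshold = 1e-4, min_support = 3L)
  retained <- filter(cons, .data$retained)

  model <- fit_expected(study$map, n_bins = cfg$n_bins)
  calls <- call_interactions(study$map, model)
  links <- link_tss(study$tss, retained, calls, bin_size = cfg$bin_size)

  classification <- classify_targets(study$tss, retained, links,
                                     regulation, dep_calls)
  coincidence <- coincide(study$elk_sites, retained)

  rescue <- NULL
  if (!is.null(cfg$rescue_background) && cfg$rescue_background %in% bgs) {
    pairs_rescue <- induction_ratios(de[[bgs[1]]], de[[cfg$rescue_background]],
                                     induced_genes)
    rescue <- classify_rescue(pairs_rescue,
                              dep_calls$gene_id[dep_calls$label == "dependent"],
                              tau = tau)
  }

  summary <- summarize_targets(
    classification, coincidences = coincidence, sites = retained,
    rescue = if (!is.null(rescue)) tidy(rescue) else NULL,
    bin_size = cfg$bin_size
  )

  truth <- study$truth
  pr <- function(pred, pos) {
    tp <- length(intersect(pred, pos))
    c(precision = if (length(pred) > 0) tp / length(pred) else NA_real_,
      recall = if (length(pos) > 0) tp / length(pos) else NA_real_)
  }
  dep_pred <- dep_calls$gene_id[dep_calls$label == "dependent"]
  dep_true <- truth$gene_id[truth$label == "induced-dependent"]
  dir_pred <- classification$gene_id[classification$class == "Direct"]
  dir_true <- truth$gene_id[truth$planted_class == "Direct"]
  ind_pred <- classification$gene_id[classification$class == "Indirect"]
  ind_true <- truth$gene_id[truth$planted_class == "Indirect"]
  metrics <- tibble(
    quantity = c("dependent", "direct", "indirect"),
    precision = c(pr(dep_pred, dep_true)["precision"],
                  pr(dir_pred, dir_true)["precision"],
                  pr(ind_pred, ind_true)["precision"]),
    recall = c(pr(dep_pred, dep_true)["recall"],
               pr(dir_pred, dir_true)["recall"],
               pr(ind_pred, ind_true)["recall"])
  )

  list(norm_factors = norms, de = de, regulation = regulation,
       partition = part, consensus_peaks = cons, interactions = calls,
       links = links, classification = classification,
       coincidence = coincidence, rescue = rescue, summary = summary,
       metrics = metrics)
}
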