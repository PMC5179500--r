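#' Pseudo-replicate consensus peak set
#'
#' Clusters peaks from all pseudo-replicates by single-linkage overlap
#' (>= 1 bp) and retains a cluster when at least `min_support` distinct
#' pseudo-replicates contribute a peak called below the p threshold. Peak
#' scores are -log10(p), so `p < p_threshold` means `score > -log10
#' (p_threshold)`. The retained cluster is reported as the union interval;
#' its summit is the mean summit of the qualifying member peaks.
#'
#' @param replicate_peaks List of interval tibbles, one per pseudo-replicate.
#' @param p_threshold Per-replicate peak p-value cutoff (default 1e-4).
#' @param min_support Minimum number of distinct supporting pseudo-replicates
#'   (default 3).
#' @return A `consensus_peaks` tibble: `chrom`, `start`, `end`, `summit`,
#'   `n_support`, `best_score`, `retained`. All clusters are reported;
#'   filter on `retained` for the high-confidence set.
#' @export
consensus <- function(replicate_peaks, p_threshold = 1e-4, min_support = 3L) {
  if (length(replicate_peaks) < min_support) {
    abort(sprintf("need at least min_support = %d pseudo-replicate sets", min_support))
  }
  score_min <- -log10(p_threshold)
  all_peaks <- bind_rows(
    purrr::imap(replicate_peaks, function(pk, i) mutate(pk, .rep = i))
  )
  if (nrow(all_peaks) == 0) {
    return(structure(
      tibble(chrom = character(), start = integer(), end = integer(),
             summit = integer(), n_support = integer(),
             best_score = double(), retained = logical()),
      class = c("consensus_peaks", class(tibble()))
    ))
  }
  gr <- intervals_to_granges(all_peaks)
  clusters <- GenomicRanges::reduce(gr, ignore.strand = TRUE, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, clusters, ignore.strand = TRUE)
  all_peaks$cluster <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  all_peaks$summit_pos <- peak_summit(all_peaks)

  out <- all_peaks |>
    group_by(.data$cluster) |>
    summarise(
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      n_support = dplyr::n_distinct(.data$.rep[.data$score > score_min]),
      best_score = max(.data$score),
      summit = as.integer(round(mean(
        .data$summit_pos[.data$score > score_min]
      ))),
      .groups = "drop"
    ) |>
    mutate(
      summit = if_else(.data$n_support > 0, .data$summit,
                       as.integer((.data$start + .data$end) %/% 2L)),
      retained = .data$n_support >= min_support
    ) |>
    select("chrom", "start", "end", "summit", "n_support", "best_score",
           "retained") |>
    arrange(.data$chrom, .data$start)
  class(out) <- c("consensus_peaks", class(out))
  out
}

#' Differential occupancy filter against a control
#'
#' Retains consensus peaks whose normalized ChIP read count exceeds the
#' control by at least `min_fold` with an NB-test p value at or below
#' `alpha`. The NB test is the package's conditional test ([nb_test()]).
#'
#' @param peaks A `consensus_peaks` tibble.
#' @param chip_counts,control_counts Per-peak raw read counts (vectors or
#'   genes-x-replicates matrices) for the ChIP and control libraries, in
#'   `peaks` row order.
#' @param sf_chip,sf_control Size factors of the ChIP and control libraries.
#' @param min_fold Minimum ChIP/control fold (default 1.5).
#' @param alpha p-value cutoff (default 0.05).
#' @param dispersion NB dispersion for the test (default 0.02); required when
#'   libraries are unreplicated.
#' @return `peaks` with added `fold`, `occupancy_p` and an updated `retained`
#'   flag (`retained` now requires consensus support *and* the occupancy
#'   filter). Peaks with no reads in either library are dropped by the filter
#'   (`p = 1`).
#' @export
differential_occupancy <- function(peaks, chip_counts, control_counts,
                                   sf_chip = 1, sf_control = 1,
                                   min_fold = 1.5, alpha = 0.05,
                                   dispersion = 0.02) {
  if (is.null(dim(chip_counts))) chip_counts <- matrix(chip_counts, ncol = length(sf_chip))
  if (is.null(dim(control_counts))) control_counts <- matrix(control_counts, ncol = length(sf_control))
  stopifnot(nrow(chip_counts) == nrow(peaks),
            nrow(control_counts) == nrow(peaks))
  # nb_test is (a = control, b = chip) so log2fc > 0 means enrichment
  res <- nb_test(control_counts, chip_counts, sf_control, sf_chip,
                 dispersion = dispersion)
  mean_chip <- rowMeans(sweep(chip_counts, 2, sf_chip, "/"))
  mean_ctrl <- rowMeans(sweep(control_counts, 2, sf_control, "/"))
  fold <- ifelse(mean_chip == 0 & mean_ctrl == 0, NA_real_,
                 mean_chip / pmax(mean_ctrl, .Machine$double.eps))
  out <- peaks |>
    mutate(
      fold = fold,
      occupancy_p = res$pvalue,
      retained = .data$retained & !is.na(fold) & fold >= min_fold &
        res$pvalue <= alpha
    )
  class(out) <- unique(c("consensus_peaks", class(out)))
  out
}

#' SRF coincidence of Elk-1 peaks
#'
#' Labels each Elk-1 peak `SRF-associated` when its summit lies within an
#' SRF peak interval extended by `slop` bp on each side, and `solo`
#' otherwise. The partition is exhaustive and exclusive.
#'
#' @param elk_peaks,srf_peaks `consensus_peaks` tibbles (or any interval
#'   tibble with a summit; [peak_summit()] conventions apply). Only retained
#'   SRF peaks should be passed if the filter is intended.
#' @param slop Extension of SRF intervals in bp (default 100).
#' @return `elk_peaks` with an added `srf_label` column.
#' @export
coincide <- function(elk_peaks, srf_peaks, slop = 100L) {
  if (nrow(elk_peaks) == 0) {
    return(mutate(elk_peaks, srf_label = character(0)))
  }
  summit <- peak_summit(elk_peaks)
  if (nrow(srf_peaks) == 0) {
    return(mutate(elk_peaks, srf_label = "solo"))
  }
  pt <- GenomicRanges::GRanges(
    seqnames = elk_peaks$chrom,
    ranges = IRanges::IRanges(start = summit + 1L, width = 1L)
  )
  srf <- GenomicRanges::GRanges(
    seqnames = srf_peaks$chrom,
    ranges = IRanges::IRanges(
      start = pmax(0L, srf_peaks$start - as.integer(slop)) + 1L,
      end = srf_peaks$end + as.integer(slop)
    )
  )
  hits <- GenomicRanges::countOverlaps(pt, srf, ignore.strand = TRUE)
  mutate(elk_peaks, srf_label = if_else(hits > 0, "SRF-associated", "solo"))
}
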