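#' Distance from TSS bases to the nearest binding site
#'
#' For each TSS base, the minimum over same-chromosome sites of 0 when the
#' base lies inside the (0-based half-open) site interval, else the gap to
#' the nearest site edge. Strand-agnostic. `Inf` when the chromosome carries
#' no site.
#'
#' @param tss_chrom,tss_pos Chromosome and base position vectors of the TSSs.
#' @param sites Interval tibble of sites.
#' @return Numeric vector of distances in bp.
#' @export
nearest_site_distance <- function(tss_chrom, tss_pos, sites) {
  vapply(seq_along(tss_pos), function(k) {
    s <- sites[sites$chrom == tss_chrom[k], , drop = FALSE]
    if (nrow(s) == 0) return(Inf)
    p <- tss_pos[k]
    inside <- p >= s$start & p < s$end
    if (any(inside)) return(0)
    min(pmax(s$start - p, p - s$end + 1L))
  }, numeric(1))
}

#' Direct / Indirect target classification
#'
#' Integrates induction calls, dependence labels, binding-site proximity and
#' Hi-C linkage into the target-gene classes: a gene is **Direct** when it is
#' induced, dependent, and its TSS is within `proximal_bp` of a site or
#' linked to a site-bearing bin by a significant interaction at any distance;
#' **Indirect** when induced, dependent, more than `distal_bp` from every
#' site, and unlinked; otherwise **Unassigned** (including the deliberate
#' 10-100 kb evidence gap, which is reported, never merged into a class).
#'
#' For multi-TSS genes the TSS minimising the site distance is used, and the
#' gene is linked when any of its TSSs is linked.
#'
#' @param tss Interval tibble of TSS annotations with `name` = gene id
#'   (multiple rows per gene allowed).
#' @param sites Interval tibble of retained binding sites.
#' @param links Output of [link_tss()] on the same `tss` rows.
#' @param induction_calls Tibble with `gene_id` and `call` from
#'   [call_regulated()].
#' @param dependence_calls Tibble with `gene_id` and `label` from
#'   [iterate_partition()] calls (`tidy()` output).
#' @param proximal_bp Direct proximity threshold (default 10,000).
#' @param distal_bp Indirect exclusion distance (default 100,000).
#' @return A tibble, one row per gene in `induction_calls`: `gene_id`,
#'   `nearest_distance`, `linked`, `n_links`, `induced`, `dependent`,
#'   `class`, and `remote` (Direct via linkage with nearest site beyond
#'   `proximal_bp`). Genes without TSS annotation are Unassigned.
#' @export
classify_targets <- function(tss, sites, links, induction_calls,
                             dependence_calls,
                             proximal_bp = 10000, distal_bp = 100000) {
  per_tss <- tibble(
    gene_id = tss$name,
    dist = nearest_site_distance(tss$chrom, tss_position(tss), sites),
    linked = links$linked,
    n_links = lengths(links$linked_bins)
  )
  per_gene <- per_tss |>
    group_by(.data$gene_id) |>
    summarise(
      nearest_distance = min(.data$dist),
      linked = any(.data$linked),
      n_links = sum(.data$n_links),
      .groups = "drop"
    )

  dep <- tibble(gene_id = dependence_calls$gene_id,
                dependent = dependence_calls$label == "dependent")
  out <- induction_calls |>
    select("gene_id", "call") |>
    left_join(per_gene, by = "gene_id") |>
    left_join(dep, by = "gene_id") |>
    mutate(
      induced = .data$call == "induced",
      dependent = !is.na(.data$dependent) & .data$dependent,
      has_tss = !is.na(.data$nearest_distance),
      linked = .data$has_tss & .data$linked,
      class = dplyr::case_when(
        !.data$has_tss ~ "Unassigned",
        .data$induced & .data$dependent &
          (.data$nearest_distance <= proximal_bp | .data$linked) ~ "Direct",
        .data$induced & .data$dependent &
          .data$nearest_distance > distal_bp & !.data$linked ~ "Indirect",
        .default = "Unassigned"
      ),
      remote = .data$class == "Direct" & .data$nearest_distance > proximal_bp
    ) |>
    select("gene_id", "nearest_distance", "linked", "n_links", "induced",
           "dependent", "class", "remote")
  n_no_tss <- sum(is.na(out$nearest_distance))
  if (n_no_tss > 0) {
    rlang::inform(sprintf(
      "classify_targets: %d gene(s) without TSS annotation set Unassigned",
      n_no_tss
    ))
  }
  out
}

#' Hypergeometric gene-set enrichment with Bonferroni adjustment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set and
#' each annotated set (intersected with the universe first), adjusted by
#' Bonferroni over the number of sets tested.
#'
#' @param query Character vector of query genes (must lie in `universe`).
#' @param annotated_sets Named list of character vectors.
#' @param universe Character vector: the gene universe.
#' @return A tibble: `set`, `universe_size`, `set_size`, `query_size`,
#'   `overlap`, `pvalue`, `p_bonferroni`.
#' @export
hypergeom_enrichment <- function(query, annotated_sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) abort("query genes must be a subset of the universe")
  n_sets <- length(annotated_sets)
  rows <- purrr::imap(annotated_sets, function(set, nm) {
    set <- intersect(unique(set), universe)
    ov <- length(intersect(set, query))
    p <- phyper(ov - 1, length(set), length(universe) - length(set),
                length(query), lower.tail = FALSE)
    tibble(set = nm, universe_size = length(universe),
           set_size = length(set), query_size = length(query),
           overlap = ov, pvalue = p,
           p_bonferroni = min(1, p * n_sets))
  })
  bind_rows(rows)
}

#' Summary report of the integrated target analysis
#'
#' Collects the headline counts and percentages of a pipeline run: induced
#' and dependent gene numbers, Direct/Indirect/Unassigned class sizes, the
#' remote-controlled fraction of Direct targets, the fraction of binding
#' sites falling in A compartments, Elk-1 SRF-associated vs solo site counts,
#' and rescued fractions by class. Every percentage equals
#' `100 * numerator / denominator` of counts also present in the report.
#'
#' @param classifications Output of [classify_targets()].
#' @param coincidences Optional output of [coincide()].
#' @param compartments Optional output of [compartment_pca()].
#' @param sites Optional interval tibble of retained sites (for the
#'   compartment fraction).
#' @param rescue Optional `tidy()` output of [classify_rescue()].
#' @param bin_size Bin width used for site-to-bin assignment.
#' @return A `target_summary` list of named scalars; `tidy()` turns it into
#'   a two-column tibble.
#' @export
summarize_targets <- function(classifications, coincidences = NULL,
                              compartments = NULL, sites = NULL,
                              rescue = NULL, bin_size = 10000L) {
  cls <- classifications
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  n_induced <- sum(cls$induced)
  n_dependent <- sum(cls$induced & cls$dependent)
  n_direct <- sum(cls$class == "Direct")
  n_indirect <- sum(cls$class == "Indirect")
  n_remote <- sum(cls$remote)
  out <- list(
    n_genes = nrow(cls),
    n_induced = n_induced,
    n_dependent = n_dependent,
    pct_dependent_of_induced = pct(n_dependent, n_induced),
    n_direct = n_direct,
    n_indirect = n_indirect,
    n_unassigned_dependent = sum(cls$induced & cls$dependent &
                                   cls$class == "Unassigned"),
    n_direct_remote = n_remote,
    pct_direct_remote = pct(n_remote, n_direct)
  )
  if (!is.null(coincidences) && nrow(coincidences) > 0) {
    n_assoc <- sum(coincidences$srf_label == "SRF-associated")
    n_solo <- sum(coincidences$srf_label == "solo")
    out$n_elk_sites <- n_assoc + n_solo
    out$n_elk_srf_associated <- n_assoc
    out$n_elk_solo <- n_solo
    out$pct_elk_srf_associated <- pct(n_assoc, n_assoc + n_solo)
  }
  if (!is.null(compartments) && !is.null(sites) && nrow(sites) > 0) {
    site_bins <- bin_of(peak_summit(sites), bin_size)
    lab <- compartments$label[match(site_bins, compartments$bin)]
    out$n_sites <- nrow(sites)
    out$n_sites_in_A <- sum(lab == "A", na.rm = TRUE)
    out$pct_sites_in_A <- pct(out$n_sites_in_A, out$n_sites)
  }
  if (!is.null(rescue) && nrow(rescue) > 0) {
    resc <- tibble(gene_id = rescue$gene_id,
                   rescued = rescue$label == "rescued") |>
      left_join(select(cls, "gene_id", "class"), by = "gene_id")
    out$n_rescued <- sum(resc$rescued)
    out$pct_rescued_of_dependent <- pct(out$n_rescued, nrow(resc))
    for (cl in c("Direct", "Indirect")) {
      sub <- filter(resc, .data$class == cl)
      out[[paste0("n_rescued_", tolower(cl))]] <- sum(sub$rescued)
      out[[paste0("pct_rescued_", tolower(cl))]] <- pct(sum(sub$rescued), nrow(sub))
    }
  }
  structure(out, class = "target_summary")
}

#' @export
print.target_summary <- function(x, ...) {
  cat("Integrated target analysis summary\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-28s %s\n", nm,
                if (is.na(v)) "NA" else format(round(v, 2))))
  }
  invisible(x)
}

#' @rdname summarize_targets
#' @param x A `target_summary`.
#' @param ... Unused.
#' @export
tidy.target_summary <- function(x, ...) {
  tibble(metric = names(x), value = as.numeric(unlist(x)))
}
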