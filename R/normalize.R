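#' Per-gene count differences between two samples
#'
#' The substrate of invariant-gene normalization: for every gene, the
#' difference in (by default log2) read counts between sample `b` and sample
#' `a`. On the log2 scale, `d_g = log2(count_b + pseudocount) -
#' log2(count_a + pseudocount)`; on the linear scale, the raw count
#' difference.
#'
#' @param counts Wide count tibble (`gene_id` + sample columns).
#' @param sample_a,sample_b Column names of the two samples; `a` is the
#'   reference of the comparison.
#' @param pseudocount Positive pseudocount added before taking logs.
#' @param diff_scale `"log2"` (default) or `"linear"`.
#' @return A tibble with columns `gene_id` and `diff`.
#' @export
pairwise_log_differences <- function(counts, sample_a, sample_b,
                                     pseudocount = 0.5,
                                     diff_scale = c("log2", "linear")) {
  diff_scale <- match.arg(diff_scale)
  if (!sample_a %in% names(counts)) abort(sprintf("unknown sample '%s'", sample_a))
  if (!sample_b %in% names(counts)) abort(sprintf("unknown sample '%s'", sample_b))
  stopifnot(pseudocount > 0)
  a <- counts[[sample_a]]
  b <- counts[[sample_b]]
  d <- if (diff_scale == "log2") {
    log2(b + pseudocount) - log2(a + pseudocount)
  } else {
    as.numeric(b - a)
  }
  tibble(gene_id = counts$gene_id, diff = d)
}

#' Select invariant genes from a difference vector
#'
#' Invariant genes are those whose between-sample count difference lies within
#' one standard deviation of the mean difference, treating the bulk of the
#' difference distribution as quasi-normal: the kept set is
#' `{g : |d_g - mu_diff| <= sigma_diff}` with `mu_diff` the mean and
#' `sigma_diff` the population standard deviation of `d`. When every
#' difference is identical (`sigma_diff = 0`) all genes are kept.
#'
#' @param d Numeric vector of per-gene differences (see
#'   [pairwise_log_differences()]).
#' @return A logical vector marking the invariant genes.
#' @export
select_invariant_genes <- function(d) {
  stopifnot(length(d) >= 2, all(is.finite(d)))
  mu <- mean(d)
  sigma <- sqrt(mean((d - mu)^2))
  if (sigma == 0) return(rep(TRUE, length(d)))
  abs(d - mu) <= sigma
}

#' Invariant-gene size factors for a count table
#'
#' For each sample, computes per-gene differences against the reference
#' sample, selects the invariant gene set (one pass of the 1-sigma rule), and
#' sets the size factor to `2^mean(d)` over that set (log2 scale) or to the
#' ratio of invariant-set means (linear scale). The reference sample's factor
#' is exactly 1. Genes with zero counts in both samples of a comparison carry
#' no scale information and are excluded before selection.
#'
#' @param counts Wide count tibble.
#' @param reference_sample Column name of the reference; defaults to the
#'   first sample column.
#' @param pseudocount,diff_scale Passed to [pairwise_log_differences()].
#' @return An `invariant_norm` object: a list with a per-sample `factors`
#'   tibble (`sample`, `mu_diff`, `sigma_diff`, `n_invariant`, `size_factor`)
#'   and the invariant-gene masks.
#' @export
compute_size_factors <- function(counts, reference_sample = NULL,
                                 pseudocount = 0.5,
                                 diff_scale = c("log2", "linear")) {
  diff_scale <- match.arg(diff_scale)
  if (nrow(counts) == 0L) abort("empty count table")
  samples <- setdiff(names(counts), "gene_id")
  if (length(samples) == 0L) abort("count table has no sample columns")
  if (is.null(reference_sample)) reference_sample <- samples[1]
  if (!reference_sample %in% samples) {
    abort(sprintf("reference sample '%s' not in table", reference_sample))
  }

  ref <- counts[[reference_sample]]
  rows <- purrr::map(samples, function(s) {
    if (s == reference_sample) {
      return(list(row = tibble(sample = s, mu_diff = 0, sigma_diff = 0,
                               n_invariant = nrow(counts), size_factor = 1),
                  mask = rep(TRUE, nrow(counts))))
    }
    informative <- !(ref == 0 & counts[[s]] == 0)
    d_all <- pairwise_log_differences(counts, reference_sample, s,
                                      pseudocount = pseudocount,
                                      diff_scale = diff_scale)$diff
    d <- d_all[informative]
    if (length(d) < 2) abort("fewer than 2 informative genes for invariant selection")
    inv <- select_invariant_genes(d)
    mu <- mean(d)
    sigma <- sqrt(mean((d - mu)^2))
    sf <- if (diff_scale == "log2") {
      2^mean(d[inv])
    } else {
      mean(counts[[s]][informative][inv] + pseudocount) /
        mean(ref[informative][inv] + pseudocount)
    }
    mask <- rep(FALSE, nrow(counts))
    mask[which(informative)[inv]] <- TRUE
    list(row = tibble(sample = s, mu_diff = mu, sigma_diff = sigma,
                      n_invariant = sum(inv), size_factor = sf),
         mask = mask)
  })

  out <- list(
    factors = bind_rows(purrr::map(rows, "row")),
    invariant_masks = setNames(purrr::map(rows, "mask"), samples),
    reference_sample = reference_sample,
    gene_id = counts$gene_id,
    diff_scale = diff_scale,
    pseudocount = pseudocount
  )
  class(out) <- "invariant_norm"
  out
}

#' @export
print.invariant_norm <- function(x, ...) {
  cat(sprintf("Invariant-gene normalization (reference: %s, scale: %s)\n",
              x$reference_sample, x$diff_scale))
  print(x$factors)
  invisible(x)
}

#' @rdname compute_size_factors
#' @param x An `invariant_norm` object.
#' @param ... Unused.
#' @export
tidy.invariant_norm <- function(x, ...) {
  x$factors
}

#' @rdname compute_size_factors
#' @export
glance.invariant_norm <- function(x, ...) {
  tibble(
    n_samples = nrow(x$factors),
    reference_sample = x$reference_sample,
    diff_scale = x$diff_scale,
    min_size_factor = min(x$factors$size_factor),
    max_size_factor = max(x$factors$size_factor)
  )
}

#' Apply size factors to a count table
#'
#' Divides each sample column by its size factor, yielding normalized
#' (generally non-integer) counts.
#'
#' @param counts Wide count tibble.
#' @param norm An `invariant_norm` from [compute_size_factors()], or a named
#'   numeric vector of size factors.
#' @return A tibble of normalized counts with the same shape.
#' @export
normalize_counts <- function(counts, norm) {
  sf <- if (inherits(norm, "invariant_norm")) {
    setNames(norm$factors$size_factor, norm$factors$sample)
  } else {
    norm
  }
  out <- counts
  for (s in setdiff(names(counts), "gene_id")) {
    if (!s %in% names(sf)) abort(sprintf("no size factor for sample '%s'", s))
    out[[s]] <- counts[[s]] / sf[[s]]
  }
  out
}
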