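#' Paired induction ratios between two backgrounds
#'
#' For each gene called induced in the reference background, extracts the
#' point `(x, y)` = (log2 induction in the reference background, log2
#' induction in the comparison background) for both the total and intronic
#' read classes. Genes missing from any of the four DE tables are excluded
#' with a message.
#'
#' @param de_wt,de_ko Named lists with elements `total` and `intronic`, each a
#'   DE tibble from [test_induction()] for the induction contrast in the
#'   reference (e.g. wild-type) and comparison (e.g. knockout) backgrounds.
#' @param induced_genes Character vector of genes called induced in the
#'   reference background.
#' @return A tibble: `gene_id`, `x_total`, `y_total`, `x_intronic`,
#'   `y_intronic`.
#' @export
induction_ratios <- function(de_wt, de_ko, induced_genes) {
  stopifnot(all(c("total", "intronic") %in% names(de_wt)),
            all(c("total", "intronic") %in% names(de_ko)))
  grab <- function(de, nm) {
    out <- select(de, "gene_id", "log2fc")
    names(out)[2] <- nm
    out
  }
  out <- tibble(gene_id = induced_genes) |>
    inner_join(grab(de_wt$total, "x_total"), by = "gene_id") |>
    inner_join(grab(de_ko$total, "y_total"), by = "gene_id") |>
    inner_join(grab(de_wt$intronic, "x_intronic"), by = "gene_id") |>
    inner_join(grab(de_ko$intronic, "y_intronic"), by = "gene_id")
  n_lost <- length(induced_genes) - nrow(out)
  if (n_lost > 0) {
    rlang::inform(sprintf(
      "induction_ratios: %d induced gene(s) missing from a DE table, excluded",
      n_lost
    ))
  }
  out
}

# Least-absolute-deviation slope through the origin: the minimiser of
# sum |y - b x| is a weighted median of the ratios y/x with weights |x|.
lad_slope_origin <- function(x, y) {
  keep <- is.finite(x) & is.finite(y) & x != 0
  x <- x[keep]
  y <- y[keep]
  if (length(x) == 0) return(NA_real_)
  r <- y / x
  w <- abs(x)
  ord <- order(r)
  r <- r[ord]
  w <- w[ord]
  cw <- cumsum(w)
  r[which(cw >= sum(w) / 2)[1]]
}

#' Fit the systematic induction relation between two backgrounds
#'
#' Fits a least-absolute-deviation slope through the origin of comparison
#' induction on reference induction (robust to the off-relation cloud), and
#' reports the Spearman correlation of the fitted points.
#'
#' @param x,y Paired log2 induction values (reference, comparison).
#' @return A `partition_fit` list: `beta`, `spearman_r`, `n`.
#' @export
fit_relation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10) abort("fit_relation needs at least 10 pairs")
  beta <- lad_slope_origin(x, y)
  r <- suppressWarnings(cor(x, y, method = "spearman"))
  structure(list(beta = beta, spearman_r = r, n = length(x)),
            class = "partition_fit")
}

#' @export
print.partition_fit <- function(x, ...) {
  cat(sprintf("Induction relation: slope %.3f, Spearman r %.3f (n = %d)\n",
              x$beta, x$spearman_r, x$n))
  invisible(x)
}

#' Iterative partition of induced genes into dependent and independent sets
#'
#' Labels each induced gene dependent (its induction follows a common
#' attenuated relation `y = beta x` in the comparison background, in both
#' read classes) or independent. Starting from the genes attenuated in both
#' read classes, the procedure alternates fitting a pooled
#' least-absolute-deviation slope through the origin on the current dependent
#' set with reassigning every gene by the residual rule
#' `|y - beta x| <= tau` in both read classes, until the label set is stable.
#' A gene can only be dependent while the fitted slope shows real attenuation
#' (`beta < 1 - delta_min`).
#'
#' @param pairs Tibble from [induction_ratios()].
#' @param tau Residual tolerance in log2 units (default 0.5).
#' @param delta_min Minimum attenuation: the dependent set is emptied if the
#'   fitted slope reaches `1 - delta_min` (default 0.2).
#' @param max_iter Iteration cap.
#' @return A `dependence_partition` list: `fit` (a `partition_fit` with
#'   `iterations` and `converged`), and `calls` (per-gene tibble with label
#'   `dependent`/`independent` and residuals). Genes with non-positive
#'   reference induction in either read class are excluded before fitting.
#' @export
iterate_partition <- function(pairs, tau = 0.5, delta_min = 0.2, max_iter = 50L) {
  stopifnot(tau > 0, delta_min >= 0, max_iter >= 1)
  if (nrow(pairs) < 10) abort("iterate_partition needs at least 10 induced genes")
  usable <- pairs$x_total > 0 & pairs$x_intronic > 0
  p <- pairs[usable, , drop = FALSE]
  if (nrow(p) < 10) abort("fewer than 10 genes with positive reference induction")

  dep <- p$y_total < p$x_total & p$y_intronic < p$x_intronic
  beta <- NA_real_
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (sum(dep) >= 2) {
      beta <- lad_slope_origin(c(p$x_total[dep], p$x_intronic[dep]),
                               c(p$y_total[dep], p$y_intronic[dep]))
    } else {
      beta <- NA_real_
    }
    if (is.na(beta) || beta >= 1 - delta_min) {
      new_dep <- rep(FALSE, nrow(p))
    } else {
      new_dep <- abs(p$y_total - beta * p$x_total) <= tau &
        abs(p$y_intronic - beta * p$x_intronic) <= tau
    }
    if (identical(new_dep, dep)) {
      converged <- TRUE
      dep <- new_dep
      break
    }
    dep <- new_dep
  }

  xs <- c(p$x_total[dep], p$x_intronic[dep])
  ys <- c(p$y_total[dep], p$y_intronic[dep])
  r <- if (sum(dep) >= 3) suppressWarnings(cor(xs, ys, method = "spearman")) else NA_real_

  fit <- structure(
    list(beta = beta, spearman_r = r, n = nrow(p), n_dependent = sum(dep),
         tau = tau, delta_min = delta_min, iterations = it,
         converged = converged),
    class = "partition_fit"
  )
  calls <- p
  calls$label <- ifelse(dep, "dependent", "independent")
  calls$resid_total <- p$y_total - beta * p$x_total
  calls$resid_intronic <- p$y_intronic - beta * p$x_intronic
  structure(list(fit = fit, calls = calls, excluded = pairs$gene_id[!usable]),
            class = "dependence_partition")
}

#' @export
print.dependence_partition <- function(x, ...) {
  cat(sprintf(
    "Dependence partition: %d/%d genes dependent; slope %.3f, Spearman r %.3f (%d iteration%s%s)\n",
    x$fit$n_dependent, x$fit$n, x$fit$beta, x$fit$spearman_r,
    x$fit$iterations, if (x$fit$iterations == 1) "" else "s",
    if (x$fit$converged) "" else ", not converged"
  ))
  invisible(x)
}

#' @rdname iterate_partition
#' @param x A `dependence_partition`.
#' @param ... Unused.
#' @export
tidy.dependence_partition <- function(x, ...) {
  x$calls
}

#' @rdname iterate_partition
#' @export
glance.dependence_partition <- function(x, ...) {
  tibble(
    beta = x$fit$beta, spearman_r = x$fit$spearman_r,
    n = x$fit$n, n_dependent = x$fit$n_dependent,
    tau = x$fit$tau, delta_min = x$fit$delta_min,
    iterations = x$fit$iterations, converged = x$fit$converged
  )
}

#' Label dependent genes rescued or refractory in a reconstituted background
#'
#' Applies the partition machinery to the relation between reference
#' (wild-type) induction and induction in a rescue background: a dependent
#' gene is rescued when it rejoins the systematic relation
#' `y = beta_r x` (residual within `tau` in both read classes) for the slope
#' fitted on the rescued cloud. The candidate set is initialised with genes
#' near full restoration (`|y - x| <= tau` in both classes).
#'
#' @param pairs_rescue Tibble like [induction_ratios()] output with `x_*` the
#'   reference-background and `y_*` the rescue-background log2 inductions.
#' @param dependent_genes Genes labelled dependent by [iterate_partition()].
#' @param tau Residual tolerance (log2 units).
#' @param beta_min Minimum rescued slope; below it the rescued set empties.
#' @param max_iter Iteration cap.
#' @return A `dependence_partition`-like list with labels
#'   `rescued`/`refractory`.
#' @export
classify_rescue <- function(pairs_rescue, dependent_genes, tau = 0.5,
                            beta_min = 0.5, max_iter = 50L) {
  p <- filter(pairs_rescue, .data$gene_id %in% dependent_genes,
              .data$x_total > 0, .data$x_intronic > 0)
  if (nrow(p) == 0) {
    return(structure(
      list(fit = structure(list(beta = NA_real_, spearman_r = NA_real_, n = 0L,
                                n_dependent = 0L, iterations = 0L,
                                converged = TRUE),
                           class = "partition_fit"),
           calls = mutate(p, label = character(0),
                          resid_total = numeric(0), resid_intronic = numeric(0))),
      class = "dependence_partition"
    ))
  }
  resc <- abs(p$y_total - p$x_total) <= tau & abs(p$y_intronic - p$x_intronic) <= tau
  beta <- NA_real_
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    if (sum(resc) >= 2) {
      beta <- lad_slope_origin(c(p$x_total[resc], p$x_intronic[resc]),
                               c(p$y_total[resc], p$y_intronic[resc]))
    } else {
      beta <- NA_real_
    }
    if (is.na(beta) || beta < beta_min) {
      new_resc <- rep(FALSE, nrow(p))
    } else {
      new_resc <- abs(p$y_total - beta * p$x_total) <= tau &
        abs(p$y_intronic - beta * p$x_intronic) <= tau
    }
    if (identical(new_resc, resc)) {
      converged <- TRUE
      resc <- new_resc
      break
    }
    resc <- new_resc
  }
  xs <- c(p$x_total[resc], p$x_intronic[resc])
  ys <- c(p$y_total[resc], p$y_intronic[resc])
  r <- if (sum(resc) >= 3) suppressWarnings(cor(xs, ys, method = "spearman")) else NA_real_
  fit <- structure(
    list(beta = beta, spearman_r = r, n = nrow(p), n_dependent = sum(resc),
         tau = tau, delta_min = NA_real_, iterations = it, converged = converged),
    class = "partition_fit"
  )
  calls <- p
  calls$label <- ifelse(resc, "rescued", "refractory")
  calls$resid_total <- p$y_total - beta * p$x_total
  calls$resid_intronic <- p$y_intronic - beta * p$x_intronic
  structure(list(fit = fit, calls = calls), class = "dependence_partition")
}
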