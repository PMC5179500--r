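# Synthetic induction-ratio clouds with known attenuation structure.
make_pairs <- function(n, frac_dep, attenuation, noise_sd, seed,
                       lfc_range = c(1, 3)) {
  set.seed(seed)
  n_dep <- round(n * frac_dep)
  x <- stats::runif(n, lfc_range[1], lfc_range[2])
  slope <- c(rep(attenuation, n_dep), rep(1, n - n_dep))
  tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    x_total = x,
    y_total = slope * x + stats::rnorm(n, 0, noise_sd),
    x_intronic = x + stats::rnorm(n, 0, noise_sd / 2),
    y_intronic = slope * x + stats::rnorm(n, 0, noise_sd),
    dep = seq_len(n) <= n_dep
  )
}

test_that("induction ratios pair genes across backgrounds and log missing ones", {
  mk <- function(g, lfc) tibble::tibble(gene_id = g, log2fc = lfc,
                                        base_mean = 1, pvalue = 1, padj = 1,
                                        dispersion = 0)
  de_wt <- list(total = mk(c("a", "b"), c(2, 2)), intronic = mk(c("a", "b"), c(2, 2)))
  de_ko <- list(total = mk(c("a", "b"), c(2, 0)), intronic = mk("a", 2))
  expect_message(p <- induction_ratios(de_wt, de_ko, c("a", "b")), "excluded")
  expect_equal(p$gene_id, "a")
  expect_equal(p$x_total, 2)
  expect_equal(p$y_total, 2)
})

test_that("the LAD fit recovers exact and noisy slopes through the origin", {
  x <- seq(0.5, 4, length.out = 50)
  f <- fit_relation(x, 0.5 * x)
  expect_equal(f$beta, 0.5, tolerance = 1e-12)
  expect_equal(f$spearman_r, 1)
  f1 <- fit_relation(x, x)
  expect_equal(f1$beta, 1, tolerance = 1e-12)
  # Laplace noise, slope 0.3
  set.seed(3)
  x <- stats::runif(500, 0.5, 3)
  y <- 0.3 * x + 0.1 * (stats::rexp(500) - stats::rexp(500))
  f2 <- fit_relation(x, y)
  expect_lt(abs(f2$beta - 0.3), 0.05)
  expect_error(fit_relation(1:2, 1:2), "at least 10")
})

test_that("no attenuation yields an empty dependent set", {
  p <- make_pairs(100, frac_dep = 0.5, attenuation = 1, noise_sd = 0.1, seed = 5)
  part <- iterate_partition(p)
  expect_equal(part$fit$n_dependent, 0L)
  expect_true(part$fit$converged)
  expect_lt(mean(tidy(part)$label == "dependent"), 0.05)
})

test_that("a planted attenuated subpopulation is recovered with its slope", {
  p <- make_pairs(400, frac_dep = 0.6, attenuation = 0.15, noise_sd = 0.15,
                  seed = 11)
  part <- iterate_partition(p)
  calls <- tidy(part)
  truth <- p$dep[match(calls$gene_id, p$gene_id)]
  acc <- mean((calls$label == "dependent") == truth)
  expect_gte(acc, 0.9)
  expect_lt(abs(part$fit$beta - 0.15), 0.1)
  expect_gt(part$fit$spearman_r, 0.3)
})

test_that("the partition is idempotent at convergence", {
  p <- make_pairs(300, frac_dep = 0.5, attenuation = 0.2, noise_sd = 0.15,
                  seed = 7)
  part <- iterate_partition(p)
  expect_true(part$fit$converged)
  # one more manual reassignment round must reproduce the labels
  beta <- part$fit$beta
  calls <- tidy(part)
  again <- abs(calls$y_total - beta * calls$x_total) <= part$fit$tau &
    abs(calls$y_intronic - beta * calls$x_intronic) <= part$fit$tau
  expect_identical(again, calls$label == "dependent")
})

test_that("stronger attenuation never reduces dependent-set recall", {
  recalls <- vapply(c(1.0, 0.5, 0.25, 0.1), function(att) {
    p <- make_pairs(300, frac_dep = 0.6, attenuation = att, noise_sd = 0.15,
                    seed = 19)
    calls <- tidy(iterate_partition(p))
    truth <- p$dep[match(calls$gene_id, p$gene_id)]
    if (att == 1) {
      mean(calls$label[truth] == "dependent")  # null: expect ~0
    } else {
      mean(calls$label[truth] == "dependent")
    }
  }, numeric(1))
  expect_true(all(diff(recalls) >= -0.02))
  expect_lt(recalls[1], 0.05)
  expect_gt(recalls[4], 0.9)
})

test_that("degenerate and tiny inputs are rejected or excluded", {
  p <- make_pairs(20, 0.5, 0.2, 0.1, seed = 1)
  p$x_total[1:3] <- 0
  part <- iterate_partition(p)
  expect_setequal(part$excluded, p$gene_id[1:3])
  expect_error(iterate_partition(p[1:2, ]), "at least 10")
})

test_that("rescue labels genes that rejoin the systematic relation", {
  # dependent genes: half rescued to full induction, half still attenuated
  set.seed(23)
  n <- 200
  x <- stats::runif(n, 1, 3)
  rescued <- seq_len(n) <= 100
  y <- ifelse(rescued, x, 0.15 * x) + stats::rnorm(n, 0, 0.12)
  pairs <- tibble::tibble(
    gene_id = sprintf("d%03d", seq_len(n)),
    x_total = x, y_total = y,
    x_intronic = x + stats::rnorm(n, 0, 0.05),
    y_intronic = ifelse(rescued, x, 0.15 * x) + stats::rnorm(n, 0, 0.12)
  )
  rr <- classify_rescue(pairs, pairs$gene_id)
  calls <- tidy(rr)
  expect_gte(mean(calls$label[rescued] == "rescued"), 0.9)
  expect_gte(mean(calls$label[!rescued] == "refractory"), 0.9)
  # rescue background identical to the knockout: nothing rescued
  pairs_ko <- dplyr::mutate(pairs,
                            y_total = 0.15 * x_total + stats::rnorm(n, 0, 0.1),
                            y_intronic = 0.15 * x_intronic + stats::rnorm(n, 0, 0.1))
  rr0 <- classify_rescue(pairs_ko, pairs_ko$gene_id)
  expect_equal(rr0$fit$n_dependent, 0L)
})

test_that("planted preferential rescue of Direct genes is reflected in the labels", {
  set.seed(29)
  n <- 200
  direct <- seq_len(n) <= 80
  # 80% of Direct rescued, 30% of the rest
  rescued <- ifelse(direct, stats::runif(n) < 0.8, stats::runif(n) < 0.3)
  x <- stats::runif(n, 1, 3)
  mk_y <- function() ifelse(rescued, x, 0.15 * x) + stats::rnorm(n, 0, 0.12)
  pairs <- tibble::tibble(gene_id = sprintf("d%03d", seq_len(n)),
                          x_total = x, y_total = mk_y(),
                          x_intronic = x, y_intronic = mk_y())
  calls <- tidy(classify_rescue(pairs, pairs$gene_id))
  frac_direct <- mean(calls$label[direct] == "rescued")
  frac_other <- mean(calls$label[!direct] == "rescued")
  expect_gt(frac_direct, frac_other)
  expect_equal(frac_direct, 0.8, tolerance = 0.1)
})
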