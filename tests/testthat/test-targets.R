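test_that("nearest site distance handles containment, gaps and empty sets", {
  sites <- tibble::tibble(chrom = "chr1", start = c(4000L, 15000L),
                          end = c(6000L, 15500L))
  expect_equal(nearest_site_distance("chr1", 5000L, sites), 0)
  expect_equal(nearest_site_distance("chr1", 5000L, sites[2, ]), 10000)
  expect_equal(nearest_site_distance("chr2", 5000L, sites), Inf)
  # just past the end of a half-open interval: distance 1
  expect_equal(nearest_site_distance("chr1", 6000L, sites[1, ]), 1)
})

mk_target_inputs <- function(dist_bp, linked, induced = TRUE, dependent = TRUE) {
  tss <- tibble::tibble(chrom = "chr1", start = 500000L, end = 501000L,
                        name = "g1", strand = "+")
  sites <- tibble::tibble(chrom = "chr1", start = 500000L + dist_bp,
                          end = 500200L + dist_bp)
  links <- tibble::tibble(name = "g1", chrom = "chr1", tss = 500000L,
                          tss_bin = 50L, linked = linked,
                          linked_bins = list(if (linked) 99L else integer(0)))
  ind <- tibble::tibble(gene_id = "g1",
                        call = if (induced) "induced" else "unchanged")
  dep <- tibble::tibble(gene_id = "g1",
                        label = if (dependent) "dependent" else "independent")
  suppressMessages(classify_targets(tss, sites, links, ind, dep))
}

test_that("classification applies the 10 kb / link / 100 kb rules", {
  # site 5 kb away, no link: Direct
  expect_equal(mk_target_inputs(5000L, FALSE)$class, "Direct")
  # nearest site 200 kb away but linked: Direct, remote-controlled
  r <- mk_target_inputs(200000L, TRUE)
  expect_equal(r$class, "Direct")
  expect_true(r$remote)
  # nearest site 50 kb, no link: the evidence gap stays Unassigned
  expect_equal(mk_target_inputs(50000L, FALSE)$class, "Unassigned")
  # >100 kb, no link: Indirect
  expect_equal(mk_target_inputs(150000L, FALSE)$class, "Indirect")
  # not dependent or not induced: never Direct/Indirect
  expect_equal(mk_target_inputs(5000L, FALSE, dependent = FALSE)$class,
               "Unassigned")
  expect_equal(mk_target_inputs(150000L, FALSE, induced = FALSE)$class,
               "Unassigned")
})

test_that("multi-TSS genes use their best TSS and any linked TSS counts", {
  tss <- tibble::tibble(chrom = "chr1",
                        start = c(500000L, 800000L),
                        end = c(501000L, 801000L),
                        name = c("g1", "g1"), strand = "+")
  sites <- tibble::tibble(chrom = "chr1", start = 505000L, end = 505200L)
  links <- tibble::tibble(name = c("g1", "g1"), chrom = "chr1",
                          tss = c(500000L, 800000L), tss_bin = c(50L, 80L),
                          linked = c(FALSE, FALSE),
                          linked_bins = list(integer(0), integer(0)))
  ind <- tibble::tibble(gene_id = "g1", call = "induced")
  dep <- tibble::tibble(gene_id = "g1", label = "dependent")
  r <- classify_targets(tss, sites, links, ind, dep)
  expect_equal(r$nearest_distance, 5000)  # the closer TSS wins
  expect_equal(r$class, "Direct")
})

test_that("genes without TSS annotation become Unassigned with a message", {
  tss <- tibble::tibble(chrom = "chr1", start = 1000L, end = 2000L,
                        name = "g1", strand = "+")
  sites <- tibble::tibble(chrom = "chr1", start = 1500L, end = 1700L)
  links <- tibble::tibble(name = "g1", chrom = "chr1", tss = 1000L,
                          tss_bin = 0L, linked = FALSE,
                          linked_bins = list(integer(0)))
  ind <- tibble::tibble(gene_id = c("g1", "g2"), call = "induced")
  dep <- tibble::tibble(gene_id = c("g1", "g2"), label = "dependent")
  expect_message(r <- classify_targets(tss, sites, links, ind, dep),
                 "without TSS")
  expect_equal(r$class[r$gene_id == "g2"], "Unassigned")
})

test_that("shrinking the link set never promotes Indirect to Direct", {
  set.seed(33)
  st <- simulate_study(sim_config(seed = 20, n_genes = 600L, n_induced = 120L,
                                  n_down = 30L, n_bins = 300L),
                       n_direct_proximal = 20L, n_direct_remote = 15L,
                       n_indirect = 25L)
  retained <- dplyr::filter(consensus(st$peak_reps), retained)
  model <- fit_expected(st$map, n_bins = st$config$n_bins)
  calls <- call_interactions(st$map, model)
  ind <- tibble::tibble(gene_id = st$truth$gene_id, call = "induced")
  dep <- tibble::tibble(gene_id = st$truth$gene_id,
                        label = ifelse(st$truth$label == "induced-dependent",
                                       "dependent", "independent"))
  links_full <- link_tss(st$tss, retained, calls, st$config$bin_size)
  calls_half <- calls
  calls_half$significant[seq(1, nrow(calls_half), by = 2)] <- FALSE
  links_half <- link_tss(st$tss, retained, calls_half, st$config$bin_size)
  c_full <- classify_targets(st$tss, retained, links_full, ind, dep)
  c_half <- classify_targets(st$tss, retained, links_half, ind, dep)
  moved <- c_full$class == "Indirect" & c_half$class == "Direct"
  expect_false(any(moved))
  # Direct can only drop to Unassigned or swap to Indirect, never appear anew
  expect_true(all(c_half$class[c_full$class == "Unassigned"] != "Direct"))
})

test_that("hypergeometric enrichment matches exact enumeration and Bonferroni", {
  u <- sprintf("u%02d", 1:10)
  res <- hypergeom_enrichment(u[1:5], list(s = u[1:5]), u)
  expect_equal(res$pvalue, 1 / choose(10, 5), tolerance = 1e-12)
  # overlap at expectation: upper-tail p >= 0.5
  u2 <- sprintf("v%03d", 1:100)
  res2 <- hypergeom_enrichment(u2[1:10], list(s = u2[6:25]), u2)
  expect_equal(res2$overlap, 5L)  # expectation = 10 * 20/100 = 2; above it
  res3 <- hypergeom_enrichment(u2[1:10], list(s = u2[9:28]), u2)
  expect_equal(res3$overlap, 2L)
  expect_gte(res3$pvalue, 0.5)
  # Bonferroni multiplies by the number of sets, capped at 1
  many <- hypergeom_enrichment(u[1:5], list(a = u[1:5], b = u[6:10],
                                            c = u[1:2], d = u[3:4], e = u[5]),
                               u)
  expect_equal(many$p_bonferroni, pmin(1, many$pvalue * 5))
  expect_error(hypergeom_enrichment("zz", list(s = u), u), "subset")
})

test_that("the summary report is internally consistent on a hand-built fixture", {
  cls <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:20),
    nearest_distance = c(rep(5000, 6), rep(2e5, 6), rep(5e4, 4), rep(1e4, 4)),
    linked = c(rep(FALSE, 6), rep(c(TRUE, FALSE), 3), rep(FALSE, 8)),
    n_links = 0L,
    induced = c(rep(TRUE, 16), rep(FALSE, 4)),
    dependent = c(rep(TRUE, 12), rep(FALSE, 8)),
    class = c(rep("Direct", 6), rep(c("Direct", "Indirect"), 3),
              rep("Unassigned", 8)),
    remote = c(rep(FALSE, 6), rep(c(TRUE, FALSE), 3), rep(FALSE, 8))
  )
  s <- summarize_targets(cls)
  expect_equal(s$n_induced, 16)
  expect_equal(s$n_dependent, 12)
  expect_equal(s$n_direct, 9)
  expect_equal(s$n_indirect, 3)
  expect_equal(s$n_direct_remote, 3)
  expect_equal(s$pct_direct_remote, 100 * 3 / 9)
  expect_equal(s$pct_dependent_of_induced, 100 * 12 / 16)
  td <- tidy(s)
  expect_equal(td$value[td$metric == "n_direct"], 9)
})

test_that("empty inputs produce an all-zero report without crashing", {
  cls <- tibble::tibble(gene_id = character(), nearest_distance = numeric(),
                        linked = logical(), n_links = integer(),
                        induced = logical(), dependent = logical(),
                        class = character(), remote = logical())
  s <- summarize_targets(cls)
  expect_equal(s$n_genes, 0)
  expect_equal(s$n_direct, 0)
  expect_true(is.na(s$pct_dependent_of_induced))
})
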