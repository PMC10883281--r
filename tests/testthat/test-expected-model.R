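# Closed-form expected hotspots, the Monte-Carlo oracle, methylation fold
# inference and overdispersion.

test_that("chunk relative rates normalise attributed counts", {
  bins <- make_bins(c(c1 = 4000), 1000)
  m <- mk_mut("c1", c(500, 1500, 2500, 3500), "C", "T", "s")
  expect_equal(chunk_relative_rates(m, bins), rep(0.25, 4))
  expect_equal(chunk_relative_rates(c(3, 1), make_bins(c(c1 = 2000), 1000)),
               c(0.75, 0.25))
  expect_equal(sum(chunk_relative_rates(c(5, 0, 2, 9),
                                        make_bins(c(c1 = 4000), 1000))), 1)
  expect_error(chunk_relative_rates(c(0, 0), make_bins(c(c1 = 2000), 1000)),
               "no attributed")
})

test_that("weight maps are normalised in every mode", {
  profs <- synthetic_signatures()
  # single-channel profile over a 10-position context class: q = 0.1
  f <- stats::setNames(rep(0, 96), sbs_channels()); f["A[C>T]G"] <- 1
  cen1 <- mk_census(0L); cen1$count[cen1$context == "ACG"] <- 10L
  wm1 <- position_weight_map(cen1, f)
  expect_equal(wm1$q, 0.1)
  expect_equal(sum(wm1$N * wm1$q), 1)
  # two chunks, rates (0.75, 0.25), identical composition: q ratio 3
  cen2 <- mk_census(50L, bins = 2)
  wm2 <- position_weight_map(cen2, profs[, "SYN_FLAT"], rates = c(.75, .25))
  expect_equal(sum(wm2$N * wm2$q), 1)
  q1 <- wm2$q[wm2$bin == 1][1]; q2 <- wm2$q[wm2$bin == 2][1]
  expect_equal(q1 / q2, 3)
  # rho = 1 reproduces the unsplit map exactly
  cenM <- mk_census(60L, meth_counts = 0.7)
  wmM <- position_weight_map(cenM, profs[, "SYN_CPG"], meth_fold = 1)
  wmU <- position_weight_map(mk_census(60L), profs[, "SYN_CPG"])
  agg <- tapply(wmM$N * wmM$q, wmM$channel, sum)
  aggU <- tapply(wmU$N * wmU$q, wmU$channel, sum)
  expect_equal(agg[names(aggU)], aggU, tolerance = 1e-12)
  expect_equal(sum(wmM$N * wmM$q), 1)
  # genome-wide mode errors when an active context is missing
  cen0 <- mk_census(10L); cen0$count[cen0$context == "ACG"] <- 0L
  expect_error(position_weight_map(cen0, f), "absent")
})

test_that("uniform chunk rates over identical chunks equal the genome-wide map", {
  profs <- synthetic_signatures()
  cen2 <- mk_census(50L, bins = 2)
  cenG <- mk_census(100L)
  e_chunk <- expected_hotspots(position_weight_map(cen2, profs[, "SYN_FLAT"],
                                                   rates = c(.5, .5)), 20, 10)
  e_gw <- expected_hotspots(position_weight_map(cenG, profs[, "SYN_FLAT"]),
                            20, 10)
  expect_equal(e_chunk$total, e_gw$total, tolerance = 1e-9)
})

test_that("expected hotspots handle degenerate cohorts and forced collisions", {
  profs <- synthetic_signatures()
  wm <- position_weight_map(mk_census(100L), profs[, "SYN_CPG"])
  expect_equal(expected_hotspots(wm, S = 1, n = 5)$total, 0)
  # one position, one alternate, q = 1, n = 1, S = 2 -> certain hotspot
  f <- stats::setNames(rep(0, 96), sbs_channels()); f["A[C>T]G"] <- 1
  cen1 <- mk_census(0L); cen1$count[cen1$context == "ACG"] <- 1L
  wm1 <- position_weight_map(cen1, f)
  expect_equal(expected_hotspots(wm1, S = 2, n = 1)$total, 1)
  expect_equal(sum(expected_hotspots(wm, 30, 5)$breakdown$expected),
               expected_hotspots(wm, 30, 5)$total)
})

test_that("expected hotspots are monotone in cohort size and burden", {
  profs <- synthetic_signatures()
  wm <- position_weight_map(mk_census(200L), profs[, "SYN_CPG"])
  es <- vapply(c(2, 5, 10, 20, 50), function(S)
    expected_hotspots(wm, S, 5)$total, numeric(1))
  en <- vapply(c(1, 2, 5, 10, 20), function(n)
    expected_hotspots(wm, 10, n)$total, numeric(1))
  expect_true(all(diff(es) > 0))
  expect_true(all(diff(en) > 0))
})

test_that("finer heterogeneous partitions never decrease the expectation", {
  profs <- synthetic_signatures()
  f <- profs[, "SYN_FLAT"]
  cenG <- mk_census(120L)
  cen2 <- mk_census(60L, bins = 2)
  cen4 <- mk_census(30L, bins = 4)
  eG <- expected_hotspots(position_weight_map(cenG, f), 50, 20)$total
  e2 <- expected_hotspots(position_weight_map(cen2, f, rates = c(.7, .3)),
                          50, 20)$total
  e4 <- expected_hotspots(position_weight_map(cen4, f,
                                              rates = c(.45, .25, .2, .1)),
                          50, 20)$total
  expect_gte(e2, eG)
  expect_gte(e4, e2)
})

test_that("the Monte-Carlo oracle agrees with the closed form on a small instance", {
  profs <- synthetic_signatures()
  wm <- position_weight_map(mk_census(500L), profs[, "SYN_CPG"])
  an <- expected_hotspots(wm, S = 20, n = 4)$total
  mc <- monte_carlo_expected(wm, S = 20, n = 4, R = 800, seed = 17)
  expect_lt(abs(an - mc$mean), 3 * mc$se)
  # degenerate cohorts and determinism
  mc1 <- monte_carlo_expected(wm, S = 1, n = 4, R = 20, seed = 1)
  expect_true(all(mc1$counts == 0))
  mc_a <- monte_carlo_expected(wm, 5, 3, R = 30, seed = 9)
  mc_b <- monte_carlo_expected(wm, 5, 3, R = 30, seed = 9)
  expect_identical(mc_a$counts, mc_b$counts)
  expect_error(monte_carlo_expected(wm, 5, sum(wm$N) * 4, R = 2, seed = 1),
               "exceeds")
})

test_that("methylation fold-change is an odds ratio with Haldane correction", {
  expect_equal(infer_methylation_foldchange(1000, 1000, 50, 50)$rho, 1)
  r <- infer_methylation_foldchange(1000, 1000, 90, 10)
  expect_equal(r$rho, (90 / 910) / (10 / 990), tolerance = 1e-12)
  expect_false(r$corrected)
  r0 <- infer_methylation_foldchange(100, 100, 10, 0)
  expect_true(r0$corrected)
  expect_true(is.finite(r0$rho))
  expect_error(infer_methylation_foldchange(0, 100, 0, 0), "both classes")
})

test_that("explained fraction is a guarded percentage", {
  expect_equal(explained_fraction(40, 40), 100)
  expect_equal(explained_fraction(40, 0), 0)
  expect_equal(explained_fraction(40, 27.3), 68.25)
  expect_warning(pct <- explained_fraction(10, 12), "more hotspots")
  expect_equal(pct, 120)
  expect_error(explained_fraction(0, 5), "undefined")
})

test_that("overdispersion fitting distinguishes Poisson from NB counts", {
  set.seed(23)
  pois <- stats::rpois(2000, 20)
  fp <- fit_overdispersion(pois)
  expect_lt(fp$alpha, 0.02)
  expect_true(fp$poisson_consistent)
  nb <- stats::rnbinom(2000, size = 2, mu = 20)   # alpha = 0.5
  fnb <- fit_overdispersion(nb)
  expect_lt(abs(fnb$alpha - 0.5) / 0.5, 0.15)
  expect_false(fnb$poisson_consistent)
  expect_equal(fit_overdispersion(rep(7L, 100))$alpha, 0)
  expect_error(fit_overdispersion(c(1.5, rep(1, 20))), "integers")
  expect_error(fit_overdispersion(rep(1L, 5)), "10 bins")
})
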