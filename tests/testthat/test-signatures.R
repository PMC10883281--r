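# Signature profiles: catalogues, normalisation, entropy, NNLS fitting,
# AIC subset search, probabilistic attribution.

test_that("catalogues count pyrimidine-collapsed channels per sample", {
  g <- as_genome(c(c1 = "AACAT", c2 = "ATGTA"))
  # c1: C>T at pos 3 in ACA; c2: G>A at pos 3, + strand context TGT -> A[C>T]A
  m <- mk_mut(c("c1", "c2"), c(3, 3), c("C", "G"), c("T", "A"),
              c("s1", "s2"))
  M <- build_catalog(m, g)
  expect_equal(M["A[C>T]A", "s1"], 1L)
  expect_equal(M["A[C>T]A", "s2"], 1L)
  expect_equal(colSums(M), c(s1 = 1, s2 = 1))
  expect_error(build_catalog(mk_mut("c1", 3, "CA", "C", "s"), g), "SNV")
  # unresolvable context (contig edge) is skipped and tallied
  m2 <- mk_mut("c1", c(1, 3), c("A", "C"), c("G", "T"), "s1")
  M2 <- build_catalog(m2, g)
  expect_equal(attr(M2, "skipped"), 1L)
  expect_equal(sum(M2), 1)
})

test_that("profile normalisation divides by triplet abundance", {
  profs <- synthetic_signatures()
  # uniform census: normalised profile proportional to the raw profile
  cen <- mk_census(100L)
  np <- normalize_profile(profs[, "SYN_CPG"], cen)
  expect_equal(unname(np), unname(profs[, "SYN_CPG"]), tolerance = 1e-12)
  # two active channels with triplet counts (2, 1) -> p = (1/3, 2/3)
  f <- stats::setNames(rep(0, 96), sbs_channels())
  f["A[C>A]A"] <- 0.5; f["A[T>A]A"] <- 0.5
  counts <- stats::setNames(rep(1, 32), sbs_contexts())
  counts["ACA"] <- 2
  np2 <- normalize_profile(f, counts)
  expect_equal(unname(np2["A[C>A]A"]), 1 / 3)
  expect_equal(unname(np2["A[T>A]A"]), 2 / 3)
  # single-channel profile is unchanged
  f3 <- stats::setNames(rep(0, 96), sbs_channels()); f3["A[C>T]G"] <- 1
  expect_equal(unname(normalize_profile(f3, cen)["A[C>T]G"]), 1)
  # zero abundance for an active channel errors
  c0 <- stats::setNames(rep(1, 32), sbs_contexts()); c0["ACG"] <- 0
  expect_error(normalize_profile(f3, c0), "zero genomic abundance")
})

test_that("profile entropy is natural-log with analytic bounds", {
  expect_equal(profile_entropy(rep(1 / 96, 96)), log(96))
  delta <- c(1, rep(0, 95))
  expect_equal(profile_entropy(delta), 0)
  expect_equal(profile_entropy(c(0.5, 0.5, rep(0, 94))), log(2))
  expect_error(profile_entropy(c(0.4, 0.4)), "probability")
})

test_that("NNLS recovers noiseless exposures and is optimal", {
  profs <- synthetic_signatures()
  E0 <- matrix(c(120, 40, 15, 5, 90, 60), 3, 2,
               dimnames = list(colnames(profs), c("a", "b")))
  M <- profs %*% E0
  fit <- fit_exposures_nnls(M, profs)
  expect_lt(max(abs(fit$exposures - E0) / E0), 1e-6)
  # zero catalogue -> zero exposures
  fit0 <- fit_exposures_nnls(matrix(0, 96, 1), profs)
  expect_equal(unname(fit0$exposures), matrix(0, 3, 1))
  # optimality probe: residual beats random non-negative perturbations
  set.seed(4)
  Mn <- M[, 1] + abs(rnorm(96, 0, 2))
  fitn <- fit_exposures_nnls(matrix(Mn, 96), profs)
  rss <- function(e) sum((profs %*% e - Mn)^2)
  base <- rss(fitn$exposures[, 1])
  set.seed(5)
  worse <- replicate(100, {
    e <- pmax(fitn$exposures[, 1] + rnorm(3, 0, 1), 0)
    rss(e)
  })
  expect_true(all(worse >= base - 1e-8))
  expect_error(fit_exposures_nnls(M[1:50, ], profs), "channel mismatch")
})

test_that("adding a signature never increases the NNLS objective", {
  profs <- random_signature_profiles(5, seed = 8)
  M <- round(profs[, 1:2] %*% matrix(c(300, 200), 2) + 2)
  for (k in 1:4) {
    r1 <- sum(fit_exposures_nnls(M, profs[, 1:k, drop = FALSE])$residuals^2)
    r2 <- sum(fit_exposures_nnls(M, profs[, 1:(k + 1), drop = FALSE])$residuals^2)
    expect_lte(r2, r1 + 1e-9)
  }
})

test_that("AIC subset search finds the generating pair", {
  cand <- random_signature_profiles(7, seed = 12, concentration = 0.2)
  E0 <- matrix(c(500, 300), 2, 3, dimnames = list(colnames(cand)[c(2, 5)], NULL))
  set.seed(13)
  M <- matrix(stats::rpois(96 * 3, cand[, c(2, 5)] %*% E0), 96, 3)
  sel <- select_signature_combination(M, cand, kmax = 3, top = 10)
  expect_setequal(sel$best, c("RSIG2", "RSIG5"))
  expect_true(all(c("RSIG2", "RSIG5") %in% sel$chosen))
  expect_gte(sel$frequency[["RSIG2"]], 0.9)  # in almost every top solution
  # kmax = 1 with a single candidate returns it
  one <- select_signature_combination(M, cand[, 2, drop = FALSE], kmax = 1)
  expect_equal(one$best, "RSIG2")
  expect_error(select_signature_combination(M, cand, kmax = 3, max_subsets = 10),
               "cap")
})

test_that("mutation probability vectors normalise exposure-weighted channels", {
  profs <- synthetic_signatures()
  # single active signature -> indicator
  p <- mutation_probability_vector("A[C>T]G", c(SYN_CPG = 5, SYN_TT = 0,
                                                SYN_FLAT = 0), profs)
  expect_equal(unname(p[1, ]), c(1, 0, 0))
  # E = (3, 1), channel probabilities (0.1, 0.3) -> (0.5, 0.5)
  S <- cbind(s1 = c(0.1, 0.9), s2 = c(0.3, 0.7))
  rownames(S) <- c("ch1", "ch2")
  p2 <- mutation_probability_vector("ch1", c(3, 1), S)
  expect_equal(unname(p2[1, ]), c(0.5, 0.5))
  # equal exposures, equal channel probabilities -> uniform
  S2 <- matrix(c(.2, .8, .2, .8), 2, 2,
               dimnames = list(c("ch1", "ch2"), c("a", "b")))
  p3 <- mutation_probability_vector("ch1", c(1, 1), S2)
  expect_equal(unname(p3[1, ]), c(0.5, 0.5))
  expect_equal(rowSums(p2), c(ch1 = 1))
  # all-zero denominator -> unattributable
  p4 <- mutation_probability_vector("ch1", c(0, 0), S)
  expect_true(all(is.na(p4)))
})

test_that("maximum-likelihood calls use strict thresholds and lexicographic ties", {
  expect_equal(assign_max_likelihood(c(a = 0.6, b = 0.4)),
               data.frame(signature = "a", high_confidence = TRUE))
  tie <- assign_max_likelihood(c(b = 0.5, a = 0.5))
  expect_equal(tie$signature, "a")
  expect_false(tie$high_confidence)
  three <- assign_max_likelihood(c(x = 0.4, y = 0.3, z = 0.3))
  expect_equal(three$signature, "x")
  expect_false(three$high_confidence)
  expect_error(assign_max_likelihood(numeric(0)), "empty")
})

test_that("hotspot attribution averages member vectors", {
  same <- rbind(c(a = .7, b = .3), c(a = .7, b = .3))
  expect_equal(assign_hotspot_signature(same)$signature, "a")
  opp <- rbind(c(a = 1, b = 0), c(a = 0, b = 1))
  res <- assign_hotspot_signature(opp)
  expect_true(res$tie)
  expect_equal(res$signature, "a")   # lexicographic
  mix <- rbind(c(a = .7, b = .3), c(a = .4, b = .6))
  res2 <- assign_hotspot_signature(mix)
  expect_equal(res2$signature, "a")
  expect_equal(unname(res2$mean_vector), c(0.55, 0.45))
  expect_error(assign_hotspot_signature(matrix(0, 0, 2)), "no member")
})

test_that("activity thresholds are inclusive at 5%", {
  E <- cbind(s1 = c(A = 5, B = 95), s2 = c(A = 4.9, B = 95.1))
  act <- active_signatures(E, totals = c(100, 100))
  expect_true(act$sample_active["A", "s1"])     # exactly 5%
  expect_false(act$sample_active["A", "s2"])    # 4.9%
  # cohort of 20 samples, active in exactly 1 -> cohort-active (5%)
  E20 <- matrix(c(rep(0, 19), 10), 1, 20, dimnames = list("A", NULL))
  act20 <- active_signatures(E20, totals = rep(100, 20))
  expect_true(act20$cohort_active["A"])
})

test_that("COSMIC-style profile TSV reader validates and reorders", {
  profs <- synthetic_signatures()
  f <- tempfile(fileext = ".tsv")
  shuffled <- sample(96)
  utils::write.table(
    data.frame(Type = sbs_channels()[shuffled], profs[shuffled, ]),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_signature_profiles(f)
  expect_equal(back, profs, tolerance = 1e-12)
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(Type = "A[C>A]A", X = 1), bad, sep = "\t",
                     row.names = FALSE)
  expect_error(read_signature_profiles(bad), "96")
})
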