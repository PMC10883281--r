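# Observed propensity subsampling, conversion rates and enrichment
# statistics.

test_that("eligibility requires both hotspot and sample thresholds", {
  hc <- matrix(0, 2, 120, dimnames = list(c("S1", "S2"), NULL))
  hc["S1", 1:101] <- 301   # 101 samples above 300 high-confidence mutations
  hc["S2", 1:100] <- 500   # only 100 qualifying samples
  res <- eligible_pairs(c(S1 = 450, S2 = 10000), hc)
  expect_true(res$eligible[res$signature == "S1"])
  expect_false(res$eligible[res$signature == "S2"])
  res2 <- eligible_pairs(c(S1 = 449), hc["S1", , drop = FALSE])
  expect_false(res2$eligible)
  # exactly 300 mutations is not "more than 300"
  hc3 <- matrix(300, 1, 101, dimnames = list("S1", NULL))
  expect_false(eligible_pairs(c(S1 = 450), hc3)$eligible)
})

test_that("observed propensity is seed-reproducible and errors on shortfall", {
  set.seed(2)
  m <- mk_mut("c", sample(1e4, 2000, replace = TRUE), "C", "T",
              rep(paste0("s", 1:10), each = 200))
  sp <- subsample_spec(n_samples = 5, muts_per_sample = 50, iterations = 50,
                       seed = 7)
  r1 <- observed_propensity(m, sp)
  r2 <- observed_propensity(m, sp)
  expect_identical(r1$counts, r2$counts)
  expect_true(r1$median >= min(r1$counts) && r1$median <= max(r1$counts))
  sp_big <- subsample_spec(n_samples = 5, muts_per_sample = 500,
                           iterations = 5)
  expect_error(observed_propensity(m, sp_big), "eligible mutations")
})

test_that("pooled propensity counts recurrent sampled mutations", {
  # pool with one shared position among all draws
  m <- rbind(mk_mut("c", rep(100, 5), "C", "T", paste0("s", 1:5)),
             mk_mut("c", 1:20, "C", "T", "s6"))
  sp <- subsample_spec(total_muts = 25, iterations = 3, grouping = "pooled",
                       seed = 3)
  r <- observed_propensity(m, sp)
  expect_equal(r$counts, rep(1L, 3))  # position 100 always recurrent
  expect_error(observed_propensity(m, subsample_spec(total_muts = 100,
                                                     grouping = "pooled")),
               "cannot draw")
})

test_that("region scope restricts the analysed positions", {
  m <- rbind(mk_mut("c", rep(50, 4), "C", "T", paste0("s", 1:4)),
             mk_mut("c", rep(500, 4), "C", "T", paste0("s", 1:4)))
  sp <- subsample_spec(total_muts = 4, iterations = 2, grouping = "pooled",
                       seed = 1)
  scope <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 100))
  r <- observed_propensity(m, sp, regions = scope)
  expect_equal(r$counts, rep(1L, 2))   # only position 50 is in scope
})

test_that("median propensity does not decrease with the per-sample draw", {
  cfg <- synthetic_config(contig_lengths = c(chrS1 = 1e5),
                          n_samples = 12, muts_per_sample = 120)
  gen <- generate_genome(cfg, seed = 81)
  sim <- simulate_cohort(gen, synthetic_signatures(), cfg, seed = 82,
                         exposures = c(1, 0, 0))
  meds <- vapply(c(40, 80, 120), function(mm) {
    sp <- subsample_spec(n_samples = 10, muts_per_sample = mm,
                         iterations = 60, seed = 83)
    observed_propensity(sim$mutations, sp)$median
  }, numeric(1))
  expect_true(all(diff(meds) >= 0))
})

test_that("conversion rate inverts an exact hotspot-burden line", {
  # every sample mutates the first h_i universal positions (h_i = b_i / 100)
  # plus private filler; any 100-sample subset sees the same exact line
  samples <- sprintf("t%03d", 1:110)
  burden <- rep(c(100, 200, 300, 400, 500), length.out = 110)
  rows <- lapply(seq_along(samples), function(i) {
    h <- burden[i] / 100
    rbind(mk_mut("c", seq_len(h), "C", "T", samples[i]),
          mk_mut("c", 1e6 + i * 1e3 + seq_len(burden[i] - h), "C", "T",
                 samples[i]))
  })
  m <- do.call(rbind, rows)
  cr <- conversion_rate(m, iterations = 20, subset = 100,
                        min_significant = 15, seed = 5)
  expect_equal(cr$conversion, 100, tolerance = 1e-9)
  expect_equal(cr$n_significant, 20L)
  # zero hotspots -> underpowered -> NA
  priv <- do.call(rbind, lapply(1:105, function(i)
    mk_mut("c", i * 1e4 + 1:20, "C", "T", sprintf("u%03d", i))))
  cr0 <- conversion_rate(priv, iterations = 10, subset = 100,
                         min_significant = 8, seed = 6)
  expect_true(is.na(cr0$conversion))
  expect_error(conversion_rate(m[m$SAMPLE %in% samples[1:50], ],
                               iterations = 2, subset = 100),
               "exceed")
})

test_that("signature fold change is 1 and non-significant under exchangeability", {
  set.seed(11)
  shares <- matrix(rgamma(40 * 4, 2), 40, 4,
                   dimnames = list(NULL, paste0("S", 1:4)))
  res <- signature_fold_change(shares, shares)
  expect_equal(res$fc, rep(1, 4))
  expect_false(any(res$significant))
})

test_that("a constructed two-fold inside share yields FC = 2", {
  # 2 signatures; inside share of S1 exactly twice its outside share
  out_s1 <- rep(0.3, 30); in_s1 <- rep(0.6, 30)
  inside <- cbind(S1 = in_s1, S2 = 1 - in_s1)
  outside <- cbind(S1 = out_s1, S2 = 1 - out_s1)
  res <- signature_fold_change(inside, outside)
  expect_equal(res$fc[res$signature == "S1"], 2)
  expect_true(res$significant[res$signature == "S1"])
  # single sample: FC reported, p undefined
  res1 <- signature_fold_change(inside[1, , drop = FALSE],
                                outside[1, , drop = FALSE])
  expect_equal(res1$fc[1], 2)
  expect_true(is.na(res1$p[1]))
})

test_that("substitution enrichment computes per-channel fold changes", {
  g <- mk_genome(2000, seed = 14)
  s <- as.character(g[[1]])
  cpos <- which(strsplit(s, "")[[1]] == "C")
  cpos <- cpos[cpos > 1 & cpos < 2000]
  inside <- mk_mut("chrT", cpos[1:40], "C",
                   rep(c("T", "G"), each = 20), "x")
  outside <- mk_mut("chrT", cpos[41:120], "C",
                    rep(c("T", "G"), c(20, 60)), "y")
  res <- substitution_enrichment(inside, outside, g, scheme = 6)
  # inside 50% C>T vs outside 25% C>T -> fold change 2
  expect_equal(res$fc[res$channel == "C>T"], 2)
  # identical sets -> all finite fold changes are 1
  res_same <- substitution_enrichment(inside, inside, g, scheme = 6)
  expect_true(all(res_same$fc[is.finite(res_same$fc)] == 1, na.rm = TRUE))
  # channel present inside, absent outside -> +Inf flagged
  res2 <- substitution_enrichment(inside, outside[1:20, ], g, scheme = 6)
  expect_true(is.infinite(res2$fc[res2$channel == "C>G"]))
  expect_true(res2$flagged[res2$channel == "C>G"])
  expect_error(substitution_enrichment(inside[0, ], outside, g), "non-empty")
})
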