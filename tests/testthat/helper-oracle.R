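# Frozen validation battery for the closed-form expected-hotspot model:
# 12 configurations spanning uneven and near-uniform profiles, chunk-rate
# heterogeneity and methylation folds rho in {1, 2, 5}, each checked
# against the Monte-Carlo oracle.

oracle_battery_configs <- function() {
  profs <- hotspotprop::synthetic_signatures()
  rnd <- hotspotprop::random_signature_profiles(2, seed = 100,
                                                concentration = 0.25)
  pw <- hotspotprop::position_weight_map
  list(
    list(wm = pw(mk_census(500L), profs[, "SYN_FLAT"]), S = 30, n = 4),
    list(wm = pw(mk_census(500L), profs[, "SYN_CPG"]), S = 30, n = 3),
    list(wm = pw(mk_census(as.integer(30 * (1:32))), profs[, "SYN_CPG"]),
         S = 20, n = 4),
    list(wm = pw(mk_census(300L, bins = 2), profs[, "SYN_FLAT"],
                 rates = c(.8, .2)), S = 25, n = 4),
    list(wm = pw(mk_census(400L, bins = 2), profs[, "SYN_CPG"],
                 rates = c(.9, .1)), S = 15, n = 3),
    list(wm = pw(mk_census(200L, bins = 4), profs[, "SYN_FLAT"],
                 rates = c(.4, .3, .2, .1)), S = 30, n = 3),
    list(wm = pw(mk_census(500L, meth_counts = 0.7), profs[, "SYN_CPG"],
                 meth_fold = 1), S = 25, n = 4),
    list(wm = pw(mk_census(500L, meth_counts = 0.7), profs[, "SYN_CPG"],
                 meth_fold = 2), S = 25, n = 4),
    list(wm = pw(mk_census(600L, meth_counts = 0.6), profs[, "SYN_CPG"],
                 meth_fold = 5), S = 20, n = 3),
    list(wm = pw(mk_census(400L, meth_counts = 0.7), profs[, "SYN_FLAT"],
                 meth_fold = 5), S = 30, n = 4),
    list(wm = pw(mk_census(450L), rnd[, 1]), S = 25, n = 4),
    list(wm = pw(mk_census(350L, bins = 2), rnd[, 2],
                 rates = c(.65, .35)), S = 25, n = 3))
}
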