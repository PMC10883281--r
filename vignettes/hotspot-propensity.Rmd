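---
title: "Hotspot propensity: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hotspot propensity: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hotspotprop)
```

This vignette is the package's account of its science: the definitions and
models it implements, the assumptions behind them, the tunable parameters
and their defaults, what the synthetic generators do and do not emulate,
and the numerical choices made where the design was genuinely open. It
states no empirical results beyond those the test suite and
`scripts/acceptance.R` themselves compute.

## The problem and the readout

A mutational **hotspot** is a single genomic position mutated to the same
alternate allele in two or more distinct samples (the alternate-specific
definition; position mode relaxes the equal-alternate requirement).
Because recurrence at one base is the only direct footprint of
single-base-resolution mutation-rate variability, the package uses
**hotspot propensity** — hotspots formed at fixed activity — as a readout
of that variability. Activity is fixed by subsampling: draw `n_samples`
qualifying samples (default 100), then `muts_per_sample` high-confidence
mutations from each without replacement (default 300), count recurrently
hit positions collapsing to at most one hotspot per position, and repeat
(default 1000 iterations), reporting the median and IQR. A pooled mode
draws a fixed total from a merged pool for datasets whose mutations are
not tied to samples (e.g. aggregated de novo germline calls), with
recurrence then meaning two sampled mutations rather than two samples.

Eligibility thresholds for a signature-cohort pair (at least 450
attributed hotspots; more than 300 high-confidence mutations per sample
in at least 101 samples) are exposed as parameters of
`eligible_pairs()` with those defaults.

## Hotspot calling and QC

`filter_mutations()` applies, in order: unknown contig; `ref == alt`;
reference-allele mismatch; unknown base within the ±2 bp context window;
complex indel (mixed insertion/deletion such as GTG>GAAA); outside
mappable regions; blacklist overlap; population-variant overlap; driver
region overlap. The first failing rule is the recorded reason, so the
per-reason tallies sum to the number of removed rows. Duplicate-sample
detection uses the sharing ratio |shared| / (n1 + n2) with a strict 0.10
threshold — the denominator reading "the total number of mutations of
both samples" as their sum — and flags pairs rather than removing them,
because removal is a curation decision. Hypermutators must exceed both an
absolute floor (10,000) and P75 + 1.5 IQR of the cohort's per-sample
counts. Within `find_hotspots()` a sample contributing the same event
twice counts once, mutation types are never merged across one position,
and output ordering is deterministic (the function is
permutation-invariant in its input).

## Signature machinery

Catalogues are 96-channel counts over pyrimidine-collapsed trinucleotide
contexts. Profile normalisation divides each channel probability by the
genomic abundance of its context and renormalises; the entropy
H = −Σₖ pₖ log pₖ of that normalised profile (natural log; 0·log 0 = 0)
measures how concentrated the process is, bounded by log 96 ≈ 4.564.
Exposures are fitted per sample by non-negative least squares
(Lawson–Hanson, via `pracma::lsqnonneg`). The combination search
enumerates all subsets of 1–4 candidates (92,170 subsets for 39
candidates) and ranks them by AIC. Because the source analysis does not
define an AIC for a constrained least-squares fit, the package uses the
Gaussian form AIC = n_obs·log(RSS/n_obs) + 2·k·n_samples with
n_obs = 96·n_samples and the free exposures as the parameter count. The
"most frequent among the top solutions" aggregation is likewise
under-specified; the package computes per-signature frequencies over the
top T solutions (T = 100 by default) and chooses the top-ranked subset
maximising the mean frequency of its members, with AIC breaking ties.
Both choices are parameters, not constants.

Per-mutation probability vectors are P(s) ∝ E_s·f_s(channel), normalised;
maximum-likelihood attribution takes the argmax with a lexicographic
tie-break and calls the mutation high-confidence only when the maximum
strictly exceeds 0.5. Hotspots are attributed by the argmax of the mean
member vector; exact ties are flagged.

## Expected-hotspot models

All three model resolutions share one scenario: S samples with identical
burden n, positions mutating independently. Each (position, alternate)
pair carries a single-draw probability q:

* **genome-wide**: q = f(c→a)/N_c — the profile over context abundance;
* **per chunk**: q = r_k·f_k(c→a)/N_{c,k}, where r_k are relative chunk
  rates estimated from maximum-likelihood-attributed counts (zero-count
  chunks get rate 0, no pseudocount) and f_k is the profile renormalised
  over the channels whose context exists in chunk k, so each chunk's
  weight mass is exactly r_k;
* **methylation-aware**: NpCpG channels split into methylated and
  unmethylated classes with q_meth = f·ρ/(ρ·N_meth + N_unmeth) and
  q_unmeth = f/(ρ·N_meth + N_unmeth), where ρ is the per-site mutability
  fold of methylated CpGs, inferred empirically as an odds ratio of
  per-site mutation occurrence (Haldane–Anscombe 0.5 correction when a
  cell is zero, flagged).

In every mode the weight map sums to 1 over all (position, alternate)
pairs — an enforced invariant. With π = 1 − (1−q)ⁿ, the probability of no
hotspot at one position-alternate over S samples is
(1−π)^S + S·π·(1−π)^{S−1}; alternates at one position are combined under
a cross-alternate independence approximation, and the regional
expectation is the sum over positions, matching the one-hotspot-per-
position counting convention of the observed side.

Two approximations are deliberate: the per-sample binomial form of π
ignores the (without-replacement) coupling among one sample's n draws,
and cross-alternate independence ignores the weak negative dependence at
one position. Neither is asserted: `monte_carlo_expected()` simulates the
generative process exactly and the test suite requires agreement within
3 standard errors across a 12-configuration battery spanning uneven and
near-uniform profiles, chunk-rate heterogeneity and ρ ∈ {1, 2, 5}
(R = 2000 cohorts each). The battery works on synthetic censuses with a
few hundred positions per context and small per-sample draws, the regime
where the approximation error is far below the Monte-Carlo resolution;
at much higher mutation densities the binomial approximation is expected
to undershoot slightly.

The oracle itself is exact but fast: positions of equal
(context, bin, methylation, feature) class have identical weights, so
sequential weighted sampling without replacement is simulated as an
exponential race between class×alternate groups — the sorted arrival
times of a group's N iid Exp(w) items generated incrementally through
memoryless gaps Exp((N−j)·w) — followed by a uniform choice of distinct
positions within each class. This is distribution-identical to the
item-level race and avoids touching every position; the same sampler
powers `simulate_cohort()`.

Binned rate heterogeneity is summarised by intercept-only
negative-binomial maximum likelihood (NB2, v = μ + αμ²; `MASS::glm.nb`,
α = 1/θ). Counts whose variance does not exceed their mean are reported
as Poisson-consistent with α = 0, and α below 0.02 is flagged
Poisson-consistent.

## Bin system

Contigs are tiled into consecutive non-overlapping bins (1 Mbp by
default); a shorter trailing bin is emitted but flagged and excluded from
selection, since downstream analyses assume full-width bins. Selection
keeps autosomal bins whose fractional overlap with the mappable region
set is strictly above the first quartile of the distribution across
candidate bins. The quantile uses linear interpolation (R type 7) and the
inequality is strict, reading "above the first quartile" literally; ties
at the quartile are excluded. The contig classification comes from an
explicit metadata sidecar rather than name parsing. Sub-bin partitions
(500 Kbp down to 10 Kbp) require the target width to divide the parent
width and children inherit the parent id, so 2196 megabase bins yield
exactly 4392 and 219,600 sub-bins at 500 Kbp and 10 Kbp.

Coordinates are 1-based closed internally (the Bioconductor convention,
`GRanges`); BED files are 0-based half-open and converted only at I/O
boundaries; mutation tables are 1-based.

## Enrichment statistics

**Signature fold change.** Per sample, probability vectors are summed
over inside-hotspot mutations and normalised to shares (likewise
outside); a signature's FC is its inside share over its outside share,
summarised as the median over active samples (activity: exposure share
≥ 5% of the sample's mutations; cohort activity: sample-active in ≥ 5%
of samples). Significance is a two-sided *paired signed-rank* test on the
(inside, outside) share pairs with Benjamini–Hochberg control at
α = 0.01. The source describes a "rank-sum" test applied to
sample-paired observations through a routine whose standard meaning is
the signed-rank test; the paired reading matches the described data
structure and is implemented, with the naming conflict recorded rather
than resolved by guesswork.

**Feature windows.** Features of 200–600 bp with ≥ 90% mappable overlap
are centred (floor midpoint) in 2000 bp windows with a 600 bp core and
700 bp flanks. The fold change is the per-bp mutation rate in the core
over the flanks — per-bp normalisation adopted because core and flank
lengths differ. The null redistributes the observed inside-window count
across window positions with probability proportional to the signature's
summed channel probability at each position's context, and the p-value is
the upper-tail mass of the observed FC under a Gaussian kernel density
fitted to the null FCs, computed by numerical integration of the fitted
density and floored at 1/n_rand. The Savitzky–Golay smoothing of pileup
profiles (window 101, polynomial order 3 — the order being a display
choice the source leaves open) is cosmetic and excluded from statistics.

**Methylation.** CpG sites average fractional methylation across
epigenomes (unweighted; sites missing in any epigenome are dropped at
table construction) and are classed methylated above 0.5. Odds ratios of
mutation or hotspot overlap between classes carry 95% Wald intervals with
Haldane correction for zero cells.

**Conversion rate.** Per replicate, 100 samples are drawn, hotspots
called on their pooled SNVs, and each sample's hotspot-membership count
regressed on its burden by OLS ("hotspots per individual" is read as
membership, the only well-defined per-sample count). With at least 750 of
1000 replicates significant (slope t-test, p < 0.05), the conversion rate
is the inverse of the median significant slope; the per-replicate
inversion order is exposed as an option since the aggregation is not
stated in the source.

## The synthetic generators

`generate_genome()` draws bases i.i.d. from a configurable composition
(default 30/20/20/30, GC 40%), then thins CpG dinucleotides to
`cpg_depletion` times the independence expectation (default 0.2, the
observed/expected CpG ratio typical of mammalian genomes). The G of a
removed CpG is resampled from {A, T} in composition proportion: drawing C
or G could create a new CpG one step downstream and bias the target
frequency, so the analytic target is kept exact in expectation at the
price of a slight A/T inflation. Mask sets are random disjoint intervals
(mappable coverage 0.95, blacklist 0.01, variant rate 1e-4, drivers
0.005). `generate_methylation()` draws each CpG from a Beta mixture with
modes Beta(20, 2) and Beta(2, 20) and methylated weight 0.75 — sharply
bimodal, as bisulfite data is, and chosen so the >0.5 classification
recovers the mixture weight. `simulate_cohort()` draws each sample's
events without replacement with weight ∝ r_k·f(c→a)/N_{c,k}, times ρ at
methylated CpGs (default fold 2) and the feature multiplier inside
feature intervals (default 1, the null), then records each event's
generating signature drawn from its posterior. Cohort defaults (100
samples × 300 mutations) mirror the activity at which propensity is read
out. Hypermutators and duplicate pairs are off by default and injected
only when asked.

What the generators do **not** emulate: chromatin organisation,
replication timing, transcription-coupled repair, sequence
context beyond the trinucleotide, indel sequence realism, or any
correlation between methylation and large-scale rate variation. Passing
tests therefore demonstrate the internal consistency of the pipeline and
the correctness of the mathematics under the stated model — not that the
model captures real mutagenesis. On real data the unexplained fraction of
hotspot propensity is precisely the interesting quantity.

## Problem sizes and numerical choices

The test suite and acceptance script choose sizes that keep the full run
in the minutes range on one CPU while leaving every statistical check
well-powered: oracle battery censuses of 200–600 positions per context
with S = 15–30 and n = 3–4 at R = 2000; parameter recovery at 2000 bins
(overdispersion) and ~8000 CpG sites (methylation fold); the
end-to-end propensity comparison on a 3 Mbp CpG-depleted genome with 150
samples × 400 mutations subsampled at 100 × 300 (the Monte-Carlo band
uses R = 200 cohorts). Mutation densities on these small genomes are far
above the tumour-realistic regime; this inflates absolute hotspot counts
but leaves the model-versus-observation comparisons valid because both
sides share the same genome.

Other numerical conventions: probability vectors must sum to 1 within
1e-9 (weight maps within 1e-9, enforced); degenerate inputs error early
and explicitly (quartile on fewer than 4 bins, deciles on fewer than 10,
empty inside/outside sets, zero observed median); `S < 2` is legal in the
expected model and yields 0; infinite fold changes (zero flank or outside
counts) are reported as `Inf` and flagged rather than clamped. All
stochastic entry points take an explicit seed and restore the caller's
RNG state.

## Known limitations

The closed form inherits its two stated approximations and is validated
only inside the battery's regime. The Lawson–Hanson NNLS is exact but
per-sample; no regularisation or bootstrap stability analysis is
provided, and de novo signature extraction is out of scope — profiles are
inputs. The synthetic CpG thinning slightly perturbs base composition.
The KDE tail p-value is a density estimate and is floored at 1/n_rand;
for very spiky null distributions the empirical exceedance (also
returned) is the more honest number.
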