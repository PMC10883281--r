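# Synthetic-data generators: genomes with tunable CpG depletion, mask sets,
# bimodal CpG methylomes, feature tracks, and mutation cohorts drawn from
# the same generative law the expected-hotspot models assume. Everything is
# reproducible from an explicit seed.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Configuration of the synthetic-data generators
#'
#' Defaults describe the study conditions the generators emulate: a CpG
#' depleted genome (observed/expected CpG ~ 0.2, as in the human genome),
#' cohorts of 100 samples contributing 300 mutations each (the activity at
#' which hotspot propensity is read out), bimodal CpG methylation with ~75%
#' of sites methylated, and a two-fold mutability increase at methylated
#' CpGs. Every probability must lie in [0, 1].
#'
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param base_comp Base composition the sequence is drawn from.
#' @param cpg_depletion Target CpG frequency as a multiple of the
#'   independence expectation (delta; 1 = no depletion).
#' @param bin_width Bin width used when the simulator stratifies rates.
#' @param chunk_concentration Dirichlet concentration for per-bin relative
#'   rates (larger = more homogeneous; `Inf` = exactly uniform).
#' @param n_samples,muts_per_sample Cohort size S and per-sample count n.
#' @param hypermutator_fraction,hypermutator_burden Fraction of samples
#'   whose burden is inflated to `hypermutator_burden` mutations.
#' @param duplicate_fraction,duplicate_shared Fraction of samples that get a
#'   duplicated partner sharing `duplicate_shared` of their events.
#' @param meth_weight Mixture weight of the methylated (high) component.
#' @param meth_beta_high,meth_beta_low Beta shape pairs of the two
#'   methylation modes.
#' @param meth_fold True mutability fold-change of methylated CpGs (rho).
#' @param n_features,feature_length,feature_multiplier Number of feature
#'   intervals, their length range (bp) and the within-feature rate
#'   multiplier (1 = null).
#' @param mappable_coverage,blacklist_coverage,variant_rate,driver_coverage
#'   Coverage of the mappable mask, blacklist, per-bp population-variant
#'   rate, and driver-region coverage.
#' @param seed Default seed recorded in outputs.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(contig_lengths = c(chrS1 = 1e6),
                             base_comp = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                             cpg_depletion = 0.2,
                             bin_width = 1e5,
                             chunk_concentration = 10,
                             n_samples = 100,
                             muts_per_sample = 300,
                             hypermutator_fraction = 0,
                             hypermutator_burden = 15000,
                             duplicate_fraction = 0,
                             duplicate_shared = 0.5,
                             meth_weight = 0.75,
                             meth_beta_high = c(20, 2),
                             meth_beta_low = c(2, 20),
                             meth_fold = 2,
                             n_features = 20,
                             feature_length = c(200, 600),
                             feature_multiplier = 1,
                             mappable_coverage = 0.95,
                             blacklist_coverage = 0.01,
                             variant_rate = 1e-4,
                             driver_coverage = 0.005,
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c(cfg$hypermutator_fraction, cfg$duplicate_fraction,
             cfg$duplicate_shared, cfg$meth_weight, cfg$mappable_coverage,
             cfg$blacklist_coverage, cfg$driver_coverage)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$cpg_depletion < 0 || cfg$meth_fold <= 0)
    stop("cpg_depletion must be >= 0 and meth_fold > 0")
  if (any(cfg$contig_lengths <= 0)) stop("contig lengths must be positive")
  stopifnot(abs(sum(cfg$base_comp) - 1) < 1e-8)
  class(cfg) <- "synthetic_config"
  cfg
}

# m random disjoint intervals of the given lengths within [1, L]
# (stick-breaking placement of the free space between intervals)
random_disjoint_intervals <- function(L, lens) {
  m <- length(lens)
  if (m == 0) return(IRanges::IRanges())
  free <- L - sum(lens)
  if (free < 0) stop("contig too short for the requested intervals")
  gaps <- if (m == 0) integer(0) else {
    u <- c(sort(runif(m)), 1)
    d <- diff(c(0, u))
    floor(d * free)[seq_len(m)]
  }
  starts <- cumsum(gaps) + cumsum(c(0, lens[-m])) + 1
  IRanges::IRanges(start = starts, width = lens)
}

#' Generate a synthetic genome plus mask sets
#'
#' Bases are drawn i.i.d. from the configured composition; CpG dinucleotides
#' are then thinned so their frequency is `cpg_depletion` times the
#' independence expectation (the G of a removed CpG is resampled from
#' \{A, T\}, which neither creates nor destroys other CpGs). Mappable,
#' blacklist, population-variant and driver masks are random disjoint
#' interval sets at the configured coverages.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return List with `genome` and `GRanges` masks `mappable`, `blacklist`,
#'   `variants`, `drivers`.
#' @export
generate_genome <- function(config, seed = config$seed) {
  with_seed(seed, {
    comp <- config$base_comp[BASES]
    contigs <- lapply(names(config$contig_lengths), function(ct) {
      L <- config$contig_lengths[[ct]]
      s <- sample(BASES, L, replace = TRUE, prob = comp)
      cg <- which(s[-L] == "C" & s[-1] == "G")
      if (length(cg) > 0 && config$cpg_depletion < 1) {
        drop <- cg[runif(length(cg)) > config$cpg_depletion]
        if (length(drop) > 0)
          s[drop + 1] <- sample(c("A", "T"), length(drop), replace = TRUE,
                                prob = comp[c("A", "T")])
      }
      paste(s, collapse = "")
    })
    names(contigs) <- names(config$contig_lengths)
    genome <- as_genome(unlist(contigs))

    masks <- list()
    one_mask <- function(cov, len_range) {
      pieces <- lapply(names(config$contig_lengths), function(ct) {
        L <- config$contig_lengths[[ct]]
        target <- cov * L
        if (target <= 0) return(GenomicRanges::GRanges())
        lens <- integer(0)
        while (sum(lens) < target)
          lens <- c(lens, sample(len_range[1]:len_range[2], 1))
        ir <- random_disjoint_intervals(L, lens)
        GenomicRanges::GRanges(ct, ir)
      })
      GenomicRanges::reduce(suppressWarnings(do.call(c, pieces)))
    }
    # mappable mask = genome minus random unmappable gaps
    gaps <- one_mask(1 - config$mappable_coverage, c(1000, 5000))
    full <- GenomicRanges::GRanges(names(config$contig_lengths),
                                   IRanges::IRanges(1, config$contig_lengths))
    masks$mappable <- GenomicRanges::setdiff(full, gaps)
    masks$blacklist <- one_mask(config$blacklist_coverage, c(200, 2000))
    nvar <- round(config$variant_rate * sum(config$contig_lengths))
    masks$variants <- if (nvar > 0) {
      ct <- sample(names(config$contig_lengths), nvar, replace = TRUE,
                   prob = config$contig_lengths)
      pos <- vapply(config$contig_lengths[ct], function(L) sample.int(L, 1), numeric(1))
      GenomicRanges::sort(GenomicRanges::GRanges(ct, IRanges::IRanges(pos, pos)))
    } else GenomicRanges::GRanges()
    masks$drivers <- one_mask(config$driver_coverage, c(1000, 5000))
    c(list(genome = genome), masks)
  })
}

#' Generate a per-CpG fractional-methylation table
#'
#' Each CpG site (keyed by the 1-based C on the + strand) receives a draw
#' from a two-component Beta mixture: a high (methylated) mode with weight
#' `meth_weight` and a low mode otherwise.
#'
#' @param genome Genome.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return data frame with columns `CONTIG`, `POS`, `FRACTION`.
#' @export
generate_methylation <- function(genome, config, seed = config$seed) {
  with_seed(seed, {
    rows <- lapply(names(genome), function(ct) {
      s <- as.character(genome[[ct]])
      b <- .base_codes(s)
      L <- length(b)
      if (L < 2) return(NULL)
      cpg <- which(b[-L] == 2L & b[-1] == 3L)
      if (length(cpg) == 0) return(NULL)
      data.frame(CONTIG = ct, POS = cpg)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab) || nrow(tab) == 0) stop("genome contains no CpG site")
    n <- nrow(tab)
    hi <- runif(n) < config$meth_weight
    frac <- numeric(n)
    frac[hi] <- rbeta(sum(hi), config$meth_beta_high[1], config$meth_beta_high[2])
    frac[!hi] <- rbeta(sum(!hi), config$meth_beta_low[1], config$meth_beta_low[2])
    tab$FRACTION <- frac
    tab
  })
}

#' Generate non-overlapping feature intervals
#'
#' Emulates a regulatory-feature track (e.g. transcription-factor binding
#' peaks): disjoint intervals with lengths uniform in the configured range.
#'
#' @param genome Genome.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return `GRanges` of features.
#' @export
generate_features <- function(genome, config, seed = config$seed) {
  with_seed(seed, {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    ct <- sample(names(genome), config$n_features, replace = TRUE, prob = lens)
    pieces <- lapply(names(genome), function(cn) {
      k <- sum(ct == cn)
      if (k == 0) return(GenomicRanges::GRanges())
      fl <- sample(config$feature_length[1]:config$feature_length[2], k,
                   replace = TRUE)
      GenomicRanges::GRanges(cn, random_disjoint_intervals(lens[[cn]], fl))
    })
    GenomicRanges::sort(suppressWarnings(do.call(c, pieces)))
  })
}

# ---------------------------------------------------------------------------
# Exact sequential weighted sampling without replacement over groups of
# equal-weight items, via an exponential race: the sorted arrival times of a
# group's N iid Exp(w) items are generated incrementally through memoryless
# gaps Exp((N - j) w), and the n globally-smallest arrivals are taken one at
# a time. Distribution-identical to item-level sampling without replacement.
race_group_counts <- function(N, w, n) {
  G <- length(N)
  stopifnot(length(w) == G)
  avail <- sum(N[w > 0])
  if (n > avail) stop("requested ", n, " draws but only ", avail,
                      " items have positive weight")
  k <- integer(G)
  rate <- N * w
  arr <- ifelse(rate > 0, rexp(G) / rate, Inf)
  for (j in seq_len(n)) {
    g <- which.min(arr)
    k[g] <- k[g] + 1L
    rem <- N[g] - k[g]
    arr[g] <- if (rem > 0) arr[g] + rexp(1) / (rem * w[g]) else Inf
  }
  k
}

# Build the sampling frame of a genome: scored positions grouped into
# classes of identical (context, bin, methylation, feature) state, with the
# per-class position lists needed to materialise draws.
sampling_frame <- function(genome, regions = NULL, bins = NULL,
                           methylation = NULL, features = NULL) {
  idx <- position_index(genome, regions = regions, bins = bins,
                        methylation = methylation, features = features)
  if (nrow(idx) == 0) stop("no scorable positions in the requested regions")
  meth_chr <- ifelse(is.na(idx$meth), "na", ifelse(idx$meth, "m", "u"))
  key <- paste(idx$context_id, ifelse(is.na(idx$bin), 0L, idx$bin),
               meth_chr, as.integer(idx$feat), sep = "|")
  f <- factor(key)
  classes <- data.frame(
    class = levels(f),
    context_id = as.integer(vapply(strsplit(levels(f), "|", fixed = TRUE), `[`, "", 1)),
    bin = as.integer(vapply(strsplit(levels(f), "|", fixed = TRUE), `[`, "", 2)),
    meth = vapply(strsplit(levels(f), "|", fixed = TRUE), `[`, "", 3),
    feat = vapply(strsplit(levels(f), "|", fixed = TRUE), `[`, "", 4) == "1",
    stringsAsFactors = FALSE)
  classes$bin[classes$bin == 0L] <- NA_integer_
  classes$N <- as.integer(table(f))
  list(index = idx, classes = classes,
       members = split(seq_len(nrow(idx)), f))
}

# Per-class-and-alternate weights for a mixture profile f_mix (named
# 96-vector summing to 1). Returns a (nclass x 3) matrix of per-item
# weights, unnormalised.
class_alt_weights <- function(frame, f_mix, chunk_rates = NULL,
                              meth_fold = 1, feature_multiplier = 1) {
  cls <- frame$classes
  meta <- .channel_meta()
  ctx32 <- sbs_contexts()
  # context x alternate channel probabilities (32 x 3) and the alternate
  # base occupying each slot
  fmat <- matrix(0, 32, 3, dimnames = list(ctx32, NULL))
  alt_of <- matrix("", 32, 3, dimnames = list(ctx32, NULL))
  seen <- integer(32)
  for (i in seq_len(96)) {
    ci <- meta$context_id[i]
    seen[ci] <- seen[ci] + 1L
    alt_of[ci, seen[ci]] <- meta$alt[i]
    fmat[ci, seen[ci]] <- f_mix[meta$channel[i]]
  }
  # N_{c,k}: context abundance within the class's bin (sum over meth/feat)
  binkey <- paste(cls$context_id, ifelse(is.na(cls$bin), 0L, cls$bin))
  Nck <- tapply(cls$N, binkey, sum)[binkey]
  w <- fmat[cls$context_id, , drop = FALSE] / as.numeric(Nck)
  if (!is.null(chunk_rates)) {
    r <- chunk_rates[ifelse(is.na(cls$bin), 1L, cls$bin)]
    w <- w * r
  }
  w[cls$meth == "m", ] <- w[cls$meth == "m", , drop = FALSE] * meth_fold
  w[cls$feat, ] <- w[cls$feat, , drop = FALSE] * feature_multiplier
  list(weights = w, alt = alt_of[cls$context_id, , drop = FALSE])
}

# Draw n distinct (position, alternate) events from a sampling frame with
# the given class x alternate weight matrix. Returns row indices into
# frame$index plus the pyrimidine-strand alternate.
draw_events <- function(frame, wmat, altmat, n) {
  Nrep <- rep(frame$classes$N, times = ncol(wmat))
  k <- race_group_counts(Nrep, as.vector(wmat), n)
  kk <- matrix(k, nrow = nrow(wmat))
  out_idx <- integer(n); out_alt <- character(n); at <- 0L
  for (g in which(rowSums(kk) > 0)) {
    mem <- frame$members[[g]]
    for (a in which(kk[g, ] > 0)) {
      cnt <- kk[g, a]
      out_idx[at + seq_len(cnt)] <- mem[sample.int(length(mem), cnt)]
      out_alt[at + seq_len(cnt)] <- altmat[g, a]
      at <- at + cnt
    }
  }
  list(idx = out_idx, alt = out_alt)
}

#' Simulate a mutation cohort from signature mixtures
#'
#' Per sample, draws `muts_per_sample` distinct (position, alternate)
#' events without replacement with probability proportional to
#' `r_k * f(c>a) / N_(c,k)` (chunk rate times channel probability over
#' within-chunk context abundance), with an extra `meth_fold` multiplier at
#' methylated CpG positions and `feature_multiplier` inside feature
#' intervals. Optional hypermutators and duplicate samples are appended. A
#' truth sidecar records each event's generating signature.
#'
#' @param gen Output of [generate_genome()] (or a bare genome, in which
#'   case the whole sequence is scorable).
#' @param profiles 96 x k signature profile matrix (columns sum to 1).
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @param exposures Per-sample signature mixture: a vector of length k
#'   (shared by all samples) or a k x `n_samples` matrix; defaults to the
#'   first signature only.
#' @param bins Optional bin `GRanges` for rate heterogeneity.
#' @param chunk_rates Optional relative rates per bin (sum 1); when `bins`
#'   is given and `chunk_rates` is `NULL`, rates are drawn from a symmetric
#'   Dirichlet with the configured concentration.
#' @param methylation Optional methylation table (activates `meth_fold`).
#' @param features Optional feature `GRanges` (activates
#'   `feature_multiplier`).
#' @return List with `mutations` (CHROMOSOME, POSITION, REF, ALT, SAMPLE,
#'   SIGNATURE_TRUE) and `truth` (seed, chunk rates, exposures, config).
#' @export
simulate_cohort <- function(gen, profiles, config, seed = config$seed,
                            exposures = NULL, bins = NULL,
                            chunk_rates = NULL, methylation = NULL,
                            features = NULL) {
  genome <- if (is.list(gen)) gen$genome else gen
  regions <- if (is.list(gen)) gen$mappable else NULL
  profiles <- as.matrix(profiles)
  k <- ncol(profiles)
  S <- config$n_samples
  if (is.null(exposures)) exposures <- c(1, rep(0, k - 1))
  E <- if (is.matrix(exposures)) exposures else
    matrix(exposures, nrow = k, ncol = S)
  if (nrow(E) != k || ncol(E) != S) stop("exposures must be k x n_samples")

  with_seed(seed, {
    frame <- sampling_frame(genome, regions = regions, bins = bins,
                            methylation = methylation, features = features)
    if (!is.null(bins) && is.null(chunk_rates)) {
      conc <- config$chunk_concentration
      chunk_rates <- if (is.infinite(conc)) rep(1 / length(bins), length(bins))
        else { g <- rgamma(length(bins), conc); g / sum(g) }
    }
    n_per <- rep(config$muts_per_sample, S)
    if (config$hypermutator_fraction > 0) {
      nh <- round(config$hypermutator_fraction * S)
      if (nh > 0) n_per[sample.int(S, nh)] <- config$hypermutator_burden
    }
    sample_ids <- sprintf("S%03d", seq_len(S))
    meta <- .channel_meta()
    ctx32 <- sbs_contexts()

    mix_cache <- new.env()
    rows <- vector("list", S)
    for (s in seq_len(S)) {
      e <- E[, s] / sum(E[, s])
      ckey <- paste(signif(e, 12), collapse = ",")
      cw <- get0(ckey, envir = mix_cache)
      if (is.null(cw)) {
        f_mix <- stats::setNames(as.vector(profiles %*% e), rownames(profiles))
        cw <- class_alt_weights(frame, f_mix,
                                chunk_rates = chunk_rates,
                                meth_fold = if (is.null(methylation)) 1 else config$meth_fold,
                                feature_multiplier = if (is.null(features)) 1 else config$feature_multiplier)
        assign(ckey, cw, envir = mix_cache)
      }
      ev <- draw_events(frame, cw$weights, cw$alt, n_per[s])
      pidx <- frame$index[ev$idx, ]
      ctx <- ctx32[pidx$context_id]
      channel <- sbs_channel_of(ctx, ev$alt)
      # generating signature drawn from the posterior E_s * f_s(channel)
      pw <- profiles[channel, , drop = FALSE] *
        matrix(E[, s], nrow = length(channel), ncol = k, byrow = TRUE)
      rs <- rowSums(pw)
      pw[rs == 0, ] <- 1
      cum <- pw %*% upper.tri(diag(k), diag = TRUE) / rowSums(pw)
      sig <- colnames(profiles)[rowSums(runif(length(channel)) > cum) + 1L]
      ref_plus <- ifelse(pidx$flipped,
                         COMPLEMENT[substr(ctx, 2, 2)], substr(ctx, 2, 2))
      alt_plus <- ifelse(pidx$flipped, COMPLEMENT[ev$alt], ev$alt)
      rows[[s]] <- data.frame(CHROMOSOME = pidx$contig, POSITION = pidx$pos,
                              REF = unname(ref_plus), ALT = unname(alt_plus),
                              SAMPLE = sample_ids[s], SIGNATURE_TRUE = sig,
                              stringsAsFactors = FALSE)
    }
    mut <- do.call(rbind, rows)

    if (config$duplicate_fraction > 0) {
      nd <- round(config$duplicate_fraction * S)
      if (nd > 0) {
        donors <- sample(sample_ids, nd)
        extra <- lapply(seq_along(donors), function(i) {
          d <- mut[mut$SAMPLE == donors[i], ]
          nsh <- round(config$duplicate_shared * nrow(d))
          shared <- d[sample.int(nrow(d), nsh), ]
          e0 <- E[, match(donors[i], sample_ids)] / sum(E[, match(donors[i], sample_ids)])
          f_mix <- stats::setNames(as.vector(profiles %*% e0), rownames(profiles))
          cw <- class_alt_weights(frame, f_mix, chunk_rates = chunk_rates,
                                  meth_fold = if (is.null(methylation)) 1 else config$meth_fold,
                                  feature_multiplier = if (is.null(features)) 1 else config$feature_multiplier)
          ev <- draw_events(frame, cw$weights, cw$alt, nrow(d) - nsh)
          pidx <- frame$index[ev$idx, ]
          ctx <- ctx32[pidx$context_id]
          fresh <- data.frame(
            CHROMOSOME = pidx$contig, POSITION = pidx$pos,
            REF = unname(ifelse(pidx$flipped, COMPLEMENT[substr(ctx, 2, 2)],
                                substr(ctx, 2, 2))),
            ALT = unname(ifelse(pidx$flipped, COMPLEMENT[ev$alt], ev$alt)),
            SAMPLE = NA_character_, SIGNATURE_TRUE = NA_character_,
            stringsAsFactors = FALSE)
          out <- rbind(shared, fresh)
          out$SAMPLE <- paste0("dup_", donors[i])
          out
        })
        mut <- rbind(mut, do.call(rbind, extra))
      }
    }
    rownames(mut) <- NULL
    list(mutations = mut,
         truth = list(seed = seed, chunk_rates = chunk_rates,
                      exposures = E, config = config))
  })
}

#' Random signature profiles
#'
#' Draws k synthetic 96-channel profiles from a symmetric Dirichlet;
#' smaller concentrations give more uneven (lower-entropy) profiles.
#'
#' @param k Number of profiles.
#' @param seed Integer seed.
#' @param concentration Dirichlet concentration (default 0.3).
#' @return 96 x k column-stochastic matrix (`RSIG1`..`RSIGk`).
#' @export
random_signature_profiles <- function(k, seed = 1L, concentration = 0.3) {
  with_seed(seed, {
    m <- matrix(rgamma(96 * k, concentration), 96, k)
    m <- sweep(m, 2, colSums(m), "/")
    dimnames(m) <- list(sbs_channels(), paste0("RSIG", seq_len(k)))
    m
  })
}

#' Built-in synthetic signature profiles
#'
#' Three clearly synthetic profiles used in examples and tests:
#' `SYN_CPG` (low entropy, C>T concentrated on the CpG-depleted NpCpG
#' contexts, emulating a deamination-like process), `SYN_TT` (T>G
#' concentrated on NpTpT contexts) and `SYN_FLAT` (near-uniform across all
#' 96 channels).
#'
#' @return 96 x 3 column-stochastic matrix.
#' @export
synthetic_signatures <- function() {
  ch <- sbs_channels()
  p_cpg <- stats::setNames(rep(1e-4, 96), ch)
  cpg_ch <- ch[substr(ch, 2, 6) == "[C>T]" & substr(ch, 7, 7) == "G"]
  p_cpg[cpg_ch] <- 1
  p_tt <- stats::setNames(rep(1e-4, 96), ch)
  tt_ch <- ch[substr(ch, 2, 6) == "[T>G]" & substr(ch, 7, 7) == "T"]
  p_tt[tt_ch] <- 1
  p_flat <- stats::setNames(rep(1, 96), ch)
  m <- cbind(SYN_CPG = p_cpg / sum(p_cpg), SYN_TT = p_tt / sum(p_tt),
             SYN_FLAT = p_flat / sum(p_flat))
  rownames(m) <- ch
  m
}
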