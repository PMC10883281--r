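# Sub-10-Kbp feature analyses: fixed-geometry windows around regulatory
# features (600 bp core centred in a 2000 bp window), pileup enrichment of
# hotspot mutations in the core versus the flanks with a sequence
# composition aware randomisation null, methylated-CpG odds ratios, and
# covariate decile summaries.

#' Build fixed-geometry windows around features
#'
#' Keeps features with length in `len_range` and mappable overlap at least
#' `min_overlap`, and centres a window of `window` bp (with a `core` bp
#' core) on each feature midpoint (floor rounding). Windows extending off
#' the contig are dropped.
#'
#' @param features Feature `GRanges`.
#' @param genome Genome.
#' @param mappable Optional mappable `GRanges` for the overlap filter.
#' @param window,core Window and core lengths in bp (defaults 2000 / 600).
#' @param len_range Feature length filter (default 200-600 bp).
#' @param min_overlap Minimum mappable-overlap fraction (default 0.9).
#' @return `GRanges` of windows with `core_start`/`core_end` metadata
#'   (flanks of (window-core)/2 bp each side).
#' @export
build_feature_windows <- function(features, genome, mappable = NULL,
                                  window = 2000, core = 600,
                                  len_range = c(200, 600), min_overlap = 0.9) {
  stopifnot((window - core) %% 2 == 0)
  w <- GenomicRanges::width(features)
  keep <- w >= len_range[1] & w <= len_range[2]
  if (!is.null(mappable)) {
    red <- GenomicRanges::reduce(mappable)
    hits <- GenomicRanges::findOverlaps(features, red)
    ovw <- numeric(length(features))
    if (length(hits) > 0) {
      iw <- GenomicRanges::width(GenomicRanges::pintersect(
        features[S4Vectors::queryHits(hits)], red[S4Vectors::subjectHits(hits)]))
      ovw <- as.numeric(tapply(iw, factor(S4Vectors::queryHits(hits),
                                          levels = seq_along(features)),
                               sum, default = 0))
    }
    keep <- keep & (ovw / w >= min_overlap)
  }
  f <- features[keep]
  if (length(f) == 0) return(GenomicRanges::GRanges())
  mid <- floor((GenomicRanges::start(f) + GenomicRanges::end(f)) / 2)
  ws <- mid - window %/% 2 + 1
  we <- ws + window - 1
  lens <- stats::setNames(Biostrings::width(genome), names(genome))
  ok <- ws >= 1 & we <= lens[as.character(GenomicRanges::seqnames(f))]
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(f)[ok],
                                IRanges::IRanges(ws[ok], we[ok]))
  half_fl <- (window - core) %/% 2
  out$core_start <- GenomicRanges::start(out) + half_fl
  out$core_end <- out$core_start + core - 1
  out$feature_id <- which(keep)[ok]
  out
}

# per-window-position mutability weights: sum over alternates of the
# profile channel probabilities of each position's context
.window_weights <- function(windows, genome, f) {
  meta <- .channel_meta()
  ctx_w <- tapply(f[meta$channel], meta$context_id, sum)  # 32-vector
  lapply(seq_along(windows), function(i) {
    ct <- as.character(GenomicRanges::seqnames(windows)[i])
    p <- GenomicRanges::start(windows)[i]:GenomicRanges::end(windows)[i]
    ctx <- pyrimidine_context(genome, ct, p)
    w <- rep(0, length(p))
    known <- !is.na(ctx)
    w[known] <- as.numeric(ctx_w[match(ctx[known], sbs_contexts())])
    w
  })
}

#' Pileup enrichment of hotspot mutations at feature cores
#'
#' Piles mutations onto aligned window coordinates and computes the fold
#' change of the per-bp mutation rate in the core versus the flanks. The
#' null redistributes the observed number of inside-window mutations
#' across window positions with probability proportional to the
#' signature's trinucleotide mutational probability at each position's
#' sequence context; significance is the upper-tail mass of the observed
#' fold change under a Gaussian kernel density fitted to the null fold
#' changes (floored at 1/n_rand). Smoothed pileup profiles
#' (Savitzky-Golay, length 101, order 3) are returned for display only.
#'
#' @param windows Windows from [build_feature_windows()].
#' @param mutations Inside-hotspot mutations (CHROMOSOME, POSITION).
#' @param genome Genome.
#' @param f Named 96-vector signature profile.
#' @param n_rand Null randomisations (default 1000).
#' @param seed Integer seed.
#' @return List: `fc`, `p`, `p_empirical`, `null_fc`, `core_count`,
#'   `flank_count`, `profile` (per-offset counts and smoothed rate),
#'   `flagged` (zero flank count).
#' @export
pileup_enrichment <- function(windows, mutations, genome, f, n_rand = 1000,
                              seed = 1L) {
  if (length(windows) == 0) stop("no windows to analyse")
  W <- GenomicRanges::width(windows)[1]
  gr <- GenomicRanges::GRanges(mutations$CHROMOSOME,
                               IRanges::IRanges(mutations$POSITION,
                                                mutations$POSITION))
  hits <- GenomicRanges::findOverlaps(gr, windows)
  if (length(hits) == 0) stop("no inside-hotspot mutation overlaps a window")
  off <- mutations$POSITION[S4Vectors::queryHits(hits)] -
    GenomicRanges::start(windows)[S4Vectors::subjectHits(hits)] + 1L
  core_lo <- windows$core_start - GenomicRanges::start(windows) + 1L
  core_hi <- windows$core_end - GenomicRanges::start(windows) + 1L
  core_len <- core_hi[1] - core_lo[1] + 1L
  flank_len <- W - core_len
  in_core <- off >= core_lo[S4Vectors::subjectHits(hits)] &
             off <= core_hi[S4Vectors::subjectHits(hits)]
  n_obs <- length(off)
  core_count <- sum(in_core)
  flank_count <- n_obs - core_count
  fc_of <- function(cc, fl) (cc / core_len) / (fl / flank_len)
  fc <- if (flank_count == 0) Inf else fc_of(core_count, flank_count)

  wts <- .window_weights(windows, genome, f)
  flat_w <- unlist(wts)
  is_core_slot <- unlist(lapply(seq_along(wts), function(i)
    seq_len(W) >= core_lo[i] & seq_len(W) <= core_hi[i]))
  null_fc <- with_seed(seed, {
    vapply(seq_len(n_rand), function(r) {
      slots <- sample.int(length(flat_w), n_obs, replace = TRUE,
                          prob = flat_w)
      cc <- sum(is_core_slot[slots])
      fl <- n_obs - cc
      if (fl == 0) Inf else fc_of(cc, fl)
    }, numeric(1))
  })
  finite_null <- null_fc[is.finite(null_fc)]
  if (is.infinite(fc)) {
    p <- 1 / n_rand
  } else {
    kd <- stats::density(finite_null, from = min(finite_null) - 1,
                         to = max(c(finite_null, fc)) + 1, n = 2048)
    dx <- diff(kd$x[1:2])
    p <- sum(kd$y[kd$x >= fc]) * dx / (sum(kd$y) * dx)
    p <- max(p, 1 / n_rand)
  }
  p_emp <- max(mean(null_fc >= fc), 1 / n_rand)

  counts <- tabulate(off, nbins = W)
  wsum <- Reduce(`+`, wts)
  rate <- counts / sum(counts)
  sg_n <- min(101, if (W %% 2 == 1) W else W - 1)
  smoothed <- signal::sgolayfilt(rate, p = 3, n = sg_n)
  list(fc = fc, p = p, p_empirical = p_emp, null_fc = null_fc,
       core_count = core_count, flank_count = flank_count,
       profile = data.frame(offset = seq_len(W), count = counts,
                            rate = rate, smoothed = smoothed,
                            context_weight = wsum),
       flagged = flank_count == 0)
}

#' Classify CpG sites by fractional methylation
#'
#' @param methylation Table with CONTIG, POS, FRACTION (mean fractional
#'   methylation across epigenomes).
#' @param threshold Sites with fraction strictly above this are methylated
#'   (default 0.5).
#' @return Input with a `CLASS` column (`"methylated"`/`"unmethylated"`).
#' @export
classify_methylation <- function(methylation, threshold = 0.5) {
  stopifnot(all(methylation$FRACTION >= 0 & methylation$FRACTION <= 1))
  methylation$CLASS <- ifelse(methylation$FRACTION > threshold,
                              "methylated", "unmethylated")
  methylation
}

#' Read a per-CpG fractional methylation table
#'
#' TSV with columns CONTIG, POS, FRACTION and optionally EPIGENOME; with
#' several epigenomes, sites are averaged (unweighted) and sites missing
#' in any epigenome are skipped.
#'
#' @param path TSV file.
#' @return Data frame with CONTIG, POS, FRACTION.
#' @export
read_methylation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("CONTIG", "POS", "FRACTION")
  if (!all(need %in% names(tab)))
    stop("methylation table needs columns ", paste(need, collapse = ", "))
  if ("EPIGENOME" %in% names(tab)) {
    ne <- length(unique(tab$EPIGENOME))
    agg <- stats::aggregate(FRACTION ~ CONTIG + POS, tab,
                            function(x) c(mean(x), length(x)))
    frac <- agg$FRACTION
    agg$FRACTION <- frac[, 1]
    agg <- agg[frac[, 2] == ne, ]   # complete across epigenomes only
  } else agg <- tab[, need]
  agg[order(agg$CONTIG, agg$POS), ]
}

#' Odds ratio of an event between methylated and unmethylated CpGs
#'
#' Builds the 2x2 table of CpG sites (event yes/no x methylated yes/no),
#' where the event is typically "carries a mutation" or "overlaps a
#' hotspot", and returns the odds ratio with its 95% Wald confidence
#' interval (Haldane 0.5 correction for zero cells, flagged).
#'
#' @param methylation Classified methylation table (see
#'   [classify_methylation()]).
#' @param events Data frame of event positions (CHROMOSOME, POSITION; the
#'   position of the CpG's C).
#' @return List with `or`, `ci`, `pct_meth`, `pct_unmeth`, `table`,
#'   `corrected`.
#' @export
methylation_odds_ratio <- function(methylation, events) {
  if (!"CLASS" %in% names(methylation))
    methylation <- classify_methylation(methylation)
  is_meth <- methylation$CLASS == "methylated"
  if (!any(is_meth) || !any(!is_meth))
    stop("need CpG sites in both methylation classes")
  key <- paste(methylation$CONTIG, methylation$POS)
  ev <- key %in% unique(paste(events$CHROMOSOME, events$POSITION))
  a <- sum(ev & is_meth); b <- sum(!ev & is_meth)
  c_ <- sum(ev & !is_meth); d <- sum(!ev & !is_meth)
  pct_meth <- 100 * a / (a + b)
  pct_unmeth <- 100 * c_ / (c_ + d)
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  or <- (a / b) / (c_ / d)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or, ci = exp(log(or) + c(-1, 1) * 1.96 * se),
       pct_meth = pct_meth, pct_unmeth = pct_unmeth,
       table = matrix(c(a, b, c_, d), 2, 2,
                      dimnames = list(c("event", "no_event"),
                                      c("meth", "unmeth"))),
       corrected = corrected)
}

#' Decile summary of signature activity against a bin-level covariate
#'
#' Ranks bins by a covariate signal, splits them into 10 equal-count
#' groups and reports the normalised signature activity inside and
#' outside hotspots per decile.
#'
#' @param signal Per-bin covariate values.
#' @param inside,outside Per-bin signature activity inside/outside
#'   hotspots (same length as `signal`).
#' @return Data frame with `decile`, `n_bins`, `signal_mean`,
#'   `inside`, `outside` (activities normalised to sum 1 across deciles).
#' @export
covariate_deciles <- function(signal, inside, outside) {
  stopifnot(length(signal) == length(inside),
            length(signal) == length(outside))
  if (length(signal) < 10) stop("need at least 10 bins for deciles")
  if (stats::var(signal) == 0)
    warning("constant covariate signal: deciles are degenerate")
  dec <- ceiling(10 * rank(signal, ties.method = "first") / length(signal))
  agg <- function(x) as.numeric(tapply(x, factor(dec, levels = 1:10), sum,
                                       default = 0))
  ins <- agg(inside); outs <- agg(outside)
  data.frame(decile = 1:10,
             n_bins = as.integer(table(factor(dec, levels = 1:10))),
             signal_mean = as.numeric(tapply(signal, factor(dec, levels = 1:10),
                                             mean, default = NA)),
             inside_total = ins, outside_total = outs,
             inside = if (sum(ins) > 0) ins / sum(ins) else ins,
             outside = if (sum(outs) > 0) outs / sum(outs) else outs)
}
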