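# Observed hotspot propensity via controlled subsampling, hotspot
# conversion rates, and the inside-versus-outside-hotspot enrichment
# statistics.

#' Signature-cohort pairs eligible for propensity analysis
#'
#' Eligible iff the signature has at least `min_hotspots` attributed
#' hotspots in the cohort and more than `min_muts` high-confidence
#' mutations per sample in at least `min_samples` samples.
#'
#' @param hotspot_counts Named vector: attributed hotspots per signature.
#' @param highconf_counts Matrix or data frame of per-sample
#'   high-confidence mutation counts (signatures x samples), or a named
#'   list of per-sample count vectors.
#' @param min_hotspots,min_muts,min_samples Eligibility thresholds
#'   (defaults 450, 300, 101; hotspots inclusive, mutations strict,
#'   samples inclusive).
#' @return Data frame with per-signature tallies and an `eligible` flag.
#' @export
eligible_pairs <- function(hotspot_counts, highconf_counts,
                           min_hotspots = 450, min_muts = 300,
                           min_samples = 101) {
  sigs <- names(hotspot_counts)
  if (is.list(highconf_counts) && !is.data.frame(highconf_counts)) {
    qual <- vapply(sigs, function(s)
      sum(highconf_counts[[s]] > min_muts), integer(1))
  } else {
    hc <- as.matrix(highconf_counts)
    qual <- vapply(sigs, function(s)
      sum(hc[s, ] > min_muts), integer(1))
  }
  data.frame(signature = sigs,
             hotspots = as.integer(hotspot_counts),
             qualifying_samples = as.integer(qual),
             eligible = hotspot_counts >= min_hotspots & qual >= min_samples)
}

#' Subsampling specification for observed hotspot propensity
#'
#' @param n_samples Samples per subsample (default 100).
#' @param muts_per_sample Mutations drawn per sample (by-sample grouping).
#' @param total_muts Mutations drawn per subsample (pooled grouping).
#' @param iterations Number of subsamples (default 1000).
#' @param grouping `"by_sample"` or `"pooled"`.
#' @param seed Integer seed.
#' @return A `subsample_spec` list.
#' @export
subsample_spec <- function(n_samples = 100, muts_per_sample = 300,
                           total_muts = n_samples * muts_per_sample,
                           iterations = 1000,
                           grouping = c("by_sample", "pooled"), seed = 1L) {
  grouping <- match.arg(grouping)
  stopifnot(n_samples >= 1, muts_per_sample >= 1, iterations >= 1)
  structure(list(n_samples = n_samples, muts_per_sample = muts_per_sample,
                 total_muts = total_muts, iterations = iterations,
                 grouping = grouping, seed = seed),
            class = "subsample_spec")
}

# integer key per (contig, position) and per (contig, position, alt)
.event_keys <- function(m) {
  pos_key <- match(paste(m$CHROMOSOME, m$POSITION), unique(paste(m$CHROMOSOME, m$POSITION)))
  alt_key <- match(m$ALT, c("A", "C", "G", "T"))
  list(pos = pos_key, posalt = pos_key * 5L + alt_key)
}

#' Observed hotspot propensity by subsampling
#'
#' Repeatedly subsamples a fixed activity (either `n_samples` samples with
#' `muts_per_sample` mutations each, drawn without replacement from the
#' qualifying samples, or `total_muts` mutations from the merged pool) and
#' counts the recurrently mutated positions: equal-alternate recurrence in
#' at least two distinct samples (by-sample) or two sampled mutations
#' (pooled), collapsed to at most one hotspot per position.
#'
#' @param mutations High-confidence SNVs of one signature (CHROMOSOME,
#'   POSITION, ALT, SAMPLE).
#' @param spec A [subsample_spec()].
#' @param regions Optional `GRanges` restricting the analysed positions
#'   (e.g. selected mappable bins).
#' @return A `propensity_result` list: per-iteration `counts`, `median`,
#'   `iqr`.
#' @export
observed_propensity <- function(mutations, spec, regions = NULL) {
  m <- as.data.frame(mutations)
  if (!is.null(regions)) {
    gr <- GenomicRanges::GRanges(m$CHROMOSOME,
                                 IRanges::IRanges(m$POSITION, m$POSITION))
    m <- m[IRanges::overlapsAny(gr, regions), , drop = FALSE]
  }
  if (spec$grouping == "by_sample")  # a sample carries an event at most once
    m <- m[!duplicated(paste(m$SAMPLE, m$CHROMOSOME, m$POSITION, m$ALT)), ,
           drop = FALSE]
  keys <- .event_keys(m)
  counts <- integer(spec$iterations)
  with_seed(spec$seed, {
    if (spec$grouping == "by_sample") {
      per_sample <- split(seq_len(nrow(m)), m$SAMPLE)
      qualifying <- per_sample[lengths(per_sample) >= spec$muts_per_sample]
      if (length(qualifying) < spec$n_samples)
        stop("only ", length(qualifying), " samples carry >= ",
             spec$muts_per_sample, " eligible mutations (need ",
             spec$n_samples, ")")
      for (it in seq_len(spec$iterations)) {
        picked <- qualifying[sample.int(length(qualifying), spec$n_samples)]
        rows <- unlist(lapply(picked, function(ix)
          ix[sample.int(length(ix), spec$muts_per_sample)]), use.names = FALSE)
        ka <- keys$posalt[rows]
        dup <- ka[duplicated(ka)]
        counts[it] <- length(unique(keys$pos[rows][ka %in% dup]))
      }
    } else {
      if (spec$total_muts > nrow(m))
        stop("pool holds ", nrow(m), " mutations; cannot draw ",
             spec$total_muts)
      for (it in seq_len(spec$iterations)) {
        rows <- sample.int(nrow(m), spec$total_muts)
        ka <- keys$posalt[rows]
        dup <- ka[duplicated(ka)]
        counts[it] <- length(unique(keys$pos[rows][ka %in% dup]))
      }
    }
  })
  structure(list(counts = counts, median = stats::median(counts),
                 iqr = stats::IQR(counts), spec = spec),
            class = "propensity_result")
}

#' Hotspot conversion rate (mutations per hotspot)
#'
#' Per iteration, draws `subset` samples without replacement, pools their
#' SNVs, identifies equal-alternate hotspots, and regresses each sample's
#' hotspot membership count on its mutation burden (OLS). If at least
#' `min_significant` iterations yield a significant slope (t-test,
#' p < 0.05), the conversion rate is the inverse of the aggregated
#' significant slope.
#'
#' @param mutations SNV data frame with SAMPLE.
#' @param iterations Number of replicates (default 1000).
#' @param subset Samples per replicate (default 100).
#' @param min_significant Minimum significant replicates (default 750,
#'   scaled to `iterations`/1000).
#' @param order `"aggregate_then_invert"` (median significant slope, then
#'   inverse; default) or `"per_replicate"` (median of per-replicate
#'   inverses).
#' @param seed Integer seed.
#' @return List with `conversion` (`NA` if underpowered), `slopes`,
#'   `n_significant`, `n_degenerate`.
#' @export
conversion_rate <- function(mutations, iterations = 1000, subset = 100,
                            min_significant = round(750 * iterations / 1000),
                            order = c("aggregate_then_invert", "per_replicate"),
                            seed = 1L) {
  order <- match.arg(order)
  m <- as.data.frame(mutations)
  samples <- unique(m$SAMPLE)
  if (length(samples) <= subset)
    stop("cohort must exceed ", subset, " samples")
  per_sample <- split(seq_len(nrow(m)), m$SAMPLE)
  keys <- .event_keys(m)
  slopes <- pvals <- rep(NA_real_, iterations)
  degenerate <- 0L
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      picked <- sample(samples, subset)
      rows <- unlist(per_sample[picked], use.names = FALSE)
      ka <- keys$posalt[rows]
      samp <- m$SAMPLE[rows]
      # distinct events per sample, then recurrence across samples
      dd <- !duplicated(paste(ka, samp))
      ka <- ka[dd]; samp <- samp[dd]; rows2 <- rows[dd]
      tab <- table(ka)
      hot <- as.integer(names(tab)[tab >= 2])
      burden <- as.numeric(table(factor(samp, levels = picked)))
      if (length(hot) == 0) { response <- rep(0, subset) } else {
        inhot <- ka %in% hot
        response <- as.numeric(table(factor(samp[inhot], levels = picked)))
      }
      if (stats::var(burden) == 0) { degenerate <- degenerate + 1L; next }
      fit <- stats::lm(response ~ burden)
      sm <- suppressWarnings(summary(fit))$coefficients
      if (nrow(sm) < 2) { degenerate <- degenerate + 1L; next }
      slopes[it] <- sm["burden", "Estimate"]
      pvals[it] <- sm["burden", "Pr(>|t|)"]
    }
  })
  sig <- !is.na(pvals) & pvals < 0.05 & slopes > 0
  conversion <- if (sum(sig) >= min_significant) {
    if (order == "aggregate_then_invert") 1 / stats::median(slopes[sig])
    else stats::median(1 / slopes[sig])
  } else NA_real_
  list(conversion = conversion, slopes = slopes, pvals = pvals,
       n_significant = sum(sig), n_degenerate = degenerate)
}

#' Signature fold change inside versus outside hotspots
#'
#' Per sample, the probability vectors of inside-hotspot mutations are
#' summed and normalised to shares (likewise outside); the fold change of
#' a signature is its inside share over its outside share, summarised as
#' the median over active samples. Significance per signature is a
#' two-sided paired signed-rank test on the (inside, outside) share pairs,
#' Benjamini-Hochberg adjusted across signatures.
#'
#' @param inside,outside Samples x signatures matrices of summed
#'   probability vectors (one row per sample).
#' @param active Optional logical samples x signatures matrix of sample
#'   activity; defaults to all active.
#' @param alpha BH significance level (default 0.01).
#' @return Data frame per signature: `fc`, `p`, `q`, `n_pairs`,
#'   `significant`; excluded sample-signature pairs (zero outside share)
#'   tallied in `attr(, "excluded")`.
#' @export
signature_fold_change <- function(inside, outside, active = NULL,
                                  alpha = 0.01) {
  inside <- as.matrix(inside); outside <- as.matrix(outside)
  stopifnot(identical(dim(inside), dim(outside)))
  if (is.null(active)) active <- matrix(TRUE, nrow(inside), ncol(inside))
  if (any(rowSums(inside) == 0) || any(rowSums(outside) == 0))
    stop("every sample needs at least one mutation inside and outside hotspots")
  ins <- inside / rowSums(inside)
  out <- outside / rowSums(outside)
  sigs <- colnames(inside)
  excluded <- 0L
  res <- lapply(seq_along(sigs), function(j) {
    use <- active[, j] & out[, j] > 0
    excluded <<- excluded + sum(active[, j] & out[, j] == 0)
    if (!any(use))
      return(data.frame(signature = sigs[j], fc = NA_real_, p = NA_real_,
                        n_pairs = 0L))
    fc <- stats::median(ins[use, j] / out[use, j])
    p <- if (sum(use) >= 2 && any(ins[use, j] != out[use, j]))
      suppressWarnings(stats::wilcox.test(ins[use, j], out[use, j],
                                          paired = TRUE)$p.value)
    else NA_real_
    data.frame(signature = sigs[j], fc = fc, p = p, n_pairs = sum(use))
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$q) & res$q < alpha
  attr(res, "excluded") <- excluded
  res
}

#' Substitution-type enrichment inside hotspots
#'
#' Fold change of each substitution channel's frequency among mutations
#' inside hotspots versus outside, in the 6-class or 96-class scheme.
#'
#' @param inside,outside SNV data frames (CHROMOSOME, POSITION, REF, ALT).
#' @param genome Genome.
#' @param scheme 6 or 96.
#' @return Data frame with `channel`, `freq_inside`, `freq_outside`, `fc`
#'   (`Inf` flagged when a channel is absent outside but present inside).
#' @export
substitution_enrichment <- function(inside, outside, genome, scheme = c(6, 96)) {
  scheme <- match.arg(as.character(scheme[1]), c("6", "96"))
  if (nrow(inside) == 0 || nrow(outside) == 0)
    stop("both the inside and outside sets must be non-empty")
  chan <- function(m) {
    out <- character(nrow(m))
    for (ct in unique(m$CHROMOSOME)) {
      rows <- which(m$CHROMOSOME == ct)
      ctx <- pyrimidine_context(genome, ct, m$POSITION[rows])
      s <- as.character(genome[[ct]])
      flip <- substring(s, m$POSITION[rows], m$POSITION[rows]) %in% c("A", "G")
      alt <- ifelse(flip, unname(COMPLEMENT[m$ALT[rows]]), m$ALT[rows])
      out[rows] <- ifelse(is.na(ctx), NA,
                          if (scheme == "96") sbs_channel_of(ctx, alt)
                          else paste0(substr(ctx, 2, 2), ">", alt))
    }
    out
  }
  levs <- if (scheme == "96") sbs_channels() else
    c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  fi <- table(factor(chan(inside), levels = levs))
  fo <- table(factor(chan(outside), levels = levs))
  pi_ <- as.numeric(fi) / sum(fi)
  po <- as.numeric(fo) / sum(fo)
  data.frame(channel = levs, freq_inside = pi_, freq_outside = po,
             fc = ifelse(po == 0 & pi_ > 0, Inf, ifelse(pi_ == 0 & po == 0,
                                                        NA, pi_ / po)),
             flagged = po == 0 & pi_ > 0)
}
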