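# Signature-profile handling: 96-channel catalogues, genome-composition
# normalisation and entropy, NNLS exposure fitting with AIC subset search,
# and probabilistic attribution of mutations and hotspots to signatures.

#' Read a COSMIC-style signature profile table
#'
#' First column `Type` holds channel labels like `A[C>A]A`; every other
#' column is one signature. Channels are reordered to the package's
#' canonical order and columns checked to sum to 1.
#'
#' @param path TSV file.
#' @return 96 x k numeric matrix with channel rownames.
#' @export
read_signature_profiles <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"Type" %in% names(tab)) stop("profile table must have a 'Type' column")
  ch <- sbs_channels()
  if (!setequal(tab$Type, ch)) stop("profile table must cover the 96 SBS channels")
  m <- as.matrix(tab[match(ch, tab$Type), setdiff(names(tab), "Type"), drop = FALSE])
  rownames(m) <- ch
  if (any(abs(colSums(m) - 1) > 1e-6))
    stop("signature profile columns must sum to 1")
  m
}

#' Build a 96-channel mutation catalogue
#'
#' Each SNV increments its pyrimidine-collapsed (context, alternate)
#' channel in its sample's column; mutations with unresolvable context are
#' skipped and tallied in `attr(, "skipped")`.
#'
#' @param mutations Mutation data frame (SNVs; other types error).
#' @param genome Genome.
#' @return 96 x samples integer matrix.
#' @export
build_catalog <- function(mutations, genome) {
  m <- as.data.frame(mutations)
  if (any(nchar(m$REF) != 1 | nchar(m$ALT) != 1))
    stop("catalogues are built from SNVs only")
  samples <- sort(unique(m$SAMPLE))
  ch <- sbs_channels()
  M <- matrix(0L, 96, length(samples), dimnames = list(ch, samples))
  skipped <- 0L
  for (ct in unique(m$CHROMOSOME)) {
    rows <- which(m$CHROMOSOME == ct)
    ctx <- pyrimidine_context(genome, ct, m$POSITION[rows])
    s <- as.character(genome[[ct]])
    centre <- substring(s, m$POSITION[rows], m$POSITION[rows])
    flip <- centre %in% c("A", "G")
    alt <- ifelse(flip, unname(COMPLEMENT[m$ALT[rows]]), m$ALT[rows])
    ok <- !is.na(ctx) & !is.na(alt) & alt != substr(ctx, 2, 2)
    skipped <- skipped + sum(!ok)
    if (any(ok)) {
      lab <- sbs_channel_of(ctx[ok], alt[ok])
      idx <- cbind(match(lab, ch), match(m$SAMPLE[rows][ok], samples))
      for (j in seq_len(nrow(idx)))
        M[idx[j, 1], idx[j, 2]] <- M[idx[j, 1], idx[j, 2]] + 1L
    }
  }
  attr(M, "skipped") <- skipped
  M
}

#' Normalise a signature profile by genomic context abundance
#'
#' Divides each channel probability by the abundance of its reference
#' triplet and renormalises to 1, yielding the per-context relative
#' mutability of the process irrespective of genome composition.
#'
#' @param f Named 96-vector of channel probabilities.
#' @param cen `context_census` (or named 32-vector of context counts).
#' @return Named 96-vector summing to 1.
#' @export
normalize_profile <- function(f, cen) {
  ch <- sbs_channels()
  f <- f[ch]
  N <- if (inherits(cen, "context_census")) census_vector(cen) else cen[sbs_contexts()]
  Nc <- N[.channel_meta()$context_id]
  if (any(f > 0 & (is.na(Nc) | Nc == 0)))
    stop("zero genomic abundance for a context with positive channel probability")
  w <- ifelse(f > 0, f / Nc, 0)
  stats::setNames(w / sum(w), ch)
}

#' Shannon entropy of a normalised profile
#'
#' Natural-log entropy with the 0 log 0 := 0 convention; bounded by
#' log(96) ~ 4.564 for the uniform profile.
#'
#' @param p Probability vector summing to 1.
#' @return Entropy in nats.
#' @export
profile_entropy <- function(p) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("p must be a probability vector")
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Fit signature exposures by non-negative least squares
#'
#' Column-wise NNLS: for each sample, exposures minimise
#' `|S e - m|^2` subject to `e >= 0` (Lawson-Hanson).
#'
#' @param M 96 x samples catalogue matrix.
#' @param S 96 x k signature profile matrix.
#' @return List with `exposures` (k x samples) and `residuals` (per-sample
#'   residual norms).
#' @export
fit_exposures_nnls <- function(M, S) {
  M <- as.matrix(M); S <- as.matrix(S)
  if (nrow(M) != nrow(S)) stop("channel mismatch between catalogue and profiles")
  k <- ncol(S)
  E <- matrix(0, k, ncol(M),
              dimnames = list(colnames(S), colnames(M)))
  res <- numeric(ncol(M))
  for (j in seq_len(ncol(M))) {
    fit <- pracma::lsqnonneg(S, M[, j])
    E[, j] <- fit$x
    res[j] <- sqrt(fit$resid.norm)
  }
  list(exposures = E, residuals = res)
}

#' Enumerate candidate signature subsets
#'
#' All subsets of sizes 1..`kmax` of the candidate set, materialised as a
#' list (the basis of the AIC combination search).
#'
#' @param candidates Character vector of signature names.
#' @param kmax Maximum subset size (default 4).
#' @return List of character vectors.
#' @export
enumerate_signature_subsets <- function(candidates, kmax = 4) {
  kmax <- min(kmax, length(candidates))
  unlist(lapply(seq_len(kmax), function(k)
    utils::combn(candidates, k, simplify = FALSE)), recursive = FALSE)
}

#' AIC search over signature combinations
#'
#' Fits every subset of 1..`kmax` candidate signatures by NNLS and ranks
#' them by AIC = n_obs log(RSS/n_obs) + 2 k n_samples with
#' n_obs = 96 n_samples. Reports the AIC-best subset, the per-signature
#' frequency among the `top` best solutions, and the chosen subset (the
#' top-ranked subset maximising the mean frequency of its members, AIC
#' breaking ties).
#'
#' @param M 96 x samples catalogue.
#' @param S 96 x candidates profile matrix.
#' @param kmax Maximum subset size.
#' @param top Number of best solutions over which signature frequencies are
#'   aggregated (default 100).
#' @param max_subsets Enumeration cap; exceeding it errors with advice to
#'   prune candidates.
#' @return List: `ranking` (data frame subset/size/rss/aic, AIC-sorted),
#'   `best` (AIC-best subset), `frequency` (named vector over candidates),
#'   `chosen`.
#' @export
select_signature_combination <- function(M, S, kmax = 4, top = 100,
                                         max_subsets = 2e5) {
  M <- as.matrix(M); S <- as.matrix(S)
  cand <- colnames(S)
  if (is.null(cand)) stop("candidate profiles must be named columns")
  subsets <- enumerate_signature_subsets(cand, kmax)
  if (length(subsets) > max_subsets)
    stop(length(subsets), " subsets exceed the cap (", max_subsets,
         "); prune the candidate list or raise max_subsets")
  ns <- ncol(M); nobs <- 96 * ns
  rss <- vapply(subsets, function(sub) {
    fit <- fit_exposures_nnls(M, S[, sub, drop = FALSE])
    sum(fit$residuals^2)
  }, numeric(1))
  kk <- lengths(subsets)
  aic <- nobs * log(pmax(rss, .Machine$double.xmin) / nobs) + 2 * kk * ns
  ord <- order(aic)
  ranking <- data.frame(
    subset = vapply(subsets, paste, character(1), collapse = "+")[ord],
    size = kk[ord], rss = rss[ord], aic = aic[ord])
  topn <- min(top, length(subsets))
  top_subsets <- subsets[ord[seq_len(topn)]]
  freq <- vapply(cand, function(sg)
    mean(vapply(top_subsets, function(s) sg %in% s, logical(1))), numeric(1))
  score <- vapply(top_subsets, function(s) mean(freq[s]), numeric(1))
  chosen <- top_subsets[[which.max(score)]]
  list(ranking = ranking, best = subsets[[ord[1]]], frequency = freq,
       chosen = chosen)
}

#' Signature probability vector of a mutation
#'
#' `P(s) = E_s f_s(channel) / sum_t E_t f_t(channel)` for one mutation's
#' channel given its sample's exposures.
#'
#' @param channel Channel label(s), e.g. `"A[C>T]A"`.
#' @param exposures Named exposure vector of the sample.
#' @param profiles 96 x k profile matrix.
#' @return Matrix (length(channel) x k) of probabilities; rows sum to 1.
#'   Rows with an all-zero denominator are `NA` (unattributable).
#' @export
mutation_probability_vector <- function(channel, exposures, profiles) {
  profiles <- as.matrix(profiles)
  k <- ncol(profiles)
  num <- profiles[channel, , drop = FALSE] *
    matrix(exposures, nrow = length(channel), ncol = k, byrow = TRUE)
  den <- rowSums(num)
  out <- num / den
  out[den == 0, ] <- NA_real_
  rownames(out) <- channel
  out
}

#' Maximum-likelihood signature call
#'
#' Argmax of a probability vector with lexicographic tie-break; the call is
#' high-confidence iff the maximum strictly exceeds the threshold.
#'
#' @param p Named probability vector (or matrix, one row per mutation).
#' @param threshold High-confidence threshold (default 0.5, strict).
#' @return Data frame with `signature` and `high_confidence`.
#' @export
assign_max_likelihood <- function(p, threshold = 0.5) {
  if (is.null(dim(p))) p <- matrix(p, 1, dimnames = list(NULL, names(p)))
  if (ncol(p) == 0) stop("empty probability vector")
  sigs <- colnames(p)
  ord <- order(sigs)
  p2 <- p[, ord, drop = FALSE]
  idx <- apply(p2, 1, which.max)
  data.frame(signature = sigs[ord][idx],
             high_confidence = apply(p, 1, max) > threshold)
}

#' Assign a hotspot to a signature
#'
#' Averages the probability vectors of the hotspot's member mutations and
#' takes the argmax (lexicographic tie-break; exact ties are flagged).
#'
#' @param vectors Matrix of member probability vectors (rows = mutations).
#' @return List with `signature`, `mean_vector`, `tie`.
#' @export
assign_hotspot_signature <- function(vectors) {
  v <- as.matrix(vectors)
  if (nrow(v) == 0) stop("hotspot has no member probability vectors")
  mv <- colMeans(v)
  ord <- order(names(mv))
  mx <- max(mv)
  winner <- names(mv)[ord][which.max(mv[ord])]
  list(signature = winner, mean_vector = mv,
       tie = sum(abs(mv - mx) < 1e-12) > 1)
}

#' Active signatures per sample and per cohort
#'
#' A signature is active in a sample iff its exposure share is at least 5%
#' of the sample's mutations; active in the cohort iff sample-active in at
#' least 5% of samples.
#'
#' @param exposures k x samples exposure matrix.
#' @param totals Optional per-sample mutation totals (defaults to exposure
#'   column sums).
#' @param sample_threshold,cohort_threshold Activity thresholds
#'   (default 0.05 each, inclusive).
#' @return List with `sample_active` (k x samples logical) and
#'   `cohort_active` (named logical).
#' @export
active_signatures <- function(exposures, totals = NULL,
                              sample_threshold = 0.05,
                              cohort_threshold = 0.05) {
  E <- as.matrix(exposures)
  if (is.null(totals)) totals <- colSums(E)
  share <- sweep(E, 2, ifelse(totals > 0, totals, 1), "/")
  sample_active <- share >= sample_threshold
  cohort_active <- rowMeans(sample_active) >= cohort_threshold
  list(sample_active = sample_active, cohort_active = cohort_active)
}
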