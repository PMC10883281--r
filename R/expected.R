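# Closed-form expected hotspot counts under the theoretical scenario of a
# cohort of S samples with identical mutation rates (n mutations each) and
# independently mutating positions, at genome-wide, per-chunk and
# methylation-aware resolution; with a Monte-Carlo oracle, empirical
# methylation fold-change inference, negative-binomial overdispersion of
# binned counts, and the explained-fraction summary.

#' Relative mutation rates per chunk
#'
#' `r_k = count_k / sum_j count_j` from maximum-likelihood-attributed
#' mutation counts per bin; zero-count chunks get rate 0 (no pseudocount).
#'
#' @param mutations Mutation data frame of one signature (CHROMOSOME,
#'   POSITION), or a precomputed count vector along `bins`.
#' @param bins Bin `GRanges`.
#' @return Numeric vector of rates along `bins`, summing to 1.
#' @export
chunk_relative_rates <- function(mutations, bins) {
  counts <- if (is.numeric(mutations)) mutations else {
    gr <- GenomicRanges::GRanges(mutations$CHROMOSOME,
                                 IRanges::IRanges(mutations$POSITION,
                                                  mutations$POSITION))
    GenomicRanges::countOverlaps(bins, gr)
  }
  if (length(counts) != length(bins)) stop("count/bin length mismatch")
  tot <- sum(counts)
  if (tot == 0) stop("no attributed mutations: chunk rates undefined")
  counts / tot
}

#' Per-position single-mutation probability map
#'
#' The probability that one drawn mutation lands on a given (position,
#' alternate) pair, by position class. Genome-wide:
#' `q(c,a) = f(c>a) / N_c`. Per-chunk: `q = r_k f_k(c>a) / N_(c,k)` with
#' `f_k` renormalised over the channels whose context exists in chunk k.
#' Methylation-aware: NpCpG channels split, with
#' `q_meth = f rho / (rho N_meth + N_unmeth)` and
#' `q_unmeth = f / (rho N_meth + N_unmeth)`. In every mode the map sums to
#' 1 over all (position, alternate) pairs.
#'
#' @param cen `context_census` (stratified by bin and/or methylation as
#'   required).
#' @param f Named 96-vector of channel probabilities.
#' @param rates Optional chunk rates (named or ordered by bin id, sum 1).
#' @param meth_fold Optional methylated-CpG mutability fold rho (requires a
#'   methylation-split census).
#' @return A `weight_map` data frame: one row per (class, alternate) with
#'   columns `context`, `bin`, `meth`, `channel`, `N` (positions in the
#'   class) and `q` (per-position probability).
#' @export
position_weight_map <- function(cen, f, rates = NULL, meth_fold = NULL) {
  meta <- .channel_meta()
  ch <- sbs_channels()
  f <- f[ch]
  if (abs(sum(f) - 1) > 1e-6) stop("profile must sum to 1")
  use_meth <- !is.null(meth_fold)
  if (use_meth && !any(!is.na(cen$meth)))
    stop("meth_fold given but census is not methylation-split")
  # per-(context, bin) abundances
  cen$binkey <- ifelse(is.na(cen$bin), 0L, cen$bin)
  binkeys <- sort(unique(cen$binkey))
  if (!is.null(rates)) {
    if (length(rates) != length(binkeys))
      stop("rates length must match the number of census bins")
    if (abs(sum(rates) - 1) > 1e-9) stop("chunk rates must sum to 1")
  } else {
    if (length(binkeys) > 1)
      stop("binned census requires chunk rates")
    rates <- 1
  }
  rows <- list()
  for (bi in seq_along(binkeys)) {
    bk <- binkeys[bi]
    sub <- cen[cen$binkey == bk, , drop = FALSE]
    Nc <- tapply(sub$count, factor(sub$context, levels = sbs_contexts()),
                 sum, default = 0)
    # renormalise f over channels whose context exists in this chunk
    present <- Nc[meta$context_id] > 0
    if (length(binkeys) == 1 && any(f > 0 & !present))
      stop("context with positive channel probability absent from the genome")
    fk <- f * as.numeric(present)
    tot <- sum(fk)
    if (tot == 0) next
    fk <- fk / tot
    r_k <- rates[bi]
    for (i in which(fk > 0)) {
      ctx <- meta$context[i]
      is_cpg <- substr(ctx, 2, 3) == "CG"
      if (use_meth && is_cpg) {
        Nm <- sum(sub$count[sub$context == ctx & sub$meth %in% "meth"])
        Nu <- sum(sub$count[sub$context == ctx & sub$meth %in% "unmeth"])
        den <- meth_fold * Nm + Nu
        if (den > 0) {
          rows[[length(rows) + 1]] <- data.frame(
            context = ctx, bin = if (bk == 0) NA_integer_ else bk,
            meth = c("meth", "unmeth"), channel = meta$channel[i],
            N = c(Nm, Nu),
            q = r_k * fk[i] * c(meth_fold, 1) / den)
        }
      } else {
        N <- as.numeric(Nc[meta$context_id[i]])
        if (N > 0)
          rows[[length(rows) + 1]] <- data.frame(
            context = ctx, bin = if (bk == 0) NA_integer_ else bk,
            meth = NA_character_, channel = meta$channel[i],
            N = N, q = r_k * fk[i] / N)
      }
    }
  }
  wm <- do.call(rbind, rows)
  wm <- wm[wm$N > 0, , drop = FALSE]
  rownames(wm) <- NULL
  tot <- sum(wm$N * wm$q)
  if (abs(tot - 1) > 1e-9)
    stop("internal error: weight map mass ", tot, " != 1")
  class(wm) <- c("weight_map", "data.frame")
  wm
}

#' Expected number of hotspots under the closed-form model
#'
#' Per (position, alternate): `pi = 1 - (1-q)^n` is the probability that a
#' sample acquires that mutation; the no-hotspot probability over S
#' samples is `(1-pi)^S + S pi (1-pi)^(S-1)`. Per position, alternates are
#' combined under cross-alternate independence, and expectations summed
#' over positions (computed channel-class-wise). Matches the observed
#' counting convention of at most one hotspot per position.
#'
#' @param wm `weight_map` from [position_weight_map()].
#' @param S Cohort size (samples); `S < 2` legally yields 0.
#' @param n Mutations per sample.
#' @return List with `total` and per-class `breakdown`.
#' @export
expected_hotspots <- function(wm, S, n) {
  stopifnot(S >= 1, n >= 1)
  pi_ <- 1 - (1 - wm$q)^n
  p_no <- (1 - pi_)^S + S * pi_ * (1 - pi_)^(S - 1)
  # per position class: product over its (up to 3) alternates
  cls <- paste(wm$context, wm$bin, wm$meth, sep = "|")
  lp <- tapply(log(pmax(p_no, .Machine$double.xmin)), cls, sum)
  Ncls <- tapply(wm$N, cls, function(x) x[1])
  h <- 1 - exp(lp)
  breakdown <- data.frame(class = names(h),
                          N = as.numeric(Ncls[names(h)]),
                          h = as.numeric(h))
  breakdown$expected <- breakdown$N * breakdown$h
  list(total = sum(breakdown$expected), breakdown = breakdown)
}

#' Monte-Carlo oracle for the expected-hotspot model
#'
#' Simulates R cohorts under the generative assumptions of the closed form
#' (per sample, n distinct (position, alternate) draws without
#' replacement, proportional to the weight map), counts positions hit in
#' at least two distinct samples with equal alternate (collapsed to one
#' hotspot per position), and returns the mean count with its standard
#' error.
#'
#' @param wm `weight_map`.
#' @param S,n Cohort size and per-sample draws.
#' @param R Number of simulated cohorts.
#' @param seed Integer seed.
#' @return List with `mean`, `se`, `counts`.
#' @export
monte_carlo_expected <- function(wm, S, n, R, seed) {
  navail <- sum(wm$N)
  if (n > navail) stop("n exceeds the number of available positions")
  G <- nrow(wm)
  # class of positions: rows of wm sharing (context, bin, meth) share
  # positions; alternates of one class index the same position pool
  cls <- paste(wm$context, wm$bin, wm$meth, sep = "|")
  cls_id <- match(cls, unique(cls))
  cls_N <- wm$N[!duplicated(cls)]
  offs <- cumsum(c(0, cls_N))[cls_id]  # position-id offset of each row's class
  counts <- integer(R)
  with_seed(seed, {
    for (r in seq_len(R)) {
      if (S < 2) { counts[r] <- 0L; next }
      ev_pos <- vector("list", S); ev_row <- vector("list", S)
      for (s in seq_len(S)) {
        k <- race_group_counts(wm$N, wm$q, n)
        hit <- which(k > 0)
        pos <- unlist(lapply(hit, function(g)
          offs[g] + sample.int(wm$N[g], k[g])), use.names = FALSE)
        ev_pos[[s]] <- pos
        ev_row[[s]] <- rep(hit, k[hit])
      }
      pos <- unlist(ev_pos); row <- unlist(ev_row)
      key <- pos * (G + 1) + row  # (position, alternate) key
      dupkey <- key[duplicated(key)]
      counts[r] <- length(unique(pos[match(unique(dupkey), key)]))
    }
  })
  list(mean = mean(counts), se = stats::sd(counts) / sqrt(R), counts = counts)
}

#' Empirical methylated-CpG mutability fold-change
#'
#' Odds ratio of per-site mutation occurrence (site mutated at least once)
#' between methylated and unmethylated CpG sites, with Haldane-Anscombe
#' 0.5 correction when a cell is zero.
#'
#' @param n_meth,n_unmeth Total methylated / unmethylated CpG sites.
#' @param mut_meth,mut_unmeth Number of those sites carrying at least one
#'   mutation.
#' @return List with `rho`, the 2x2 `table`, and `corrected`.
#' @export
infer_methylation_foldchange <- function(n_meth, n_unmeth, mut_meth, mut_unmeth) {
  if (n_meth == 0 || n_unmeth == 0) stop("need CpG sites in both classes")
  a <- mut_meth; b <- n_meth - mut_meth
  c_ <- mut_unmeth; d <- n_unmeth - mut_unmeth
  corrected <- any(c(a, b, c_, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5 }
  list(rho = (a / b) / (c_ / d),
       table = matrix(c(a, b, c_, d), 2, 2,
                      dimnames = list(c("mutated", "unmutated"),
                                      c("meth", "unmeth"))),
       corrected = corrected)
}

#' CpG sites hit by a set of mutations
#'
#' Maps each mutation falling on either strand of a CpG dinucleotide to the
#' site key (1-based position of the C on the + strand) and returns the
#' distinct mutated sites. Used to build the 2x2 tables behind
#' [infer_methylation_foldchange()] and [methylation_odds_ratio()].
#'
#' @param genome Genome.
#' @param mutations Mutation data frame (CHROMOSOME, POSITION).
#' @return Data frame with `CONTIG`, `POS` (one row per mutated CpG site).
#' @export
mutated_cpg_sites <- function(genome, mutations) {
  m <- as.data.frame(mutations)
  rows <- lapply(unique(m$CHROMOSOME), function(ct) {
    s <- as.character(genome[[ct]])
    len <- nchar(s)
    p <- m$POSITION[m$CHROMOSOME == ct]
    base <- substring(s, p, p)
    nxt <- ifelse(p < len, substring(s, p + 1, p + 1), "")
    prv <- ifelse(p > 1, substring(s, p - 1, p - 1), "")
    key <- ifelse(base == "C" & nxt == "G", p,
                  ifelse(base == "G" & prv == "C", p - 1L, NA_integer_))
    key <- unique(key[!is.na(key)])
    if (length(key) == 0) return(NULL)
    data.frame(CONTIG = ct, POS = as.integer(key))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(CONTIG = character(), POS = integer()) else out
}

#' Fraction of observed hotspot propensity explained by a model
#'
#' @param observed Observed median hotspot count (> 0).
#' @param expected Expected hotspot count under the model.
#' @return Percentage (values above 100 are allowed and flagged via a
#'   warning).
#' @export
explained_fraction <- function(observed, expected) {
  if (observed == 0) stop("observed median is 0: explained fraction undefined")
  pct <- 100 * expected / observed
  if (pct > 100) warning("model expects more hotspots than observed (",
                         round(pct, 1), "%)")
  pct
}

#' Overdispersion of binned mutation counts
#'
#' Intercept-only negative-binomial (NB2) maximum likelihood on per-bin
#' counts, parameterised as `v = mu + alpha mu^2`; `alpha = 0` is Poisson.
#'
#' @param counts Non-negative integer counts per bin (>= 10 bins).
#' @param poisson_tol `alpha` below this is reported Poisson-consistent.
#' @return List with `alpha`, `se`, `mu`, `poisson_consistent`.
#' @export
fit_overdispersion <- function(counts, poisson_tol = 0.02) {
  if (length(counts) < 10) stop("need at least 10 bins")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  mu <- mean(counts)
  if (stats::var(counts) <= mu)   # at or below Poisson variance
    return(list(alpha = 0, se = NA_real_, mu = mu, poisson_consistent = TRUE))
  fit <- tryCatch(
    suppressWarnings(MASS::glm.nb(counts ~ 1)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(alpha = 0, se = NA_real_, mu = mu, poisson_consistent = TRUE))
  alpha <- 1 / fit$theta
  se <- if (!is.null(fit$SE.theta)) fit$SE.theta / fit$theta^2 else NA_real_
  list(alpha = alpha, se = se, mu = mu,
       poisson_consistent = alpha < poisson_tol)
}
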