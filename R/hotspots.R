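# Mutation QC and hotspot identification: per-mutation filters against the
# reference and the mask sets, cohort-level sample QC (duplicate pairs,
# hypermutators), and recurrence detection.

#' Classify a mutation by its ref/alt alleles
#'
#' @param ref,alt Character vectors of reference and alternate alleles over
#'   A/C/G/T.
#' @return Character vector in `SNV`, `MNV`, `INS`, `DEL`, `COMPLEX`.
#'   Insertions/deletions must share the leading anchor base; mixed
#'   length-changing events (e.g. GTG>GAAA) are `COMPLEX`.
#' @export
classify_mutation_type <- function(ref, alt) {
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt)))
    stop("ref/alt alleles must be non-empty strings over A, C, G, T")
  lr <- nchar(ref); la <- nchar(alt)
  out <- rep("COMPLEX", length(ref))
  out[lr == 1 & la == 1] <- "SNV"
  out[lr > 1 & lr == la] <- "MNV"
  ins <- la > lr & substr(alt, 1, lr) == ref
  del <- lr > la & substr(ref, 1, la) == alt
  out[ins] <- "INS"
  out[del] <- "DEL"
  out
}

#' Filter a mutation table against the reference and mask sets
#'
#' Applies, in order: unknown contig; ref == alt; reference-allele mismatch
#' with the genome; unknown base (N) within the +/-2 bp context window;
#' complex indel; outside the mappable regions; overlapping the blacklist;
#' overlapping a population-variant position; overlapping a driver region.
#' The first failing rule is the recorded removal reason.
#'
#' @param mutations Data frame with CHROMOSOME, POSITION, REF, ALT, SAMPLE.
#' @param genome Genome.
#' @param masks List with optional `GRanges` elements `mappable`,
#'   `blacklist`, `variants`, `drivers`.
#' @return List with `kept` (the surviving rows, plus a TYPE column),
#'   `removed` (rows with a REASON column) and `tally` (per-reason counts).
#' @export
filter_mutations <- function(mutations, genome, masks = list()) {
  m <- as.data.frame(mutations)
  reason <- rep(NA_character_, nrow(m))
  flag <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- code
  }

  flag(!(m$CHROMOSOME %in% names(genome)), "unknown_contig")
  flag(m$REF == m$ALT, "ref_equals_alt")

  ok <- is.na(reason)
  gref <- rep(NA_character_, nrow(m))
  ctx_has_n <- rep(FALSE, nrow(m))
  for (ct in unique(m$CHROMOSOME[ok])) {
    s <- as.character(genome[[ct]])
    len <- nchar(s)
    rows <- which(ok & m$CHROMOSOME == ct)
    p <- m$POSITION[rows]; lr <- nchar(m$REF[rows])
    inb <- p >= 1 & p + lr - 1 <= len
    gref[rows[inb]] <- substring(s, p[inb], p[inb] + lr[inb] - 1)
    # pentanucleotide context window around the start position
    a <- pmax(1, p - 2); b <- pmin(len, p + 2)
    ctx_has_n[rows] <- grepl("[^ACGT]", substring(s, a, b))
    ctx_has_n[rows[!inb]] <- TRUE
  }
  flag(is.na(gref) | gref != m$REF, "ref_mismatch")
  flag(ctx_has_n, "n_context")
  type <- rep(NA_character_, nrow(m))
  ok <- is.na(reason)
  type[ok] <- classify_mutation_type(m$REF[ok], m$ALT[ok])
  flag(!is.na(type) & type == "COMPLEX", "complex_type")

  gr <- GenomicRanges::GRanges(
    ifelse(m$CHROMOSOME %in% names(genome), m$CHROMOSOME, names(genome)[1]),
    IRanges::IRanges(pmax(1, m$POSITION),
                     pmax(1, m$POSITION + pmax(nchar(m$REF) - 1, 0))))
  in_mask <- function(mask) IRanges::overlapsAny(gr, mask)
  if (!is.null(masks$mappable)) flag(!in_mask(masks$mappable), "unmappable")
  if (!is.null(masks$blacklist)) flag(in_mask(masks$blacklist), "blacklist")
  if (!is.null(masks$variants)) flag(in_mask(masks$variants), "population_variant")
  if (!is.null(masks$drivers)) flag(in_mask(masks$drivers), "driver_region")

  kept <- m[is.na(reason), , drop = FALSE]
  kept$TYPE <- type[is.na(reason)]
  removed <- m[!is.na(reason), , drop = FALSE]
  removed$REASON <- reason[!is.na(reason)]
  tally <- table(factor(removed$REASON, levels = c(
    "unknown_contig", "ref_equals_alt", "ref_mismatch", "n_context",
    "complex_type", "unmappable", "blacklist", "population_variant",
    "driver_region")))
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed, tally = tally)
}

#' Flag sample pairs sharing an excessive fraction of mutations
#'
#' For each pair, sharing = |identical mutations| / (n1 + n2); pairs above
#' the threshold are flagged (candidates for same-donor duplicates).
#'
#' @param mutations Mutation data frame (CHROMOSOME, POSITION, REF, ALT,
#'   SAMPLE).
#' @param threshold Sharing fraction above which a pair is flagged
#'   (default 0.10, strict).
#' @return Data frame of pairs with `shared`, `n1`, `n2`, `sharing`,
#'   `flagged`.
#' @export
detect_duplicates <- function(mutations, threshold = 0.10) {
  samples <- unique(mutations$SAMPLE)
  if (length(samples) < 2) stop("need at least 2 samples")
  key <- paste(mutations$CHROMOSOME, mutations$POSITION, mutations$REF,
               mutations$ALT)
  keys <- lapply(split(key, mutations$SAMPLE), unique)
  n <- lengths(keys)
  pairs <- utils::combn(samples, 2)
  shared <- apply(pairs, 2, function(p)
    length(intersect(keys[[p[1]]], keys[[p[2]]])))
  out <- data.frame(sample1 = pairs[1, ], sample2 = pairs[2, ],
                    shared = shared,
                    n1 = as.integer(n[pairs[1, ]]),
                    n2 = as.integer(n[pairs[2, ]]))
  out$sharing <- out$shared / (out$n1 + out$n2)
  out$flagged <- out$sharing > threshold
  out
}

#' Flag hypermutated samples
#'
#' A sample is flagged iff its mutation count exceeds `abs_min` AND exceeds
#' P75 + 1.5 IQR of the cohort's per-sample counts.
#'
#' @param counts Named vector of per-sample mutation counts (or a mutation
#'   data frame, in which case counts are tabulated from SAMPLE).
#' @param abs_min Absolute count floor (default 10,000).
#' @return Data frame with `sample`, `count`, `threshold`, `flagged`.
#' @export
detect_hypermutators <- function(counts, abs_min = 10000) {
  if (is.data.frame(counts)) counts <- table(counts$SAMPLE)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  if (length(counts) < 4) stop("need at least 4 samples for quartiles")
  q <- stats::quantile(counts, c(0.25, 0.75), type = 7)
  thr <- unname(q[2] + 1.5 * (q[2] - q[1]))
  data.frame(sample = names(counts), count = unname(counts),
             threshold = thr,
             flagged = unname(counts > abs_min & counts > thr))
}

#' Identify mutational hotspots
#'
#' Groups mutations by genomic key and emits groups carried by two or more
#' distinct samples. In `alternate_specific` mode the key is
#' (contig, position, ref, alt) — e.g. two C>T transitions at the same
#' base; `position` mode relaxes the equal-alternate requirement. Mutation
#' types are never merged: each type is grouped separately.
#'
#' @param mutations Mutation data frame; a TYPE column is computed when
#'   absent. A sample contributing the same event twice counts once.
#' @param mode `"alternate_specific"` (default) or `"position"`.
#' @return Data frame with CHROMOSOME, POSITION, REF, ALT (`"*"` in
#'   position mode), MUT_TYPE, N_SAMPLES, SAMPLES (semicolon-joined,
#'   sorted), deterministically sorted by coordinate then alternate.
#' @export
find_hotspots <- function(mutations, mode = c("alternate_specific", "position")) {
  mode <- match.arg(mode)
  m <- as.data.frame(mutations)
  if (nrow(m) == 0)
    return(data.frame(CHROMOSOME = character(), POSITION = integer(),
                      REF = character(), ALT = character(),
                      MUT_TYPE = character(), N_SAMPLES = integer(),
                      SAMPLES = character()))
  if (is.null(m$TYPE)) m$TYPE <- classify_mutation_type(m$REF, m$ALT)
  # a sample contributing the same event twice counts once
  m <- m[!duplicated(m[, c("CHROMOSOME", "POSITION", "REF", "ALT", "SAMPLE")]), ]
  key <- if (mode == "alternate_specific")
    paste(m$TYPE, m$CHROMOSOME, m$POSITION, m$REF, m$ALT, sep = "\r")
  else
    paste(m$TYPE, m$CHROMOSOME, m$POSITION, sep = "\r")
  # within a group each sample counts once
  dd <- !duplicated(paste(key, m$SAMPLE, sep = "\r"))
  m <- m[dd, ]; key <- key[dd]
  spl <- split(seq_len(nrow(m)), key)
  sizes <- lengths(spl)
  hot <- spl[sizes >= 2]
  if (length(hot) == 0)
    return(find_hotspots(m[0, ], mode))
  rows <- vapply(hot, `[`, integer(1), 1)
  out <- data.frame(
    CHROMOSOME = m$CHROMOSOME[rows],
    POSITION = m$POSITION[rows],
    REF = vapply(hot, function(i) min(m$REF[i]), character(1)),
    ALT = if (mode == "position") "*" else m$ALT[rows],
    MUT_TYPE = m$TYPE[rows],
    N_SAMPLES = as.integer(sizes[sizes >= 2]),
    SAMPLES = vapply(hot, function(i)
      paste(sort(m$SAMPLE[i]), collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  ord <- order(out$CHROMOSOME, out$POSITION, out$ALT, out$MUT_TYPE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# TSV I/O (header required: CHROMOSOME, POSITION, REF, ALT, SAMPLE)

#' Read a mutation table
#'
#' @param path TSV with header columns CHROMOSOME, POSITION, REF, ALT,
#'   SAMPLE (extra columns preserved).
#' @return Data frame.
#' @export
read_mutations <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("CHROMOSOME", "POSITION", "REF", "ALT", "SAMPLE")
  if (!all(need %in% names(m)))
    stop("mutation table must have header columns ",
         paste(need, collapse = ", "))
  m$POSITION <- as.integer(m$POSITION)
  m
}

#' Write a mutation or hotspot table as TSV
#'
#' @param x Data frame.
#' @param path Output file.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
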