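# Reference sequence handling: FASTA-backed genomes, pyrimidine-collapsed
# trinucleotide contexts, and the position index / context census that the
# expected-hotspot models and the cohort simulator are built on.

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @param contig_class Optional named character vector classifying contigs
#'   (`"autosome"` or `"other"`); unclassified contigs default to
#'   `"autosome"`. Stored as metadata and consulted by
#'   [select_mappable_bins()].
#' @return A [Biostrings::DNAStringSet] with per-contig class metadata.
#' @export
read_genome <- function(path, contig_class = NULL) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  as_genome(g, contig_class)
}

#' Coerce sequences to the genome container used by the package
#'
#' @param x Named character vector or `DNAStringSet` (contig name -> sequence).
#' @param contig_class Optional named classification, see [read_genome()].
#' @return `DNAStringSet` with `contig_class` metadata.
#' @export
as_genome <- function(x, contig_class = NULL) {
  g <- if (methods::is(x, "DNAStringSet")) x else Biostrings::DNAStringSet(x)
  if (is.null(names(g)) || anyDuplicated(names(g)))
    stop("genome contigs must have unique names")
  if (any(Biostrings::width(g) == 0)) stop("genome contigs must be non-empty")
  cls <- stats::setNames(rep("autosome", length(g)), names(g))
  if (!is.null(contig_class)) cls[names(contig_class)] <- contig_class
  S4Vectors::metadata(g)$contig_class <- cls
  g
}

contig_classes <- function(genome) {
  cls <- S4Vectors::metadata(genome)$contig_class
  if (is.null(cls)) cls <- stats::setNames(rep("autosome", length(genome)), names(genome))
  cls
}

#' Pyrimidine-collapsed trinucleotide context at a position
#'
#' Returns the 3-mer centred at a 1-based position, reverse-complemented when
#' the central base is a purine so the centre is always C or T. `NA` when the
#' window leaves the contig or contains an unknown base.
#'
#' @param genome Genome (see [as_genome()]).
#' @param contig Contig name.
#' @param pos1 1-based position(s) within the contig.
#' @return Character vector of pyrimidine-centred triplets (or `NA`).
#' @export
pyrimidine_context <- function(genome, contig, pos1) {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  len <- length(genome[[contig]])
  if (any(pos1 < 1 | pos1 > len)) stop("position out of contig bounds")
  b <- .base_codes(as.character(genome[[contig]]))
  out <- rep(NA_character_, length(pos1))
  ok <- pos1 >= 2 & pos1 <= len - 1
  if (any(ok)) {
    p <- pos1[ok]
    code <- 16L * (b[p - 1] - 1L) + 4L * (b[p] - 1L) + (b[p + 1] - 1L) + 1L
    ctx <- rep(NA_character_, length(p))
    valid <- !is.na(code)
    ctx[valid] <- sbs_contexts()[.triplet64()$context_id[code[valid]]]
    out[ok] <- ctx
  }
  out
}

# ---------------------------------------------------------------------------
# Position index: one row per scored genomic position with its collapsed
# context, bin membership, CpG methylation class and feature membership.
# This is the workhorse table behind census(), the weight maps and the
# cohort simulator.

# methylation: data.frame(CONTIG, POS, FRACTION) keyed by the 1-based C of a
# CpG on the + strand. Returns data.frame(contig, pos, context_id, strand
# flipped flag, bin, meth, feat).
position_index <- function(genome, regions = NULL, bins = NULL,
                           methylation = NULL, features = NULL) {
  ctx32 <- sbs_contexts()
  res <- vector("list", length(genome))
  for (i in seq_along(genome)) {
    contig <- names(genome)[i]
    s <- as.character(genome[[i]])
    len <- nchar(s)
    if (len < 3) { res[[i]] <- NULL; next }
    b <- .base_codes(s)
    p <- 2:(len - 1)
    code <- 16L * (b[p - 1] - 1L) + 4L * (b[p] - 1L) + (b[p + 1] - 1L) + 1L
    keep <- !is.na(code)
    p <- p[keep]; code <- code[keep]
    df <- data.frame(contig = rep(contig, length(p)), pos = p,
                     context_id = .triplet64()$context_id[code],
                     flipped = .triplet64()$flipped[code],
                     stringsAsFactors = FALSE)
    # CpG key: centre C followed by G -> key pos; centre G preceded by C -> key pos-1
    is_cg_c <- b[df$pos] == 2L & b[df$pos + 1] == 3L
    is_cg_g <- b[df$pos] == 3L & b[df$pos - 1] == 2L
    df$cpg_key <- ifelse(is_cg_c, df$pos, ifelse(is_cg_g, df$pos - 1L, NA_integer_))
    res[[i]] <- df
  }
  idx <- do.call(rbind, res)
  if (is.null(idx))
    idx <- data.frame(contig = character(), pos = integer(),
                      context_id = integer(), flipped = logical(),
                      cpg_key = integer())
  # universe of candidate positions: every position of `regions` (or of the
  # whole genome); skipped = universe size minus scored positions
  if (!is.null(regions)) {
    universe <- sum(GenomicRanges::width(GenomicRanges::reduce(regions)))
    gr <- GenomicRanges::GRanges(idx$contig, IRanges::IRanges(idx$pos, idx$pos))
    inside <- IRanges::overlapsAny(gr, regions)
    idx <- idx[inside, , drop = FALSE]
  } else {
    universe <- sum(Biostrings::width(genome))
  }
  idx$bin <- rep(NA_integer_, nrow(idx))
  if (!is.null(bins)) {
    gr <- GenomicRanges::GRanges(idx$contig, IRanges::IRanges(idx$pos, idx$pos))
    hit <- GenomicRanges::findOverlaps(gr, bins, select = "first")
    idx$bin <- as.integer(hit)
  }
  idx$meth <- rep(NA, nrow(idx))
  if (!is.null(methylation)) {
    key <- paste(idx$contig, idx$cpg_key)
    mk <- paste(methylation$CONTIG, methylation$POS)
    frac <- methylation$FRACTION[match(key, mk)]
    idx$meth <- ifelse(is.na(idx$cpg_key), NA,
                       !is.na(frac) & frac > 0.5)
  }
  idx$feat <- rep(FALSE, nrow(idx))
  if (!is.null(features) && length(features) > 0) {
    gr <- GenomicRanges::GRanges(idx$contig, IRanges::IRanges(idx$pos, idx$pos))
    idx$feat <- IRanges::overlapsAny(gr, features)
  }
  attr(idx, "skipped") <- universe - nrow(idx)
  rownames(idx) <- NULL
  idx
}

#' Census of pyrimidine-collapsed trinucleotides
#'
#' Counts the collapsed trinucleotide of every scored position, optionally
#' stratified by genomic bin and (for NpCpG contexts) by the methylation
#' class of the underlying CpG site. Positions whose +/-1 bp window leaves
#' the contig or contains an unknown base are skipped and tallied.
#'
#' @param genome Genome.
#' @param regions Optional `GRanges` restricting the scored positions
#'   (e.g. the mappable genome); `NULL` scores every position.
#' @param bins Optional bin `GRanges` (see [make_bins()]) for per-bin counts.
#' @param methylation Optional methylation table
#'   (`CONTIG`, `POS`, `FRACTION`; `POS` = 1-based C of the CpG). CpG sites
#'   with fraction > 0.5 are classed methylated; NpCpG positions are then
#'   counted separately per class.
#' @return A `context_census` data frame with columns `context`, `bin`,
#'   `meth` (`NA` where unstratified) and `count`; the number of skipped
#'   positions is in `attr(, "skipped")`.
#' @export
census <- function(genome, regions = NULL, bins = NULL, methylation = NULL) {
  idx <- position_index(genome, regions = regions, bins = bins,
                        methylation = methylation)
  ctx32 <- sbs_contexts()
  grp <- list(context = factor(ctx32[idx$context_id], levels = ctx32))
  if (!is.null(bins)) grp$bin <- factor(idx$bin, levels = seq_along(bins))
  if (!is.null(methylation)) {
    meth <- ifelse(is.na(idx$meth), "none", ifelse(idx$meth, "meth", "unmeth"))
    grp$meth <- factor(meth, levels = c("none", "meth", "unmeth"))
  }
  tab <- as.data.frame(table(grp), stringsAsFactors = FALSE)
  names(tab)[names(tab) == "Freq"] <- "count"
  if (!is.null(bins)) tab$bin <- as.integer(tab$bin) else tab$bin <- NA_integer_
  if (!is.null(methylation)) {
    # meth split applies only to NpCpG contexts; other contexts keep meth = NA
    is_cpg_ctx <- substr(tab$context, 2, 3) == "CG"
    tab <- tab[(is_cpg_ctx & tab$meth != "none") |
               (!is_cpg_ctx & tab$meth == "none"), , drop = FALSE]
    tab$meth[tab$meth == "none"] <- NA_character_
  } else tab$meth <- NA_character_
  tab <- tab[, c("context", "bin", "meth", "count")]
  rownames(tab) <- NULL
  attr(tab, "skipped") <- attr(idx, "skipped")
  class(tab) <- c("context_census", "data.frame")
  tab
}

#' Collapse a census over bins and/or methylation strata
#'
#' @param cen A `context_census`.
#' @param by One of `"context"` (fully collapsed), `"context_bin"` or
#'   `"context_meth"`.
#' @return Aggregated `context_census`.
#' @export
collapse_census <- function(cen, by = c("context", "context_bin", "context_meth")) {
  by <- match.arg(by)
  keys <- switch(by,
    context = list(context = cen$context),
    context_bin = list(context = cen$context, bin = cen$bin),
    context_meth = list(context = cen$context, meth = cen$meth))
  agg <- stats::aggregate(list(count = cen$count), by = lapply(keys, function(k) {
    k[is.na(k)] <- if (is.numeric(k)) -1L else "NA"; k
  }), FUN = sum)
  if (is.null(agg$bin)) agg$bin <- NA_integer_ else agg$bin[agg$bin == -1L] <- NA_integer_
  if (is.null(agg$meth)) agg$meth <- NA_character_ else agg$meth[agg$meth == "NA"] <- NA_character_
  agg <- agg[, c("context", "bin", "meth", "count")]
  class(agg) <- c("context_census", "data.frame")
  agg
}

# named 32-vector of context counts (fully collapsed)
census_vector <- function(cen) {
  v <- stats::setNames(numeric(32), sbs_contexts())
  agg <- tapply(cen$count, factor(cen$context, levels = sbs_contexts()), sum,
                default = 0)
  v[names(agg)] <- agg
  v
}
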