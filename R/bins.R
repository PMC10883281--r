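# Genomic bin system: fixed-width tiling of contigs, mappability-based bin
# selection, and sub-bin partitioning down to 10 Kbp. Bins are GRanges with
# `bin_id`, `parent_id` and `partial` metadata columns.

#' Tile contigs into consecutive non-overlapping bins
#'
#' @param genome Genome, or a named numeric vector of contig lengths.
#' @param width Bin width in bp (e.g. `1e6`).
#' @return `GRanges` of bins; a shorter trailing bin per contig is emitted
#'   with `partial = TRUE`.
#' @export
make_bins <- function(genome, width) {
  stopifnot(width > 0)
  lens <- if (is.numeric(genome)) genome else
    stats::setNames(Biostrings::width(genome), names(genome))
  if (is.null(names(lens))) stop("contig lengths must be named")
  pieces <- lapply(names(lens), function(ct) {
    len <- lens[[ct]]
    starts <- seq(1, len, by = width)
    ends <- pmin(starts + width - 1, len)
    data.frame(ct = ct, start = starts, end = ends)
  })
  tab <- do.call(rbind, pieces)
  bins <- GenomicRanges::GRanges(tab$ct, IRanges::IRanges(tab$start, tab$end),
                                 partial = (tab$end - tab$start + 1) < width)
  bins$bin_id <- seq_along(bins)
  bins$parent_id <- bins$bin_id
  bins$width_class <- width
  bins
}

#' Select high-mappability bins
#'
#' Computes each bin's fractional overlap with the mappable region set and
#' keeps bins whose fraction lies strictly above the first quartile
#' (linear-interpolation quantile) of the distribution across candidate
#' bins. Partial trailing bins and bins on non-autosomal contigs are
#' excluded from candidacy.
#'
#' @param bins `GRanges` from [make_bins()].
#' @param mappable `GRanges` of mappable sequence.
#' @param contig_class Optional named vector (`"autosome"`/`"other"`);
#'   unnamed contigs are treated as autosomal.
#' @param include_partial Keep trailing short bins as candidates
#'   (default `FALSE`).
#' @return Subset of `bins` with a `mappable_fraction` column; the quartile
#'   used is stored in `attr(, "q1")`.
#' @export
select_mappable_bins <- function(bins, mappable, contig_class = NULL,
                                 include_partial = FALSE) {
  cls <- rep("autosome", length(bins))
  if (!is.null(contig_class)) {
    m <- match(as.character(GenomicRanges::seqnames(bins)), names(contig_class))
    cls[!is.na(m)] <- contig_class[m[!is.na(m)]]
  }
  cand <- cls == "autosome"
  if (!include_partial) cand <- cand & !bins$partial
  cand_bins <- bins[cand]
  if (length(cand_bins) < 4)
    stop("fewer than 4 candidate bins: first quartile undefined")
  ov <- GenomicRanges::reduce(mappable)
  hits <- GenomicRanges::findOverlaps(cand_bins, ov)
  ovw <- numeric(length(cand_bins))
  if (length(hits) > 0) {
    w <- GenomicRanges::width(GenomicRanges::pintersect(
      cand_bins[S4Vectors::queryHits(hits)], ov[S4Vectors::subjectHits(hits)]))
    ovw <- as.numeric(tapply(w, factor(S4Vectors::queryHits(hits),
                                       levels = seq_along(cand_bins)),
                             sum, default = 0))
  }
  frac <- ovw / GenomicRanges::width(cand_bins)
  q1 <- unname(stats::quantile(frac, 0.25, type = 7))
  keep <- frac > q1
  if (!any(keep))
    warning("no bin strictly exceeds the first quartile of mappable fraction")
  out <- cand_bins[keep]
  out$mappable_fraction <- frac[keep]
  attr(out, "q1") <- q1
  out
}

#' Partition bins into consecutive sub-bins
#'
#' @param bins Parent bins (`GRanges`; typically selected 1 Mbp bins).
#' @param width Target sub-bin width; must divide every parent width.
#' @return `GRanges` of sub-bins; `parent_id` carries the parent's `bin_id`.
#' @export
partition_bins <- function(bins, width) {
  pw <- GenomicRanges::width(bins)
  if (any(pw %% width != 0))
    stop("target width ", width, " does not divide all parent bin widths")
  k <- pw %/% width
  starts <- rep(GenomicRanges::start(bins), k) +
    width * (sequence(k) - 1)
  out <- GenomicRanges::GRanges(
    rep(GenomicRanges::seqnames(bins), k),
    IRanges::IRanges(starts, starts + width - 1),
    partial = FALSE,
    bin_id = NA_integer_,
    parent_id = rep(bins$bin_id, k),
    width_class = width)
  out$bin_id <- seq_along(out)
  out
}

# ---------------------------------------------------------------------------
# Region/BED I/O. BED files are 0-based half-open; rtracklayer converts to
# the 1-based closed GRanges used internally.

#' Read a BED file as a region set
#'
#' @param path BED file (first 3+ columns used).
#' @param canonical Sort and merge per contig (default `TRUE`).
#' @return `GRanges`.
#' @export
read_bed <- function(path, canonical = TRUE) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                               GenomicRanges::ranges(gr),
                               name = if (!is.null(gr$name)) gr$name else NA)
  if (canonical) GenomicRanges::reduce(GenomicRanges::sort(gr)) else gr
}

#' Write regions or bins to BED
#'
#' Bins are written with their parent-bin id in the BED name column.
#'
#' @param gr `GRanges`.
#' @param path Output file.
#' @export
write_bed <- function(gr, path) {
  nm <- if (!is.null(gr$parent_id)) paste0("parent_", gr$parent_id)
        else if (!is.null(gr$name)) gr$name else "."
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
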