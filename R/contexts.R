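# Trinucleotide-context bookkeeping shared by every module: the 96 SBS
# channels (pyrimidine-centred "X[R>A]Y"), the 32 pyrimidine-collapsed
# triplets, and fast integer encodings of both.

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a nucleotide string
#'
#' Plain-character helper used throughout for strand collapsing of short
#' contexts; sequences containing characters outside A/C/G/T error.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- vapply(strsplit(x, ""), function(ch) {
    cc <- COMPLEMENT[ch]
    if (anyNA(cc)) stop("non-ACGT character in sequence: ", paste(ch, collapse = ""))
    paste(rev(unname(cc)), collapse = "")
  }, character(1))
  out
}

#' The 32 pyrimidine-centred trinucleotides
#'
#' Ordered with centre C before centre T, 5' flank fastest within centre,
#' matching the COSMIC channel layout.
#'
#' @return Character vector of length 32, e.g. `"ACA"`.
#' @export
sbs_contexts <- function() {
  unlist(lapply(c("C", "T"), function(ctr)
    as.vector(t(outer(BASES, BASES, function(a, b) paste0(a, ctr, b))))))
}

#' The 96 single-base-substitution channels
#'
#' COSMIC-style labels `"A[C>A]A"`: six pyrimidine substitutions
#' (C>A, C>G, C>T, T>A, T>C, T>G), 16 flank contexts each.
#'
#' @return Character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  unlist(lapply(subs, function(s) {
    ctr <- substr(s, 1, 1)
    as.vector(t(outer(BASES, BASES, function(a, b)
      paste0(a, "[", s, "]", b))))
  }))
}

# channel index (1..96) -> context index (1..32) and alternate base
.channel_meta <- local({
  ch <- NULL
  function() {
    if (is.null(ch)) {
      labs <- sbs_channels()
      ref <- substr(labs, 3, 3)
      alt <- substr(labs, 5, 5)
      ctx <- paste0(substr(labs, 1, 1), ref, substr(labs, 7, 7))
      ch <<- data.frame(channel = labs, context = ctx, ref = ref, alt = alt,
                        context_id = match(ctx, sbs_contexts()),
                        stringsAsFactors = FALSE)
    }
    ch
  }
})

#' Map a (pyrimidine context, alternate) pair to its SBS channel label
#'
#' @param context Pyrimidine-centred trinucleotide (e.g. `"ACA"`).
#' @param alt Alternate base on the pyrimidine strand.
#' @return Channel label, e.g. `"A[C>T]A"`.
#' @export
sbs_channel_of <- function(context, alt) {
  lab <- paste0(substr(context, 1, 1), "[", substr(context, 2, 2), ">",
                alt, "]", substr(context, 3, 3))
  bad <- !(lab %in% sbs_channels())
  if (any(bad)) stop("invalid (context, alt) pair: ", lab[bad][1])
  lab
}

# Integer base codes: A=1 C=2 G=3 T=4, NA otherwise. Input a character
# string; returns an integer vector along the sequence.
.base_codes <- function(seq) {
  r <- as.integer(charToRaw(seq))
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A") + 1L] <- 1L; lut[utf8ToInt("a") + 1L] <- 1L
  lut[utf8ToInt("C") + 1L] <- 2L; lut[utf8ToInt("c") + 1L] <- 2L
  lut[utf8ToInt("G") + 1L] <- 3L; lut[utf8ToInt("g") + 1L] <- 3L
  lut[utf8ToInt("T") + 1L] <- 4L; lut[utf8ToInt("t") + 1L] <- 4L
  lut[r + 1L]
}

# 64 raw triplet codes (16*(b1-1) + 4*(b2-1) + b3) -> pyrimidine context id
# (1..32) plus a flag for whether the triplet was purine-centred (collapsed
# by reverse complement).
.triplet64 <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      ctx32 <- sbs_contexts()
      g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                       stringsAsFactors = FALSE)[, 3:1]
      trip <- paste0(g$b1, g$b2, g$b3)
      pyr <- g$b2 %in% c("C", "T")
      collapsed <- ifelse(pyr, trip, revcomp(trip))
      tab <<- data.frame(code = seq_len(64), triplet = trip,
                         context_id = match(collapsed, ctx32),
                         flipped = !pyr, stringsAsFactors = FALSE)
    }
    tab
  }
})
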