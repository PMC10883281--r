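# Shared fixtures: all built in code, no files.

# context census from a named (or unnamed, recycled) count vector
mk_census <- function(counts = 100L, bins = NULL, meth_counts = NULL) {
  ctx <- hotspotprop::sbs_contexts()
  if (is.null(bins)) {
    cen <- data.frame(context = ctx, bin = NA_integer_,
                      meth = NA_character_,
                      count = as.integer(rep_len(counts, 32)))
  } else {
    cen <- do.call(rbind, lapply(seq_len(bins), function(b)
      data.frame(context = ctx, bin = b, meth = NA_character_,
                 count = as.integer(rep_len(counts, 32)))))
  }
  if (!is.null(meth_counts)) {
    # split NpCpG rows into meth/unmeth with the given proportions
    ncg <- substr(cen$context, 2, 3) == "CG"
    split_rows <- do.call(rbind, lapply(which(ncg), function(i) {
      tot <- cen$count[i]
      nm <- round(tot * meth_counts)
      data.frame(context = cen$context[i], bin = cen$bin[i],
                 meth = c("meth", "unmeth"), count = c(nm, tot - nm))
    }))
    cen <- rbind(cen[!ncg, ], split_rows)
  }
  class(cen) <- c("context_census", "data.frame")
  cen
}

# random ACGT genome of length L
mk_genome <- function(L, seed = 1, name = "chrT") {
  hotspotprop:::with_seed(seed, {
    s <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    hotspotprop::as_genome(stats::setNames(s, name))
  })
}

# quick mutation table constructor
mk_mut <- function(chrom, pos, ref, alt, sample) {
  data.frame(CHROMOSOME = chrom, POSITION = as.integer(pos), REF = ref,
             ALT = alt, SAMPLE = sample, stringsAsFactors = FALSE)
}
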