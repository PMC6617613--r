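# Fixtures are generated in code; seeds are fixed for reproducibility.

rand_genome <- function(n, seed, gc = 0.5, name = "chr1") {
  set.seed(seed)
  setNames(random_sequence(n, gc), name)
}

# genome with `n` exact copies of `unit` separated by NN spacers: with m = 0
# the mismatch neighborhood of each copy is the copy set itself
ncopy_genome <- function(unit, n) {
  c(chr1 = paste(rep(unit, n), collapse = "NN"))
}

# unique background with a period-d tandem array in the middle
tandem_genome <- function(seed, unit_len = 10, n_units = 40, flank = 500) {
  set.seed(seed)
  unit <- random_sequence(unit_len)
  c(chr1 = paste0(random_sequence(flank),
                  paste(rep(unit, n_units), collapse = ""),
                  random_sequence(flank)))
}

# build a mappability_track directly from score vectors (for aggregation tests)
make_track <- function(scores, params = NULL) {
  structure(list(scores = scores, params = params),
            class = "mappability_track")
}

# pure-R brute-force single-end placements, independent of the C++ engine
brute_se_placements <- function(read, genome, m) {
  r <- nchar(read)
  rc <- revcomp(read)
  hits <- list()
  for (chrom in names(genome)) {
    s <- genome[[chrom]]
    chars <- strsplit(s, "")[[1]]
    rch <- strsplit(read, "")[[1]]
    cch <- strsplit(rc, "")[[1]]
    for (q in 0:(nchar(s) - r)) {
      win <- chars[(q + 1):(q + r)]
      if (any(win == "N")) next
      if (sum(win != rch) <= m)
        hits[[length(hits) + 1]] <- data.frame(chrom = chrom, pos = q,
                                               strand = "+")
      if (sum(win != cch) <= m)
        hits[[length(hits) + 1]] <- data.frame(chrom = chrom, pos = q,
                                               strand = "-")
    }
  }
  if (length(hits) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character()))
  do.call(rbind, hits)
}

sort_placements <- function(df) {
  df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}
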