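# R surface of the scoring engine: k-mer counting, exhaustive single-end and
# paired-end alignment, per-position mappability tracks, and the naive oracle.

#' Count exact k-mer placements genome-wide
#'
#' For every k-mer present in the genome on either strand, counts the number
#' of exact (position, strand) placements: forward occurrences plus positions
#' where the reverse complement matches.  Windows containing N are skipped.
#' The table is therefore closed under reverse complement, and palindromic
#' k-mers count each position twice (once per strand).
#'
#' @param genome named character vector of chromosome sequences.
#' @param k k-mer length.
#' @return A named numeric vector of counts with attribute `k`, class
#'   `kmer_counts`.
#' @examples
#' count_kmers(c(chr1 = "ACGTACGT"), 4)["ACGT"]  # 4: palindromic, 2 per strand
#' @export
count_kmers <- function(genome, k) {
  genome <- validate_genome(genome)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  res <- cpp_count_kmers(unname(genome), k)
  out <- setNames(res$count, res$kmer)
  attr(out, "k") <- k
  class(out) <- "kmer_counts"
  out
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat(sprintf("kmer_counts: %d distinct %d-mers, %g total placements\n",
              length(x), attr(x, "k"), sum(unclass(x))))
  invisible(x)
}

#' Extract the simulated read pair originating at a position
#'
#' The fragment is the `fragment_length` window starting at `pos`; read 1 is
#' its first `read_length` bases, read 2 the reverse complement of its last
#' `read_length` bases (forward-reverse library), and the interior gap is
#' discarded.
#'
#' @param genome genome.
#' @param chrom chromosome name.
#' @param pos 0-based fragment start.
#' @param params paired-end [map_params()].
#' @return `list(read1, read2)`, or `NULL` when the fragment window runs off
#'   the chromosome or contains N (the position is undefined, not an error).
#' @export
extract_pair <- function(genome, chrom, pos, params) {
  genome <- validate_genome(genome)
  stopifnot(inherits(params, "map_params"), params$mode == "paired")
  seq <- genome[[chrom]]
  L <- params$fragment_length
  r <- params$read_length
  if (pos < 0L || pos + L > nchar(seq)) return(NULL)
  frag <- substr(seq, pos + 1L, pos + L)
  if (grepl("N", frag, fixed = TRUE)) return(NULL)
  list(read1 = substr(frag, 1L, r),
       read2 = revcomp(substr(frag, L - r + 1L, L)))
}

#' Exhaustive single-end alignment
#'
#' Returns every placement (position, strand) where the read matches the
#' genome with at most `mismatches` mismatches (gapless Hamming distance,
#' both strands).  Target windows containing N never match.
#'
#' @param read read sequence (ACGT only).
#' @param genome genome.
#' @param mismatches maximum mismatches.
#' @return `data.frame(chrom, pos, strand)`, one row per placement.
#' @export
align_all_se <- function(read, genome, mismatches = 3L) {
  genome <- validate_genome(genome)
  df <- cpp_align_se(read, unname(genome), as.integer(mismatches))
  data.frame(chrom = names(genome)[df$chrom_idx + 1L], pos = df$pos,
             strand = df$strand, stringsAsFactors = FALSE)
}

#' Exhaustive paired-end alignment
#'
#' Returns every forward-reverse placement of the pair: both mates within the
#' per-read mismatch allowance, leftmost read first, and implied fragment
#' length within `[insert_min, insert_max]`.  Placements differing only in
#' fragment length are distinct.
#'
#' @param read1,read2 mate sequences as produced by [extract_pair()].
#' @param genome genome.
#' @param params paired-end [map_params()].
#' @return `data.frame(chrom, s1, s2, fragment_len, strand)` with `s1` the
#'   leftmost read start and `s2` the mate start.
#' @export
align_all_pe <- function(read1, read2, genome, params) {
  genome <- validate_genome(genome)
  stopifnot(inherits(params, "map_params"), params$mode == "paired")
  df <- cpp_align_pe(read1, read2, unname(genome), params$mismatches,
                     params$insert_min, params$insert_max)
  data.frame(chrom = names(genome)[df$chrom_idx + 1L], s1 = df$s1,
             s2 = df$s2, fragment_len = df$fragment_len, strand = df$strand,
             stringsAsFactors = FALSE)
}

#' Compute a mappability track
#'
#' For every position p the score is the reciprocal of the number of mappings
#' of the read (or read pair) originating at p, attributed to the forward
#' start coordinate:
#'
#' * method 1 sums the exact occurrence counts of all distinct library
#'   k-mers (fragments, in paired mode) that align at p in forward
#'   orientation;
#' * method 2 counts all placements of the focal read or pair itself.
#'
#' The two methods are exactly equivalent for single-end libraries; for
#' paired-end libraries they agree at most positions but can differ.
#' Positions whose read/fragment window runs off the chromosome or contains N
#' are undefined (NA).
#'
#' @param genome genome.
#' @param params [map_params()].
#' @param counts optional [count_kmers()] table (k = read length for
#'   single-end, k = fragment length for paired-end); computed on the fly
#'   when `NULL`.  Only used by method 1.
#' @return A `mappability_track`: per-chromosome numeric vectors of scores in
#'   (0, 1] with NA for undefined positions, plus the parameters used.
#' @examples
#' g <- c(chr1 = "ACGTTTACCGGTTAACGGT")
#' mappability_track(g, map_params(5, mismatches = 0))
#' @export
mappability_track <- function(genome, params, counts = NULL) {
  genome <- validate_genome(genome)
  stopifnot(inherits(params, "map_params"))
  k <- if (params$mode == "single") params$read_length else params$fragment_length
  if (params$method == 1L) {
    if (is.null(counts)) {
      counts <- count_kmers(genome, k)
    } else {
      if (!inherits(counts, "kmer_counts")) stop("counts must be a kmer_counts table")
      if (!identical(as.integer(attr(counts, "k")), as.integer(k)))
        stop(sprintf("counts table k (%d) does not match params (expected %d)",
                     attr(counts, "k"), k))
    }
    kn <- names(counts)
    kv <- as.numeric(counts)
  } else {
    kn <- character()
    kv <- numeric()
  }
  scores <- if (params$mode == "single") {
    cpp_track_se(unname(genome), params$read_length, params$mismatches,
                 params$method, kn, kv)
  } else {
    cpp_track_pe(unname(genome), params$read_length, params$fragment_length,
                 params$mismatches, params$insert_min, params$insert_max,
                 params$method, kn, kv)
  }
  names(scores) <- names(genome)
  new_mappability_track(scores, params)
}

#' Naive per-position mappability oracle
#'
#' Recomputes the score of a single position by a direct full scan over all
#' (position, strand) windows -- and, in paired mode, all mate placements and
#' insert sizes -- with no index or shortcut.  Intended for verification; it
#' is the arbiter for [mappability_track()] in the test suite.
#'
#' @param genome genome.
#' @param chrom chromosome name.
#' @param pos 0-based position.
#' @param params [map_params()].
#' @return The score, or NA if the position is undefined.
#' @export
oracle_score <- function(genome, chrom, pos, params) {
  genome <- validate_genome(genome)
  stopifnot(inherits(params, "map_params"))
  ci <- match(chrom, names(genome))
  if (is.na(ci)) stop("unknown chromosome: ", chrom)
  if (params$mode == "single") {
    cpp_oracle_se(unname(genome), ci - 1L, as.integer(pos),
                  params$read_length, params$mismatches, params$method)
  } else {
    cpp_oracle_pe(unname(genome), ci - 1L, as.integer(pos),
                  params$read_length, params$fragment_length,
                  params$mismatches, params$insert_min, params$insert_max,
                  params$method)
  }
}
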