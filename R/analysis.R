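# Statistical comparisons and consensus-coordinate analysis.

#' Two-sided permutation test for a difference of group means
#'
#' The statistic is `mean(a) - mean(b)`.  Labels are shuffled over the pooled
#' values preserving group sizes.  In sampled mode the two-sided p-value uses
#' the add-one rule `p = (1 + #{|perm| >= |obs|}) / (n_perm + 1)`, so the
#' smallest attainable p is `1/(n_perm + 1)` and p can never be 0.  When the
#' number of distinct label splits `choose(n, |a|)` is small (at most
#' `max_splits`), all splits are enumerated instead and the p-value is exact:
#' the proportion of splits (including the observed one) whose absolute
#' statistic reaches `|obs|`.
#'
#' @param a,b numeric vectors of group values (e.g. per-locus percent-unique
#'   scores).
#' @param n_perm number of random permutations in sampled mode.
#' @param seed optional seed for reproducibility (sampled mode); the global
#'   RNG state is restored afterwards.
#' @param exhaustive `"auto"` (enumerate when feasible), `"never"` or
#'   `"always"`.
#' @param max_splits feasibility cap on `choose(n, |a|)` for `"auto"`.
#' @return A `perm_test` object: `obs_diff`, `p_value`, `n_perm` (permutations
#'   or splits used), `method`, `seed`.
#' @examples
#' permutation_test(c(10, 12, 14), c(30, 31, 29))  # exhaustive, 20 splits
#' @export
permutation_test <- function(a, b, n_perm = 9999L, seed = NULL,
                             exhaustive = c("auto", "never", "always"),
                             max_splits = 20000) {
  exhaustive <- match.arg(exhaustive)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 1L || length(b) < 1L) stop("both groups must be non-empty")
  if (anyNA(a) || anyNA(b)) stop("NA values in input")
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  eps <- 1e-9 * (1 + abs(obs))  # guard against floating-point ties

  nsplit <- choose(n, na)
  do_exact <- switch(exhaustive,
                     always = TRUE,
                     never = FALSE,
                     auto = nsplit <= max_splits)
  if (do_exact) {
    idx <- combn(n, na)
    tot <- sum(pool)
    stats <- apply(idx, 2L, function(i) {
      sa <- sum(pool[i])
      sa / na - (tot - sa) / (n - na)
    })
    hits <- sum(abs(stats) >= abs(obs) - eps)
    p <- hits / ncol(idx)
    res <- list(obs_diff = obs, p_value = p, n_perm = ncol(idx),
                method = "exhaustive", seed = seed)
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    tot <- sum(pool)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      sa <- sum(pool[sample.int(n, na)])
      stat <- sa / na - (tot - sa) / (n - na)
      if (abs(stat) >= abs(obs) - eps) hits <- hits + 1L
    }
    p <- (1 + hits) / (n_perm + 1)
    res <- list(obs_diff = obs, p_value = p, n_perm = as.integer(n_perm),
                method = "sampled", seed = seed)
  }
  structure(res, class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Two-sided permutation test (%s, %d %s)\n", x$method, x$n_perm,
              if (x$method == "exhaustive") "splits" else "permutations"))
  cat(sprintf("  observed mean difference: %.6g\n  p-value: %.6g\n",
              x$obs_diff, x$p_value))
  invisible(x)
}

#' Align a locus sequence to a subfamily consensus
#'
#' Semi-global alignment: the locus is aligned end-to-end while consensus
#' overhangs at either end are free, so 5'-truncated copies align to a
#' consensus suffix at no cost.  Affine gap scoring (a gap of length g costs
#' `gap_open + g * gap_extend`); ties are broken deterministically (highest
#' score, then leftmost consensus end, substitutions preferred over gaps).
#'
#' @param locus_seq locus sequence in element orientation (reverse-complement
#'   minus-strand loci before calling).
#' @param consensus consensus sequence.
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @param min_score alignments scoring below this floor are flagged
#'   unalignable.
#' @return `list(map, score, aligned)`; `map[i]` is the 0-based consensus
#'   coordinate of locus position `i - 1`, NA for locus bases opposite a
#'   consensus gap.  When `aligned` is FALSE the map should not be used.
#' @export
align_to_consensus <- function(locus_seq, consensus, match = 1L,
                               mismatch = -1L, gap_open = -5L,
                               gap_extend = -1L, min_score = -Inf) {
  if (!nzchar(locus_seq) || !nzchar(consensus)) stop("empty sequence")
  res <- cpp_align_consensus(toupper(locus_seq), toupper(consensus),
                             as.integer(match), as.integer(mismatch),
                             as.integer(gap_open), as.integer(gap_extend))
  list(map = res$map, score = res$score, aligned = res$score >= min_score)
}

# per-locus score vector in element orientation: position i of the element
# corresponds to genome position start+i (+ strand) or end-1-i (- strand)
locus_scores_oriented <- function(track, locus) {
  v <- track$scores[[locus$chrom]][(locus$start + 1L):locus$end]
  if (locus$strand == "-") rev(v) else v
}

#' Mappability profile along a consensus sequence
#'
#' Maps every locus onto the subfamily consensus (via supplied truth maps or
#' the built-in semi-global aligner) and pools, for each consensus position,
#' the per-locus position scores mapped there.
#'
#' @param track a `mappability_track`.
#' @param annotation annotation rows of the loci to profile.
#' @param consensus consensus sequence (required unless `maps` is given).
#' @param genome genome (required when aligning; locus sequences are
#'   extracted and minus-strand loci reverse-complemented).
#' @param maps optional named list of precomputed coordinate maps (0-based
#'   consensus coordinates per locus position, element orientation), e.g. the
#'   simulator's truth maps; bypasses alignment.
#' @param min_score alignment score floor; unalignable loci are skipped.
#' @return `data.frame(position, depth, median, q1, q3)` over all consensus
#'   positions; quartiles use linear interpolation and are NA where depth is
#'   0.
#' @export
consensus_profile <- function(track, annotation, consensus = NULL,
                              genome = NULL, maps = NULL, min_score = -Inf) {
  stopifnot(inherits(track, "mappability_track"))
  if (is.null(maps) && (is.null(consensus) || is.null(genome)))
    stop("supply either precomputed maps or consensus + genome")
  clen <- if (!is.null(consensus)) nchar(consensus) else
    max(unlist(maps), na.rm = TRUE) + 1L
  pooled <- vector("list", clen)
  depth <- integer(clen)
  for (i in seq_len(nrow(annotation))) {
    locus <- annotation[i, ]
    map <- if (!is.null(maps)) {
      maps[[locus$locus_id]]
    } else {
      seq <- substr(genome[[locus$chrom]], locus$start + 1L, locus$end)
      if (locus$strand == "-") seq <- revcomp(seq)
      al <- align_to_consensus(seq, consensus, min_score = min_score)
      if (!al$aligned) next
      al$map
    }
    if (is.null(map)) next
    sc <- locus_scores_oriented(track, locus)
    ok <- !is.na(map) & !is.na(sc)
    cpos <- map[ok] + 1L
    val <- sc[ok]
    for (j in seq_along(cpos)) {
      pooled[[cpos[j]]] <- c(pooled[[cpos[j]]], val[j])
      depth[cpos[j]] <- depth[cpos[j]] + 1L
    }
  }
  qs <- vapply(pooled, function(v) {
    if (length(v) == 0L) return(c(NA_real_, NA_real_, NA_real_))
    quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  }, numeric(3))
  data.frame(position = 0:(clen - 1L), depth = depth,
             median = qs[2, ], q1 = qs[1, ], q3 = qs[3, ])
}

#' Classify a locus into a sub-clade by diagnostic consensus positions
#'
#' Reads the locus bases mapped to the diagnostic consensus positions (e.g.
#' the characteristic 3' UTR trinucleotide of human L1: ACA for L1HS-Ta, ACG
#' for L1HS-preTa) and returns the matching label.  Loci where any
#' diagnostic site is truncated away or gapped are `"unclassified"`.
#'
#' @param map coordinate map from [align_to_consensus()] (or a truth map).
#' @param locus_seq locus sequence in element orientation.
#' @param diagnostic `list(positions = <0-based consensus positions>,
#'   labels = c(VARIANT = "label", ...))`, e.g.
#'   `list(positions = c(5930, 5931, 5932), labels = c(ACA = "Ta", ACG = "preTa"))`.
#' @return The matched label, or `"unclassified"`.
#' @export
classify_subclade <- function(map, locus_seq, diagnostic) {
  stopifnot(is.list(diagnostic), length(diagnostic$labels) > 0L)
  pos <- as.integer(diagnostic$positions)
  idx <- match(pos, map)
  if (anyNA(idx)) return("unclassified")
  bases <- strsplit(locus_seq, "")[[1]][idx]
  variant <- paste(bases, collapse = "")
  lab <- unname(diagnostic$labels[variant])
  if (length(lab) != 1L || is.na(lab)) "unclassified" else lab
}
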