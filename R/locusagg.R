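# Locus-level aggregation of mappability tracks, subfamily summaries, and
# library comparisons.
#
# The locus rule is conservative: a locus is uniquely mappable only if every
# defined read/fragment start position inside it has score exactly 1, which
# also prevents inflation from unique flanking sequence.  Undefined positions
# (N windows, chromosome end) are excluded from both numerator and
# denominator, mirroring a simulated read set in which those reads never
# existed.

#' Score one locus from a mappability track
#'
#' Positions considered are read/fragment start positions p with
#' `start <= p < end` whose score is defined; reads may extend past the locus
#' end.
#'
#' @param track a `mappability_track`.
#' @param locus one-row annotation `data.frame` (or a list with `chrom`,
#'   `start`, `end`, `locus_id`).
#' @return A one-row `data.frame` with `n_positions`, `n_unique`,
#'   `percent_unique` (NA when no position is defined), `is_unique`,
#'   `mean_score`.
#' @export
score_locus <- function(track, locus) {
  stopifnot(inherits(track, "mappability_track"))
  chrom <- locus$chrom
  if (!chrom %in% names(track$scores))
    stop("track does not cover chromosome ", chrom)
  v <- track$scores[[chrom]]
  if (locus$start < 0L || locus$end > length(v))
    stop("locus ", locus$locus_id, " is off the chromosome")
  s <- v[(locus$start + 1L):locus$end]
  s <- s[!is.na(s)]
  n <- length(s)
  nu <- sum(s == 1)
  data.frame(
    locus_id = locus$locus_id,
    n_positions = n,
    n_unique = nu,
    percent_unique = if (n > 0L) 100 * nu / n else NA_real_,
    is_unique = n > 0L && nu == n,
    mean_score = if (n > 0L) mean(s) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Score every locus of an annotation
#'
#' @param track a `mappability_track`.
#' @param annotation annotation `data.frame` (see [te_annotation()]).
#' @return A locus score `data.frame`: the annotation columns plus
#'   `n_positions`, `n_unique`, `percent_unique`, `is_unique`, `mean_score`
#'   and a `params` label, ordered by (chrom, start).
#' @export
score_loci <- function(track, annotation) {
  stopifnot(inherits(track, "mappability_track"))
  if (nrow(annotation) == 0L) {
    out <- cbind(annotation,
                 data.frame(n_positions = integer(), n_unique = integer(),
                            percent_unique = numeric(), is_unique = logical(),
                            mean_score = numeric(), params = character(),
                            stringsAsFactors = FALSE))
    return(out)
  }
  res <- lapply(seq_len(nrow(annotation)), function(i)
    score_locus(track, annotation[i, ]))
  sc <- do.call(rbind, res)
  out <- cbind(annotation, sc[, setdiff(names(sc), "locus_id"), drop = FALSE])
  out$params <- if (!is.null(track$params)) params_label(track$params) else NA_character_
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize locus scores by subfamily, family and class
#'
#' @param scores locus score `data.frame` from [score_loci()].
#' @return A list of three `data.frame`s (`subfamily`, `family`, `te_class`),
#'   each with `copy_number` (locus count), `percent_loci_unique`
#'   (100 * uniquely mappable loci / copy number) and `avg_percent_unique`
#'   (mean of per-locus percent unique, NA-scored loci excluded), ordered by
#'   (class, family, subfamily).
#' @export
summarize_loci <- function(scores) {
  roll <- function(keys) {
    grp <- interaction(lapply(keys, function(k) scores[[k]]), drop = TRUE,
                       lex.order = TRUE)
    idx <- split(seq_len(nrow(scores)), grp)
    rows <- lapply(idx, function(i) {
      out <- scores[i[1], keys, drop = FALSE]
      out$copy_number <- length(i)
      out$percent_loci_unique <- 100 * sum(scores$is_unique[i]) / length(i)
      out$avg_percent_unique <- mean(scores$percent_unique[i], na.rm = TRUE)
      out
    })
    df <- do.call(rbind, rows)
    # order by class, then family, then subfamily
    df <- df[do.call(order, unname(df[rev(keys)])), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  list(
    subfamily = roll(c("subfamily", "family", "te_class")),
    family = roll(c("family", "te_class")),
    te_class = roll("te_class")
  )
}

#' Per-locus differences between score sets
#'
#' For each requested ordered (a, b) pair of libraries the difference is
#' `percent_unique[a] - percent_unique[b]` per locus; for a paired-end a and
#' single-end b, negative values flag loci where paired-end mappability is
#' lower than single-end.
#'
#' @param score_sets named list of locus score `data.frame`s over identical
#'   locus sets.
#' @param pairs optional 2-column matrix/data.frame of library-name pairs
#'   (a, b); defaults to all ordered pairs of distinct names.
#' @return Long `data.frame(library_a, library_b, locus_id, diff)`.
#' @export
compare_libraries <- function(score_sets, pairs = NULL) {
  nms <- names(score_sets)
  if (is.null(nms) || length(nms) < 2L)
    stop("score_sets must be a named list of at least two score sets")
  ids <- lapply(score_sets, function(s) sort(s$locus_id))
  for (i in seq_along(ids)[-1]) {
    if (!identical(ids[[1]], ids[[i]])) {
      missing <- c(setdiff(ids[[1]], ids[[i]]), setdiff(ids[[i]], ids[[1]]))
      stop("locus sets differ between '", nms[1], "' and '", nms[i], "': ",
           paste(head(missing, 10), collapse = ", "))
    }
  }
  if (is.null(pairs)) {
    pairs <- expand.grid(a = nms, b = nms, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  }
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- score_sets[[pairs[i, 1]]]
    b <- score_sets[[pairs[i, 2]]]
    b <- b[match(a$locus_id, b$locus_id), , drop = FALSE]
    data.frame(library_a = pairs[i, 1], library_b = pairs[i, 2],
               locus_id = a$locus_id,
               diff = a$percent_unique - b$percent_unique,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Filter loci for fair library comparisons
#'
#' Drops loci whose every paired-end library is already 100% unique (no
#' difference left to measure) and loci shorter than `min_len` (so that the
#' longest fragment library has defined positions to compare).
#'
#' @param annotation annotation `data.frame`.
#' @param score_sets named list of locus score `data.frame`s.
#' @param paired names of the paired-end score sets in `score_sets`.
#' @param min_len minimum locus length in bp (default 300).
#' @return The retained subset of `annotation`.
#' @export
filter_for_comparison <- function(annotation, score_sets,
                                  paired = names(score_sets),
                                  min_len = 300L) {
  stopifnot(all(paired %in% names(score_sets)))
  pu <- sapply(paired, function(nm) {
    s <- score_sets[[nm]]
    s$percent_unique[match(annotation$locus_id, s$locus_id)]
  })
  pu <- matrix(pu, nrow = nrow(annotation))
  all100 <- apply(pu, 1L, function(x) all(!is.na(x) & x == 100))
  short <- (annotation$end - annotation$start) < min_len
  annotation[!all100 & !short, , drop = FALSE]
}
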