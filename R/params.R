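#' Mappability scoring parameters
#'
#' Bundles the read library and alignment parameters that define a
#' mappability track: read length, mismatch allowance, single- or paired-end
#' mode, the simulated fragment length, the insert-size range accepted during
#' paired alignment, and which of the two calculation methods to use.
#'
#' For paired-end mode the simulated fragment is the full `fragment_length`
#' window; the two reads are its first `read_length` bases and the reverse
#' complement of its last `read_length` bases (forward-reverse orientation),
#' with the interior gap discarded.  During alignment a placement is accepted
#' when both mates match with at most `mismatches` mismatches each and the
#' implied fragment length lies in `[insert_min, insert_max]`.  Placements of
#' the same pair that differ only in fragment length are counted as distinct
#' mappings.
#'
#' @param read_length read length in bp (r >= 1).
#' @param mismatches maximum mismatches allowed per read (Hamming distance,
#'   gapless); must be smaller than `read_length`.
#' @param mode `"single"` or `"paired"`.
#' @param fragment_length full fragment length in bp for paired mode
#'   (>= 2 * read_length); ignored for single-end.
#' @param insert_min,insert_max accepted fragment-length range during paired
#'   alignment.  Defaults to `max(2 * read_length, fragment_length - 50)` and
#'   `fragment_length + 50`, a symmetric slack around the simulated fragment
#'   length.  Must bracket `fragment_length`, and `insert_min` may not be
#'   smaller than `read_length` (mates are reported leftmost-first).
#' @param method `1` (sum exact occurrence counts of all library k-mers
#'   aligning at a position) or `2` (count all placements of the position's
#'   own read or pair).  The two are exactly equivalent for single-end
#'   libraries and may differ slightly for paired-end ones.
#'
#' @return An object of class `map_params`.
#' @examples
#' map_params(76, mismatches = 3)
#' map_params(76, mismatches = 3, mode = "paired", fragment_length = 242)
#' @export
map_params <- function(read_length, mismatches = 3L,
                       mode = c("single", "paired"),
                       fragment_length = NULL,
                       insert_min = NULL, insert_max = NULL,
                       method = 1L) {
  mode <- match.arg(mode)
  r <- as.integer(read_length)
  m <- as.integer(mismatches)
  method <- as.integer(method)
  if (is.na(r) || r < 1L) stop("read_length must be a positive integer")
  if (is.na(m) || m < 0L) stop("mismatches must be non-negative")
  if (m >= r) stop("mismatches must be smaller than read_length")
  if (!method %in% c(1L, 2L)) stop("method must be 1 or 2")

  if (mode == "paired") {
    if (is.null(fragment_length))
      stop("paired mode requires fragment_length")
    L <- as.integer(fragment_length)
    if (L < 2L * r) stop("fragment_length must be at least 2 * read_length")
    imin <- if (is.null(insert_min)) max(2L * r, L - 50L) else as.integer(insert_min)
    imax <- if (is.null(insert_max)) L + 50L else as.integer(insert_max)
    if (imin < r) stop("insert_min may not be smaller than read_length")
    if (imin > L || imax < L)
      stop("insert range [insert_min, insert_max] must contain fragment_length")
  } else {
    L <- NA_integer_
    imin <- NA_integer_
    imax <- NA_integer_
  }
  structure(
    list(read_length = r, mismatches = m, mode = mode,
         fragment_length = L, insert_min = imin, insert_max = imax,
         method = method),
    class = "map_params"
  )
}

#' @export
print.map_params <- function(x, ...) {
  if (x$mode == "single") {
    cat(sprintf("map_params: single-end, r = %d bp, <= %d mismatches, method %d\n",
                x$read_length, x$mismatches, x$method))
  } else {
    cat(sprintf(
      "map_params: paired-end, r = %d bp, fragment = %d bp (gap %d bp),\n  insert range [%d, %d], <= %d mismatches per mate, method %d\n",
      x$read_length, x$fragment_length,
      x$fragment_length - 2L * x$read_length,
      x$insert_min, x$insert_max, x$mismatches, x$method))
  }
  invisible(x)
}

# short label used in tables and file names, e.g. "se50m3" / "pe76f242m3"
params_label <- function(params) {
  if (params$mode == "single") {
    sprintf("se%dm%d", params$read_length, params$mismatches)
  } else {
    sprintf("pe%df%dm%d", params$read_length, params$fragment_length,
            params$mismatches)
  }
}
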