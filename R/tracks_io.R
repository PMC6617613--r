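# Mappability track container and on-disk formats (bedGraph, fixedStep wiggle).
#
# Scores are indexed by read/fragment start position, 0-based.  Undefined
# positions (window off the chromosome end or containing N) are NA.  Defined
# scores are written with 17 significant digits so a write/read round trip
# reproduces them bit-exactly.

new_mappability_track <- function(scores, params = NULL) {
  stopifnot(is.list(scores), !is.null(names(scores)))
  structure(list(scores = scores, params = params),
            class = "mappability_track")
}

#' @export
print.mappability_track <- function(x, ...) {
  ndef <- sum(vapply(x$scores, function(v) sum(!is.na(v)), 0))
  ntot <- sum(lengths(x$scores))
  nuni <- sum(vapply(x$scores, function(v) sum(v == 1, na.rm = TRUE), 0))
  cat(sprintf("mappability track: %d chromosome(s), %d positions (%d defined, %.1f%% unique)\n",
              length(x$scores), ntot, ndef,
              if (ndef > 0) 100 * nuni / ndef else NA_real_))
  if (!is.null(x$params)) print(x$params)
  invisible(x)
}

#' @export
summary.mappability_track <- function(object, ...) {
  v <- unlist(object$scores, use.names = FALSE)
  summary(v[!is.na(v)])
}

fmt_score <- function(x) sprintf("%.17g", x)

#' Write a mappability track
#'
#' bedGraph output uses 0-based half-open intervals covering maximal runs of
#' equal score; fixedStep wiggle output is 1-based with one `fixedStep`
#' declaration per contiguous defined run.  Undefined positions are omitted
#' in both formats.
#'
#' @param track a `mappability_track` (or a named list of score vectors).
#' @param path output path.
#' @param format `"bedgraph"` or `"wiggle"`.
#' @param name track name written in the header line.
#' @return The path, invisibly.
#' @export
write_track <- function(track, path, format = c("bedgraph", "wiggle"),
                        name = "temap") {
  format <- match.arg(format)
  scores <- if (inherits(track, "mappability_track")) track$scores else track
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "bedgraph") {
    writeLines(sprintf('track type=bedGraph name="%s"', name), con)
    for (chrom in names(scores)) {
      v <- scores[[chrom]]
      if (all(is.na(v))) next
      key <- ifelse(is.na(v), NA_character_, fmt_score(v))
      r <- rle(key)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      keep <- !is.na(r$values)
      if (!any(keep)) next
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep], ends[keep],
                         r$values[keep]), con)
    }
  } else {
    writeLines(sprintf('track type=wiggle_0 name="%s"', name), con)
    for (chrom in names(scores)) {
      v <- scores[[chrom]]
      def <- !is.na(v)
      if (!any(def)) next
      r <- rle(def)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths
      for (i in which(r$values)) {
        writeLines(sprintf("fixedStep chrom=%s start=%d step=1",
                           chrom, starts[i] + 1L), con)
        writeLines(fmt_score(v[(starts[i] + 1L):ends[i]]), con)
      }
    }
  }
  invisible(path)
}

#' Read a mappability track
#'
#' Auto-detects bedGraph vs fixedStep wiggle from the content.  Positions not
#' covered by the file are NA (undefined).
#'
#' @param path track file written by [write_track()].
#' @param seqlengths named integer vector of chromosome lengths (e.g.
#'   `nchar(genome)`).
#' @return A `mappability_track` (without parameter metadata).
#' @export
read_track <- function(path, seqlengths) {
  if (is.character(seqlengths)) seqlengths <- nchar(validate_genome(seqlengths))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  scores <- lapply(seqlengths, function(n) rep(NA_real_, n))
  names(scores) <- names(seqlengths)
  body <- lines[!grepl("^track", lines)]
  if (length(body) == 0L) return(new_mappability_track(scores))
  if (any(grepl("^fixedStep", body))) {
    chrom <- NULL; pos <- 0L
    for (ln in body) {
      if (startsWith(ln, "fixedStep")) {
        chrom <- sub('.*chrom=([^ ]+).*', "\\1", ln)
        pos <- as.integer(sub('.*start=([0-9]+).*', "\\1", ln)) - 1L
        if (!chrom %in% names(scores)) stop("unknown chromosome: ", chrom)
      } else {
        scores[[chrom]][pos + 1L] <- as.numeric(ln)
        pos <- pos + 1L
      }
    }
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    for (x in f) {
      chrom <- x[[1]]
      if (!chrom %in% names(scores)) stop("unknown chromosome: ", chrom)
      s <- as.integer(x[[2]]); e <- as.integer(x[[3]])
      scores[[chrom]][(s + 1L):e] <- as.numeric(x[[4]])
    }
  }
  new_mappability_track(scores)
}

#' Write a locus score table as TSV
#'
#' One row per locus, ordered by (chrom, start).  `percent_unique` is printed
#' with fixed 4-decimal formatting; `mean_score` with full precision.
#'
#' @param scores locus score `data.frame` from [score_loci()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_locus_table <- function(scores, path) {
  if (anyDuplicated(scores$locus_id)) stop("duplicate locus_id")
  df <- scores[order(scores$chrom, scores$start, scores$end), , drop = FALSE]
  df$percent_unique <- ifelse(is.na(df$percent_unique), "NA",
                              sprintf("%.4f", df$percent_unique))
  df$mean_score <- ifelse(is.na(df$mean_score), "NA", fmt_score(df$mean_score))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a locus score table written by [write_locus_table()]
#'
#' @param path TSV path.
#' @return A locus score `data.frame`.
#' @export
read_locus_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$percent_unique <- as.numeric(df$percent_unique)
  df$mean_score <- as.numeric(df$mean_score)
  df$is_unique <- as.logical(df$is_unique)
  df
}
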