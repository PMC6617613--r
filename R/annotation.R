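#' Construct a TE annotation table
#'
#' The annotation representation used throughout the package: one row per
#' repeat locus, 0-based half-open coordinates, with the nested RepeatMasker
#' taxonomy (subfamily / family / class) and a unique locus identifier.
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @param subfamily,family,te_class repeat taxonomy labels (e.g. L1HS / L1 /
#'   LINE).
#' @param locus_id unique identifiers; generated from coordinates and
#'   subfamily when `NULL`.
#' @param genome optional genome; when given, intervals are checked against
#'   chromosome bounds.
#' @return A `data.frame` with columns `chrom, start, end, strand, subfamily,
#'   family, te_class, locus_id`, ordered by (chrom, start).
#' @export
te_annotation <- function(chrom, start, end, strand = "+",
                          subfamily = "TE", family = subfamily,
                          te_class = "TE", locus_id = NULL, genome = NULL) {
  n <- length(chrom)
  ann <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    subfamily = rep_len(as.character(subfamily), n),
    family = rep_len(as.character(family), n),
    te_class = rep_len(as.character(te_class), n),
    stringsAsFactors = FALSE
  )
  if (any(ann$start < 0L) || any(ann$start >= ann$end))
    stop("intervals must satisfy 0 <= start < end")
  if (!all(ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(locus_id)) {
    locus_id <- make.unique(
      paste(ann$subfamily, ann$chrom, ann$start, ann$end, sep = "_"),
      sep = ".")
  }
  ann$locus_id <- as.character(locus_id)
  if (anyDuplicated(ann$locus_id))
    stop("locus_id values must be unique")
  if (!is.null(genome)) {
    genome <- validate_genome(genome)
    lens <- nchar(genome)
    bad <- !(ann$chrom %in% names(genome)) | ann$end > lens[ann$chrom]
    bad[is.na(bad)] <- TRUE
    if (any(bad))
      stop("loci exceed genome bounds: ",
           paste(ann$locus_id[bad], collapse = ", "))
  }
  ann[order(ann$chrom, ann$start, ann$end), , drop = FALSE]
}

#' Read a TE annotation
#'
#' Supports the RepeatMasker `.out` dialect and BED6+.  RepeatMasker 1-based
#' inclusive coordinates are converted to 0-based half-open; strand `"C"`
#' becomes `"-"`; the "class/family" column is split on `"/"` into class and
#' family (rows without a slash use the same label for both).  BED name
#' fields are interpreted as `subfamily:family:class` or
#' `subfamily:family:class:locus_id`.
#'
#' @param path input file.
#' @param dialect `"repeatmasker"` (`.out`) or `"bed"`.
#' @param genome optional genome for bounds checking; offending loci are
#'   listed in the error.
#' @param drop_overlapping drop RepeatMasker rows flagged `*` (overlapping a
#'   higher-scoring match).  Default keeps them.
#' @return An annotation `data.frame` (see [te_annotation()]).
#' @export
read_annotation <- function(path, dialect = c("repeatmasker", "bed"),
                            genome = NULL, drop_overlapping = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "repeatmasker") {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    fields <- strsplit(trimws(lines), "[ \t]+")
    is_data <- vapply(fields, function(f)
      length(f) >= 14L && grepl("^[0-9]+$", f[[1]]), TRUE)
    fields <- fields[is_data]
    if (length(fields) == 0L) stop("no data rows in RepeatMasker file: ", path)
    starred <- vapply(fields, function(f) identical(f[length(f)], "*"), TRUE)
    if (drop_overlapping) fields <- fields[!starred]
    chrom <- vapply(fields, `[`, "", 5L)
    qbeg <- as.integer(vapply(fields, `[`, "", 6L))
    qend <- as.integer(vapply(fields, `[`, "", 7L))
    strand <- vapply(fields, `[`, "", 9L)
    strand <- ifelse(strand == "C", "-", strand)
    subfam <- vapply(fields, `[`, "", 10L)
    clsfam <- vapply(fields, `[`, "", 11L)
    parts <- strsplit(clsfam, "/", fixed = TRUE)
    te_class <- vapply(parts, `[`, "", 1L)
    family <- vapply(parts, function(p) if (length(p) >= 2L) p[[2]] else p[[1]], "")
    ann <- te_annotation(chrom, qbeg - 1L, qend, strand, subfam, family,
                         te_class, genome = genome)
  } else {
    df <- read.delim(path, header = FALSE, sep = "", comment.char = "#",
                     stringsAsFactors = FALSE)
    if (ncol(df) < 6L) stop("BED file must have at least 6 columns")
    toks <- strsplit(as.character(df[[4]]), ":", fixed = TRUE)
    subfam <- vapply(toks, `[`, "", 1L)
    family <- vapply(toks, function(p) if (length(p) >= 2L) p[[2]] else p[[1]], "")
    te_class <- vapply(toks, function(p) if (length(p) >= 3L) p[[3]] else p[[1]], "")
    ids <- vapply(toks, function(p) if (length(p) >= 4L) p[[4]] else NA_character_, "")
    if (anyNA(ids)) ids <- NULL
    ann <- te_annotation(df[[1]], df[[2]], df[[3]], as.character(df[[6]]),
                         subfam, family, te_class, locus_id = ids,
                         genome = genome)
  }
  ann
}

#' Write a TE annotation as BED6+
#'
#' The name field encodes `subfamily:family:class:locus_id`, so
#' [read_annotation()] round-trips all fields.
#'
#' @param annotation annotation `data.frame`.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_annotation_bed <- function(annotation, path) {
  if (nrow(annotation) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- paste(annotation$subfamily, annotation$family,
                annotation$te_class, annotation$locus_id, sep = ":")
  df <- data.frame(annotation$chrom, annotation$start, annotation$end,
                   name, 0L, annotation$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
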