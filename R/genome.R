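#' Read a genome from a FASTA file
#'
#' Sequences are uppercased and validated against the `{A,C,G,T,N}` alphabet.
#' IUPAC ambiguity codes other than N are either rejected (`ambiguous =
#' "error"`) or masked to N (`ambiguous = "mask"`).
#'
#' @param path path to a (multi-record) FASTA file.
#' @param ambiguous what to do with non-ACGTN characters: `"error"` or
#'   `"mask"` (replace with N).
#' @return A named character vector of uppercase chromosome sequences
#'   (the genome representation used throughout the package).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT", ">chr2", "GGGG"), fa)
#' g <- read_genome_fasta(fa)
#' nchar(g)
#' @export
read_genome_fasta <- function(path, ambiguous = c("error", "mask")) {
  ambiguous <- match.arg(ambiguous)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- vapply(strsplit(names(ss), "[ \t]"), `[`, "", 1L)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    if (ambiguous == "error")
      stop("non-ACGTN characters in record(s): ",
           paste(names(seqs)[bad], collapse = ", "))
    seqs[bad] <- gsub("[^ACGTN]", "N", seqs[bad])
  }
  validate_genome(seqs)
}

#' Write a genome to a FASTA file
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @param width line width for wrapping.
#' @return The path, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  genome <- validate_genome(genome)
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Validate a genome object
#'
#' A genome is a named character vector of non-empty uppercase sequences over
#' `{A,C,G,T,N}` with unique, non-empty chromosome names.
#'
#' @param genome candidate genome.
#' @return The validated genome (invisibly usable), or an error.
#' @export
validate_genome <- function(genome) {
  if (!is.character(genome) || length(genome) == 0L)
    stop("genome must be a non-empty named character vector")
  nm <- names(genome)
  if (is.null(nm) || any(!nzchar(nm)) || anyNA(nm))
    stop("all chromosomes must be named")
  if (anyDuplicated(nm)) stop("duplicate chromosome names")
  if (any(!nzchar(genome))) stop("empty chromosome sequence")
  if (any(grepl("[^ACGTN]", genome)))
    stop("genome sequences may contain only A, C, G, T, N")
  genome
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (A, C, G, T, N).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}
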