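# Synthetic genomes with planted TE subfamilies.
#
# The generator emulates the structure that drives TE mappability in real
# genomes: subfamilies of varying copy number (more copies -> lower
# mappability), per-copy divergence as an age proxy (older copies have
# accumulated substitutions and are more unique), 5'-truncated L1-like
# insertions (retrotransposition initiates at the 3' end and often fails to
# reach the 5' end), and recent segmental duplications (verbatim copies that
# depress mappability of everything inside them).  Copies carry no indels, so
# planted truth maps are exact and the Hamming-based scoring core applies.

#' Specify a synthetic TE subfamily
#'
#' @param name subfamily label (e.g. `"L1sim"`).
#' @param consensus consensus sequence (ACGT only).
#' @param copy_number number of copies to plant.
#' @param sub_rate per-base substitution probability applied to each copy
#'   (age proxy; 0 = identical copies).
#' @param truncation_5p retained 3' fraction: a scalar in (0, 1] for a fixed
#'   fraction (1 = full length), or `c(min, max)` for a uniform draw per copy.
#' @param strand_prob probability a copy is planted on the + strand.
#' @param family,te_class taxonomy labels for the annotation.
#' @return A `subfamily_spec` list.
#' @export
subfamily_spec <- function(name, consensus, copy_number, sub_rate = 0,
                           truncation_5p = 1, strand_prob = 0.5,
                           family = name, te_class = "TE") {
  if (grepl("[^ACGT]", consensus)) stop("consensus must be over ACGT")
  if (copy_number < 0) stop("copy_number must be >= 0")
  if (sub_rate < 0 || sub_rate >= 1) stop("sub_rate must be in [0, 1)")
  tr <- as.numeric(truncation_5p)
  if (!length(tr) %in% 1:2 || any(tr <= 0) || any(tr > 1))
    stop("truncation_5p must be a fraction in (0, 1] or a (min, max) pair")
  if (strand_prob < 0 || strand_prob > 1) stop("strand_prob must be in [0, 1]")
  structure(list(name = name, consensus = toupper(consensus),
                 copy_number = as.integer(copy_number), sub_rate = sub_rate,
                 truncation_5p = tr, strand_prob = strand_prob,
                 family = family, te_class = te_class),
            class = "subfamily_spec")
}

#' Configure a synthetic genome simulation
#'
#' @param background_length background chromosome length in bp.
#' @param gc_content background GC fraction.
#' @param subfamilies list of [subfamily_spec()] objects.
#' @param segdups list of segmental duplications, each
#'   `list(start =, end =, n_copies =)` in coordinates of the planted genome;
#'   each copy is appended verbatim at the chromosome end after TE planting,
#'   and loci fully inside the region are duplicated with fresh locus ids.
#' @param seed RNG seed for reproducibility.
#' @return A `sim_config` list.
#' @export
sim_config <- function(background_length, gc_content = 0.41,
                       subfamilies = list(), segdups = list(), seed = 1L) {
  if (background_length <= 0) stop("background_length must be positive")
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0, 1)")
  for (sf in subfamilies)
    if (!inherits(sf, "subfamily_spec")) stop("subfamilies must be subfamily_spec objects")
  structure(list(background_length = as.integer(background_length),
                 gc_content = gc_content, subfamilies = subfamilies,
                 segdups = segdups, seed = as.integer(seed)),
            class = "sim_config")
}

#' Mutate one copy of a consensus sequence
#'
#' Applies 5' truncation first (a 3' suffix of the consensus is retained),
#' then i.i.d. substitutions at `sub_rate` to a uniformly chosen different
#' base.  No indels.  Uses the current RNG state.
#'
#' @param consensus consensus sequence.
#' @param spec a [subfamily_spec()].
#' @return `list(seq, truth_map)` where `truth_map[i]` is the 0-based
#'   consensus coordinate of copy position `i - 1`.
#' @export
mutate_copy <- function(consensus, spec) {
  L <- nchar(consensus)
  tr <- spec$truncation_5p
  frac <- if (length(tr) == 2L) runif(1, tr[1], tr[2]) else tr
  keep <- max(1L, as.integer(round(frac * L)))
  off <- L - keep
  chars <- strsplit(substr(consensus, off + 1L, L), "")[[1]]
  if (spec$sub_rate > 0) {
    hit <- which(runif(keep) < spec$sub_rate)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      alt <- setdiff(bases, chars[i])
      chars[i] <- alt[sample.int(3L, 1L)]
    }
  }
  list(seq = paste(chars, collapse = ""),
       truth_map = off:(L - 1L))
}

#' Simulate a genome with planted TE copies
#'
#' Generates an i.i.d. background chromosome at the configured GC content,
#' plants mutated subfamily copies at uniform non-overlapping positions
#' (overwriting the background), then applies segmental duplications by
#' appending verbatim copies of finished regions.  Fully reproducible from
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param chrom_name chromosome name for the output genome.
#' @return `list(genome, annotation, truth)`: the genome (named character
#'   vector), a TE annotation `data.frame`, and a named list of truth maps
#'   (per locus, the 0-based consensus coordinate of each locus position in
#'   element orientation).
#' @export
simulate_genome <- function(config, chrom_name = "chr1") {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed)

  n <- config$background_length
  gc <- config$gc_content
  bg <- sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))

  placed_start <- integer(0)
  placed_end <- integer(0)
  rows <- list()
  truth <- list()
  for (sf in config$subfamilies) {
    if (sf$copy_number == 0L) next
    for (i in seq_len(sf$copy_number)) {
      cp <- mutate_copy(sf$consensus, sf)
      len <- nchar(cp$seq)
      if (len > n) stop("copy of '", sf$name, "' longer than background")
      ok <- FALSE
      for (try in 1:1000) {
        s <- sample.int(n - len + 1L, 1L) - 1L
        e <- s + len
        if (!any(s < placed_end & e > placed_start)) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place copies without overlap; ",
                    "reduce copy load or enlarge the background")
      strand <- if (runif(1) < sf$strand_prob) "+" else "-"
      ins <- if (strand == "+") cp$seq else revcomp(cp$seq)
      bg[(s + 1L):e] <- strsplit(ins, "")[[1]]
      placed_start <- c(placed_start, s)
      placed_end <- c(placed_end, e)
      id <- sprintf("%s_%03d", sf$name, i)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom_name, start = s, end = e, strand = strand,
        subfamily = sf$name, family = sf$family, te_class = sf$te_class,
        locus_id = id, stringsAsFactors = FALSE)
      truth[[id]] <- cp$truth_map
    }
  }
  ann <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), subfamily = character(),
               family = character(), te_class = character(),
               locus_id = character(), stringsAsFactors = FALSE)

  seq <- paste(bg, collapse = "")
  for (sd in config$segdups) {
    s <- as.integer(sd$start); e <- as.integer(sd$end)
    ncp <- as.integer(sd$n_copies)
    if (s < 0L || e > nchar(seq) || s >= e) stop("invalid segdup region")
    region <- substr(seq, s + 1L, e)
    for (k in seq_len(ncp)) {
      at <- nchar(seq)  # appended verbatim at the chromosome end
      seq <- paste0(seq, region)
      inside <- which(ann$start >= s & ann$end <= e &
                      !grepl("_dup", ann$locus_id, fixed = TRUE))
      if (length(inside)) {
        dup <- ann[inside, , drop = FALSE]
        shift <- at - s
        dup$start <- dup$start + shift
        dup$end <- dup$end + shift
        newid <- paste0(dup$locus_id, "_dup", k)
        for (j in seq_along(inside)) truth[[newid[j]]] <- truth[[dup$locus_id[j]]]
        dup$locus_id <- newid
        ann <- rbind(ann, dup)
      }
    }
  }

  genome <- setNames(seq, chrom_name)
  if (nrow(ann)) ann <- ann[order(ann$chrom, ann$start), , drop = FALSE]
  rownames(ann) <- NULL
  list(genome = genome, annotation = ann, truth = truth)
}

#' Write a simulation config as YAML
#'
#' Schema: top-level keys `background_length`, `gc_content`, `seed`,
#' `subfamilies` (list of subfamily entries with the [subfamily_spec()]
#' fields) and `segdups` (list of `start`/`end`/`n_copies` entries).
#'
#' @param config a [sim_config()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- list(
    background_length = config$background_length,
    gc_content = config$gc_content,
    seed = config$seed,
    subfamilies = lapply(config$subfamilies, function(sf) unclass(sf)),
    segdups = config$segdups
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation config written by [write_sim_config()]
#'
#' @param path YAML path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  subs <- lapply(x$subfamilies, function(sf) {
    subfamily_spec(sf$name, sf$consensus, sf$copy_number,
                   sub_rate = sf$sub_rate %||% 0,
                   truncation_5p = sf$truncation_5p %||% 1,
                   strand_prob = sf$strand_prob %||% 0.5,
                   family = sf$family %||% sf$name,
                   te_class = sf$te_class %||% "TE")
  })
  sim_config(x$background_length, gc_content = x$gc_content %||% 0.41,
             subfamilies = subs, segdups = x$segdups %||% list(),
             seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random ACGT sequence
#'
#' Convenience for building fixtures and demo consensus sequences; uses the
#' current RNG state.
#'
#' @param n length in bp.
#' @param gc GC fraction.
#' @return A single sequence string.
#' @export
random_sequence <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
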