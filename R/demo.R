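# End-to-end demonstration pipeline on a simulated genome.

#' Default demonstration simulation config
#'
#' A compact genome that exercises the features driving TE mappability: a
#' young, barely diverged L1-like subfamily with 5' truncation, an older,
#' diverged sibling, a high-copy Alu-like SINE, and one segmental
#' duplication spanning an old-subfamily locus.
#'
#' @param seed global seed; stage seeds are derived by fixed offsets.
#' @param background_length background chromosome length (default 80 kb).
#' @return A [sim_config()].
#' @export
demo_config <- function(seed = 1L, background_length = 80000L) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed + 1000L)
  l1_young_cons <- random_sequence(3000, gc = 0.42)
  l1_old_cons <- random_sequence(3000, gc = 0.42)
  alu_cons <- random_sequence(300, gc = 0.55)
  subs <- list(
    subfamily_spec("L1young", l1_young_cons, copy_number = 6, sub_rate = 0.01,
                   truncation_5p = c(0.3, 1), strand_prob = 0.5,
                   family = "L1", te_class = "LINE"),
    subfamily_spec("L1old", l1_old_cons, copy_number = 6, sub_rate = 0.12,
                   truncation_5p = c(0.3, 1), strand_prob = 0.5,
                   family = "L1", te_class = "LINE"),
    subfamily_spec("AluSim", alu_cons, copy_number = 20, sub_rate = 0.08,
                   truncation_5p = 1, strand_prob = 0.5,
                   family = "Alu", te_class = "SINE")
  )
  cfg <- sim_config(background_length, gc_content = 0.41, subfamilies = subs,
                    seed = seed + 1L)
  # place one segmental duplication around an L1old locus: simulate once to
  # find its coordinates (the re-simulation from the same seed is identical)
  sim <- simulate_genome(cfg)
  old_loci <- sim$annotation[sim$annotation$subfamily == "L1old", ]
  if (nrow(old_loci) > 0L) {
    loc <- old_loci[1L, ]
    cfg$segdups <- list(list(start = max(0L, loc$start - 100L),
                             end = min(nchar(sim$genome[[1]]), loc$end + 100L),
                             n_copies = 1L))
  }
  cfg
}

#' Run the demonstration pipeline
#'
#' Simulates a genome with planted TE subfamilies, computes six mappability
#' tracks (single-end 50/76/100 bp and paired-end 50/76/100 bp with
#' fragments 200/242/300 bp, 3 mismatches), aggregates locus and subfamily
#' summaries, compares libraries, runs a permutation test between the young
#' and old L1-like subfamilies, and profiles the young subfamily along its
#' consensus.  All outputs are written to `out_dir`; identical seed and
#' config reproduce identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global seed, fanned out to stage seeds by fixed offsets.
#' @param config optional [sim_config()]; default [demo_config()].
#' @param mismatches mismatch allowance per read.
#' @param method mappability calculation method (1 or 2).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the output paths and in-memory results
#'   (annotation, locus scores per library, summaries, permutation test,
#'   consensus profile).
#' @export
run_demo <- function(out_dir = file.path(tempdir(), "temap_demo"), seed = 1L,
                     config = NULL, mismatches = 3L, method = 1L,
                     quiet = FALSE) {
  say <- function(...) if (!quiet) message("[temap demo] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("demo stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- demo_config(seed)

  say("simulating genome (seed ", config$seed, ")")
  sim <- stage("simulate", simulate_genome(config))
  genome <- sim$genome
  ann <- sim$annotation
  say(sprintf("genome: %d bp, %d planted loci", sum(nchar(genome)), nrow(ann)))
  write_sim_config(config, file.path(out_dir, "config.yaml"))
  write_genome_fasta(genome, file.path(out_dir, "genome.fa"))
  write_annotation_bed(ann, file.path(out_dir, "annotation.bed"))
  if (length(sim$truth)) {
    tm <- do.call(rbind, lapply(names(sim$truth), function(id)
      data.frame(locus_id = id, locus_pos = seq_along(sim$truth[[id]]) - 1L,
                 consensus_pos = sim$truth[[id]], stringsAsFactors = FALSE)))
    write.table(tm, file.path(out_dir, "truth_maps.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  libs <- list(
    se50 = map_params(50, mismatches, "single", method = method),
    se76 = map_params(76, mismatches, "single", method = method),
    se100 = map_params(100, mismatches, "single", method = method),
    pe50 = map_params(50, mismatches, "paired", 200, method = method),
    pe76 = map_params(76, mismatches, "paired", 242, method = method),
    pe100 = map_params(100, mismatches, "paired", 300, method = method)
  )
  scores <- list()
  tracks <- list()
  for (nm in names(libs)) {
    say("scoring library ", nm)
    tr <- stage(nm, mappability_track(genome, libs[[nm]]))
    tracks[[nm]] <- tr
    write_track(tr, file.path(out_dir, paste0("track_", nm, ".bedgraph")),
                name = paste0("temap_", nm))
    sc <- stage(paste0("aggregate_", nm), score_loci(tr, ann))
    scores[[nm]] <- sc
    if (nrow(sc)) write_locus_table(sc, file.path(out_dir, paste0("loci_", nm, ".tsv")))
  }

  say("summarizing subfamilies (pe76)")
  summaries <- if (nrow(ann)) summarize_loci(scores$pe76) else NULL
  if (!is.null(summaries)) {
    for (lev in names(summaries))
      write.table(summaries[[lev]],
                  file.path(out_dir, paste0("summary_", lev, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }

  comparison <- NULL
  if (nrow(ann)) {
    keep <- filter_for_comparison(ann, scores, paired = c("pe50", "pe76", "pe100"))
    if (nrow(keep)) {
      subset_scores <- lapply(scores, function(s)
        s[s$locus_id %in% keep$locus_id, , drop = FALSE])
      pairs <- expand.grid(a = c("pe50", "pe76", "pe100"),
                           b = c("se50", "se76", "se100"),
                           stringsAsFactors = FALSE)
      comparison <- stage("compare", compare_libraries(subset_scores, pairs))
      write.table(comparison, file.path(out_dir, "comparison.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  permtest <- NULL
  young <- scores$pe76$percent_unique[scores$pe76$subfamily == "L1young"]
  old <- scores$pe76$percent_unique[scores$pe76$subfamily == "L1old"]
  young <- young[!is.na(young)]; old <- old[!is.na(old)]
  if (length(young) && length(old)) {
    say("permutation test: young vs old L1 subfamily")
    permtest <- stage("permtest",
                      permutation_test(young, old, n_perm = 9999L,
                                       seed = seed + 2L))
    writeLines(utils::capture.output(print(permtest)),
               file.path(out_dir, "permtest.txt"))
  }

  profile <- NULL
  young_ann <- ann[ann$subfamily == "L1young", , drop = FALSE]
  if (nrow(young_ann)) {
    say("consensus profile: L1young (truth maps)")
    profile <- stage("profile",
                     consensus_profile(tracks$pe76, young_ann,
                                       maps = sim$truth))
    write.table(profile, file.path(out_dir, "profile_L1young.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  say("done: ", out_dir)
  invisible(list(out_dir = out_dir, config = config, genome = genome,
                 annotation = ann, truth = sim$truth, scores = scores,
                 summaries = summaries, comparison = comparison,
                 permtest = permtest, profile = profile))
}
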