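test_that("mutate_copy applies truncation then substitutions, no indels", {
  set.seed(1)
  cons <- random_sequence(300)
  sf_id <- subfamily_spec("x", cons, 1, sub_rate = 0, truncation_5p = 1)
  cp <- mutate_copy(cons, sf_id)
  expect_identical(cp$seq, cons)
  expect_identical(cp$truth_map, 0:299)

  sf_tr <- subfamily_spec("x", cons, 1, sub_rate = 0, truncation_5p = 0.5)
  cp <- mutate_copy(cons, sf_tr)
  expect_identical(cp$seq, substr(cons, 151, 300))  # retained 3' suffix
  expect_identical(cp$truth_map, 150:299)

  # observed mismatch fraction within 3 binomial SDs of the rate
  set.seed(2)
  long <- random_sequence(10000)
  sf_mu <- subfamily_spec("x", long, 1, sub_rate = 0.05)
  cp <- mutate_copy(long, sf_mu)
  expect_identical(nchar(cp$seq), 10000L)
  mm <- mean(strsplit(cp$seq, "")[[1]] != strsplit(long, "")[[1]])
  sd3 <- 3 * sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(mm - 0.05), sd3)
})

test_that("simulate_genome is reproducible and annotates planted copies exactly", {
  set.seed(3)
  cons <- random_sequence(400)
  cfg <- sim_config(20000, subfamilies = list(
    subfamily_spec("fam", cons, 4, sub_rate = 0, truncation_5p = c(0.5, 1))),
    seed = 7)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1, s2)  # same seed, byte-identical

  # truth-vs-annotation identity: each locus is exactly the consensus suffix
  # recorded in its truth map, on the annotated strand
  for (i in seq_len(nrow(s1$annotation))) {
    loc <- s1$annotation[i, ]
    seq <- substr(s1$genome[[loc$chrom]], loc$start + 1, loc$end)
    if (loc$strand == "-") seq <- revcomp(seq)
    tm <- s1$truth[[loc$locus_id]]
    expect_identical(seq, substr(cons, tm[1] + 1, 400))
    expect_identical(nchar(seq), length(tm))
  }
})

test_that("an empty config yields pure background", {
  cfg <- sim_config(500, seed = 9)
  sim <- simulate_genome(cfg)
  expect_identical(unname(nchar(sim$genome)), 500L)
  expect_equal(nrow(sim$annotation), 0)
  expect_length(sim$truth, 0)
})

test_that("planted identical copies recover 1/n mappability", {
  set.seed(4)
  cons <- random_sequence(300)
  cfg <- sim_config(15000, subfamilies = list(
    subfamily_spec("fam", cons, 4, sub_rate = 0, truncation_5p = 1,
                   strand_prob = 1)), seed = 11)
  sim <- simulate_genome(cfg)
  tr <- mappability_track(sim$genome, map_params(30, 0, method = 2))
  loc <- sim$annotation[1, ]
  interior <- tr$scores$chr1[(loc$start + 1):(loc$end - 30 + 1)]
  expect_true(all(interior == 0.25))
})

test_that("a segmental duplication drops the duplicated locus below 100% unique", {
  set.seed(5)
  cons <- random_sequence(300)
  cfg <- sim_config(8000, subfamilies = list(
    subfamily_spec("old", cons, 1, sub_rate = 0.15, strand_prob = 1)),
    seed = 13)
  base <- simulate_genome(cfg)
  loc <- base$annotation[1, ]
  cfg$segdups <- list(list(start = loc$start - 50, end = loc$end + 50,
                           n_copies = 1))
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$annotation), 2)
  tr <- mappability_track(sim$genome, map_params(30, 0, method = 2))
  sc <- score_loci(tr, sim$annotation)
  # a single diverged copy would be unique; its verbatim duplicate is not
  expect_true(all(sc$percent_unique < 100))
})

test_that("simulation configs round-trip through YAML", {
  set.seed(6)
  cfg <- sim_config(1000, gc_content = 0.45, subfamilies = list(
    subfamily_spec("a", random_sequence(50), 2, sub_rate = 0.1,
                   truncation_5p = c(0.4, 1), strand_prob = 0.7,
                   family = "F", te_class = "LINE")),
    segdups = list(list(start = 10, end = 60, n_copies = 2)), seed = 3)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_identical(simulate_genome(back), simulate_genome(cfg))
})
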