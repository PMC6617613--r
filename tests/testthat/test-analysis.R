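test_that("permutation test matches exact enumeration and is symmetric", {
  a <- c(10, 40, 25)
  b <- c(50, 80, 95)
  res <- permutation_test(a, b, exhaustive = "always")
  expect_identical(res$method, "exhaustive")
  expect_equal(res$n_perm, choose(6, 3))
  # independent enumeration of all 20 label splits
  pool <- c(a, b)
  splits <- combn(6, 3)
  stats <- apply(splits, 2, function(i) mean(pool[i]) - mean(pool[-i]))
  obs <- mean(a) - mean(b)
  expect_equal(res$obs_diff, obs)
  expect_equal(res$p_value, mean(abs(stats) >= abs(obs) - 1e-12))
  # two-sided symmetry
  expect_equal(permutation_test(b, a, exhaustive = "always")$p_value,
               res$p_value)

  # identical groups: every split is at least as extreme as |obs| = 0
  same <- permutation_test(c(1, 2, 3), c(3, 1, 2), exhaustive = "always")
  expect_equal(same$obs_diff, 0)
  expect_equal(same$p_value, 1)
})

test_that("sampled p-values respect the add-one floor and approach the exact value", {
  # fully separated groups large enough that no sampled relabeling ties the
  # observed statistic: the add-one floor is attained exactly
  a <- rep(0, 10); b <- rep(100, 10)
  res <- permutation_test(a, b, n_perm = 999, seed = 4, exhaustive = "never")
  expect_equal(res$p_value, 1 / 1000)  # minimum attainable p

  set.seed(61)
  a4 <- rnorm(4, 0); b4 <- rnorm(4, 1.5)
  exact <- permutation_test(a4, b4, exhaustive = "always")
  sampled <- permutation_test(a4, b4, n_perm = 20000, seed = 5,
                              exhaustive = "never")
  expect_lt(abs(sampled$p_value - exact$p_value), 0.02)

  expect_error(permutation_test(numeric(0), b), "non-empty")
})

test_that("a diverged subfamily separates from an identical-copy one", {
  set.seed(62)
  cfg <- sim_config(30000, subfamilies = list(
    subfamily_spec("young", random_sequence(400), 6, sub_rate = 0.005),
    subfamily_spec("old", random_sequence(400), 6, sub_rate = 0.15)),
    seed = 23)
  sim <- simulate_genome(cfg)
  tr <- mappability_track(sim$genome, map_params(30, 3, method = 1))
  sc <- score_loci(tr, sim$annotation)
  young <- sc$percent_unique[sc$subfamily == "young"]
  old <- sc$percent_unique[sc$subfamily == "old"]
  res <- permutation_test(young, old, n_perm = 999, seed = 6)
  expect_lt(res$obs_diff, 0)  # active-like copies are less mappable
  expect_lte(res$p_value, 0.05)
})

test_that("semi-global alignment recovers truth maps on simulated copies", {
  set.seed(63)
  cons <- random_sequence(400)
  al <- align_to_consensus(cons, cons)
  expect_identical(al$map, 0:399)  # identity

  suffix <- substr(cons, 151, 400)
  al2 <- align_to_consensus(suffix, cons)
  expect_identical(al2$map, 150:399)

  sf <- subfamily_spec("x", cons, 1, sub_rate = 0.1, truncation_5p = c(0.3, 1))
  for (i in 1:5) {
    cp <- mutate_copy(cons, sf)
    al3 <- align_to_consensus(cp$seq, cons)
    expect_identical(al3$map, as.integer(cp$truth_map))
  }

  # score floor flags garbage as unalignable
  set.seed(64)
  junk <- random_sequence(400)
  expect_false(align_to_consensus(junk, cons, min_score = 200)$aligned)
})

test_that("consensus profiles pool per-position scores with correct depth", {
  ann <- data.frame(chrom = "chr1", start = 0L, end = 10L, strand = "+",
                    subfamily = "x", family = "x", te_class = "TE",
                    locus_id = "a", stringsAsFactors = FALSE)
  tr <- make_track(list(chr1 = rep(1, 10)))
  prof <- consensus_profile(tr, ann, maps = list(a = 0:9))
  expect_equal(prof$depth, rep(1, 10))
  expect_equal(prof$median, rep(1, 10))

  # 5'-truncated family: depth non-decreasing toward the 3' end
  set.seed(65)
  cons <- random_sequence(300)
  cfg <- sim_config(20000, subfamilies = list(
    subfamily_spec("l1", cons, 8, sub_rate = 0.05,
                   truncation_5p = c(0.3, 1))), seed = 29)
  sim <- simulate_genome(cfg)
  trk <- mappability_track(sim$genome, map_params(25, 1, method = 2))
  prof2 <- consensus_profile(trk, sim$annotation, maps = sim$truth)
  expect_true(all(diff(prof2$depth) >= 0))

  # median equals a naive per-column recomputation
  naive <- lapply(1:300, function(j) numeric(0))
  for (i in seq_len(nrow(sim$annotation))) {
    locus <- sim$annotation[i, ]
    v <- trk$scores$chr1[(locus$start + 1):locus$end]
    if (locus$strand == "-") v <- rev(v)
    tm <- sim$truth[[locus$locus_id]]
    for (k in seq_along(tm)) {
      if (!is.na(v[k]))
        naive[[tm[k] + 1]] <- c(naive[[tm[k] + 1]], v[k])
    }
  }
  med <- vapply(naive, function(x) if (length(x)) median(x) else NA_real_, 0)
  expect_equal(prof2$median, med)
  expect_equal(prof2$depth, lengths(naive))
})

test_that("diagnostic trinucleotides classify sub-clades", {
  diag <- list(positions = c(100, 101, 102),
               labels = c(ACA = "Ta", ACG = "preTa"))
  cons <- paste0(strrep("G", 100), "ACA", strrep("G", 50))
  locus_ta <- cons
  expect_identical(
    classify_subclade(align_to_consensus(locus_ta, cons)$map, locus_ta, diag),
    "Ta")
  locus_pre <- paste0(strrep("G", 100), "ACG", strrep("G", 50))
  expect_identical(
    classify_subclade(align_to_consensus(locus_pre, cons)$map, locus_pre, diag),
    "preTa")
  # truncated past the site
  trunc <- substr(cons, 121, 153)
  al <- align_to_consensus(trunc, cons)
  expect_identical(classify_subclade(al$map, trunc, diag), "unclassified")
  # non-diagnostic variant
  locus_other <- paste0(strrep("G", 100), "TTT", strrep("G", 50))
  expect_identical(
    classify_subclade(align_to_consensus(locus_other, cons)$map, locus_other,
                      diag),
    "unclassified")
})
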