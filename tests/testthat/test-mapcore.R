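test_that("count_kmers counts (position, strand) placements exactly", {
  # palindromic 4-mer in ACGTACGT: 2 forward + 2 reverse-complement matches
  expect_equal(unname(count_kmers(c(chr1 = "ACGTACGT"), 4)["ACGT"]), 4)
  # AAAA occurs once; its reverse complement TTTT does not occur
  cnt <- count_kmers(c(chr1 = "AAAA"), 4)
  expect_equal(unname(cnt["AAAA"]), 1)
  expect_equal(unname(cnt["TTTT"]), 1)  # rc-closure: TTTT matches on '-'
  # windows overlapping N are skipped entirely
  cnt <- count_kmers(c(chr1 = "ACGNACG"), 3)
  expect_false(any(grepl("N", names(cnt))))
  expect_equal(unname(cnt["ACG"]), 2)  # two forward occurrences, no rc
})

test_that("extract_pair implements the forward-reverse fragment convention", {
  set.seed(31)
  seq <- random_sequence(200)
  g <- c(chr1 = seq)
  p <- map_params(50, 3, "paired", 200)
  pair <- extract_pair(g, "chr1", 0, p)
  expect_identical(pair$read1, substr(seq, 1, 50))
  expect_identical(pair$read2, revcomp(substr(seq, 151, 200)))
  # the discarded interior gap for the 76 bp / 242 bp library is 90 bp
  p76 <- map_params(76, 3, "paired", 242)
  expect_equal(p76$fragment_length - 2 * p76$read_length, 90)
  # out-of-range and N windows are undefined, not errors
  expect_null(extract_pair(g, "chr1", 1, p))
  gN <- c(chr1 = paste0(substr(seq, 1, 100), "N", substr(seq, 102, 200)))
  expect_null(extract_pair(gN, "chr1", 0, p))
})

test_that("align_all_se is exhaustive and matches a pure-R brute force", {
  g <- rand_genome(300, seed = 32)
  read <- substr(g[[1]], 101, 115)
  hits <- align_all_se(read, g, 0)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$pos, 100)

  # two copies differing by 2 bases are both found at m = 3
  unit <- substr(g[[1]], 1, 30)
  unit2 <- paste0("TT", substr(unit, 3, 30))
  g2 <- c(chr1 = paste0(unit, strrep("N", 5), unit2))
  hits2 <- align_all_se(unit, g2, 3)
  expect_gte(nrow(hits2), 2)
  expect_true(all(c(0, 35) %in% hits2$pos[hits2$strand == "+"]))

  # full equivalence with an independent R implementation
  g3 <- rand_genome(400, seed = 33)
  for (q in c(0, 57, 200)) {
    read <- substr(g3[[1]], q + 1, q + 15)
    got <- sort_placements(align_all_se(read, g3, 2))
    want <- sort_placements(brute_se_placements(read, g3, 2))
    expect_equal(got, want)
  }
})

test_that("align_all_pe enumerates insert-size variants as distinct placements", {
  set.seed(34)
  # unique fragment, fixed insert: exactly the self placement
  g <- rand_genome(500, seed = 35)
  p <- map_params(20, 0, "paired", 60, insert_min = 60, insert_max = 60)
  pr <- extract_pair(g, "chr1", 100, p)
  hits <- align_all_pe(pr$read1, pr$read2, g, p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$s1, 100)
  expect_equal(hits$fragment_len, 60)

  # period-10 tandem: same s1, multiple fragment lengths within the slack
  gt <- tandem_genome(36, unit_len = 10, n_units = 30, flank = 200)
  pt <- map_params(20, 0, "paired", 60, insert_min = 50, insert_max = 70)
  prt <- extract_pair(gt, "chr1", 250, pt)
  ht <- align_all_pe(prt$read1, prt$read2, gt, pt)
  by_s1 <- table(ht$s1[ht$strand == "+"])
  expect_true(any(by_s1 >= 2))  # >= 2 insert sizes at one start
  multi <- ht[ht$strand == "+" & ht$s1 == as.integer(names(which.max(by_s1))), ]
  expect_gte(length(unique(multi$fragment_len)), 2)

  # two exact copies of a fragment-sized window -> 2 placements at m = 0
  set.seed(37)
  frag <- random_sequence(80)
  g2 <- c(chr1 = paste0(random_sequence(200), frag, random_sequence(200), frag,
                        random_sequence(50)))
  p2 <- map_params(20, 0, "paired", 80)
  pr2 <- extract_pair(g2, "chr1", 200, p2)
  expect_equal(nrow(align_all_pe(pr2$read1, pr2$read2, g2, p2)), 2)
})

test_that("tracks are reciprocals of positive integers; 1 iff a single placement", {
  g <- rand_genome(1500, seed = 38)
  for (mode_params in list(map_params(20, 2, method = 2),
                           map_params(20, 1, "paired", 50, method = 2))) {
    tr <- mappability_track(g, mode_params)
    v <- tr$scores$chr1
    def <- v[!is.na(v)]
    expect_true(all(def > 0 & def <= 1))
    inv <- 1 / def
    expect_true(all(abs(inv - round(inv)) < 1e-9))
  }
  # a random genome with no near-duplicate windows scores 1 everywhere defined
  tr <- mappability_track(g, map_params(25, 0, method = 2))
  v <- tr$scores$chr1
  expect_true(all(v[!is.na(v)] == 1))
  # undefined tail: the last r-1 positions have no full window
  expect_true(all(is.na(v[(1500 - 25 + 2):1500])))
})

test_that("N-containing focal windows are undefined", {
  g <- c(chr1 = paste0(strrep("ACGT", 10), "N", strrep("TGCA", 10)))
  tr <- mappability_track(g, map_params(8, 0, method = 2))
  v <- tr$scores$chr1
  # every start whose 8-window covers position 41 (index 41, 0-based 40)
  expect_true(all(is.na(v[34:41])))
  expect_false(is.na(v[33]))
  expect_false(is.na(v[42]))
})

test_that("single-end methods 1 and 2 agree exactly; k-mismatch table is rejected", {
  g <- rand_genome(2000, seed = 39)
  t1 <- mappability_track(g, map_params(20, 2, method = 1))
  t2 <- mappability_track(g, map_params(20, 2, method = 2))
  expect_identical(t1$scores, t2$scores)
  wrong <- count_kmers(g, 19)
  expect_error(mappability_track(g, map_params(20, 2, method = 1), wrong),
               "does not match")
})

test_that("the indexed engine matches the naive oracle on mixed fixtures", {
  # compact mixed fixture: repeats, a tandem, an N patch
  set.seed(40)
  unit <- random_sequence(15)
  rep1 <- random_sequence(60)
  g <- c(chr1 = paste0(random_sequence(200), rep1, random_sequence(100),
                       paste(rep(unit, 8), collapse = ""), "NNN",
                       rep1, random_sequence(150)))
  positions <- seq(0, nchar(g[[1]]) - 60, by = 7)
  for (params in list(map_params(20, 0, method = 1),
                      map_params(20, 2, method = 2),
                      map_params(15, 1, "paired", 45, method = 1),
                      map_params(15, 1, "paired", 45, method = 2))) {
    tr <- mappability_track(g, params)
    for (p in positions) {
      expect_equal(oracle_score(g, "chr1", p, params),
                   tr$scores$chr1[p + 1],
                   label = sprintf("%s method %d p=%d", params$mode,
                                   params$method, p))
    }
  }
})

test_that("single-end scores are non-decreasing in read length", {
  set.seed(41)
  cons <- random_sequence(200)
  cfg <- sim_config(6000, subfamilies = list(
    subfamily_spec("fam", cons, 3, sub_rate = 0.03)), seed = 17)
  sim <- simulate_genome(cfg)
  t1 <- mappability_track(sim$genome, map_params(20, 2, method = 2))
  t2 <- mappability_track(sim$genome, map_params(35, 2, method = 2))
  v1 <- t1$scores$chr1; v2 <- t2$scores$chr1
  common <- !is.na(v1) & !is.na(v2)
  expect_true(all(v2[common] >= v1[common]))
})
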