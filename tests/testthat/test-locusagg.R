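loc <- function(start, end, id, chrom = "chr1", strand = "+",
                subfamily = "X", family = "X", te_class = "TE") {
  data.frame(chrom = chrom, start = start, end = end, strand = strand,
             subfamily = subfamily, family = family, te_class = te_class,
             locus_id = id, stringsAsFactors = FALSE)
}

test_that("score_locus applies the conservative uniqueness rule", {
  tr <- make_track(list(chr1 = c(rep(1, 10), rep(NA, 5))))
  s <- score_locus(tr, loc(0, 10, "a"))
  expect_equal(s$percent_unique, 100)
  expect_true(s$is_unique)

  # one multi-mapping position disqualifies the whole locus
  tr2 <- make_track(list(chr1 = c(rep(1, 5), 0.5, rep(1, 4))))
  s2 <- score_locus(tr2, loc(0, 10, "a"))
  expect_false(s2$is_unique)
  expect_equal(s2$percent_unique, 90)

  # undefined positions are excluded from numerator and denominator
  tr3 <- make_track(list(chr1 = c(rep(1, 9), NA)))
  s3 <- score_locus(tr3, loc(0, 10, "a"))
  expect_equal(s3$n_positions, 9)
  expect_equal(s3$percent_unique, 100)
  expect_true(s3$is_unique)

  # no defined positions: percent missing, not unique
  tr4 <- make_track(list(chr1 = rep(NA_real_, 10)))
  s4 <- score_locus(tr4, loc(0, 10, "a"))
  expect_true(is.na(s4$percent_unique))
  expect_false(s4$is_unique)

  expect_error(score_locus(tr, loc(5, 20, "a")), "off the chromosome")
})

test_that("summaries aggregate and conserve counts across rollup levels", {
  ann <- rbind(
    loc(0, 10, "a1", subfamily = "AluY", family = "Alu", te_class = "SINE"),
    loc(20, 30, "a2", subfamily = "AluY", family = "Alu", te_class = "SINE"),
    loc(40, 50, "a3", subfamily = "AluSx", family = "Alu", te_class = "SINE"),
    loc(60, 70, "l1", subfamily = "L1HS", family = "L1", te_class = "LINE"))
  v <- rep(1, 80); v[25] <- 0.5  # a2 not unique
  tr <- make_track(list(chr1 = v))
  sc <- score_loci(tr, ann)
  sm <- summarize_loci(sc)
  aluy <- sm$subfamily[sm$subfamily$subfamily == "AluY", ]
  expect_equal(aluy$copy_number, 2)
  expect_equal(aluy$percent_loci_unique, 50)
  expect_equal(sum(sm$subfamily$copy_number), nrow(ann))
  expect_equal(sum(sm$family$copy_number), nrow(ann))
  expect_equal(sum(sm$te_class$copy_number), nrow(ann))
  alu <- sm$family[sm$family$family == "Alu", ]
  expect_equal(alu$copy_number, 3)
  # 4 loci, 3 unique
  expect_equal(sum(sm$te_class$copy_number * sm$te_class$percent_loci_unique) / 100, 3)
})

test_that("compare_libraries differences are antisymmetric and validated", {
  ann <- rbind(loc(0, 10, "a"), loc(20, 30, "b"))
  t_hi <- make_track(list(chr1 = rep(1, 40)))
  v <- rep(1, 40); v[1:10] <- 0.5
  t_lo <- make_track(list(chr1 = v))
  sets <- list(pe = score_loci(t_hi, ann), se = score_loci(t_lo, ann))

  same <- compare_libraries(list(x = sets$pe, y = sets$pe))
  expect_true(all(same$diff == 0))

  d <- compare_libraries(sets, pairs = data.frame(a = "pe", b = "se"))
  expect_equal(d$diff[d$locus_id == "a"], 100)
  rev <- compare_libraries(sets, pairs = data.frame(a = "se", b = "pe"))
  expect_equal(d$diff, -rev$diff)

  bad <- sets
  bad$se <- bad$se[bad$se$locus_id != "b", ]
  expect_error(compare_libraries(bad), "b")
})

test_that("a constructed PE-lower locus yields a negative difference", {
  # unique flank positions whose mate falls in a tandem array: read1 is
  # unique (SE = 1) but the pair maps at several insert sizes (PE < 1)
  g <- tandem_genome(51, unit_len = 10, n_units = 30, flank = 300)
  ann <- loc(260, 280, "edge")
  se <- mappability_track(g, map_params(20, 0, method = 2))
  pe <- mappability_track(g, map_params(20, 0, "paired", 60,
                                        insert_min = 50, insert_max = 70,
                                        method = 2))
  d <- compare_libraries(list(pe = score_loci(pe, ann),
                              se = score_loci(se, ann)),
                         pairs = data.frame(a = "pe", b = "se"))
  expect_lt(d$diff, 0)
})

test_that("filter_for_comparison drops saturated and short loci", {
  ann <- rbind(loc(0, 250, "short"),     # < 300 bp
               loc(300, 700, "sat"),     # all PE libraries at 100
               loc(800, 1200, "keep"))
  mk <- function(p) {
    s <- score_loci(make_track(list(chr1 = rep(1, 1300))), ann)
    s$percent_unique <- p
    s
  }
  sets <- list(pe50 = mk(c(100, 100, 100)),
               pe76 = mk(c(100, 100, 99)),
               pe100 = mk(c(100, 100, 100)))
  kept <- filter_for_comparison(ann, sets, paired = names(sets))
  expect_identical(kept$locus_id, "keep")
})

test_that("unique flanks cannot flip a non-unique locus to unique", {
  v <- c(rep(1, 20), rep(0.5, 10), rep(1, 20))
  tr <- make_track(list(chr1 = v))
  core <- score_locus(tr, loc(20, 30, "core"))
  extended <- score_locus(tr, loc(10, 40, "ext"))
  expect_false(core$is_unique)
  expect_false(extended$is_unique)
  expect_gt(extended$percent_unique, core$percent_unique)
})
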