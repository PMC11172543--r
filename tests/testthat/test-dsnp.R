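test_that("the three-filter truth table retains only fully qualifying SNPs", {
  ann <- rbind(
    make_ann("1H", 100, transcript = "A.1", sift_class = "deleterious",
             sift_score = 0.01),                        # in
    make_ann("1H", 200, transcript = "B.1", sift_class = "tolerated",
             sift_score = 0.2),                         # SIFT fails
    make_ann("1H", 300, transcript = "C.1", sift_class = "deleterious",
             sift_score = 0.01),                        # RS fails
    make_ann("1H", 400, transcript = "D.1", canonical = FALSE,
             sift_class = "deleterious", sift_score = 0.01),  # canonical
    make_ann("1H", 500, transcript = "E.1",
             consequence = "synonymous_variant"))       # consequence
  track <- make_track(rep("1H", 5), c(100, 200, 300, 400, 500),
                      c(1.2, 2.0, -0.5, 1.0, 3.0))
  ds <- identify_dsnps(ann, track)
  expect_equal(n_dsnps(ds), 1L)
  expect_equal(ds$pos, 100)
  expect_equal(ds$rs_score, 1.2)
})

test_that("RS threshold is strict and SIFT threshold inclusive by default", {
  ann <- rbind(
    make_ann("1H", 100, sift_class = "deleterious", sift_score = 0.05),
    make_ann("1H", 200, sift_class = "deleterious", sift_score = 0.01))
  track <- make_track(c("1H", "1H"), c(100, 200), c(1.0, 0.0))
  ds <- identify_dsnps(ann, track)
  # pos 100: SIFT exactly 0.05 qualifies (<=); pos 200: RS exactly 0 fails
  expect_equal(ds$pos, 100)
  # strict SIFT mode excludes the boundary score
  expect_equal(n_dsnps(identify_dsnps(ann, track, sift_strict = TRUE)), 0L)
})

test_that("a position absent from the constraint track fails the RS filter", {
  ann <- make_ann("5H", 42, sift_class = "deleterious", sift_score = 0.001)
  ds <- identify_dsnps(ann, make_track("1H", 1, 2.5))
  expect_equal(n_dsnps(ds), 0L)
  expect_equal(n_dsnps(identify_dsnps(ann[0, ], make_track("1H", 1, 2.5))),
               0L)
})

test_that("when every filter passes, L equals the canonical missense count", {
  n <- 12
  ann <- make_ann(chrom = rep("2H", n), pos = 1:n * 10,
                  transcript = paste0("T", 1:n),
                  sift_class = "deleterious",
                  sift_score = runif(n, 0, 0.05))
  track <- make_track(rep("2H", n), 1:n * 10, runif(n, 0.1, 4))
  expect_equal(n_dsnps(identify_dsnps(ann, track)), n)
})

test_that("dSNP filter equals brute-force predicate evaluation on random tables", {
  set.seed(401)
  for (rep in 1:20) {
    case <- random_annotation_case(sample(5:100, 1))
    sift_max <- sample(c(0.05, 0.3, 0.8), 1)
    rs_min <- sample(c(0, 0.5), 1)
    canonical_only <- sample(c(TRUE, FALSE), 1)
    ds <- identify_dsnps(case$ann, case$track, sift_max = sift_max,
                         rs_min = rs_min, canonical_only = canonical_only)
    got <- sort(paste(ds$chrom, ds$pos, ds$alt, sep = ":"))
    want <- brute_dsnp_keys(case$ann, case$track, sift_max = sift_max,
                            rs_min = rs_min,
                            canonical_only = canonical_only)
    expect_equal(got, want)
  }
})

test_that("tightening either threshold never increases L", {
  set.seed(402)
  for (rep in 1:10) {
    case <- random_annotation_case(80)
    L <- function(s, r) n_dsnps(identify_dsnps(case$ann, case$track,
                                               sift_max = s, rs_min = r))
    expect_true(L(0.05, 0) >= L(0.01, 0))
    expect_true(L(0.5, 0) >= L(0.05, 0))
    expect_true(L(0.5, 0) >= L(0.5, 1))
    expect_true(L(0.05, 0.5) >= L(0.01, 1.5))
  }
})

test_that("consequence tallies cover the closed vocabulary and LOF sum", {
  empty <- tally_consequences(make_ann())
  expect_equal(empty$total, 0L)
  expect_equal(empty$lof_total, 0L)
  expect_true(all(empty$counts == 0L))

  ann <- make_ann(chrom = rep("1H", 6), pos = 1:6,
                  consequence = c("stop_gained", "stop_gained",
                                  "splice_region_variant",
                                  "missense_variant",
                                  "synonymous_variant", "intron_variant"))
  tl <- tally_consequences(ann)
  expect_equal(unname(tl$counts["stop_gained"]), 2L)
  expect_equal(tl$lof_total, 3L)
  expect_equal(tl$total, 6L)
})

test_that("per-SNP tallying keeps one most-severe consequence per locus", {
  ann <- rbind(
    make_ann("1H", 100, transcript = "t1",
             consequence = "missense_variant"),
    make_ann("1H", 100, transcript = "t2", consequence = "stop_gained"),
    make_ann("1H", 100, transcript = "t3",
             consequence = "intron_variant"),
    make_ann("2H", 50, transcript = "t4",
             consequence = "synonymous_variant"))
  per_ann <- tally_consequences(ann, per_snp = FALSE)
  per_snp <- tally_consequences(ann, per_snp = TRUE)
  expect_equal(per_ann$total, 4L)
  expect_equal(per_snp$total, 2L)
  expect_equal(unname(per_snp$counts["stop_gained"]), 1L)
  expect_equal(unname(per_snp$counts["missense_variant"]), 0L)
})

test_that("SIFT tallies count the four classes", {
  ann <- make_ann(chrom = rep("1H", 6), pos = 1:6,
                  sift_class = c("deleterious", "deleterious",
                                 "tolerated_low_confidence",
                                 "tolerated_low_confidence",
                                 "tolerated_low_confidence",
                                 NA),
                  sift_score = c(0.0, 0.01, 0.4, 0.5, 0.6, NA))
  ts <- tally_sift(ann)
  expect_equal(unname(ts$counts["deleterious"]), 2L)
  expect_equal(unname(ts$counts["tolerated_low_confidence"]), 3L)
  expect_equal(ts$total, 5L)
  one <- tally_sift(make_ann("1H", 1, sift_class = "tolerated",
                             sift_score = 0.3))
  expect_equal(unname(one$counts["tolerated"]), 1L)
  expect_equal(one$total, 1L)
})

test_that("per-chromosome counts conserve L", {
  ds <- identify_dsnps(
    make_ann(chrom = c("1H", "1H", "2H"), pos = c(1, 2, 3),
             transcript = paste0("t", 1:3), sift_class = "deleterious",
             sift_score = 0.01),
    make_track(c("1H", "1H", "2H"), c(1, 2, 3), c(1, 1, 1)))
  expect_equal(per_chromosome_counts(ds), c("1H" = 2L, "2H" = 1L))

  b <- shared_bundle()
  ds2 <- identify_dsnps(b$annotations, b$constraint)
  expect_equal(sum(per_chromosome_counts(ds2)), n_dsnps(ds2))
})
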