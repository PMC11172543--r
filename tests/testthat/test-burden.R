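dset_for <- function(gm) {
  out <- data.frame(chrom = gm$loci$chrom, pos = gm$loci$pos,
                    ref = gm$loci$ref, alt = gm$loci$alt,
                    gene = NA_character_, transcript = NA_character_,
                    sift_score = NA_real_, rs_score = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("dsnp_set", "data.frame")
  out
}

test_that("deleterious genotype counts follow the dosage codes", {
  gm <- make_gm(rbind(c(2, 2, 1, 0),
                      c(0, 0, 0, 0),
                      c(NA, NA, NA, NA)))
  cnt <- count_deleterious_genotypes(gm, dset_for(gm))
  expect_equal(cnt$n_hom, c(2L, 0L, 0L))
  expect_equal(cnt$n_het, c(1L, 0L, 0L))
})

test_that("a dSNP locus missing from the matrix errors with its name", {
  gm <- make_gm(rbind(c(0, 1)))
  ds <- dset_for(gm)
  ds$pos[2] <- 999L
  expect_error(count_deleterious_genotypes(gm, ds), "1H:999")
})

test_that("burden statistics follow the 2h, e over 2L formulation", {
  b <- burden(13, 0, 407)
  expect_equal(b$total_burden, 26 / 814)
  expect_equal(b$hom_burden, 26 / 814)
  expect_equal(b$het_burden, 0)

  z <- burden(0, 0, 50)
  expect_equal(unlist(z), c(hom_burden = 0, het_burden = 0,
                            total_burden = 0))

  expect_error(burden(1, 1, 0), "positive")
  expect_error(burden(-1, 0, 10), "non-negative")
  expect_error(burden(6, 5, 10), "exceed")
})

test_that("total burden is exactly the sum of its parts and scales as 1/L", {
  set.seed(21)
  for (rep in 1:50) {
    L <- sample(1:500, 1)
    h <- sample(0:L, 1)
    e <- sample(0:(L - h), 1)
    b <- burden(h, e, L)
    expect_identical(b$total_burden, b$hom_burden + b$het_burden)
    b2 <- burden(h, e, 2 * L)
    expect_equal(b2$total_burden, b$total_burden / 2)
    expect_equal(b2$hom_burden, b$hom_burden / 2)
    expect_equal(b2$het_burden, b$het_burden / 2)
  }
})

test_that("cohort mean burden equals the burden of the mean counts", {
  b <- shared_bundle()
  ds <- identify_dsnps(b$annotations, b$constraint)
  est <- burden_estimates(b$genotypes, ds)
  expect_equal(mean(est$total_burden),
               burden(mean(est$n_hom), mean(est$n_het),
                      n_dsnps(ds))$total_burden,
               tolerance = 1e-12)
})

test_that("missing genotypes count as non-carriers; per-sample policy shrinks L", {
  gm <- make_gm(rbind(c(2, NA, 1, NA),
                      c(2, 2, 2, 2)))
  ds <- dset_for(gm)
  est <- burden_estimates(gm, ds)
  expect_equal(est$total_burden, c((2 * 1 + 1) / 8, 1))
  est2 <- burden_estimates(gm, ds, missing_policy = "per_sample")
  expect_equal(est2$total_burden, c((2 * 1 + 1) / 4, 1))

  all_missing <- make_gm(rbind(c(NA, NA), c(0, 1)))
  expect_error(burden_estimates(all_missing, dset_for(all_missing),
                                missing_policy = "per_sample"),
               "no called dSNP genotypes")
})

test_that("zero-burden samples are exactly those with no deleterious alleles", {
  est <- data.frame(sample = c("a", "b"), n_het = c(0L, 0L),
                    n_hom = c(0L, 1L),
                    burden(c(0, 1), c(0, 0), 10))
  expect_equal(zero_burden_samples(est), "a")
  expect_equal(zero_burden_samples(est[0, ]), character(0))

  # planted all-reference samples in a synthetic cohort
  b <- generate_bundle(synthetic_config(n_samples = 60, n_loci = 100,
                                        n_dsnp = 10, seed = 5))
  ds <- identify_dsnps(b$annotations, b$constraint)
  est2 <- burden_estimates(b$genotypes, ds)
  planted_zero <- b$truth_samples$sample[b$truth_samples$n_hom == 0 &
                                           b$truth_samples$n_het == 0]
  expect_setequal(zero_burden_samples(est2), planted_zero)
})

test_that("carrier frequency is the carrier fraction carriers / N", {
  gm <- make_gm(rbind(c(2, 1, 0),
                      c(0, 1, 0),
                      c(0, 2, 0),
                      c(0, 0, 0)))
  sp <- carrier_spectrum(gm, dset_for(gm))
  expect_equal(sp$loci$carrier_count, c(1L, 3L, 0L))
  expect_equal(sp$loci$carrier_frequency, c(1, 3, 0) / 4)
  expect_equal(sum(sp$bins$count), n_dsnps(dset_for(gm)))

  all_carriers <- make_gm(matrix(2, nrow = 3, ncol = 2))
  sp2 <- carrier_spectrum(all_carriers, dset_for(all_carriers))
  expect_true(all(sp2$loci$carrier_frequency == 1))
})

test_that("rarity thresholds report 1-, 5- and 20-carrier fractions", {
  b <- shared_bundle()
  ds <- identify_dsnps(b$annotations, b$constraint)
  sp <- carrier_spectrum(b$genotypes, ds)
  counts <- sp$loci$carrier_count
  expect_equal(sp$rarity$n_dsnps,
               c(sum(counts <= 1), sum(counts <= 5), sum(counts <= 20)))
  expect_equal(sp$rarity$max_frequency, c(1, 5, 20) / sp$N)
  expect_equal(sum(sp$bins$count), n_dsnps(ds))
})
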