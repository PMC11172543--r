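vcf_text <- function(records, samples) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records)
}

write_vcf_fixture <- function(records, samples) {
  path <- tempfile(fileext = ".vcf")
  writeLines(vcf_text(records, samples), path)
  path
}

test_that("GT fields map to alt-allele dosages with missing as NA", {
  p <- write_vcf_fixture(
    "1H\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t./.\t1/1",
    paste0("s", 1:4))
  gm <- read_genotypes(p)
  expect_equal(unname(gm$dosage[, 1]), c(0L, 1L, NA, 2L))
  expect_equal(gm$samples, paste0("s", 1:4))

  p1 <- write_vcf_fixture("1H\t100\t.\tA\tG\t.\tPASS\t.\tGT\t1/1", "only")
  expect_equal(unname(read_genotypes(p1)$dosage), matrix(2L, 1, 1))
})

test_that("phased and unphased genotypes are equivalent", {
  pu <- write_vcf_fixture(
    "1H\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1/1", c("a", "b"))
  pp <- write_vcf_fixture(
    "1H\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1", c("a", "b"))
  expect_equal(read_genotypes(pu)$dosage, read_genotypes(pp)$dosage)
})

test_that("multi-allelic and non-SNP records error or skip on request", {
  recs <- c("1H\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1",
            "1H\t200\t.\tA\tG,T\t.\tPASS\t.\tGT\t0/1",
            "1H\t300\t.\tAT\tA\t.\tPASS\t.\tGT\t0/1")
  p <- write_vcf_fixture(recs, "s1")
  expect_error(read_genotypes(p), "1H:200")
  expect_warning(gm <- read_genotypes(p, skip_nonbiallelic = TRUE),
                 "skipping 2")
  expect_equal(nrow(gm$loci), 1L)
  expect_equal(gm$loci$pos, 100L)
})

test_that("synthetic VCF round-trips dosages and ordering exactly", {
  b <- generate_bundle(synthetic_config(n_samples = 10, n_loci = 20,
                                        n_dsnp = 4, seed = 11))
  p <- tempfile(fileext = ".vcf")
  write_genotypes(b$genotypes, p)
  back <- read_genotypes(p)
  expect_equal(back$dosage, b$genotypes$dosage)
  expect_equal(back$samples, b$genotypes$samples)
  expect_equal(back$loci$chrom, b$genotypes$loci$chrom)
  expect_equal(back$loci$pos, b$genotypes$loci$pos)
})

test_that("every dosage is a legal code and per-locus codes sum to N", {
  gm <- shared_bundle()$genotypes
  expect_true(all(gm$dosage %in% c(0L, 1L, 2L, NA)))
  n0 <- colSums(gm$dosage == 0L, na.rm = TRUE)
  n1 <- colSums(gm$dosage == 1L, na.rm = TRUE)
  n2 <- colSums(gm$dosage == 2L, na.rm = TRUE)
  nm <- colSums(is.na(gm$dosage))
  expect_true(all(n0 + n1 + n2 + nm == length(gm$samples)))
})

test_that("annotation SIFT fields parse to class and score", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Location\tAllele\tGene\tFeature\tConsequence\tCANONICAL\tSIFT",
    "1H:100\tG\tg1\tg1.1\tmissense_variant\tYES\tdeleterious(0.01)",
    "1H:200\tT\tg2\tg2.1\tsynonymous_variant\tYES\t-",
    "2H:300\tA\tg3\tg3.1\tmissense_variant\t-\ttolerated(0.34)",
    "2H:400\tC\tg3\tg3.2\tmissense_variant\tYES\tdeleterious_low_confidence(0.02)",
    "3H:500\tG\tg4\tg4.1\tintron_variant\tYES\t"), path)
  ann <- read_annotations(path)
  expect_equal(nrow(ann), 5L)
  expect_equal(ann$sift_class[1], "deleterious")
  expect_equal(ann$sift_score[1], 0.01)
  expect_true(is.na(ann$sift_score[2]) && is.na(ann$sift_class[2]))
  expect_equal(ann$canonical, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(ann$sift_class[4], "deleterious_low_confidence")
  expect_true(is.na(ann$sift_score[5]))
})

test_that("malformed SIFT errors with line number; unknown consequence warns", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Location\tAllele\tGene\tFeature\tConsequence\tCANONICAL\tSIFT",
    "1H:100\tG\tg1\tg1.1\tmissense_variant\tYES\tdeleterious(0.01)",
    "1H:200\tT\tg2\tg2.1\tmissense_variant\tYES\tdeleterious(oops"), path)
  expect_error(read_annotations(path), "line 3")

  path2 <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Location\tAllele\tGene\tFeature\tConsequence\tCANONICAL\tSIFT",
    "1H:100\tG\tg1\tg1.1\tframeshift_variant\tYES\t-"), path2)
  expect_warning(ann <- read_annotations(path2), "frameshift_variant")
  expect_equal(ann$consequence, "other")
})

test_that("comma-separated consequence terms collapse to the most severe", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "Location\tAllele\tGene\tFeature\tConsequence\tCANONICAL\tSIFT",
    "1H:100\tG\tg1\tg1.1\tsplice_region_variant,intron_variant\tYES\t-"),
    path)
  expect_equal(read_annotations(path)$consequence,
               "splice_region_variant")
})

test_that("constraint track lookup returns scores or NA and rejects conflicts", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tscore", "1H\t100\t1.5", "1H\t100\t1.5",
               "2H\t50\t-0.3"), path)
  tr <- read_constraint(path)
  expect_equal(nrow(tr), 2L)  # exact duplicate collapsed
  expect_equal(constraint_lookup(tr, "1H", 100), 1.5)
  expect_true(is.na(constraint_lookup(tr, "1H", 101)))
  expect_equal(constraint_lookup(tr, c("2H", "1H"), c(50, 100)),
               c(-0.3, 1.5))

  bad <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tscore", "1H\t100\t1.5", "1H\t100\t2.0"), bad)
  expect_error(read_constraint(bad), "1H:100")
})

test_that("passport regions fill from a country mapping and group counts match", {
  path <- tempfile(fileext = ".csv")
  writeLines(c(
    "sample,panel,material_type,growth_habit,row_type,country,region,core_flag",
    "s1,P,Landrace,Spring,Two-rowed,Ethiopia,,Non-core",
    "s2,P,Landrace,Spring,Two-rowed,Ethiopia,,Non-core",
    "s3,P,Cultivar,Winter,Six-rowed,Ethiopia,,Core",
    "s4,P,Cultivar,Winter,Six-rowed,Ethiopia,,Core",
    "s5,P,Landrace,Spring,Two-rowed,Japan,,Non-core",
    "s6,P,Cultivar,Spring,Two-rowed,Japan,,Non-core"), path)
  pp <- read_passport(path, region_map = c(Ethiopia = "regionA",
                                           Japan = "regionB"))
  expect_equal(unname(table(pp$region)["regionA"]), 4L)
  expect_equal(unname(table(pp$region)["regionB"]), 2L)

  # without a mapping, blanks become Unknown
  pp2 <- read_passport(path)
  expect_true(all(pp2$region == "Unknown"))
})

test_that("passport samples absent from genotypes warn but are retained", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample,country", "s1,Ethiopia", "s2,Japan", "ghost,Chad"),
             path)
  pp <- read_passport(path)
  expect_equal(nrow(pp), 3L)
  expect_warning(al <- align_passport(pp, c("s1", "s2", "s9")), "ghost")
  expect_equal(al$sample, c("s1", "s2", "s9"))
  expect_equal(al$country, c("Ethiopia", "Japan", "Unknown"))
})
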