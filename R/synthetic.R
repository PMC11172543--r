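## Small country -> region vocabulary used for synthetic passports. The
## real agri-ecological classification is user-supplied input data; this
## synthetic stand-in only needs to be internally consistent.
SYN_REGION_MAP <- c(
  "Germany" = "European-Siberian Centre",
  "Sweden" = "European-Siberian Centre",
  "Ethiopia" = "Ethiopian Centre",
  "Japan" = "East Asiatic Centre",
  "Nepal" = "East Asiatic Centre",
  "Turkey" = "Near Eastern Centre",
  "Syria" = "Near Eastern Centre",
  "Morocco" = "Mediterranean Centre",
  "Spain" = "Mediterranean Centre",
  "Iran" = "Middle Asian Centre",
  "Afghanistan" = "Middle Asian Centre",
  "USA" = "New World Centre",
  "Canada" = "New World Centre"
)

#' Configuration for the synthetic input generator
#'
#' Defines the statistical structure of a generated cohort: a
#' predominantly homozygous inbred crop genotyped at a sparse SNP panel,
#' a small planted set of deleterious loci with a strongly skewed
#' carrier-count spectrum, around 2.9% missing calls, additive group-level
#' burden differences, and a few exact-duplicate accessions.
#'
#' @param n_samples number of samples (default 500).
#' @param n_loci number of SNP loci (default 2000).
#' @param n_dsnp number of planted deleterious loci (default 50); must
#'   not exceed `n_loci`.
#' @param carrier_zipf_s Zipf mass parameter for carrier counts (default
#'   1.5; larger values skew the spectrum toward rare alleles).
#' @param carrier_max_fraction largest carrier fraction a locus may reach
#'   (default 0.2).
#' @param target_rare_fraction optional target fraction of dSNPs with
#'   carrier fraction at or below `rare_threshold`; `NULL` (default)
#'   draws all counts from one Zipf law.
#' @param rare_threshold carrier-fraction rarity cutoff (default 0.001).
#' @param selfing_rate probability that a carrier is homozygous (default
#'   0.99, emulating a highly inbred crop).
#' @param missing_rate per-call missing probability (default 0.029).
#' @param group_spec planted group structure: a list with `variable` (a
#'   passport column name), `proportions` (named, summing to 1) and
#'   `effects` (named positive weights; a sample's weight multiplies its
#'   chance of being drawn as a carrier, so expected burden scales with
#'   it).
#' @param n_duplicate_clusters number of exact-duplicate sample pairs
#'   planted to give the APD distribution a redundant tail (default 5).
#' @param seed integer RNG seed; identical seed and config give
#'   byte-identical output files.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 500L, n_loci = 2000L,
                             n_dsnp = 50L, carrier_zipf_s = 1.5,
                             carrier_max_fraction = 0.2,
                             target_rare_fraction = NULL,
                             rare_threshold = 0.001,
                             selfing_rate = 0.99, missing_rate = 0.029,
                             group_spec = list(
                               variable = "material_type",
                               proportions = c(Landrace = 0.6,
                                               Cultivar = 0.3,
                                               Breeding_material = 0.1),
                               effects = c(Landrace = 1.3, Cultivar = 1.0,
                                           Breeding_material = 0.85)),
                             n_duplicate_clusters = 5L, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              n_loci = as.integer(n_loci), n_dsnp = as.integer(n_dsnp),
              carrier_zipf_s = carrier_zipf_s,
              carrier_max_fraction = carrier_max_fraction,
              target_rare_fraction = target_rare_fraction,
              rare_threshold = rare_threshold,
              selfing_rate = selfing_rate, missing_rate = missing_rate,
              group_spec = group_spec,
              n_duplicate_clusters = as.integer(n_duplicate_clusters),
              seed = as.integer(seed))
  if (cfg$n_dsnp > cfg$n_loci)
    stop("n_dsnp cannot exceed n_loci", call. = FALSE)
  rates <- c(cfg$selfing_rate, cfg$missing_rate, cfg$carrier_max_fraction)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]", call. = FALSE)
  gs <- cfg$group_spec
  if (!is.null(gs)) {
    if (is.null(names(gs$proportions)) ||
        !setequal(names(gs$proportions), names(gs$effects)))
      stop("group_spec proportions and effects must share group names",
           call. = FALSE)
    if (any(gs$effects <= 0)) stop("group effects must be positive",
                                   call. = FALSE)
  }
  class(cfg) <- "synthetic_config"
  cfg
}

#' Draw a planted carrier-count spectrum
#'
#' Draws per-dSNP carrier counts from a Zipf-like law over
#' `1..floor(carrier_max_fraction * n_samples)`. When
#' `target_rare_fraction` is supplied, each locus is rare (carrier
#' fraction at or below `rare_threshold`) with that probability, and its
#' count is drawn from the Zipf law restricted to the rare or the common
#' range accordingly; at 400+ loci the realized rare fraction falls
#' within about +/-0.05 of the target.
#'
#' @param n_dsnp number of deleterious loci.
#' @param n_samples cohort size.
#' @param target_rare_fraction optional rare-mass target in (0, 1).
#' @param rare_threshold carrier-fraction rarity cutoff (default 0.001).
#' @param zipf_s Zipf mass parameter (default 1.5).
#' @param max_fraction largest carrier fraction (default 0.2).
#' @return integer vector of carrier counts (length `n_dsnp`).
#' @export
plant_spectrum <- function(n_dsnp, n_samples,
                           target_rare_fraction = NULL,
                           rare_threshold = 0.001, zipf_s = 1.5,
                           max_fraction = 0.2) {
  n_dsnp <- as.integer(n_dsnp)
  if (n_dsnp == 0L) return(integer(0))
  max_count <- max(1L, as.integer(floor(max_fraction * n_samples)))
  zipf_draw <- function(n, lo, hi) {
    k <- lo:hi
    w <- k^(-zipf_s)
    k[sample.int(length(k), n, replace = TRUE, prob = w)]
  }
  if (is.null(target_rare_fraction))
    return(zipf_draw(n_dsnp, 1L, max_count))
  if (target_rare_fraction <= 0 || target_rare_fraction >= 1)
    stop("target_rare_fraction must lie in (0, 1)", call. = FALSE)
  max_rare <- as.integer(floor(rare_threshold * n_samples))
  if (max_rare < 1L)
    stop("infeasible rarity target: one carrier already exceeds ",
         "carrier fraction ", rare_threshold, " at n_samples = ",
         n_samples, call. = FALSE)
  lo_common <- max_rare + 1L
  hi_common <- max(lo_common, max_count)
  rare <- stats::runif(n_dsnp) < target_rare_fraction
  counts <- integer(n_dsnp)
  if (any(rare)) counts[rare] <- zipf_draw(sum(rare), 1L, max_rare)
  if (any(!rare)) counts[!rare] <- zipf_draw(sum(!rare), lo_common,
                                             hi_common)
  counts
}

#' Plant group structure and build a synthetic passport
#'
#' Assigns each sample to a group of `group_spec$variable` with the
#' configured proportions, fills the remaining passport descriptors from
#' small fixed vocabularies, and reports the planted per-group carrier
#' weight, whose ordering the realized group mean burdens follow in
#' expectation.
#'
#' Called inside [generate_bundle] under its seed; seed the RNG yourself
#' for standalone use.
#'
#' @param config a [synthetic_config].
#' @return list with `passport` (a `passport_table`-shaped data.frame),
#'   `weights` (per-sample carrier weight) and `expected` (per-group
#'   `group`, `n`, `weight`, `relative_burden`).
#' @export
plant_groups <- function(config) {
  n <- config$n_samples
  samples <- sprintf("S%05d", seq_len(n))
  gs <- config$group_spec
  if (is.null(gs)) {
    group <- rep("All", n)
    effects <- c(All = 1)
    variable <- "material_type"
  } else {
    variable <- gs$variable
    props <- gs$proportions / sum(gs$proportions)
    counts <- diff(round(cumsum(c(0, props)) * n))
    group <- rep(names(props), counts)
    keep <- counts > 0L
    counts <- counts[keep]
    effects <- gs$effects[names(props)][keep]
  }
  weights <- unname(effects[group])
  pass <- data.frame(sample = samples,
                     panel = sample(c("Genebank_A", "Genebank_B"), n,
                                    replace = TRUE, prob = c(0.9, 0.1)),
                     material_type = "Unknown",
                     growth_habit = sample(c("Spring", "Winter",
                                             "Intermediate"), n,
                                           replace = TRUE,
                                           prob = c(0.72, 0.2, 0.08)),
                     row_type = sample(c("Two-rowed", "Six-rowed",
                                         "Intermedium"), n,
                                       replace = TRUE,
                                       prob = c(0.35, 0.55, 0.1)),
                     country = sample(names(SYN_REGION_MAP), n,
                                      replace = TRUE),
                     region = NA_character_,
                     core_flag = sample(c("Core", "Non-core"), n,
                                        replace = TRUE, prob = c(0.05,
                                                                 0.95)),
                     stringsAsFactors = FALSE)
  pass$region <- unname(SYN_REGION_MAP[pass$country])
  pass[[variable]] <- group
  n_g <- if (is.null(gs)) n else as.integer(counts)
  expected <- data.frame(group = names(effects),
                         n = n_g,
                         weight = unname(effects),
                         relative_burden = unname(effects) /
                           sum(effects * n_g / n),
                         stringsAsFactors = FALSE)
  list(passport = pass, weights = weights, expected = expected,
       variable = variable)
}

## Deterministic fixed-format writers (LF endings, fixed decimals) so a
## given seed + config reproduces output files byte for byte.
write_lines_lf <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

write_tsv_fixed <- function(df, path) {
  header <- paste(names(df), collapse = "\t")
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  write_lines_lf(c(header, body), path)
}

#' Generate a complete synthetic input bundle
#'
#' Builds an internally consistent set of pipeline inputs — a VCF
#' genotype matrix, a per-(variant, transcript) annotation TSV, a
#' constraint-score TSV, a passport CSV — plus truth tables recording the
#' planted dSNP loci, per-sample deleterious genotype counts and
#' per-locus carrier counts.
#'
#' The planted dSNPs are exactly the loci whose annotation passes the
#' identification filters (canonical missense, SIFT <= 0.05, RS > 0);
#' every decoy locus fails at least one filter, cycling through the five
#' failure modes (tolerated SIFT, non-canonical transcript, position
#' absent from the constraint track, non-positive RS, non-missense
#' consequence). Genotypes are placed per locus by drawing the planted
#' number of carriers without replacement (weighted by the planted group
#' effects), so locus-level truth is exact rather than expected; carriers
#' are homozygous with probability `selfing_rate`. Missing calls are then
#' masked at `missing_rate`, and duplicate clusters are planted by
#' copying finished sample rows. Truth tables are computed from the final
#' matrix, so planted-recovery checks are exact under the
#' missing-as-noncarrier counting convention.
#'
#' @param config a [synthetic_config].
#' @param outdir optional directory; when given, writes `genotypes.vcf`,
#'   `annotations.tsv`, `constraint.tsv`, `passport.csv`,
#'   `region_map.csv`, `truth_samples.tsv`, `truth_loci.tsv`.
#' @return list of class `synthetic_bundle` with the in-memory objects
#'   (`genotypes`, `annotations`, `constraint`, `passport`, `dsnp_loci`,
#'   `truth_samples`, `truth_loci`, `expected_groups`, `group_variable`,
#'   `config`, and `paths` when `outdir` was given).
#' @export
generate_bundle <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  N <- config$n_samples
  M <- config$n_loci

  # loci spread over 7 chromosomes, positions unique within chromosome
  chroms <- paste0(1:7, "H")
  chrom <- sort(sample(chroms, M, replace = TRUE))
  pos <- integer(M)
  for (ch in chroms) {
    i <- which(chrom == ch)
    pos[i] <- sort(sample.int(5e7, length(i)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L),
                character(1))
  loci <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     id = sprintf("snp%05d", seq_len(M)),
                     stringsAsFactors = FALSE)
  is_dsnp <- logical(M)
  is_dsnp[sample.int(M, config$n_dsnp)] <- TRUE

  grp <- plant_groups(config)

  # carrier counts: planted spectrum at dSNPs, one shared Zipf law at
  # decoys (decoy loci carry ordinary variation)
  counts <- integer(M)
  counts[is_dsnp] <- plant_spectrum(
    config$n_dsnp, N, config$target_rare_fraction, config$rare_threshold,
    config$carrier_zipf_s, config$carrier_max_fraction)
  counts[!is_dsnp] <- plant_spectrum(
    M - config$n_dsnp, N, NULL, config$rare_threshold,
    config$carrier_zipf_s, config$carrier_max_fraction)

  dosage <- matrix(0L, N, M)
  for (j in seq_len(M)) {
    carriers <- sample.int(N, counts[j], prob = grp$weights)
    hom <- stats::runif(counts[j]) < config$selfing_rate
    dosage[carriers, j] <- ifelse(hom, 2L, 1L)
  }
  if (config$missing_rate > 0)
    dosage[stats::runif(N * M) < config$missing_rate] <- NA_integer_

  # duplicate clusters: copy finished rows so duplicates are exact
  if (config$n_duplicate_clusters > 0 && N >= 2L) {
    k <- min(config$n_duplicate_clusters, floor(N / 2))
    picks <- sample.int(N, 2L * k)
    for (i in seq_len(k))
      dosage[picks[2L * i], ] <- dosage[picks[2L * i - 1L], ]
  }

  gm <- genotype_matrix(dosage, loci, grp$passport$sample)

  ann <- build_synthetic_annotations(loci, is_dsnp)
  constraint <- ann$constraint
  annotations <- ann$parsed

  d <- dosage[, is_dsnp, drop = FALSE]
  truth_samples <- data.frame(
    sample = grp$passport$sample,
    group = grp$passport[[grp$variable]],
    n_hom = as.integer(rowSums(d == 2L, na.rm = TRUE)),
    n_het = as.integer(rowSums(d == 1L, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  truth_loci <- data.frame(
    chrom = loci$chrom, pos = loci$pos, alt = loci$alt,
    is_dsnp = is_dsnp, planted_carriers = counts,
    carrier_count = as.integer(colSums(dosage >= 1L, na.rm = TRUE)),
    allele_count = as.integer(colSums(dosage, na.rm = TRUE)),
    stringsAsFactors = FALSE)

  bundle <- list(genotypes = gm, annotations = annotations,
                 constraint = constraint, passport = grp$passport,
                 dsnp_loci = loci[is_dsnp, , drop = FALSE],
                 truth_samples = truth_samples, truth_loci = truth_loci,
                 expected_groups = grp$expected,
                 group_variable = grp$variable, config = config)
  class(bundle) <- "synthetic_bundle"

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      vcf = file.path(outdir, "genotypes.vcf"),
      annotations = file.path(outdir, "annotations.tsv"),
      constraint = file.path(outdir, "constraint.tsv"),
      passport = file.path(outdir, "passport.csv"),
      region_map = file.path(outdir, "region_map.csv"),
      truth_samples = file.path(outdir, "truth_samples.tsv"),
      truth_loci = file.path(outdir, "truth_loci.tsv"))
    write_genotypes(gm, paths$vcf)
    write_tsv_fixed(ann$file, paths$annotations)
    write_tsv_fixed(data.frame(chrom = constraint$chrom,
                               pos = constraint$pos,
                               score = sprintf("%.4f", constraint$rs)),
                    paths$constraint)
    pass_out <- grp$passport
    write_lines_lf(c(paste(names(pass_out), collapse = ","),
                     do.call(paste, c(pass_out, sep = ","))),
                   paths$passport)
    write_lines_lf(c("country,region",
                     paste(names(SYN_REGION_MAP), SYN_REGION_MAP,
                           sep = ",")), paths$region_map)
    write_tsv_fixed(truth_samples, paths$truth_samples)
    write_tsv_fixed(data.frame(
      chrom = truth_loci$chrom, pos = truth_loci$pos,
      alt = truth_loci$alt,
      is_dsnp = ifelse(truth_loci$is_dsnp, "TRUE", "FALSE"),
      planted_carriers = truth_loci$planted_carriers,
      carrier_count = truth_loci$carrier_count,
      allele_count = truth_loci$allele_count), paths$truth_loci)
    bundle$paths <- paths
  }
  bundle
}

## Annotation + constraint synthesis. dSNPs pass all filters; decoys
## cycle through five single-filter failure modes. Returns the parsed
## annotation_table, the constraint_track, and the writable file image.
build_synthetic_annotations <- function(loci, is_dsnp) {
  M <- nrow(loci)
  consequence <- character(M)
  canonical <- rep("YES", M)
  sift <- rep("-", M)
  rs <- rep(NA_real_, M)

  di <- which(is_dsnp)
  consequence[di] <- "missense_variant"
  s <- round(stats::runif(length(di), 0, 0.05), 4)
  sift[di] <- sprintf("deleterious(%.4f)", s)
  rs[di] <- round(stats::runif(length(di), 0.01, 5), 4)

  oi <- which(!is_dsnp)
  mode <- (seq_along(oi) - 1L) %% 5L + 1L
  other_classes <- setdiff(CONSEQUENCE_CLASSES, "missense_variant")
  for (k in seq_along(oi)) {
    j <- oi[k]
    switch(mode[k],
      { # tolerated SIFT, everything else qualifying
        consequence[j] <- "missense_variant"
        sc <- round(stats::runif(1, 0.0501, 1), 4)
        cls <- if (stats::runif(1) < 0.1) "tolerated_low_confidence"
               else "tolerated"
        sift[j] <- sprintf("%s(%.4f)", cls, sc)
        rs[j] <- round(stats::runif(1, 0.01, 5), 4)
      },
      { # deleterious SIFT but non-canonical transcript
        consequence[j] <- "missense_variant"
        canonical[j] <- "-"
        cls <- if (stats::runif(1) < 0.1) "deleterious_low_confidence"
               else "deleterious"
        sift[j] <- sprintf("%s(%.4f)", cls,
                           round(stats::runif(1, 0, 0.049), 4))
        rs[j] <- round(stats::runif(1, 0.01, 5), 4)
      },
      { # deleterious SIFT but position absent from constraint track
        consequence[j] <- "missense_variant"
        sift[j] <- sprintf("deleterious(%.4f)",
                           round(stats::runif(1, 0, 0.049), 4))
      },
      { # deleterious SIFT but non-positive RS
        consequence[j] <- "missense_variant"
        sift[j] <- sprintf("deleterious(%.4f)",
                           round(stats::runif(1, 0, 0.049), 4))
        rs[j] <- round(stats::runif(1, -3, 0), 4)
      },
      { # non-missense consequence
        consequence[j] <- other_classes[(k %% length(other_classes)) + 1L]
      })
  }

  gene <- paste0("GENE", formatC(seq_len(M), width = 5, flag = "0"))
  file <- data.frame(
    Location = paste(loci$chrom, loci$pos, sep = ":"),
    Allele = loci$alt,
    Gene = gene,
    Feature = paste0(gene, ".1"),
    Consequence = consequence,
    CANONICAL = canonical,
    SIFT = sift,
    stringsAsFactors = FALSE)

  has_rs <- !is.na(rs)
  constraint <- data.frame(chrom = loci$chrom[has_rs],
                           pos = loci$pos[has_rs], rs = rs[has_rs],
                           stringsAsFactors = FALSE)
  class(constraint) <- c("constraint_track", "data.frame")

  sift_parsed <- parse_sift(file$SIFT)
  parsed <- data.frame(
    chrom = loci$chrom, pos = loci$pos, alt = loci$alt, gene = gene,
    transcript = file$Feature, consequence = consequence,
    canonical = canonical == "YES", sift_class = sift_parsed$class,
    sift_score = sift_parsed$score, stringsAsFactors = FALSE)
  class(parsed) <- c("annotation_table", "data.frame")

  list(parsed = parsed, file = file, constraint = constraint)
}
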