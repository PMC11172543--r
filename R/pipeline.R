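#' Default pipeline configuration
#'
#' @param vcf,annotations,constraint,passport input file paths.
#' @param region_map optional country-to-region mapping CSV path.
#' @param outdir output directory.
#' @param sift_max,sift_strict,rs_min,canonical_only dSNP filter
#'   thresholds (see [identify_dsnps]).
#' @param missing_policy burden denominator policy (see
#'   [burden_estimates]).
#' @param distance APD distance (see [apd_vector]).
#' @param exclude_labels labels excluded from ANOVA (default "Unknown").
#' @param group_by passport columns to summarise and test over.
#' @param zone_apd_min,zone_burden_max selection-zone thresholds; when
#'   `NULL` they default to the cohort's upper-quartile APD and
#'   lower-quartile burden.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, annotations, constraint, passport,
                       region_map = NULL, outdir,
                       sift_max = 0.05, sift_strict = FALSE, rs_min = 0,
                       canonical_only = TRUE,
                       missing_policy = "zero",
                       distance = "allele_sharing",
                       exclude_labels = "Unknown",
                       group_by = c("panel", "material_type",
                                    "growth_habit", "row_type", "country",
                                    "region", "core_flag"),
                       zone_apd_min = NULL, zone_burden_max = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [run_config] arguments;
#' relative input paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return list of class `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base, p))
  }
  for (f in c("vcf", "annotations", "constraint", "passport",
              "region_map"))
    y[[f]] <- resolve(y[[f]])
  do.call(run_config, y)
}

write_table_atomic <- function(df, path, sep = "\t") {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  header <- paste(names(df), collapse = sep)
  body <- if (nrow(df)) do.call(paste, c(lapply(df, as.character),
                                         sep = sep)) else character(0)
  write_lines_lf(c(header, body), tmp)
  file.rename(tmp, path)
  invisible(path)
}

fmt_fixed <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(round(x, digits), digits = digits,
                                 format = "f"))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full burden-characterization pipeline
#'
#' Orchestrates the end-to-end analysis: read inputs, identify dSNPs,
#' estimate per-sample burdens and the carrier spectrum, compute APDs,
#' summarise and test burden by passport grouping, correlate burden with
#' APD, and apply the selection-zone rule. Writes `dsnps.tsv`,
#' `burdens.tsv`, `spectrum.tsv`, `apd.tsv`, one `group_<var>.tsv` and
#' ANOVA row per grouping, `zone.tsv` and `run_report.json` to the output
#' directory. Tables are written atomically (temp file then rename) with
#' fixed decimal formatting: burdens at 5 decimals, carrier frequencies
#' at 6, APDs at 6.
#'
#' @param config a [run_config], or a path to a YAML file for
#'   [read_run_config].
#' @return the run report (also written as JSON), invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)

  gm <- stage("read_genotypes", read_genotypes(config$vcf))
  ann <- stage("read_annotations", read_annotations(config$annotations))
  track <- stage("read_constraint", read_constraint(config$constraint))
  pass <- stage("read_passport", {
    p <- read_passport(config$passport, region_map = config$region_map)
    align_passport(p, gm$samples)
  })

  dset <- stage("identify_dsnps", identify_dsnps(
    ann, track, sift_max = config$sift_max, rs_min = config$rs_min,
    canonical_only = config$canonical_only,
    sift_strict = config$sift_strict, loci = gm$loci))
  if (n_dsnps(dset) == 0L)
    stop("pipeline stage 'identify_dsnps' failed: no dSNPs pass the ",
         "filters", call. = FALSE)

  est <- stage("burden", burden_estimates(
    gm, dset, missing_policy = config$missing_policy))
  spec <- stage("spectrum", carrier_spectrum(gm, dset))
  apd <- stage("apd", apd_vector(gm, distance = config$distance))

  groups <- list()
  anovas <- list()
  for (v in intersect(config$group_by, names(pass))) {
    labels <- pass[[v]]
    groups[[v]] <- group_summary(est$total_burden, labels)
    anovas[[v]] <- tryCatch(
      anova_oneway(est$total_burden, labels,
                   exclude = config$exclude_labels),
      error = function(e) NULL)
  }

  corr <- stage("correlate", correlate_burden_apd(est$total_burden,
                                                  apd$apd))
  apd_min <- config$zone_apd_min
  burden_max <- config$zone_burden_max
  if (is.null(apd_min))
    apd_min <- unname(stats::quantile(apd$apd, 0.75))
  if (is.null(burden_max))
    burden_max <- unname(stats::quantile(est$total_burden, 0.25))
  zone <- stage("zone", selection_zone(est$total_burden, apd$apd,
                                       apd_min, burden_max,
                                       samples = est$sample))

  out <- config$outdir
  stage("write_outputs", {
    write_table_atomic(data.frame(
      chrom = dset$chrom, pos = dset$pos, ref = dset$ref, alt = dset$alt,
      gene = dset$gene, transcript = dset$transcript,
      sift_score = fmt_fixed(dset$sift_score, 4),
      rs_score = fmt_fixed(dset$rs_score, 4)),
      file.path(out, "dsnps.tsv"))
    write_table_atomic(data.frame(
      sample = est$sample, n_het = est$n_het, n_hom = est$n_hom,
      hom_burden = fmt_fixed(est$hom_burden, 5),
      het_burden = fmt_fixed(est$het_burden, 5),
      total_burden = fmt_fixed(est$total_burden, 5)),
      file.path(out, "burdens.tsv"))
    write_table_atomic(data.frame(
      chrom = spec$loci$chrom, pos = spec$loci$pos, alt = spec$loci$alt,
      carrier_count = spec$loci$carrier_count,
      carrier_frequency = fmt_fixed(spec$loci$carrier_frequency, 6)),
      file.path(out, "spectrum.tsv"))
    write_table_atomic(data.frame(
      sample = apd$sample, apd = fmt_fixed(apd$apd, 6),
      n_comparisons = apd$n_comparisons), file.path(out, "apd.tsv"))
    for (v in names(groups))
      write_table_atomic(format_group_summary(groups[[v]], digits = 5L),
                         file.path(out, paste0("group_", v, ".tsv")))
    anova_rows <- do.call(rbind, lapply(names(anovas), function(v) {
      a <- anovas[[v]]
      if (is.null(a)) return(NULL)
      data.frame(grouping = v, F = fmt_fixed(a$F, 4),
                 df_between = a$df_between, df_within = a$df_within,
                 p_value = formatC(a$p_value, digits = 4, format = "g"))
    }))
    if (!is.null(anova_rows))
      write_table_atomic(anova_rows, file.path(out, "anova.tsv"))
    write_table_atomic(data.frame(sample = zone$members),
                       file.path(out, "zone.tsv"))
  })

  inputs <- c(vcf = config$vcf, annotations = config$annotations,
              constraint = config$constraint, passport = config$passport)
  report <- list(
    parameters = list(sift_max = config$sift_max,
                      sift_strict = config$sift_strict,
                      rs_min = config$rs_min,
                      canonical_only = config$canonical_only,
                      missing_policy = config$missing_policy,
                      distance = config$distance,
                      exclude_labels = config$exclude_labels,
                      zone_apd_min = apd_min,
                      zone_burden_max = burden_max),
    inputs = as.list(tools::md5sum(inputs)),
    headline = list(
      n_samples = length(gm$samples),
      n_loci = nrow(gm$loci),
      L = n_dsnps(dset),
      dsnps_per_chromosome = as.list(per_chromosome_counts(dset)),
      mean_total_burden = mean(est$total_burden),
      min_total_burden = min(est$total_burden),
      max_total_burden = max(est$total_burden),
      n_zero_burden = length(zero_burden_samples(est)),
      rare_fraction_le_20_carriers =
        spec$rarity$fraction[spec$rarity$max_carriers == 20L],
      burden_apd_r = corr$r,
      burden_apd_p = corr$p_value,
      zone_n = zone$n))
  report_path <- file.path(out, "run_report.json")
  tmp <- tempfile(tmpdir = out, fileext = ".tmp")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, report_path)
  invisible(report)
}
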