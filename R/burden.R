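## Match dSNP loci to genotype-matrix columns; error naming the first
## missing locus.
match_dsnp_loci <- function(gm, dset) {
  idx <- match(locus_key(dset), locus_key(gm$loci))
  if (anyNA(idx)) {
    bad <- dset[is.na(idx), , drop = FALSE]
    stop("dSNP locus absent from genotype matrix: ",
         first_locus_label(bad), call. = FALSE)
  }
  idx
}

#' Count deleterious genotypes per sample
#'
#' At the identified dSNP loci, counts for each sample the homozygous
#' deleterious genotypes h (dosage 2) and heterozygous deleterious
#' genotypes e (dosage 1). Missing calls contribute to neither count
#' (missing-as-noncarrier convention; the denominator handling is chosen
#' in [burden_estimates]).
#'
#' @param gm a [genotype_matrix].
#' @param dset a `dsnp_set`; every locus must be present in `gm`.
#' @return data.frame with columns `sample`, `n_hom` (h), `n_het` (e).
#' @export
count_deleterious_genotypes <- function(gm, dset) {
  idx <- match_dsnp_loci(gm, dset)
  d <- gm$dosage[, idx, drop = FALSE]
  data.frame(sample = gm$samples,
             n_hom = as.integer(rowSums(d == 2L, na.rm = TRUE)),
             n_het = as.integer(rowSums(d == 1L, na.rm = TRUE)),
             stringsAsFactors = FALSE)
}

#' Mutation burden per deleterious locus
#'
#' The three burden statistics for a sample carrying h homozygous and e
#' heterozygous deleterious genotypes over L dSNP loci, each normalized
#' by twice the dSNP count (the number of genotyped deleterious allele
#' slots):
#' \deqn{B_{hom} = 2h / (2L), \quad B_{het} = e / (2L), \quad
#'       B_{tot} = (2h + e) / (2L)}
#' so that \eqn{B_{tot} = B_{hom} + B_{het}} holds exactly.
#'
#' @param h,e counts (vectorized); non-negative, `h + e <= L`.
#' @param L number of dSNP loci; must be positive.
#' @return data.frame with columns `hom_burden`, `het_burden`,
#'   `total_burden`.
#' @export
burden <- function(h, e, L) {
  if (length(L) != 1L || !is.finite(L) || L <= 0)
    stop("L must be a single positive dSNP count (no dSNPs identified?)",
         call. = FALSE)
  if (any(h < 0) || any(e < 0)) stop("h and e must be non-negative",
                                     call. = FALSE)
  if (any(h + e > L)) stop("h + e cannot exceed L", call. = FALSE)
  hom <- 2 * h / (2 * L)
  het <- e / (2 * L)
  # summing the components keeps B_tot = B_hom + B_het bit-exact
  data.frame(hom_burden = hom, het_burden = het,
             total_burden = hom + het)
}

#' Per-sample burden estimates
#'
#' Combines [count_deleterious_genotypes] and [burden] over a cohort.
#' Under the default `missing_policy = "zero"` a missing call at a dSNP
#' locus contributes zero deleterious alleles and the denominator stays
#' 2L for every sample (appropriate when, as for the barley panel, the
#' genotype matrix was imputed upstream and residual missingness is
#' minimal). `missing_policy = "per_sample"` instead shrinks the
#' denominator to twice the number of non-missing dSNP genotypes of each
#' sample.
#'
#' @param gm a [genotype_matrix].
#' @param dset a `dsnp_set`.
#' @param missing_policy `"zero"` (default) or `"per_sample"`.
#' @return data.frame of class `burden_estimates` with columns `sample`,
#'   `n_het`, `n_hom`, `hom_burden`, `het_burden`, `total_burden`;
#'   attribute `L` records the locus count.
#' @export
burden_estimates <- function(gm, dset,
                             missing_policy = c("zero", "per_sample")) {
  missing_policy <- match.arg(missing_policy)
  L <- n_dsnps(dset)
  if (L == 0L) stop("no dSNPs identified; burden is undefined",
                    call. = FALSE)
  cnt <- count_deleterious_genotypes(gm, dset)
  if (missing_policy == "zero") {
    b <- burden(cnt$n_hom, cnt$n_het, L)
  } else {
    idx <- match_dsnp_loci(gm, dset)
    L_i <- rowSums(!is.na(gm$dosage[, idx, drop = FALSE]))
    if (any(L_i == 0L))
      stop("sample with no called dSNP genotypes under per-sample policy: ",
           gm$samples[L_i == 0L][1], call. = FALSE)
    hom <- 2 * cnt$n_hom / (2 * L_i)
    het <- cnt$n_het / (2 * L_i)
    b <- data.frame(hom_burden = hom, het_burden = het,
                    total_burden = hom + het)
  }
  out <- data.frame(sample = cnt$sample, n_het = cnt$n_het,
                    n_hom = cnt$n_hom, b, stringsAsFactors = FALSE)
  attr(out, "L") <- L
  class(out) <- c("burden_estimates", "data.frame")
  out
}

#' Samples with zero mutation burden
#'
#' A zero estimate does not mean the sample carries no deleterious
#' mutations, only that none were observed at the genotyped dSNP loci.
#'
#' @param estimates a `burden_estimates` data.frame.
#' @return character vector of sample ids with `total_burden == 0`.
#' @export
zero_burden_samples <- function(estimates) {
  estimates$sample[estimates$total_burden == 0]
}

#' Carrier-frequency spectrum of the deleterious alleles
#'
#' For each dSNP locus, counts the samples carrying at least one copy of
#' the deleterious allele (dosage 1 or 2) and reports the carrier
#' frequency f = carriers / N. This carrier-fraction convention is what
#' the rarity thresholds refer to: with N samples, a singleton allele has
#' f = 1/N. The spectrum is binned over f, with default break points at
#' the three reporting thresholds (1, 5 and 20 carriers) plus a
#' log-spaced tail; rarity counts at those thresholds are reported
#' directly.
#'
#' @param gm a [genotype_matrix].
#' @param dset a `dsnp_set`.
#' @param breaks optional increasing vector of bin upper bounds on f
#'   (the lowest bin is (0, breaks[1]]).
#' @return list of class `carrier_spectrum` with elements `loci`
#'   (per-locus `chrom`, `pos`, `alt`, `carrier_count`,
#'   `carrier_frequency`), `bins` (`upper`, `count`), `rarity`
#'   (`max_carriers`, `max_frequency`, `n_dsnps`, `fraction`), `N`, `L`.
#' @export
carrier_spectrum <- function(gm, dset, breaks = NULL) {
  idx <- match_dsnp_loci(gm, dset)
  d <- gm$dosage[, idx, drop = FALSE]
  N <- length(gm$samples)
  carriers <- as.integer(colSums(d >= 1L, na.rm = TRUE))
  f <- carriers / N
  if (is.null(breaks)) {
    breaks <- sort(unique(c(1 / N, 5 / N, 20 / N,
                            0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1)))
    breaks <- breaks[breaks <= 1]
  }
  if (is.unsorted(breaks, strictly = TRUE) || any(breaks <= 0))
    stop("breaks must be strictly increasing and positive", call. = FALSE)
  if (max(breaks) < 1) breaks <- c(breaks, 1)
  bin <- findInterval(f, c(0, breaks), left.open = TRUE,
                      rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks))
  thresholds <- c(1L, 5L, 20L)
  rarity <- data.frame(
    max_carriers = thresholds,
    max_frequency = thresholds / N,
    n_dsnps = vapply(thresholds, function(k) sum(carriers <= k), integer(1)),
    fraction = vapply(thresholds, function(k) mean(carriers <= k),
                      numeric(1))
  )
  structure(list(
    loci = data.frame(chrom = dset$chrom, pos = dset$pos, alt = dset$alt,
                      carrier_count = carriers, carrier_frequency = f,
                      stringsAsFactors = FALSE),
    bins = data.frame(upper = breaks, count = counts),
    rarity = rarity, N = N, L = n_dsnps(dset)), class = "carrier_spectrum")
}

#' @export
print.carrier_spectrum <- function(x, ...) {
  cat("carrier spectrum of", x$L, "dSNPs in", x$N, "samples\n")
  r <- x$rarity
  for (i in seq_len(nrow(r)))
    cat(sprintf("  <= %d carrier(s) (f <= %.6f): %d dSNPs (%.1f%%)\n",
                r$max_carriers[i], r$max_frequency[i], r$n_dsnps[i],
                100 * r$fraction[i]))
  invisible(x)
}
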