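# Shared fixture builders and independent oracle implementations.

# Quick genotype-matrix constructor: dosage given samples x loci.
make_gm <- function(dosage, chrom = NULL, pos = NULL, samples = NULL) {
  dosage <- as.matrix(dosage)
  m <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("1H", m)
  if (is.null(pos)) pos <- seq_len(m) * 100L
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(dosage)))
  refs <- rep(c("A", "C"), length.out = m)
  alts <- rep(c("G", "T"), length.out = m)
  genotype_matrix(dosage, data.frame(chrom = chrom, pos = pos,
                                     ref = refs, alt = alts,
                                     id = paste0("v", seq_len(m))),
                  samples)
}

# Annotation-table row builder mirroring read_annotations output.
make_ann <- function(chrom = character(0), pos = integer(0), alt = "G",
                     gene = "G1",
                     transcript = "G1.1", consequence = "missense_variant",
                     canonical = TRUE, sift_class = NA_character_,
                     sift_score = NA_real_) {
  n <- length(chrom)
  for (a in c("alt", "gene", "transcript", "consequence", "canonical",
              "sift_class", "sift_score"))
    if (length(get(a)) != n) assign(a, rep_len(get(a), n))
  out <- data.frame(chrom = chrom, pos = pos, alt = alt, gene = gene,
                    transcript = transcript, consequence = consequence,
                    canonical = canonical, sift_class = sift_class,
                    sift_score = sift_score, stringsAsFactors = FALSE)
  class(out) <- c("annotation_table", "data.frame")
  out
}

make_track <- function(chrom, pos, rs) {
  out <- data.frame(chrom = chrom, pos = as.integer(pos), rs = rs,
                    stringsAsFactors = FALSE)
  class(out) <- c("constraint_track", "data.frame")
  out
}

# Brute-force dSNP oracle: evaluate the three predicates row by row,
# then deduplicate loci. Independent of identify_dsnps internals.
brute_dsnp_keys <- function(ann, track, sift_max = 0.05, rs_min = 0,
                            canonical_only = TRUE, sift_strict = FALSE) {
  keys <- character(0)
  for (i in seq_len(nrow(ann))) {
    r <- ann[i, ]
    if (r$consequence != "missense_variant") next
    if (canonical_only && !isTRUE(r$canonical)) next
    if (is.na(r$sift_score)) next
    pass_sift <- if (sift_strict) r$sift_score < sift_max
                 else r$sift_score <= sift_max
    if (!pass_sift) next
    rs <- NA_real_
    for (j in seq_len(nrow(track)))
      if (track$chrom[j] == r$chrom && track$pos[j] == r$pos)
        rs <- track$rs[j]
    if (is.na(rs) || rs <= rs_min) next
    keys <- c(keys, paste(r$chrom, r$pos, r$alt, sep = ":"))
  }
  sort(unique(keys))
}

# Naive O(N^2 M) APD oracle via the scalar pairwise function.
naive_apd <- function(gm, distance = "allele_sharing") {
  n <- nrow(gm$dosage)
  sapply(seq_len(n), function(i) {
    mean(sapply(setdiff(seq_len(n), i), function(j)
      pairwise_difference(gm$dosage[i, ], gm$dosage[j, ],
                          distance = distance)))
  })
}

# Textbook one-way ANOVA oracle from the sums of squares.
textbook_anova <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tapply(y, g, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((y - means[g])^2)
  k <- nlevels(g)
  n <- length(y)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# A small random annotation table + constraint track for property tests.
random_annotation_case <- function(n_rows) {
  chrom <- sample(paste0(1:3, "H"), n_rows, replace = TRUE)
  pos <- sample.int(1000, n_rows, replace = TRUE)
  has_sift <- runif(n_rows) < 0.8
  cons <- sample(c("missense_variant", "synonymous_variant",
                   "intron_variant"), n_rows, replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  ann <- make_ann(chrom = chrom, pos = pos,
                  alt = sample(c("A", "C", "G", "T"), n_rows,
                               replace = TRUE),
                  transcript = paste0("T", seq_len(n_rows)),
                  consequence = cons,
                  canonical = runif(n_rows) < 0.7,
                  sift_class = ifelse(has_sift, "deleterious",
                                      NA_character_),
                  sift_score = ifelse(has_sift,
                                      round(runif(n_rows), 3), NA))
  upos <- unique(data.frame(chrom = chrom, pos = pos))
  scored <- runif(nrow(upos)) < 0.7
  track <- make_track(upos$chrom[scored], upos$pos[scored],
                      round(runif(sum(scored), -2, 4), 3))
  list(ann = ann, track = track)
}

# One shared small bundle for IO-level tests (built once per test run).
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "burdenscan-shared-bundle")
      cache <<- generate_bundle(
        synthetic_config(n_samples = 80, n_loci = 300, n_dsnp = 15,
                         seed = 42), dir)
    }
    cache
  }
})
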