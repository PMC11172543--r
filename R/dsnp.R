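#' Tally annotation consequence classes
#'
#' Counts annotation records per consequence class over the closed
#' 16-class vocabulary and sums the seven loss-of-function classes
#' (splice_region, stop_gained, splice_donor, start_lost, splice_acceptor,
#' stop_lost, stop_retained). With `per_snp = TRUE` each SNP (keyed by
#' chrom, pos, alt) contributes only its single most severe consequence
#' under the documented severity ranking; otherwise every
#' (variant, transcript) record is counted. Records classed `"other"` are
#' reported separately and excluded from `total` and `lof_total`.
#'
#' @param annotations an `annotation_table` from [read_annotations].
#' @param per_snp collapse to one consequence per SNP before tallying.
#' @return list of class `consequence_tally` with `counts` (named integer
#'   over the 16 classes), `total`, `lof_total` and `n_other`.
#' @export
tally_consequences <- function(annotations, per_snp = FALSE) {
  cons <- annotations$consequence
  if (isTRUE(per_snp) && nrow(annotations)) {
    sev <- match(cons, CONSEQUENCE_CLASSES, nomatch = length(CONSEQUENCE_CLASSES) + 1L)
    ord <- order(locus_key(annotations), sev)
    keep <- !duplicated(locus_key(annotations)[ord])
    cons <- cons[ord][keep]
  }
  counts <- vapply(CONSEQUENCE_CLASSES, function(cl) sum(cons == cl),
                   integer(1))
  structure(list(counts = counts,
                 total = sum(counts),
                 lof_total = sum(counts[LOF_CLASSES]),
                 n_other = sum(cons == "other")),
            class = "consequence_tally")
}

#' @export
print.consequence_tally <- function(x, ...) {
  cat("consequence tally:", x$total, "records over 16 classes;",
      x$lof_total, "loss-of-function\n")
  print(x$counts)
  invisible(x)
}

#' Tally SIFT prediction classes
#'
#' @param annotations an `annotation_table`.
#' @return list of class `sift_tally` with `counts` (named integer over
#'   the four SIFT classes) and `total`; records without a SIFT
#'   prediction do not contribute.
#' @export
tally_sift <- function(annotations) {
  cls <- annotations$sift_class
  counts <- vapply(SIFT_CLASSES, function(cl)
    sum(cls == cl, na.rm = TRUE), integer(1))
  structure(list(counts = counts, total = sum(counts)),
            class = "sift_tally")
}

#' @export
print.sift_tally <- function(x, ...) {
  cat("SIFT predictions:", x$total, "records\n")
  print(x$counts)
  invisible(x)
}

#' Identify predicted deleterious SNPs
#'
#' Applies the three-filter cascade that defines a dSNP: a missense
#' annotation on a canonical transcript (when `canonical_only`), a SIFT
#' score at or below `sift_max` (0.05 or less is considered deleterious;
#' set `sift_strict = TRUE` for a strict `<` comparison), and a
#' rejected-substitution constraint score strictly greater than `rs_min`
#' at the variant position. A position absent from the constraint track
#' fails the RS criterion: a positive-score-only track encodes
#' non-qualifying positions by omission.
#'
#' The deleterious allele is the alternate allele of the annotated
#' variant; no ancestral-state repolarization is attempted. One entry is
#' returned per locus (chrom, pos, alt), ordered by chromosome then
#' position; when several transcript rows qualify at a locus, the row
#' with the lowest SIFT score is kept.
#'
#' @param annotations an `annotation_table`.
#' @param constraint a `constraint_track`.
#' @param sift_max maximum qualifying SIFT score (default 0.05).
#' @param rs_min RS threshold; qualifying positions have `rs > rs_min`
#'   (default 0, strict).
#' @param canonical_only restrict to canonical-transcript annotations
#'   (default `TRUE`).
#' @param sift_strict use `sift_score < sift_max` instead of `<=`.
#' @param loci optional data.frame of genotyped loci (chrom, pos, ref,
#'   alt) used to fill the `ref` column of the output.
#' @return data.frame of class `dsnp_set` with columns `chrom`, `pos`,
#'   `ref`, `alt`, `gene`, `transcript`, `sift_score`, `rs_score`. The
#'   number of rows is L, the burden denominator.
#' @export
identify_dsnps <- function(annotations, constraint, sift_max = 0.05,
                           rs_min = 0, canonical_only = TRUE,
                           sift_strict = FALSE, loci = NULL) {
  stopifnot(is.finite(sift_max), is.finite(rs_min))
  a <- annotations
  if (!nrow(a)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      gene = character(), transcript = character(),
                      sift_score = numeric(), rs_score = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("dsnp_set", "data.frame")
    return(out)
  }
  sift_ok <- !is.na(a$sift_score) &
    (if (sift_strict) a$sift_score < sift_max else a$sift_score <= sift_max)
  keep <- a$consequence == "missense_variant" & sift_ok
  if (canonical_only) keep <- keep & a$canonical
  rs <- constraint_lookup(constraint, a$chrom, a$pos)
  keep <- keep & !is.na(rs) & rs > rs_min
  hits <- a[keep, , drop = FALSE]
  rs <- rs[keep]
  # one row per locus: lowest SIFT first, then deterministic (chrom, pos)
  ord <- order(hits$chrom, hits$pos, hits$sift_score, hits$transcript)
  hits <- hits[ord, , drop = FALSE]
  rs <- rs[ord]
  first <- !duplicated(locus_key(hits))
  hits <- hits[first, , drop = FALSE]
  rs <- rs[first]
  ref <- rep(NA_character_, nrow(hits))
  if (!is.null(loci)) {
    idx <- match(locus_key(hits), locus_key(loci))
    ref[!is.na(idx)] <- loci$ref[idx[!is.na(idx)]]
  }
  out <- data.frame(chrom = hits$chrom, pos = hits$pos, ref = ref,
                    alt = hits$alt, gene = hits$gene,
                    transcript = hits$transcript,
                    sift_score = hits$sift_score, rs_score = rs,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("dsnp_set", "data.frame")
  out
}

#' Number of identified dSNP loci
#'
#' @param dset a `dsnp_set`.
#' @return integer L, the burden denominator.
#' @export
n_dsnps <- function(dset) nrow(dset)

#' Count dSNPs per chromosome
#'
#' @param dset a `dsnp_set`.
#' @return named integer vector; counts sum to `n_dsnps(dset)`.
#' @export
per_chromosome_counts <- function(dset) {
  tab <- table(dset$chrom)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}
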