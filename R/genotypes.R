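#' Genotype matrix container
#'
#' A `genotype_matrix` holds alternate-allele dosages for N samples at M
#' biallelic SNP loci, together with per-locus metadata. Dosages are coded
#' 0 (homozygous reference), 1 (heterozygous), 2 (homozygous alternate) and
#' `NA` (missing call). Coordinates are 1-based, following the VCF
#' convention; any companion per-position table (e.g. a constraint-score
#' track) must use the same convention.
#'
#' @param dosage integer matrix, samples in rows, loci in columns; values
#'   in `{0, 1, 2, NA}`.
#' @param loci data.frame with columns `chrom`, `pos`, `ref`, `alt`, `id`
#'   (one row per dosage column, in column order).
#' @param samples character vector of sample identifiers (one per row).
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage`, `loci` and `samples`.
#' @export
genotype_matrix <- function(dosage, loci, samples) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(loci$id)) loci$id <- rep(NA_character_, nrow(loci))
  loci <- data.frame(
    chrom = as.character(loci$chrom),
    pos = as.integer(loci$pos),
    ref = as.character(loci$ref),
    alt = as.character(loci$alt),
    id = as.character(loci$id),
    stringsAsFactors = FALSE
  )
  samples <- as.character(samples)
  if (nrow(dosage) != length(samples))
    stop("dosage has ", nrow(dosage), " rows but ", length(samples),
         " sample ids were given", call. = FALSE)
  if (ncol(dosage) != nrow(loci))
    stop("dosage has ", ncol(dosage), " columns but ", nrow(loci),
         " loci were given", call. = FALSE)
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    stop("dosage values must be 0, 1, 2 or NA", call. = FALSE)
  validate_loci(loci)
  rownames(dosage) <- samples
  colnames(dosage) <- locus_key(loci)
  structure(list(dosage = dosage, loci = loci, samples = samples),
            class = "genotype_matrix")
}

validate_loci <- function(loci) {
  if (any(is.na(loci$pos)) || any(loci$pos < 1L))
    stop("locus positions must be integers >= 1", call. = FALSE)
  snp <- nchar(loci$ref) == 1L & nchar(loci$alt) == 1L &
    loci$ref %in% c("A", "C", "G", "T") & loci$alt %in% c("A", "C", "G", "T")
  if (!all(snp))
    stop("loci must be biallelic single-base SNPs; offending record: ",
         first_locus_label(loci[!snp, , drop = FALSE]), call. = FALSE)
  if (any(loci$ref == loci$alt))
    stop("ref and alt allele must differ; offending record: ",
         first_locus_label(loci[loci$ref == loci$alt, , drop = FALSE]),
         call. = FALSE)
  invisible(loci)
}

first_locus_label <- function(loci) {
  paste0(loci$chrom[1], ":", loci$pos[1])
}

#' Locus join key
#'
#' Loci are keyed by `(chrom, pos, alt)`. The alternate allele is part of
#' the key so that annotations at multi-annotated positions cannot be
#' mispaired with the wrong substitution.
#'
#' @param x data.frame with `chrom`, `pos`, `alt` columns.
#' @return character vector of keys.
#' @keywords internal
locus_key <- function(x) {
  paste(x$chrom, x$pos, x$alt, sep = ":")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$loci), "loci\n")
  n_mis <- sum(is.na(x$dosage))
  cat(sprintf("  missing calls: %d (%.2f%%)\n",
              n_mis, 100 * n_mis / length(x$dosage)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

## GT string -> dosage lookup. Phased and unphased separators are
## equivalent; any genotype containing a missing allele is a missing call.
.gt_map <- c(
  "0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
  "./." = NA_integer_, "." = NA_integer_, "./0" = NA_integer_,
  "0/." = NA_integer_, "./1" = NA_integer_, "1/." = NA_integer_
)

#' Read a biallelic SNP genotype matrix from VCF
#'
#' Parses a VCF 4.x file (plain or gzipped) and converts GT fields to
#' alternate-allele dosages. `./.` becomes a missing call; phased (`0|1`)
#' and unphased (`0/1`) genotypes are treated identically. Sample order
#' and record order are preserved.
#'
#' @param path path to a VCF file.
#' @param skip_nonbiallelic if `FALSE` (default) a multi-allelic or
#'   non-SNP record is a hard error naming the record; if `TRUE` such
#'   records are dropped with a warning.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, skip_nonbiallelic = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- methods::slot(v, "fix")
  gt <- methods::slot(v, "gt")
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no genotype columns: ", path, call. = FALSE)
  loci <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = as.character(fix[, "ALT"]),
    id = as.character(fix[, "ID"]),
    stringsAsFactors = FALSE
  )
  loci$id[loci$id == "."] <- NA_character_
  ok <- nchar(loci$ref) == 1L & !is.na(loci$alt) & nchar(loci$alt) == 1L &
    loci$ref %in% c("A", "C", "G", "T") & loci$alt %in% c("A", "C", "G", "T")
  if (!all(ok)) {
    bad <- loci[!ok, , drop = FALSE]
    if (skip_nonbiallelic) {
      warning("skipping ", nrow(bad), " multi-allelic/non-SNP record(s), ",
              "first at ", first_locus_label(bad), call. = FALSE)
      gt <- gt[ok, , drop = FALSE]
      loci <- loci[ok, , drop = FALSE]
    } else {
      stop("multi-allelic or non-SNP record at ", first_locus_label(bad),
           " (use skip_nonbiallelic = TRUE to drop such records)",
           call. = FALSE)
    }
  }
  fmt <- gt[, 1L]
  if (!all(vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) "GT" %in% f, logical(1))))
    stop("VCF FORMAT lacks a GT field", call. = FALSE)
  calls <- gt[, -1L, drop = FALSE]
  samples <- colnames(calls)
  # GT is the leading FORMAT field per VCF spec ordering used here
  core <- sub(":.*$", "", calls)
  core <- gsub("|", "/", core, fixed = TRUE)
  core[is.na(core)] <- "./."  # vcfR reports fully missing calls as NA
  dos <- .gt_map[core]
  unknown <- is.na(dos) & !(core %in% names(.gt_map))
  if (any(unknown))
    stop("unparseable GT value '", core[which(unknown)[1]], "'",
         call. = FALSE)
  dosage <- matrix(dos, nrow = length(samples), ncol = nrow(loci),
                   byrow = TRUE)
  genotype_matrix(dosage, loci, samples)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits a plain-text VCF with GT-only genotype fields (`0/0`, `0/1`,
#' `1/1`, `./.`), UTF-8 encoded with LF line endings. Output is
#' byte-deterministic for a given input.
#'
#' @param gm a [genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=burdenscan",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##contig=<ID=", unique(gm$loci$chrom), ">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = nrow(gm$dosage), ncol = ncol(gm$dosage))
  obs <- !is.na(gm$dosage)
  gt[obs] <- gt_code[gm$dosage[obs] + 1L]
  id <- gm$loci$id
  id[is.na(id)] <- "."
  body <- paste(gm$loci$chrom, gm$loci$pos, id, gm$loci$ref, gm$loci$alt,
                ".", "PASS", ".", "GT",
                apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
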