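## Closed consequence vocabulary (the 16 classes tallied for this SNP
## panel), ordered from most to least severe following the standard
## variant-effect-annotator severity ranking. Anything else maps to
## "other" at read time.
CONSEQUENCE_CLASSES <- c(
  "splice_acceptor_variant",
  "splice_donor_variant",
  "stop_gained",
  "stop_lost",
  "start_lost",
  "missense_variant",
  "splice_region_variant",
  "stop_retained_variant",
  "synonymous_variant",
  "5_prime_UTR_variant",
  "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant",
  "intron_variant",
  "upstream_gene_variant",
  "downstream_gene_variant",
  "intergenic_variant"
)

## The seven classes counted as loss-of-function.
LOF_CLASSES <- c(
  "splice_region_variant", "stop_gained", "splice_donor_variant",
  "start_lost", "splice_acceptor_variant", "stop_lost",
  "stop_retained_variant"
)

SIFT_CLASSES <- c("deleterious", "deleterious_low_confidence",
                  "tolerated", "tolerated_low_confidence")

#' Read a per-(variant, transcript) annotation table
#'
#' Parses the tab-separated annotation dialect with columns `Location`
#' (`chrom:pos`), `Allele`, `Gene`, `Feature` (transcript id),
#' `Consequence`, `CANONICAL` (`YES` or blank/`-`) and `SIFT`
#' (`class(score)` or blank/`-`). A row may list several comma-separated
#' consequence terms; the most severe one under the documented severity
#' ranking is kept. Unknown consequence terms are mapped to `"other"`
#' with a warning.
#'
#' @param path path to the annotation TSV.
#' @return data.frame of class `annotation_table` with columns `chrom`,
#'   `pos`, `alt`, `gene`, `transcript`, `consequence`, `canonical`
#'   (logical), `sift_class`, `sift_score`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = NULL, quote = "")
  need <- c("Location", "Allele", "Feature", "Consequence", "CANONICAL",
            "SIFT")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  loc <- strsplit(tab$Location, ":", fixed = TRUE)
  bad_loc <- lengths(loc) != 2L
  if (any(bad_loc))
    stop("malformed Location field at line ", which(bad_loc)[1] + 1L,
         call. = FALSE)
  chrom <- vapply(loc, `[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(loc, `[`, character(1), 2L)))
  if (anyNA(pos))
    stop("non-numeric position in Location at line ",
         which(is.na(pos))[1] + 1L, call. = FALSE)

  cons <- resolve_consequences(tab$Consequence)

  sift <- parse_sift(tab$SIFT)
  gene <- if (is.null(tab$Gene)) rep(NA_character_, nrow(tab)) else tab$Gene
  out <- data.frame(
    chrom = chrom,
    pos = pos,
    alt = tab$Allele,
    gene = gene,
    transcript = tab$Feature,
    consequence = cons,
    canonical = tab$CANONICAL == "YES",
    sift_class = sift$class,
    sift_score = sift$score,
    stringsAsFactors = FALSE
  )
  class(out) <- c("annotation_table", "data.frame")
  out
}

## Collapse comma-separated consequence terms to the single most severe
## term; unknown terms become "other" (warned once, listing the terms).
resolve_consequences <- function(x) {
  parts <- strsplit(x, ",", fixed = TRUE)
  all_terms <- unique(unlist(parts))
  unknown <- setdiff(all_terms, CONSEQUENCE_CLASSES)
  if (length(unknown))
    warning("unknown consequence term(s) mapped to 'other': ",
            paste(sort(unknown), collapse = ", "), call. = FALSE)
  vapply(parts, function(p) {
    r <- match(p, CONSEQUENCE_CLASSES)
    if (all(is.na(r))) "other" else CONSEQUENCE_CLASSES[min(r, na.rm = TRUE)]
  }, character(1))
}

## "deleterious(0.01)" -> class + score; "-" or "" -> absent.
parse_sift <- function(x) {
  absent <- is.na(x) | x == "" | x == "-"
  cls <- rep(NA_character_, length(x))
  score <- rep(NA_real_, length(x))
  todo <- which(!absent)
  if (length(todo)) {
    m <- regmatches(x[todo],
                    regexec("^([a-z_]+)\\(([0-9eE.+-]+)\\)$", x[todo]))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad))
      stop("malformed SIFT field '", x[todo][bad][1], "' at line ",
           todo[bad][1] + 1L, call. = FALSE)
    cls[todo] <- vapply(m, `[`, character(1), 2L)
    score[todo] <- as.numeric(vapply(m, `[`, character(1), 3L))
    bad_cls <- !(cls[todo] %in% SIFT_CLASSES)
    if (any(bad_cls))
      stop("unknown SIFT class '", cls[todo][bad_cls][1], "' at line ",
           todo[bad_cls][1] + 1L, call. = FALSE)
    if (any(score[todo] < 0 | score[todo] > 1))
      stop("SIFT score outside [0, 1] at line ",
           todo[score[todo] < 0 | score[todo] > 1][1] + 1L, call. = FALSE)
  }
  list(class = cls, score = score)
}

#' Read a per-position constraint-score track
#'
#' Reads a TSV with columns `chrom`, `pos`, `score` holding
#' rejected-substitution (RS) constraint scores. Positions are 1-based on
#' the same assembly as the genotype matrix. Duplicate `(chrom, pos)`
#' entries with conflicting scores are an error; exact duplicates are
#' collapsed.
#'
#' @param path path to the TSV.
#' @return data.frame of class `constraint_track` with columns `chrom`,
#'   `pos`, `rs`.
#' @export
read_constraint <- function(path) {
  if (!file.exists(path)) stop("constraint file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L)
    stop("constraint track needs chrom, pos, score columns", call. = FALSE)
  out <- data.frame(chrom = as.character(tab[[1L]]),
                    pos = as.integer(tab[[2L]]),
                    rs = as.numeric(tab[[3L]]),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  key <- paste(out$chrom, out$pos, sep = ":")
  dup <- duplicated(key)
  if (any(dup))
    stop("conflicting constraint scores at ", key[dup][1], call. = FALSE)
  class(out) <- c("constraint_track", "data.frame")
  out
}

#' Look up constraint scores by position
#'
#' @param track a [read_constraint] result.
#' @param chrom,pos vectors of chromosome names and 1-based positions.
#' @return numeric vector of RS scores; `NA` where the position is absent
#'   from the track.
#' @export
constraint_lookup <- function(track, chrom, pos) {
  idx <- match(paste(chrom, pos, sep = ":"),
               paste(track$chrom, track$pos, sep = ":"))
  track$rs[idx]
}

PASSPORT_FIELDS <- c("panel", "material_type", "growth_habit", "row_type",
                     "country", "region", "core_flag")

#' Read a sample passport table
#'
#' Reads a CSV with one row per sample and categorical descriptor columns
#' `panel`, `material_type`, `growth_habit`, `row_type`, `country`,
#' `region`, `core_flag`. Blank or missing values become `"Unknown"`.
#' When `region` is blank it can be derived from `country` through a
#' user-supplied mapping (the agri-ecological region classification is
#' input data, not code).
#'
#' @param path path to the passport CSV; the first column is the sample id.
#' @param region_map optional country-to-region mapping: a named character
#'   vector, a data.frame with columns `country` and `region`, or a path
#'   to a two-column CSV.
#' @return data.frame of class `passport_table` with column `sample`
#'   followed by the descriptor columns.
#' @export
read_passport <- function(path, region_map = NULL) {
  if (!file.exists(path)) stop("passport file not found: ", path,
                               call. = FALSE)
  tab <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  names(tab)[1L] <- "sample"
  for (f in PASSPORT_FIELDS) {
    if (is.null(tab[[f]])) tab[[f]] <- NA_character_
    tab[[f]] <- as.character(tab[[f]])
  }
  if (!is.null(region_map)) {
    map <- normalize_region_map(region_map)
    blank <- is.na(tab$region) | tab$region == "Unknown"
    hit <- map[tab$country[blank]]
    tab$region[blank][!is.na(hit)] <- hit[!is.na(hit)]
  }
  for (f in PASSPORT_FIELDS)
    tab[[f]][is.na(tab[[f]])] <- "Unknown"
  if (anyDuplicated(tab$sample))
    stop("duplicate sample id in passport: ",
         tab$sample[duplicated(tab$sample)][1], call. = FALSE)
  out <- tab[, c("sample", PASSPORT_FIELDS)]
  class(out) <- c("passport_table", "data.frame")
  out
}

normalize_region_map <- function(region_map) {
  if (is.character(region_map) && length(region_map) == 1L &&
      file.exists(region_map))
    region_map <- utils::read.csv(region_map, stringsAsFactors = FALSE)
  if (is.data.frame(region_map)) {
    map <- region_map[[2L]]
    names(map) <- region_map[[1L]]
  } else {
    map <- region_map
  }
  if (is.null(names(map)))
    stop("region_map must map country names to regions", call. = FALSE)
  map
}

#' Align a passport table with a genotype sample list
#'
#' Samples present in the passport but absent from the genotypes raise a
#' warning and are retained; genotyped samples absent from the passport
#' are filled in with all-"Unknown" descriptors.
#'
#' @param passport a [read_passport] result.
#' @param samples character vector of genotyped sample ids.
#' @return `passport_table` reordered to `samples`.
#' @export
align_passport <- function(passport, samples) {
  extra <- setdiff(passport$sample, samples)
  if (length(extra))
    warning(length(extra), " passport sample(s) absent from genotypes ",
            "(e.g. ", extra[1], ")", call. = FALSE)
  idx <- match(samples, passport$sample)
  out <- passport[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  out$sample <- samples
  out[is.na(idx), PASSPORT_FIELDS] <- "Unknown"
  rownames(out) <- NULL
  class(out) <- c("passport_table", "data.frame")
  out
}
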