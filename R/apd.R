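#' Pairwise genetic difference between two dosage vectors
#'
#' The default allele-sharing distance is the mean over co-genotyped loci
#' of `|a - b| / 2`, so two identical genotypes score 0 and opposite
#' homozygotes score 1. `"simple_matching"` instead scores the proportion
#' of co-genotyped loci with unequal dosage. Loci missing in either
#' sample are ignored (pairwise deletion).
#'
#' @param a,b integer dosage vectors of equal length (values 0/1/2/NA).
#' @param distance `"allele_sharing"` (default) or `"simple_matching"`.
#' @return a number in `[0, 1]`.
#' @export
pairwise_difference <- function(a, b,
                                distance = c("allele_sharing",
                                             "simple_matching")) {
  distance <- match.arg(distance)
  if (length(a) != length(b))
    stop("dosage vectors must have equal length", call. = FALSE)
  obs <- !is.na(a) & !is.na(b)
  if (!any(obs))
    stop("no co-genotyped loci between the two samples", call. = FALSE)
  if (distance == "allele_sharing")
    mean(abs(a[obs] - b[obs]) / 2)
  else
    mean(a[obs] != b[obs])
}

#' Average pairwise difference (APD) per sample
#'
#' For each sample, the mean of its pairwise genetic differences to every
#' other sample. The larger a sample's APD, the more genetically distinct
#' it is from the rest of the cohort; near-duplicates have low APD.
#'
#' The N x N distance computation is performed blockwise through dosage
#' indicator matrix products (memory O(N * block_size) beyond the inputs),
#' and is exactly equivalent to the naive double loop over
#' [pairwise_difference].
#'
#' @param gm a [genotype_matrix] with at least two samples.
#' @param distance `"allele_sharing"` (default) or `"simple_matching"`.
#' @param block_size number of samples per block (default 512).
#' @return data.frame of class `apd_vector` with columns `sample`, `apd`,
#'   `n_comparisons` (= N - 1).
#' @export
apd_vector <- function(gm, distance = c("allele_sharing",
                                        "simple_matching"),
                       block_size = 512L) {
  distance <- match.arg(distance)
  stopifnot(inherits(gm, "genotype_matrix"))
  N <- length(gm$samples)
  if (N < 2L) stop("APD needs at least two samples", call. = FALSE)
  d <- gm$dosage
  I0 <- matrix(0, N, ncol(d)); I0[!is.na(d) & d == 0L] <- 1
  I1 <- matrix(0, N, ncol(d)); I1[!is.na(d) & d == 1L] <- 1
  I2 <- matrix(0, N, ncol(d)); I2[!is.na(d) & d == 2L] <- 1
  Obs <- I0 + I1 + I2
  tI0 <- t(I0); tI1 <- t(I1); tI2 <- t(I2); tObs <- t(Obs)
  apd <- numeric(N)
  starts <- seq(1L, N, by = block_size)
  for (s in starts) {
    rows <- s:min(s + block_size - 1L, N)
    C <- Obs[rows, , drop = FALSE] %*% tObs
    if (distance == "allele_sharing") {
      # sum over loci of |a - b|: dosage gaps of 1 and 2 weighted 1 and 2
      S <- I0[rows, , drop = FALSE] %*% tI1 +
        I1[rows, , drop = FALSE] %*% tI0 +
        I1[rows, , drop = FALSE] %*% tI2 +
        I2[rows, , drop = FALSE] %*% tI1 +
        2 * (I0[rows, , drop = FALSE] %*% tI2 +
               I2[rows, , drop = FALSE] %*% tI0)
      D <- S / (2 * C)
    } else {
      M <- I0[rows, , drop = FALSE] %*% tI0 +
        I1[rows, , drop = FALSE] %*% tI1 +
        I2[rows, , drop = FALSE] %*% tI2
      D <- 1 - M / C
    }
    diag_idx <- cbind(seq_along(rows), rows)
    off <- C
    off[diag_idx] <- 1  # self-comparison never flags the C == 0 check
    if (any(off == 0)) {
      j <- which(off == 0, arr.ind = TRUE)[1L, ]
      stop("no co-genotyped loci between samples ",
           gm$samples[rows[j[1L]]], " and ", gm$samples[j[2L]],
           call. = FALSE)
    }
    D[diag_idx] <- 0
    apd[rows] <- rowSums(D) / (N - 1L)
  }
  out <- data.frame(sample = gm$samples, apd = apd,
                    n_comparisons = N - 1L, stringsAsFactors = FALSE)
  class(out) <- c("apd_vector", "data.frame")
  out
}
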