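#' Group-wise summary of burden estimates
#'
#' Per-group count, mean, sample standard deviation (n - 1 denominator),
#' minimum and maximum. SD is reported as `NA` for single-sample groups.
#' Values are returned at full precision; rounding is a formatting
#' concern (see [format_group_summary]).
#'
#' @param values numeric vector (typically per-sample total burden).
#' @param labels group label per value; `"Unknown"` is a valid label.
#' @return data.frame of class `group_summary` with columns `group`, `n`,
#'   `mean`, `sd`, `min`, `max`, ordered by group label.
#' @export
group_summary <- function(values, labels) {
  if (!length(values)) stop("no values to summarise", call. = FALSE)
  if (length(values) != length(labels))
    stop("values and labels differ in length", call. = FALSE)
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- values[labels == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("group_summary", "data.frame")
  out
}

#' Format a group summary with fixed rounding
#'
#' Applies the reporting convention: 5 decimals for country-level tables,
#' 4 for coarser groupings (pass `digits`). Uses R's round-half-even.
#'
#' @param gs a `group_summary`.
#' @param digits decimal places for the statistics columns.
#' @return data.frame with character-formatted statistic columns.
#' @export
format_group_summary <- function(gs, digits = 5L) {
  fmt <- function(v) ifelse(is.na(v), "NA",
                            formatC(round(v, digits), digits = digits,
                                    format = "f"))
  data.frame(group = gs$group, n = gs$n, mean = fmt(gs$mean),
             sd = fmt(gs$sd), min = fmt(gs$min), max = fmt(gs$max),
             stringsAsFactors = FALSE)
}

#' One-way fixed-effects ANOVA
#'
#' Tests equality of group means with the standard one-way F statistic
#' F = (SSB / (k - 1)) / (SSW / (n - k)), fitted via [stats::lm]. Groups
#' in `exclude` (by default the `"Unknown"` label) are dropped before
#' testing; excluded labels still appear in [group_summary] tables.
#' Degenerate inputs are resolved explicitly: zero between-group sum of
#' squares gives F = 0 (p = 1); zero within-group sum of squares with a
#' real between-group difference gives F = Inf, p = 0, with a warning.
#'
#' @param values numeric vector.
#' @param labels group label per value.
#' @param exclude labels dropped before testing (default `"Unknown"`).
#' @return list of class `anova_result` with `F`, `df_between`,
#'   `df_within`, `p_value`, `ss_between`, `ss_within`, `n`, `k`.
#' @export
anova_oneway <- function(values, labels, exclude = "Unknown") {
  labels <- as.character(labels)
  keep <- !(labels %in% exclude) & !is.na(values) & !is.na(labels)
  y <- values[keep]
  g <- factor(labels[keep])
  k <- nlevels(g)
  n <- length(y)
  if (k < 2L) stop("ANOVA needs at least two groups after exclusion",
                   call. = FALSE)
  if (n <= k) stop("ANOVA needs more observations than groups",
                   call. = FALSE)
  # degenerate (perfect or null) fits are resolved explicitly below, so
  # anova.lm's unreliability warning for those cases is redundant
  tab <- suppressWarnings(stats::anova(stats::lm(y ~ g)))
  ssb <- tab[["Sum Sq"]][1L]
  ssw <- tab[["Sum Sq"]][2L]
  df_b <- tab[["Df"]][1L]
  df_w <- tab[["Df"]][2L]
  tol <- max(1e-24, 1e-14 * (ssb + ssw))
  if (ssb <= tol) {
    f <- 0
    p <- 1
  } else if (ssw <= tol) {
    warning("zero within-group variance with a between-group difference",
            call. = FALSE)
    f <- Inf
    p <- 0
  } else {
    f <- tab[["F value"]][1L]
    p <- tab[["Pr(>F)"]][1L]
  }
  structure(list(F = f, df_between = df_b, df_within = df_w,
                 p_value = p, ss_between = ssb, ss_within = ssw,
                 n = n, k = k),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g (k = %d, n = %d)\n",
              x$df_between, x$df_within, x$F, x$p_value, x$k, x$n))
  invisible(x)
}

#' Correlation between mutation burden and genetic distinctness
#'
#' Pearson correlation between per-sample total burden and APD, with the
#' two-sided p-value from the t transform of r. At genebank cohort sizes
#' (tens of thousands of samples) even tiny correlations are formally
#' significant, so interpretation should rest on r itself.
#'
#' @param burdens,apds equal-length paired numeric vectors, n >= 3.
#' @return list of class `burden_apd_cor` with `r`, `p_value`, `n`.
#' @export
correlate_burden_apd <- function(burdens, apds) {
  if (length(burdens) != length(apds))
    stop("burden and APD vectors differ in length", call. = FALSE)
  ok <- !is.na(burdens) & !is.na(apds)
  x <- burdens[ok]
  y <- apds[ok]
  if (length(x) < 3L) stop("need at least three paired values",
                           call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in burden or APD; correlation undefined",
         call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x)),
            class = "burden_apd_cor")
}

#' @export
print.burden_apd_cor <- function(x, ...) {
  cat(sprintf("burden-APD Pearson r = %.4f (n = %d, p = %.3g)\n",
              x$r, x$n, x$p_value))
  invisible(x)
}

#' Selection target zone: distinct, low-burden germplasm
#'
#' Implements the rectangle rule for germplasm choice: retain samples
#' whose genetic distinctness (APD) is at least `apd_min` and whose total
#' mutation burden is at most `burden_max`. Zero-burden samples always
#' qualify when their APD clears the threshold.
#'
#' @param burdens,apds equal-length per-sample vectors.
#' @param apd_min,burden_max finite zone thresholds.
#' @param samples optional sample ids (defaults to names or indices).
#' @return list of class `selection_zone` with `apd_min`, `burden_max`,
#'   `members` (sample ids), `n`.
#' @export
selection_zone <- function(burdens, apds, apd_min, burden_max,
                           samples = NULL) {
  stopifnot(is.finite(apd_min), is.finite(burden_max))
  if (length(burdens) != length(apds))
    stop("burden and APD vectors differ in length", call. = FALSE)
  if (is.null(samples))
    samples <- if (!is.null(names(burdens))) names(burdens)
               else as.character(seq_along(burdens))
  inside <- apds >= apd_min & burdens <= burden_max
  inside[is.na(inside)] <- FALSE
  structure(list(apd_min = apd_min, burden_max = burden_max,
                 members = samples[inside], n = sum(inside)),
            class = "selection_zone")
}

#' @export
print.selection_zone <- function(x, ...) {
  cat(sprintf("selection zone (APD >= %.4g, burden <= %.4g): %d sample(s)\n",
              x$apd_min, x$burden_max, x$n))
  invisible(x)
}
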