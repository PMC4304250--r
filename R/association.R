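#' Cross-tabulate a clinical covariate against subtype labels
#'
#' Builds the contingency table of a categorical covariate by subtype,
#' together with within-subtype percentages (denominator = subtype size,
#' rounded to one decimal), the layout of a clinicopathologic
#' characteristics table.
#'
#' @param clinical Data frame with one row per sample.
#' @param covariate Name of a categorical column of \code{clinical}.
#' @param labels Subtype label per sample (same order as \code{clinical}).
#' @return Object of class \code{"crosstab"}: list with \code{counts}
#'   (levels x subtypes), \code{percent} (same shape, one decimal),
#'   \code{covariate}.
#' @examples
#' cl <- data.frame(r_status = c("R0", "R0", "R1R2"))
#' crosstab(cl, "r_status", c(1, 1, 2))
#' @export
crosstab <- function(clinical, covariate, labels) {
  if (!covariate %in% names(clinical)) {
    stop(sprintf("unknown covariate '%s'", covariate))
  }
  if (length(labels) != nrow(clinical)) {
    stop("labels must cover all samples")
  }
  cov_f <- clinical[[covariate]]
  if (!is.factor(cov_f)) cov_f <- factor(cov_f)  # keep preset levels
  counts <- table(cov_f, factor(labels))
  counts <- unclass(counts)
  group_n <- colSums(counts)
  percent <- round(100 * sweep(counts, 2, pmax(group_n, 1), "/"), 1)
  structure(list(counts = counts, percent = percent, covariate = covariate),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat(sprintf("Crosstab of '%s' (count, %% within group):\n", x$covariate))
  disp <- matrix(sprintf("%d (%.1f%%)", x$counts, x$percent),
                 nrow = nrow(x$counts), dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Association test for a contingency table
#'
#' Fisher's exact test (two-sided, by point-probability summation) for 2x2
#' tables, Pearson chi-square otherwise; the method can be forced. A table
#' with a zero row or column margin carries no association information and
#' returns p = 1 with a message.
#'
#' @param x A \code{"crosstab"} or a count matrix.
#' @param method \code{"auto"} (default), \code{"fisher"} or \code{"chisq"}.
#' @return The p-value.
#' @export
categorical_test <- function(x, method = c("auto", "fisher", "chisq")) {
  method <- match.arg(method)
  counts <- if (inherits(x, "crosstab")) x$counts else as.matrix(x)
  if (sum(counts) == 0) stop("empty table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    message("degenerate table (zero margin); p defined as 1")
    return(1)
  }
  if (method == "auto") {
    method <- if (all(dim(counts) == c(2, 2))) "fisher" else "chisq"
  }
  if (method == "fisher") {
    stats::fisher.test(counts)$p.value
  } else {
    suppressWarnings(stats::chisq.test(counts)$p.value)
  }
}

#' Kruskal-Wallis rank test of a continuous variable across groups
#'
#' Rank-based H statistic with tie correction, referred to a chi-square
#' with k - 1 df. All-identical values carry no rank information: H = 0,
#' p = 1.
#'
#' @param values Numeric vector.
#' @param labels Group label per value (>= 2 groups, each non-empty).
#' @return List with \code{statistic} (H) and \code{p_value}.
#' @export
kruskal_wallis <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least two groups")
  if (length(values) != length(labels)) stop("values and labels differ in length")
  if (stats::var(values) == 0) {
    return(list(statistic = 0, p_value = 1))
  }
  kt <- stats::kruskal.test(values, labels)
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}
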