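#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two samples, the workhorse test for comparing
#' per-patient cell-type fractions or marker medians between outcome groups.
#' The p-value is exact (by enumeration of rank arrangements, via the null
#' distribution of U) when the pooled sample size is at most 12 and there are
#' no ties; otherwise the normal approximation with tie correction is used,
#' without continuity correction.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return A tibble with one row: `u` (the U statistic of `x`), `p_value`
#'   (two-sided), `n_x`, `n_y`, and `method` ("exact" or "normal").
#' @examples
#' mann_whitney_u(c(0.9, 0.8, 0.7), c(0.1, 0.2, 0.3))
#' @export
mann_whitney_u <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) {
    rlang::abort("`x` and `y` must each contain at least one value.")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  # an all-tied comparison has zero variance in the normal approximation
  p <- if (is.finite(wt$p.value)) min(wt$p.value, 1) else 1
  tibble::tibble(
    u = unname(wt$statistic),
    p_value = p,
    n_x = length(x),
    n_y = length(y),
    method = if (exact) "exact" else "normal"
  )
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value.
#' Used e.g. to check that per-patient cell counts do not drive the number of
#' phenotypes detected.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return A tibble with `rho`, `p_value` and `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) rlang::abort("Need at least 3 paired observations.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Spearman correlation is undefined for constant input.")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' the observed table's probability.
#'
#' @param table A 2x2 matrix of non-negative integer counts.
#' @return A tibble with `p_value` and `odds_ratio` (conditional MLE).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) rlang::abort("`table` must be 2x2.")
  if (any(table < 0) || any(table != round(table))) {
    rlang::abort("Counts must be non-negative integers.")
  }
  ft <- stats::fisher.test(table)
  tibble::tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate))
}

#' Kaplan-Meier curves and Mantel-Cox log-rank test
#'
#' Product-limit recurrence-free survival per group and the log-rank
#' (Mantel-Cox) chi-square comparing groups. Time zero is primary treatment;
#' `event = 1` marks recurrence and `event = 0` censoring (end of follow-up or
#' death from other causes).
#'
#' @param outcomes A data frame with columns `time_months` (positive) and
#'   `event` (0/1), one row per patient.
#' @param groups A vector (length `nrow(outcomes)`) of group labels.
#' @return An object of class `imc_survfit` with elements `fit`
#'   (a [survival::survfit] object), `chisq`, `df`, `p_value`, and `groups`, a
#'   tibble of per-group patient and event counts with a `label` column
#'   formatted "n (events)" for figure legends.
#' @examples
#' d <- tibble::tibble(time_months = c(3, 8, 14, 20, 30, 40),
#'                     event = c(1, 1, 1, 0, 0, 0))
#' km_logrank(d, groups = c("low", "low", "low", "high", "high", "high"))
#' @export
km_logrank <- function(outcomes, groups) {
  stopifnot(all(c("time_months", "event") %in% names(outcomes)))
  if (any(outcomes$time_months <= 0)) rlang::abort("`time_months` must be positive.")
  if (!all(outcomes$event %in% c(0, 1))) rlang::abort("`event` must be 0 or 1.")
  groups <- as.factor(groups)
  if (length(groups) != nrow(outcomes)) {
    rlang::abort("`groups` must have one label per outcome row.")
  }
  if (nlevels(droplevels(groups)) < 2L) rlang::abort("Need at least 2 groups.")
  if (sum(outcomes$event) < 1L) rlang::abort("Need at least one event.")
  dat <- data.frame(
    time = outcomes$time_months, event = outcomes$event, group = groups
  )
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = dat)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  df <- length(sd$n) - 1L
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  per_group <- tibble::tibble(
    group = sub("^group=", "", names(sd$n)),
    n = as.integer(sd$n),
    events = as.integer(sd$obs)
  ) |>
    dplyr::mutate(label = sprintf("%d (%d)", .data$n, .data$events))
  structure(
    list(fit = fit, chisq = unname(sd$chisq), df = df, p_value = p,
         groups = per_group),
    class = "imc_survfit"
  )
}

#' @export
print.imc_survfit <- function(x, ...) {
  cat("Kaplan-Meier recurrence-free survival comparison\n")
  cat(sprintf("  log-rank (Mantel-Cox) chi-square = %.3f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p_value))
  cat("  patients (events): ",
      paste(x$groups$group, x$groups$label, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Dichotomize per-patient values into two groups
#'
#' @param values Numeric vector of per-patient summaries (e.g. median
#'   epithelial vimentin expression, or IHC staining index).
#' @param rule One of `"median"` (at or below the median -> "low"),
#'   `"lowest_quartile"` (at or below the 25th percentile -> "low"), or
#'   `"zero_vs_positive"` (exactly zero -> "loss", otherwise "positive").
#' @return A factor with levels `c("low", "high")` or
#'   `c("loss", "positive")`.
#' @export
dichotomize <- function(values, rule = c("median", "lowest_quartile",
                                         "zero_vs_positive")) {
  rule <- match.arg(rule)
  values <- as.numeric(values)
  if (rule == "lowest_quartile" && length(values) < 4L) {
    rlang::abort("The quartile rule needs at least 4 patients.")
  }
  if (length(unique(values)) == 1L && rule != "zero_vs_positive") {
    rlang::abort("All values are equal; the split is degenerate.")
  }
  switch(rule,
    median = {
      cut_at <- stats::median(values)
      factor(ifelse(values <= cut_at, "low", "high"), levels = c("low", "high"))
    },
    lowest_quartile = {
      cut_at <- stats::quantile(values, 0.25, names = FALSE)
      factor(ifelse(values <= cut_at, "low", "high"), levels = c("low", "high"))
    },
    zero_vs_positive = {
      factor(ifelse(values == 0, "loss", "positive"),
             levels = c("loss", "positive"))
    }
  )
}

#' Immunohistochemistry staining index
#'
#' The semi-quantitative staining index (SI) is the product of a staining
#' intensity score (loss = 0, weak = 1, moderate = 2, strong = 3) and a
#' positive-area score (<10% = 1, 10-50% = 2, >50% = 3), so its attainable
#' values are exactly {0, 1, 2, 3, 4, 6, 9}.
#'
#' @param intensity_score Integer(s) in {0, 1, 2, 3}.
#' @param area_score Integer(s) in {1, 2, 3}.
#' @return Integer vector of SI values.
#' @examples
#' staining_index(3, 3) # 9, the maximum
#' @export
staining_index <- function(intensity_score, area_score) {
  if (!all(intensity_score %in% 0:3)) {
    rlang::abort("`intensity_score` must be in {0, 1, 2, 3}.")
  }
  if (!all(area_score %in% 1:3)) {
    rlang::abort("`area_score` must be in {1, 2, 3}.")
  }
  as.integer(intensity_score) * as.integer(area_score)
}

#' Select high-purity samples by expression-derived score
#'
#' Picks the `floor(fraction * n)` samples with the lowest purity score
#' (lower score = higher tumor purity, the ESTIMATE convention), used to
#' restrict bulk expression comparisons to epithelial-rich samples. Ties are
#' broken deterministically by sample id.
#'
#' @param scores A data frame with columns `sample_id` and `score`, or a
#'   named numeric vector.
#' @param fraction Fraction of samples to keep, in (0, 1); default 0.33.
#' @return A tibble of the selected rows, sorted by score then id, with the
#'   number selected as attribute `n_selected`.
#' @export
select_high_purity <- function(scores, fraction = 0.33) {
  if (is.numeric(scores)) {
    scores <- tibble::tibble(
      sample_id = if (is.null(names(scores))) as.character(seq_along(scores))
                  else names(scores),
      score = unname(scores)
    )
  }
  stopifnot(all(c("sample_id", "score") %in% names(scores)))
  if (fraction <= 0 || fraction >= 1) rlang::abort("`fraction` must be in (0, 1).")
  n <- nrow(scores)
  if (n < 3L) rlang::abort("Need at least 3 samples.")
  n_sel <- floor(fraction * n)
  if (n_sel < 1L) rlang::abort("`fraction` selects zero samples.")
  out <- scores |>
    dplyr::arrange(.data$score, .data$sample_id) |>
    dplyr::slice_head(n = n_sel)
  attr(out, "n_selected") <- n_sel
  out
}
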