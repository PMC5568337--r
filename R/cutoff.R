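#' Relative ratio of case:control composition above a score cutoff
#'
#' The enrichment statistic for a score threshold: with `a` cases and `b`
#' controls at or above the cutoff out of `A` total cases and `B` total
#' controls, the relative ratio is `(a/b) / (A/B)` - the case:control ratio
#' in the high-score stratum expressed with the full-sample ratio set to 1.
#'
#' @param a,b Case and control counts at or above the cutoff.
#' @param A,B Total case and control counts (`A > 0`, `B > 0`).
#' @return A double. `b = 0` with `a > 0` returns `Inf` (complete
#'   separation); `a = b = 0` returns `NaN` (undefined, empty stratum).
#' @examples
#' relative_ratio(29, 11, 255, 246) # ~2.54
#' @export
relative_ratio <- function(a, b, A, B) {
  if (!is_count(a) || !is_count(b) || !is_count(A) || !is_count(B)) {
    abort_contract("counts must be single non-negative integers")
  }
  if (A <= 0 || B <= 0) abort_contract("totals A and B must be positive")
  if (a > A || b > B) {
    abort_contract("stratum counts cannot exceed totals (a <= A, b <= B)")
  }
  if (a == 0 && b == 0) return(NaN)
  if (b == 0) return(Inf)
  (a / b) / (A / B)
}

#' Pearson chi-square test for a 2x2 table
#'
#' One-degree-of-freedom Pearson chi-square, optionally with the Yates
#' continuity correction. Tables with a zero row or column margin are
#' rejected as degenerate.
#'
#' @param x A 2x2 matrix of non-negative counts.
#' @param yates Apply the Yates continuity correction.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `yates`.
#' @examples
#' chi_square_2x2(matrix(c(20, 10, 10, 20), 2), yates = FALSE)
#' @export
chi_square_2x2 <- function(x, yates = FALSE) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) abort_contract("x must be a 2x2 table")
  if (any(!is.finite(x)) || any(x < 0)) {
    abort_contract("counts must be finite and non-negative")
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    abort_degenerate("2x2 table has a zero margin")
  }
  ct <- suppressWarnings(stats::chisq.test(x, correct = yates))
  tibble::tibble(
    statistic = unname(ct$statistic),
    df = 1L,
    p_value = unname(ct$p.value),
    yates = yates
  )
}

#' Enrichment analysis at one score cutoff
#'
#' Counts cases (default HTG) and controls with score at or above `threshold`,
#' computes the relative ratio against the full sample, and tests the
#' partition table `(score >= t vs score < t) x (case vs control)` with the
#' Pearson chi-square, both uncorrected and Yates-corrected. Degenerate
#' partition tables (e.g. a threshold that includes or excludes everyone)
#' yield `NA` test columns with an explanatory flag.
#'
#' @param data A `grs_cohort` or data frame with the score and group columns.
#' @param threshold Score cutoff (participants with `score >= threshold` are
#'   in the high-score stratum).
#' @param score,group Column names.
#' @param case_group,control_group Group labels to compare.
#' @return A one-row tibble: `threshold`, `a`, `b`, `A`, `B`,
#'   `relative_ratio`, `ratio_flag` (`"ok"`, `"infinite"`, `"undefined"`),
#'   `chi2_uncorrected`, `p_uncorrected`, `chi2_yates`, `p_yates`,
#'   `test_flag`.
#' @export
cutoff_table <- function(data, threshold, score = "grs", group = "group",
                         case_group = "HTG", control_group = "control") {
  data <- as_analysis_df(data)
  d <- data[data[[group]] %in% c(case_group, control_group), , drop = FALSE]
  d <- d[!is.na(d[[score]]), ]
  is_case <- d[[group]] == case_group
  A <- sum(is_case)
  B <- sum(!is_case)
  if (A == 0L || B == 0L) {
    abort_contract("need at least one case and one control row")
  }
  hi <- d[[score]] >= threshold
  a <- sum(hi & is_case)
  b <- sum(hi & !is_case)
  rr <- relative_ratio(a, b, A, B)
  flag <- if (is.nan(rr)) "undefined" else if (is.infinite(rr)) "infinite" else "ok"
  tab <- matrix(c(a, A - a, b, B - b), nrow = 2L, byrow = TRUE,
                dimnames = list(c(case_group, control_group),
                                c("high", "low")))
  tests <- tryCatch(
    list(
      un = chi_square_2x2(tab, yates = FALSE),
      ya = chi_square_2x2(tab, yates = TRUE),
      flag = "ok"
    ),
    iopgrs_degenerate_error = function(e) {
      list(un = tibble::tibble(statistic = NA_real_, p_value = NA_real_),
           ya = tibble::tibble(statistic = NA_real_, p_value = NA_real_),
           flag = "degenerate_table")
    }
  )
  tibble::tibble(
    threshold = threshold,
    a = a, b = b, A = A, B = B,
    relative_ratio = rr,
    ratio_flag = flag,
    chi2_uncorrected = tests$un$statistic,
    p_uncorrected = tests$un$p_value,
    chi2_yates = tests$ya$statistic,
    p_yates = tests$ya$p_value,
    test_flag = tests$flag
  )
}

#' Scan all score cutoffs
#'
#' Applies [cutoff_table()] across a grid of thresholds (default the integer
#' range 0-18 of the unweighted nine-variant score). The counts `a` and `b`
#' are non-increasing in the threshold and the relative ratio at the minimum
#' attainable threshold is exactly 1.
#'
#' @inheritParams cutoff_table
#' @param thresholds Numeric vector of cutoffs (integers for the unweighted
#'   score; any grid for weighted scores).
#' @return A tibble of class `grs_cutoff_scan`, one row per threshold.
#' @export
cutoff_scan <- function(data, thresholds = 0:18, score = "grs",
                        group = "group", case_group = "HTG",
                        control_group = "control") {
  out <- purrr::map_dfr(
    thresholds,
    function(t) cutoff_table(data, t, score = score, group = group,
                             case_group = case_group,
                             control_group = control_group)
  )
  class(out) <- c("grs_cutoff_scan", class(out))
  out
}
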