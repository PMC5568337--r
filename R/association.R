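# coerce a grs_cohort or ready-made analysis tibble to the modelling frame
as_analysis_df <- function(x) {
  if (inherits(x, "grs_cohort")) cohort_data(x) else tibble::as_tibble(x)
}

#' Multiple linear regression with standardized coefficients
#'
#' Ordinary least squares with an intercept; for each predictor the
#' standardized coefficient `beta = b * sd(x) / sd(y)` is reported alongside
#' the raw coefficient and its raw-scale standard error (the convention used
#' in clinical regression tables that print standardized Beta next to
#' raw-scale SE), with two-sided t-test p-values and the joint model F test.
#'
#' Rows with a missing outcome or predictor are dropped and counted in
#' `n_used`. Constant predictor columns and rank-deficient designs are
#' rejected with informative errors.
#'
#' @param data A data frame (or `grs_cohort`).
#' @param outcome Name of the outcome column.
#' @param predictors Character vector of predictor column names.
#' @return An object of class `grs_lm` with a `coefficients` tibble (`term`,
#'   `estimate`, `se`, `beta_standardized`, `statistic`, `p_value`), the model
#'   `f_statistic`, `f_p_value`, `n_used`, `r_squared` and the underlying
#'   `fit`.
#' @examples
#' d <- data.frame(y = rnorm(50), x = rnorm(50))
#' tidy(standardized_lm(d, "y", "x"))
#' @export
standardized_lm <- function(data, outcome, predictors) {
  data <- as_analysis_df(data)
  missing_cols <- setdiff(c(outcome, predictors), names(data))
  if (length(missing_cols)) {
    abort_schema(paste0("missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  d <- data[, c(outcome, predictors), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(predictors) + 1L) {
    abort_contract("insufficient data: need n > number of predictors + 1")
  }
  sds <- vapply(d[predictors], stats::sd, numeric(1))
  if (any(sds == 0)) {
    abort_collinearity(paste0(
      "constant predictor column(s): ",
      paste(predictors[sds == 0], collapse = ", ")
    ))
  }
  fit <- stats::lm(stats::reformulate(sprintf("`%s`", predictors),
                                      sprintf("`%s`", outcome)),
                   data = d)
  if (anyNA(stats::coef(fit))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    abort_collinearity(paste0(
      "rank-deficient design; linearly dependent column(s): ",
      paste(gsub("`", "", aliased), collapse = ", ")
    ))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  terms_raw <- gsub("`", "", rownames(co)[-1L])
  sd_y <- stats::sd(d[[outcome]])
  coefs <- tibble::tibble(
    term = terms_raw,
    estimate = unname(co[-1L, "Estimate"]),
    se = unname(co[-1L, "Std. Error"]),
    beta_standardized = unname(co[-1L, "Estimate"] * sds[terms_raw]) / sd_y,
    statistic = unname(co[-1L, "t value"]),
    p_value = unname(co[-1L, "Pr(>|t|)"])
  )
  fs <- sm$fstatistic
  structure(
    list(
      coefficients = coefs,
      f_statistic = unname(fs["value"]),
      f_p_value = unname(stats::pf(fs["value"], fs["numdf"], fs["dendf"],
                                   lower.tail = FALSE)),
      n_used = n,
      r_squared = sm$r.squared,
      adj_r_squared = sm$adj.r.squared,
      sigma = sm$sigma,
      outcome = outcome,
      fit = fit
    ),
    class = "grs_lm"
  )
}

#' @export
print.grs_lm <- function(x, ...) {
  cat("<grs_lm> outcome:", x$outcome, " n =", x$n_used, "\n")
  print(x$coefficients)
  cat(sprintf("model F = %.3f, p = %.3g, R^2 = %.4f\n",
              x$f_statistic, x$f_p_value, x$r_squared))
  invisible(x)
}

#' Stage wrappers for the standard regression analyses
#'
#' Fixed-predictor conveniences over [standardized_lm()], operating on a
#' cohort (or its flattened analysis tibble):
#' * `iop_on_variants()` - maximum IOP on age, sex and the nine per-variant
#'   dosages (per-variant effect table).
#' * `iop_on_grs()` - maximum IOP on age, sex and the unweighted GRS.
#' * `vcdr_on_grs()` - mean VCDR on age, sex and the unweighted GRS.
#' * `iop_vcdr_correlation()` - mean VCDR on maximum IOP alone; the
#'   standardized coefficient of a single-predictor model equals the Pearson
#'   correlation.
#'
#' @param x A `grs_cohort` or analysis tibble (needs columns `max_iop_mmHg`,
#'   `mean_vcdr`, `age_years`, `male`, `grs` and, for `iop_on_variants`, the
#'   dosage columns).
#' @param panel Variant panel naming the dosage columns.
#' @param score Score column for the GRS models.
#' @return A `grs_lm` object.
#' @name stage_regressions
NULL

#' @rdname stage_regressions
#' @export
iop_on_variants <- function(x, panel = iop_variant_panel()) {
  standardized_lm(x, "max_iop_mmHg", c("age_years", "male", panel$rsid))
}

#' @rdname stage_regressions
#' @export
iop_on_grs <- function(x, score = "grs") {
  standardized_lm(x, "max_iop_mmHg", c("age_years", "male", score))
}

#' @rdname stage_regressions
#' @export
vcdr_on_grs <- function(x, score = "grs") {
  standardized_lm(x, "mean_vcdr", c("age_years", "male", score))
}

#' @rdname stage_regressions
#' @export
iop_vcdr_correlation <- function(x) {
  standardized_lm(x, "mean_vcdr", "max_iop_mmHg")
}

#' One-way ANOVA with Bonferroni post hoc comparisons
#'
#' Compares a score across the three diagnostic groups with a fixed-effects
#' one-way ANOVA, followed by all pairwise two-sided t-tests using the pooled
#' (full-model) variance. Unadjusted pairwise p-values are reported alongside
#' the Bonferroni threshold `alpha / 3` and the 3-fold-multiplied adjusted
#' values; significance is declared at `p < alpha / 3`.
#'
#' @param data A `grs_cohort` or data frame.
#' @param score Score column name.
#' @param group Group column name (must contain at least three levels).
#' @param var_equal `TRUE` (default) for classical pooled-variance pairwise
#'   t-tests; `FALSE` for the Welch variant.
#' @param alpha Family significance level (default 0.05).
#' @return An object of class `grs_anova`: `group_stats` tibble, overall
#'   `f_statistic`/`p_value` (with df), `pairwise` tibble (`pair`,
#'   `p_unadjusted`, `p_bonferroni`, `significant`), and the Bonferroni
#'   threshold used.
#' @export
anova_bonferroni <- function(data, score = "grs", group = "group",
                             var_equal = TRUE, alpha = 0.05) {
  data <- as_analysis_df(data)
  d <- data[, c(score, group)]
  names(d) <- c("score", "group")
  d <- d[stats::complete.cases(d), ]
  d$group <- factor(d$group)
  k <- nlevels(droplevels(d$group))
  if (k < 3L) {
    abort_contract("anova_bonferroni requires at least 3 non-empty groups")
  }
  d$group <- droplevels(d$group)
  if (nrow(d) < 2L || all(tapply(d$score, d$group, stats::var) == 0)) {
    abort_contract("need >= 2 observations and nonzero variance in >= 1 group")
  }
  fit <- stats::aov(score ~ group, data = d)
  an <- summary(fit)[[1L]]
  pw <- stats::pairwise.t.test(d$score, d$group, p.adjust.method = "none",
                               pool.sd = var_equal)
  pm <- pw$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  n_pairs <- choose(k, 2L)
  pairwise <- tibble::tibble(
    pair = paste(rownames(pm)[pairs[, 1L]], colnames(pm)[pairs[, 2L]],
                 sep = " vs "),
    p_unadjusted = pm[pairs],
    p_bonferroni = pmin(1, pm[pairs] * n_pairs),
    significant = pm[pairs] < alpha / n_pairs
  )
  structure(
    list(
      group_stats = d |>
        dplyr::group_by(.data$group) |>
        dplyr::summarise(n = dplyr::n(), mean = mean(.data$score),
                         sd = stats::sd(.data$score), .groups = "drop"),
      f_statistic = an[["F value"]][1L],
      df = c(an[["Df"]][1L], an[["Df"]][2L]),
      p_value = an[["Pr(>F)"]][1L],
      pairwise = pairwise,
      alpha_bonferroni = alpha / n_pairs,
      var_equal = var_equal,
      n_used = nrow(d)
    ),
    class = "grs_anova"
  )
}

#' @export
print.grs_anova <- function(x, ...) {
  cat(sprintf("<grs_anova> F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1L], x$df[2L], x$f_statistic, x$p_value))
  print(x$group_stats)
  cat(sprintf("pairwise (threshold p < %.4f):\n", x$alpha_bonferroni))
  print(x$pairwise)
  invisible(x)
}

#' Age/sex-adjusted logistic regression of diagnostic group on the GRS
#'
#' Fits a logistic model of case status (`contrast` group vs controls) on
#' age, male sex and the unweighted GRS, reporting per-unit odds ratios with
#' Wald 95% confidence intervals. (Quasi-)complete separation is flagged and
#' numeric odds ratios withheld for the affected fit.
#'
#' @param x A `grs_cohort` or analysis tibble with columns `group`,
#'   `age_years`, `male` and the score column.
#' @param contrast Case group: `"HTG"` or `"NTG"`.
#' @param control_group Reference group label (default `"control"`).
#' @param score Score column name.
#' @return An object of class `grs_logistic` with a `coefficients` tibble
#'   (`term`, `estimate`, `se`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`), `contrast`, `n_cases`, `n_controls`, `separation`.
#' @export
logistic_group_on_grs <- function(x, contrast = c("HTG", "NTG"),
                                  control_group = "control",
                                  score = "grs") {
  contrast <- match.arg(contrast)
  data <- as_analysis_df(x)
  d <- data[data$group %in% c(contrast, control_group), ,
            drop = FALSE]
  d <- d[stats::complete.cases(d[, c("group", "age_years", "male", score)]), ]
  n_cases <- sum(d$group == contrast)
  n_controls <- sum(d$group == control_group)
  if (n_cases == 0L || n_controls == 0L) {
    abort_contract(paste0(
      "both '", contrast, "' and '", control_group, "' must be non-empty"
    ))
  }
  d$case <- as.integer(d$group == contrast)
  fml <- stats::reformulate(c("age_years", "male", sprintf("`%s`", score)),
                            "case")
  fit_warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = d),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        fit_warned <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  co <- summary(fit)$coefficients
  est <- co[-1L, "Estimate"]
  se <- co[-1L, "Std. Error"]
  separated <- fit_warned || !fit$converged || any(abs(est) > 10) ||
    any(se > 50)
  coefs <- tibble::tibble(
    term = gsub("`", "", rownames(co)[-1L]),
    estimate = unname(est),
    se = unname(se),
    odds_ratio = if (separated) NA_real_ else exp(unname(est)),
    ci_low = if (separated) NA_real_ else exp(unname(est) - 1.959964 * se),
    ci_high = if (separated) NA_real_ else exp(unname(est) + 1.959964 * se),
    p_value = if (separated) NA_real_ else unname(co[-1L, "Pr(>|z|)"])
  )
  structure(
    list(coefficients = coefs, contrast = paste0(contrast, "-vs-",
                                                 control_group),
         n_cases = n_cases, n_controls = n_controls,
         separation = separated, fit = fit),
    class = "grs_logistic"
  )
}

#' @export
print.grs_logistic <- function(x, ...) {
  cat("<grs_logistic>", x$contrast,
      sprintf("(%d cases, %d controls)", x$n_cases, x$n_controls))
  if (x$separation) cat("  [separation detected: estimates withheld]")
  cat("\n")
  print(x$coefficients)
  invisible(x)
}
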