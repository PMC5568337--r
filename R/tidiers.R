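#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for fitted stage objects
#'
#' `tidy()` returns the per-term (or per-pair) tibble of a fitted stage;
#' `glance()` returns a one-row model summary.
#'
#' @param x A `grs_lm`, `grs_anova` or `grs_logistic` object.
#' @param ... Unused.
#' @return A tibble.
#' @name grs_tidiers
NULL

#' @rdname grs_tidiers
#' @method tidy grs_lm
#' @export
tidy.grs_lm <- function(x, ...) x$coefficients

#' @rdname grs_tidiers
#' @method glance grs_lm
#' @export
glance.grs_lm <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic, f_p_value = x$f_p_value,
    r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
    sigma = x$sigma, n_used = x$n_used
  )
}

#' @rdname grs_tidiers
#' @method tidy grs_anova
#' @export
tidy.grs_anova <- function(x, ...) x$pairwise

#' @rdname grs_tidiers
#' @method glance grs_anova
#' @export
glance.grs_anova <- function(x, ...) {
  tibble::tibble(
    f_statistic = x$f_statistic, df1 = x$df[1L], df2 = x$df[2L],
    p_value = x$p_value, alpha_bonferroni = x$alpha_bonferroni,
    n_used = x$n_used
  )
}

#' @rdname grs_tidiers
#' @method tidy grs_logistic
#' @export
tidy.grs_logistic <- function(x, ...) x$coefficients

#' @rdname grs_tidiers
#' @method glance grs_logistic
#' @export
glance.grs_logistic <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast, n_cases = x$n_cases, n_controls = x$n_controls,
    separation = x$separation
  )
}
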