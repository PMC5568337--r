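#' Unweighted genetic risk score (risk-allele count)
#'
#' Sums the risk-allele dosages of the panel variants for each participant,
#' giving an integer score in `[0, 2 * n_variants]` (0-18 for the default
#' nine-variant panel).
#'
#' @param genotypes Genotype tibble with `participant_id` and one dosage
#'   column (0/1/2 or `NA`) per panel rsID.
#' @param panel Variant panel; every panel rsID must be a genotype column.
#' @param missing_policy `"exclude"` drops participants with any missing
#'   dosage; `"mean_impute"` replaces each missing dosage with that variant's
#'   observed mean dosage (scores may then be non-integer).
#' @return A tibble with `participant_id`, `grs` and `kind = "unweighted"`.
#'   Attributes: `n_missing_handled` (participants dropped or imputed) and
#'   `imputed`.
#' @examples
#' g <- simulate_genotypes(iop_variant_panel(), n = 4, seed = 1)
#' grs_unweighted(g, iop_variant_panel())
#' @export
grs_unweighted <- function(genotypes, panel = iop_variant_panel(),
                           missing_policy = c("exclude", "mean_impute")) {
  missing_policy <- match.arg(missing_policy)
  m <- dosage_matrix(genotypes, panel$rsid)
  has_missing <- apply(m, 1L, anyNA)
  imputed <- FALSE
  if (missing_policy == "mean_impute" && any(has_missing)) {
    col_means <- colMeans(m, na.rm = TRUE)
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- col_means[j]
    }
    imputed <- TRUE
    keep <- rep(TRUE, nrow(m))
  } else {
    keep <- !has_missing
  }
  out <- tibble::tibble(
    participant_id = genotypes$participant_id[keep],
    grs = as.numeric(rowSums(m[keep, , drop = FALSE])),
    kind = "unweighted"
  )
  attr(out, "n_missing_handled") <- sum(has_missing)
  attr(out, "imputed") <- imputed
  out
}

#' Weighted genetic risk score (log odds-ratio weights)
#'
#' Computes `sum(dosage * weight)` per participant, with weights on the
#' natural-log odds-ratio scale (one per panel variant). Use [or_to_weights()]
#' to convert an odds-ratio table from [estimate_allele_ors()].
#'
#' @inheritParams grs_unweighted
#' @param weights Named numeric vector of log odds ratios, names = rsIDs.
#'   Every scored variant must have a finite weight.
#' @param panel Optional variant panel: when supplied, every panel variant
#'   must have a weight (a missing one is a schema error). Leave `NULL` when
#'   scoring a deliberate subset, e.g. after [or_to_weights()] has dropped a
#'   separated variant.
#' @return A tibble with `participant_id`, `grs`, `kind = "weighted"`;
#'   attributes `weights_used`, `n_missing_handled`, `imputed`.
#' @export
grs_weighted <- function(genotypes, weights,
                         missing_policy = c("exclude", "mean_impute"),
                         panel = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (!is.null(panel)) {
    unweighted_rsids <- setdiff(panel$rsid, names(weights))
    if (length(unweighted_rsids)) {
      abort_schema(paste0(
        "no weight supplied for panel variant(s): ",
        paste(unweighted_rsids, collapse = ", ")
      ))
    }
  }
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    abort_schema("weights must be a named vector (names = rsIDs)")
  }
  if (any(!is.finite(weights))) {
    abort_schema(paste0(
      "non-finite weight for variant(s): ",
      paste(names(weights)[!is.finite(weights)], collapse = ", ")
    ))
  }
  m <- dosage_matrix(genotypes, names(weights))
  has_missing <- apply(m, 1L, anyNA)
  imputed <- FALSE
  if (missing_policy == "mean_impute" && any(has_missing)) {
    col_means <- colMeans(m, na.rm = TRUE)
    for (j in seq_len(ncol(m))) {
      nas <- is.na(m[, j])
      if (any(nas)) m[nas, j] <- col_means[j]
    }
    imputed <- TRUE
    keep <- rep(TRUE, nrow(m))
  } else {
    keep <- !has_missing
  }
  out <- tibble::tibble(
    participant_id = genotypes$participant_id[keep],
    grs = as.numeric(m[keep, , drop = FALSE] %*% unname(weights)),
    kind = "weighted"
  )
  attr(out, "weights_used") <- weights
  attr(out, "n_missing_handled") <- sum(has_missing)
  attr(out, "imputed") <- imputed
  out
}

#' Per-variant risk-allele odds ratios
#'
#' For each panel variant independently, fits a single-predictor logistic
#' regression of case status on risk-allele dosage (additive coding) and
#' reports the per-allele odds ratio with a Wald 95% confidence interval.
#' Quasi- or complete separation is flagged and the estimate withheld rather
#' than reporting a divergent value.
#'
#' @param genotypes Genotype tibble (dosage columns per rsID).
#' @param case Logical (or 0/1) vector aligned to genotype rows: `TRUE` for
#'   cases. At least two cases and two controls are required.
#' @param rsids Variants to fit; defaults to every non-id genotype column.
#' @return A tibble with `rsid`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `n_cases`, `n_controls`, `separation`.
#' @export
estimate_allele_ors <- function(genotypes, case, rsids = NULL) {
  case <- as.logical(case)
  if (length(case) != nrow(genotypes)) {
    abort_contract("case labels must align with genotype rows")
  }
  if (sum(case, na.rm = TRUE) < 2 || sum(!case, na.rm = TRUE) < 2) {
    abort_degenerate("need at least 2 cases and 2 controls")
  }
  rsids <- rsids %||% setdiff(names(genotypes), "participant_id")
  m <- dosage_matrix(genotypes, rsids)
  purrr::map_dfr(seq_along(rsids), function(j) {
    d <- m[, j]
    ok <- !is.na(d) & !is.na(case)
    fit_warned <- FALSE
    fit <- withCallingHandlers(
      stats::glm(case[ok] ~ d[ok], family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          fit_warned <<- TRUE
          invokeRestart("muffleWarning")
        }
      }
    )
    co <- summary(fit)$coefficients
    beta <- co["d[ok]", "Estimate"]
    se <- co["d[ok]", "Std. Error"]
    separated <- fit_warned || !fit$converged || abs(beta) > 10 || se > 50
    tibble::tibble(
      rsid = rsids[j],
      odds_ratio = if (separated) NA_real_ else exp(beta),
      ci_low = if (separated) NA_real_ else exp(beta - 1.959964 * se),
      ci_high = if (separated) NA_real_ else exp(beta + 1.959964 * se),
      p_value = if (separated) NA_real_ else co["d[ok]", "Pr(>|z|)"],
      n_cases = sum(case[ok]),
      n_controls = sum(!case[ok]),
      separation = separated
    )
  })
}

#' Convert an odds-ratio table to log-OR score weights
#'
#' Takes the output of [estimate_allele_ors()] and returns named natural-log
#' odds-ratio weights for [grs_weighted()]. Variants flagged for separation
#' (no estimable OR) are dropped with a warning, keeping the estimator
#' unpenalized.
#'
#' @param or_table Tibble from [estimate_allele_ors()].
#' @return Named numeric vector of log odds ratios.
#' @export
or_to_weights <- function(or_table) {
  bad <- or_table$separation | !is.finite(or_table$odds_ratio)
  if (any(bad)) {
    rlang::warn(paste0(
      "excluding variant(s) with unestimable odds ratio from weighting: ",
      paste(or_table$rsid[bad], collapse = ", ")
    ))
  }
  kept <- or_table[!bad, ]
  stats::setNames(log(kept$odds_ratio), kept$rsid)
}
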