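#' Synthetic cohort generator parameters
#'
#' Builds the parameter set of the two-liability generative model behind the
#' synthetic cohort generator. The defaults are the frozen output of the
#' moment-matching calibration described in the methods vignette; they
#' reproduce, in large simulated cohorts, the group-level moments of the
#' clinical study the package emulates (control mean maximum IOP 15.0 mmHg,
#' NTG 18.4, HTG 28.6; mean unweighted GRS 8.7 in controls and 9.1 in HTG;
#' pooled standardized IOP-VCDR coefficient near 0.48).
#'
#' The model, per participant: risk-allele dosages are drawn under
#' Hardy-Weinberg equilibrium; latent IOP is `baseline + sum(dosage * effect)
#' + age_effect * (age - age_reference) + male_effect * male + glaucoma_offset
#' * vulnerable + N(0, sd)`; glaucomatous vulnerability is an independent
#' Bernoulli latent; above 22 mmHg the observed maximum IOP is inflated by a
#' log-normal excess (the long right tail of a maximum statistic in treated
#' high-tension disease); mean VCDR is linear in maximum IOP plus a glaucoma
#' offset with Gaussian noise, clamped to [0, 1]. Maximum IOP is rounded to
#' one decimal (tonometry granularity) and VCDR to two before diagnostic-group
#' assignment: HTG = vulnerable & IOP >= 22; NTG = vulnerable & IOP <= 21;
#' control = not vulnerable & IOP <= 21 & VCDR <= 0.4.
#'
#' @param panel Variant panel tibble; see [iop_variant_panel()].
#' @param baseline_iop_mmHg Baseline latent IOP (mmHg) at zero dosage, the
#'   reference age, female sex, no vulnerability.
#' @param age_effect_mmHg Additive IOP change per year of age.
#' @param age_reference_years Age at which the age term is zero.
#' @param male_effect_mmHg Additive IOP change for male sex (male = 1).
#' @param iop_noise Residual latent-IOP noise spec: `list(family = "gaussian",
#'   sd = ...)`.
#' @param glaucoma_iop_offset_mmHg Additive latent-IOP elevation in
#'   glaucoma-vulnerable subjects (disease-related pressure elevation beyond
#'   the common-variant effects).
#' @param htg_tail Observed-maximum inflation above the diagnostic threshold:
#'   `list(family = "lognormal", meanlog, sdlog, threshold_mmHg)`.
#' @param vulnerability_prevalence Probability of the glaucomatous
#'   vulnerability latent (stand-in for non-IOP-related genetic load).
#' @param vcdr_model Mean vertical cup-to-disc ratio model:
#'   `list(intercept, iop_slope, glaucoma_offset, noise_sd)`.
#' @param groups Per-group quotas and demographic proposal distributions: a
#'   tibble with columns `group`, `n`, `age_mean`, `age_sd`, `male_fraction`.
#' @param max_attempts_factor Rejection-sampling cap: at most
#'   `max_attempts_factor * sum(quotas)` proposals per group before a
#'   generation-infeasible error.
#'
#' @return A list of class `grs_generator_params`.
#' @examples
#' p <- generator_params()
#' p$groups
#' @export
generator_params <- function(panel = iop_variant_panel(),
                             baseline_iop_mmHg = 13.26,
                             age_effect_mmHg = -0.03,
                             age_reference_years = 65,
                             male_effect_mmHg = 0.8,
                             iop_noise = list(family = "gaussian", sd = 2.72),
                             glaucoma_iop_offset_mmHg = 4.62,
                             htg_tail = list(family = "lognormal",
                                             meanlog = 0.957, sdlog = 1.142,
                                             threshold_mmHg = 22),
                             vulnerability_prevalence = 0.5,
                             vcdr_model = list(intercept = 0.345,
                                               iop_slope = 0.002,
                                               glaucoma_offset = 0.45,
                                               noise_sd = 0.14),
                             groups = tibble::tibble(
                               group = c("control", "NTG", "HTG"),
                               n = c(246L, 261L, 255L),
                               age_mean = c(67.7, 63.8, 63.7),
                               age_sd = c(11.2, 13.3, 14.2),
                               male_fraction = c(0.366, 0.391, 0.612)
                             ),
                             max_attempts_factor = 1000) {
  params <- structure(
    list(
      panel = panel,
      baseline_iop_mmHg = baseline_iop_mmHg,
      age_effect_mmHg = age_effect_mmHg,
      age_reference_years = age_reference_years,
      male_effect_mmHg = male_effect_mmHg,
      iop_noise = iop_noise,
      glaucoma_iop_offset_mmHg = glaucoma_iop_offset_mmHg,
      htg_tail = htg_tail,
      vulnerability_prevalence = vulnerability_prevalence,
      vcdr_model = vcdr_model,
      groups = groups,
      max_attempts_factor = max_attempts_factor
    ),
    class = "grs_generator_params"
  )
  validate_generator_params(params)
  params
}

#' Validate generator parameters
#'
#' @param params A `grs_generator_params` list.
#' @return `params`, invisibly, or a configuration error.
#' @export
validate_generator_params <- function(params) {
  validate_panel(params$panel, allow_monomorphic = TRUE)
  g <- params$groups
  needed <- c("group", "n", "age_mean", "age_sd", "male_fraction")
  if (!all(needed %in% names(g))) {
    abort_schema("groups must have columns group, n, age_mean, age_sd, male_fraction")
  }
  if (!all(c("control", "NTG", "HTG") %in% g$group)) {
    abort_config("groups must include control, NTG and HTG rows")
  }
  if (any(g$n <= 0) || any(g$n != round(g$n))) {
    abort_config("group quotas must be positive integers")
  }
  if (params$iop_noise$sd < 0 || params$vcdr_model$noise_sd < 0) {
    abort_config("noise scales must be >= 0")
  }
  p <- params$vulnerability_prevalence
  if (!is.finite(p) || p <= 0 || p >= 1) {
    abort_config("vulnerability_prevalence must lie in (0, 1)")
  }
  if (!identical(params$htg_tail$family, "lognormal")) {
    abort_config("htg_tail$family must be 'lognormal'")
  }
  if (!identical(params$iop_noise$family, "gaussian")) {
    abort_config("iop_noise$family must be 'gaussian'")
  }
  invisible(params)
}

#' @export
print.grs_generator_params <- function(x, ...) {
  cat("<grs_generator_params>\n")
  cat("  panel:", nrow(x$panel), "variants; mean risk-allele freq",
      sprintf("%.4f", mean(x$panel$risk_allele_freq)), "\n")
  cat(sprintf("  latent IOP: %.2f + dosage*effect %+.3f*(age-%g) %+.2f*male %+.2f*vulnerable + N(0, %.2f)\n",
              x$baseline_iop_mmHg, x$age_effect_mmHg, x$age_reference_years,
              x$male_effect_mmHg, x$glaucoma_iop_offset_mmHg, x$iop_noise$sd))
  cat(sprintf("  HTG tail: +lognormal(%.3f, %.3f) above %g mmHg\n",
              x$htg_tail$meanlog, x$htg_tail$sdlog, x$htg_tail$threshold_mmHg))
  cat(sprintf("  VCDR: %.3f %+.4f*IOP %+.2f*glaucoma + N(0, %.2f), clamped [0,1]\n",
              x$vcdr_model$intercept, x$vcdr_model$iop_slope,
              x$vcdr_model$glaucoma_offset, x$vcdr_model$noise_sd))
  cat("  quotas:", paste(sprintf("%s=%d", x$groups$group, x$groups$n),
                         collapse = ", "), "\n")
  invisible(x)
}
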