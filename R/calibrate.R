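#' Default calibration targets
#'
#' The group-level moments the shipped generator defaults were calibrated to:
#' mean maximum IOP per group, mean unweighted GRS in controls and HTG, and
#' the pooled standardized coefficient of mean VCDR on maximum IOP.
#'
#' @return A tibble with columns `group`, `statistic`, `value`, `tolerance`.
#' @export
default_calibration_targets <- function() {
  tibble::tribble(
    ~group,    ~statistic,       ~value, ~tolerance,
    "control", "mean_max_iop",   15.0,   0.3,
    "NTG",     "mean_max_iop",   18.4,   0.3,
    "HTG",     "mean_max_iop",   28.6,   0.5,
    "control", "mean_grs",       8.7,    0.15,
    "HTG",     "mean_grs",       9.1,    0.15,
    "pooled",  "iop_vcdr_beta",  0.48,   0.05
  )
}

# simulate the statistics named by `targets` under `params`
measure_targets <- function(params, targets, n_per_group, seed) {
  groups_needed <- unique(targets$group[targets$group != "pooled"])
  draws <- stats::setNames(
    lapply(seq_along(groups_needed), function(i) {
      simulate_group_draws(params, groups_needed[i], n_per_group,
                           seed = seed + i)
    }),
    groups_needed
  )
  pooled_beta <- NA_real_
  if (any(targets$statistic == "iop_vcdr_beta")) {
    scale <- max(1L, floor(2000 / sum(params$groups$n)))
    p2 <- params
    p2$groups$n <- as.integer(params$groups$n * scale)
    cohort <- sample_cohort(p2, seed = seed + 100L)
    pooled_beta <- iop_vcdr_correlation(
      cohort_data(cohort)
    )$coefficients$beta_standardized[1L]
  }
  vapply(seq_len(nrow(targets)), function(i) {
    g <- targets$group[i]
    switch(
      targets$statistic[i],
      mean_max_iop = mean(draws[[g]]$max_iop_mmHg),
      mean_grs = mean(draws[[g]]$grs),
      iop_vcdr_beta = pooled_beta,
      abort_config(paste0("unknown calibration statistic: ",
                          targets$statistic[i]))
    )
  }, numeric(1))
}

#' Calibrate generator defaults to target moments
#'
#' Iterative moment-matching search: simulates large eligible strata under
#' the current parameters, measures each target statistic, and applies
#' first-order parameter updates (baseline IOP for the control mean, glaucoma
#' offset for the NTG mean, tail location for the HTG mean, allele frequency
#' for the control GRS mean, per-allele IOP effect for the HTG-control GRS
#' separation, VCDR noise for the pooled IOP-VCDR coefficient) until every
#' target is met within its tolerance or `max_iter` is exhausted.
#'
#' The shipped [generator_params()] defaults are the frozen output of this
#' procedure run at large n; see the methods vignette.
#'
#' @param targets Tibble with columns `group`, `statistic` (`mean_max_iop`,
#'   `mean_grs`, `iop_vcdr_beta`), `value`, `tolerance`. An empty target list
#'   returns the initial parameters unchanged.
#' @param search_spec List: `params` (initial [generator_params()]),
#'   `n_per_group` (eligible draws per measured group per iteration),
#'   `max_iter`, `seed`.
#' @return A `grs_generator_params` object with attribute `"calibration"`, a
#'   tibble reporting each target's achieved value and whether its tolerance
#'   was met. If any target remains unmet a calibration-failure error listing
#'   the unmet targets is raised.
#' @export
calibrate_defaults <- function(targets = default_calibration_targets(),
                               search_spec = list()) {
  spec <- utils::modifyList(
    list(params = generator_params(), n_per_group = 20000L, max_iter = 8L,
         seed = 1L),
    search_spec
  )
  params <- spec$params
  if (nrow(targets) == 0L) {
    attr(params, "calibration") <- tibble::tibble(
      group = character(), statistic = character(), value = numeric(),
      tolerance = numeric(), achieved = numeric(), met = logical()
    )
    return(params)
  }
  achieved <- rep(NA_real_, nrow(targets))
  for (iter in seq_len(spec$max_iter)) {
    achieved <- measure_targets(params, targets, spec$n_per_group,
                                seed = spec$seed + 1000L * iter)
    gap <- targets$value - achieved
    met <- abs(gap) <= targets$tolerance
    if (all(met)) break
    for (i in seq_len(nrow(targets))) {
      if (met[i]) next
      key <- paste(targets$group[i], targets$statistic[i])
      if (key == "control mean_max_iop") {
        params$baseline_iop_mmHg <- params$baseline_iop_mmHg + gap[i]
      } else if (key == "NTG mean_max_iop") {
        params$glaucoma_iop_offset_mmHg <-
          params$glaucoma_iop_offset_mmHg + gap[i]
      } else if (key == "HTG mean_max_iop") {
        tail_mean <- exp(params$htg_tail$meanlog +
                           params$htg_tail$sdlog^2 / 2)
        shift <- (tail_mean + gap[i]) / tail_mean
        params$htg_tail$meanlog <- params$htg_tail$meanlog +
          log(max(shift, 0.2))
      } else if (key == "control mean_grs") {
        f <- pmin(0.99, pmax(
          0.01, params$panel$risk_allele_freq + gap[i] / 18
        ))
        params$panel$risk_allele_freq <- f
      } else if (key == "HTG mean_grs") {
        # the HTG enrichment over the population mean scales ~linearly in the
        # per-allele effect; local slope ~2.1 GRS-units per (mmHg/allele)
        params$panel$iop_effect_mmHg <- pmax(
          0, params$panel$iop_effect_mmHg + gap[i] / 2.1
        )
      } else if (key == "pooled iop_vcdr_beta") {
        # the pooled coefficient decreases in the within-group VCDR noise
        ratio <- achieved[i] / targets$value[i]
        params$vcdr_model$noise_sd <- min(
          0.4, max(0.02, params$vcdr_model$noise_sd * ratio^0.8)
        )
      } else {
        abort_config(paste0("no update rule for calibration target: ", key))
      }
    }
    validate_generator_params(params)
  }
  report <- dplyr::mutate(targets, achieved = achieved,
                          met = abs(.data$value - achieved) <=
                            .data$tolerance)
  attr(params, "calibration") <- report
  if (!all(report$met)) {
    unmet <- report[!report$met, ]
    rlang::abort(
      paste0(
        "calibration failed to meet target(s): ",
        paste(sprintf("%s %s (target %.3g, achieved %.3g)", unmet$group,
                      unmet$statistic, unmet$value, unmet$achieved),
              collapse = "; ")
      ),
      class = "iopgrs_calibration_failure",
      report = report,
      params = params
    )
  }
  params
}
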