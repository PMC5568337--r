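#' Simulate risk-allele dosages under Hardy-Weinberg equilibrium
#'
#' Draws an `n` x `nrow(panel)` dosage matrix: the dosage at each variant is
#' the number of risk alleles in a diploid genotype, i.e. the sum of two
#' independent Bernoulli draws with the variant's risk-allele frequency.
#'
#' @param panel Variant panel tibble (see [iop_variant_panel()]).
#' @param n Number of participants to simulate.
#' @param seed Optional integer seed; identical inputs give identical output.
#' @param allow_monomorphic Permit frequencies of exactly 0 or 1 (an explicit
#'   override for degenerate configurations).
#' @return A tibble with `participant_id` followed by one integer dosage
#'   column per rsID.
#' @examples
#' g <- simulate_genotypes(iop_variant_panel(), n = 5, seed = 1)
#' @export
simulate_genotypes <- function(panel, n, seed = NULL,
                               allow_monomorphic = FALSE) {
  validate_panel(panel, allow_monomorphic = allow_monomorphic)
  if (!is_count(n) || n < 1) abort_contract("n must be a positive integer")
  with_seed(seed, {
    dose <- vapply(
      panel$risk_allele_freq,
      function(f) stats::rbinom(n, size = 2L, prob = f),
      integer(n)
    )
    dose <- matrix(as.integer(dose), nrow = n)
    colnames(dose) <- panel$rsid
    dplyr::bind_cols(
      tibble::tibble(participant_id = sprintf("P%05d", seq_len(n))),
      tibble::as_tibble(dose)
    )
  })
}

# dosage sub-matrix (participants x panel rsids) from a genotype tibble,
# erroring on absent panel columns
dosage_matrix <- function(genotypes, rsids) {
  missing_cols <- setdiff(rsids, names(genotypes))
  if (length(missing_cols)) {
    abort_schema(paste0(
      "genotype table is missing panel variant(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  m <- as.matrix(genotypes[, rsids, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- m[!is.na(m)]
  if (length(bad) && any(!(bad %in% c(0, 1, 2)))) {
    abort_schema("dosages must be 0, 1 or 2 (or missing)")
  }
  m
}

#' Simulate phenotypes for a genotyped sample
#'
#' Applies the generative model described in [generator_params()] to a dosage
#' table: draws age and sex from group-specific proposal distributions, the
#' glaucomatous vulnerability latent, latent and observed maximum IOP (with
#' the log-normal inflation above the 22 mmHg threshold), and mean VCDR, then
#' assigns the diagnostic group. Maximum IOP is rounded to one decimal and
#' VCDR to two before group assignment.
#'
#' @param genotypes Genotype tibble from [simulate_genotypes()] (columns must
#'   match `params$panel`).
#' @param params A [generator_params()] object.
#' @param seed Optional integer seed.
#' @param stratum Optional group name (`"control"`, `"NTG"`, `"HTG"`): draw
#'   age/sex from that group's proposal distribution for every participant.
#'   Default `NULL` mixes the three proposals in quota proportion.
#' @return A tibble with columns `participant_id`, `age_years`, `sex`
#'   (`"M"`/`"F"`), `male` (0/1), `glaucoma` (logical vulnerability latent),
#'   `latent_iop_mmHg`, `max_iop_mmHg`, `mean_vcdr`, `group` (`NA` when the
#'   draw fits no diagnostic group) and `eligible`.
#' @export
simulate_phenotypes <- function(genotypes, params, seed = NULL,
                                stratum = NULL) {
  validate_generator_params(params)
  m <- dosage_matrix(genotypes, params$panel$rsid)
  if (anyNA(m)) abort_schema("simulated phenotypes require complete dosages")
  n <- nrow(m)
  grp <- params$groups
  with_seed(seed, {
    if (is.null(stratum)) {
      idx <- sample.int(nrow(grp), n, replace = TRUE, prob = grp$n / sum(grp$n))
    } else {
      if (!stratum %in% grp$group) {
        abort_contract(paste0("unknown stratum: ", stratum))
      }
      idx <- rep(match(stratum, grp$group), n)
    }
    age <- stats::rnorm(n, grp$age_mean[idx], grp$age_sd[idx])
    male <- stats::rbinom(n, 1L, grp$male_fraction[idx])
    vuln <- stats::rbinom(n, 1L, params$vulnerability_prevalence) == 1L
    genetic <- as.numeric(m %*% params$panel$iop_effect_mmHg)
    latent <- params$baseline_iop_mmHg + genetic +
      params$age_effect_mmHg * (age - params$age_reference_years) +
      params$male_effect_mmHg * male +
      params$glaucoma_iop_offset_mmHg * vuln +
      stats::rnorm(n, 0, params$iop_noise$sd)
    thr <- params$htg_tail$threshold_mmHg
    tail_excess <- ifelse(
      latent >= thr,
      stats::rlnorm(n, params$htg_tail$meanlog, params$htg_tail$sdlog),
      0
    )
    max_iop <- round(latent + tail_excess, 1)
    vm <- params$vcdr_model
    vcdr <- vm$intercept + vm$iop_slope * max_iop +
      vm$glaucoma_offset * vuln + stats::rnorm(n, 0, vm$noise_sd)
    vcdr <- round(pmin(1, pmax(0, vcdr)), 2)
    group <- rep(NA_character_, n)
    group[vuln & max_iop >= 22] <- "HTG"
    group[vuln & max_iop <= 21] <- "NTG"
    group[!vuln & max_iop <= 21 & vcdr <= 0.4] <- "control"
    tibble::tibble(
      participant_id = genotypes$participant_id,
      age_years = age,
      sex = ifelse(male == 1L, "M", "F"),
      male = as.integer(male),
      glaucoma = vuln,
      latent_iop_mmHg = latent,
      max_iop_mmHg = max_iop,
      mean_vcdr = vcdr,
      group = group,
      eligible = !is.na(group)
    )
  })
}

# draw eligible participants of one diagnostic group by rejection sampling;
# returns list(genotypes, phenotypes) with exactly n rows (or an infeasibility
# error once the proposal budget is exhausted)
reject_sample_group <- function(params, group, n, max_attempts) {
  batch <- max(1000L, as.integer(ceiling(n * 4)))
  geno_acc <- list()
  pheno_acc <- list()
  got <- 0L
  attempts <- 0L
  while (got < n) {
    if (attempts >= max_attempts) {
      abort_infeasible(paste0(
        "could not generate enough '", group, "' participants after ",
        attempts, " proposals; check generator parameters"
      ))
    }
    take <- min(batch, max_attempts - attempts)
    g <- simulate_genotypes(params$panel, take)
    ph <- simulate_phenotypes(g, params, stratum = group)
    keep <- which(!is.na(ph$group) & ph$group == group)
    attempts <- attempts + take
    if (length(keep)) {
      keep <- keep[seq_len(min(length(keep), n - got))]
      geno_acc[[length(geno_acc) + 1L]] <- g[keep, , drop = FALSE]
      pheno_acc[[length(pheno_acc) + 1L]] <- ph[keep, , drop = FALSE]
      got <- got + length(keep)
    }
  }
  genotypes <- dplyr::bind_rows(geno_acc)
  phenotypes <- dplyr::bind_rows(pheno_acc)
  # batches restart their id counters; reassign unique ids, keeping the
  # row alignment between the two tables
  ids <- sprintf("P%05d", seq_len(nrow(genotypes)))
  genotypes$participant_id <- ids
  phenotypes$participant_id <- ids
  list(genotypes = genotypes, phenotypes = phenotypes)
}

#' Sample a quota case-control cohort
#'
#' Rejection-samples eligible participants until each diagnostic-group quota
#' in `params$groups` is met exactly. Proposal demographics are drawn from the
#' target group's configured distribution; acceptance is determined by the
#' generative model, so e.g. the male excess among high-tension cases emerges
#' partly from the IOP model itself.
#'
#' @param params A [generator_params()] object.
#' @param seed Optional integer seed; the whole cohort is reproducible.
#' @return An object of class `grs_cohort`: a list with tibbles `genotypes`
#'   and `phenotypes` (row-aligned via `participant_id`) and `params_used`.
#' @examples
#' \donttest{
#' cohort <- sample_cohort(generator_params(), seed = 1)
#' table(cohort$phenotypes$group)
#' }
#' @export
sample_cohort <- function(params = generator_params(), seed = NULL) {
  validate_generator_params(params)
  total <- sum(params$groups$n)
  max_attempts <- as.integer(params$max_attempts_factor * total)
  with_seed(seed, {
    parts <- lapply(seq_len(nrow(params$groups)), function(i) {
      reject_sample_group(params, params$groups$group[i],
                          params$groups$n[i], max_attempts)
    })
    genotypes <- dplyr::bind_rows(lapply(parts, `[[`, "genotypes"))
    phenotypes <- dplyr::bind_rows(lapply(parts, `[[`, "phenotypes"))
    ids <- sprintf("P%05d", seq_len(nrow(genotypes)))
    genotypes$participant_id <- ids
    phenotypes$participant_id <- ids
    structure(
      list(genotypes = genotypes, phenotypes = phenotypes,
           params_used = params),
      class = "grs_cohort"
    )
  })
}

#' @export
print.grs_cohort <- function(x, ...) {
  cat("<grs_cohort>", nrow(x$phenotypes), "participants,",
      nrow(x$params_used$panel), "variants\n")
  print(dplyr::count(x$phenotypes, .data$group))
  invisible(x)
}

#' Simulate eligible draws from one diagnostic group
#'
#' Convenience wrapper around the rejection sampler for moment estimation on
#' large strata (calibration checks, acceptance runs): returns `n` eligible
#' participants of `group` with their unweighted GRS attached.
#'
#' @inheritParams sample_cohort
#' @param group `"control"`, `"NTG"` or `"HTG"`.
#' @param n Number of eligible participants to return.
#' @return A tibble of phenotypes with a `grs` column.
#' @export
simulate_group_draws <- function(params = generator_params(), group, n,
                                 seed = NULL) {
  validate_generator_params(params)
  if (!group %in% params$groups$group) {
    abort_contract(paste0("unknown group: ", group))
  }
  max_attempts <- as.integer(params$max_attempts_factor * n)
  with_seed(seed, {
    out <- reject_sample_group(params, group, n, max_attempts)
    scores <- grs_unweighted(out$genotypes, params$panel)
    dplyr::left_join(out$phenotypes, scores[, c("participant_id", "grs")],
                     by = "participant_id")
  })
}

#' Flatten a cohort for modelling
#'
#' Joins phenotypes, per-variant dosages and the unweighted GRS into one
#' analysis tibble (one row per participant), the shape the association and
#' cutoff stages consume.
#'
#' @param cohort A `grs_cohort` object.
#' @param missing_policy Passed to [grs_unweighted()].
#' @return A tibble with phenotype columns, one dosage column per rsID, and
#'   `grs`.
#' @export
cohort_data <- function(cohort, missing_policy = c("exclude", "mean_impute")) {
  stopifnot(inherits(cohort, "grs_cohort"))
  scores <- grs_unweighted(cohort$genotypes, cohort$params_used$panel,
                           missing_policy = missing_policy)
  cohort$phenotypes |>
    dplyr::left_join(cohort$genotypes, by = "participant_id") |>
    dplyr::inner_join(scores[, c("participant_id", "grs")],
                      by = "participant_id")
}

#' Simulate a case-control sample with a known per-allele odds ratio
#'
#' Retrospective sampler for calibration and power studies: controls carry
#' Hardy-Weinberg genotypes at the panel frequencies; case genotypes are drawn
#' from the odds-ratio-tilted genotype distribution (equivalently,
#' Hardy-Weinberg at frequency `f*OR / (1 - f + f*OR)` per locus). By
#' construction the retrospective log-odds of case status are linear in the
#' total risk-allele count with slope `log(or_per_allele)`, so an
#' age/sex-adjusted logistic regression of case status on the unweighted GRS
#' is correctly specified with true per-allele OR `or_per_allele`. Age and sex
#' are drawn independently of genotype from the configured group proposals
#' (cases use the `case_group` row, controls the `"control"` row), so they do
#' not confound the genetic effect.
#'
#' @param panel Variant panel.
#' @param or_per_allele True per-risk-allele odds ratio (common to all
#'   variants).
#' @param n_case,n_control Sample sizes.
#' @param params Generator parameters (for the demographic proposals).
#' @param case_group Group row used for case demographics (default `"HTG"`).
#' @param seed Optional integer seed.
#' @return A tibble with `participant_id`, dosage columns, `case` (0/1),
#'   `age_years`, `male` and `grs`.
#' @export
simulate_case_control <- function(panel = iop_variant_panel(),
                                  or_per_allele = 1.12,
                                  n_case = 255, n_control = 246,
                                  params = generator_params(),
                                  case_group = "HTG",
                                  seed = NULL) {
  validate_panel(panel)
  if (!is.finite(or_per_allele) || or_per_allele <= 0) {
    abort_config("or_per_allele must be finite and positive")
  }
  grp <- params$groups
  i_case <- match(case_group, grp$group)
  i_ctrl <- match("control", grp$group)
  if (is.na(i_case)) abort_contract(paste0("unknown case_group: ", case_group))
  with_seed(seed, {
    f <- panel$risk_allele_freq
    f_case <- f * or_per_allele / (1 - f + f * or_per_allele)
    draw <- function(n, freqs) {
      m <- vapply(freqs, function(p) stats::rbinom(n, 2L, p), integer(n))
      matrix(as.integer(m), nrow = n, dimnames = list(NULL, panel$rsid))
    }
    dose <- rbind(draw(n_case, f_case), draw(n_control, f))
    n <- n_case + n_control
    idx <- c(rep(i_case, n_case), rep(i_ctrl, n_control))
    out <- dplyr::bind_cols(
      tibble::tibble(participant_id = sprintf("P%05d", seq_len(n))),
      tibble::as_tibble(dose)
    )
    out$case <- c(rep(1L, n_case), rep(0L, n_control))
    out$age_years <- stats::rnorm(n, grp$age_mean[idx], grp$age_sd[idx])
    out$male <- stats::rbinom(n, 1L, grp$male_fraction[idx])
    out$grs <- as.numeric(rowSums(dose))
    out
  })
}
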