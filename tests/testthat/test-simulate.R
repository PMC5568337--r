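test_that("genotype simulation honours degenerate and Hardy-Weinberg frequencies", {
  zero <- simulate_genotypes(toy_panel(freq = 0), n = 5, seed = 1,
                             allow_monomorphic = TRUE)
  expect_true(all(as.matrix(zero[, -1]) == 0))
  expect_error(simulate_genotypes(toy_panel(freq = 0), n = 5),
               class = "iopgrs_config_error")

  g <- simulate_genotypes(toy_panel(n_var = 2, freq = 0.5), n = 50000,
                          seed = 2)
  m <- as.matrix(g[, -1])
  expect_true(all(abs(colMeans(m) - 1) < 0.02))
  # genotype class proportions near 1/4, 1/2, 1/4 (binomial error)
  props <- table(factor(m[, 1], levels = 0:2)) / nrow(m)
  expect_true(all(abs(props - c(0.25, 0.5, 0.25)) < 0.01))
})

test_that("simulation is reproducible given a seed", {
  panel <- iop_variant_panel()
  expect_identical(simulate_genotypes(panel, 100, seed = 9),
                   simulate_genotypes(panel, 100, seed = 9))
  p <- small_params(c(10L, 10L, 10L))
  c1 <- sample_cohort(p, seed = 5)
  c2 <- sample_cohort(p, seed = 5)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$phenotypes, c2$phenotypes)
})

test_that("latent IOP is an exact additive function of dosages at zero noise", {
  params <- generator_params(
    age_effect_mmHg = 0, male_effect_mmHg = 0,
    glaucoma_iop_offset_mmHg = 0,
    iop_noise = list(family = "gaussian", sd = 0)
  )
  g <- simulate_genotypes(params$panel, 50, seed = 3)
  ph <- simulate_phenotypes(g, params, seed = 4)
  expected <- params$baseline_iop_mmHg +
    as.numeric(as.matrix(g[, -1]) %*% params$panel$iop_effect_mmHg)
  expect_equal(ph$latent_iop_mmHg, expected, tolerance = 1e-12)

  # single-variant effect: dosage 2 vs dosage 0 differ by exactly 2 * effect
  panel1 <- toy_panel(n_var = 1, freq = 0.5, effect = 1.0)
  params1 <- generator_params(
    panel = panel1, age_effect_mmHg = 0, male_effect_mmHg = 0,
    glaucoma_iop_offset_mmHg = 0, iop_noise = list(family = "gaussian", sd = 0)
  )
  g1 <- make_genotypes(matrix(c(0L, 2L), ncol = 1), rsids = panel1$rsid)
  ph1 <- simulate_phenotypes(g1, params1, seed = 1)
  expect_equal(diff(ph1$latent_iop_mmHg), 2.0, tolerance = 1e-12)
})

test_that("every sampled participant satisfies its group's clinical constraints", {
  cohort <- sample_cohort(small_params(c(25L, 25L, 25L)), seed = 11)
  ph <- cohort$phenotypes
  expect_equal(unname(table(ph$group)[c("control", "NTG", "HTG")]),
               c(25L, 25L, 25L), ignore_attr = TRUE)
  expect_true(all(ph$max_iop_mmHg[ph$group == "HTG"] >= 22))
  expect_true(all(ph$max_iop_mmHg[ph$group != "HTG"] <= 21))
  expect_true(all(ph$mean_vcdr[ph$group == "control"] <= 0.4))
  expect_true(all(!ph$glaucoma[ph$group == "control"]))
  expect_true(all(ph$glaucoma[ph$group != "control"]))
})

test_that("a starved quota raises a generation-infeasible error naming the group", {
  p <- generator_params(vulnerability_prevalence = 1e-6,
                        max_attempts_factor = 3)
  expect_error(simulate_group_draws(p, "NTG", 5, seed = 1),
               regexp = "NTG", class = "iopgrs_infeasible_error")
})

test_that("regression on a large simulated sample recovers the per-allele IOP effects", {
  params <- generator_params()
  g <- simulate_genotypes(params$panel, 100000, seed = 21)
  ph <- simulate_phenotypes(g, params, seed = 22)
  d <- dplyr::bind_cols(ph, g[, -1])
  fit <- stats::lm(
    stats::reformulate(c("age_years", "male", "glaucoma", params$panel$rsid),
                       "latent_iop_mmHg"),
    data = d
  )
  co <- summary(fit)$coefficients[params$panel$rsid, ]
  expect_true(all(
    abs(co[, "Estimate"] - params$panel$iop_effect_mmHg) <
      3 * co[, "Std. Error"]
  ))
  # the VCDR slope on observed IOP is likewise recovered
  fit_v <- stats::lm(mean_vcdr ~ max_iop_mmHg + glaucoma, data = ph)
  co_v <- summary(fit_v)$coefficients["max_iop_mmHg", ]
  expect_lt(abs(co_v["Estimate"] - params$vcdr_model$iop_slope),
            4 * co_v["Std. Error"] + 1e-4)
})

test_that("phenotype simulation rejects genotype tables that do not match the panel", {
  params <- generator_params()
  g <- simulate_genotypes(toy_panel(), 10, seed = 1)
  expect_error(simulate_phenotypes(g, params), class = "iopgrs_schema_error")
})

test_that("tilted case-control draws carry the configured per-allele odds ratio", {
  d <- simulate_case_control(or_per_allele = 1.5, n_case = 6000,
                             n_control = 6000, seed = 33)
  fit <- stats::glm(case ~ age_years + male + grs, family = stats::binomial(),
                    data = d)
  co <- summary(fit)$coefficients["grs", ]
  expect_lt(abs(co["Estimate"] - log(1.5)), 3 * co["Std. Error"])
})
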