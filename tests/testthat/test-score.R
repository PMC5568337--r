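test_that("unweighted GRS is the risk-allele count with range 0-18", {
  g <- make_genotypes(rbind(
    rep(0L, 9), rep(2L, 9), c(1L, 0L, 2L, 1L, 0L, 1L, 2L, 0L, 1L)
  ))
  s <- grs_unweighted(g, iop_variant_panel())
  expect_equal(s$grs, c(0, 18, 8))
  expect_equal(unique(s$kind), "unweighted")
  expect_equal(attr(s, "n_missing_handled"), 0L)
})

test_that("scores respect bounds, monotonicity and permutation equivariance", {
  panel <- iop_variant_panel()
  g <- simulate_genotypes(panel, 200, seed = 14)
  s <- grs_unweighted(g, panel)
  expect_true(all(s$grs >= 0 & s$grs <= 18))

  # +1 to a single dosage raises the unweighted score by exactly 1 and the
  # weighted score by exactly that variant's weight
  w <- setNames(log(seq(1.1, 1.9, by = 0.1)), panel$rsid)
  g2 <- g
  i <- which(g2$rs2472493 < 2)[1]
  g2$rs2472493[i] <- g2$rs2472493[i] + 1L
  expect_equal(grs_unweighted(g2, panel)$grs[i], s$grs[i] + 1)
  expect_equal(grs_weighted(g2, w)$grs[i],
               grs_weighted(g, w)$grs[i] + w[["rs2472493"]])

  perm <- sample(nrow(g))
  s_perm <- grs_unweighted(g[perm, ], panel)
  expect_equal(s_perm$grs, s$grs[perm])
})

test_that("missing dosages follow the exclude and mean-impute policies", {
  g <- make_genotypes(rbind(rep(1L, 9), rep(2L, 9), rep(0L, 9)))
  g$rs1052990[2] <- NA_integer_
  s_ex <- grs_unweighted(g, iop_variant_panel(), missing_policy = "exclude")
  expect_equal(nrow(s_ex), 2L)
  expect_equal(attr(s_ex, "n_missing_handled"), 1L)
  s_im <- grs_unweighted(g, iop_variant_panel(),
                         missing_policy = "mean_impute")
  expect_equal(nrow(s_im), 3L)
  # imputed dosage is the observed mean (1 + 0) / 2 = 0.5
  expect_equal(s_im$grs[2], 16 + 0.5)
  expect_true(attr(s_im, "imputed"))

  expect_error(grs_unweighted(g[, 1:9], iop_variant_panel()),
               regexp = "rs747782", class = "iopgrs_schema_error")
})

test_that("weighted GRS is the dosage-weighted sum of natural-log odds ratios", {
  panel <- iop_variant_panel()
  null_w <- setNames(rep(0, 9), panel$rsid)
  g <- simulate_genotypes(panel, 20, seed = 3)
  expect_true(all(grs_weighted(g, null_w)$grs == 0))

  one <- make_genotypes(matrix(c(2L, rep(0L, 8)), nrow = 1))
  w <- setNames(c(log(2), rep(0, 8)), panel$rsid)
  expect_equal(grs_weighted(one, w)$grs, 2 * log(2))

  # equal weights make the weighted score proportional to the count
  w_eq <- setNames(rep(0.3, 9), panel$rsid)
  expect_equal(grs_weighted(g, w_eq)$grs,
               0.3 * grs_unweighted(g, panel)$grs)

  expect_error(grs_weighted(g, w_eq[-1], panel = panel),
               class = "iopgrs_schema_error")
  w_bad <- w_eq
  w_bad[2] <- Inf
  expect_error(grs_weighted(g, w_bad), class = "iopgrs_schema_error")
})

test_that("identical case and control dosage distributions give OR = 1", {
  g <- make_genotypes(matrix(rep(0:2, each = 2), ncol = 1),
                      rsids = "rsT1")
  case <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  or_tab <- estimate_allele_ors(g, case)
  expect_equal(or_tab$odds_ratio, 1, tolerance = 1e-8)
  expect_false(or_tab$separation)
})

test_that("per-allele OR on binary dosages matches the brute-force MLE and table OR", {
  dosage <- c(rep(2L, 40), rep(0L, 40))
  case <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 30))
  g <- make_genotypes(matrix(dosage, ncol = 1), rsids = "rsT1")
  or_tab <- estimate_allele_ors(g, case)
  slope <- brute_force_logistic_slope(dosage, case)
  expect_equal(or_tab$odds_ratio, exp(slope), tolerance = 1e-6)
  # per-allele OR is the square root of the 2x2 table OR: sqrt(9) = 3
  expect_equal(or_tab$odds_ratio, 3, tolerance = 1e-6)
  expect_equal(or_tab$odds_ratio^2, (30 * 30) / (10 * 10), tolerance = 1e-6)
})

test_that("degenerate labels and separation are flagged, not estimated", {
  g <- make_genotypes(matrix(c(0L, 1L, 2L, 0L), ncol = 1), rsids = "rsT1")
  expect_error(estimate_allele_ors(g, rep(TRUE, 4)),
               class = "iopgrs_degenerate_error")

  # complete separation: case iff dosage 2
  sep_dosage <- c(rep(2L, 10), rep(0L, 10))
  sep_case <- sep_dosage == 2L
  g_sep <- make_genotypes(matrix(sep_dosage, ncol = 1), rsids = "rsT1")
  or_sep <- estimate_allele_ors(g_sep, sep_case)
  expect_true(or_sep$separation)
  expect_true(is.na(or_sep$odds_ratio))
  expect_warning(w <- or_to_weights(or_sep), regexp = "rsT1")
  expect_length(w, 0)
})

test_that("OR estimates are consistent and CIs cover in repeated sampling", {
  true_or <- 1.2
  reps <- 120
  covered <- logical(reps)
  est <- numeric(reps)
  for (r in seq_len(reps)) {
    d <- simulate_case_control(or_per_allele = true_or, n_case = 400,
                               n_control = 400, seed = 7000 + r)
    or_tab <- estimate_allele_ors(d[, c("participant_id",
                                        iop_variant_panel()$rsid)],
                                  d$case == 1L,
                                  rsids = "rs1052990")
    est[r] <- or_tab$odds_ratio
    covered[r] <- or_tab$ci_low <= true_or && true_or <= or_tab$ci_high
  }
  expect_lt(abs(mean(est) - true_or), 3 * stats::sd(est) / sqrt(reps))
  # nominal 95% coverage within a 3-sigma binomial band for 120 replicates
  expect_gt(mean(covered), 0.89)
})
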