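test_that("a perfectly correlated predictor has standardized beta 1", {
  d <- data.frame(x = seq(1, 20))
  d$y <- 3 + 2 * d$x
  fit <- suppressWarnings(standardized_lm(d, "y", "x"))  # perfect fit
  expect_equal(fit$coefficients$beta_standardized, 1, tolerance = 1e-10)
  expect_lt(fit$coefficients$p_value, 1e-12)
})

test_that("OLS estimates equal the normal-equations oracle on a fixed design", {
  set.seed(77)
  n <- 20
  d <- data.frame(x1 = rnorm(n), x2 = runif(n, -2, 2),
                  x3 = rbinom(n, 2, 0.5))
  d$y <- 1 + 0.5 * d$x1 - 1.2 * d$x2 + 0.3 * d$x3 + rnorm(n, sd = 0.7)
  fit <- standardized_lm(d, "y", c("x1", "x2", "x3"))
  X <- cbind(1, as.matrix(d[, c("x1", "x2", "x3")]))
  beta_oracle <- solve(t(X) %*% X, t(X) %*% d$y)[, 1]
  expect_equal(fit$coefficients$estimate, unname(beta_oracle[-1]),
               tolerance = 1e-8)
  # residual-based SEs agree with the closed form too
  resid <- d$y - X %*% beta_oracle
  s2 <- sum(resid^2) / (n - ncol(X))
  se_oracle <- sqrt(diag(s2 * solve(t(X) %*% X)))[-1]
  expect_equal(fit$coefficients$se, unname(se_oracle), tolerance = 1e-8)
})

test_that("standardized beta is invariant to affine rescaling of x and y", {
  set.seed(5)
  d <- data.frame(x = rnorm(60), z = rnorm(60))
  d$y <- 1 + d$x - 0.5 * d$z + rnorm(60)
  base <- standardized_lm(d, "y", c("x", "z"))$coefficients$beta_standardized
  d2 <- within(d, {
    x <- 100 * x - 7
    z <- 0.01 * z + 3
    y <- 42 * y + 1000
  })
  resc <- standardized_lm(d2, "y", c("x", "z"))$coefficients$beta_standardized
  expect_equal(base, resc, tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  d <- data.frame(y = rnorm(30), x = rnorm(30), cst = 1)
  expect_error(standardized_lm(d, "y", c("x", "cst")),
               regexp = "cst", class = "iopgrs_collinearity_error")
  d$x2 <- 2 * d$x
  expect_error(standardized_lm(d, "y", c("x", "x2")),
               class = "iopgrs_collinearity_error")
  expect_error(standardized_lm(d[1:3, ], "y", c("x", "x2")),
               class = "iopgrs_contract_error")
  expect_error(standardized_lm(d, "y", "nope"),
               class = "iopgrs_schema_error")
})

test_that("results are invariant to input row order and count dropped rows", {
  set.seed(12)
  d <- data.frame(y = rnorm(50), x = rnorm(50), w = rnorm(50))
  d$y[3] <- NA
  fit1 <- standardized_lm(d, "y", c("x", "w"))
  fit2 <- standardized_lm(d[sample(50), ], "y", c("x", "w"))
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-12)
  expect_equal(fit1$n_used, 49L)
})

test_that("null predictors reject at about the nominal 5% rate", {
  set.seed(2024)
  reps <- 400
  p <- vapply(seq_len(reps), function(i) {
    d <- data.frame(y = rnorm(100), x = rnorm(100))
    standardized_lm(d, "y", "x")$coefficients$p_value
  }, numeric(1))
  # 3-sigma binomial band around 0.05 for 400 replicates
  expect_gt(mean(p < 0.05), 0.017)
  expect_lt(mean(p < 0.05), 0.083)
})

test_that("the model F equals the squared t for a single binary predictor", {
  set.seed(8)
  d <- data.frame(g = rep(0:1, each = 25))
  d$y <- rnorm(50, mean = d$g)
  fit <- standardized_lm(d, "y", "g")
  expect_equal(fit$f_statistic, fit$coefficients$statistic^2,
               tolerance = 1e-10)
  # and both match the classical pooled two-sample t-test
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(fit$f_statistic, unname(tt$statistic^2), tolerance = 1e-10)
})

test_that("the three-group ANOVA reports F, group stats and Bonferroni pairs", {
  set.seed(31)
  d <- data.frame(
    grs = c(rnorm(50, 0), rnorm(50, 0), rnorm(50, 10)),
    group = rep(c("control", "NTG", "HTG"), each = 50)
  )
  a <- anova_bonferroni(d, score = "grs")
  expect_equal(nrow(a$pairwise), 3L)
  expect_equal(a$alpha_bonferroni, 0.05 / 3)
  expect_lt(a$p_value, 1e-6)
  sig <- a$pairwise$significant
  names(sig) <- a$pairwise$pair
  involves_htg <- grepl("HTG", a$pairwise$pair)
  expect_true(all(sig[involves_htg]))
  expect_false(any(sig[!involves_htg]))
  expect_error(anova_bonferroni(d[d$group != "NTG", ], score = "grs"),
               class = "iopgrs_contract_error")
})

test_that("pairwise p-values use the requested pooled or Welch t-test", {
  set.seed(32)
  d <- data.frame(
    grs = c(rnorm(30, 0, 1), rnorm(40, 0.5, 3), rnorm(50, 1, 0.5)),
    group = rep(c("control", "NTG", "HTG"), times = c(30, 40, 50))
  )
  welch <- anova_bonferroni(d, var_equal = FALSE)
  pair_p <- welch$pairwise$p_unadjusted[welch$pairwise$pair %in%
                                          c("NTG vs HTG", "HTG vs NTG")]
  direct <- t.test(d$grs[d$group == "HTG"], d$grs[d$group == "NTG"])$p.value
  expect_equal(pair_p, direct, tolerance = 1e-12)
})

test_that("logistic stage flags separation instead of reporting divergent ORs", {
  set.seed(41)
  n <- 60
  d <- data.frame(
    age_years = rnorm(n, 65, 10), male = rbinom(n, 1, 0.5),
    grs = sample(0:18, n, replace = TRUE)
  )
  d$group <- ifelse(d$grs >= 9, "HTG", "control")
  fit <- logistic_group_on_grs(d, contrast = "HTG")
  expect_true(fit$separation)
  expect_true(all(is.na(fit$coefficients$odds_ratio)))

  expect_error(
    logistic_group_on_grs(d[d$group == "HTG", ], contrast = "HTG"),
    class = "iopgrs_contract_error"
  )
})

test_that("tidy and glance expose the stage results as tibbles", {
  cohort <- sample_cohort(small_params(c(30L, 30L, 30L)), seed = 2)
  d <- cohort_data(cohort)
  lm_fit <- iop_on_grs(d)
  expect_named(tidy(lm_fit),
               c("term", "estimate", "se", "beta_standardized", "statistic",
                 "p_value"))
  expect_equal(glance(lm_fit)$n_used, 90L)
  an <- anova_bonferroni(d)
  expect_equal(nrow(tidy(an)), 3L)
  lg <- logistic_group_on_grs(d, "NTG")
  expect_equal(glance(lg)$contrast, "NTG-vs-control")
  expect_s3_class(autoplot(an), "ggplot")
})
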