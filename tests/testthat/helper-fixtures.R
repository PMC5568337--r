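# fixtures are built in code; no binary data on disk

toy_panel <- function(n_var = 3L, freq = 0.5, effect = 0) {
  tibble::tibble(
    rsid = paste0("rsT", seq_len(n_var)),
    risk_allele = rep("A", n_var),
    locus = paste0("LOC", seq_len(n_var)),
    risk_allele_freq = rep_len(freq, n_var),
    iop_effect_mmHg = rep_len(effect, n_var)
  )
}

# genotype tibble from an explicit dosage matrix (rows = participants)
make_genotypes <- function(mat, rsids = NULL) {
  mat <- as.matrix(mat)
  rsids <- rsids %||% iop_variant_panel()$rsid[seq_len(ncol(mat))]
  colnames(mat) <- rsids
  dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("P%05d", seq_len(nrow(mat)))),
    tibble::as_tibble(mat)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

small_params <- function(n = c(20L, 20L, 20L), ...) {
  p <- generator_params(...)
  p$groups$n <- as.integer(n)
  p
}

# brute-force logistic MLE on (dosage, case) pairs: direct optimisation of the
# log-likelihood, independent of stats::glm
brute_force_logistic_slope <- function(dosage, case) {
  nll <- function(par) {
    eta <- par[1] + par[2] * dosage
    -sum(case * eta - log1p(exp(eta)))
  }
  stats::optim(c(0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))$par[2]
}

# textbook Pearson chi-square for a 2x2 table, written out from the
# (ad - bc)^2 formulation rather than observed-expected sums
chi2_formula_oracle <- function(tab, yates = FALSE) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}
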