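#' The nine-variant IOP risk panel
#'
#' Returns the default variant panel used throughout the package: nine
#' biallelic variants identified by genome-wide association studies as
#' associated with intraocular pressure (IOP), each described by its rsID, the
#' risk allele for IOP elevation, and the gene at or nearest the locus.
#'
#' Risk-allele frequencies and per-allele IOP effects (mmHg per risk-allele
#' copy) drive the synthetic cohort generator only; they are the frozen output
#' of the moment-matching calibration described in the methods vignette, not
#' estimates from any genotyped cohort, and can be overridden column-wise.
#'
#' @param risk_allele_freq Risk-allele frequency applied to every variant
#'   (recycled), or a length-9 vector. Must lie in (0, 1) for simulation.
#' @param iop_effect_mmHg Additive per-allele effect on latent IOP in mmHg,
#'   recycled likewise.
#'
#' @return A tibble with columns `rsid`, `risk_allele`, `locus`,
#'   `risk_allele_freq`, `iop_effect_mmHg`, one row per variant.
#' @examples
#' iop_variant_panel()
#' @export
iop_variant_panel <- function(risk_allele_freq = 0.4847,
                              iop_effect_mmHg = 0.205) {
  tibble::tibble(
    rsid = c(
      "rs1052990", "rs11656696", "rs59072263", "rs2472493", "rs58073046",
      "rs2286885", "rs6445055", "rs8176743", "rs747782"
    ),
    risk_allele = c("T", "C", "G", "C", "G", "T", "G", "A", "G"),
    locus = c(
      "CAV2", "GAS7", "GLCCI1/ICA1", "ABCA1", "ARHGEF12",
      "FAM125B", "FNDC3B", "ABO", "PTPRJ"
    ),
    risk_allele_freq = rep_len(risk_allele_freq, 9L),
    iop_effect_mmHg = rep_len(iop_effect_mmHg, 9L)
  )
}

#' Validate a variant panel
#'
#' Checks structural invariants of a panel tibble: required columns, unique
#' rsIDs, single-letter alleles, frequencies in (0, 1) (unless monomorphic
#' entries are explicitly allowed) and non-negative IOP effects.
#'
#' @param panel A tibble as returned by [iop_variant_panel()].
#' @param allow_monomorphic Permit frequencies of exactly 0 or 1 (degenerate
#'   loci used in some tests and edge cases).
#' @return The panel, invisibly, if valid; otherwise a configuration error.
#' @export
validate_panel <- function(panel, allow_monomorphic = FALSE) {
  needed <- c("rsid", "risk_allele", "locus", "risk_allele_freq",
              "iop_effect_mmHg")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols)) {
    abort_schema(paste0(
      "panel is missing column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  if (anyDuplicated(panel$rsid)) {
    abort_config("panel rsIDs must be unique")
  }
  if (!all(grepl("^[ACGT]$", panel$risk_allele))) {
    abort_config("risk_allele must be a single nucleotide letter (A/C/G/T)")
  }
  f <- panel$risk_allele_freq
  if (any(!is.finite(f)) || any(f < 0 | f > 1)) {
    abort_config("risk_allele_freq must be finite and in [0, 1]")
  }
  if (!allow_monomorphic && any(f <= 0 | f >= 1)) {
    abort_config(
      "risk_allele_freq must lie strictly in (0, 1) for simulation; ",
      body = "set allow_monomorphic = TRUE to permit degenerate frequencies"
    )
  }
  if (any(!is.finite(panel$iop_effect_mmHg)) || any(panel$iop_effect_mmHg < 0)) {
    abort_config("iop_effect_mmHg must be finite and >= 0")
  }
  invisible(panel)
}
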