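#' Read and write genotype and phenotype tables
#'
#' Genotype CSVs have a `participant_id` column followed by one integer
#' dosage column (0/1/2) per rsID; missing dosages are empty cells.
#' Phenotype CSVs have columns `participant_id`, `age_years`, `sex` (M/F),
#' `max_iop_mmHg` (one decimal), `mean_vcdr` (two decimals) and `group`
#' (`control`/`NTG`/`HTG`). Reading a phenotype table re-derives the `male`
#' indicator and the `glaucoma` flag (`TRUE` for NTG/HTG rows).
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return Readers return tibbles; writers return `path` invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_genotypes_csv <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_genotypes_csv <- function(path) {
  out <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           .default = readr::col_integer()
                         ))
  if (!"participant_id" %in% names(out)) {
    abort_schema("genotype CSV must have a participant_id column")
  }
  out
}

#' @rdname cohort_io
#' @export
write_phenotypes_csv <- function(x, path) {
  out <- tibble::tibble(
    participant_id = x$participant_id,
    age_years = x$age_years,
    sex = x$sex,
    max_iop_mmHg = sprintf("%.1f", x$max_iop_mmHg),
    mean_vcdr = sprintf("%.2f", x$mean_vcdr),
    group = x$group
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_phenotypes_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           participant_id = readr::col_character(),
                           age_years = readr::col_double(),
                           sex = readr::col_character(),
                           max_iop_mmHg = readr::col_double(),
                           mean_vcdr = readr::col_double(),
                           group = readr::col_character()
                         ))
  needed <- c("participant_id", "age_years", "sex", "max_iop_mmHg",
              "mean_vcdr", "group")
  missing_cols <- setdiff(needed, names(out))
  if (length(missing_cols)) {
    abort_schema(paste0("phenotype CSV missing column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  out$male <- as.integer(out$sex == "M")
  out$glaucoma <- out$group %in% c("NTG", "HTG")
  out
}

#' Extract panel risk-allele dosages from a VCF
#'
#' Matches panel variants by the VCF `ID` field, validates the risk allele
#' against REF/ALT (a risk allele matching neither is a hard error - no
#' silent strand flips), and counts risk-allele copies per genotype call.
#' Missing calls (`./.`) become missing dosages for the scoring policy to
#' handle. Panel rsIDs absent from the file are reported via a warning and
#' the `missing_variants` attribute.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param panel Variant panel tibble.
#' @return A genotype tibble (`participant_id` + one dosage column per found
#'   rsID) with attribute `missing_variants`.
#' @export
read_genotypes_vcf <- function(path, panel = iop_variant_panel()) {
  validate_panel(panel, allow_monomorphic = TRUE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  ids <- fix[, "ID"]
  found <- panel$rsid[panel$rsid %in% ids]
  missing_variants <- setdiff(panel$rsid, found)
  if (length(missing_variants)) {
    rlang::warn(paste0(
      "panel variant(s) absent from VCF: ",
      paste(missing_variants, collapse = ", ")
    ))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  dose_cols <- lapply(found, function(rs) {
    i <- match(rs, ids)
    ref <- unname(fix[i, "REF"])
    alt <- unname(fix[i, "ALT"])
    risk <- panel$risk_allele[match(rs, panel$rsid)]
    if (!risk %in% c(ref, alt)) {
      abort_config(paste0(
        "risk allele ", risk, " for ", rs, " matches neither REF (", ref,
        ") nor ALT (", alt, "); check strand/alleles"
      ))
    }
    risk_idx <- if (identical(risk, ref)) "0" else "1"
    calls <- gt[i, ]
    vapply(calls, function(call) {
      if (is.na(call) || grepl("\\.", call)) return(NA_integer_)
      alleles <- strsplit(call, "[/|]")[[1L]]
      sum(alleles == risk_idx)
    }, integer(1), USE.NAMES = FALSE)
  })
  names(dose_cols) <- found
  out <- dplyr::bind_cols(
    tibble::tibble(participant_id = samples),
    tibble::as_tibble(dose_cols)
  )
  attr(out, "missing_variants") <- missing_variants
  out
}

#' Read and write generator configuration profiles
#'
#' Generator parameters serialize to a structured JSON profile (panel rows
#' plus the scalar model settings). The packaged default profile - the frozen
#' calibration shipped as the [generator_params()] defaults - lives at
#' `system.file("extdata", "calibrated_profile.json", package = "iopgrs")`.
#' Reading validates the structure and returns a `grs_generator_params`
#' object.
#'
#' @param params A [generator_params()] object.
#' @param path JSON file path.
#' @return `read_generator_config()` returns a `grs_generator_params`;
#'   `write_generator_config()` returns `path` invisibly.
#' @name generator_config
NULL

#' @rdname generator_config
#' @export
write_generator_config <- function(params, path) {
  validate_generator_params(params)
  x <- unclass(params)
  x$panel <- as.list(x$panel)
  x$groups <- as.list(x$groups)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname generator_config
#' @export
read_generator_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  needed <- c("panel", "baseline_iop_mmHg", "age_effect_mmHg",
              "age_reference_years", "male_effect_mmHg", "iop_noise",
              "glaucoma_iop_offset_mmHg", "htg_tail",
              "vulnerability_prevalence", "vcdr_model", "groups",
              "max_attempts_factor")
  missing_keys <- setdiff(needed, names(x))
  if (length(missing_keys)) {
    abort_schema(paste0("generator config missing key(s): ",
                        paste(missing_keys, collapse = ", ")))
  }
  generator_params(
    panel = tibble::as_tibble(x$panel),
    baseline_iop_mmHg = x$baseline_iop_mmHg,
    age_effect_mmHg = x$age_effect_mmHg,
    age_reference_years = x$age_reference_years,
    male_effect_mmHg = x$male_effect_mmHg,
    iop_noise = as.list(x$iop_noise),
    glaucoma_iop_offset_mmHg = x$glaucoma_iop_offset_mmHg,
    htg_tail = as.list(x$htg_tail),
    vulnerability_prevalence = x$vulnerability_prevalence,
    vcdr_model = as.list(x$vcdr_model),
    groups = tibble::as_tibble(x$groups) |>
      dplyr::mutate(n = as.integer(.data$n)),
    max_attempts_factor = x$max_attempts_factor
  )
}
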