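pipeline_stage_names <- function() {
  c("scores", "linear_iop_variants", "linear_iop_grs", "linear_vcdr_grs",
    "linear_iop_vcdr", "anova_grs", "logistic_ntg", "logistic_htg",
    "cutoff_scan")
}

# stages that consume the unweighted GRS
grs_dependent_stages <- function() {
  c("linear_iop_grs", "linear_vcdr_grs", "anova_grs", "logistic_ntg",
    "logistic_htg", "cutoff_scan")
}

#' Pipeline run configuration
#'
#' Describes one end-to-end run: the cohort source (either generator
#' parameters for a synthetic cohort or paths to genotype/phenotype CSVs -
#' exactly one of the two), the variant panel, the stages to run, and the
#' seed.
#'
#' @param generator A [generator_params()] object, or `NULL` when reading
#'   tables from disk.
#' @param genotypes_path,phenotypes_path CSV paths for a real cohort
#'   (both or neither).
#' @param panel Variant panel.
#' @param stages `"all"` or a character vector drawn from
#'   `scores`, `linear_iop_variants`, `linear_iop_grs`, `linear_vcdr_grs`,
#'   `linear_iop_vcdr`, `anova_grs`, `logistic_ntg`, `logistic_htg`,
#'   `cutoff_scan`.
#' @param seed Integer seed recorded in the report and used for simulation.
#' @param cutoff_thresholds Threshold grid for the cutoff scan.
#' @return A list of class `grs_run_config`.
#' @export
pipeline_config <- function(generator = generator_params(),
                            genotypes_path = NULL,
                            phenotypes_path = NULL,
                            panel = iop_variant_panel(),
                            stages = "all",
                            seed = 1L,
                            cutoff_thresholds = 0:18) {
  from_files <- !is.null(genotypes_path) || !is.null(phenotypes_path)
  if (from_files && (is.null(genotypes_path) || is.null(phenotypes_path))) {
    abort_config("genotypes_path and phenotypes_path must be given together")
  }
  if (from_files && !is.null(generator)) {
    abort_config(
      "supply exactly one cohort source: generator params or table paths",
      body = "set generator = NULL when reading tables"
    )
  }
  if (!from_files && is.null(generator)) {
    abort_config("supply generator params or genotype/phenotype table paths")
  }
  if (identical(stages, "all")) stages <- pipeline_stage_names()
  unknown <- setdiff(stages, pipeline_stage_names())
  if (length(unknown)) {
    abort_config(paste0("unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  needs_scores <- intersect(stages, grs_dependent_stages())
  if (length(needs_scores) && !"scores" %in% stages) {
    abort_config(paste0(
      "stage(s) ", paste(needs_scores, collapse = ", "),
      " require the 'scores' stage"
    ))
  }
  structure(
    list(generator = generator, genotypes_path = genotypes_path,
         phenotypes_path = phenotypes_path, panel = panel, stages = stages,
         seed = as.integer(seed), cutoff_thresholds = cutoff_thresholds),
    class = "grs_run_config"
  )
}

# Table 1-style cohort summary
summarise_cohort <- function(phenotypes) {
  phenotypes |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      age_mean = mean(.data$age_years),
      age_sd = stats::sd(.data$age_years),
      pct_male = 100 * mean(.data$male),
      max_iop_mean = mean(.data$max_iop_mmHg),
      max_iop_sd = stats::sd(.data$max_iop_mmHg),
      vcdr_mean = mean(.data$mean_vcdr),
      vcdr_sd = stats::sd(.data$mean_vcdr),
      .groups = "drop"
    )
}

grs_lm_to_list <- function(x) {
  list(
    coefficients = as.list(tibble::as_tibble(x$coefficients)),
    f_statistic = x$f_statistic, f_p_value = x$f_p_value,
    n_used = x$n_used, r_squared = x$r_squared
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates cohort acquisition (simulation or CSV ingestion), unweighted
#' scoring, the four standardized linear regressions, the three-group ANOVA
#' with Bonferroni post hoc, the two age/sex-adjusted logistic contrasts, and
#' the cutoff scan. Every stage key is present in the report; stages not
#' requested are marked skipped. Identical config and seed give identical
#' reports.
#'
#' @param config A [pipeline_config()] object.
#' @return A list of class `grs_report`: `cohort_summary`, `stages` (one
#'   entry per stage), and `provenance` (seed, config hash, package version).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "grs_run_config")) {
    abort_config("config must be built with pipeline_config()")
  }
  if (is.null(config$generator)) {
    genotypes <- read_genotypes_csv(config$genotypes_path)
    phenotypes <- read_phenotypes_csv(config$phenotypes_path)
    panel <- config$panel
  } else {
    cohort <- sample_cohort(config$generator, seed = config$seed)
    genotypes <- cohort$genotypes
    phenotypes <- cohort$phenotypes
    panel <- config$generator$panel
  }
  stages <- config$stages
  res <- stats::setNames(
    vector("list", length(pipeline_stage_names())), pipeline_stage_names()
  )
  df <- NULL
  if ("scores" %in% stages) {
    scores <- grs_unweighted(genotypes, panel)
    df <- phenotypes |>
      dplyr::left_join(genotypes, by = "participant_id") |>
      dplyr::inner_join(scores[, c("participant_id", "grs")],
                        by = "participant_id")
    res$scores <- list(
      n_scored = nrow(scores),
      n_missing_handled = attr(scores, "n_missing_handled"),
      mean = mean(scores$grs), sd = stats::sd(scores$grs),
      min = min(scores$grs), max = max(scores$grs)
    )
  } else {
    df <- dplyr::left_join(phenotypes, genotypes, by = "participant_id")
  }
  run_stage <- function(name, fn) {
    if (name %in% stages) fn() else list(skipped = TRUE)
  }
  res$linear_iop_variants <- run_stage("linear_iop_variants", function() {
    grs_lm_to_list(iop_on_variants(df, panel))
  })
  res$linear_iop_grs <- run_stage("linear_iop_grs", function() {
    grs_lm_to_list(iop_on_grs(df))
  })
  res$linear_vcdr_grs <- run_stage("linear_vcdr_grs", function() {
    grs_lm_to_list(vcdr_on_grs(df))
  })
  res$linear_iop_vcdr <- run_stage("linear_iop_vcdr", function() {
    grs_lm_to_list(iop_vcdr_correlation(df))
  })
  res$anova_grs <- run_stage("anova_grs", function() {
    a <- anova_bonferroni(df)
    list(group_stats = as.list(a$group_stats |>
                                 dplyr::mutate(group = as.character(.data$group))),
         f_statistic = a$f_statistic, df1 = a$df[1L], df2 = a$df[2L],
         p_value = a$p_value,
         pairwise = as.list(a$pairwise),
         alpha_bonferroni = a$alpha_bonferroni)
  })
  logistic_to_list <- function(fit) {
    list(coefficients = as.list(fit$coefficients), contrast = fit$contrast,
         n_cases = fit$n_cases, n_controls = fit$n_controls,
         separation = fit$separation)
  }
  res$logistic_ntg <- run_stage("logistic_ntg", function() {
    logistic_to_list(logistic_group_on_grs(df, contrast = "NTG"))
  })
  res$logistic_htg <- run_stage("logistic_htg", function() {
    logistic_to_list(logistic_group_on_grs(df, contrast = "HTG"))
  })
  res$cutoff_scan <- run_stage("cutoff_scan", function() {
    scan <- cutoff_scan(df, thresholds = config$cutoff_thresholds)
    as.list(tibble::as_tibble(scan))
  })
  for (nm in names(res)) {
    if (is.null(res[[nm]])) res[[nm]] <- list(skipped = TRUE)
  }
  structure(
    list(
      cohort_summary = as.list(summarise_cohort(phenotypes)),
      stages = res,
      provenance = list(
        seed = config$seed,
        config_hash = rlang::hash(config),
        package_version = as.character(utils::packageVersion("iopgrs"))
      )
    ),
    class = "grs_report"
  )
}

#' @export
print.grs_report <- function(x, ...) {
  cat("<grs_report> seed", x$provenance$seed, "\n")
  cat("groups:", paste(sprintf("%s n=%d", x$cohort_summary$group,
                               x$cohort_summary$n), collapse = ", "), "\n")
  ran <- names(x$stages)[!vapply(x$stages, function(s)
    isTRUE(s$skipped), logical(1))]
  cat("stages run:", paste(ran, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize and validate pipeline reports
#'
#' `write_report()` writes a report as JSON at full numeric precision (no
#' timestamps, so identical runs are byte-identical). `read_report()` reads
#' it back as plain lists. `validate_report()` checks a report (object or
#' JSON path) against the JSON schema shipped at
#' `system.file("schema", "report-schema.json", package = "iopgrs")` using a
#' minimal structural validator (type / required-property checks).
#'
#' @param report A `grs_report` (or equivalent list).
#' @param path File path.
#' @param schema_path Path to a JSON schema.
#' @return `write_report()` returns `path` invisibly; `validate_report()`
#'   returns `TRUE` invisibly or raises a schema error naming the offending
#'   key path.
#' @name report_io
NULL

#' @rdname report_io
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname report_io
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

# minimal JSON-schema walker: supports type, properties, required, items
check_schema_node <- function(x, schema, where) {
  type <- schema$type
  ok_type <- function(t) {
    switch(t,
      object = is.list(x) && (length(x) == 0L || !is.null(names(x))),
      array = is.list(x) || (is.atomic(x) && is.null(names(x))),
      number = is.numeric(x) || is.null(x),
      integer = is.numeric(x),
      string = is.character(x) || is.null(x),
      boolean = is.logical(x),
      TRUE
    )
  }
  if (!is.null(type) && !any(vapply(unlist(type), ok_type, logical(1)))) {
    abort_schema(paste0("schema violation at ", where, ": expected ",
                        paste(unlist(type), collapse = "|")))
  }
  for (req in unlist(schema$required)) {
    if (!req %in% names(x)) {
      abort_schema(paste0("schema violation at ", where,
                          ": missing required key '", req, "'"))
    }
  }
  for (prop in names(schema$properties)) {
    if (prop %in% names(x)) {
      check_schema_node(x[[prop]], schema$properties[[prop]],
                        paste0(where, "/", prop))
    }
  }
  if (!is.null(schema$items) && length(x)) {
    for (i in seq_along(x)) {
      check_schema_node(x[[i]], schema$items, paste0(where, "[", i, "]"))
    }
  }
  invisible(TRUE)
}

#' @rdname report_io
#' @export
validate_report <- function(report,
                            schema_path = system.file(
                              "schema", "report-schema.json",
                              package = "iopgrs"
                            )) {
  if (is.character(report) && length(report) == 1L && file.exists(report)) {
    report <- read_report(report)
  }
  schema <- jsonlite::read_json(schema_path, simplifyVector = FALSE)
  check_schema_node(unclass(report), schema, where = "")
  invisible(TRUE)
}
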