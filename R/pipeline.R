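# Top-level pipeline: prevalence -> GIF -> relative risks -> pedigree scan,
# with a consolidated, re-derivable report.

#' Pipeline configuration
#'
#' Parameters shared across the analysis stages: the case definition
#' (`bmi < bmi_threshold`, inclusive age window), the control-resampling and
#' dGIF settings, the relative-risk degree range, and the high-risk pedigree
#' thresholds.
#'
#' @param bmi_threshold Case cut-off (strict `<`).
#' @param age_min,age_max Inclusive age window for case selection.
#' @param n_control_sets Matched control sets for the GIF test.
#' @param dgif_min_distance Smallest genetic distance counted by the dGIF.
#' @param max_degree Largest degree of relationship in the RR table.
#' @param alpha,min_cases High-risk pedigree selection thresholds.
#' @param bin_width Birth-year bin width for cohorts and matching.
#' @param seed Integer seed for control resampling.
#' @return A list of class `fa_run_config`.
#' @export
run_config <- function(bmi_threshold = 18.5, age_min = 25, age_max = 64,
                       n_control_sets = 1000, dgif_min_distance = 4,
                       max_degree = 7, alpha = 1e-4, min_cases = 10,
                       bin_width = 5, seed = 1) {
  stopifnot(bmi_threshold > 0, age_min <= age_max, n_control_sets >= 1,
            dgif_min_distance >= 1, max_degree >= 1)
  structure(list(
    bmi_threshold = bmi_threshold, age_min = age_min, age_max = age_max,
    n_control_sets = n_control_sets, dgif_min_distance = dgif_min_distance,
    max_degree = max_degree, alpha = alpha, min_cases = min_cases,
    bin_width = bin_width, seed = seed
  ), class = "fa_run_config")
}

#' @rdname run_config
#' @param path A YAML file whose keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full familial-aggregation pipeline
#'
#' Builds the analysis table, then computes the age-specific prevalence
#' table, the GIF/dGIF test with matched-control resampling, the
#' relative-risk table for degrees 1..`max_degree`, and the founder
#' descendancy scan with high-risk selection. Every number in the report is
#' re-derivable from the inputs, the configuration and the seed.
#'
#' @param ped A [pedigree()] (or path to a pedigree TSV).
#' @param phenotype A phenotype tibble (or path to a phenotype TSV).
#' @param config A [run_config()].
#' @param output_dir Optional directory; when given, a JSON report and TSV
#'   tables (prevalence, GIF curves, RR, scan) are written there.
#' @return A list of class `fa_report` with elements `params`, `counts`,
#'   `prevalence`, `gif`, `rr`, `scan`, `high_risk`.
#' @export
run_pipeline <- function(ped, phenotype, config = run_config(),
                         output_dir = NULL) {
  if (is.character(ped)) ped <- read_pedigree(ped)
  if (is.character(phenotype)) phenotype <- read_phenotype(phenotype)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }
  tbl <- stage("analysis_table",
               build_analysis_table(ped, phenotype, config$bmi_threshold))
  prev <- stage("prevalence", prevalence_by_age(tbl))
  cases <- select_cases(tbl, config$age_min, config$age_max)
  gif_res <- stage("gif", run_gif_analysis(
    ped, phenotype, bmi_threshold = config$bmi_threshold,
    age_min = config$age_min, age_max = config$age_max,
    n_sets = config$n_control_sets, seed = config$seed,
    dgif_min_distance = config$dgif_min_distance,
    bin_width = config$bin_width
  ))
  rr <- stage("relative_risk", relative_risk_table(
    ped, cases, tbl, max_degree = config$max_degree,
    bin_width = config$bin_width
  ))
  scan <- stage("scan", scan_pedigrees(ped, tbl, cases = cases,
                                       bin_width = config$bin_width))
  hr <- select_high_risk(scan, alpha = config$alpha,
                         min_cases = config$min_cases)
  report <- structure(list(
    params = unclass(config),
    counts = list(
      n_individuals = nrow(ped),
      n_complete = sum(is_complete(ped)),
      n_phenotyped = sum(tbl$phenotyped),
      n_cases = sum(tbl$is_case),
      n_cases_window = length(cases)
    ),
    prevalence = prev,
    gif = gif_res,
    rr = rr,
    scan = scan,
    high_risk = hr
  ), class = "fa_report")
  if (!is.null(output_dir)) write_report(report, output_dir)
  report
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (parameters, counts, GIF summary, high-risk list) and
#' TSV tables mirroring the analysis outputs: `prevalence.tsv`,
#' `gif_curve.tsv` (case and mean-control contribution curves),
#' `relative_risk.tsv`, `pedigree_scan.tsv`.
#'
#' @param report An `fa_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$prevalence, file.path(dir, "prevalence.tsv"),
                   progress = FALSE)
  curve <- dplyr::bind_rows(
    report$gif$curve_case %>% mutate(group = "case"),
    report$gif$curve_control %>% mutate(group = "control_mean")
  )
  readr::write_tsv(curve, file.path(dir, "gif_curve.tsv"), progress = FALSE)
  readr::write_tsv(tidy(report$rr), file.path(dir, "relative_risk.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(report$scan), file.path(dir, "pedigree_scan.tsv"),
                   progress = FALSE)
  json <- list(
    params = report$params,
    counts = report$counts,
    gif = as.list(glance(report$gif)),
    gif_p_display = report$gif$gif_p$display,
    dgif_p_display = report$gif$dgif_p$display,
    relative_risk = tidy(report$rr),
    high_risk = tidy(report$high_risk)
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Check a pipeline report for structural completeness
#'
#' Verifies the presence and shape of every report element (parameters,
#' counts, prevalence table, GIF result, RR table, scan). Used by tests and
#' by `run_pipeline()` consumers as a light schema check.
#'
#' @param report An `fa_report`.
#' @return `TRUE` (invisibly) or an error describing the defect.
#' @export
validate_report <- function(report) {
  need <- c("params", "counts", "prevalence", "gif", "rr", "scan",
            "high_risk")
  missing <- setdiff(need, names(report))
  if (length(missing) > 0) {
    abort(paste0("report is missing elements: ",
                 paste(missing, collapse = ", ")))
  }
  stopifnot(
    inherits(report$gif, "fa_gif"),
    inherits(report$rr, "fa_rr"),
    inherits(report$scan, "fa_scan"),
    all(c("age_low", "age_high", "cases", "n", "prevalence",
          "ci_low", "ci_high") %in% names(report$prevalence)),
    all(c("degree", "n_relatives", "observed", "expected", "rr",
          "ci_low", "ci_high", "p_value") %in% names(report$rr))
  )
  invisible(TRUE)
}

#' @export
print.fa_report <- function(x, ...) {
  cat("Familial-aggregation pipeline report\n")
  cat(sprintf("  individuals %d, phenotyped %d, cases %d (window %d)\n",
              x$counts$n_individuals, x$counts$n_phenotyped,
              x$counts$n_cases, x$counts$n_cases_window))
  print(x$gif)
  cat(sprintf("  high-risk pedigrees: %d\n", nrow(x$high_risk)))
  invisible(x)
}
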