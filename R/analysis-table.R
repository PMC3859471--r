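# Per-person analysis table: the join of genealogy and phenotype on which the
# GIF, relative-risk and pedigree-scan stages all operate.

#' Build the per-person analysis table
#'
#' Joins a pedigree with a phenotype table and derives the fields every
#' downstream stage needs: age at the (most recent) record, completeness of
#' genealogy data, eligibility as a phenotyped individual, and case status
#' under the strict `bmi < threshold` rule.
#'
#' Eligibility mirrors the study's chain: an individual is `phenotyped` only
#' if it passes the genealogy-completeness filter *and* has a BMI record.
#'
#' @param ped A [pedigree()].
#' @param phenotype Tibble with columns `id`, `bmi`, `record_year` (one row
#'   per individual; duplicates are resolved to the most recent record).
#' @param bmi_threshold Case cut-off; cases have `bmi < bmi_threshold`.
#' @return Tibble with one row per pedigree member: `id`, `sex`, `birth_year`,
#'   `birthplace`, `bmi`, `record_year`, `age`, `complete`, `phenotyped`,
#'   `is_case`.
#' @export
build_analysis_table <- function(ped, phenotype, bmi_threshold = 18.5) {
  stopifnot(bmi_threshold > 0)
  ph <- resolve_most_recent(phenotype)
  tbl <- ped %>%
    as_tibble() %>%
    select("id", "sex", "birth_year", "birthplace") %>%
    left_join(ph, by = "id") %>%
    mutate(
      age = .data$record_year - .data$birth_year,
      complete = is_complete(ped),
      phenotyped = .data$complete & !is.na(.data$bmi),
      is_case = .data$phenotyped & .data$bmi < bmi_threshold
    )
  tbl
}

# Most-recent-record rule: when several phenotype records exist for one id,
# keep the one with the latest record_year (ties: largest BMI record wins so
# the choice is deterministic).
resolve_most_recent <- function(phenotype) {
  stopifnot(all(c("id", "bmi", "record_year") %in% names(phenotype)))
  phenotype %>%
    as_tibble() %>%
    mutate(id = as.character(.data$id)) %>%
    select("id", "bmi", "record_year") %>%
    arrange(.data$id, desc(.data$record_year), desc(.data$bmi)) %>%
    distinct(.data$id, .keep_all = TRUE)
}

# 5-year birth cohort bin (lower edge).
birth_bin <- function(birth_year, bin_width = 5) {
  bin_width * floor(birth_year / bin_width)
}

# Case ids under an optional age window (inclusive), among phenotyped rows.
select_cases <- function(tbl, age_min = NULL, age_max = NULL) {
  out <- tbl %>% filter(.data$is_case)
  if (!is.null(age_min)) out <- out %>% filter(.data$age >= age_min)
  if (!is.null(age_max)) out <- out %>% filter(.data$age <= age_max)
  out$id
}
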