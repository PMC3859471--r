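# Readers and writers for the tab-separated pedigree and phenotype formats.

#' Read and write pedigree files
#'
#' The pedigree file is tab-separated with a header row and columns
#' `id  father_id  mother_id  sex  birth_year  birthplace`; a `0` or empty
#' field marks a missing parent (.fam-style parent encoding). Extra columns
#' are preserved. Reading validates the genealogy: unknown parent ids,
#' non-male fathers / non-female mothers and parentage cycles are errors
#' naming the offending ids; malformed rows are reported with line numbers.
#'
#' @param path File path.
#' @return `read_pedigree()` returns a [pedigree()].
#' @export
read_pedigree <- function(path) {
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    father_id = readr::col_character(),
    mother_id = readr::col_character(),
    sex = readr::col_character(),
    birth_year = readr::col_integer(),
    birthplace = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed pedigree rows at lines: ",
                 paste(unique(probs$row), collapse = ", ")))
  }
  pedigree(raw)
}

#' @rdname read_pedigree
#' @param ped A [pedigree()].
#' @export
write_pedigree <- function(ped, path) {
  out <- as_tibble(ped) %>%
    mutate(
      father_id = ifelse(is.na(.data$father_id), "0", .data$father_id),
      mother_id = ifelse(is.na(.data$mother_id), "0", .data$mother_id)
    )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write phenotype files
#'
#' Tab-separated with a header row; either `id  bmi  record_year` or
#' `id  weight  height  record_year`, in which case BMI is computed as
#' weight/height^2 (`units = "metric"`: kg and m) or after lb/in -> kg/m
#' conversion (`units = "imperial"`). When an individual has several records,
#' the most recent (largest `record_year`) is kept.
#'
#' @param path File path.
#' @param units `"metric"` or `"imperial"`, used only with the
#'   weight/height schema.
#' @return Tibble with columns `id`, `bmi`, `record_year`, one row per
#'   individual.
#' @export
read_phenotype <- function(path, units = c("metric", "imperial")) {
  units <- match.arg(units)
  raw <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE))
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed phenotype rows at lines: ",
                 paste(unique(probs$row), collapse = ", ")))
  }
  if (all(c("weight", "height") %in% names(raw)) && !("bmi" %in% names(raw))) {
    w <- raw$weight
    h <- raw$height
    if (units == "imperial") {
      w <- w * 0.45359237
      h <- h * 0.0254
    }
    raw$bmi <- w / h^2
  }
  if (!all(c("id", "bmi", "record_year") %in% names(raw))) {
    abort("phenotype file needs columns id, bmi (or weight+height), record_year")
  }
  resolve_most_recent(raw)
}

#' @rdname read_phenotype
#' @param phenotype Tibble with columns `id`, `bmi`, `record_year`.
#' @export
write_phenotype <- function(phenotype, path) {
  readr::write_tsv(phenotype %>% select("id", "bmi", "record_year"),
                   path, progress = FALSE)
  invisible(path)
}
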