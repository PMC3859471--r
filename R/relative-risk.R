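# Cohort-standardized relative risks in relatives, prevalence tables, and the
# interval/p-value machinery behind them.

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' The beta-quantile form of the exact interval: lower limit
#' `qbeta(alpha/2, k, n - k + 1)` (0 when `k = 0`), upper limit
#' `qbeta(1 - alpha/2, k + 1, n - k)` (1 when `k = n`).
#'
#' @param k Number of successes (vectorised).
#' @param n Number of trials.
#' @param level Confidence level.
#' @return Tibble with columns `low`, `high`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (any(n < 1) || any(k < 0) || any(k > n)) {
    abort("clopper_pearson requires 0 <= k <= n, n >= 1")
  }
  alpha <- 1 - level
  low <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  tibble(low = low, high = high)
}

#' Phenotype prevalence by age group
#'
#' Cases and phenotyped counts per age bin with exact binomial confidence
#' intervals, the shape of the study's age-specific prevalence table.
#'
#' @param tbl An analysis table from [build_analysis_table()], or any tibble
#'   with logical `phenotyped`, `is_case` and numeric `age` columns.
#' @param age_breaks Left edges of the age bins plus a final right edge
#'   (default five-year bins 15 to 80, then 80+).
#' @param level Confidence level for the Clopper-Pearson interval.
#' @return Tibble with `age_low`, `age_high` (inclusive), `cases`, `n`,
#'   `prevalence` (percent), `ci_low`, `ci_high` (percent). Empty bins have
#'   `NA` prevalence and are flagged by `n = 0`.
#' @export
prevalence_by_age <- function(tbl, age_breaks = c(seq(15, 80, by = 5), Inf),
                              level = 0.95) {
  ph <- tbl %>% filter(.data$phenotyped, !is.na(.data$age))
  lows <- age_breaks[-length(age_breaks)]
  highs <- age_breaks[-1] - 1
  out <- purrr::map2_dfr(lows, highs, function(lo, hi) {
    sub <- ph %>% filter(.data$age >= lo, .data$age <= hi)
    tibble(age_low = lo, age_high = hi,
           cases = sum(sub$is_case), n = nrow(sub))
  })
  ci <- clopper_pearson(pmin(out$cases, pmax(out$n, 1)), pmax(out$n, 1), level)
  out %>%
    mutate(
      prevalence = ifelse(.data$n > 0, 100 * .data$cases / .data$n, NA_real_),
      ci_low = ifelse(.data$n > 0, 100 * ci$low, NA_real_),
      ci_high = ifelse(.data$n > 0, 100 * ci$high, NA_real_)
    )
}

#' Total cases inside an age window of a prevalence table
#'
#' Sums the per-bin case counts of [prevalence_by_age()] output over the bins
#' fully contained in the inclusive age window (the study's 25-64 filter).
#'
#' @param prev_tbl Output of [prevalence_by_age()] (or a tibble with
#'   `age_low`, `age_high`, `cases`).
#' @param age_min,age_max Inclusive window bounds.
#' @return Integer case total.
#' @export
age_window_cases <- function(prev_tbl, age_min, age_max) {
  prev_tbl %>%
    filter(.data$age_low >= age_min, .data$age_high <= age_max) %>%
    pull(.data$cases) %>%
    sum()
}

#' Assign birth-year/sex/birthplace cohorts and their phenotype rates
#'
#' Every phenotyped individual is assigned to a cohort defined by its
#' five-year birth-year bin, sex, and birthplace; the cohort-specific rate is
#' the number of cases divided by the number of phenotyped individuals in the
#' cohort. These internal rates are the reference used for expected case
#' counts in relatives and founder descendancies.
#'
#' @param tbl An analysis table from [build_analysis_table()].
#' @param bin_width Birth-year bin width in years.
#' @return List with `members` (tibble `id`, `cohort`) and `rates` (tibble
#'   `cohort`, `birth_bin`, `sex`, `birthplace`, `n_phenotyped`, `n_cases`,
#'   `rate`). Individuals with a missing stratum attribute are dropped with a
#'   warning reporting how many.
#' @export
assign_cohorts <- function(tbl, bin_width = 5) {
  ph <- tbl %>% filter(.data$phenotyped)
  bad <- is.na(ph$birth_year) | is.na(ph$sex) | is.na(ph$birthplace)
  if (any(bad)) {
    warn(paste0(sum(bad),
                " phenotyped individuals lack a stratum attribute; excluded"))
    ph <- ph[!bad, ]
  }
  ph <- ph %>%
    mutate(
      birth_bin = birth_bin(.data$birth_year, bin_width),
      cohort = paste(.data$birth_bin, .data$sex, .data$birthplace, sep = "/")
    )
  rates <- ph %>%
    group_by(.data$cohort, .data$birth_bin, .data$sex, .data$birthplace) %>%
    summarise(n_phenotyped = dplyr::n(), n_cases = sum(.data$is_case),
              .groups = "drop") %>%
    mutate(rate = .data$n_cases / .data$n_phenotyped)
  list(members = ph %>% select("id", "cohort"), rates = rates)
}

#' Expected case count in a set of phenotyped individuals
#'
#' Number of relatives (or descendants) in each cohort times the cohort rate,
#' summed over cohorts.
#'
#' @param ids Character vector of (deduplicated, phenotyped) individual ids.
#' @param cohorts Output of [assign_cohorts()].
#' @return A nonnegative number.
#' @export
expected_cases <- function(ids, cohorts) {
  cohorts$members %>%
    filter(.data$id %in% ids) %>%
    count(.data$cohort) %>%
    inner_join(cohorts$rates %>% select("cohort", "rate"), by = "cohort") %>%
    summarise(expected = sum(.data$n * .data$rate)) %>%
    pull(.data$expected)
}

#' Ratio confidence interval for observed/expected counts
#'
#' Log-scale large-sample interval for a standardized ratio `observed /
#' expected` with the expected count treated as fixed:
#' `RR * exp(+/- z * sqrt(1 / observed))`. Positivity-preserving; with
#' `observed = 0` the lower limit is 0 and the upper limit is the one-sided
#' Poisson bound `-log(alpha/2) / expected`.
#'
#' @param observed Observed count (vectorised).
#' @param expected Expected count, strictly positive.
#' @param level Confidence level.
#' @return Tibble with columns `low`, `high`.
#' @export
agresti_ci <- function(observed, expected, level = 0.95) {
  if (any(expected <= 0)) abort("expected must be > 0")
  if (any(observed < 0)) abort("observed must be >= 0")
  z <- qnorm(1 - (1 - level) / 2)
  rr <- observed / expected
  low <- ifelse(observed == 0, 0, rr * exp(-z * sqrt(1 / observed)))
  high <- ifelse(observed == 0,
                 -log((1 - level) / 2) / expected,
                 rr * exp(z * sqrt(1 / observed)))
  tibble(low = low, high = high)
}

#' Two-sided Poisson p-value for observed vs expected counts
#'
#' Default is the exact Poisson tail: twice the smaller of `P(X <= obs)` and
#' `P(X >= obs)` for `X ~ Poisson(expected)`, capped at 1. `method =
#' "normal"` uses the two-sided normal tail at
#' `z = (obs - expected) / sqrt(expected)`.
#'
#' @param observed Observed count (vectorised).
#' @param expected Expected count, strictly positive.
#' @param method `"poisson"` (exact, doubled smaller tail) or `"normal"`.
#' @return Numeric vector of p-values.
#' @export
poisson_two_sided_p <- function(observed, expected,
                                method = c("poisson", "normal")) {
  method <- match.arg(method)
  if (any(expected <= 0)) abort("expected must be > 0")
  if (method == "poisson") {
    lower <- ppois(observed, expected)
    upper <- ppois(observed - 1, expected, lower.tail = FALSE)
    pmin(1, 2 * pmin(lower, upper))
  } else {
    z <- (observed - expected) / sqrt(expected)
    2 * stats::pnorm(-abs(z))
  }
}

#' Relative risk of the phenotype in relatives, by degree
#'
#' For each degree 1..`max_degree`: relatives of the proband set at that
#' minimal degree (counted without duplication, probands excluded) are
#' intersected with the phenotyped pool; observed is the number of cases among
#' them, expected applies the internal cohort-specific rates, RR =
#' observed/expected with the ratio CI of [agresti_ci()] and the two-sided
#' Poisson p of [poisson_two_sided_p()].
#'
#' @param ped A [pedigree()].
#' @param probands Character vector of proband (case) ids.
#' @param tbl Analysis table from [build_analysis_table()].
#' @param max_degree Largest degree reported.
#' @param level CI confidence level.
#' @param bin_width Cohort birth-year bin width.
#' @return A tibble of class `fa_rr` with columns `degree`, `n_relatives`,
#'   `observed`, `expected`, `rr`, `ci_low`, `ci_high`, `p_value`. Degrees
#'   where `expected = 0` have `NA` RR and are flagged by the `expected`
#'   column itself.
#' @export
relative_risk_table <- function(ped, probands, tbl, max_degree = 7,
                                level = 0.95, bin_width = 5) {
  cohorts <- assign_cohorts(tbl, bin_width)
  rel <- relatives_by_degree(ped, probands, max_degree)
  ph <- tbl %>% filter(.data$phenotyped)
  rel <- rel %>% inner_join(ph %>% select("id", "is_case"), by = "id")
  rows <- purrr::map_dfr(seq_len(max_degree), function(d) {
    ids <- rel$id[rel$degree == d]
    observed <- sum(rel$is_case[rel$degree == d])
    expected <- if (length(ids) > 0) expected_cases(ids, cohorts) else 0
    tibble(degree = d, n_relatives = length(ids),
           observed = observed, expected = expected)
  })
  ok <- rows$expected > 0
  ci <- agresti_ci(pmax(rows$observed, 0), ifelse(ok, rows$expected, 1), level)
  out <- rows %>%
    mutate(
      rr = ifelse(ok, .data$observed / .data$expected, NA_real_),
      ci_low = ifelse(ok, ci$low, NA_real_),
      ci_high = ifelse(ok, ci$high, NA_real_),
      p_value = ifelse(ok,
                       poisson_two_sided_p(.data$observed,
                                           ifelse(ok, .data$expected, 1)),
                       NA_real_)
    )
  class(out) <- c("fa_rr", class(out))
  out
}

#' @export
print.fa_rr <- function(x, ...) {
  cat("Relative risk in relatives by degree\n")
  NextMethod()
}

#' Tidiers for relative-risk tables
#'
#' `tidy()` returns the underlying tibble; `glance()` a one-row summary with
#' the first-degree RR and the number of degrees showing RR > 1.
#'
#' @param x An `fa_rr` object.
#' @param ... Unused.
#' @export
tidy.fa_rr <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fa_rr")
  as_tibble(out)
}

#' @rdname tidy.fa_rr
#' @export
glance.fa_rr <- function(x, ...) {
  tibble(
    max_degree = max(x$degree),
    n_relatives = sum(x$n_relatives),
    rr_first_degree = x$rr[x$degree == 1],
    n_degrees_elevated = sum(x$rr > 1, na.rm = TRUE)
  )
}

#' Plot relative risks by degree
#'
#' RR point estimates with confidence intervals against degree of
#' relationship; the dashed line marks RR = 1.
#'
#' @param object An `fa_rr` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fa_rr <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$degree, .data$rr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_x_continuous(breaks = df$degree) +
    ggplot2::labs(x = "degree of relationship", y = "relative risk") +
    ggplot2::theme_minimal()
}
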