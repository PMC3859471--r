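# Genealogical Index of Familiality: average pairwise relatedness of a case
# set, significance by comparison with matched control sets.

#' Genealogical Index of Familiality of a set
#'
#' The GIF is the mean pairwise relatedness coefficient over all unordered
#' pairs of the member set, scaled by `scale` (10^5 by the classic
#' convention). With `min_distance = 4` only pairs at genetic distance >= 4
#' (first cousins and beyond) contribute to the numerator, giving the distant
#' GIF (dGIF) used to separate genetic from shared-environment clustering;
#' the denominator remains the count of all pairs, so dGIF <= GIF.
#'
#' @param ped A [pedigree()].
#' @param members Character vector of at least two member ids.
#' @param min_distance Smallest genetic distance counted in the numerator.
#' @param scale Multiplicative display scale.
#' @param pairs Optional precomputed [kinship_pairs()] tibble for `members`.
#' @return A single nonnegative number.
#' @export
gif <- function(ped, members, min_distance = 1, scale = 1e5, pairs = NULL) {
  members <- unique(as.character(members))
  if (length(members) < 2) abort("gif requires at least 2 members")
  if (is.null(pairs)) pairs <- kinship_pairs(ped, members)
  gif_from_distances(pairs$distance, length(members), min_distance, scale)
}

gif_from_distances <- function(distances, n_members, min_distance, scale) {
  n_pairs <- choose(n_members, 2)
  d <- distances[distances >= min_distance]
  scale * sum(2^(-d)) / n_pairs
}

#' Contribution of each genetic distance to the GIF
#'
#' Decomposes the GIF into per-distance terms: at distance `d` the entry is
#' `scale * n_pairs(d) * 2^(-d) / n_all_pairs`. Entries sum to the GIF of the
#' same set. The shape of this curve (e.g. excess at distances >= 4) shows
#' whether clustering is carried by close or by distant relationships.
#'
#' @inheritParams gif
#' @return Tibble with columns `distance`, `n_pairs`, `contribution`.
#' @export
contribution_curve <- function(ped, members, scale = 1e5, pairs = NULL) {
  members <- unique(as.character(members))
  if (length(members) < 2) abort("contribution_curve requires >= 2 members")
  if (is.null(pairs)) pairs <- kinship_pairs(ped, members)
  n_all <- choose(length(members), 2)
  pairs %>%
    count(.data$distance, name = "n_pairs") %>%
    mutate(contribution = scale * .data$n_pairs * 2^(-.data$distance) / n_all) %>%
    arrange(.data$distance)
}

#' Sample control sets matched to cases
#'
#' Draws `n_sets` control sets, each the size of the case set, matched to the
#' cases by birth-year bin, sex, and birthplace. Within a set, controls are
#' drawn without replacement from the non-case candidates of the case's
#' stratum; sets are sampled independently of each other (the same individual
#' may serve in many sets). If a stratum has fewer non-case candidates than
#' cases, the birth-year bin is widened by one bin on each side; if still
#' short, an error names the stratum rather than silently mismatching.
#'
#' @param strata Tibble of candidate individuals with columns `id`, `sex`,
#'   `birth_year`, `birthplace` (typically the phenotype-eligible,
#'   completeness-passing pool).
#' @param cases Character vector of case ids (must be a subset of `strata$id`).
#' @param n_sets Number of control sets.
#' @param seed Integer seed; the draw is deterministic given `seed`.
#' @param bin_width Birth-year bin width in years.
#' @return List of `n_sets` character vectors, each of length `length(cases)`.
#' @export
sample_matched_controls <- function(strata, cases, n_sets = 1000, seed = 1,
                                    bin_width = 5) {
  cases <- unique(as.character(cases))
  if (!all(cases %in% strata$id)) {
    abort("all cases must be present in the candidate strata table")
  }
  strata <- strata %>%
    mutate(
      bin = birth_bin(.data$birth_year, bin_width),
      stratum = paste(.data$bin, .data$sex, .data$birthplace, sep = "/")
    )
  is_case <- strata$id %in% cases
  case_tab <- strata[is_case, ]
  need <- table(case_tab$stratum)

  pool_exact <- split(strata$id[!is_case], strata$stratum[!is_case])
  # relaxation ladder: same sex/birthplace, birth bin +/- one bin
  wide_key <- function(bin, sex, bp) paste(bin, sex, bp, sep = "/")
  pool_wide <- lapply(names(need), function(s) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    bin <- as.numeric(parts[1])
    keys <- wide_key(c(bin - bin_width, bin, bin + bin_width),
                     parts[2], parts[3])
    unique(unlist(pool_exact[keys], use.names = FALSE))
  })
  names(pool_wide) <- names(need)

  short <- names(need)[vapply(names(need), function(s)
    length(pool_wide[[s]]) < need[[s]], logical(1))]
  if (length(short) > 0) {
    abort(paste0(
      "control stratum exhausted even after widening the birth-year bin: ",
      paste(short, collapse = "; ")))
  }

  strata_order <- sort(names(need))
  withr::with_seed(seed, {
    lapply(seq_len(n_sets), function(.s) {
      used <- character(0)
      for (s in strata_order) {
        k <- need[[s]]
        pool <- setdiff(pool_exact[[s]] %||% character(0), used)
        if (length(pool) >= k) {
          pick <- if (length(pool) == k) pool else sample(pool, k)
        } else {
          extra <- setdiff(pool_wide[[s]], c(used, pool))
          if (length(pool) + length(extra) < k) {
            abort(paste0("control stratum exhausted within a set: ", s))
          }
          pick <- c(pool, sample(extra, k - length(pool)))
        }
        used <- c(used, pick)
      }
      used
    })
  })
}

#' Empirical p-value of a case statistic against control statistics
#'
#' The rank-based significance used for the GIF test: the proportion of
#' control statistics at least as large as the case statistic (ties count
#' toward the tail). When no control reaches the case value the display
#' string reports the resolution bound, e.g. `"<0.001"` for 1,000 controls.
#'
#' @param case_stat Observed statistic.
#' @param control_stats Nonempty numeric vector of control statistics.
#' @return List with `p` (numeric in \[0,1\]), `n_ge` (count of controls >=
#'   case), `n` and `display` (string).
#' @export
empirical_p <- function(case_stat, control_stats) {
  if (length(control_stats) == 0) abort("control_stats must be nonempty")
  n <- length(control_stats)
  n_ge <- sum(control_stats >= case_stat)
  p <- n_ge / n
  display <- if (n_ge == 0) {
    paste0("<", format(1 / n, scientific = FALSE, drop0trailing = TRUE))
  } else {
    format(p, digits = 3)
  }
  list(p = p, n_ge = n_ge, n = n, display = display)
}

#' Run the full GIF analysis
#'
#' Selects cases (completeness filter, BMI record, optional age window,
#' `bmi < bmi_threshold`), computes the case GIF and dGIF, samples matched
#' control sets from the phenotyped pool, computes the same statistics for
#' every control set, and reports empirical p-values and the
#' contribution-by-distance curves for cases and (averaged) controls.
#'
#' @param ped A [pedigree()].
#' @param phenotype Phenotype tibble (`id`, `bmi`, `record_year`).
#' @param bmi_threshold Case cut-off (strict `<`).
#' @param age_min,age_max Optional inclusive age window for case selection
#'   (ages at the most recent record).
#' @param n_sets Number of matched control sets.
#' @param seed Integer seed for control sampling.
#' @param dgif_min_distance Smallest genetic distance counted by the dGIF.
#' @param scale GIF display scale.
#' @param bin_width Birth-year bin width used for matching.
#' @return An object of class `fa_gif`: a list with elements `n_cases`,
#'   `case_gif`, `control_gifs`, `gif_p`, `case_dgif`, `control_dgifs`,
#'   `dgif_p`, `curve_case`, `curve_control`, `params`.
#' @export
run_gif_analysis <- function(ped, phenotype, bmi_threshold = 18.5,
                             age_min = NULL, age_max = NULL, n_sets = 1000,
                             seed = 1, dgif_min_distance = 4, scale = 1e5,
                             bin_width = 5) {
  tbl <- build_analysis_table(ped, phenotype, bmi_threshold)
  pool <- tbl %>% filter(.data$phenotyped)
  cases <- select_cases(tbl, age_min, age_max)
  if (length(cases) < 2) {
    abort("GIF analysis requires at least 2 cases after filtering")
  }

  ix <- ped_index(ped)
  anc <- ancestor_dt(ix)
  # all member sets come from the phenotyped pool; shrink the join table once
  pool_idx <- match(pool$id, ped$id)
  anc <- anc[list(id = pool_idx), on = "id", nomatch = NULL]
  setkeyv(anc, "id")
  set_stats <- function(ids) {
    ii <- match(ids, ped$id)
    pr <- kinship_pairs_idx(anc, ii)
    n_all <- choose(length(ids), 2)
    list(
      gif = scale * sum(2^(-pr$distance)) / n_all,
      dgif = scale *
        sum(2^(-pr$distance[pr$distance >= dgif_min_distance])) / n_all,
      curve = tabulate_curve(pr$distance, n_all, scale)
    )
  }

  cs <- set_stats(cases)
  control_sets <- sample_matched_controls(
    pool %>% select("id", "sex", "birth_year", "birthplace"),
    cases, n_sets = n_sets, seed = seed, bin_width = bin_width
  )
  ctl <- lapply(control_sets, set_stats)
  control_gifs <- vapply(ctl, `[[`, numeric(1), "gif")
  control_dgifs <- vapply(ctl, `[[`, numeric(1), "dgif")

  curve_ctl <- dplyr::bind_rows(lapply(ctl, `[[`, "curve")) %>%
    group_by(.data$distance) %>%
    summarise(
      n_pairs = sum(.data$n_pairs) / n_sets,
      contribution = sum(.data$contribution) / n_sets,
      .groups = "drop"
    )

  structure(list(
    n_cases = length(cases),
    cases = cases,
    case_gif = cs$gif,
    control_gifs = control_gifs,
    gif_p = empirical_p(cs$gif, control_gifs),
    case_dgif = cs$dgif,
    control_dgifs = control_dgifs,
    dgif_p = empirical_p(cs$dgif, control_dgifs),
    curve_case = cs$curve,
    curve_control = curve_ctl,
    params = list(
      bmi_threshold = bmi_threshold, age_min = age_min, age_max = age_max,
      n_sets = n_sets, seed = seed, dgif_min_distance = dgif_min_distance,
      scale = scale, bin_width = bin_width
    )
  ), class = "fa_gif")
}

tabulate_curve <- function(distances, n_all, scale) {
  if (length(distances) == 0) {
    return(tibble(distance = integer(0), n_pairs = integer(0),
                  contribution = numeric(0)))
  }
  tb <- table(distances)
  d <- as.integer(names(tb))
  n <- as.integer(tb)
  tibble(distance = d, n_pairs = n,
         contribution = scale * n * 2^(-d) / n_all)
}

#' @export
print.fa_gif <- function(x, ...) {
  cat("GIF analysis\n")
  cat(sprintf("  cases: %d, control sets: %d\n",
              x$n_cases, length(x$control_gifs)))
  cat(sprintf("  case GIF  %.2f  (mean control %.2f)  empirical p %s\n",
              x$case_gif, mean(x$control_gifs), x$gif_p$display))
  cat(sprintf("  case dGIF %.2f  (mean control %.2f)  empirical p %s\n",
              x$case_dgif, mean(x$control_dgifs), x$dgif_p$display))
  invisible(x)
}

#' Tidiers for GIF results
#'
#' `tidy()` returns one row per statistic (GIF, dGIF) with the case value,
#' mean control value and empirical p-value; `glance()` returns a one-row
#' summary.
#'
#' @param x An `fa_gif` object.
#' @param ... Unused.
#' @export
tidy.fa_gif <- function(x, ...) {
  tibble(
    statistic = c("gif", "dgif"),
    case = c(x$case_gif, x$case_dgif),
    control_mean = c(mean(x$control_gifs), mean(x$control_dgifs)),
    p_empirical = c(x$gif_p$p, x$dgif_p$p),
    p_display = c(x$gif_p$display, x$dgif_p$display)
  )
}

#' @rdname tidy.fa_gif
#' @export
glance.fa_gif <- function(x, ...) {
  tibble(
    n_cases = x$n_cases,
    n_control_sets = length(x$control_gifs),
    case_gif = x$case_gif,
    control_gif = mean(x$control_gifs),
    gif_p = x$gif_p$p,
    case_dgif = x$case_dgif,
    control_dgif = mean(x$control_dgifs),
    dgif_p = x$dgif_p$p
  )
}

#' Plot the contribution-by-distance curves
#'
#' Case curve against the mean matched-control curve, by genetic distance.
#'
#' @param object An `fa_gif` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fa_gif <- function(object, ...) {
  df <- dplyr::bind_rows(
    object$curve_case %>% mutate(group = "cases"),
    object$curve_control %>% mutate(group = "controls (mean)")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$distance, .data$contribution,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "genetic distance",
                  y = "contribution to GIF",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
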