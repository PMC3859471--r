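# High-risk pedigree discovery: founder-anchored case clusters and the
# observed-vs-expected excess test on each founder descendancy.

# Anchors for clusters: founding couples (both spouses founders, sharing at
# least one child) by default, or single founders. Each anchor is a set of
# one or two founder ids; the descendancy is the union of both spouses'.
cluster_anchors <- function(ped, anchor = c("couple", "founder")) {
  anchor <- match.arg(anchor)
  fnd <- founders(ped)
  if (anchor == "founder") {
    out <- lapply(fnd, identity)
  } else {
    kids <- ped %>%
      as_tibble() %>%
      filter(!is.na(.data$father_id), !is.na(.data$mother_id),
             .data$father_id %in% fnd, .data$mother_id %in% fnd) %>%
      distinct(.data$father_id, .data$mother_id)
    couples <- purrr::map2(kids$father_id, kids$mother_id, c)
    paired <- unique(unlist(couples))
    singles <- lapply(setdiff(fnd, paired), identity)
    out <- c(couples, singles)
  }
  names(out) <- vapply(out, paste, character(1), collapse = "+")
  out[order(names(out))]
}

# One-pass descendant lookup: which of `candidate_ids` descend from any
# member of each anchor. Inverts the ancestor-depth table instead of running
# one BFS per anchor.
anchor_descendant_sets <- function(ped, anchors, candidate_ids) {
  ix <- ped_index(ped)
  adt <- ancestor_dt(ix)
  cand_idx <- match(candidate_ids, ped$id)
  f_idx <- match(unique(unlist(anchors)), ped$id)
  keep <- adt[["id"]] %in% cand_idx & adt[["anc"]] %in% f_idx & adt[["m"]] > 0
  sub <- adt[keep]
  by_f <- split(ped$id[sub[["id"]]], ped$id[sub[["anc"]]])
  lapply(anchors, function(a) {
    sort(unique(unlist(by_f[a], use.names = FALSE)))
  })
}

#' Founder-anchored clusters of related cases
#'
#' For every founding couple (or single founder), the set of cases descending
#' from it. Clusters of fewer than two cases are dropped, and any cluster
#' whose case set is a subset of another retained cluster's is removed, so no
#' cluster is a subset of any other while individuals may still belong to
#' several clusters.
#'
#' @param ped A [pedigree()].
#' @param cases Character vector of case ids.
#' @param anchor `"couple"` (default) anchors clusters at founding pairs,
#'   `"founder"` at single founders.
#' @return Tibble with columns `anchor` (label), `founder_ids` (list),
#'   `members` (list of case ids), `size`; ordered by anchor label.
#' @export
find_case_clusters <- function(ped, cases, anchor = c("couple", "founder")) {
  anchors <- cluster_anchors(ped, anchor)
  cases <- unique(as.character(cases))
  member_sets <- anchor_descendant_sets(ped, anchors, cases)
  keep <- lengths(member_sets) >= 2
  anchors <- anchors[keep]
  member_sets <- member_sets[keep]
  # maximality: drop clusters whose member set is contained in another's
  n <- length(member_sets)
  if (n > 1) {
    key <- vapply(member_sets, paste, character(1), collapse = "|")
    is_sub <- rep(FALSE, n)
    sizes <- lengths(member_sets)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && !is_sub[i] &&
            (sizes[i] < sizes[j] || (sizes[i] == sizes[j] && key[i] == key[j] && i > j)) &&
            all(member_sets[[i]] %in% member_sets[[j]])) {
          is_sub[i] <- TRUE
        }
      }
    }
    anchors <- anchors[!is_sub]
    member_sets <- member_sets[!is_sub]
  }
  tibble(
    anchor = names(anchors),
    founder_ids = unname(anchors),
    members = unname(member_sets),
    size = unname(lengths(member_sets))
  )
}

#' Excess-case test on a founder descendancy
#'
#' Compares the observed number of cases among the phenotyped descendants of
#' a founder (or founding couple) with the number expected under the internal
#' cohort-specific rates; significance is the one-sided Poisson upper tail
#' `P(X >= observed)` at mean `expected`.
#'
#' @param ped A [pedigree()].
#' @param founder_ids One or two founder ids anchoring the descendancy.
#' @param tbl Analysis table from [build_analysis_table()].
#' @param cohorts Output of [assign_cohorts()] on `tbl` (computed if `NULL`).
#' @return One-row tibble: `anchor`, `n_descendants_phenotyped`, `observed`,
#'   `expected`, `p_excess`. With zero phenotyped descendants the test is
#'   undefined: `expected = 0`, `p_excess = NA`.
#' @export
descendant_excess_test <- function(ped, founder_ids, tbl, cohorts = NULL) {
  if (is.null(cohorts)) cohorts <- assign_cohorts(tbl)
  ix <- ped_index(ped)
  ai <- match(founder_ids, ped$id)
  if (anyNA(ai)) abort("unknown founder ids")
  desc <- ped$id[descendants_idx(ix, ai)]
  ph <- tbl %>% filter(.data$phenotyped, .data$id %in% desc)
  observed <- sum(ph$is_case)
  n_ph <- nrow(ph)
  expected <- if (n_ph > 0) expected_cases(ph$id, cohorts) else 0
  p <- if (n_ph == 0 || expected <= 0) {
    NA_real_
  } else {
    ppois(observed - 1, expected, lower.tail = FALSE)
  }
  tibble(
    anchor = paste(founder_ids, collapse = "+"),
    n_descendants_phenotyped = n_ph,
    observed = observed,
    expected = expected,
    p_excess = p
  )
}

#' Scan all founder descendancies for an excess of cases
#'
#' Finds the maximal founder-anchored case clusters, then applies the
#' [descendant_excess_test()] to each retained cluster's descendancy. Case
#' clusters are typically built from an age-restricted case set while the
#' excess test counts every case among the phenotyped descendants.
#'
#' @param ped A [pedigree()].
#' @param tbl Analysis table from [build_analysis_table()].
#' @param cases Case ids used to form clusters (e.g. the age-windowed cases);
#'   defaults to all cases in `tbl`.
#' @param anchor Passed to [find_case_clusters()].
#' @param bin_width Cohort bin width for expected counts.
#' @return Tibble of class `fa_scan`, one row per retained cluster: the
#'   cluster columns plus the excess-test columns, sorted by `p_excess`.
#' @export
scan_pedigrees <- function(ped, tbl, cases = NULL,
                           anchor = c("couple", "founder"), bin_width = 5) {
  if (is.null(cases)) cases <- tbl$id[tbl$is_case]
  clusters <- find_case_clusters(ped, cases, anchor)
  cohorts <- assign_cohorts(tbl, bin_width)
  ph <- tbl %>%
    filter(.data$phenotyped) %>%
    select("id", "is_case") %>%
    inner_join(cohorts$members, by = "id") %>%
    inner_join(cohorts$rates %>% select("cohort", "rate"), by = "cohort")
  dsets <- anchor_descendant_sets(ped, setNames(clusters$founder_ids,
                                                clusters$anchor), ph$id)
  long <- tibble(
    anchor = rep(clusters$anchor, lengths(dsets)),
    id = unlist(dsets, use.names = FALSE)
  ) %>%
    inner_join(ph, by = "id")
  tests <- long %>%
    group_by(.data$anchor) %>%
    summarise(
      n_descendants_phenotyped = dplyr::n(),
      observed = sum(.data$is_case),
      expected = sum(.data$rate),
      .groups = "drop"
    ) %>%
    mutate(p_excess = ifelse(
      .data$expected > 0,
      ppois(.data$observed - 1, .data$expected, lower.tail = FALSE),
      NA_real_
    ))
  out <- clusters %>%
    select("anchor", "founder_ids", "members", "size") %>%
    left_join(tests, by = "anchor") %>%
    mutate(
      n_descendants_phenotyped = dplyr::coalesce(.data$n_descendants_phenotyped, 0L),
      observed = dplyr::coalesce(.data$observed, 0L),
      expected = dplyr::coalesce(.data$expected, 0)
    ) %>%
    arrange(.data$p_excess, .data$anchor)
  class(out) <- c("fa_scan", class(out))
  out
}

#' Select high-risk pedigrees
#'
#' Filters a scan to descendancies with a significant excess (`p_excess <
#' alpha`) and at least `min_cases` observed cases, sorted by `p_excess`.
#'
#' @param scan An `fa_scan` tibble from [scan_pedigrees()].
#' @param alpha Significance threshold.
#' @param min_cases Minimum observed case count.
#' @return The filtered `fa_scan` tibble.
#' @export
select_high_risk <- function(scan, alpha = 1e-4, min_cases = 10) {
  scan %>%
    filter(!is.na(.data$p_excess), .data$p_excess < alpha,
           .data$observed >= min_cases) %>%
    arrange(.data$p_excess)
}

#' @export
print.fa_scan <- function(x, ...) {
  cat("Founder-descendancy excess-case scan\n")
  NextMethod()
}

#' Tidiers for pedigree scans
#'
#' `tidy()` drops the list columns; `glance()` summarises cluster counts and
#' sizes.
#'
#' @param x An `fa_scan` object.
#' @param ... Unused.
#' @export
tidy.fa_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "fa_scan")
  out <- as_tibble(out)
  out[, !vapply(out, is.list, logical(1))]
}

#' @rdname tidy.fa_scan
#' @export
glance.fa_scan <- function(x, ...) {
  tibble(
    n_clusters = nrow(x),
    min_size = if (nrow(x)) min(x$size) else NA_integer_,
    max_size = if (nrow(x)) max(x$size) else NA_integer_,
    n_significant = sum(x$p_excess < 1e-4, na.rm = TRUE)
  )
}

#' Plot a pedigree scan
#'
#' Observed vs expected case counts per founder descendancy, coloured by
#' excess significance.
#'
#' @param object An `fa_scan` object.
#' @param alpha Threshold used for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fa_scan <- function(object, alpha = 1e-4, ...) {
  df <- tidy(object) %>%
    mutate(significant = !is.na(.data$p_excess) & .data$p_excess < alpha)
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed,
                                   colour = .data$significant)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "expected cases", y = "observed cases",
                  colour = paste0("p < ", format(alpha))) +
    ggplot2::theme_minimal()
}
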