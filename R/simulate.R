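# Liability-threshold genealogy simulator: deep founder-descendant
# genealogies with a familially correlated binary phenotype and
# recent-generations-only (driver's-license-style) ascertainment.

#' Default age-specific target prevalence map
#'
#' U-shaped age profile for the low-BMI phenotype: high in adolescence,
#' falling through midlife, rising again in old age. The default values are
#' the age-specific rates observed in the study population (0.4-11%).
#'
#' @return Tibble with columns `age_low`, `age_high`, `prevalence`.
#' @export
default_prevalence_map <- function() {
  tibble(
    age_low = c(seq(15, 80, by = 5)),
    age_high = c(seq(19, 79, by = 5), 120),
    prevalence = c(0.110, 0.046, 0.025, 0.019, 0.014, 0.011, 0.008,
                   0.006, 0.004, 0.005, 0.007, 0.010, 0.014, 0.021)
  )
}

#' Simulation configuration
#'
#' Parameters of the genealogy/phenotype simulator. The liability of an
#' individual is `L = A + C + E` with additive-genetic variance `h2`
#' (midparent transmission), shared-sibship environment variance `c2`, and
#' residual `1 - h2 - c2`, so `L` is standard normal marginally; the case
#' threshold is set per age bin so the realised prevalence matches
#' `prevalence_by_age`. BMI is emitted as a decreasing linear transform of
#' liability anchored so `bmi < 18.5` exactly when the liability exceeds the
#' threshold.
#'
#' @param n_founder_couples Founder couples in generation 1.
#' @param n_generations Total generations (>= 3 so the completeness filter
#'   can pass).
#' @param mean_children Mean children per couple (Poisson).
#' @param immigrant_spouse_fraction Probability that an individual marries a
#'   founder-by-marriage with no recorded parents (born out of state).
#' @param generation_span Years between generation birth-year bases; birth
#'   years get uniform jitter within the span.
#' @param start_year Birth-year base of generation 1.
#' @param p_utah_birth Probability an in-genealogy birth is flagged in-state.
#' @param h2 Additive-genetic (narrow-sense) liability variance share.
#' @param c2 Shared-sibship environment liability variance share.
#' @param prevalence_by_age Target prevalence per age bin (tibble `age_low`,
#'   `age_high`, `prevalence`).
#' @param phenotyped_generations Number of most recent generations carrying
#'   BMI records (ascertainment); earlier generations stay in the genealogy
#'   unphenotyped.
#' @param reference_year Year of the BMI records; default places the youngest
#'   generation at ages 15 to `15 + generation_span`.
#' @param duplicate_record_fraction Fraction of phenotyped individuals given
#'   an additional, older BMI record (exercises the most-recent-record rule).
#' @param bmi_slope BMI units per liability unit in the emitted transform.
#' @return A list of class `fa_sim_config`.
#' @export
sim_config <- function(n_founder_couples = 100,
                       n_generations = 6,
                       mean_children = 3,
                       immigrant_spouse_fraction = 0.2,
                       generation_span = 25,
                       start_year = 1820,
                       p_utah_birth = 0.9,
                       h2 = 0.6,
                       c2 = 0.1,
                       prevalence_by_age = default_prevalence_map(),
                       phenotyped_generations = 3,
                       reference_year = NULL,
                       duplicate_record_fraction = 0,
                       bmi_slope = 3.8) {
  stopifnot(
    n_founder_couples >= 1, n_generations >= 3, mean_children > 0,
    generation_span > 0, bmi_slope > 0,
    phenotyped_generations >= 1, phenotyped_generations <= n_generations
  )
  for (p in c(immigrant_spouse_fraction, p_utah_birth, h2, c2)) {
    if (p < 0 || p > 1) abort("probabilities and variance shares must be in [0, 1]")
  }
  if (h2 + c2 > 1) abort("h2 + c2 must not exceed 1")
  if (any(prevalence_by_age$prevalence <= 0) ||
      any(prevalence_by_age$prevalence >= 1)) {
    abort("target prevalences must be in (0, 1)")
  }
  if (is.null(reference_year)) {
    reference_year <- start_year + n_generations * generation_span + 15
  }
  structure(list(
    n_founder_couples = n_founder_couples,
    n_generations = n_generations,
    mean_children = mean_children,
    immigrant_spouse_fraction = immigrant_spouse_fraction,
    generation_span = generation_span,
    start_year = start_year,
    p_utah_birth = p_utah_birth,
    h2 = h2, c2 = c2,
    prevalence_by_age = prevalence_by_age,
    phenotyped_generations = phenotyped_generations,
    reference_year = reference_year,
    duplicate_record_fraction = duplicate_record_fraction,
    bmi_slope = bmi_slope
  ), class = "fa_sim_config")
}

#' Simulate a founder-descendant genealogy
#'
#' Generation-structured population: founder couples in generation 1;
#' within-generation mating (full-sibling marriages excluded) plus
#' immigrant spouses (founders-by-marriage with no recorded parents, born out
#' of state); children per couple Poisson-distributed; sex a fair coin; birth
#' years are the generation base plus uniform jitter. Deterministic given
#' `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A [pedigree()] with an extra `generation` column.
#' @export
simulate_genealogy <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "fa_sim_config"))
  withr::with_seed(seed, simulate_genealogy_impl(cfg))
}

simulate_genealogy_impl <- function(cfg) {
  span <- cfg$generation_span
  gen_base <- function(g) cfg$start_year + (g - 1) * span
  rows <- list()
  counter <- 0L
  new_ids <- function(k) {
    out <- sprintf("I%06d", counter + seq_len(k))
    counter <<- counter + k
    out
  }
  add <- function(id, father, mother, sex, by, bp, gen) {
    rows[[length(rows) + 1L]] <<- tibble(
      id = id, father_id = father, mother_id = mother, sex = sex,
      birth_year = as.integer(by), birthplace = bp, generation = gen
    )
  }

  nf <- cfg$n_founder_couples
  fa_ids <- new_ids(nf)
  mo_ids <- new_ids(nf)
  add(fa_ids, NA_character_, NA_character_, "male",
      floor(gen_base(1) + runif(nf, 0, span)),
      ifelse(runif(nf) < cfg$p_utah_birth, "in_state", "out_of_state"), 1L)
  add(mo_ids, NA_character_, NA_character_, "female",
      floor(gen_base(1) + runif(nf, 0, span)),
      ifelse(runif(nf) < cfg$p_utah_birth, "in_state", "out_of_state"), 1L)
  couples <- list(father = fa_ids, mother = mo_ids)
  # parent lookup for the sib-marriage check
  par_of <- c(
    setNames(rep(NA_character_, 2 * nf), c(fa_ids, mo_ids))
  )
  couple_key <- setNames(rep(NA_character_, 2 * nf), c(fa_ids, mo_ids))

  for (g in seq_len(cfg$n_generations - 1)) {
    # children of generation-g couples
    kids <- NULL
    for (try in seq_len(20)) {
      nk <- rpois(length(couples$father), cfg$mean_children)
      if (sum(nk) > 0) break
    }
    if (sum(nk) == 0) abort("lineage went extinct; increase mean_children")
    kid_fa <- rep(couples$father, nk)
    kid_mo <- rep(couples$mother, nk)
    k <- length(kid_fa)
    kid_id <- new_ids(k)
    kid_sex <- ifelse(runif(k) < 0.5, "male", "female")
    add(kid_id, kid_fa, kid_mo, kid_sex,
        floor(gen_base(g + 1) + runif(k, 0, span)),
        ifelse(runif(k) < cfg$p_utah_birth, "in_state", "out_of_state"),
        g + 1L)
    couple_key[kid_id] <- paste(kid_fa, kid_mo)
    if (g + 1 == cfg$n_generations) break

    # marriages within generation g + 1
    imm <- runif(k) < cfg$immigrant_spouse_fraction
    fathers <- character(0)
    mothers <- character(0)
    if (any(imm)) {
      imm_id <- new_ids(sum(imm))
      imm_sex <- ifelse(kid_sex[imm] == "male", "female", "male")
      add(imm_id, NA_character_, NA_character_, imm_sex,
          floor(gen_base(g + 1) + runif(sum(imm), 0, span)),
          "out_of_state", g + 1L)
      couple_key[imm_id] <- NA_character_
      fathers <- ifelse(kid_sex[imm] == "male", kid_id[imm], imm_id)
      mothers <- ifelse(kid_sex[imm] == "male", imm_id, kid_id[imm])
    }

    pool_m <- sample(kid_id[!imm & kid_sex == "male"])
    pool_f <- sample(kid_id[!imm & kid_sex == "female"])
    np <- min(length(pool_m), length(pool_f))
    pool_m <- pool_m[seq_len(np)]
    pool_f <- pool_f[seq_len(np)]
    if (np > 0) {
      # repair full-sibling pairings by swapping partners
      sib <- function(a, b) {
        !is.na(couple_key[a]) & !is.na(couple_key[b]) &
          couple_key[a] == couple_key[b]
      }
      drop <- rep(FALSE, np)
      for (i in seq_len(np)) {
        if (sib(pool_m[i], pool_f[i])) {
          j <- which(!sib(pool_m[i], pool_f) & !sib(pool_m, pool_f[i]) &
                       seq_len(np) != i & !drop)
          if (length(j) > 0) {
            j <- j[1]
            tmp <- pool_f[i]
            pool_f[i] <- pool_f[j]
            pool_f[j] <- tmp
          } else {
            drop[i] <- TRUE
          }
        }
      }
      fathers <- c(fathers, pool_m[!drop])
      mothers <- c(mothers, pool_f[!drop])
    }
    couples <- list(father = fathers, mother = mothers)
  }

  pedigree(dplyr::bind_rows(rows))
}

#' Simulate liabilities and BMI phenotypes on a genealogy
#'
#' Additive-genetic liability is transmitted as the midparent mean plus a
#' segregation deviation of variance `h2/2` (founders and immigrants draw
#' `N(0, h2)`); a sibship-shared environmental component of variance `c2` is
#' drawn per parental couple; the residual makes the liability standard
#' normal. The case threshold is the normal quantile of the age-bin target
#' prevalence, and the emitted BMI is `18.5 - bmi_slope * (L - threshold)`,
#' so `bmi < 18.5` if and only if the liability crosses the threshold.
#'
#' @param ped A genealogy from [simulate_genealogy()] (needs `generation`).
#' @param cfg The [sim_config()] used to build it.
#' @param seed Integer seed.
#' @return Tibble with one row per individual: `id`, `bmi`, `record_year`,
#'   plus audit columns `liability`, `genetic`, `shared`, `threshold`,
#'   `case_true`, `age`.
#' @export
simulate_phenotypes <- function(ped, cfg, seed = 1) {
  stopifnot(inherits(cfg, "fa_sim_config"))
  withr::with_seed(seed, simulate_phenotypes_impl(ped, cfg))
}

simulate_phenotypes_impl <- function(ped, cfg) {
  ix <- ped_index(ped)
  n <- ix$n
  h2 <- cfg$h2
  c2 <- cfg$c2
  # additive values, vectorised level by level (parents before children)
  depth <- integer(n)
  for (i in ix$order) {
    f <- ix$fa[i]
    mth <- ix$mo[i]
    depth[i] <- max(if (is.na(f)) 0L else depth[f] + 1L,
                    if (is.na(mth)) 0L else depth[mth] + 1L)
  }
  has_par <- !is.na(ix$fa) & !is.na(ix$mo)
  a <- numeric(n)
  a[!has_par] <- rnorm(sum(!has_par), 0, sqrt(h2))
  for (lev in sort(unique(depth[has_par]))) {
    k <- which(has_par & depth == lev)
    a[k] <- (a[ix$fa[k]] + a[ix$mo[k]]) / 2 + rnorm(length(k), 0, sqrt(h2 / 2))
  }
  sibship <- ifelse(is.na(ped$father_id) | is.na(ped$mother_id),
                    paste0("self:", ped$id),
                    paste(ped$father_id, ped$mother_id))
  sib_groups <- unique(sibship)
  c_draw <- setNames(rnorm(length(sib_groups), 0, sqrt(c2)), sib_groups)
  cshared <- unname(c_draw[sibship])
  e <- rnorm(n, 0, sqrt(1 - h2 - c2))
  liab <- a + cshared + e

  age <- cfg$reference_year - ped$birth_year
  thr <- age_thresholds(age, cfg$prevalence_by_age)
  bmi <- 18.5 - cfg$bmi_slope * (liab - thr)
  out <- tibble(
    id = ped$id,
    bmi = bmi,
    record_year = as.integer(cfg$reference_year),
    liability = liab,
    genetic = a,
    shared = cshared,
    threshold = thr,
    case_true = liab > thr,
    age = age
  )
  if (cfg$duplicate_record_fraction > 0) {
    pick <- runif(n) < cfg$duplicate_record_fraction
    extra <- out[pick, ] %>%
      mutate(
        record_year = .data$record_year - sample(3:15, sum(pick), replace = TRUE),
        bmi = .data$bmi + rnorm(sum(pick), 0, 1.5)
      )
    out <- dplyr::bind_rows(out, extra) %>% arrange(.data$id)
  }
  out
}

# Per-individual liability threshold from the age-bin target prevalence;
# ages outside the map clamp to the nearest bin.
age_thresholds <- function(age, prev_map) {
  age <- pmin(pmax(age, min(prev_map$age_low)), max(prev_map$age_high))
  bin <- findInterval(age, prev_map$age_low)
  qnorm(1 - prev_map$prevalence[bin])
}

#' Restrict phenotypes to the most recent generations
#'
#' Driver's-license-style ascertainment: BMI records are retained only for
#' individuals in the last `phenotyped_generations` generations; earlier
#' individuals stay in the genealogy and contribute relatedness paths but
#' carry no phenotype.
#'
#' @param ped Genealogy with a `generation` column.
#' @param phenotype Phenotype tibble from [simulate_phenotypes()].
#' @param cfg The [sim_config()].
#' @return The filtered phenotype tibble.
#' @export
apply_ascertainment <- function(ped, phenotype, cfg) {
  cutoff <- cfg$n_generations - cfg$phenotyped_generations
  keep <- ped$id[ped$generation > cutoff]
  phenotype %>% filter(.data$id %in% keep)
}

#' Simulate a complete study population
#'
#' Composes [simulate_genealogy()], [simulate_phenotypes()] and
#' [apply_ascertainment()].
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (the genealogy uses `seed`, phenotypes
#'   `seed + 1`).
#' @return List of class `fa_simpop`: `pedigree`, `phenotype` (ascertained,
#'   columns `id`, `bmi`, `record_year`), and `truth` (full audit table with
#'   liabilities).
#' @export
simulate_population <- function(cfg = sim_config(), seed = 1) {
  ped <- simulate_genealogy(cfg, seed)
  truth <- simulate_phenotypes(ped, cfg, seed + 1)
  pheno <- apply_ascertainment(ped, truth, cfg) %>%
    select("id", "bmi", "record_year")
  structure(list(pedigree = ped, phenotype = pheno, truth = truth,
                 config = cfg, seed = seed),
            class = "fa_simpop")
}

#' @export
print.fa_simpop <- function(x, ...) {
  cat(sprintf(
    "Simulated population: %d individuals, %d generations, %d phenotype records\n",
    nrow(x$pedigree), max(x$pedigree$generation), nrow(x$phenotype)))
  invisible(x)
}
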