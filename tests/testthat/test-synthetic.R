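test_that("simulator is deterministic and generation-structured", {
  cfg <- sim_config(n_founder_couples = 15, n_generations = 3,
                    mean_children = 2)
  p1 <- simulate_genealogy(cfg, seed = 9)
  p2 <- simulate_genealogy(cfg, seed = 9)
  expect_identical(as_tibble(p1), as_tibble(p2))
  p3 <- simulate_genealogy(cfg, seed = 10)
  expect_false(identical(as_tibble(p1), as_tibble(p3)))

  # construction guarantees: gen-3 individuals have known parents and
  # grandparents
  g3 <- p1[p1$generation == 3, ]
  expect_true(all(!is.na(g3$father_id) & !is.na(g3$mother_id)))
  fa <- p1[match(g3$father_id, p1$id), ]
  expect_true(all(fa$generation == 2 | is.na(fa$father_id)))

  # populations are whole: sexes of parents respected by pedigree()
  expect_s3_class(p1, "fa_pedigree")

  # with no immigrant spouses, all founders sit in generation 1
  cfg0 <- sim_config(n_founder_couples = 15, n_generations = 4,
                     immigrant_spouse_fraction = 0)
  p0 <- simulate_genealogy(cfg0, seed = 2)
  expect_true(all(p0$generation[match(founders(p0), p0$id)] == 1))

  expect_error(sim_config(h2 = 0.7, c2 = 0.5), "h2 \\+ c2")
})

test_that("liability model calibrates marginal prevalence to the target", {
  flat <- tibble::tibble(age_low = 15, age_high = 120, prevalence = 0.02)
  cfg <- sim_config(n_founder_couples = 120, n_generations = 5,
                    h2 = 0.4, c2 = 0.2, prevalence_by_age = flat,
                    phenotyped_generations = 5)
  pop <- simulate_population(cfg, seed = 61)
  truth <- pop$truth
  n <- nrow(truth)
  p_hat <- mean(truth$case_true)
  expect_equal(p_hat, 0.02, tolerance = 4 * sqrt(0.02 * 0.98 / n) / 0.02)
  # BMI transform is anchored at the threshold: case <=> bmi < 18.5
  expect_identical(truth$bmi < 18.5, truth$case_true)
})

test_that("familial liability correlations match the additive decomposition", {
  # generation-2 offspring have mutually unrelated founder parents, so the
  # textbook expectations r_sib = h2/2 + c2 and r_po = h2/2 hold exactly
  # (deeper generations add consanguinity from cousin marriages)
  cfg <- sim_config(n_founder_couples = 800, n_generations = 3,
                    h2 = 0.6, c2 = 0.1, phenotyped_generations = 3)
  pop <- simulate_population(cfg, seed = 77)
  ped <- pop$pedigree
  liab <- stats::setNames(pop$truth$liability, pop$truth$id)

  kids <- ped[ped$generation == 2 & !is.na(ped$father_id), ]
  fam <- split(kids$id, paste(kids$father_id, kids$mother_id))
  sib_pairs <- do.call(rbind, lapply(fam[lengths(fam) > 1], function(s)
    t(utils::combn(s, 2))))
  r_sib <- stats::cor(liab[sib_pairs[, 1]], liab[sib_pairs[, 2]])
  expect_lt(abs(r_sib - (cfg$h2 / 2 + cfg$c2)), 0.05)

  r_po <- stats::cor(liab[kids$id], liab[kids$father_id])
  expect_lt(abs(r_po - cfg$h2 / 2), 0.05)

  # first cousins: r = h2/8 (distance-4 same-generation pairs)
  cfg4 <- sim_config(n_founder_couples = 250, n_generations = 4,
                     h2 = 0.6, c2 = 0.1, phenotyped_generations = 4)
  pop4 <- simulate_population(cfg4, seed = 79)
  g3 <- pop4$pedigree$id[pop4$pedigree$generation == 3]
  kp <- kinship_pairs(pop4$pedigree, g3)
  cz <- kp[kp$distance == 4, ]
  liab4 <- stats::setNames(pop4$truth$liability, pop4$truth$id)
  r_cousin <- stats::cor(liab4[cz$id_a], liab4[cz$id_b])
  expect_lt(abs(r_cousin - cfg4$h2 / 8), 0.06)
  expect_lt(r_cousin, r_sib)

  # independence when h2 = c2 = 0
  cfg0 <- sim_config(n_founder_couples = 800, n_generations = 3,
                     h2 = 0, c2 = 0, phenotyped_generations = 3)
  pop0 <- simulate_population(cfg0, seed = 78)
  liab0 <- stats::setNames(pop0$truth$liability, pop0$truth$id)
  kids0 <- pop0$pedigree[pop0$pedigree$generation == 2 &
                           !is.na(pop0$pedigree$father_id), ]
  fam0 <- split(kids0$id, paste(kids0$father_id, kids0$mother_id))
  sp0 <- do.call(rbind, lapply(fam0[lengths(fam0) > 1], function(s)
    t(utils::combn(s, 2))))
  r0 <- stats::cor(liab0[sp0[, 1]], liab0[sp0[, 2]])
  expect_lt(abs(r0), 4 / sqrt(nrow(sp0)))
})

test_that("ascertainment keeps phenotypes only in recent generations", {
  cfg <- sim_config(n_founder_couples = 20, n_generations = 5,
                    phenotyped_generations = 2)
  pop <- simulate_population(cfg, seed = 19)
  gens <- pop$pedigree$generation[match(pop$phenotype$id, pop$pedigree$id)]
  expect_true(all(gens > 3))
  # ancestors remain in the genealogy and still carry relatedness paths
  unphen <- setdiff(pop$pedigree$id, pop$phenotype$id)
  expect_gt(length(unphen), 0)
  two <- pop$phenotype$id[1:2]
  d_asc <- genetic_distance(pop$pedigree, two[1], two[2])
  # phenotyping everyone changes member sets but not pair relatedness
  cfg_all <- sim_config(n_founder_couples = 20, n_generations = 5,
                        phenotyped_generations = 5)
  pop_all <- simulate_population(cfg_all, seed = 19)
  expect_identical(as_tibble(pop_all$pedigree), as_tibble(pop$pedigree))
  expect_equal(genetic_distance(pop_all$pedigree, two[1], two[2]), d_asc)
  expect_equal(nrow(pop_all$phenotype), nrow(pop_all$pedigree))
})

test_that("duplicate-record mode exercises the most-recent-record rule", {
  cfg <- sim_config(n_founder_couples = 25, n_generations = 4,
                    duplicate_record_fraction = 0.5)
  pop <- simulate_population(cfg, seed = 33)
  expect_gt(nrow(pop$phenotype), length(unique(pop$phenotype$id)))
  tbl <- build_analysis_table(pop$pedigree, pop$phenotype)
  # resolution keeps the latest record for every duplicated id
  dup_id <- pop$phenotype$id[duplicated(pop$phenotype$id)][1]
  recs <- pop$phenotype[pop$phenotype$id == dup_id, ]
  expect_equal(tbl$record_year[tbl$id == dup_id], max(recs$record_year))
})
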