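test_that("pedigree validation catches structural errors", {
  base <- nuclear_family()
  expect_s3_class(base, "fa_pedigree")

  bad <- tibble::tibble(
    id = c("a", "b"), father_id = c("b", "a"), mother_id = c(NA, NA),
    sex = "male", birth_year = 1900, birthplace = "in_state"
  )
  expect_error(pedigree(bad), "cycle")

  expect_error(pedigree(dplyr::bind_rows(
    ped_row("a"), ped_row("b", fa = "zz")
  )), "unknown father_id")

  expect_error(pedigree(dplyr::bind_rows(
    ped_row("a", sex = "female", by = 1900),
    ped_row("b", fa = "a")
  )), "father is not male")

  expect_error(pedigree(dplyr::bind_rows(ped_row("a"), ped_row("a"))),
               "duplicated")
})

test_that("completeness filter applies the parents/grandparents/great-grandparents rule", {
  # all 8 great-grandparents known
  expect_true("x" %in% complete_ids(ancestry_pedigree(0)))
  # exactly 6 of 8 known: still included
  expect_true("x" %in% complete_ids(ancestry_pedigree(2)))
  # only 5 of 8: excluded
  expect_false("x" %in% complete_ids(ancestry_pedigree(3)))
  # founders and shallow ancestors are excluded
  ped <- ancestry_pedigree(0)
  expect_setequal(complete_ids(ped), "x")
  expect_false(any(founders(ped) %in% complete_ids(ped)))
  expect_identical(filter_complete(ped)$id, "x")
})

test_that("genetic distance matches the meiotic-path definition", {
  ped <- cousin_pedigree()
  expect_equal(genetic_distance(ped, "gf", "s1"), 1) # parent/offspring
  expect_equal(genetic_distance(ped, "s1", "s2"), 2) # full siblings
  expect_equal(genetic_distance(ped, "s1", "c2"), 3) # avuncular
  expect_equal(genetic_distance(ped, "c1", "c2"), 4) # first cousins
  expect_equal(genetic_distance(ped, "w1", "w2"), Inf) # disjoint founders
  expect_equal(genetic_distance(ped, "gf", "c1"), 2) # grandparent
  expect_error(genetic_distance(ped, "gf", "nope"), "unknown ids")
  expect_error(genetic_distance(ped, "gf", "gf"), "self")
})

test_that("relatedness coefficients reproduce the standard kinship ladder", {
  ped <- cousin_pedigree()
  expect_identical(relatedness_coefficient(ped, "gf", "s1"), 0.5)
  expect_identical(relatedness_coefficient(ped, "s1", "s2"), 0.25)
  expect_identical(relatedness_coefficient(ped, "s1", "c2"), 0.125)
  expect_identical(relatedness_coefficient(ped, "c1", "c2"), 0.0625)
  expect_identical(relatedness_coefficient(ped, "w1", "w2"), 0)
})

test_that("degree of relationship follows the relation-graph shortest path", {
  ped <- cousin_pedigree()
  expect_equal(degree_of_relationship(ped, "s1", "c1"), 1)
  expect_equal(degree_of_relationship(ped, "gm", "c1"), 2) # grandmother
  expect_equal(degree_of_relationship(ped, "s1", "c2"), 2) # uncle
  expect_equal(degree_of_relationship(ped, "c1", "c2"), 3) # first cousin

  # half-siblings (one shared parent) classify as second degree because the
  # sibling edge requires both parents shared
  half <- pedigree(dplyr::bind_rows(
    ped_row("f", sex = "male", by = 1900),
    ped_row("m1", sex = "female", by = 1901),
    ped_row("m2", sex = "female", by = 1903),
    ped_row("h1", "f", "m1", "male", 1930),
    ped_row("h2", "f", "m2", "female", 1931)
  ))
  expect_equal(degree_of_relationship(half, "h1", "h2"), 2)
  expect_equal(bf_degree(half, "h1", "h2"), 2)

  # great-grandchild is third degree
  chain <- pedigree(dplyr::bind_rows(
    ped_row("a", sex = "male", by = 1900),
    ped_row("b", "a", NA, "male", 1925),
    ped_row("c", "b", NA, "male", 1950),
    ped_row("d", "c", NA, "male", 1975)
  ))
  expect_equal(degree_of_relationship(chain, "a", "d"), 3)
})

test_that("relatives_by_degree buckets at minimal degree without duplication", {
  ped <- pedigree(dplyr::bind_rows(
    ped_row("f", sex = "male", by = 1900),
    ped_row("m", sex = "female", by = 1902),
    ped_row("p", "f", "m", "male", 1930),
    ped_row("s", "f", "m", "female", 1932)
  ))
  rel <- relatives_by_degree(ped, "p", max_degree = 3)
  expect_setequal(rel$id[rel$degree == 1], c("f", "m", "s"))

  # sibling of one proband, cousin of another: only the degree-1 bucket
  ped2 <- cousin_pedigree()
  extra <- pedigree(dplyr::bind_rows(
    as_tibble(ped2)[, 1:6],
    ped_row("c1b", "s1", "w1", "male", 1963)
  ))
  rel2 <- relatives_by_degree(extra, c("c1", "c2"), max_degree = 5)
  expect_equal(rel2$degree[rel2$id == "c1b"], 1L)
  expect_equal(sum(rel2$id == "c1b"), 1L)

  # probands related to another proband appear in a bucket; self never does
  expect_true("c2" %in% rel2$id || "c1" %in% rel2$id)
  expect_equal(rel2$degree[rel2$id == "c1"], 3L)
})

test_that("relatives_by_degree agrees with the exhaustive relation-path oracle", {
  ped <- random_pedigree(50, seed = 402)
  probands <- ped$id[c(10, 25, 40)]
  rel <- relatives_by_degree(ped, probands, max_degree = 7)
  for (id in ped$id) {
    dmin <- suppressWarnings(min(vapply(
      setdiff(probands, id), function(p) bf_degree(ped, p, id), numeric(1))))
    if (is.finite(dmin) && dmin >= 1 && dmin <= 7) {
      expect_equal(rel$degree[rel$id == id], as.integer(dmin))
    } else {
      expect_false(id %in% rel$id)
    }
  }
})

test_that("founders and descendants enumerate the genealogy correctly", {
  # founder couple, 3 children (spouses unrelated), 9 grandchildren
  rows <- list(ped_row("f", sex = "male", by = 1900),
               ped_row("m", sex = "female", by = 1901))
  for (i in 1:3) {
    rows <- c(rows, list(
      ped_row(paste0("ch", i), "f", "m", "male", 1930),
      ped_row(paste0("sp", i), sex = "female", by = 1930)
    ))
    for (j in 1:3) {
      rows <- c(rows, list(ped_row(paste0("gc", i, j), paste0("ch", i),
                                   paste0("sp", i), "female", 1960)))
    }
  }
  ped <- pedigree(dplyr::bind_rows(rows))
  expect_length(descendants(ped, "f"), 12)
  expect_length(descendants(ped, "gc11"), 0)
  expect_setequal(founders(ped), c("f", "m", paste0("sp", 1:3)))

  chain <- pedigree(dplyr::bind_rows(
    ped_row("r", sex = "male", by = 1900),
    ped_row("s1c", "r", NA, "male", 1920),
    ped_row("s2c", "s1c", NA, "male", 1940),
    ped_row("s3c", "s2c", NA, "male", 1960)
  ))
  expect_length(descendants(chain, "r"), 3)
})

test_that("kinship obeys symmetry, the halving law, and the degree bound", {
  for (seed in 1:4) {
    ped <- random_pedigree(45, seed = seed)
    ids <- ped$id
    pairs <- t(utils::combn(sample(ids, 12), 2))
    d_ab <- genetic_distance(ped, pairs[, 1], pairs[, 2])
    d_ba <- genetic_distance(ped, pairs[, 2], pairs[, 1])
    expect_equal(d_ab, d_ba)
    # halving law: the coefficient is exactly 2^(-d), so one extra meiosis
    # halves it
    k <- relatedness_coefficient(ped, pairs[, 1], pairs[, 2])
    fin <- is.finite(d_ab)
    expect_equal(k[fin], 2^(-d_ab[fin]))
    expect_equal(k[!fin], rep(0, sum(!fin)))
    # each meiotic step is a relation-graph edge
    deg <- degree_of_relationship(ped, pairs[, 1], pairs[, 2])
    expect_true(all(deg[fin] <= d_ab[fin]))
  }
})

test_that("distance and degree match brute-force enumeration on random pedigrees", {
  for (seed in c(7, 19, 31)) {
    ped <- random_pedigree(55, seed = seed)
    ids <- withr::with_seed(seed, sample(ped$id, 10))
    pairs <- t(utils::combn(ids, 2))
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]
      b <- pairs[r, 2]
      expect_equal(genetic_distance(ped, a, b), bf_genetic_distance(ped, a, b),
                   info = paste(seed, a, b))
      expect_equal(degree_of_relationship(ped, a, b), bf_degree(ped, a, b),
                   info = paste(seed, a, b))
    }
  }
})

test_that("kinship_pairs enumerates exactly the related pairs", {
  ped <- random_pedigree(40, seed = 88)
  ids <- ped$id[seq(2, 40, by = 2)]
  kp <- kinship_pairs(ped, ids)
  expect_true(all(kp$coefficient == 2^(-kp$distance)))
  # cross-check each reported pair and each omitted pair against brute force
  seen <- paste(pmin(kp$id_a, kp$id_b), pmax(kp$id_a, kp$id_b))
  cmb <- t(utils::combn(ids, 2))
  for (r in seq_len(nrow(cmb))) {
    d <- bf_genetic_distance(ped, cmb[r, 1], cmb[r, 2])
    key <- paste(min(cmb[r, ]), max(cmb[r, ]))
    if (is.finite(d)) {
      expect_true(key %in% seen)
      expect_equal(kp$distance[seen == key], as.integer(d))
    } else {
      expect_false(key %in% seen)
    }
  }
})
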