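# Small pedigree builders and independent brute-force oracles.

ped_row <- function(id, fa = NA, mo = NA, sex = "male", by = 1950,
                    bp = "in_state") {
  tibble::tibble(id = id, father_id = fa, mother_id = mo, sex = sex,
                 birth_year = by, birthplace = bp)
}

# founder couple, two children
nuclear_family <- function() {
  pedigree(dplyr::bind_rows(
    ped_row("f", sex = "male", by = 1900),
    ped_row("m", sex = "female", by = 1902),
    ped_row("a", "f", "m", "male", 1930),
    ped_row("b", "f", "m", "female", 1932)
  ))
}

# founder couple, two sibling sons married to unrelated spouses, one child
# each: c1 and c2 are first cousins
cousin_pedigree <- function() {
  pedigree(dplyr::bind_rows(
    ped_row("gf", sex = "male", by = 1900),
    ped_row("gm", sex = "female", by = 1902),
    ped_row("s1", "gf", "gm", "male", 1930),
    ped_row("s2", "gf", "gm", "male", 1932),
    ped_row("w1", sex = "female", by = 1931),
    ped_row("w2", sex = "female", by = 1933),
    ped_row("c1", "s1", "w1", "female", 1960),
    ped_row("c2", "s2", "w2", "male", 1962)
  ))
}

# full known ancestry to great-grandparents for individual "x", with
# `drop_ggp` great-grandparents unrecorded (their child's parent links cut)
ancestry_pedigree <- function(drop_ggp = 0) {
  rows <- list()
  # generation 1: 8 great-grandparents (4 couples), some possibly dropped
  keep <- rep(TRUE, 8)
  if (drop_ggp > 0) keep[seq_len(drop_ggp)] <- FALSE
  ggp_ids <- paste0("ggp", 1:8)
  for (i in 1:8) {
    if (keep[i]) {
      rows[[length(rows) + 1]] <- ped_row(
        ggp_ids[i], sex = if (i %% 2 == 1) "male" else "female", by = 1850)
    }
  }
  # generation 2: 4 grandparents; parent links only where the ggp exists
  gp_sex <- c("male", "female", "male", "female")
  for (j in 1:4) {
    fa_i <- 2 * j - 1
    mo_i <- 2 * j
    rows[[length(rows) + 1]] <- ped_row(
      paste0("gp", j),
      if (keep[fa_i]) ggp_ids[fa_i] else NA,
      if (keep[mo_i]) ggp_ids[mo_i] else NA,
      gp_sex[j], 1880)
  }
  rows[[length(rows) + 1]] <- ped_row("fa", "gp1", "gp2", "male", 1910)
  rows[[length(rows) + 1]] <- ped_row("mo", "gp3", "gp4", "female", 1912)
  rows[[length(rows) + 1]] <- ped_row("x", "fa", "mo", "male", 1940)
  pedigree(dplyr::bind_rows(rows))
}

# Random acyclic pedigree: individual i may only have parents with smaller
# index, so the parent-child graph is a DAG by construction. Produces
# half-sib webs and multi-founder lineages.
random_pedigree <- function(n, seed, p_child = 0.7) {
  withr::with_seed(seed, {
    sex <- sample(c("male", "female"), n, replace = TRUE)
    sex[1:4] <- c("male", "female", "male", "female")
    fa <- rep(NA_character_, n)
    mo <- rep(NA_character_, n)
    ids <- sprintf("p%02d", seq_len(n))
    for (i in 5:n) {
      if (runif(1) < p_child) {
        males <- which(sex[1:(i - 1)] == "male")
        females <- which(sex[1:(i - 1)] == "female")
        if (length(males) > 0 && length(females) > 0) {
          fa[i] <- ids[sample(males, 1)]
          mo[i] <- ids[sample(females, 1)]
        }
      }
    }
    pedigree(tibble::tibble(
      id = ids, father_id = fa, mother_id = mo, sex = sex,
      birth_year = 1900 + seq_len(n), birthplace = "in_state"
    ))
  })
}

# --- brute-force oracles (deliberately naive; independent of the package's
# --- ancestor-map / igraph machinery) ---

# all ancestors of `a` with minimal depth, by exhaustive path recursion
bf_ancestors <- function(ped, a) {
  rec <- function(id, d) {
    out <- stats::setNames(d, id)
    i <- which(ped$id == id)
    f <- ped$father_id[i]
    m <- ped$mother_id[i]
    if (!is.na(f)) out <- c(out, rec(f, d + 1))
    if (!is.na(m)) out <- c(out, rec(m, d + 1))
    out
  }
  v <- rec(a, 0)
  tapply(v, names(v), min)
}

bf_genetic_distance <- function(ped, a, b) {
  aa <- bf_ancestors(ped, a)
  bb <- bf_ancestors(ped, b)
  shared <- intersect(names(aa), names(bb))
  if (length(shared) == 0) return(Inf)
  min(aa[shared] + bb[shared])
}

# adjacency of the relation graph (parents, offspring, full siblings),
# then plain queue BFS
bf_degree <- function(ped, a, b) {
  n <- nrow(ped)
  adj <- matrix(FALSE, n, n)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) adj[i, p] <- adj[p, i] <- TRUE
    }
    if (!is.na(fa[i]) && !is.na(mo[i])) {
      sibs <- which(!is.na(fa) & !is.na(mo) & fa == fa[i] & mo == mo[i])
      for (s in setdiff(sibs, i)) adj[i, s] <- adj[s, i] <- TRUE
    }
  }
  src <- which(ped$id == a)
  dst <- which(ped$id == b)
  dist <- rep(Inf, n)
  dist[src] <- 0
  queue <- src
  while (length(queue) > 0) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (w in which(adj[v, ])) {
      if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist[dst]
}

# direct double-loop GIF
bf_gif <- function(ped, members, min_distance = 1, scale = 1e5) {
  members <- unique(members)
  k <- length(members)
  tot <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- bf_genetic_distance(ped, members[i], members[j])
      if (is.finite(d) && d >= min_distance) tot <- tot + 2^(-d)
    }
  }
  scale * tot / choose(k, 2)
}

# brute-force founder-anchored clusters with maximality filter
bf_clusters <- function(ped, cases, anchors) {
  bf_desc <- function(ids) {
    out <- character(0)
    frontier <- ids
    repeat {
      kids <- ped$id[(!is.na(ped$father_id) & ped$father_id %in% frontier) |
                       (!is.na(ped$mother_id) & ped$mother_id %in% frontier)]
      kids <- setdiff(kids, out)
      if (length(kids) == 0) break
      out <- c(out, kids)
      frontier <- kids
    }
    setdiff(out, ids)
  }
  sets <- lapply(anchors, function(a) sort(intersect(bf_desc(a), cases)))
  keep <- lengths(sets) >= 2
  sets <- sets[keep]
  anchors <- anchors[keep]
  if (length(sets) > 1) {
    sizes <- lengths(sets)
    key <- vapply(sets, paste, character(1), collapse = "|")
    sub <- vapply(seq_along(sets), function(i) {
      any(vapply(seq_along(sets), function(j) {
        i != j && all(sets[[i]] %in% sets[[j]]) &&
          (sizes[i] < sizes[j] || (key[i] == key[j] && i > j))
      }, logical(1)))
    }, logical(1))
    sets <- sets[!sub]
    anchors <- anchors[!sub]
  }
  list(anchors = anchors, sets = sets)
}

# small simulated population shared by several test files
sim_small_pop <- function(seed = 11, h2 = 0.6, c2 = 0.1,
                          n_founder_couples = 60, n_generations = 6) {
  cfg <- sim_config(n_founder_couples = n_founder_couples,
                    n_generations = n_generations, h2 = h2, c2 = c2)
  simulate_population(cfg, seed = seed)
}
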