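# Genealogy data model: validation, indexing, ancestor closure.

#' Construct and validate a pedigree
#'
#' A pedigree is a tibble with one row per individual and columns `id`,
#' `father_id`, `mother_id`, `sex`, `birth_year`, `birthplace`. Parent ids are
#' `NA` when unknown; `"0"` and `""` are also accepted and normalised to `NA`.
#' Additional columns (e.g. `generation` from the simulator) are preserved.
#'
#' Validation enforces: unique non-missing ids; every referenced parent exists;
#' fathers are male and mothers female; the parent-child graph is acyclic
#' (nobody is their own ancestor).
#'
#' @param x A data frame with the columns above.
#' @return A validated tibble of class `fa_pedigree`.
#' @examples
#' ped <- pedigree(tibble::tibble(
#'   id = c("f", "m", "c1", "c2"),
#'   father_id = c(NA, NA, "f", "f"),
#'   mother_id = c(NA, NA, "m", "m"),
#'   sex = c("male", "female", "female", "male"),
#'   birth_year = c(1950, 1952, 1975, 1978),
#'   birthplace = "in_state"
#' ))
#' genetic_distance(ped, "c1", "c2")
#' @export
pedigree <- function(x) {
  req <- c("id", "father_id", "mother_id", "sex", "birth_year", "birthplace")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("pedigree is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- as_tibble(x)
  x$id <- as.character(x$id)
  x$father_id <- normalize_parent(x$father_id)
  x$mother_id <- normalize_parent(x$mother_id)
  x$sex <- normalize_sex(x$sex)
  x$birth_year <- as.integer(x$birth_year)
  x$birthplace <- normalize_birthplace(x$birthplace)

  if (anyNA(x$id) || any(x$id == "")) abort("pedigree ids must be non-missing")
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated pedigree ids: ",
                 paste(unique(dup), collapse = ", ")))
  }
  for (col in c("father_id", "mother_id")) {
    bad <- setdiff(stats::na.omit(x[[col]]), x$id)
    if (length(bad) > 0) {
      abort(paste0("unknown ", col, " referenced: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
  }
  fa <- match(x$father_id, x$id)
  mo <- match(x$mother_id, x$id)
  bad_fa <- which(!is.na(fa) & x$sex[fa] != "male")
  if (length(bad_fa) > 0) {
    abort(paste0("father is not male for: ",
                 paste(head(x$id[bad_fa], 5), collapse = ", ")))
  }
  bad_mo <- which(!is.na(mo) & x$sex[mo] != "female")
  if (length(bad_mo) > 0) {
    abort(paste0("mother is not female for: ",
                 paste(head(x$id[bad_mo], 5), collapse = ", ")))
  }
  ord <- topo_order(fa, mo)
  if (anyNA(ord$order)) {
    abort(paste0("parentage cycle detected involving: ",
                 paste(head(x$id[ord$in_cycle], 10), collapse = ", ")))
  }
  class(x) <- c("fa_pedigree", class(x))
  x
}

normalize_parent <- function(p) {
  p <- as.character(p)
  p[!is.na(p) & (p == "0" | p == "")] <- NA_character_
  p
}

normalize_sex <- function(s) {
  s <- tolower(as.character(s))
  out <- dplyr::case_when(
    s %in% c("male", "m", "1") ~ "male",
    s %in% c("female", "f", "2") ~ "female",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) abort("sex must be one of male/female (or M/F, 1/2)")
  out
}

normalize_birthplace <- function(b) {
  b <- tolower(as.character(b))
  out <- dplyr::case_when(
    b %in% c("in_state", "in-state", "utah", "in") ~ "in_state",
    b %in% c("out_of_state", "out-of-state", "other", "out") ~ "out_of_state",
    TRUE ~ NA_character_
  )
  if (anyNA(out)) abort("birthplace must be in_state or out_of_state")
  out
}

# Kahn topological sort over parent -> child edges. Returns the processing
# order (parents before children) and a logical marking nodes on a cycle.
# The queue doubles as the order vector (head-pointer scan, no popping).
topo_order <- function(fa, mo) {
  n <- length(fa)
  indeg <- (!is.na(fa)) + (!is.na(mo))
  parent <- c(fa, mo)
  child <- rep.int(seq_len(n), 2L)
  ok <- !is.na(parent)
  children <- split(child[ok], factor(parent[ok], levels = seq_len(n)))
  queue <- integer(n)
  init <- which(indeg == 0L)
  queue[seq_along(init)] <- init
  qt <- length(init)
  qh <- 0L
  while (qh < qt) {
    qh <- qh + 1L
    for (ch in children[[queue[qh]]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) {
        qt <- qt + 1L
        queue[qt] <- ch
      }
    }
  }
  if (qt < n) {
    list(order = NA, in_cycle = setdiff(seq_len(n), queue[seq_len(qt)]),
         children = children)
  } else {
    list(order = queue, in_cycle = integer(0), children = children)
  }
}

# Integer-index view of a pedigree used by all graph computations.
ped_index <- function(ped) {
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  ord <- topo_order(fa, mo)
  list(id = ped$id, n = length(ped$id), fa = fa, mo = mo,
       order = ord$order, children = ord$children)
}

#' Ancestor closure with meiotic depths
#'
#' For every individual, the set of its ancestors (including itself at depth 0)
#' with the minimal number of meioses separating them. This is the engine
#' behind genetic distance and kinship: the genetic distance between `a` and
#' `b` is the minimum over shared ancestors of the two depths summed.
#'
#' @param ped An [pedigree()] object.
#' @return A tibble with columns `id`, `ancestor`, `meioses`.
#' @export
ancestor_table <- function(ped) {
  ix <- ped_index(ped)
  maps <- ancestor_maps(ix)
  lens <- lengths(maps$keys)
  tibble(
    id = ped$id[rep.int(seq_len(ix$n), lens)],
    ancestor = ped$id[unlist(maps$keys, use.names = FALSE)],
    meioses = unlist(maps$vals, use.names = FALSE)
  )
}

# Internal: list of (keys = ancestor indices, vals = min meioses) per
# individual, self included at depth 0. Processed in topological order so
# parent maps exist before children need them.
ancestor_maps <- function(ix) {
  keys <- vector("list", ix$n)
  vals <- vector("list", ix$n)
  for (i in ix$order) {
    k <- i
    v <- 0L
    f <- ix$fa[i]
    if (!is.na(f)) {
      k <- c(k, keys[[f]])
      v <- c(v, vals[[f]] + 1L)
    }
    mth <- ix$mo[i]
    if (!is.na(mth)) {
      k <- c(k, keys[[mth]])
      v <- c(v, vals[[mth]] + 1L)
    }
    if (length(k) > 1) {
      o <- order(k, v)
      k <- k[o]
      v <- v[o]
      keep <- !duplicated(k)
      k <- k[keep]
      v <- v[keep]
    }
    keys[[i]] <- k
    vals[[i]] <- v
  }
  list(keys = keys, vals = vals)
}

# Internal: data.table(id = individual index, anc = ancestor index, m = depth)
ancestor_dt <- function(ix) {
  maps <- ancestor_maps(ix)
  lens <- lengths(maps$keys)
  dt <- data.table(
    id = rep.int(seq_len(ix$n), lens),
    anc = unlist(maps$keys, use.names = FALSE),
    m = unlist(maps$vals, use.names = FALSE)
  )
  setkeyv(dt, "anc")
  dt
}

#' Pairwise genetic distance
#'
#' The minimal number of meioses connecting two individuals through a common
#' ancestor (an individual counts as its own ancestor, so parent-offspring is
#' distance 1, full siblings 2, avunculars 3, first cousins 4). `Inf` when no
#' common ancestor exists.
#'
#' @param ped A [pedigree()].
#' @param a,b Character vectors of ids, recycled to common length; `a[i] !=
#'   b[i]` required.
#' @return Numeric vector of distances (`Inf` = unrelated).
#' @export
genetic_distance <- function(ped, a, b) {
  ix <- ped_index(ped)
  ai <- match(as.character(a), ped$id)
  bi <- match(as.character(b), ped$id)
  if (anyNA(ai) || anyNA(bi)) {
    abort(paste0("unknown ids: ", paste(
      unique(c(a[is.na(ai)], b[is.na(bi)])), collapse = ", ")))
  }
  len <- max(length(ai), length(bi))
  ai <- rep_len(ai, len)
  bi <- rep_len(bi, len)
  if (any(ai == bi)) abort("genetic distance is undefined for self-pairs")
  maps <- ancestor_maps(ix)
  vapply(seq_len(len), function(j) {
    ka <- maps$keys[[ai[j]]]
    kb <- maps$keys[[bi[j]]]
    pos <- match(ka, kb)
    ok <- !is.na(pos)
    if (!any(ok)) return(Inf)
    min(maps$vals[[ai[j]]][ok] + maps$vals[[bi[j]]][pos[ok]])
  }, numeric(1))
}

#' Pairwise relatedness coefficient
#'
#' The kinship-style coefficient used by the GIF statistic:
#' \eqn{2^{-d}} where \eqn{d} is the [genetic_distance()]; 0.50 for
#' parent/offspring, 0.25 for siblings, 0.125 for avunculars, 0.0625 for first
#' cousins, and 0 for unrelated pairs. A single shortest path is used;
#' multiple common ancestors and inbreeding loops do not add contributions.
#'
#' @inheritParams genetic_distance
#' @return Numeric vector in \[0, 0.5\].
#' @export
relatedness_coefficient <- function(ped, a, b) {
  2^(-genetic_distance(ped, a, b))
}

#' All related pairs within a set
#'
#' Enumerates every unordered pair of distinct individuals in `ids` with a
#' finite genetic distance, with the distance and coefficient. Pairs with no
#' common ancestor are omitted (coefficient 0).
#'
#' @param ped A [pedigree()].
#' @param ids Character vector of member ids.
#' @param anc Optional precomputed internal ancestor table (for repeated calls
#'   over subsets of the same pedigree); leave `NULL` normally.
#' @return Tibble with columns `id_a`, `id_b`, `distance`, `coefficient`;
#'   `id_a < id_b` lexicographically on internal index.
#' @export
kinship_pairs <- function(ped, ids, anc = NULL) {
  ix <- ped_index(ped)
  ii <- match(unique(as.character(ids)), ped$id)
  if (anyNA(ii)) abort("kinship_pairs: unknown ids")
  if (is.null(anc)) anc <- ancestor_dt(ix)
  pr <- kinship_pairs_idx(anc, ii)
  tibble(
    id_a = ped$id[pr$id],
    id_b = ped$id[pr$i.id],
    distance = pr$distance,
    coefficient = 2^(-pr$distance)
  )
}

# Internal workhorse: related pairs among individual indices `ii`, given the
# keyed ancestor data.table. Self-join on shared ancestors, then minimum
# summed depth per pair.
kinship_pairs_idx <- function(adt, ii) {
  at <- adt[list(id = ii), on = "id", nomatch = NULL]
  if (nrow(at) == 0) {
    return(data.table(id = integer(), i.id = integer(), distance = integer()))
  }
  setkeyv(at, "anc")
  j <- at[at, on = "anc", allow.cartesian = TRUE]
  lower <- j[["id"]] < j[["i.id"]]
  j <- j[lower]
  if (nrow(j) == 0) {
    return(data.table(id = integer(), i.id = integer(), distance = integer()))
  }
  j[, list(distance = min(m + i.m)), by = c("id", "i.id")]
}

#' Genealogy-completeness filter
#'
#' Individuals with high-quality genealogy data: both parents known, all four
#' grandparents known, and at least six of the eight great-grandparent slots
#' known. Only such individuals enter case, control and relative counts, so
#' cases and controls are comparable in quantity of genealogy data.
#'
#' @param ped A [pedigree()].
#' @return `is_complete()`: logical vector along `ped` rows. `complete_ids()`:
#'   character vector of qualifying ids. `filter_complete()`: the qualifying
#'   rows of `ped`.
#' @export
is_complete <- function(ped) {
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  slot <- function(p, side) {
    # index of the father (side = 1) / mother (side = 2) of parent index p
    out <- rep(NA_integer_, length(p))
    ok <- !is.na(p)
    out[ok] <- if (side == 1) fa[p[ok]] else mo[p[ok]]
    out
  }
  gp <- cbind(slot(fa, 1), slot(fa, 2), slot(mo, 1), slot(mo, 2))
  ggp <- cbind(slot(gp[, 1], 1), slot(gp[, 1], 2),
               slot(gp[, 2], 1), slot(gp[, 2], 2),
               slot(gp[, 3], 1), slot(gp[, 3], 2),
               slot(gp[, 4], 1), slot(gp[, 4], 2))
  !is.na(fa) & !is.na(mo) &
    rowSums(!is.na(gp)) == 4L &
    rowSums(!is.na(ggp)) >= 6L
}

#' @rdname is_complete
#' @export
complete_ids <- function(ped) ped$id[is_complete(ped)]

#' @rdname is_complete
#' @export
filter_complete <- function(ped) ped[is_complete(ped), , drop = FALSE]

#' Founders and descendants
#'
#' Founders are individuals with neither parent recorded. Descendants of an
#' individual are the transitive closure of child links, excluding the
#' individual itself.
#'
#' @param ped A [pedigree()].
#' @param a A single id.
#' @return Character vector of ids.
#' @export
founders <- function(ped) {
  ped$id[is.na(ped$father_id) & is.na(ped$mother_id)]
}

#' @rdname founders
#' @export
descendants <- function(ped, a) {
  ix <- ped_index(ped)
  ai <- match(as.character(a), ped$id)
  if (is.na(ai)) abort(paste0("unknown id: ", a))
  ped$id[descendants_idx(ix, ai)]
}

# Internal: integer indices of descendants of any of the indices in `ai`.
descendants_idx <- function(ix, ai) {
  seen <- rep(FALSE, ix$n)
  frontier <- ai
  while (length(frontier) > 0) {
    kids <- unique(unlist(ix$children[frontier], use.names = FALSE))
    kids <- kids[!seen[kids]]
    seen[kids] <- TRUE
    frontier <- kids
  }
  seen[ai] <- FALSE
  which(seen)
}

# Relation graph: undirected edges between each individual and its parents
# (hence offspring) plus full-sibling edges (both parents shared).
relation_graph <- function(ped) {
  ix <- ped_index(ped)
  pc <- rbind(
    cbind(which(!is.na(ix$fa)), ix$fa[!is.na(ix$fa)]),
    cbind(which(!is.na(ix$mo)), ix$mo[!is.na(ix$mo)])
  )
  both <- which(!is.na(ix$fa) & !is.na(ix$mo))
  sib_edges <- NULL
  if (length(both) > 0) {
    fam <- split(both, paste(ix$fa[both], ix$mo[both]))
    fam <- fam[lengths(fam) > 1]
    sib_edges <- do.call(rbind, lapply(fam, function(s) t(utils::combn(s, 2))))
  }
  el <- rbind(pc, sib_edges)
  g <- igraph::make_empty_graph(n = ix$n, directed = FALSE)
  if (!is.null(el) && nrow(el) > 0) {
    g <- igraph::add_edges(g, t(el))
  }
  g
}

#' Degree of relationship
#'
#' Shortest path length between two individuals in the relation graph whose
#' edges join each individual to its parents, offspring, and full siblings:
#' parent/sibling/offspring = 1, grandparent/avuncular/half-sibling = 2,
#' first cousin/great-grandchild = 3, etc. `Inf` when unconnected.
#'
#' This is the recursive closure "second-degree relatives are the first-degree
#' relatives of the first-degree relatives" taken literally.
#'
#' @inheritParams genetic_distance
#' @return Numeric vector of degrees (`Inf` = unconnected).
#' @export
degree_of_relationship <- function(ped, a, b) {
  a <- as.character(a)
  b <- as.character(b)
  ai <- match(a, ped$id)
  bi <- match(b, ped$id)
  if (anyNA(ai) || anyNA(bi)) {
    abort(paste0("unknown ids: ", paste(
      unique(c(a[is.na(ai)], b[is.na(bi)])), collapse = ", ")))
  }
  len <- max(length(ai), length(bi))
  ai <- rep_len(ai, len)
  bi <- rep_len(bi, len)
  if (any(ai == bi)) abort("degree is undefined for self-pairs")
  g <- relation_graph(ped)
  d <- igraph::distances(g, v = unique(ai), to = unique(bi), mode = "all")
  d[cbind(match(ai, unique(ai)), match(bi, unique(bi)))]
}

#' Relatives of a proband set, bucketed by minimal degree
#'
#' Every individual connected to at least one *other* proband in the relation
#' graph within `max_degree` steps is assigned to exactly one bucket: its
#' minimal degree of relationship to any proband (so a sibling of one proband
#' who is also a cousin of another counts once, as first-degree). Nobody is a
#' relative of itself, but a proband related to another proband does appear —
#' with the full case set as probands, a case sibling of another case is
#' both a proband and a countable first-degree relative, which is what makes
#' observed case counts among relatives meaningful.
#'
#' @param ped A [pedigree()].
#' @param probands Character vector of proband ids.
#' @param max_degree Largest degree bucket to return.
#' @return Tibble with columns `id`, `degree`.
#' @export
relatives_by_degree <- function(ped, probands, max_degree = 7) {
  stopifnot(max_degree >= 1)
  pi <- match(unique(as.character(probands)), ped$id)
  if (anyNA(pi)) abort("relatives_by_degree: unknown proband ids")
  g <- relation_graph(ped)
  d <- igraph::distances(g, v = pi, to = igraph::V(g), mode = "all")
  d[cbind(seq_along(pi), pi)] <- Inf  # self-relation never counts
  dmin <- if (length(pi) == 1) as.numeric(d) else apply(d, 2, min)
  keep <- which(is.finite(dmin) & dmin >= 1 & dmin <= max_degree)
  tibble(id = ped$id[keep], degree = as.integer(dmin[keep])) %>%
    arrange(.data$degree, .data$id)
}
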