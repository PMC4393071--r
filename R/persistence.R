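#' Build the single-linkage merge tree of a point cloud
#'
#' Sweeps the cutoff radius upward over a distance matrix, connecting points
#' whose distance falls strictly below the cutoff, and records the sequence of
#' component-merge events (a Kruskal-style union-find pass over edges sorted by
#' distance, ties ordered by vertex indices). The merge tree is the common
#' substrate for barcodes, component queries, and join-order tracking.
#'
#' @param d Symmetric distance matrix with dimnames (as produced by
#'   [pairwise_distances()] or `as.matrix(dist(...))`).
#' @return A `merge_tree`: list with `items` (identifiers), `n`, `events`
#'   (tibble `radius`, `i`, `j` of the merges in sweep order) and `max_radius`.
#' @export
merge_tree <- function(d) {
  if (inherits(d, "dist")) {
    d <- as.matrix(d)
  }
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  items <- rownames(d)
  if (is.null(items)) {
    items <- as.character(seq_len(n))
  }
  if (n < 1) {
    topo_abort("empty distance matrix", "topo_error_validation")
  }
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0)) {
    topo_abort("distance matrix must be symmetric with zero diagonal",
               "topo_error_validation")
  }
  events <- tibble::tibble(radius = numeric(0), i = integer(0), j = integer(0))
  if (n > 1) {
    ut <- which(upper.tri(d), arr.ind = TRUE)
    radius <- d[upper.tri(d)]
    ord <- order(radius, ut[, 1], ut[, 2])
    parent <- seq_len(n)
    find <- function(k) {
      while (parent[k] != k) {
        parent[k] <<- parent[parent[k]]
        k <- parent[k]
      }
      k
    }
    keep <- logical(length(ord))
    for (e in seq_along(ord)) {
      a <- find(ut[ord[e], 1])
      b <- find(ut[ord[e], 2])
      if (a != b) {
        parent[b] <- a
        keep[e] <- TRUE
      }
    }
    sel <- ord[keep]
    events <- tibble::tibble(radius = d[upper.tri(d)][sel],
                             i = ut[sel, 1], j = ut[sel, 2])
  }
  structure(
    list(items = items, n = n, events = events,
         max_radius = if (n > 1) max(d) else 0),
    class = "merge_tree"
  )
}

#' @export
print.merge_tree <- function(x, ...) {
  cat("Merge tree over", x$n, "items;", nrow(x$events),
      "merge events; max radius", format(x$max_radius, digits = 4), "\n")
  invisible(x)
}

## Replay the merge events up to (strictly below) a cutoff, tracking for each
## surviving component its members, their join radii into the surviving
## lineage, and the radius at which the component first reached n_min members
## (the "birth" of its bar). The elder rule is applied at the n_min level: on
## a merge, the component whose size-n_min birth is earlier survives; if
## neither (or both equally) qualifies, the component holding the smallest
## item index survives. Returns the set of live components and the intervals
## of the bars that died.
sweep_components <- function(tree, n_min, r_c = Inf) {
  n <- tree$n
  parent <- seq_len(n)
  find <- function(k) {
    while (parent[k] != k) {
      parent[k] <<- parent[parent[k]]
      k <- parent[k]
    }
    k
  }
  members <- as.list(seq_len(n))
  jr <- rep(list(0), n)
  birth <- rep(if (n_min == 1) 0 else NA_real_, n)
  bar_rep <- if (n_min == 1) seq_len(n) else rep(NA_integer_, n)
  intervals <- list()
  ev <- tree$events
  for (e in seq_len(nrow(ev))) {
    r <- ev$radius[e]
    if (r >= r_c) break
    a <- find(ev$i[e])
    b <- find(ev$j[e])
    ba <- birth[a]
    bb <- birth[b]
    surv <- if (!is.na(ba) && !is.na(bb)) {
      if (ba < bb) a
      else if (bb < ba) b
      else if (min(members[[a]]) < min(members[[b]])) a else b
    } else if (!is.na(ba)) {
      a
    } else if (!is.na(bb)) {
      b
    } else {
      if (min(members[[a]]) < min(members[[b]])) a else b
    }
    oth <- if (surv == a) b else a
    if (!is.na(birth[oth])) {
      intervals[[length(intervals) + 1]] <- list(
        rep = bar_rep[oth], birth = birth[oth], death = r,
        members = members[[oth]], jr = jr[[oth]]
      )
    }
    jr[[surv]] <- c(jr[[surv]], rep(r, length(members[[oth]])))
    members[[surv]] <- c(members[[surv]], members[[oth]])
    members[oth] <- list(NULL)
    jr[oth] <- list(NULL)
    parent[oth] <- surv
    if (is.na(birth[surv]) && length(members[[surv]]) >= n_min) {
      birth[surv] <- r
      bar_rep[surv] <- min(members[[surv]])
    }
  }
  roots <- which(parent == seq_len(n))
  roots <- roots[vapply(roots, function(k) find(k) == k, logical(1))]
  alive <- lapply(roots, function(k) {
    list(rep = bar_rep[k], birth = birth[k], death = Inf,
         members = members[[k]], jr = jr[[k]])
  })
  list(alive = alive, intervals = intervals)
}

member_tibble <- function(tree, comp) {
  ord <- order(comp$jr, comp$members)
  tibble::tibble(item_id = tree$items[comp$members[ord]],
                 join_radius = comp$jr[ord])
}

#' Persistence barcode of connected components with a minimum-size constraint
#'
#' Classical zero-dimensional persistence tracks every point from radius 0; to
#' suppress sub-scale fragments, a component here is only awarded a bar once it
#' has accumulated `n_min` members -- equivalently, each simplex's filtration
#' time is promoted to the time its component reaches `n_min` elements. A
#' bar's birth is that radius; its death is the radius at which the component
#' is absorbed into an elder component (`Inf` for the final survivor).
#' Components absorbed before ever reaching `n_min` produce no bar. With
#' `n_min = 1` this reduces to standard single-linkage persistence: all births
#' are 0 and deaths are the merge heights.
#'
#' @param tree A [merge_tree()].
#' @param n_min Minimum component size for a bar (positive integer).
#' @return A `topo_barcode`: tibble with columns `component_id` (identifier of
#'   the smallest-index member at birth), `birth`, `death`, `size`, `min_member`
#'   and list-column `members` (tibbles of `item_id`, `join_radius` in join
#'   order). Attributes `n_min` and `max_radius`.
#' @export
barcode <- function(tree, n_min = 1) {
  stopifnot(inherits(tree, "merge_tree"), n_min >= 1)
  n_min <- as.integer(n_min)
  sw <- sweep_components(tree, n_min)
  bars <- c(sw$intervals, Filter(function(cm) !is.na(cm$birth), sw$alive))
  rows <- lapply(bars, function(cm) {
    tibble::tibble(
      component_id = tree$items[cm$rep],
      birth = cm$birth,
      death = cm$death,
      size = length(cm$members),
      min_member = min(cm$members),
      members = list(member_tibble(tree, cm))
    )
  })
  out <- if (length(rows) > 0) {
    dplyr::arrange(dplyr::bind_rows(rows), .data$birth, .data$min_member)
  } else {
    tibble::tibble(component_id = character(0), birth = numeric(0),
                   death = numeric(0), size = integer(0),
                   min_member = integer(0), members = list())
  }
  structure(out, n_min = n_min, max_radius = tree$max_radius,
            items = tree$items,
            class = c("topo_barcode", class(out)))
}

#' Connected components at a fixed cutoff radius
#'
#' Components of the graph whose edges satisfy `d < r_c` (strict inequality).
#' Only components with at least `n_min` members are reported; members are
#' listed in the order they joined the surviving component (ties broken by
#' item index). The sizes of *all* components, reported or not, are available
#' in the `"all_sizes"` attribute, so the reported membership plus the
#' unreported remainder always partitions the full item set.
#'
#' @param tree A [merge_tree()].
#' @param r_c Cutoff radius (non-negative).
#' @param n_min Minimum reported component size.
#' @return Tibble with columns `component_id`, `item_id`, `join_radius`,
#'   `join_rank`; attributes `r_c`, `n_min`, `all_sizes`.
#' @export
components_at <- function(tree, r_c, n_min = 1) {
  stopifnot(inherits(tree, "merge_tree"), r_c >= 0, n_min >= 1)
  sw <- sweep_components(tree, as.integer(n_min), r_c = r_c)
  sizes <- vapply(sw$alive, function(cm) length(cm$members), integer(1))
  qual <- sw$alive[sizes >= n_min]
  ord <- order(vapply(qual, function(cm) cm$birth, numeric(1)),
               vapply(qual, function(cm) min(cm$members), integer(1)))
  qual <- qual[ord]
  rows <- lapply(qual, function(cm) {
    mt <- member_tibble(tree, cm)
    mt <- dplyr::mutate(mt, component_id = tree$items[cm$rep], .before = 1)
    dplyr::mutate(mt, join_rank = dplyr::row_number())
  })
  out <- if (length(rows) > 0) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(component_id = character(0), item_id = character(0),
                   join_radius = numeric(0), join_rank = integer(0))
  }
  structure(out, r_c = r_c, n_min = as.integer(n_min), all_sizes = sizes,
            class = c("topo_components", class(out)))
}

#' Most persistent components of a barcode
#'
#' Ranks bars by persistence (death minus birth, infinite deaths evaluated at
#' the maximum pairwise radius), breaking ties by earlier birth and then by
#' smallest member index, and returns the identifiers of the top `k`. Fewer
#' than `k` bars signals that no robust partition exists, which terminates the
#' recursion in the hierarchical pipeline.
#'
#' @param bc A [barcode()].
#' @param k Number of components to select.
#' @return Character vector of `k` component identifiers.
#' @export
top_persistent_components <- function(bc, k = 2) {
  stopifnot(inherits(bc, "topo_barcode"), k >= 1)
  if (nrow(bc) < k) {
    rlang::abort(
      sprintf("no robust partition: barcode has %d bar(s), need %d", nrow(bc), k),
      class = c("topo_error_insufficient_components", "topo_no_partition",
                "topo_error")
    )
  }
  finite_death <- ifelse(is.finite(bc$death), bc$death, attr(bc, "max_radius"))
  pers <- finite_death - bc$birth
  ord <- order(-pers, bc$birth, bc$min_member)
  bc$component_id[ord[seq_len(k)]]
}

#' Cutoff radius just before two components combine
#'
#' Finds the radius at which the lineages of two components become connected.
#' Because component membership uses the strict rule `d < r_c`, evaluating
#' [components_at()] at the returned radius yields the two groups at their
#' maximal membership, just prior to their combining into a single component.
#'
#' @param tree A [merge_tree()].
#' @param a,b Component identifiers (items representing each lineage, as
#'   returned by [top_persistent_components()]).
#' @return The merge radius of the two lineages.
#' @export
pre_merge_cutoff <- function(tree, a, b) {
  stopifnot(inherits(tree, "merge_tree"))
  if (identical(a, b)) {
    topo_abort("cannot compute pre-merge cutoff of a component with itself",
               "topo_error_validation")
  }
  ia <- match(a, tree$items)
  ib <- match(b, tree$items)
  if (is.na(ia) || is.na(ib)) {
    topo_abort("unknown component identifier", "topo_error_validation")
  }
  parent <- seq_len(tree$n)
  find <- function(k) {
    while (parent[k] != k) {
      parent[k] <<- parent[parent[k]]
      k <- parent[k]
    }
    k
  }
  ev <- tree$events
  for (e in seq_len(nrow(ev))) {
    ra <- find(ev$i[e])
    rb <- find(ev$j[e])
    if (ra != rb) {
      parent[rb] <- ra
    }
    if (find(ia) == find(ib)) {
      return(ev$radius[e])
    }
  }
  topo_abort("components never merge (distance matrix may contain NAs)",
             "topo_error_validation")
}
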