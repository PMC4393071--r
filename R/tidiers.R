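#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a persistence barcode
#'
#' @param x A `topo_barcode`.
#' @param ... Unused.
#' @return Tibble with one row per bar: `component_id`, `birth`, `death`,
#'   `persistence` (infinite deaths evaluated at the maximum radius), `size`.
#' @method tidy topo_barcode
#' @export
tidy.topo_barcode <- function(x, ...) {
  finite_death <- ifelse(is.finite(x$death), x$death, attr(x, "max_radius"))
  tibble::tibble(
    component_id = x$component_id,
    birth = x$birth,
    death = x$death,
    persistence = finite_death - x$birth,
    size = x$size
  )
}

#' @rdname tidy.topo_barcode
#' @return For `glance`: a one-row tibble with `n_bars`, `n_min`,
#'   `max_radius`, `max_persistence`.
#' @method glance topo_barcode
#' @export
glance.topo_barcode <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_bars = nrow(x),
    n_min = attr(x, "n_min"),
    max_radius = attr(x, "max_radius"),
    max_persistence = if (nrow(td) > 0) max(td$persistence) else NA_real_
  )
}

#' Tidy a gene panel pair
#'
#' @param x A `panel_pair`.
#' @param ... Unused.
#' @return Tibble with `panel`, `gene_id`, `join_radius`, `join_rank`,
#'   `in_panel` (whether the gene survived truncation to the first `n_g`
#'   joiners).
#' @method tidy panel_pair
#' @export
tidy.panel_pair <- function(x, ...) {
  fc <- x$full_components
  dplyr::mutate(
    tibble::tibble(panel = fc$panel, gene_id = fc$item_id,
                   join_radius = fc$join_radius, join_rank = fc$join_rank),
    in_panel = .data$gene_id %in% c(x$panel_1, x$panel_2)
  )
}

#' Tidy a hierarchical partition tree
#'
#' @param x A `partition_tree`.
#' @param ... Unused.
#' @return Tibble with one row per node: `node`, `depth`, `n_samples`,
#'   `is_leaf`, `leaf_reason`, `cutoff_radius`, `n_core_1`, `n_core_2`.
#' @method tidy partition_tree
#' @export
tidy.partition_tree <- function(x, ...) {
  dplyr::bind_rows(lapply(tree_nodes(x), function(nd) {
    is_leaf <- is.null(nd$children)
    tibble::tibble(
      node = nd$id,
      depth = nd$depth,
      n_samples = length(nd$sample_ids),
      is_leaf = is_leaf,
      leaf_reason = if (is_leaf) nd$leaf_reason else NA_character_,
      cutoff_radius = if (is_leaf) NA_real_ else nd$cutoff_radius,
      n_core_1 = if (is_leaf) NA_integer_ else nrow(nd$cores[[1]]),
      n_core_2 = if (is_leaf) NA_integer_ else nrow(nd$cores[[2]])
    )
  }))
}

#' @rdname tidy.partition_tree
#' @return For `glance`: one row with `n_nodes`, `n_leaves`, `max_depth`,
#'   `n_samples_root`, `n_samples_in_leaves`.
#' @method glance partition_tree
#' @export
glance.partition_tree <- function(x, ...) {
  td <- tidy(x)
  lc <- leaf_cores(x)
  tibble::tibble(
    n_nodes = nrow(td),
    n_leaves = sum(td$is_leaf),
    max_depth = max(td$depth),
    n_samples_root = td$n_samples[td$node == "root"],
    n_samples_in_leaves = nrow(lc)
  )
}

#' Tidy a fitted subtype model
#'
#' @param x A `subtype_model`.
#' @param ... Unused.
#' @return Tibble with one row per core group: `node`, `group`, `n_core`,
#'   `radius`, `n_panel_genes`.
#' @method tidy subtype_model
#' @export
tidy.subtype_model <- function(x, ...) {
  dplyr::bind_rows(lapply(x$nodes, function(nd) {
    dplyr::bind_rows(lapply(nd$groups, function(g) {
      tibble::tibble(node = nd$id, group = g$label,
                     n_core = length(g$sample_ids), radius = g$radius,
                     n_panel_genes = length(nd$panel_genes))
    }))
  }))
}

#' @rdname tidy.subtype_model
#' @return For `glance`: one row with `n_splits`, `n_groups`,
#'   `n_distinct_panel_genes` (the size of the total gene signature).
#' @method glance subtype_model
#' @export
glance.subtype_model <- function(x, ...) {
  tibble::tibble(
    n_splits = length(x$nodes),
    n_groups = 2 * length(x$nodes),
    n_distinct_panel_genes =
      length(unique(unlist(lapply(x$nodes, `[[`, "panel_genes"))))
  )
}
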