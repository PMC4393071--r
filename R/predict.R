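#' Fit the hierarchical subtype prediction model
#'
#' For every internal node of a partition tree and each of its two core
#' groups, computes the group's assignment radius: the maximum over core
#' members of that member's mean correlation distance (over the node's
#' refined panel genes) to the remaining members. By construction every core
#' member lies within its own group's radius, and the radius is attained by
#' at least one member. New samples falling strictly inside exactly one
#' radius inherit that group's branch.
#'
#' @param tree A `partition_tree` with at least one split.
#' @param x Expression tibble containing the panel genes and core samples
#'   (normally the training matrix the tree was grown from).
#' @return A `subtype_model`: list of per-node entries, each holding the
#'   node's panel genes and, per core group, the member profiles and radius.
#' @export
fit_subtype_model <- function(tree, x) {
  stopifnot(inherits(tree, "partition_tree"))
  x <- validate_expression(x)
  internal <- Filter(function(nd) !is.null(nd$children), tree_nodes(tree))
  if (length(internal) == 0) {
    topo_abort("partition tree has no splits to model", "topo_error_validation")
  }
  nodes <- lapply(internal, function(nd) {
    genes <- panel_genes(nd$panels)
    groups <- lapply(1:2, function(k) {
      core <- nd$cores[[k]]
      if (nrow(core) < 2) {
        topo_abort("degenerate core group of size < 2", "topo_error_degenerate")
      }
      sub <- select_samples(select_genes(x, genes), core$sample_id)
      d <- pairwise_distances(sub, axis = "samples")
      loo <- rowSums(d) / (nrow(d) - 1)
      list(label = nd$children[[k]]$id,
           child_is_leaf = is.null(nd$children[[k]]$children),
           sample_ids = core$sample_id,
           radius = max(loo),
           core = as_expression_matrix(sub))
    })
    list(id = nd$id, panel_genes = genes, groups = groups)
  })
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  structure(list(nodes = nodes, root = "root"), class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("Subtype model with", length(x$nodes), "split(s)\n")
  for (nd in x$nodes) {
    for (g in nd$groups) {
      cat(sprintf("  %s -> %s: %d core samples, radius %.3f\n",
                  nd$id, g$label, length(g$sample_ids), g$radius))
    }
  }
  invisible(x)
}

#' Assign new samples to subtype core groups
#'
#' Walks each query sample down the model tree. At every node the sample's
#' mean correlation distance to each core group is computed over that node's
#' panel genes; the sample descends into a group only if the mean distance is
#' strictly below the group's radius. Below both radii, it descends into the
#' nearer group and is flagged ambiguous; below neither, the walk stops and
#' the deepest group reached is reported (`"unassigned"` if that happens at
#' the root). The criteria are deliberately strict -- unassignment is
#' preferred to misassignment -- but can be relaxed by inflating all radii
#' with `relax > 1`.
#'
#' @param object A `subtype_model`.
#' @param newdata Expression tibble of query samples (must contain every
#'   panel gene used by the model).
#' @param relax Multiplier applied to all radii (default 1, the strict rule).
#' @param ... Unused.
#' @return Tibble with one row per query sample: `sample_id`, `prediction`
#'   (group label or `"unassigned"`), `path`, `ambiguous`, and a `distances`
#'   list-column of per-node tibbles (`node`, `group`, `mean`, `sd`, `radius`,
#'   `within`), where `sd` is the dispersion of the sample's distances across
#'   the core members.
#' @export
predict.subtype_model <- function(object, newdata, relax = 1, ...) {
  stopifnot(relax > 0)
  newdata <- validate_expression(newdata)
  needed <- unique(unlist(lapply(object$nodes, `[[`, "panel_genes")))
  missing_genes <- setdiff(needed, newdata$gene_id)
  if (length(missing_genes) > 0) {
    topo_abort(
      paste0("query profiles are missing ", length(missing_genes),
             " panel gene(s): ", paste(head(missing_genes, 10), collapse = ", ")),
      "topo_error_incomplete_profile"
    )
  }
  mat <- as_expression_matrix(newdata)
  assign_one <- function(sample_id) {
    profile <- mat[, sample_id]
    node_id <- object$root
    label <- "unassigned"
    path <- character(0)
    ambiguous <- FALSE
    dist_rows <- list()
    repeat {
      nd <- object$nodes[[node_id]]
      path <- c(path, node_id)
      q <- profile[nd$panel_genes]
      stats_g <- lapply(nd$groups, function(g) {
        dd <- apply(g$core, 2, function(member) correlation_distance(q, member))
        list(mean = mean(dd), sd = sd(dd))
      })
      means <- vapply(stats_g, `[[`, numeric(1), "mean")
      radii <- vapply(nd$groups, `[[`, numeric(1), "radius") * relax
      within <- means < radii
      dist_rows[[length(dist_rows) + 1]] <- tibble::tibble(
        node = node_id,
        group = vapply(nd$groups, `[[`, character(1), "label"),
        mean = means,
        sd = vapply(stats_g, `[[`, numeric(1), "sd"),
        radius = radii,
        within = within
      )
      if (!any(within)) {
        break
      }
      k <- if (all(within)) {
        ambiguous <- TRUE
        which.min(means)
      } else {
        which(within)
      }
      label <- nd$groups[[k]]$label
      if (nd$groups[[k]]$child_is_leaf || !label %in% names(object$nodes)) {
        path <- c(path, label)
        break
      }
      node_id <- label
    }
    tibble::tibble(
      sample_id = sample_id,
      prediction = label,
      path = paste(path, collapse = " > "),
      ambiguous = ambiguous,
      distances = list(dplyr::bind_rows(dist_rows))
    )
  }
  dplyr::bind_rows(lapply(colnames(mat), assign_one))
}

#' Write a subtype model to JSON
#'
#' Serializes a fitted model (panel genes, core profiles, radii) so that
#' prediction can run without refitting, e.g. from the command-line interface.
#'
#' @param model A `subtype_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subtype_model <- function(model, path) {
  stopifnot(inherits(model, "subtype_model"))
  ser <- list(
    root = model$root,
    nodes = lapply(unname(model$nodes), function(nd) {
      list(
        id = nd$id,
        panel_genes = nd$panel_genes,
        groups = lapply(nd$groups, function(g) {
          list(label = g$label,
               child_is_leaf = g$child_is_leaf,
               sample_ids = g$sample_ids,
               radius = g$radius,
               genes = rownames(g$core),
               core = unname(g$core))
        })
      )
    })
  )
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a subtype model from JSON
#'
#' @param path Path written by [write_subtype_model()].
#' @return A `subtype_model`.
#' @export
read_subtype_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                             simplifyDataFrame = FALSE)
  nodes <- lapply(ser$nodes, function(nd) {
    groups <- lapply(nd$groups, function(g) {
      core <- g$core
      if (!is.matrix(core)) {
        core <- do.call(rbind, core)
      }
      rownames(core) <- g$genes
      colnames(core) <- g$sample_ids
      list(label = g$label, child_is_leaf = g$child_is_leaf,
           sample_ids = g$sample_ids, radius = g$radius, core = core)
    })
    list(id = nd$id, panel_genes = nd$panel_genes, groups = groups)
  })
  names(nodes) <- vapply(nodes, `[[`, character(1), "id")
  structure(list(nodes = nodes, root = ser$root), class = "subtype_model")
}
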