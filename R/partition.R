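#' Configuration for sample bisection and core trimming
#'
#' @param n_min_samples Minimum sample-component size for a bar (default 10).
#' @param theta Coherence threshold: a candidate sample (taken in join order)
#'   is admitted to the core iff its mean correlation distance to the
#'   already-admitted members is at most `theta`. Mutually exclusive with
#'   `core_fraction`.
#' @param core_fraction Alternative trimming rule: keep the first
#'   `ceiling(core_fraction * group size)` joiners.
#' @return A `trim_config` list.
#' @export
trim_config <- function(n_min_samples = 10, theta = 0.5, core_fraction = NULL) {
  stopifnot(n_min_samples >= 2)
  if (!is.null(core_fraction)) {
    stopifnot(core_fraction > 0, core_fraction <= 1)
    theta <- NULL
  } else {
    stopifnot(is.numeric(theta), theta >= 0)
  }
  structure(
    list(n_min_samples = as.integer(n_min_samples), theta = theta,
         core_fraction = core_fraction),
    class = "trim_config"
  )
}

#' Bisect a sample set using a gene panel
#'
#' Restricts the expression matrix to the panel genes, computes sample-sample
#' correlation distances, and extracts the two most persistent
#' size-constrained components at their maximal membership just prior to
#' combining. Members are returned in join order: samples joining a component
#' early are the most tightly correlated with it.
#'
#' @param x Expression tibble restricted to the sample set under analysis.
#' @param panels A `panel_pair` from [build_panels()].
#' @param trim A [trim_config()] (supplies `n_min_samples`).
#' @return A `sample_bisection`: list with `group_1`, `group_2` (tibbles
#'   `sample_id`, `join_radius`, `join_rank`, most persistent component
#'   first), `cutoff_radius`, and `barcode`. Signals no-partition when fewer
#'   than two qualifying bars exist.
#' @export
bisect_samples <- function(x, panels, trim = trim_config()) {
  x <- validate_expression(x)
  genes <- panel_genes(panels)
  if (length(genes) == 0) {
    topo_abort("empty gene panel", "topo_error_validation")
  }
  if (length(sample_ids(x)) < 2 * trim$n_min_samples) {
    no_partition(sprintf(
      "cannot bisect %d samples with minimum component size %d",
      length(sample_ids(x)), trim$n_min_samples))
  }
  xp <- select_genes(x, genes)
  d <- pairwise_distances(xp, axis = "samples")
  tree <- merge_tree(d)
  bc <- barcode(tree, n_min = trim$n_min_samples)
  top2 <- top_persistent_components(bc, 2)
  cutoff <- pre_merge_cutoff(tree, top2[1], top2[2])
  comps <- components_at(tree, cutoff, n_min = trim$n_min_samples)
  grp <- function(rep_item) {
    cid <- comps$component_id[match(rep_item, comps$item_id)]
    out <- dplyr::filter(comps, .data$component_id == cid)
    tibble::tibble(sample_id = out$item_id, join_radius = out$join_radius,
                   join_rank = out$join_rank)
  }
  structure(
    list(group_1 = grp(top2[1]), group_2 = grp(top2[2]),
         cutoff_radius = cutoff, barcode = bc),
    class = "sample_bisection"
  )
}

#' Trim a raw sample group to its coherent core
#'
#' Admits group members in join order. Under the `theta` rule, a candidate is
#' admitted iff its mean correlation distance (over the panel genes) to the
#' already-admitted members is at most `theta`; the first joiner is admitted
#' unconditionally. Under the `core_fraction` rule, the first
#' `ceiling(f * group size)` joiners are kept. This makes the visual "keep the
#' tightly correlated left part of the heat map" step quantitative and
#' reproducible.
#'
#' @param group A join-ordered group tibble from [bisect_samples()].
#' @param x Expression tibble containing the group's samples.
#' @param panels The `panel_pair` that produced the bisection.
#' @param trim A [trim_config()].
#' @return A `core_group` tibble (`sample_id`, `join_radius`, `join_rank`)
#'   restricted to admitted members, in join order.
#' @export
trim_to_core <- function(group, x, panels, trim = trim_config()) {
  x <- validate_expression(x)
  xp <- select_genes(x, panel_genes(panels))
  xp <- select_samples(xp, group$sample_id)
  if (!is.null(trim$core_fraction)) {
    n_keep <- ceiling(trim$core_fraction * nrow(group))
    core <- head(group, n_keep)
  } else {
    d <- pairwise_distances(xp, axis = "samples")
    ids <- group$sample_id[group$sample_id %in% rownames(d)]
    admitted <- ids[1]
    for (cand in ids[-1]) {
      if (mean(d[cand, admitted]) <= trim$theta) {
        admitted <- c(admitted, cand)
      }
    }
    core <- group[group$sample_id %in% admitted, ]
  }
  if (nrow(core) < 2) {
    topo_abort("degenerate core: fewer than 2 samples admitted",
               "topo_error_degenerate")
  }
  structure(core, class = c("core_group", class(core)))
}

#' Refine gene panels on the core samples
#'
#' Re-runs the full gene-selection stage (sigma screen plus persistent
#' homology over the whole gene universe) on the matrix restricted to the
#' union of the two core groups. Once incoherent samples are trimmed away, a
#' different, sharper gene set typically separates the cores.
#'
#' @param cores List of two `core_group` tibbles.
#' @param x Expression tibble containing all genes and the core samples.
#' @param config A [panel_config()].
#' @param annotation Optional gene annotation for confounder exclusion.
#' @return A refined `panel_pair`.
#' @export
refine_panels <- function(cores, x, config = panel_config(), annotation = NULL) {
  core_samples <- c(cores[[1]]$sample_id, cores[[2]]$sample_id)
  xc <- select_samples(validate_expression(x), core_samples)
  screened <- screen_genes(xc, config, annotation)
  build_panels(xc, screened$gene_id, config)
}

#' Hierarchical bisection of samples into core subtype groups
#'
#' The full pipeline, applied recursively: screen genes by sigma, group them
#' by persistent homology into a panel pair, bisect the samples, trim each
#' group to its coherent core, refine the panels on the cores, then recurse
#' into each core. A branch terminates (becomes a leaf) when no robust
#' partition exists: fewer than two persistent components, a trimmed core
#' below `n_min_samples`, too few samples, or too few genes with a defined
#' sigma. The tree depth is therefore data-determined, yielding both the
#' number of subtypes and their genetic proximity structure.
#'
#' @param x Expression tibble (all genes, all samples).
#' @param config A [panel_config()].
#' @param trim A [trim_config()].
#' @param annotation Optional gene annotation for confounder exclusion.
#' @return A `partition_tree`: nested list of nodes, each with `id`,
#'   `sample_ids`, `depth`, and for internal nodes `panels` (refined),
#'   `panels_initial`, `cutoff_radius`, `cores` (list of two core tibbles) and
#'   `children` (list of two subtrees); leaves carry a `leaf_reason`.
#' @export
hierarchical_partition <- function(x, config = panel_config(),
                                   trim = trim_config(), annotation = NULL) {
  x <- validate_expression(x)
  grow <- function(samples, id, depth) {
    leaf <- function(reason) {
      list(id = id, sample_ids = samples, depth = depth, children = NULL,
           leaf_reason = reason)
    }
    if (length(samples) < 2 * trim$n_min_samples) {
      return(leaf("too few samples"))
    }
    tryCatch({
      xs <- select_samples(x, samples)
      screened <- screen_genes(xs, config, annotation)
      panels0 <- build_panels(xs, screened$gene_id, config)
      bis <- bisect_samples(xs, panels0, trim)
      core_1 <- trim_to_core(bis$group_1, xs, panels0, trim)
      core_2 <- trim_to_core(bis$group_2, xs, panels0, trim)
      if (nrow(core_1) < trim$n_min_samples ||
          nrow(core_2) < trim$n_min_samples) {
        no_partition("a trimmed core fell below n_min_samples")
      }
      refined <- refine_panels(list(core_1, core_2), xs, config, annotation)
      list(
        id = id, sample_ids = samples, depth = depth,
        panels = refined, panels_initial = panels0,
        cutoff_radius = bis$cutoff_radius,
        cores = list(core_1, core_2),
        children = list(
          grow(core_1$sample_id, paste0(id, "/1"), depth + 1),
          grow(core_2$sample_id, paste0(id, "/2"), depth + 1)
        ),
        leaf_reason = NULL
      )
    },
    topo_no_partition = function(e) leaf(conditionMessage(e)),
    topo_error_insufficient = function(e) leaf(conditionMessage(e)),
    topo_error_degenerate = function(e) leaf(conditionMessage(e)))
  }
  root <- grow(sample_ids(x), "root", 0L)
  structure(list(root = root, config = config, trim = trim),
            class = "partition_tree")
}

tree_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    out[[length(out) + 1]] <<- node
    if (!is.null(node$children)) {
      lapply(node$children, walk)
    }
    invisible(NULL)
  }
  walk(tree$root)
  out
}

#' @export
print.partition_tree <- function(x, ...) {
  nodes <- tree_nodes(x)
  cat("Hierarchical partition tree:", length(nodes), "node(s)\n")
  for (nd in nodes) {
    cat(strrep("  ", nd$depth), "- ", nd$id, " (", length(nd$sample_ids),
        " samples)",
        if (is.null(nd$children)) paste0(" [leaf: ", nd$leaf_reason, "]") else "",
        "\n", sep = "")
  }
  invisible(x)
}

#' Leaf core groups of a partition tree
#'
#' @param tree A `partition_tree`.
#' @return Tibble with columns `node`, `sample_id`, `depth`: every sample in a
#'   leaf node, labelled by the leaf identifier. Samples trimmed away along
#'   the way do not appear.
#' @export
leaf_cores <- function(tree) {
  nodes <- Filter(function(nd) is.null(nd$children), tree_nodes(tree))
  dplyr::bind_rows(lapply(nodes, function(nd) {
    tibble::tibble(node = nd$id, sample_id = nd$sample_ids, depth = nd$depth)
  }))
}

#' Panel-by-core ordered expression submatrix for heat-map rendering
#'
#' Emits the panel-gene by core-sample submatrix with rows grouped panel-1
#' genes then panel-2 genes and columns in join order within each core group,
#' the layout in which coherent cores appear as sharp blocks. Group boundary
#' indices are stored as attributes for external rendering; [autoplot()]
#' draws it directly.
#'
#' @param cores List of two core-group tibbles (join-ordered).
#' @param panels A `panel_pair`.
#' @param x Expression tibble containing the panel genes and core samples.
#' @return A `topo_heatmap` tibble: `gene_id`, `panel`, then one column per
#'   core sample in display order. Attributes `n_genes_1` and `n_samples_1`
#'   give the row/column boundaries.
#' @export
heatmap_order <- function(cores, panels, x) {
  x <- validate_expression(x)
  genes <- panel_genes(panels)
  samples <- c(cores[[1]]$sample_id, cores[[2]]$sample_id)
  xo <- select_samples(select_genes(x, genes), samples)
  out <- dplyr::mutate(
    xo,
    panel = rep(c("panel_1", "panel_2"),
                c(length(panels$panel_1), length(panels$panel_2))),
    .after = "gene_id"
  )
  structure(out,
            n_genes_1 = length(panels$panel_1),
            n_samples_1 = nrow(cores[[1]]),
            class = c("topo_heatmap", class(out)))
}
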