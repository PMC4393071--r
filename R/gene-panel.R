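#' Configuration for gene screening and panel construction
#'
#' Bundles the tunable parameters of the gene-selection stage. Defaults follow
#' the profiling pipeline's standard settings: keep the `n_sigma_genes = 60`
#' genes with smallest nondimensionalized standard deviation, require gene
#' components of at least `n_min_genes = 5` members in the barcode, and keep
#' the first `n_g = 15` genes to join each of the two most persistent
#' components.
#'
#' @param n_sigma_genes Number of genes retained by the sigma screen.
#' @param n_min_genes Minimum gene-component size for a bar.
#' @param n_g Panel size: the first `n_g` joiners of each component are kept.
#' @param outlier_sd Outlier threshold for [sigma_stat()].
#' @param exclusion_chromosomes Chromosome labels whose genes are removed
#'   before taking the top `n_sigma_genes` (default `"Y"`, excluding the
#'   sex-linked confounder block).
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_sigma_genes = 60, n_min_genes = 5, n_g = 15,
                         outlier_sd = 8, exclusion_chromosomes = "Y") {
  stopifnot(n_sigma_genes >= 2, n_min_genes >= 2, n_g >= 1, outlier_sd > 0)
  if (2 * n_g > n_sigma_genes) {
    topo_abort("panel size n_g must satisfy 2 * n_g <= n_sigma_genes",
               "topo_error_validation")
  }
  structure(
    list(n_sigma_genes = as.integer(n_sigma_genes),
         n_min_genes = as.integer(n_min_genes),
         n_g = as.integer(n_g),
         outlier_sd = outlier_sd,
         exclusion_chromosomes = exclusion_chromosomes),
    class = "panel_config"
  )
}

#' Screen genes by bimodality, excluding confounder groups
#'
#' Ranks genes ascending by the nondimensionalized standard deviation
#' ([sigma_ranking()]), removes genes on excluded chromosomes (or in an
#' explicit exclusion list when no annotation is available -- e.g. a manually
#' identified sex-linked group), and returns the first `n_sigma_genes`
#' survivors.
#'
#' @param x Expression tibble.
#' @param config A [panel_config()].
#' @param annotation Optional annotation tibble (`gene_id`, `chromosome`).
#' @param exclude_genes Optional character vector of genes to drop regardless
#'   of annotation.
#' @return Tibble of selected genes (`gene_id`, `sigma`, `n_used`,
#'   `n_discarded`, `rank`), ascending in `sigma`.
#' @export
screen_genes <- function(x, config = panel_config(), annotation = NULL,
                         exclude_genes = NULL) {
  x <- validate_expression(x)
  rk <- sigma_ranking(x, outlier_sd = config$outlier_sd)
  rk <- dplyr::filter(rk, .data$defined)
  chr <- annotation_lookup(annotation, rk$gene_id)
  keep <- !(chr %in% config$exclusion_chromosomes) &
    !(rk$gene_id %in% exclude_genes)
  rk <- rk[keep, ]
  if (nrow(rk) < config$n_sigma_genes) {
    topo_abort(
      sprintf("only %d genes with defined sigma after exclusions, need %d",
              nrow(rk), config$n_sigma_genes),
      "topo_error_insufficient"
    )
  }
  dplyr::select(head(rk, config$n_sigma_genes),
                "gene_id", "sigma", "n_used", "n_discarded", "rank")
}

#' Build a pair of gene panels by persistent homology
#'
#' Computes gene-gene correlation distances over the samples of `x`, sweeps
#' the merge tree, takes the two most persistent components of the
#' size-constrained barcode, evaluates their membership just before they
#' combine ([pre_merge_cutoff()]), and truncates each membership to the first
#' `n_g` genes to join. The two panels capture anti-correlated co-expression
#' modules: the molecular signature of a sample bisection.
#'
#' @param x Expression tibble, already restricted to the sample set under
#'   analysis.
#' @param genes Character vector of screened gene identifiers (join order of
#'   the result is independent of this order).
#' @param config A [panel_config()].
#' @return A `panel_pair`: list with `panel_1`, `panel_2` (character vectors
#'   in join order, most persistent component first), `cutoff_radius`,
#'   `full_components` (tibble of untruncated memberships), and `barcode`.
#'   Signals a no-partition condition when fewer than two qualifying bars
#'   exist.
#' @export
build_panels <- function(x, genes, config = panel_config()) {
  x <- validate_expression(x)
  if (length(genes) < 2 * config$n_min_genes) {
    topo_abort("need at least 2 * n_min_genes genes to build panels",
               "topo_error_insufficient")
  }
  xg <- select_genes(x, genes)
  d <- pairwise_distances(xg, axis = "genes")
  tree <- merge_tree(d)
  bc <- barcode(tree, n_min = config$n_min_genes)
  top2 <- top_persistent_components(bc, 2)
  cutoff <- pre_merge_cutoff(tree, top2[1], top2[2])
  comps <- components_at(tree, cutoff, n_min = config$n_min_genes)
  comp_of <- function(rep_item) {
    cid <- comps$component_id[match(rep_item, comps$item_id)]
    dplyr::filter(comps, .data$component_id == cid)
  }
  full_1 <- comp_of(top2[1])
  full_2 <- comp_of(top2[2])
  structure(
    list(
      panel_1 = head(full_1$item_id, config$n_g),
      panel_2 = head(full_2$item_id, config$n_g),
      cutoff_radius = cutoff,
      full_components = dplyr::bind_rows(
        dplyr::mutate(full_1, panel = "panel_1", .before = 1),
        dplyr::mutate(full_2, panel = "panel_2", .before = 1)
      ),
      barcode = bc,
      config = config
    ),
    class = "panel_pair"
  )
}

#' @export
print.panel_pair <- function(x, ...) {
  cat("Gene panel pair (cutoff radius ", format(x$cutoff_radius, digits = 4),
      ")\n", sep = "")
  cat("  panel_1 (", length(x$panel_1), " genes): ",
      paste(head(x$panel_1, 8), collapse = ", "),
      if (length(x$panel_1) > 8) ", ..." else "", "\n", sep = "")
  cat("  panel_2 (", length(x$panel_2), " genes): ",
      paste(head(x$panel_2, 8), collapse = ", "),
      if (length(x$panel_2) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

panel_genes <- function(panels) c(panels$panel_1, panels$panel_2)
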