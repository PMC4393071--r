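#' Design for a planted-subtype expression matrix
#'
#' Describes a synthetic cohort with known (planted) subtype structure, the
#' statistical shape the profiling pipeline assumes in real tumor data:
#' marker-gene modules whose per-subtype mean shifts make their marginal
#' distributions bimodal mixtures of unit-noise Gaussians, within-module
#' coherence induced by a shared latent factor (the minimal model of
#' subnetwork co-regulation), independent background genes, and an optional
#' sex-linked confounder block annotated to chromosome Y.
#'
#' With three subtypes (the default), the first two are siblings: one module
#' pair separates `{A1, A2}` from `B` and a second pair separates `A1` from
#' `A2` only (contrast zero on `B`), giving a two-level hierarchy in which
#' the sibling split is only recoverable after the first bisection. With two
#' subtypes a single module pair is planted.
#'
#' @param subtypes Named integer vector of per-subtype sample counts; length
#'   2 or 3. With 3 subtypes the first two are the sibling pair.
#' @param markers_per_module Genes per marker module (default 15).
#' @param n_background Independent background genes (default 40).
#' @param effect_size Mean expression difference between the up- and
#'   down-regulated subtype groups of a module (default 2; with the default
#'   noise this is a mixture separation of 4 noise SDs).
#' @param module_loading Loading of the shared per-module latent factor
#'   (default 0.4).
#' @param noise_sd Per-gene additive noise SD for marker and confounder genes
#'   (default 0.5); background genes are unit-variance noise.
#' @param confounder Plant a sex-linked confounder block? (default TRUE).
#' @param n_confounder Genes in the confounder block (default 6).
#' @param confounder_effect Mean difference between sexes for confounder
#'   genes (default 2).
#' @return A `planted_design` list.
#' @export
planted_design <- function(subtypes = c(A1 = 30, A2 = 30, B = 40),
                           markers_per_module = 15,
                           n_background = 40,
                           effect_size = 2,
                           module_loading = 0.4,
                           noise_sd = 0.5,
                           confounder = TRUE,
                           n_confounder = 6,
                           confounder_effect = 2) {
  if (is.null(names(subtypes)) || any(!nzchar(names(subtypes))) ||
      anyDuplicated(names(subtypes)) || any(subtypes < 1) ||
      !length(subtypes) %in% 2:3) {
    topo_abort("subtypes must be 2 or 3 uniquely named positive counts",
               "topo_error_design")
  }
  stopifnot(markers_per_module >= 2, n_background >= 0, effect_size >= 0,
            noise_sd >= 0, module_loading >= 0)
  sn <- names(subtypes)
  contrast <- function(...) {
    stats::setNames(c(...), sn)
  }
  modules <- if (length(subtypes) == 2) {
    list(up_1 = contrast(1, -1), up_2 = contrast(-1, 1))
  } else {
    list(
      up_A  = contrast(1, 1, -1),
      up_B  = contrast(-1, -1, 1),
      up_A1 = contrast(1, -1, 0),
      up_A2 = contrast(-1, 1, 0)
    )
  }
  structure(
    list(subtypes = subtypes, modules = modules,
         markers_per_module = as.integer(markers_per_module),
         n_background = as.integer(n_background),
         effect_size = effect_size, module_loading = module_loading,
         noise_sd = noise_sd, confounder = isTRUE(confounder),
         n_confounder = as.integer(n_confounder),
         confounder_effect = confounder_effect),
    class = "planted_design"
  )
}

#' Generate a planted-subtype expression matrix
#'
#' A pure function of `(design, seed)`: identical inputs give byte-identical
#' outputs, and the gene universe is fixed by the design alone, so matrices
#' generated under different seeds (e.g. training and held-out cohorts) share
#' gene identities and planted structure but not values.
#'
#' @param design A [planted_design()].
#' @param seed Integer seed.
#' @param sample_prefix Prefix for generated sample identifiers (default
#'   `"S"`; use a different prefix for held-out cohorts).
#' @return List with elements `expression` (tibble `gene_id` + samples),
#'   `labels` (tibble `sample_id`, `subtype`, `sex`), `modules` (tibble
#'   `gene_id`, `module`, `role`), and `annotation` (tibble `gene_id`,
#'   `chromosome`; confounder genes on `"Y"`).
#' @export
simulate_expression <- function(design, seed = 1, sample_prefix = "S") {
  stopifnot(inherits(design, "planted_design"))
  M <- sum(design$subtypes)
  samples <- sprintf("%s%03d", sample_prefix, seq_len(M))
  subtype <- rep(names(design$subtypes), design$subtypes)
  gene_sets <- c(
    lapply(names(design$modules), function(m) {
      sprintf("%s_%02d", m, seq_len(design$markers_per_module))
    }),
    if (design$confounder) {
      list(sprintf("sexY_%02d", seq_len(design$n_confounder)))
    },
    if (design$n_background > 0) {
      list(sprintf("bg_%02d", seq_len(design$n_background)))
    }
  )
  withr::with_seed(seed, {
    sex <- sample(c("F", "M"), M, replace = TRUE)
    blocks <- list()
    for (mi in seq_along(design$modules)) {
      m <- names(design$modules)[mi]
      shift <- (design$effect_size / 2) * design$modules[[m]][subtype]
      factor_m <- rnorm(M)
      block <- t(vapply(seq_len(design$markers_per_module), function(g) {
        shift + design$module_loading * factor_m + rnorm(M, sd = design$noise_sd)
      }, numeric(M)))
      rownames(block) <- gene_sets[[mi]]
      blocks[[m]] <- block
    }
    if (design$confounder) {
      shift <- (design$confounder_effect / 2) * ifelse(sex == "M", 1, -1)
      factor_c <- rnorm(M)
      block <- t(vapply(seq_len(design$n_confounder), function(g) {
        shift + design$module_loading * factor_c + rnorm(M, sd = design$noise_sd)
      }, numeric(M)))
      rownames(block) <- sprintf("sexY_%02d", seq_len(design$n_confounder))
      blocks[["confounder"]] <- block
    }
    if (design$n_background > 0) {
      block <- matrix(rnorm(design$n_background * M), nrow = design$n_background)
      rownames(block) <- sprintf("bg_%02d", seq_len(design$n_background))
      blocks[["background"]] <- block
    }
    mat <- do.call(rbind, blocks)
    colnames(mat) <- samples
    autosomes <- sample(c(as.character(1:22), "X"), nrow(mat), replace = TRUE)
  })
  genes <- rownames(mat)
  role <- ifelse(startsWith(genes, "sexY_"), "confounder",
                 ifelse(startsWith(genes, "bg_"), "background", "marker"))
  module_of <- sub("_[0-9]+$", "", genes)
  expression <- tibble::as_tibble(cbind(
    tibble::tibble(gene_id = genes),
    tibble::as_tibble(mat)
  ))
  list(
    expression = expression,
    labels = tibble::tibble(sample_id = samples, subtype = subtype, sex = sex),
    modules = tibble::tibble(gene_id = genes, module = module_of, role = role),
    annotation = tibble::tibble(
      gene_id = genes,
      chromosome = ifelse(role == "confounder", "Y", autosomes)
    )
  )
}

#' Generate a geometric point cloud with a known topology
#'
#' Seeded generators for the shapes used to exercise the persistence and
#' homology code: well-separated Gaussian cluster blobs, a circle (one loop),
#' a figure-eight (two loops sharing a point), and a torus surface sample.
#'
#' @param shape One of `"clusters"`, `"circle"`, `"figure8"`, `"torus"`.
#' @param n Total number of points (minimum depends on shape).
#' @param noise SD of isotropic Gaussian jitter added to the coordinates.
#' @param seed Integer seed.
#' @param k Number of blobs (clusters shape only).
#' @param separation Distance between adjacent blob centers (clusters).
#' @param spread Within-blob SD (clusters).
#' @return List with `coords` (tibble `id`, `x`, `y`\[, `z`\]) and `dist`
#'   (Euclidean distance matrix with point ids as dimnames).
#' @export
simulate_point_cloud <- function(shape = c("clusters", "circle", "figure8", "torus"),
                                 n = 20, noise = 0, seed = 1,
                                 k = 2, separation = 4, spread = 0.5) {
  shape <- match.arg(shape)
  minimum <- c(clusters = k, circle = 3, figure8 = 6, torus = 8)[[shape]]
  if (n < minimum) {
    topo_abort(sprintf("shape '%s' needs at least %d points", shape, minimum),
               "topo_error_design")
  }
  coords <- withr::with_seed(seed, {
    switch(shape,
      clusters = {
        sizes <- diff(floor(seq(0, n, length.out = k + 1)))
        centers <- (seq_len(k) - 1) * separation
        do.call(rbind, lapply(seq_len(k), function(b) {
          cbind(rnorm(sizes[b], centers[b], spread), rnorm(sizes[b], 0, spread))
        }))
      },
      circle = {
        th <- 2 * pi * (seq_len(n) - 1) / n
        cbind(cos(th), sin(th)) + matrix(rnorm(2 * n, sd = noise), ncol = 2)
      },
      figure8 = {
        n1 <- ceiling(n / 2)
        n2 <- n - n1
        th1 <- 2 * pi * (seq_len(n1) - 1) / n1
        th2 <- 2 * pi * (seq_len(n2) - 1) / n2
        rbind(cbind(cos(th1) - 1, sin(th1)),
              cbind(cos(th2) + 1, sin(th2))) +
          matrix(rnorm(2 * n, sd = noise), ncol = 2)
      },
      torus = {
        u <- runif(n, 0, 2 * pi)
        v <- runif(n, 0, 2 * pi)
        R <- 2
        r <- 0.7
        cbind((R + r * cos(v)) * cos(u),
              (R + r * cos(v)) * sin(u),
              r * sin(v)) + matrix(rnorm(3 * n, sd = noise), ncol = 3)
      }
    )
  })
  ids <- sprintf("p%03d", seq_len(n))
  rownames(coords) <- ids
  d <- as.matrix(dist(coords))
  coord_tbl <- tibble::as_tibble(coords, .name_repair = ~ c("x", "y", "z")[seq_along(.x)])
  coord_tbl <- dplyr::mutate(coord_tbl, id = ids, .before = 1)
  list(coords = coord_tbl, dist = d)
}
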