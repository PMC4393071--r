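# Shared fixtures and independent oracles. Oracles are deliberately naive
# re-implementations (double loops, direct formulas, graph traversal via
# igraph) kept separate from the code paths they check.

toy_expression <- function() {
  tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    S1 = c(0.5, -1.25, 3.0),
    S2 = c(2.0, 0.125, -4.0),
    S3 = c(-1.0, 2.5, 0.75)
  )
}

noise_expression <- function(n_genes = 80, n_samples = 60, seed = 7) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(NULL, sprintf("S%03d", seq_len(n_samples))))
    dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%03d", seq_len(n_genes))),
      tibble::as_tibble(m)
    )
  })
}

# Direct one-pass evaluation of the raw width statistic (no outlier pass):
# population variance over squared mean absolute deviation.
sigma_oracle <- function(v) {
  m <- sum(v) / length(v)
  varp <- sum((v - m)^2) / length(v)
  mad <- sum(abs(v - m)) / length(v)
  varp / mad^2
}

# Partition of items under the strict-threshold graph, by graph traversal.
graph_components_oracle <- function(d, r_c) {
  A <- d < r_c
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  split(rownames(d), igraph::components(g)$membership)
}

# Canonical form of a partition (set of sorted member vectors) for equality
# checks independent of component labels and order.
canonical_partition <- function(groups) {
  groups <- lapply(groups, function(g) sort(as.character(g)))
  unname(groups[order(vapply(groups, `[`, character(1), 1))])
}

partition_from_components <- function(comps, tree) {
  reported <- split(comps$item_id, comps$component_id)
  # re-attach unreported items (size < n_min) as singleton-ish leftovers only
  # when n_min = 1 queries are compared; callers pass n_min = 1 here
  reported
}

random_cloud <- function(n, seed, dim = 2) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * dim), n, dim)
  })
  rownames(m) <- sprintf("p%02d", seq_len(n))
  as.matrix(dist(m))
}

# A 7-vertex triangulation of the torus: faces {i, i+1, i+3} and
# {i, i+2, i+3} mod 7; every edge of K7 lies in exactly two triangles.
torus_complex <- function() {
  faces <- c(
    lapply(0:6, function(i) (c(i, i + 1, i + 3) %% 7) + 1),
    lapply(0:6, function(i) (c(i, i + 2, i + 3) %% 7) + 1)
  )
  simplicial_complex(faces)
}

octahedron_complex <- function() {
  faces <- apply(expand.grid(c(1, 2), c(3, 4), c(5, 6)), 1, c,
                 simplify = FALSE)
  simplicial_complex(faces)
}

figure8_complex <- function() {
  simplicial_complex(list(c(1, 2), c(2, 3), c(3, 1),
                          c(1, 4), c(4, 5), c(5, 1)))
}

# Map tree leaves to planted subtype labels by majority vote on the training
# cohort, for scoring held-out predictions.
leaf_label_map <- function(tree, labels) {
  lc <- leaf_cores(tree)
  truth <- labels$subtype[match(lc$sample_id, labels$sample_id)]
  tapply(truth, lc$node, function(s) names(which.max(table(s))))
}
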