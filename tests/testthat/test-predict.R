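# A hand-buildable one-split tree over toy profiles, for radius arithmetic.
toy_tree <- function(x, core1, core2, genes1, genes2) {
  leaf <- function(id, s) list(id = id, sample_ids = s, depth = 1L,
                               children = NULL, leaf_reason = "toy")
  panels <- structure(list(panel_1 = genes1, panel_2 = genes2,
                           cutoff_radius = NA_real_), class = "panel_pair")
  core_tbl <- function(s) tibble::tibble(sample_id = s,
                                         join_radius = 0,
                                         join_rank = seq_along(s))
  root <- list(id = "root", sample_ids = c(core1, core2), depth = 0L,
               panels = panels, panels_initial = panels,
               cutoff_radius = NA_real_,
               cores = list(core_tbl(core1), core_tbl(core2)),
               children = list(leaf("root/1", core1), leaf("root/2", core2)),
               leaf_reason = NULL)
  structure(list(root = root, config = panel_config(), trim = trim_config()),
            class = "partition_tree")
}

trained <- local({
  des <- planted_design()
  sim <- simulate_expression(des, seed = 42)
  tree <- hierarchical_partition(sim$expression, annotation = sim$annotation)
  list(design = des, sim = sim, tree = tree,
       model = fit_subtype_model(tree, sim$expression))
})

test_that("a core of two identical samples has assignment radius zero", {
  x <- tibble::tibble(gene_id = sprintf("g%d", 1:6),
                      a = c(1, 2, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6),
                      c = c(6, 5, 4, 3, 2, 1), d = c(6, 5, 4, 2, 3, 1))
  tree <- toy_tree(x, c("a", "b"), c("c", "d"), sprintf("g%d", 1:3),
                   sprintf("g%d", 4:6))
  model <- fit_subtype_model(tree, x)
  td <- tidy(model)
  expect_equal(td$radius[td$group == "root/1"], 0)
  expect_gt(td$radius[td$group == "root/2"], 0)
})

test_that("the radius is the max leave-one-out mean distance, by enumeration", {
  withr::with_seed(31, {
    x <- dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("g%d", 1:8)),
      tibble::as_tibble(matrix(rnorm(8 * 5), 8, 5,
                               dimnames = list(NULL, letters[1:5])))
    )
  })
  tree <- toy_tree(x, c("a", "b", "c"), c("d", "e"),
                   sprintf("g%d", 1:4), sprintf("g%d", 5:8))
  model <- fit_subtype_model(tree, x)
  m <- as_expression_matrix(x)
  pd <- function(i, j) correlation_distance(m[, i], m[, j])
  loo <- c(mean(c(pd("a", "b"), pd("a", "c"))),
           mean(c(pd("b", "a"), pd("b", "c"))),
           mean(c(pd("c", "a"), pd("c", "b"))))
  td <- tidy(model)
  expect_equal(td$radius[td$group == "root/1"], max(loo))
})

test_that("every core member is re-assigned to its own group", {
  lc <- leaf_cores(trained$tree)
  some <- lc[seq(1, nrow(lc), by = 7), ]
  pred <- predict(trained$model,
                  trained$sim$expression[c("gene_id", some$sample_id)])
  expect_equal(pred$prediction, some$node)
  expect_false(any(pred$ambiguous))
})

test_that("held-out samples are assigned their planted subtype, never another", {
  held <- simulate_expression(
    planted_design(subtypes = c(A1 = 20, A2 = 20, B = 20)),
    seed = 1042, sample_prefix = "H")
  pred <- predict(trained$model, held$expression)
  map <- leaf_label_map(trained$tree, trained$sim$labels)
  truth <- held$labels$subtype[match(pred$sample_id, held$labels$sample_id)]
  assigned <- pred$prediction != "unassigned"
  leaf_pred <- pred$prediction %in% names(map)
  # no sample is assigned a leaf of a different subtype
  expect_true(all(map[pred$prediction[leaf_pred]] == truth[leaf_pred]))
  expect_gt(mean(assigned & leaf_pred), 0.9)
})

test_that("a pure-noise profile is unassigned at the root", {
  genes <- trained$sim$expression$gene_id
  withr::with_seed(77, {
    q <- tibble::tibble(gene_id = genes, noise1 = rnorm(length(genes)))
  })
  pred <- predict(trained$model, q)
  expect_equal(pred$prediction, "unassigned")
  d0 <- pred$distances[[1]]
  expect_true(all(d0$mean[d0$node == "root"] > d0$radius[d0$node == "root"]))
})

test_that("missing panel genes are reported by name", {
  x <- trained$sim$expression
  dropped <- trained$model$nodes$root$panel_genes[1]
  expect_error(
    predict(trained$model, x[x$gene_id != dropped, ]),
    regexp = dropped,
    class = "topo_error_incomplete_profile"
  )
})

test_that("assignment is invariant to affine rescaling of the query profile", {
  held <- simulate_expression(trained$design, seed = 55, sample_prefix = "Q")
  q <- held$expression[c("gene_id", sprintf("Q%03d", 1:5))]
  q_scaled <- dplyr::mutate(q, dplyr::across(-"gene_id", ~ 3.7 * .x - 2.2))
  p1 <- predict(trained$model, q)
  p2 <- predict(trained$model, q_scaled)
  expect_equal(p1$prediction, p2$prediction)
  expect_equal(p1$distances, p2$distances, tolerance = 1e-10)
})

test_that("relaxing the radii only widens the assigned set", {
  genes <- trained$sim$expression$gene_id
  withr::with_seed(78, {
    q <- dplyr::bind_cols(
      tibble::tibble(gene_id = genes),
      tibble::as_tibble(matrix(rnorm(length(genes) * 6), ncol = 6,
                               dimnames = list(NULL, sprintf("N%d", 1:6))))
    )
  })
  strict <- predict(trained$model, q)
  relaxed <- predict(trained$model, q, relax = 10)
  expect_true(all(strict$prediction == "unassigned"))
  expect_true(all(relaxed$prediction != "unassigned"))
})

test_that("a model round-trips through JSON serialization", {
  p <- withr::local_tempfile(fileext = ".json")
  write_subtype_model(trained$model, p)
  m2 <- read_subtype_model(p)
  expect_equal(tidy(m2), tidy(trained$model))
  held <- simulate_expression(trained$design, seed = 91, sample_prefix = "R")
  expect_equal(predict(m2, held$expression),
               predict(trained$model, held$expression))
})
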