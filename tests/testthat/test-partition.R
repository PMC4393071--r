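two_subtype_sim <- function(seed = 5) {
  simulate_expression(planted_design(subtypes = c(A = 30, B = 30)), seed = seed)
}

fit_panels <- function(sim) {
  sel <- screen_genes(sim$expression, panel_config(), sim$annotation)
  build_panels(sim$expression, sel$gene_id, panel_config())
}

test_that("trim config accepts exactly one trimming rule", {
  expect_equal(trim_config()$theta, 0.5)
  tc <- trim_config(core_fraction = 0.5)
  expect_null(tc$theta)
  expect_error(trim_config(n_min_samples = 1))
})

test_that("bisection of a planted two-subtype cohort matches the labels", {
  sim <- two_subtype_sim()
  bis <- bisect_samples(sim$expression, fit_panels(sim), trim_config())
  truth <- split(sim$labels$sample_id, sim$labels$subtype)
  got <- canonical_partition(list(bis$group_1$sample_id, bis$group_2$sample_id))
  expect_equal(got, canonical_partition(truth))
  # join order is recorded and nondecreasing
  expect_true(all(diff(bis$group_1$join_radius) >= 0))
})

test_that("too few samples signal no-partition rather than an error", {
  sim <- two_subtype_sim()
  x3 <- sim$expression[c("gene_id", "S001", "S002", "S031")]
  expect_error(bisect_samples(x3, fit_panels(sim), trim_config()),
               class = "topo_no_partition")
})

test_that("a duplicated sample lands in the same group as its twin", {
  sim <- two_subtype_sim()
  x <- dplyr::mutate(sim$expression, dup = .data$S001)
  bis <- bisect_samples(x, fit_panels(sim), trim_config())
  grp_of <- function(s) {
    if (s %in% bis$group_1$sample_id) 1L
    else if (s %in% bis$group_2$sample_id) 2L
    else NA_integer_
  }
  expect_equal(grp_of("dup"), grp_of("S001"))
})

test_that("core trimming admits coherent joiners and rejects stragglers", {
  sim <- two_subtype_sim()
  panels <- fit_panels(sim)
  bis <- bisect_samples(sim$expression, panels, trim_config())
  # vacuous threshold keeps the whole group
  whole <- trim_to_core(bis$group_1, sim$expression, panels,
                        trim_config(theta = 2))
  expect_equal(whole$sample_id, bis$group_1$sample_id)
  # append 5 pure-noise stragglers to the group and to the matrix
  withr::with_seed(99, {
    noise_cols <- matrix(rnorm(nrow(sim$expression) * 5), ncol = 5,
                         dimnames = list(NULL, sprintf("straggler%d", 1:5)))
  })
  x2 <- dplyr::bind_cols(sim$expression, tibble::as_tibble(noise_cols))
  grp2 <- dplyr::bind_rows(
    bis$group_1,
    tibble::tibble(sample_id = colnames(noise_cols),
                   join_radius = max(bis$group_1$join_radius) + 0.3,
                   join_rank = nrow(bis$group_1) + 1:5)
  )
  core <- trim_to_core(grp2, x2, panels, trim_config(theta = 0.5))
  expect_equal(core$sample_id, bis$group_1$sample_id)
  # fractional rule keeps exactly the first joiners
  frac <- trim_to_core(grp2, x2, panels, trim_config(core_fraction = 0.4))
  expect_equal(frac$sample_id, head(grp2$sample_id, 14))
})

test_that("cores shrink or stay equal as theta decreases", {
  sim <- two_subtype_sim()
  panels <- fit_panels(sim)
  bis <- bisect_samples(sim$expression, panels, trim_config())
  thetas <- c(1.2, 0.8, 0.5, 0.35)
  cores <- lapply(thetas, function(th) {
    trim_to_core(bis$group_1, sim$expression, panels,
                 trim_config(theta = th))$sample_id
  })
  for (k in seq_along(cores)[-1]) {
    expect_true(all(cores[[k]] %in% cores[[k - 1]]))
  }
})

test_that("refining on full-group cores equals re-running on their union", {
  sim <- two_subtype_sim()
  panels <- fit_panels(sim)
  bis <- bisect_samples(sim$expression, panels, trim_config())
  cores <- list(
    trim_to_core(bis$group_1, sim$expression, panels, trim_config(theta = 2)),
    trim_to_core(bis$group_2, sim$expression, panels, trim_config(theta = 2))
  )
  refined <- refine_panels(cores, sim$expression, panel_config(), sim$annotation)
  xu <- sim$expression[c("gene_id",
                         c(cores[[1]]$sample_id, cores[[2]]$sample_id))]
  sel <- screen_genes(xu, panel_config(), sim$annotation)
  direct <- build_panels(xu, sel$gene_id, panel_config())
  expect_equal(refined$panel_1, direct$panel_1)
  expect_equal(refined$panel_2, direct$panel_2)
  expect_equal(refined$cutoff_radius, direct$cutoff_radius)
  # on a single-tier fixture the refined panels match the initial module split
  expect_setequal(c(refined$panel_1, refined$panel_2),
                  c(panels$panel_1, panels$panel_2))
})

test_that("hierarchical partition recovers the planted two-level tree", {
  sim <- simulate_expression(planted_design(), seed = 42)
  tree <- hierarchical_partition(sim$expression, annotation = sim$annotation)
  td <- tidy(tree)
  expect_equal(max(td$depth), 2)
  expect_equal(sum(!td$is_leaf), 2) # root and the sibling-pair node split
  lc <- leaf_cores(tree)
  truth <- sim$labels$subtype[match(lc$sample_id, sim$labels$sample_id)]
  # each leaf is pure and each subtype maps to exactly one leaf
  expect_true(all(rowSums(table(lc$node, truth) > 0) == 1))
  expect_equal(length(unique(lc$node)), 3)
  # the outgroup B splits off at the root; the sibling pair splits below
  b_leaf <- unique(lc$node[truth == "B"])
  expect_true(b_leaf %in% c("root/1", "root/2"))
  a_leaves <- unique(lc$node[truth != "B"])
  expect_true(all(nchar(a_leaves) > nchar(b_leaf)))
})

test_that("a two-subtype cohort gives a depth-one tree, noise a bare root", {
  sim <- two_subtype_sim()
  tree <- hierarchical_partition(sim$expression, annotation = sim$annotation)
  g <- glance(tree)
  expect_equal(g$max_depth, 1)
  expect_equal(g$n_leaves, 2)
  noise_tree <- hierarchical_partition(noise_expression(seed = 7))
  expect_equal(glance(noise_tree)$n_nodes, 1)
  expect_true(tidy(noise_tree)$is_leaf[1])
})

test_that("identical inputs give byte-identical partition serializations", {
  sim <- simulate_expression(planted_design(), seed = 13)
  t1 <- hierarchical_partition(sim$expression, annotation = sim$annotation)
  t2 <- hierarchical_partition(sim$expression, annotation = sim$annotation)
  expect_identical(jsonlite::toJSON(tidy(t1), digits = NA),
                   jsonlite::toJSON(tidy(t2), digits = NA))
  lc1 <- leaf_cores(t1)
  lc2 <- leaf_cores(t2)
  expect_identical(lc1, lc2)
})

test_that("heat-map export orders rows by panel and columns by join order", {
  sim <- two_subtype_sim()
  panels <- fit_panels(sim)
  bis <- bisect_samples(sim$expression, panels, trim_config())
  cores <- list(
    trim_to_core(bis$group_1, sim$expression, panels, trim_config()),
    trim_to_core(bis$group_2, sim$expression, panels, trim_config())
  )
  hm <- heatmap_order(cores, panels, sim$expression)
  expect_equal(hm$gene_id, c(panels$panel_1, panels$panel_2))
  expect_equal(sum(hm$panel == "panel_1"), length(panels$panel_1))
  expect_equal(setdiff(names(hm), c("gene_id", "panel")),
               c(cores[[1]]$sample_id, cores[[2]]$sample_id))
  expect_equal(attr(hm, "n_samples_1"), nrow(cores[[1]]))
  # values are carried over unchanged
  expect_equal(hm$S001[1],
               sim$expression$S001[sim$expression$gene_id == hm$gene_id[1]])
})
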