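test_that("two-sided add-one p-values follow the counting rule", {
  expect_equal(pvalue_two_sided(0, c(0.5, -1, 2)), 1)
  expect_equal(pvalue_two_sided(2.0, c(0.1, -0.3, 2.5)), 0.5)
  expect_equal(pvalue_two_sided(10, rnorm(99)), 1 / 100)
  # monotone nonincreasing in |observed|
  perm <- rnorm(200)
  ps <- vapply(seq(0, 3, by = 0.1), function(o) pvalue_two_sided(o, perm), 0)
  expect_true(all(diff(ps) <= 0))
  expect_error(pvalue_two_sided(NA, 1:3), "non-finite")
  expect_error(pvalue_two_sided(1, numeric(0)), "empty")
})

test_that("a relabeled copy of a group yields zero differences and p = 1", {
  spec <- generate_true_network(n_groups = 1, sparsity = 0.3, seed = 61,
                                node_labels = c("a", "b", "c"))
  cfg <- simulation_config(n_subjects_per_group = 6, n_days = 3,
                           missing_rate = 0, seed = 62)
  d <- generate_dataset(spec, cfg)
  tab <- suppressMessages(
    nonparanormal_transform(assemble_analysis_table(d)))
  tabB <- tab
  tabB$subject_id <- paste0("copy_", tabB$subject_id)
  tabB$group <- "group2"
  attr(tabB, "node_labels") <- attr(tab, "node_labels")
  res <- permutation_compare(tab, tabB, n_permutations = 50, seed = 3,
                             engine = "ols")
  expect_true(all(abs(res$table$observed) < 1e-10))
  expect_true(all(res$table$p == 1))
})

test_that("Monte-Carlo comparison matches an exhaustive enumeration oracle on 3+3 subjects", {
  spec <- generate_true_network(n_groups = 2, sparsity = 0.4, seed = 63,
                                node_labels = c("a", "b"))
  pair <- simulate_pair(spec, n_subjects = 3, n_days = 3, seed = 64,
                        missing_rate = 0, marginal_maps = "identity",
                        transform = FALSE)
  res <- permutation_compare(pair$A, pair$B, seed = 1, exhaustive = TRUE,
                             engine = "ols", standardize = FALSE,
                             statistics = "edges")
  expect_equal(res$n_permutations, choose(6, 3))

  # oracle: enumerate splits; per group, subject-dummy least squares per node
  oracle <- exhaustive_oracle(pair$A, pair$B, c("a", "b"))
  expect_equal(res$table$observed, oracle$observed, tolerance = 1e-9)
  expect_equal(res$table$p, oracle$p, tolerance = 1e-12)
})

test_that("permutations keep each subject's series intact and are reproducible", {
  spec <- generate_true_network(n_groups = 2, sparsity = 0.3, seed = 65,
                                node_labels = c("a", "b", "c"))
  pair <- simulate_pair(spec, n_subjects = 5, n_days = 3, seed = 66)
  r1 <- permutation_compare(pair$A, pair$B, n_permutations = 60, seed = 9,
                            engine = "ols", keep_splits = TRUE)
  r2 <- permutation_compare(pair$A, pair$B, n_permutations = 60, seed = 9,
                            engine = "ols")
  expect_identical(r1$table$p, r2$table$p)
  # every permuted group-1 is a 5-subject subset of the pooled subjects
  all_subj <- c(paste0("A:", unique(pair$A$subject_id)),
                paste0("B:", unique(pair$B$subject_id)))
  expect_true(all(apply(r1$splits, 2, function(g1)
    length(g1) == 5 && !anyDuplicated(g1) && all(g1 %in% all_subj))))
})

test_that("observed differences equal the two observed-group fits", {
  spec <- generate_true_network(n_groups = 2, sparsity = 0.3, seed = 67,
                                node_labels = c("a", "b", "c"),
                                group_delta = list(from = "a", to = "b",
                                                   delta = 0.2))
  pair <- simulate_pair(spec, n_subjects = 8, n_days = 3, seed = 68)
  res <- permutation_compare(pair$A, pair$B, n_permutations = 30, seed = 4,
                             engine = "ols")
  BA <- fit_temporal_network(build_lagged_design(pair$A), engine = "ols")$B
  BB <- fit_temporal_network(build_lagged_design(pair$B), engine = "ols")$B
  edges <- res$table[res$table$type == "edge", ]
  expect_equal(edges$observed, as.vector(BA - BB), tolerance = 1e-10)
  conn <- res$table[res$table$type == "connectivity", ]
  expect_equal(conn$observed,
               global_connectivity(BA) - global_connectivity(BB),
               tolerance = 1e-10)
  expect_true(all(res$table$p > 0 & res$table$p <= 1))
})
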