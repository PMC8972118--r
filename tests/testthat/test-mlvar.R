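toy_table <- function() {
  set.seed(8)
  df <- expand.grid(beep = 1:8, day = 1:4, subject_id = sprintf("s%02d", 1:6),
                    stringsAsFactors = FALSE)
  df$group <- "g"
  df$a <- rnorm(nrow(df)); df$b <- rnorm(nrow(df))
  make_table(df[, c("subject_id", "group", "day", "beep", "a", "b")],
             c("a", "b"))
}

test_that("lagged design pairs consecutive beeps within days only", {
  df <- data.frame(subject_id = "s1", group = "g",
                   day = c(1, 1, 2, 2, 2), beep = c(3, 4, 1, 2, 4),
                   a = c(1, 2, 3, 4, 6), b = c(0, 1, 0, 1, 0))
  df <- rbind(df, within(df, subject_id <- "s2"))
  d <- build_lagged_design(make_table(df, c("a", "b")))
  # per subject: (d1 b3->b4) and (d2 b1->b2); beep 4 of day 2 is not
  # consecutive, and day 1 -> day 2 is an overnight gap
  expect_equal(nrow(d$y), 4L)
  expect_equal(sort(unique(d$y[, "a"])), c(2, 4))

  # a missing endpoint drops the pair
  df2 <- df
  df2$a[2] <- NA
  d2 <- build_lagged_design(make_table(df2, c("a", "b")))
  expect_equal(nrow(d2$y), 3L)

  df3 <- df[df$beep == 1, ]
  expect_error(build_lagged_design(make_table(df3, c("a", "b"))),
               "no valid lag-1 pairs")
})

test_that("within-person centering makes estimates shift-invariant", {
  tab <- toy_table()
  n1 <- fit_temporal_network(build_lagged_design(tab), engine = "ols")
  tab2 <- tab
  shift <- stats::setNames(rnorm(6, 0, 50), sprintf("s%02d", 1:6))
  tab2$a <- tab2$a + shift[tab2$subject_id]
  n2 <- fit_temporal_network(build_lagged_design(tab2), engine = "ols",
                             standardize = FALSE)
  n1u <- fit_temporal_network(build_lagged_design(tab), engine = "ols",
                              standardize = FALSE)
  expect_equal(n1u$B, n2$B, tolerance = 1e-8)
})

test_that("engines agree with a pooled least-squares oracle when subjects are exchangeable", {
  tab <- toy_table()
  d <- build_lagged_design(tab)
  fit <- fit_temporal_network(d, engine = "ols", standardize = FALSE)
  # oracle: subject-dummy regression via base lm, slopes only
  for (j in 1:2) {
    o <- lm(d$y[, j] ~ d$x + factor(d$subject))
    expect_equal(unname(fit$B[j, ]), unname(coef(o)[2:3]), tolerance = 1e-10)
  }
  # mixed model agrees closely on white-noise data with no subject effects
  fml <- fit_temporal_network(d, engine = "lmm", standardize = FALSE)
  expect_lt(max(abs(fml$B - fit$B)), 0.02)
})

test_that("multilevel estimation rejects a single subject", {
  df <- data.frame(subject_id = "s1", group = "g", day = 1, beep = 1:10,
                   a = rnorm(10), b = rnorm(10))
  expect_error(fit_temporal_network(build_lagged_design(make_table(df, c("a", "b")))),
               "2 subjects")
})

test_that("significant_edges filters, orders, and counts as forced", {
  net <- structure(list(node_labels = letters[1:7],
                        B = matrix(0.1, 7, 7, dimnames = list(letters[1:7], letters[1:7])),
                        SE = matrix(0.01, 7, 7), p = matrix(0.5, 7, 7)),
                   class = "temporal_network")
  net$p[2, 3] <- 0.01
  e <- significant_edges(net, 0.05)
  expect_equal(nrow(e), 1L)
  expect_equal(e$predictor, "c"); expect_equal(e$outcome, "b")

  expect_equal(nrow(significant_edges(net, 1e-9)), 0L)

  net$p[] <- 0.01
  all_e <- significant_edges(net, 0.05)
  expect_equal(nrow(all_e), 49L)
  expect_equal(sum(all_e$predictor == all_e$outcome), 7L)

  # stable ordering: |weight| descending, ties by label
  net$B[3, 1] <- -0.9
  e2 <- significant_edges(net, 0.05)
  expect_equal(e2$weight[1], -0.9)
  expect_true(!is.unsorted(rev(abs(e2$weight))))
})

test_that("network JSON round-trips", {
  tab <- toy_table()
  net <- fit_temporal_network(build_lagged_design(tab), engine = "ols")
  f <- tempfile(fileext = ".json")
  network_to_json(net, f)
  net2 <- network_from_json(f)
  expect_equal(net$B, net2$B, tolerance = 1e-12)
  expect_equal(net$p, net2$p, tolerance = 1e-12)
  expect_equal(net2$n_subjects, 6)
})

test_that("recovery error shrinks with more subjects and longer series", {
  spec <- generate_true_network(n_groups = 1, sparsity = 0.3, seed = 51,
                                random_effect_sd = 0)
  err <- function(n_subj, n_days, seed) {
    cfg <- simulation_config(n_subjects_per_group = n_subj, n_days = n_days,
                             missing_rate = 0, marginal_maps = "identity",
                             seed = seed)
    d <- generate_dataset(spec, cfg)
    tab <- suppressMessages(assemble_analysis_table(d))
    fit <- fit_temporal_network(build_lagged_design(tab), engine = "ols",
                                standardize = FALSE)
    max(abs(fit$B - spec$B[[1]]))
  }
  small <- mean(vapply(1:3, function(s) err(8, 2, s), 0))
  large <- mean(vapply(1:3, function(s) err(40, 7, s + 10), 0))
  expect_lt(large, small)
})
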