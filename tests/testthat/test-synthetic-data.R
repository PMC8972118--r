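test_that("true-network generator honours sparsity and group deltas", {
  # sparsity 0: no off-diagonal edges in either group
  s0 <- generate_true_network(n_groups = 2, sparsity = 0, seed = 1)
  for (B in s0$B) expect_true(all(B[row(B) != col(B)] == 0))

  # a single-edge group delta appears in exactly one cell
  sd <- generate_true_network(
    n_groups = 2, sparsity = 0.3, seed = 2,
    group_delta = list(from = "loneliness", to = "restriction", delta = 0.12))
  D <- sd$B[[2]] - sd$B[[1]]
  expect_equal(D["restriction", "loneliness"], 0.12)
  expect_equal(sum(D != 0), 1L)

  # spectral radii capped
  expect_true(all(vapply(sd$B, emanet:::spectral_radius, 0) <= 0.9))

  # Monte-Carlo: off-diagonal nonzero fraction tracks the sparsity target
  fr <- vapply(1:1000, function(s) {
    B <- generate_true_network(n_groups = 1, sparsity = 0.3, seed = s)$B[[1]]
    mean(B[row(B) != col(B)] != 0)
  }, 0)
  expect_lt(abs(mean(fr) - 0.3), 0.02)
})

test_that("dataset generation is deterministic and respects the schedule", {
  spec <- generate_true_network(n_groups = 2, sparsity = 0.3, seed = 5)
  cfg <- simulation_config(n_subjects_per_group = 5, n_days = 3, seed = 11)
  d1 <- generate_dataset(spec, cfg)
  d2 <- generate_dataset(spec, cfg)
  expect_identical(d1, d2)

  # beeps fall inside 08:00-22:00 and inside their 105-minute block
  hod <- as.numeric(format(d1$timestamp, "%H")) +
    as.numeric(format(d1$timestamp, "%M")) / 60 +
    as.numeric(format(d1$timestamp, "%S")) / 3600
  expect_true(all(hod >= 8 & hod < 22))
  block_start <- 8 + (d1$beep - 1) * 105 / 60
  expect_true(all(hod >= block_start & hod < block_start + 105 / 60))

  # timestamps strictly increasing within subject, keys unique
  for (s in unique(d1$subject_id)) {
    ts <- d1$timestamp[d1$subject_id == s]
    expect_true(all(diff(as.numeric(ts)) > 0))
  }
  expect_false(anyDuplicated(d1[c("subject_id", "day", "beep")]) > 0)

  # observed scales honour their declared ranges
  for (v in c("loneliness", "worry", "restriction", "info_seeking", "stress"))
    expect_true(all(d1[[v]] >= 0 & d1[[v]] <= 100, na.rm = TRUE))
  expect_true(all(d1$social_contact %in% 1:7 | is.na(d1$social_contact)))
  expect_true(all(d1$physical_activity > 0, na.rm = TRUE))
})

test_that("realized MCAR missingness matches the configured rate", {
  spec <- generate_true_network(n_groups = 1, sparsity = 0.3, seed = 6)
  cfg <- simulation_config(n_subjects_per_group = 100, n_days = 7,
                           missing_rate = 0.175, seed = 21)
  d <- generate_dataset(spec, cfg)
  miss <- mean(is.na(d$loneliness))
  expect_lt(abs(miss - 0.175), 0.02)
  # per-subject realized missingness never exceeds 0.5
  per_subj <- tapply(is.na(d$loneliness), d$subject_id, mean)
  expect_true(all(per_subj <= 0.5))
})

test_that("subject matrices are stationary and the latent variance matches theory", {
  spec <- generate_true_network(n_groups = 1, sparsity = 0.4, seed = 7,
                                random_effect_sd = 0.08)
  set.seed(3)
  for (i in 1:25) {
    Bi <- emanet:::draw_subject_matrix(spec$B[[1]], spec$random_effect_sd)
    expect_lt(emanet:::spectral_radius(Bi), 1)
  }
  # long single-subject series: empirical variance vs stationary solution
  p <- 7
  lab <- spec$node_labels
  cfg <- simulation_config(n_subjects_per_group = 1, n_days = 500,
                           beeps_per_day = 8, missing_rate = 0,
                           marginal_maps = "identity", seed = 9)
  spec0 <- true_network_spec(lab, spec$B[[1]], random_effect_sd = 0,
                             innovation_cov = spec$innovation_cov)
  d <- generate_dataset(spec0, cfg)
  # stationary covariance by fixed-point iteration of S = B S B' + Q
  B <- spec$B[[1]]; S <- spec$innovation_cov
  for (i in 1:500) S <- B %*% S %*% t(B) + spec$innovation_cov
  emp <- diag(cov(as.matrix(d[, lab])))
  expect_lt(max(abs(emp - diag(S)) / diag(S)), 0.15)
})

test_that("config invariants are enforced and marginal maps preserve ranks", {
  expect_error(simulation_config(missing_rate = 0.6), "missing_rate")
  expect_error(simulation_config(beeps_per_day = 9, block_minutes = 105),
               "do not fit")
  x <- sort(rnorm(200))
  for (map in list(list(type = "vas", scale = 1),
                   list(type = "lognormal", mu = 0, sigma = 0.3))) {
    y <- emanet:::apply_marginal(x, map)
    expect_true(all(diff(y) > 0))
  }
  lik <- emanet:::apply_marginal(x, list(type = "likert7", latent_sd = 1.2))
  expect_true(all(diff(lik) >= 0))  # monotone with ties
})

test_that("EMA CSV round-trips losslessly", {
  spec <- generate_true_network(n_groups = 2, sparsity = 0.2, seed = 8)
  cfg <- simulation_config(n_subjects_per_group = 4, n_days = 2, seed = 13)
  d <- generate_dataset(spec, cfg)
  f <- tempfile(fileext = ".csv")
  write_ema_csv(d, f)
  d2 <- read_ema_csv(f)
  expect_equal(as.data.frame(d)[, -5], as.data.frame(d2)[, -5],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(as.numeric(d$timestamp) - as.numeric(d2$timestamp))), 1e-2)
})
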