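two_subject_ema <- function() {
  d <- expand.grid(beep = 1:4, day = 1:2, subject_id = c("s1", "s2"),
                   stringsAsFactors = FALSE)
  d$group <- "g1"
  d$timestamp <- as.POSIXct("2021-01-04", tz = "UTC") +
    (d$day - 1) * 86400 + d$beep * 3600
  set.seed(2)
  d$a <- runif(nrow(d), 0, 100)
  d$b <- runif(nrow(d), 0, 100)
  structure(d[, c("subject_id", "group", "day", "beep", "timestamp", "a", "b")],
            node_labels = c("a", "b"), provenance = "synthetic",
            class = c("ema_dataset", "data.frame"))
}

test_that("table assembly joins activity, keeps partial rows, drops heavy missers", {
  ema <- two_subject_ema()
  act <- data.frame(subject_id = "s1", beep_time = ema$timestamp[1],
                    mean_enmo = 33)
  tab <- assemble_analysis_table(ema, act)
  expect_true("physical_activity" %in% attr(tab, "node_labels"))
  expect_equal(sum(!is.na(tab$physical_activity)), 1L)
  expect_equal(tab$physical_activity[tab$subject_id == "s1" &
                                       tab$day == 1 & tab$beep == 1], 33)
  # EMA beeps without an actigraphy window are retained with missing activity
  expect_equal(nrow(tab), nrow(ema))

  # a subject missing > 50% of prompts is excluded with a message
  ema2 <- ema
  ema2$a[ema2$subject_id == "s2"][1:5] <- NA
  ema2$b[ema2$subject_id == "s2"][1:5] <- NA
  expect_message(tab2 <- assemble_analysis_table(ema2), "excluding 1 subject")
  expect_false("s2" %in% tab2$subject_id)
  expect_equal(attr(tab2, "excluded_subjects"), "s2")

  # partial coverage overrides an existing activity column only where the
  # device produced a summary, and ISO-8601 text timestamps are accepted
  ema3 <- ema
  ema3$physical_activity <- 99
  attr(ema3, "node_labels") <- c("a", "b", "physical_activity")
  act3 <- data.frame(subject_id = "s1",
                     timestamp = format(ema$timestamp[1:2],
                                        "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"),
                     mean_enmo = c(41, NA))
  tab3 <- assemble_analysis_table(ema3, act3)
  got <- tab3[tab3$subject_id == "s1" & tab3$day == 1, "physical_activity"]
  expect_equal(got[1:2], c(41, NA))
  expect_true(all(got[-(1:2)] == 99))

  # degenerate joins fail loudly
  expect_error(assemble_analysis_table(
    ema, data.frame(subject_id = "zz", beep_time = ema$timestamp[1],
                    mean_enmo = 1)), "no subjects")
  dup <- rbind(ema, ema[1, ])
  expect_error(assemble_analysis_table(dup), "duplicate")
})

test_that("nonparanormal transform matches the truncated-ECDF oracle exactly", {
  set.seed(5)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    v <- sample(c(rnorm(n), round(rnorm(n), 1)), n)  # mix in ties
    df <- data.frame(subject_id = "s1", group = "g1", day = 1,
                     beep = seq_len(n), x = v)
    out <- nonparanormal_transform(make_table(df, "x"))
    expect_equal(out$x, npn_oracle(v), tolerance = 1e-12)
  }
})

test_that("transform is rank-preserving and invariant to monotone distortion", {
  set.seed(6)
  for (rep in 1:500) {
    n <- sample(10:60, 1)
    v <- rnorm(n)
    df <- data.frame(subject_id = "s1", group = "g1", day = 1,
                     beep = seq_len(n), x = v)
    z <- nonparanormal_transform(make_table(df, "x"))$x
    # order-preserving: no inversions anywhere; strict preservation holds
    # away from the truncated tails
    expect_true(monotone_no_inversions(v, z))
    interior <- z > min(z) & z < max(z)
    expect_identical(rank(z[interior]), rank(v[interior]))
    g <- sample(list(function(u) exp(u), function(u) u^3,
                     function(u) atan(u) * 5), 1)[[1]]
    df2 <- df; df2$x <- g(v)
    expect_equal(nonparanormal_transform(make_table(df2, "x"))$x, z,
                 tolerance = 1e-12)
  }
})

test_that("transform handles ties, idempotence, missing data, and errors", {
  v <- c(3, 1, 3, 2, NA, 3)
  df <- data.frame(subject_id = "s", group = "g", day = 1, beep = 1:6, x = v)
  z <- nonparanormal_transform(make_table(df, "x"))$x
  expect_true(is.na(z[5]))
  expect_equal(length(unique(z[c(1, 3, 6)])), 1L)  # ties map together
  df2 <- df; df2$x <- z
  expect_equal(nonparanormal_transform(make_table(df2, "x"))$x, z,
               tolerance = 1e-12)
  dfc <- df; dfc$x <- 7
  expect_error(nonparanormal_transform(make_table(dfc, "x")), "'x' is constant")
})

test_that("post-transform marginals are approximately standard normal", {
  set.seed(7)
  n <- 800
  df <- data.frame(subject_id = "s", group = "g", day = 1, beep = 1:n,
                   x = rexp(n)^2)
  z <- nonparanormal_transform(make_table(df, "x"))$x
  ks <- suppressWarnings(ks.test(z, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(z)), 0.05)
  expect_lt(abs(sd(z) - 1), 0.05)
})

test_that("group pooling fits separate CDFs per group", {
  df <- data.frame(subject_id = rep(c("s1", "s2"), each = 20),
                   group = rep(c("g1", "g2"), each = 20),
                   day = 1, beep = rep(1:20, 2),
                   x = c(rnorm(20, 0, 1), rnorm(20, 100, 1)))
  z <- nonparanormal_transform(make_table(df, "x"))$x
  # each group is gaussianized around zero despite the location shift
  expect_lt(abs(mean(z[1:20])), 0.2)
  expect_lt(abs(mean(z[21:40])), 0.2)
})
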