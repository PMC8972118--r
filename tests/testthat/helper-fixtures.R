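# Shared fixtures and independent oracles used across test files.

# Wrap a plain data.frame as an analysis_table.
make_table <- function(df, labels) {
  structure(df, node_labels = labels, groups = unique(df$group),
            class = c("analysis_table", "data.frame"))
}

# Long table of independent series, one per subject: x[t] = phi x[t-1] + e
# (phi = 1 gives a random walk). Beeps run within a single day per block of
# `beeps` so no pairs are lost to day boundaries unless n_days > 1.
make_ar_table <- function(n_subjects, n_beeps, phi, seed, n_days = 1,
                          group = "g1", label = "x") {
  set.seed(seed)
  rows <- lapply(seq_len(n_subjects), function(s) {
    per_day <- n_beeps %/% n_days
    e <- rnorm(n_beeps)
    x <- numeric(n_beeps)
    x[1] <- if (phi < 1) rnorm(1, 0, sqrt(1 / (1 - phi^2))) else e[1]
    for (t in 2:n_beeps) x[t] <- phi * x[t - 1] + e[t]
    data.frame(subject_id = sprintf("s%03d", s), group = group,
               day = rep(seq_len(n_days), each = per_day),
               beep = rep(seq_len(per_day), n_days), x = x)
  })
  make_table(do.call(rbind, rows), label)
}

# Independent truncated-ECDF gaussianization oracle (naive loops).
npn_oracle <- function(v) {
  n <- length(v)
  delta <- 1 / (4 * n^(1 / 4) * sqrt(pi * log(n)))
  sapply(v, function(vi) {
    # average-tie rank via explicit counting
    r <- sum(v < vi) + (sum(v == vi) + 1) / 2
    qnorm(min(max(r / n, delta), 1 - delta))
  })
}

# Brute-force per-sample ENMO oracle with explicit epoch loop.
enmo_oracle <- function(time, x, y, z, epoch_length) {
  v <- numeric(length(x))
  for (i in seq_along(x)) {
    r <- sqrt(x[i]^2 + y[i]^2 + z[i]^2) - 1000
    v[i] <- max(r, 0)
  }
  ep <- floor((time - time[1]) / epoch_length)
  out <- data.frame(epoch = sort(unique(ep)), enmo = NA_real_)
  for (k in seq_len(nrow(out)))
    out$enmo[k] <- mean(v[ep == out$epoch[k]])
  out
}

# Closed-form Welch statistics.
welch_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# z must be a nondecreasing function of v (ties in v map to one z value;
# distinct v values never invert). Tail truncation of the gaussianization
# may merge extreme ranks, so strict rank equality is not required there.
monotone_no_inversions <- function(v, z) {
  o <- order(v)
  ties_ok <- all(tapply(z, v, function(u) length(unique(u)) == 1L))
  ties_ok && !is.unsorted(z[o])
}

# Independent exhaustive permutation oracle for edge differences: every
# subject split is enumerated; each group network is fit by subject-dummy
# least squares via base lm (no package estimation code). Unstandardized.
exhaustive_oracle <- function(tabA, tabB, labels) {
  tab <- rbind(as.data.frame(tabA), as.data.frame(tabB))
  tab$subject_id <- paste0(rep(c("A:", "B:"), c(nrow(tabA), nrow(tabB))),
                           tab$subject_id)
  p <- length(labels)
  fitB <- function(ids) {
    sub <- tab[tab$subject_id %in% ids, ]
    sub <- sub[order(sub$subject_id, sub$day, sub$beep), ]
    i <- seq_len(nrow(sub) - 1)
    ok <- sub$subject_id[i] == sub$subject_id[i + 1] &
      sub$day[i] == sub$day[i + 1] & sub$beep[i + 1] - sub$beep[i] == 1
    X <- as.matrix(sub[, labels, drop = FALSE])[i, , drop = FALSE][ok, , drop = FALSE]
    subj <- factor(sub$subject_id[i][ok])
    B <- matrix(NA_real_, p, p)
    for (j in seq_len(p)) {
      y <- sub[[labels[j]]][i + 1][ok]
      B[j, ] <- coef(lm(y ~ X + subj))[2:(p + 1)]
    }
    B
  }
  subs <- unique(tab$subject_id)
  obsA <- subs[startsWith(subs, "A:")]
  observed <- as.vector(fitB(obsA) - fitB(setdiff(subs, obsA)))
  splits <- combn(subs, length(obsA))
  perm <- apply(splits, 2, function(g1)
    as.vector(fitB(g1) - fitB(setdiff(subs, g1))))
  perm <- matrix(perm, nrow = p * p)
  pv <- vapply(seq_along(observed), function(k)
    mean(abs(perm[k, ]) >= abs(observed[k]) - 1e-12), 0)
  list(observed = observed, p = pv, n_splits = ncol(splits))
}

# Two-group dataset pair from one generating spec, returned as split
# analysis tables ready for permutation comparison.
simulate_pair <- function(spec, n_subjects, n_days, seed,
                          missing_rate = 0.175, marginal_maps = "ema",
                          transform = TRUE) {
  cfg <- simulation_config(n_subjects_per_group = n_subjects,
                           n_days = n_days, missing_rate = missing_rate,
                           marginal_maps = marginal_maps, seed = seed)
  d <- generate_dataset(spec, cfg)
  tab <- suppressMessages(assemble_analysis_table(d))
  if (transform) tab <- nonparanormal_transform(tab)
  split_group <- function(g) {
    s <- tab[tab$group == g, , drop = FALSE]
    attr(s, "node_labels") <- attr(tab, "node_labels")
    class(s) <- class(tab)
    s
  }
  list(A = split_group("group1"), B = split_group("group2"))
}
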