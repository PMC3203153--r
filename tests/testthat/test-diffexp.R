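make_bundle <- function(values, detection = NULL) {
  n_pat <- ncol(values) / 2
  patients <- sprintf("P%02d", seq_len(n_pat))
  colnames(values) <- c(paste0(patients, "_T"), paste0(patients, "_N"))
  if (is.null(detection)) {
    detection <- matrix(TRUE, nrow(values), ncol(values))
  }
  dimnames(detection) <- dimnames(values)
  expression_bundle(
    values, detection,
    tibble::tibble(
      sample_id = colnames(values),
      patient_id = rep(patients, 2),
      tissue = rep(c("tumor", "normal"), each = n_pat)
    )
  )
}

test_that("detection filter keeps exactly the features detected somewhere", {
  v <- matrix(runif(3 * 12, 1, 10), 3, 12,
    dimnames = list(c("g1", "g2", "g3"), NULL)
  )
  det <- matrix(TRUE, 3, 12)
  det[2, ] <- FALSE
  b <- make_bundle(v, det)
  out <- detection_filter(b)
  expect_identical(rownames(out$values), c("G1", "G3"))

  all_b <- make_bundle(v)
  expect_identical(detection_filter(all_b)$values, all_b$values)

  # oracle: per-row any()
  set.seed(42)
  v2 <- matrix(runif(50 * 12, 1, 10), 50, 12,
    dimnames = list(sprintf("g%02d", 1:50), NULL)
  )
  det2 <- matrix(runif(50 * 12) < 0.1, 50, 12)
  b2 <- make_bundle(v2, det2)
  expect_identical(
    rownames(detection_filter(b2)$values),
    rownames(b2$values)[apply(b2$detection, 1, any)]
  )
})

test_that("log2 median centering matches hand arithmetic and zeroes every median", {
  v <- matrix(c(2, 4, 16), 3, 1)
  v <- cbind(v, v) # one patient pair, identical columns
  rownames(v) <- c("a", "b", "c")
  out <- log2_median_center(make_bundle(v))
  expect_equal(unname(out$values[, 1]), c(-1, 0, 2))
  expect_identical(out$scale, "log2_centered")

  set.seed(7)
  v2 <- matrix(runif(40 * 8, 0.5, 100), 40, 8,
    dimnames = list(sprintf("g%02d", 1:40), NULL)
  )
  out2 <- log2_median_center(make_bundle(v2))
  expect_equal(unname(apply(out2$values, 2, median)), rep(0, 8))

  v3 <- v2; v3[1, 1] <- -1
  expect_error(make_bundle(v3), "strictly positive")
})

test_that("consistent-direction filter applies the strict per-pair sign rule", {
  d <- rbind(
    up = c(1, 2, 0.5),
    none_mixed = c(1, -1, 1),
    none_zero = c(1, 1, 0),
    down = c(-0.2, -3, -1)
  )
  res <- consistent_direction(delta_bundle(d))
  expect_identical(res$direction, c("up", "none", "none", "down"))
  expect_equal(res$mean_delta[1], mean(c(1, 2, 0.5)))

  # oracle: brute-force sign scan on random matrices
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rnorm(50 * 6), 50, 6,
      dimnames = list(sprintf("g%02d", 1:50), NULL)
    )
    m[sample(length(m), 20)] <- 0 # plant exact zeros
    res <- consistent_direction(delta_bundle(m))
    expect_identical(res$direction, unname(oracle_direction(m)))
  }
})

test_that("up/down/none partition the feature set exactly", {
  set.seed(13)
  m <- matrix(rnorm(200 * 6, sd = 2), 200, 6,
    dimnames = list(sprintf("g%03d", 1:200), NULL)
  )
  res <- consistent_direction(delta_bundle(m))
  expect_equal(
    sum(res$direction == "up") + sum(res$direction == "down") +
      sum(res$direction == "none"),
    200
  )
  expect_setequal(unique(res$direction), c("up", "down", "none"))
})

test_that("paired d statistic matches the closed form and its limits", {
  expect_equal(sam_paired_d(c(0, 0, 0), 0.1), 0)
  expect_equal(sam_paired_d(c(1, 2, 3), 0), 2 / (1 / sqrt(3)))
  expect_error(sam_paired_d(c(1), 0.1), "at least 2")
  expect_error(sam_paired_d(c(1, 1, 1), 0), "degenerate scatter")

  # |d| strictly decreasing in s0
  deltas <- c(0.4, 1.1, 0.7, 0.9)
  ds <- vapply(c(0, 0.1, 0.5, 2), function(s0) abs(sam_paired_d(deltas, s0)),
    numeric(1)
  )
  expect_true(all(diff(ds) < 0))

  # s0 = 0 equals the one-sample t statistic
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(6)
    expect_equal(sam_paired_d(x, 0), unname(t.test(x)$statistic))
  }
})

test_that("permutation q-values: constant-zero data are never significant", {
  m <- matrix(0, 20, 4, dimnames = list(sprintf("g%02d", 1:20), NULL))
  res <- sam_permutation_test(m, sam_config(n_permutations = 16))
  expect_true(all(res$q == 1))
  expect_true(res$exhaustive)
})

test_that("a strongly shifted feature attains the minimum q-value", {
  set.seed(21)
  m <- matrix(rnorm(201 * 6), 201, 6)
  m[201, ] <- 10 + rnorm(6) # ~10 sigma planted shift
  rownames(m) <- sprintf("g%03d", 1:201)
  res <- suppressMessages(sam_permutation_test(m, sam_config(rng_seed = 9)))
  expect_equal(which.min(res$q), 201)
  expect_lt(res$q[201], min(res$q[-201]) + 1e-12)
})

test_that("exhaustive enumeration replaces sampling when 2^n fits the budget", {
  set.seed(2)
  m <- matrix(rnorm(30 * 5), 30, 5, dimnames = list(sprintf("g%02d", 1:30), NULL))
  expect_message(
    res <- sam_permutation_test(m, sam_config(n_permutations = 1000)),
    "exhaustive"
  )
  expect_identical(res$n_permutations, 32L)
  # deterministic regardless of seed when exhaustive
  res2 <- suppressMessages(
    sam_permutation_test(m, sam_config(n_permutations = 1000, rng_seed = 99))
  )
  expect_identical(res$q, res2$q)
})

test_that("sampled permutations are reproducible from the seed", {
  set.seed(3)
  m <- matrix(rnorm(40 * 12), 40, 12,
    dimnames = list(sprintf("g%02d", 1:40), NULL)
  )
  cfg <- sam_config(n_permutations = 200, rng_seed = 4)
  r1 <- sam_permutation_test(m, cfg)
  r2 <- sam_permutation_test(m, cfg)
  expect_identical(r1$q, r2$q)
  expect_false(r1$exhaustive)
})

test_that("percentages reproduce printed-report arithmetic with half-up rounding", {
  expect_equal(percent_of(13, 581), 2.24)
  expect_equal(percent_of(0, 100), 0)
  expect_equal(percent_of(48841, 70320), 69.46)
  expect_equal(percent_of(26, 581), 4.48) # 4.47504 rounds half-up
  expect_error(percent_of(1, 0), "positive")
  expect_equal(round_half_up(2.675, 2), 2.68)
  expect_equal(round_half_up(-2.675, 2), -2.68)
})

test_that("tidy/glance/autoplot expose the fit as tables and a plot", {
  sim <- generate_bundle(sim_config(n_genes = 120, n_mirnas = 20, rng_seed = 6))
  fit <- suppressMessages(diff_expression(sim$mrna))
  tab <- tidy(fit)
  expect_named(tab, c("feature_id", "direction", "mean_delta", "d_stat", "q_value"))
  expect_true(all(tab$q_value >= 0 & tab$q_value <= 1))
  g <- glance(fit)
  expect_equal(g$n_up + g$n_down + sum(tab$direction == "none"), g$n_features)
  expect_s3_class(autoplot(fit), "ggplot")
})
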