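test_that("pooling averages consecutive groups and conserves the grand mean", {
  expect_equal(pool_trials(c(1, 2, 3, 4), 4), 2.5)
  expect_equal(pool_trials(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  expect_equal(pool_trials(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5, 5))
  expect_error(pool_trials(1:4, 0), "k must be")

  set.seed(19)
  x <- rnorm(40)
  pooled <- pool_trials(x, 4)
  expect_length(pooled, 10)
  expect_equal(pooled,
               vapply(split(x, rep(1:10, each = 4)), mean, numeric(1)),
               ignore_attr = TRUE)
  expect_equal(mean(pooled), mean(x))  # all groups full
})

test_that("recruitment curves pair pooled sizes with the intensity ladder", {
  sched <- rep(seq(5, 13, 2), each = 4)
  trials <- data.frame(reference = seq_along(sched),
                       target = rev(seq_along(sched)))
  rc <- build_recruitment_curve(trials, sched, pool = 4)
  expect_equal(rc$points$intensity, seq(5, 13, 2))
  expect_equal(rc$points$n, rep(4L, 5))
  expect_equal(rc$m_max, max(rc$points$reference))
  expect_equal(rc$h_max, max(rc$points$target))

  # constant-intensity run: a single-valued curve
  one <- build_recruitment_curve(data.frame(reference = c(2, 4, 6, 8),
                                            target = c(1, 1, 1, 1)),
                                 rep(20, 4), pool = 4)
  expect_equal(nrow(one$points), 1L)
  expect_equal(one$m_max, 5)

  # schedule length mismatch falls back to the group index with a warning
  expect_warning(
    rc2 <- build_recruitment_curve(trials, sched[-1], pool = 4),
    "schedule"
  )
  expect_equal(rc2$points$intensity, 1:5)
})

test_that("a noise-free sweep yields the canonical recruitment shapes", {
  set.seed(31)
  p <- silent_participant()
  tab <- simulate_sweep(p, seq(5, 41, 2), 4)
  rc <- build_recruitment_curve(tab, tab$intensity_mA, pool = 4)
  # M-wave rises then saturates (nondecreasing); H-reflex rises then falls
  expect_true(all(diff(rc$points$reference) >= -1e-9))
  peak <- which.max(rc$points$target)
  expect_gt(peak, 1)
  expect_lt(peak, nrow(rc$points))
  expect_true(all(diff(rc$points$target[1:peak]) >= -1e-9))
  expect_true(all(diff(rc$points$target[peak:nrow(rc$points)]) <= 1e-9))
})

test_that("distribution summaries and percentile lines are definitional", {
  d <- compute_distribution(1:100, percentile = 66)
  expect_equal(d$percentile_lines[["down"]],
               as.numeric(quantile(1:100, 0.66, type = 7)))
  expect_equal(d$percentile_lines[["up"]],
               as.numeric(quantile(1:100, 0.34, type = 7)))
  expect_equal(d$mean, 50.5)
  expect_equal(compute_distribution(7)$median, 7)
  expect_error(compute_distribution(numeric(0)), "empty")

  set.seed(23)
  u <- runif(10000)
  expect_lt(abs(compute_distribution(u, 66)$percentile_lines[["down"]] - 0.66),
            0.02)
})

test_that("criteria classify the defining sample at the target fraction", {
  set.seed(29)
  for (rep_i in 1:10) {
    n <- sample(c(20, 75, 500), 1)
    x <- rlnorm(n)
    P <- sample(c(25, 50, 66, 90), 1)
    crit <- criterion_from_distribution(x, P, "down")
    frac <- mean(classify_trial(x, crit))
    expect_gte(frac, P / 100 - 1 / n - 1e-12)
    expect_lte(frac, P / 100 + 1 / n + 1e-12)
    # up/down symmetry of thresholds
    up <- criterion_from_distribution(x, 100 - P, "up")
    expect_equal(up$threshold, crit$threshold)
  }
  # boundary: up-conditioning at P = 100 -> threshold is the minimum
  x <- rlnorm(50)
  b <- criterion_from_distribution(x, 100, "up")
  expect_equal(b$threshold, min(x))
  expect_true(all(classify_trial(x, b)))
  expect_error(criterion_from_distribution(x, 0, "down"), "percentile")
})

test_that("trial classification uses the declared tie rule", {
  crit <- structure(list(direction = "down", threshold = 3.0,
                         target_percentile = 66),
                    class = "conditioning_criterion")
  expect_true(classify_trial(2.9, crit))
  expect_false(classify_trial(3.1, crit))
  expect_true(classify_trial(3.0, crit))  # tie counts as success
  up <- structure(list(direction = "up", threshold = 3.0,
                       target_percentile = 66),
                  class = "conditioning_criterion")
  expect_true(classify_trial(3.0, up))
  expect_false(classify_trial(2.9, up))
})

test_that("the cumulative success rate matches the brute-force ratio", {
  expect_equal(success_rate(c(TRUE, TRUE, FALSE)),
               c(100, 100, 200 / 3))
  expect_equal(success_rate(rep(TRUE, 5)), rep(100, 5))
  expect_length(success_rate(logical(0)), 0)
  set.seed(37)
  o <- runif(200) < 0.6
  brute <- vapply(seq_along(o), function(i) 100 * sum(o[1:i]) / i, numeric(1))
  expect_equal(success_rate(o), brute)
})

test_that("reference stability flags deviations beyond tolerance", {
  r <- assess_reference_stability(rep(4, 20), nominal = 4)
  expect_false(r$flagged)
  expect_true(is.na(r$first_flagged_trial))

  r2 <- assess_reference_stability(rep(5, 20), nominal = 4,
                                   tolerance_pct = 15)
  expect_true(r2$flagged)  # run mean 25% above nominal

  # drift onset: the first flagged trial matches a brute-force scan
  sizes <- 4 * (1 + seq(0, 0.4, length.out = 30))
  r3 <- assess_reference_stability(sizes, 4, 15)
  expect_equal(r3$first_flagged_trial,
               which(abs(sizes - 4) / 4 > 0.15)[1])
  expect_error(assess_reference_stability(sizes, 0), "nominal")
})
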