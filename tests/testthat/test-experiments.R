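test_that("linear_fit recovers exact lines and matches the closed form", {
  x <- c(1, 2, 3, 4)
  expect_equal(linear_fit(x, x), c(alpha = 1, beta = 0), tolerance = 1e-12)
  expect_equal(linear_fit(x, 0.5 * x + 0.2), c(alpha = 0.5, beta = 0.2),
               tolerance = 1e-12)
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(20); y <- rnorm(20)
    f <- linear_fit(x, y)
    slope <- cov(x, y) / var(x)
    expect_equal(unname(f["alpha"]), slope, tolerance = 1e-10)
    expect_equal(unname(f["beta"]), mean(y) - slope * mean(x), tolerance = 1e-10)
  }
  expect_error(linear_fit(rep(1, 3), 1:3), "constant")
})

test_that("r_squared equals 1 - SS_res/SS_tot and vanishes for noise", {
  x <- 1:10
  expect_equal(r_squared(x, 2 * x - 3), 1, tolerance = 1e-12)
  set.seed(32)
  for (i in 1:5) {
    x <- rnorm(30); y <- 0.4 * x + rnorm(30)
    fit <- lm(y ~ x)
    expect_equal(r_squared(x, y),
                 1 - sum(resid(fit)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-10)
  }
  x <- rnorm(1000); y <- rnorm(1000)
  expect_lt(r_squared(x, y), 0.05)
  expect_error(r_squared(rep(1, 3), 1:3), "zero variance")
})

test_that("find_transition locates the logistic inflection", {
  grid <- seq(2, 6, 0.1)
  curve <- 1 / (1 + exp(-(grid - 4)))
  expect_equal(as.numeric(find_transition(grid, curve, "ascending_sigmoid")), 4)
  # descending mode on the mirrored curve
  expect_equal(as.numeric(find_transition(grid, 1 - curve, "descending_segment")), 4)
})

test_that("find_transition handles degenerate curves per the tie-break rule", {
  grid <- seq(1, 3, 0.5)
  expect_warning(
    t_lin <- find_transition(grid, 2 * grid, "ascending_sigmoid"),
    "constant")
  expect_equal(as.numeric(t_lin), 1)  # smallest grid tau on ties
  expect_error(find_transition(grid, rep(1, 5), "ascending_sigmoid"),
               "no transition")
  expect_error(suppressWarnings(
    find_transition(grid, 2 * grid, "descending_segment")), "descending")
  expect_error(find_transition(grid[1:2], 1:2), "3 grid points")
})

test_that("derive_seed is deterministic, distinct and within integer range", {
  s1 <- derive_seed(1, "sweep", 3.25, 4)
  expect_identical(s1, derive_seed(1, "sweep", 3.25, 4))
  expect_true(s1 >= 0 && s1 < 2^31 - 1)
  seeds <- vapply(1:500, function(i) derive_seed(7, "x", i), integer(1))
  expect_equal(anyDuplicated(seeds), 0L)
})

test_that("tau_sweep emits well-formed aggregates on a toy system", {
  sw <- tau_sweep("normal", p_random = 0.2, tau_grid = c(0.5, 1, 2),
                  reps = 2, r = 50, seed = 5, n = 12)
  expect_equal(nrow(sw$data), 6)
  expect_equal(sw$summary$tau, c(0.5, 1, 2))
  expect_equal(sw$summary$reps, rep(2L, 3))
  expect_true(all(is.finite(sw$summary$mean_Q)))
  expect_true(all(sw$data$outliers >= 0 & sw$data$outliers <= 1))
  # bit-for-bit reproducible from (config, seed)
  sw2 <- tau_sweep("normal", p_random = 0.2, tau_grid = c(0.5, 1, 2),
                   reps = 2, r = 50, seed = 5, n = 12)
  expect_identical(sw$data, sw2$data)
  expect_error(tau_sweep("normal", 0.2, c(1, 2), reps = 1, r = 10, seed = 1),
               "2 replicates")
})

test_that("modularity_distributions returns one Q per replicate per tau", {
  d <- modularity_distributions("lognormal", c(1, 2), reps = 3, r = 40,
                                seed = 8, n = 12)
  expect_equal(nrow(d), 6)
  expect_equal(as.vector(table(d$tau)), c(3L, 3L))
  expect_true(all(d$class %in% c("modular", "intermediate", "centralized")))
})

test_that("initial_final_correlation pairs up replicates reproducibly", {
  c1 <- initial_final_correlation("normal", tau = 1, reps = 5, r = 40,
                                  seed = 9, n = 12)
  expect_equal(nrow(c1$pairs), 5)
  expect_true(abs(c1$rho) <= 1)
  c2 <- initial_final_correlation("normal", tau = 1, reps = 5, r = 40,
                                  seed = 9, n = 12)
  expect_identical(c1$pairs, c2$pairs)
})

test_that("two_stage shares stage 1 across tau_test values", {
  ts <- two_stage("normal", tau_transition = 1.5, tau_test = c(1, 2),
                  reps = 3, r1 = 30, r2 = 30, seed = 11, n = 12)
  p1 <- ts$pairs[ts$pairs$tau_test == 1, ]
  p2 <- ts$pairs[ts$pairs$tau_test == 2, ]
  expect_identical(p1$Q_4000, p2$Q_4000)   # same stage-1 networks
  expect_identical(p1$Q_initial, p2$Q_initial)
  expect_false(identical(p1$Q_8000, p2$Q_8000))
  expect_equal(nrow(ts$fits), 2)
  expect_true(all(ts$fits$r2 >= 0 & ts$fits$r2 <= 1))
})

test_that("bootstrap_r2 honours the resampling contract", {
  line <- cbind(seq(0, 1, length.out = 250), seq(0, 1, length.out = 250) * 2 + 1)
  b <- bootstrap_r2(line, reps_boot = 50, seed = 3)
  expect_equal(b$mean, 1, tolerance = 1e-12)
  expect_equal(b$sd, 0, tolerance = 1e-12)

  set.seed(4)
  noisy <- cbind(rnorm(300), rnorm(300))
  b1 <- bootstrap_r2(noisy, reps_boot = 100, seed = 12)
  b2 <- bootstrap_r2(noisy, reps_boot = 100, seed = 12)
  expect_identical(b1$values, b2$values)
  expect_length(b1$values, 100)

  small <- noisy[1:50, ]
  expect_error(bootstrap_r2(small, strict = TRUE), "at least 200")
  expect_warning(b3 <- bootstrap_r2(small, reps_boot = 20, seed = 1), "using all")
  expect_length(b3$values, 20)
})
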