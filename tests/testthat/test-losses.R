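test_that("dice loss matches hand-computed values and its endpoints", {
  ## perfect one-hot prediction -> 0
  y <- c(0L, 1L, 2L, 1L)
  P <- matrix(0, 4, 3); P[cbind(1:4, y + 1L)] <- 1
  expect_lt(dice_loss(P, y), 1e-5)

  ## one-hot prediction of a class disjoint from truth -> ~1
  Pwrong <- matrix(0, 4, 3); Pwrong[, 3] <- 1
  expect_gt(dice_loss(Pwrong, c(0L, 1L, 0L, 1L)), 1 - 1e-5)

  ## 2-pixel 2-class case against scalar arithmetic
  P2 <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  y2 <- c(0L, 1L)
  eps <- 1e-6
  d0 <- 2 * 0.8 / (0.8^2 + 0.4^2 + 1 + eps)
  d1 <- 2 * 0.6 / (0.2^2 + 0.6^2 + 1 + eps)
  expect_equal(dice_loss(P2, y2), 1 - (d0 + d1) / 2, tolerance = 1e-12)

  expect_error(dice_loss(P2, c(255L, 255L)), "ignored")
})

test_that("focal loss matches the scalar formula and reduces to cross-entropy", {
  ## single pixel, T = 2, p = (0.9, 0.1), true class 0, gamma = 2
  cfg <- loss_config(gamma = 2, beta = c(1, 1))
  val <- focal_loss(matrix(c(0.9, 0.1), 1), 0L, cfg)
  expect_equal(val, 2 * (1 - 0.9)^2 * (-log(0.9)), tolerance = 1e-10)

  ## perfect one-hot prediction -> ~0 (within the probability clamp)
  P <- matrix(0, 5, 3); yy <- c(0L, 1L, 2L, 0L, 1L)
  P[cbind(1:5, yy + 1L)] <- 1
  expect_lt(focal_loss(P, yy, cfg <- loss_config(gamma = 2, beta = rep(1, 3))), 1e-5)

  ## gamma = 0, beta = 1: equals one-vs-rest cross-entropy (independent oracle)
  set.seed(11)
  P <- rand_prob(64, 4)
  y <- sample(0:3, 64, TRUE)
  ce <- 0
  for (i in 1:64) for (t in 0:3) {
    h <- if (y[i] == t) P[i, t + 1] else 1 - P[i, t + 1]
    ce <- ce - log(min(max(h, 1e-7), 1 - 1e-7))
  }
  cfg0 <- loss_config(gamma = 0, beta = rep(1, 4))
  expect_equal(focal_loss(P, y, cfg0), ce / 64, tolerance = 1e-6)

  expect_error(focal_loss(P, y, loss_config(beta = c(1, 1))), "beta")
})

test_that("focal loss strictly decreases as the true-class probability grows", {
  cfg <- loss_config(gamma = 2, beta = c(1, 1, 1))
  ps <- seq(0.2, 0.95, by = 0.05)
  vals <- vapply(ps, function(p) {
    P <- matrix(c(p, (1 - p) / 2, (1 - p) / 2), 1)
    focal_loss(P, 0L, cfg)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("supervised loss interpolates linearly between dice and focal", {
  set.seed(5)
  P <- rand_prob(32, 3)
  y <- sample(0:2, 32, TRUE)
  d <- dice_loss(P, y)
  f <- focal_loss(P, y, loss_config())
  expect_equal(supervised_loss(P, y, loss_config(rho = 0)), d)
  expect_equal(supervised_loss(P, y, loss_config(rho = 1)), f)
  for (rho in c(0.25, 0.5, 0.75))
    expect_equal(supervised_loss(P, y, loss_config(rho = rho)),
                 (1 - rho) * d + rho * f, tolerance = 1e-12)
})

test_that("losses are invariant to permuting pixel order", {
  set.seed(8)
  P <- rand_prob(40, 3)
  y <- sample(c(0:2, 255L), 40, TRUE)
  perm <- sample(40)
  cfg <- loss_config(beta = rep(1, 3))
  expect_equal(dice_loss(P, y), dice_loss(P[perm, ], y[perm]), tolerance = 1e-12)
  expect_equal(focal_loss(P, y, cfg), focal_loss(P[perm, ], y[perm], cfg),
               tolerance = 1e-12)
})

test_that("consistency loss matches brute-force MSE and its closed forms", {
  set.seed(3)
  for (k in 1:20) {
    A <- rand_prob(4, 2); B <- rand_prob(4, 2)
    bf <- mean((A - B)^2)
    expect_equal(consistency_loss(A, B), bf, tolerance = 1e-12)
    expect_equal(consistency_loss(B, A), bf, tolerance = 1e-12)  # symmetric
  }
  A <- rand_prob(10, 3)
  expect_identical(consistency_loss(A, A), 0)
  ## constant offset d at every entry -> d^2
  d <- 0.01
  expect_equal(consistency_loss(A, A + d), d^2, tolerance = 1e-12)
  expect_error(consistency_loss(A, rand_prob(9, 3)), "shape")
})

test_that("lambda ramp has the Gaussian ramp-up shape", {
  cfg <- loss_config(lambda_max = 1, ramp_length = 100L)
  expect_equal(lambda_schedule(0, cfg), exp(-5), tolerance = 1e-12)
  expect_equal(lambda_schedule(50, cfg), exp(-1.25), tolerance = 1e-12)
  expect_identical(lambda_schedule(100, cfg), 1)
  expect_identical(lambda_schedule(250, cfg), 1)
  steps <- 0:120
  vals <- lambda_schedule(steps, cfg)
  expect_true(all(diff(vals) >= 0))                     # monotone
  cfg2 <- loss_config(lambda_max = 0.5, ramp_length = 10L)
  expect_equal(lambda_schedule(10, cfg2), 0.5)
  expect_error(lambda_schedule(3, loss_config()), "ramp_length")
})

test_that("total loss is sup + lambda * con", {
  expect_identical(total_loss(0.4, 0.1, 0.5), 0.45)
  expect_identical(total_loss(0.4, 0.1, 0), 0.4)
  expect_identical(total_loss(0.4, 0, 1), 0.4)
  expect_error(total_loss(0.4, 0.1, -1), "nonnegative")
})

test_that("class weights are inverse-frequency, mean-1 and positive", {
  lab <- matrix(c(rep(0L, 30), rep(1L, 9), 255L), 5, 8)
  w <- class_weights(list(lab), 3)
  expect_equal(mean(w), 1)
  expect_true(all(w > 0))
  expect_gt(w[2], w[1])          # rarer class gets a larger weight
  expect_equal(w[1] / w[2], 9 / 30, tolerance = 1e-12)
  expect_equal(w[3], max(w))     # absent class capped at the largest weight
})
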