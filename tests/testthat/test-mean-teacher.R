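make_pair <- function(seed = 1, width = 4) {
  model_pair(net_build(network_config(3, "tiny", base_width = width), seed = seed))
}

test_that("EMA update follows theta* <- alpha theta* + (1 - alpha) theta", {
  pair <- make_pair(1)
  set.seed(2)
  pair$student$params <- stabseg:::param_map(pair$student$params,
                                            function(x) x + stats::rnorm(length(x)))
  ## alpha = 0 copies the student exactly
  p0 <- ema_update(pair, alpha = 0)
  expect_identical(p0$teacher$params, pair$student$params)
  ## alpha = 1 leaves the teacher unchanged
  p1 <- ema_update(pair, alpha = 1)
  expect_identical(p1$teacher$params, pair$teacher$params)
  expect_identical(p1$student$params, pair$student$params)  # student untouched
  ## scalar check: theta* = 1, theta = 0, alpha = 0.99 -> 0.99
  ps <- pair
  ps$teacher$params <- stabseg:::param_map(ps$teacher$params, function(x) x * 0 + 1)
  ps$student$params <- stabseg:::param_map(ps$student$params, function(x) x * 0)
  out <- ema_update(ps, alpha = 0.99)
  expect_true(all(abs(stabseg:::param_flatten(out$teacher$params) - 0.99) < 1e-15))
})

test_that("teacher converges geometrically to a constant student", {
  for (alpha in c(0.99, 0.999)) {
    pair <- make_pair(3)
    theta_c <- stabseg:::param_flatten(pair$student$params)
    ## displace the teacher, then update k times with the student fixed
    pair$teacher$params <- stabseg:::param_map(pair$teacher$params, function(x) x + 1)
    gap0 <- stabseg:::param_flatten(pair$teacher$params) - theta_c
    for (k in 1:20) pair <- ema_update(pair, alpha = alpha)
    gap <- stabseg:::param_flatten(pair$teacher$params) - theta_c
    expect_equal(gap, alpha^20 * gap0, tolerance = 1e-12)
  }
})

test_that("the smoothing coefficient switches at the ramp-up boundary", {
  cfg <- ema_config(alpha_rampup = 0.5, alpha_main = 0.9, rampup_steps = 10L)
  pair <- make_pair(4)
  pair$teacher$params <- stabseg:::param_map(pair$teacher$params, function(x) x * 0 + 1)
  pair$student$params <- stabseg:::param_map(pair$student$params, function(x) x * 0)
  pair$step <- 10L   # on the boundary: ramp-up alpha applies
  out <- ema_update(pair, cfg)
  expect_equal(stabseg:::param_flatten(out$teacher$params)[1], 0.5, tolerance = 1e-15)
  pair$step <- 11L   # past it: main alpha applies
  out <- ema_update(pair, cfg)
  expect_equal(stabseg:::param_flatten(out$teacher$params)[1], 0.9, tolerance = 1e-15)
})

test_that("teacher parameters stay within the convex hull of student history", {
  set.seed(12)
  pair <- make_pair(5)
  lo <- hi <- stabseg:::param_flatten(pair$student$params)
  for (k in 1:15) {
    pair$student$params <- stabseg:::param_map(pair$student$params,
                                               function(x) x + stats::rnorm(length(x), 0, 0.1))
    th <- stabseg:::param_flatten(pair$student$params)
    lo <- pmin(lo, th); hi <- pmax(hi, th)
    pair <- ema_update(pair, alpha = 0.9)
  }
  te <- stabseg:::param_flatten(pair$teacher$params)
  expect_true(all(te >= lo - 1e-12 & te <= hi + 1e-12))
})

test_that("a training step runs, logs finite losses and leaves the teacher EMA-coupled", {
  set.seed(30)
  data <- micro_dataset()
  lcfg <- loss_config(ramp_length = 10L)
  ecfg <- ema_config(rampup_steps = 5L)
  pair <- make_pair(6, width = 6)
  opt <- rmsprop_init(pair$student$params)
  res <- training_step(pair, data$labeled[1], data$unlabeled[1:3],
                       lcfg, ecfg, opt)
  expect_true(all(is.finite(res$losses)))
  expect_identical(res$pair$step, 1L)
  expect_gte(res$losses[["con"]], 0)
  expect_error(training_step(pair, list(), data$unlabeled[1:2], lcfg, ecfg, opt),
               "labeled batch is empty")
  ## empty unlabeled batch: consistency computed on labeled members only
  res2 <- training_step(pair, data$labeled[1:2], list(), lcfg, ecfg, opt)
  expect_true(is.finite(res2$losses[["con"]]))
})

test_that("training is deterministic given identical seeds and states", {
  data <- micro_dataset()
  lcfg <- loss_config(ramp_length = 10L)
  ecfg <- ema_config(rampup_steps = 5L)
  run_trace <- function() {
    set.seed(77)
    pair <- make_pair(6, width = 6)
    opt <- rmsprop_init(pair$student$params)
    traces <- numeric(0)
    for (k in 1:4) {
      res <- training_step(pair, data$labeled[1], data$unlabeled[1:3],
                           lcfg, ecfg, opt, pre_cfg = preprocess_config())
      pair <- res$pair; opt <- res$opt_state
      traces <- c(traces, res$losses)
    }
    list(traces = traces, params = stabseg:::param_flatten(pair$student$params))
  }
  a <- run_trace(); b <- run_trace()
  expect_identical(a, b)
})

test_that("with lambda = 0 and identical nets the step is purely supervised", {
  set.seed(40)
  data <- micro_dataset()
  lcfg <- loss_config(ramp_length = 10L, lambda_max = 0)
  ecfg <- ema_config(rampup_steps = 5L)
  pair <- make_pair(8, width = 6)
  opt <- rmsprop_init(pair$student$params)
  res <- training_step(pair, data$labeled[1], data$unlabeled[1:3], lcfg, ecfg, opt)
  expect_identical(res$losses[["lambda"]], 0)
  expect_identical(res$losses[["con"]], 0)
  expect_identical(res$losses[["total"]], res$losses[["sup"]])
})
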