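test_that("batch sampler enforces composition and epoch coverage", {
  set.seed(50)
  data <- micro_dataset(n_labeled = 5, n_unlabeled = 12)
  set.seed(1)
  batches <- batch_sampler(data, c(1L, 3L))
  expect_length(batches, 5L)
  for (b in batches) {
    expect_length(b$labeled, 1L)
    expect_length(b$unlabeled, 3L)
    expect_true(all(b$labeled %in% names(data$labeled)))
    expect_true(all(b$unlabeled %in% names(data$unlabeled)))
  }
  ## every labeled record visited at least once
  expect_setequal(unlist(lapply(batches, `[[`, "labeled")), names(data$labeled))
  ## deterministic under a fixed RNG state
  set.seed(2); b1 <- batch_sampler(data, c(2L, 2L))
  set.seed(2); b2 <- batch_sampler(data, c(2L, 2L))
  expect_identical(b1, b2)
  ## empty unlabeled pool: falls back to all-labeled batches of the same size
  data0 <- data; data0$unlabeled <- list()
  set.seed(3)
  fb <- batch_sampler(data0, c(1L, 3L))
  expect_true(all(vapply(fb, function(b) length(b$labeled), integer(1)) == 4L))
  expect_true(all(vapply(fb, function(b) length(b$unlabeled), integer(1)) == 0L))
  expect_error(batch_sampler(data, c(0L, 4L)), "infeasible")
})

test_that("degenerate rounds are handled explicitly", {
  set.seed(51)
  data <- micro_dataset(n_labeled = 3, n_unlabeled = 6)
  cfg <- micro_config(epochs = 0)
  expect_warning(st <- run_round(round_state(1L, data), cfg), "untrained")
  expect_identical(st$metrics$error, "no_training")
  empty <- data; empty$labeled <- list()
  expect_error(run_round(round_state(1L, empty), micro_config()), "empty")
  ## empty unlabeled pool degrades to supervised-only with a warning
  nou <- data; nou$unlabeled <- list()
  expect_warning(st2 <- run_round(round_state(1L, nou), micro_config()),
                 "supervised-only")
  expect_true(st2$metrics$supervised_mode)
})

test_that("round-remainder quota admits floor(fraction * remaining), min 1", {
  set.seed(52)
  data <- micro_dataset(n_labeled = 4, n_unlabeled = 40, H = 16)
  cfg <- micro_config(seed = 5, epochs = 1, rounds = 3)
  states <- run_pipeline(data, cfg)
  admitted <- vapply(states, function(s)
    if (!is.null(s$selection)) s$selection$n_admitted else 0L, integer(1))
  expect_identical(admitted, c(10L, 7L, 5L))  # floor of 25% of 40, 30, 23
  ## conservation of training records at every round
  for (s in states)
    expect_identical(length(s$dataset$labeled) + length(s$dataset$unlabeled), 44L)
  ## id sets are preserved across rounds (no loss, no duplication)
  ids1 <- sort(c(names(states[[1]]$dataset$labeled), names(states[[1]]$dataset$unlabeled)))
  ids3 <- sort(c(names(states[[3]]$dataset$labeled), names(states[[3]]$dataset$unlabeled)))
  expect_identical(ids1, ids3)
  ## labeled set grows by the admissions of earlier rounds
  expect_identical(length(states[[2]]$dataset$labeled), 14L)
  expect_identical(length(states[[3]]$dataset$labeled), 21L)
  ## admitted records carry pseudo provenance and the admitting round
  adm <- states[[2]]$dataset$labeled[states[[1]]$selection$selected]
  expect_true(all(vapply(adm, `[[`, "", "provenance") == "pseudo"))
  expect_true(all(vapply(adm, `[[`, integer(1), "round_admitted") == 1L))
})

test_that("a single round with selection off never selects", {
  set.seed(53)
  data <- micro_dataset(n_labeled = 3, n_unlabeled = 8)
  cfg <- micro_config(seed = 2, epochs = 1, rounds = 1, selection_fraction = 0)
  states <- run_pipeline(data, cfg)
  expect_length(states, 1L)
  expect_null(states[[1]]$selection)
  expect_length(states[[1]]$dataset$unlabeled, 8L)
})

test_that("validation and test records never enter training or scoring", {
  set.seed(54)
  data <- micro_dataset(n_labeled = 3, n_unlabeled = 8, n_val = 2, n_test = 2)
  cfg <- micro_config(seed = 3, epochs = 1, rounds = 2)
  states <- run_pipeline(data, cfg)
  eval_ids <- c(vapply(data$val, `[[`, "", "id"), vapply(data$test, `[[`, "", "id"))
  for (s in states) {
    expect_length(intersect(eval_ids, names(s$dataset$labeled)), 0L)
    expect_length(intersect(eval_ids, names(s$dataset$unlabeled)), 0L)
    if (!is.null(s$selection))
      expect_length(intersect(eval_ids, s$selection$scores$image_id), 0L)
  }
})

test_that("pipeline runs are reproducible under a fixed master seed", {
  set.seed(55)
  data <- micro_dataset(n_labeled = 3, n_unlabeled = 8)
  cfg <- micro_config(seed = 11, epochs = 1, rounds = 2)
  a <- run_pipeline(data, cfg)
  b <- run_pipeline(data, cfg)
  expect_identical(lapply(a, function(s) s$metrics$loss_log),
                   lapply(b, function(s) s$metrics$loss_log))
  expect_identical(a[[2]]$pair$teacher$params, b[[2]]$pair$teacher$params)
})

test_that("the pipeline with consistency and selection off equals the plain supervised loop", {
  set.seed(56)
  data <- micro_dataset(n_labeled = 4, n_unlabeled = 8)
  cfg <- micro_config(seed = 21, epochs = 2, rounds = 1, selection_fraction = 0,
                      loss = loss_config(lambda_max = 0))
  states <- run_pipeline(data, cfg)
  base <- supervised_baseline(data, cfg)
  expect_identical(states[[1]]$metrics$loss_log, base$loss_log)
  expect_identical(states[[1]]$pair$student$params, base$pair$student$params)
  expect_identical(states[[1]]$pair$teacher$params, base$pair$teacher$params)
})
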