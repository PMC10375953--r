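test_that("forward pass satisfies the shape and softmax contracts", {
  m <- net_build(network_config(4, "tiny"), seed = 1)
  img <- matrix(stats::runif(64 * 64), 64, 64)
  out <- net_forward(m, img)
  expect_identical(dim(out$probs), c(64L, 64L, 4L))
  P <- matrix(out$probs, 64 * 64, 4)
  expect_true(all(abs(rowSums(P) - 1) < 1e-10))
  expect_true(all(P >= 0))
  expect_warning(net_forward(m, img * 500), "unnormalized")
})

test_that("initialization and unperturbed forwards are deterministic", {
  a <- net_build(network_config(3, "multires"), seed = 7)
  b <- net_build(network_config(3, "multires"), seed = 7)
  expect_identical(a$params, b$params)
  img <- matrix(stats::runif(32 * 32), 32, 32)
  expect_identical(net_forward(a, img)$probs, net_forward(a, img)$probs)
  ## perturbed forwards reproduce under a fixed RNG state
  set.seed(3); p1 <- net_forward(a, img, list(noise_sd = 0.05, dropout_on = TRUE))$probs
  set.seed(3); p2 <- net_forward(a, img, list(noise_sd = 0.05, dropout_on = TRUE))$probs
  expect_identical(p1, p2)
  set.seed(4); p3 <- net_forward(a, img, list(noise_sd = 0.05, dropout_on = TRUE))$probs
  expect_false(identical(p1, p3))
})

test_that("the tiny default stays small and multires validates divisibility", {
  expect_lt(n_parameters(net_build(network_config(4, "tiny"), seed = 1)), 1e5)
  m <- net_build(network_config(4, "multires", n_streams = 3), seed = 1)
  expect_error(net_forward(m, matrix(0.5, 30, 30)), "divisible")
  ## n_streams = 1 degenerates to a plain conv stack and still works
  m1 <- net_build(network_config(4, "multires", n_streams = 1), seed = 1)
  out <- net_forward(m1, matrix(stats::runif(16 * 16), 16, 16))
  expect_identical(dim(out$probs), c(16L, 16L, 4L))
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  lcfg <- loss_config(ramp_length = 10)
  for (variant in c("tiny", "multires")) {
    cfg <- network_config(3, variant, base_width = 4, n_streams = 2,
                          n_exchange_blocks = 1)
    m <- net_build(cfg, seed = 7)
    img <- matrix(stats::runif(64), 8, 8)
    lab <- matrix(sample(0:2, 64, TRUE), 8, 8)
    lab[1:4] <- ignore_label()
    fw <- net_forward(m, img, want_cache = TRUE)
    sl <- stabseg:::supervised_loss_grad(unclass(fw$probs), lab, lcfg)
    gr <- net_backward(m, fw$cache, sl$grad)
    loss_at <- function(model)
      stabseg:::supervised_loss_grad(unclass(net_forward(model, img)$probs),
                                     lab, lcfg)$value
    eps <- 1e-6
    for (nm in names(m$params)) {
      th <- m$params[[nm]]$W
      for (i in sample(length(th), min(3, length(th)))) {
        mp <- m; mp$params[[nm]]$W[i] <- th[i] + eps
        mm <- m; mm$params[[nm]]$W[i] <- th[i] - eps
        num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
        expect_equal(gr[[nm]]$W[i], num, tolerance = 1e-4)
      }
    }
  }
})

test_that("multires output is translation-consistent on the interior", {
  m <- net_build(network_config(3, "multires", n_streams = 2,
                                n_exchange_blocks = 1), seed = 5)
  set.seed(6)
  img <- matrix(stats::runif(64 * 64), 64, 64)
  sh <- 4L  # a multiple of the coarsest stride
  p0 <- unclass(net_forward(m, img)$probs)
  shifted <- img * 0
  shifted[, (sh + 1):64] <- img[, 1:(64 - sh)]
  p1 <- unclass(net_forward(m, shifted)$probs)
  crop0 <- p0[17:48, 17:48, ]
  crop1 <- p1[17:48, (17 + sh):(48 + sh), ]
  expect_lt(mean(abs(crop0 - crop1)), 0.02)
})

test_that("a batched forward equals stacked single-image forwards", {
  set.seed(33)
  imgs <- lapply(1:3, function(k) matrix(stats::runif(32 * 32), 32, 32))
  for (variant in c("tiny", "multires")) {
    m <- net_build(network_config(3, variant, base_width = 4), seed = 11)
    Pb <- net_forward_batch(m, imgs)$probs
    for (b in 1:3) {
      Ps <- stabseg:::as_prob_matrix(unclass(net_forward(m, imgs[[b]])$probs))
      rows <- ((b - 1) * 1024 + 1):(b * 1024)
      expect_equal(Pb[rows, ], Ps, tolerance = 1e-12)
    }
  }
})

test_that("predicted masks are argmax labels restricted to the ROI", {
  set.seed(9)
  m <- net_build(network_config(3, "tiny", base_width = 4), seed = 2)
  rec <- rand_record(16, 16)
  mask <- net_predict_mask(m, rec)
  expect_true(all(mask[rec$roi == 0] == ignore_label()))
  inside <- mask[rec$roi == 1]
  expect_true(all(inside %in% 0:2))
  P <- matrix(unclass(net_forward(m, rec$image)$probs), 256, 3)
  expect_identical(as.integer(mask[rec$roi == 1]),
                   (max.col(P, ties.method = "first") - 1L)[rec$roi == 1])
})
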