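## Shared fixture builders; all randomness is drawn from the global RNG so
## callers control determinism with set.seed().

## Random valid probability map (n_pixels x T).
rand_prob <- function(npx, n_classes) {
  z <- matrix(stats::rnorm(npx * n_classes), npx, n_classes)
  e <- exp(z)
  e / rowSums(e)
}

## Random labeled record with a circular ROI.
rand_record <- function(H = 16, W = 16, n_classes = 3, id = "r1", roi = TRUE) {
  img <- matrix(stats::runif(H * W), H, W)
  lab <- matrix(sample(seq_len(n_classes) - 1L, H * W, TRUE), H, W)
  r <- NULL
  if (roi) {
    i <- rep(seq_len(H), W); j <- rep(seq_len(W), each = H)
    r <- matrix(as.integer(((i - H / 2)^2 + (j - W / 2)^2) <= (0.45 * H)^2), H, W)
    lab[r == 0] <- ignore_label()
    img[r == 0] <- 0
  }
  segmentation_record(img, lab, r, id = id)
}

## A small dataset of random records for orchestration tests (no texture
## structure needed; geometry only).
micro_dataset <- function(n_labeled = 4, n_unlabeled = 8, H = 16, n_classes = 3,
                          n_val = 2, n_test = 2) {
  mk <- function(prefix, n, with_label) {
    lapply(seq_len(n), function(k) {
      r <- rand_record(H, H, n_classes, id = sprintf("%s%02d", prefix, k))
      if (!with_label) r$label <- NULL
      r
    })
  }
  dataset_state(mk("l", n_labeled, TRUE), mk("u", n_unlabeled, FALSE),
                mk("v", n_val, TRUE), mk("t", n_test, TRUE))
}

## Tiny config for fast orchestration tests.
micro_config <- function(seed = 1, epochs = 2, rounds = 1, ...) {
  run_config(max_rounds = rounds, epochs_per_round = epochs, seed = seed,
             network = network_config(3, "tiny", base_width = 6),
             preprocess = preprocess_config(augmentations = "noise",
                                            noise_sd = 0.01),
             ...)
}

## Independent brute-force mean IoU over classes present in either mask.
bf_mean_iou <- function(a, b) {
  av <- as.vector(a); bv <- as.vector(b)
  keep <- av != 255 & bv != 255
  av <- av[keep]; bv <- bv[keep]
  cls <- sort(unique(c(av, bv)))
  total <- 0
  for (t in cls) {
    inter <- 0; uni <- 0
    for (i in seq_along(av)) {
      ia <- av[i] == t; ib <- bv[i] == t
      if (ia && ib) inter <- inter + 1
      if (ia || ib) uni <- uni + 1
    }
    total <- total + inter / uni
  }
  total / length(cls)
}
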