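#' Network configuration
#'
#' Architecture of the segmentation backbone. Two variants are provided:
#' `"tiny"`, a three-layer convolutional stack small enough for CPU test
#' epochs in seconds, and `"multires"`, a miniature parallel multi-resolution
#' network that keeps a full-resolution convolution stream throughout and
#' repeatedly fuses information across resolutions by resize-and-sum — the
#' two defining properties of high-resolution segmentation backbones.
#'
#' @param n_classes Number of output classes `T >= 2`.
#' @param variant `"tiny"` or `"multires"`.
#' @param n_streams Parallel resolution streams (multires only, `>= 1`;
#'   stream `s` runs at `1/2^(s-1)` resolution).
#' @param base_width Channels per stream (default 16).
#' @param n_exchange_blocks Number of cross-resolution fusion blocks
#'   (multires only).
#' @param dropout_rate Dropout probability on the final feature map
#'   (default 0.5), active only when a forward pass is perturbed.
#' @return An object of class `network_config`.
#' @export
network_config <- function(n_classes, variant = c("tiny", "multires"),
                           n_streams = 2, base_width = 16,
                           n_exchange_blocks = 2, dropout_rate = 0.5) {
  variant <- match.arg(variant)
  if (!is_count(n_classes, 2L)) stop("'n_classes' must be an integer >= 2")
  if (!is_count(n_streams)) stop("'n_streams' must be a positive integer")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("'dropout_rate' must be in [0, 1)")
  structure(list(n_classes = as.integer(n_classes), variant = variant,
                 n_streams = as.integer(n_streams),
                 base_width = as.integer(base_width),
                 n_exchange_blocks = as.integer(n_exchange_blocks),
                 dropout_rate = dropout_rate),
            class = "network_config")
}

## ---- convolution plumbing (shifted-GEMM 3x3 conv, compiled) ---------------

## 3x3 same-padding convolution of a stacked (B*H*W x Cin) feature matrix.
## Returns the (B*H*W x Cout) output and the padded input (kept for the
## backward pass).  Weight rows are ordered offset-major (di fastest), Cin
## entries per offset.
conv_fwd <- function(x, p, H, W, B = 1L, relu = FALSE) {
  r <- conv3x3_fwd_cpp(x, p$W, p$b, H, W, B, relu)
  list(out = r$out, X = r$xp)
}

## `act` is the layer's (post-ReLU) activation; when given, the upstream
## gradient is masked by the ReLU derivative inside the kernel.
conv_bwd <- function(dout, X, p, H, W, Cin, want_dx = TRUE, B = 1L, act = NULL) {
  r <- conv3x3_bwd_cpp(dout, X, p$W, H, W, B, want_dx, act)
  list(grad = list(W = r$W, b = r$b), dx = r$dx)
}

## 2x average-pool downsample / nearest-neighbour upsample and adjoints, on
## (B*H*W x C) stacked matrices.  The batch axis rides along as extra
## channels: a (B*H*W x C) matrix reinterprets losslessly as (H*W x B*C)
## because both flatten column-major with the pixel index fastest.
down2 <- function(x, H, W) {
  C <- ncol(x)
  a <- array(x, c(H, W, C))
  o <- (a[seq(1, H, 2), seq(1, W, 2), , drop = FALSE] +
          a[seq(2, H, 2), seq(1, W, 2), , drop = FALSE] +
          a[seq(1, H, 2), seq(2, W, 2), , drop = FALSE] +
          a[seq(2, H, 2), seq(2, W, 2), , drop = FALSE]) / 4
  matrix(o, (H / 2) * (W / 2), C)
}

up2 <- function(x, H, W) {
  C <- ncol(x)
  a <- array(x, c(H, W, C))
  o <- a[rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), , drop = FALSE]
  matrix(o, 4L * H * W, C)
}

## Batched spatial ops: fold the batch axis into the channel axis (see note
## above down2), apply the single-image op, unfold.
spatial_b <- function(x, H, W, B, f, h_out, w_out) {
  if (B == 1L) return(f(x, H, W))
  C <- ncol(x)
  dim(x) <- c(H * W, B * C)
  o <- f(x, H, W)
  dim(o) <- c(h_out * w_out * B, C)
  o
}
down2b <- function(x, H, W, B = 1L) spatial_b(x, H, W, B, down2, H / 2, W / 2)
up2b <- function(x, H, W, B = 1L) spatial_b(x, H, W, B, up2, 2L * H, 2L * W)
down2_adj <- function(d, H, W, B = 1L) up2b(d, H / 2, W / 2, B) / 4   # H, W of the input
up2_adj <- function(d, H, W, B = 1L) down2b(d, 2L * H, 2L * W, B) * 4 # H, W of the input

## Resize a stacked (B*h*w x C) map from resolution level `from` to level
## `to` (level L runs at 1/2^(L-1) of base HxW).
resize_level <- function(x, from, to, H, W, B = 1L) {
  h <- H / 2^(from - 1L); w <- W / 2^(from - 1L)
  while (from > to) { x <- up2b(x, h, w, B); h <- 2 * h; w <- 2 * w; from <- from - 1L }
  while (from < to) { x <- down2b(x, h, w, B); h <- h / 2; w <- w / 2; from <- from + 1L }
  x
}

## Adjoint of resize_level (gradient at level `to` back to level `from`).
resize_level_adj <- function(d, from, to, H, W, B = 1L) {
  ## reverse the chain: resize from->to is a sequence of up2/down2 ops
  h <- H / 2^(to - 1L); w <- W / 2^(to - 1L)
  lvl <- to
  while (lvl > from) { d <- down2_adj(d, 2 * h, 2 * w, B); h <- 2 * h; w <- 2 * w; lvl <- lvl - 1L }
  while (lvl < from) { d <- up2_adj(d, h / 2, w / 2, B); h <- h / 2; w <- w / 2; lvl <- lvl + 1L }
  d
}

softmax_rows <- function(z) {
  e <- exp(z - row_max(z))
  e / rowSums(e)
}

softmax_bwd <- function(p, dp) {
  p * (dp - rowSums(dp * p))
}

## He-normal initialization drawn from the current RNG stream.
init_conv <- function(fan_in, n_out) {
  list(W = matrix(stats::rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)), fan_in, n_out),
       b = numeric(n_out))
}

#' Build a segmentation network
#'
#' Initializes the parameters of the configured backbone. Weights use
#' He-normal initialization; passing a seed makes initialization
#' deterministic, while `seed = NULL` draws from the current RNG stream
#' (used inside training loops so a whole round is governed by one seed).
#'
#' @param config A [network_config()].
#' @param seed Integer seed or `NULL`.
#' @return An object of class `seg_network` holding `config` and `params`.
#' @export
net_build <- function(config, seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  Wd <- config$base_width
  TT <- config$n_classes
  params <- if (config$variant == "tiny") {
    list(c1 = init_conv(9L, Wd), c2 = init_conv(9L * Wd, Wd),
         c3 = init_conv(9L * Wd, Wd), head = init_conv(Wd, TT))
  } else {
    p <- list(stem = init_conv(9L, Wd))
    if (config$n_streams > 1)
      for (s in 2:config$n_streams) p[[paste0("init", s)]] <- init_conv(9L * Wd, Wd)
    for (b in seq_len(config$n_exchange_blocks))
      for (s in seq_len(config$n_streams))
        p[[paste0("ex", b, "_", s)]] <- init_conv(9L * Wd, Wd)
    p$head <- init_conv(Wd, TT)
    p
  }
  structure(list(config = config, params = params), class = "seg_network")
}

#' Number of trainable parameters
#'
#' @param model A `seg_network`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' Forward pass
#'
#' Maps an `H x W` normalized image to per-pixel class probabilities
#' (softmax over the class axis). Perturbations — additive input noise and
#' dropout on the final feature map — are drawn from R's global RNG stream,
#' so a perturbed forward is reproducible under [set.seed()]; with
#' perturbations off the forward is deterministic.
#'
#' @param model A `seg_network` from [net_build()].
#' @param image Numeric `H x W` matrix, expected in `[0, 1]` (a warning is
#'   issued for clearly unnormalized input). For the multires variant, `H`
#'   and `W` must be divisible by `2^(n_streams - 1)`.
#' @param perturb List with `noise_sd` (additive input noise SD, default 0)
#'   and `dropout_on` (logical, default `FALSE`).
#' @param want_cache Keep intermediate activations for [net_backward()].
#' @return A list with `probs` (an `(H, W, T)` array of class
#'   `probability_map`) and, if requested, `cache`.
#' @export
net_forward <- function(model, image, perturb = list(noise_sd = 0, dropout_on = FALSE),
                        want_cache = FALSE) {
  fw <- net_forward_batch(model, list(image), perturb, want_cache)
  probs <- fw$probs
  dim(probs) <- c(nrow(image), ncol(image), model$config$n_classes)
  class(probs) <- "probability_map"
  out <- list(probs = probs)
  if (want_cache) out$cache <- fw$cache
  out
}

#' Batched forward pass
#'
#' Runs [net_forward()] on a batch of same-shape images stacked into one set
#' of matrix operations (one convolution GEMM per layer for the whole
#' batch). Used by the training loop; perturbations are drawn once for the
#' whole stack.
#'
#' @inheritParams net_forward
#' @param images List of `H x W` matrices sharing one shape.
#' @return A list with `probs`, a stacked `(B*H*W x T)` probability matrix
#'   (rows of member b occupy block b), and optionally `cache`.
#' @export
net_forward_batch <- function(model, images,
                              perturb = list(noise_sd = 0, dropout_on = FALSE),
                              want_cache = FALSE) {
  B <- length(images)
  H <- nrow(images[[1]]); W <- ncol(images[[1]])
  cfg <- model$config
  if (cfg$variant == "multires") {
    div <- 2^(cfg$n_streams - 1L)
    if (H %% div != 0 || W %% div != 0)
      stop("H and W must be divisible by 2^(n_streams - 1)")
  }
  x <- matrix(unlist(images, use.names = FALSE), B * H * W, 1L)
  rng <- range(x)
  if (rng[1] < -0.5 || rng[2] > 1.5)
    warning("input intensities look unnormalized; expected roughly [0, 1]")
  noise_sd <- perturb$noise_sd %||% 0
  if (noise_sd > 0)
    x <- x + stats::rnorm(B * H * W, 0, noise_sd)
  fw <- if (cfg$variant == "tiny") forward_tiny(model, x, H, W, B, perturb)
        else forward_multires(model, x, H, W, B, perturb)
  out <- list(probs = fw$probs)
  if (want_cache) out$cache <- c(fw$cache, list(H = H, W = W, B = B))
  out
}

dropout_mask <- function(n, C, rate, on) {
  if (!on || rate <= 0) return(NULL)
  matrix((stats::runif(n * C) >= rate) / (1 - rate), n, C)
}

forward_tiny <- function(model, x, H, W, B, perturb) {
  p <- model$params
  c1 <- conv_fwd(x, p$c1, H, W, B, relu = TRUE); a1 <- c1$out
  c2 <- conv_fwd(a1, p$c2, H, W, B, relu = TRUE); a2 <- c2$out
  c3 <- conv_fwd(a2, p$c3, H, W, B, relu = TRUE); a3 <- c3$out
  mask <- dropout_mask(B * H * W, ncol(a3), model$config$dropout_rate,
                       isTRUE(perturb$dropout_on))
  d <- if (is.null(mask)) a3 else a3 * mask
  logits <- sweep(d %*% p$head$W, 2L, p$head$b, `+`)
  probs <- softmax_rows(logits)
  list(probs = probs,
       cache = list(x = x, X1 = c1$X, a1 = a1, X2 = c2$X, a2 = a2,
                    X3 = c3$X, a3 = a3, mask = mask, d = d, probs_m = probs))
}

forward_multires <- function(model, x, H, W, B, perturb) {
  p <- model$params; cfg <- model$config
  S <- cfg$n_streams; E <- cfg$n_exchange_blocks
  cache <- list()
  st <- conv_fwd(x, p$stem, H, W, B, relu = TRUE)
  cache$stem <- st
  streams <- list(st$out)
  if (S > 1) {
    for (s in 2:S) {
      h <- H / 2^(s - 2L); w <- W / 2^(s - 2L)
      dn <- down2b(streams[[s - 1L]], h, w, B)
      cv <- conv_fwd(dn, p[[paste0("init", s)]], h / 2, w / 2, B, relu = TRUE)
      cache[[paste0("init", s)]] <- cv
      streams[[s]] <- cv$out
    }
  }
  for (b in seq_len(E)) {
    couts <- vector("list", S)
    for (s in seq_len(S)) {
      h <- H / 2^(s - 1L); w <- W / 2^(s - 1L)
      cv <- conv_fwd(streams[[s]], p[[paste0("ex", b, "_", s)]], h, w, B, relu = TRUE)
      cache[[paste0("ex", b, "_", s)]] <- cv
      couts[[s]] <- cv$out
    }
    streams <- lapply(seq_len(S), function(s) {
      acc <- couts[[s]]
      for (m in seq_len(S)) if (m != s)
        acc <- acc + resize_level(couts[[m]], m, s, H, W, B)
      acc
    })
    cache[[paste0("couts", b)]] <- couts
  }
  a_top <- streams[[1L]]
  mask <- dropout_mask(B * H * W, ncol(a_top), cfg$dropout_rate, isTRUE(perturb$dropout_on))
  d <- if (is.null(mask)) a_top else a_top * mask
  logits <- sweep(d %*% p$head$W, 2L, p$head$b, `+`)
  probs <- softmax_rows(logits)
  cache$top <- list(a_top = a_top, mask = mask, d = d)
  cache$probs_m <- probs
  list(probs = probs, cache = cache)
}

#' Backward pass
#'
#' Backpropagates a gradient with respect to the per-pixel class
#' probabilities through the softmax and the network body, returning
#' parameter gradients with the same structure as `model$params`.
#'
#' @param model A `seg_network`.
#' @param cache Cache returned by [net_forward()] with `want_cache = TRUE`.
#' @param dprobs Gradient of the loss w.r.t. the probability map
#'   (`(H, W, T)` array or `(n_pixels x T)` matrix).
#' @return A named list of gradients (`W`, `b` per layer).
#' @export
net_backward <- function(model, cache, dprobs) {
  dP <- as_prob_matrix(if (inherits(dprobs, "probability_map")) unclass(dprobs) else dprobs)
  dz <- softmax_bwd(cache$probs_m, dP)
  if (model$config$variant == "tiny") backward_tiny(model, cache, dz)
  else backward_multires(model, cache, dz)
}

backward_tiny <- function(model, cache, dlogits) {
  p <- model$params
  H <- cache$H; W <- cache$W; B <- cache$B %||% 1L
  g_head <- list(W = crossprod(cache$d, dlogits), b = colSums(dlogits))
  dd <- dlogits %*% t(p$head$W)
  da3 <- if (is.null(cache$mask)) dd else dd * cache$mask
  b3 <- conv_bwd(da3, cache$X3, p$c3, H, W, ncol(cache$a2), B = B, act = cache$a3)
  b2 <- conv_bwd(b3$dx, cache$X2, p$c2, H, W, ncol(cache$a1), B = B, act = cache$a2)
  b1 <- conv_bwd(b2$dx, cache$X1, p$c1, H, W, 1L, want_dx = FALSE, B = B,
                 act = cache$a1)
  list(c1 = b1$grad, c2 = b2$grad, c3 = b3$grad, head = g_head)
}

backward_multires <- function(model, cache, dlogits) {
  p <- model$params; cfg <- model$config
  S <- cfg$n_streams; E <- cfg$n_exchange_blocks
  H <- cache$H; W <- cache$W; B <- cache$B %||% 1L
  grads <- list()
  g_head <- list(W = crossprod(cache$top$d, dlogits), b = colSums(dlogits))
  grads$head <- g_head
  dd <- dlogits %*% t(p$head$W)
  da_top <- if (is.null(cache$top$mask)) dd else dd * cache$top$mask

  ## gradient w.r.t. the post-fusion streams: head touches stream 1 only
  dstreams <- vector("list", S)
  dstreams[[1L]] <- da_top
  for (s in seq_len(S))
    if (is.null(dstreams[[s]]))
      dstreams[[s]] <- matrix(0, B * (H / 2^(s - 1L)) * (W / 2^(s - 1L)), cfg$base_width)

  for (b in rev(seq_len(E))) {
    dcouts <- vector("list", S)
    for (m in seq_len(S)) {
      acc <- dstreams[[m]]
      for (s in seq_len(S)) if (s != m)
        acc <- acc + resize_level_adj(dstreams[[s]], m, s, H, W, B)
      dcouts[[m]] <- acc
    }
    new_dstreams <- vector("list", S)
    for (s in seq_len(S)) {
      h <- H / 2^(s - 1L); w <- W / 2^(s - 1L)
      cv <- cache[[paste0("ex", b, "_", s)]]
      bk <- conv_bwd(dcouts[[s]], cv$X, p[[paste0("ex", b, "_", s)]], h, w,
                     cfg$base_width, B = B, act = cv$out)
      grads[[paste0("ex", b, "_", s)]] <- bk$grad
      new_dstreams[[s]] <- bk$dx
    }
    dstreams <- new_dstreams
  }

  if (S > 1) {
    for (s in S:2) {
      h <- H / 2^(s - 2L); w <- W / 2^(s - 2L)
      cv <- cache[[paste0("init", s)]]
      bk <- conv_bwd(dstreams[[s]], cv$X, p[[paste0("init", s)]], h / 2, w / 2,
                     cfg$base_width, B = B, act = cv$out)
      grads[[paste0("init", s)]] <- bk$grad
      dstreams[[s - 1L]] <- dstreams[[s - 1L]] + down2_adj(bk$dx, h, w, B)
    }
  }
  bk <- conv_bwd(dstreams[[1L]], cache$stem$X, p$stem, H, W, 1L,
                 want_dx = FALSE, B = B, act = cache$stem$out)
  grads$stem <- bk$grad
  grads[names(p)]
}

#' Predict a label mask for one slice
#'
#' Unperturbed forward pass followed by a per-pixel argmax; pixels outside
#' the record's ROI receive the ignore label.
#'
#' @param model A `seg_network`.
#' @param record A [segmentation_record()].
#' @return An integer `H x W` mask with values in `0..T-1` or
#'   [ignore_label()].
#' @export
net_predict_mask <- function(model, record) {
  fw <- net_forward(model, record$image)
  P <- as_prob_matrix(unclass(fw$probs))
  mask <- matrix(row_argmax(P) - 1L, nrow(record$image), ncol(record$image))
  if (!is.null(record$roi)) mask[record$roi == 0] <- IGNORE_LABEL
  mask
}
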