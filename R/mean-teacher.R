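#' EMA configuration
#'
#' Smoothing coefficients for the teacher update
#' \eqn{\theta^*_z = \alpha \theta^*_{z-1} + (1 - \alpha) \theta_z}. A
#' smaller alpha is used during the ramp-up phase so a still-poor student
#' influences the teacher less slowly; after `rampup_steps` the main alpha
#' takes over.
#'
#' @param alpha_rampup Alpha during ramp-up (default 0.99).
#' @param alpha_main Alpha afterwards (default 0.999).
#' @param rampup_steps Length of the ramp-up phase in steps; `NULL` defers
#'   the choice to the training loop (10% of a round's steps).
#' @return An object of class `ema_config`.
#' @export
ema_config <- function(alpha_rampup = 0.99, alpha_main = 0.999, rampup_steps = NULL) {
  for (a in c(alpha_rampup, alpha_main))
    if (!(a > 0 && a < 1)) stop("alpha values must lie in (0, 1)")
  structure(list(alpha_rampup = alpha_rampup, alpha_main = alpha_main,
                 rampup_steps = rampup_steps),
            class = "ema_config")
}

#' Student/teacher model pair
#'
#' Couples a student network with its exponential-moving-average teacher.
#' Only the student ever receives gradient updates; the teacher is refreshed
#' by [ema_update()] after each step.
#'
#' @param student A `seg_network`.
#' @param teacher Optional `seg_network` with identical architecture;
#'   defaults to a copy of the student.
#' @return An object of class `model_pair` with a step counter `step`.
#' @export
model_pair <- function(student, teacher = NULL) {
  teacher <- teacher %||% student
  if (!identical(student$config, teacher$config))
    stop("student and teacher architectures differ")
  structure(list(student = student, teacher = teacher, step = 0L),
            class = "model_pair")
}

## Elementwise combination of two parameter lists.
param_combine <- function(a, b, f) {
  out <- a
  for (nm in names(a)) {
    out[[nm]]$W <- f(a[[nm]]$W, b[[nm]]$W)
    out[[nm]]$b <- f(a[[nm]]$b, b[[nm]]$b)
  }
  out
}

param_map <- function(a, f) {
  for (nm in names(a)) {
    a[[nm]]$W <- f(a[[nm]]$W)
    a[[nm]]$b <- f(a[[nm]]$b)
  }
  a
}

## Flatten parameters to one numeric vector (testing / diagnostics).
param_flatten <- function(params) {
  unlist(lapply(params, function(p) c(as.vector(p$W), p$b)), use.names = FALSE)
}

#' EMA teacher update
#'
#' Replaces every teacher parameter by
#' `alpha * teacher + (1 - alpha) * student`. The alpha is chosen from the
#' pair's step counter against `config$rampup_steps` unless given explicitly.
#' The student is untouched.
#'
#' @param pair A [model_pair()].
#' @param config An [ema_config()] (its `rampup_steps` must be set unless
#'   `alpha` is supplied).
#' @param alpha Optional explicit smoothing coefficient in `[0, 1]`
#'   (0 copies the student; 1 leaves the teacher unchanged).
#' @return The updated [model_pair()].
#' @export
ema_update <- function(pair, config = ema_config(rampup_steps = 1), alpha = NULL) {
  stopifnot(inherits(pair, "model_pair"))
  if (is.null(alpha)) {
    if (is.null(config$rampup_steps)) stop("'rampup_steps' must be set")
    alpha <- if (pair$step <= config$rampup_steps) config$alpha_rampup else config$alpha_main
  }
  pair$teacher$params <- param_combine(pair$teacher$params, pair$student$params,
                                       function(t, s) alpha * t + (1 - alpha) * s)
  pair
}

## ---- optimizer ------------------------------------------------------------

#' RMSprop optimizer state
#'
#' Momentum-free adaptive optimizer: per-parameter squared-gradient
#' accumulators with decay 0.9.
#'
#' @param params A parameter list (e.g. `model$params`).
#' @param lr Learning rate (default 1e-3).
#' @return An object of class `rmsprop_state`.
#' @export
rmsprop_init <- function(params, lr = 1e-3) {
  structure(list(v = param_map(params, function(x) x * 0), lr = lr,
                 decay = 0.9, eps = 1e-8),
            class = "rmsprop_state")
}

#' One RMSprop step
#'
#' @param params Current parameters.
#' @param grads Gradients with the same structure.
#' @param state An [rmsprop_init()] state.
#' @return List with updated `params` and `state`.
#' @export
rmsprop_step <- function(params, grads, state) {
  v <- state$v
  for (nm in names(params)) {
    v[[nm]]$W <- state$decay * v[[nm]]$W + (1 - state$decay) * grads[[nm]]$W^2
    v[[nm]]$b <- state$decay * v[[nm]]$b + (1 - state$decay) * grads[[nm]]$b^2
    params[[nm]]$W <- params[[nm]]$W - state$lr * grads[[nm]]$W / (sqrt(v[[nm]]$W) + state$eps)
    params[[nm]]$b <- params[[nm]]$b - state$lr * grads[[nm]]$b / (sqrt(v[[nm]]$b) + state$eps)
  }
  state$v <- v
  list(params = params, state = state)
}

## ---- training step --------------------------------------------------------

#' One Mean-Teacher training step
#'
#' Augments each batch member, runs independently perturbed student and
#' teacher forwards, computes the supervised compound loss on the labeled
#' members and the MSE consistency loss between teacher and student on all
#' members, takes one RMSprop step on the student with the total loss
#' `Lsup + lambda * Lcon`, and finally refreshes the teacher by EMA.
#' The teacher forward uses input noise but no dropout, and never receives
#' gradients. When `loss_config$lambda_max == 0` the step reduces to a pure
#' supervised update: no teacher forward is run and no unlabeled member is
#' touched, so the RNG stream matches a plain supervised loop exactly.
#'
#' @param pair A [model_pair()].
#' @param labeled_batch Non-empty list of labeled [segmentation_record()]s.
#' @param unlabeled_batch List of unlabeled records (may be empty; the
#'   consistency loss is then computed on the labeled members only).
#' @param loss_cfg A [loss_config()] with `ramp_length` set.
#' @param ema_cfg An [ema_config()] with `rampup_steps` set.
#' @param opt_state An [rmsprop_init()] state for the student.
#' @param pre_cfg A [preprocess_config()], or `NULL` to skip augmentation.
#' @param perturb_noise_sd Input-noise SD for the perturbed forwards.
#' @return List with the updated `pair`, `opt_state`, and a named numeric
#'   `losses` vector (`sup`, `dice`, `focal`, `con`, `lambda`, `total`).
#' @export
training_step <- function(pair, labeled_batch, unlabeled_batch = list(),
                          loss_cfg, ema_cfg, opt_state, pre_cfg = NULL,
                          perturb_noise_sd = 0.05) {
  if (length(labeled_batch) == 0) stop("labeled batch is empty; supervised loss undefined")
  step <- pair$step
  supervised_only <- loss_cfg$lambda_max == 0
  lam <- if (supervised_only) 0 else lambda_schedule(step, loss_cfg)

  ## one augmented (geometric) view per member; the student and teacher
  ## forwards below then add independent input noise
  recs <- c(labeled_batch, if (!supervised_only) unlabeled_batch)
  if (!is.null(pre_cfg)) recs <- lapply(recs, augment, config = pre_cfg)
  n_l <- length(labeled_batch)
  images <- lapply(recs, `[[`, "image")
  npx <- length(images[[1]])

  sf <- net_forward_batch(pair$student, images,
                          list(noise_sd = perturb_noise_sd, dropout_on = TRUE),
                          want_cache = TRUE)
  P <- sf$probs
  lab_rows <- seq_len(n_l * npx)
  y <- unlist(lapply(recs[seq_len(n_l)], function(r) as.vector(r$label)))
  sl <- supervised_loss_grad(P[lab_rows, , drop = FALSE], y, loss_cfg)
  dP <- matrix(0, nrow(P), ncol(P))
  dP[lab_rows, ] <- sl$grad

  con_v <- 0
  if (!supervised_only) {
    tf <- net_forward_batch(pair$teacher, images,
                            list(noise_sd = perturb_noise_sd, dropout_on = FALSE))
    roi <- unlist(lapply(recs, function(r)
      if (is.null(r$roi)) rep(TRUE, npx) else as.vector(r$roi == 1)))
    cg <- consistency_loss_grad(tf$probs, P, roi)
    con_v <- cg$value
    dP <- dP + lam * cg$grad
  }
  grads <- net_backward(pair$student, sf$cache, dP)
  sup_v <- sl$value; dice_v <- sl$dice; focal_v <- sl$focal

  upd <- rmsprop_step(pair$student$params, grads, opt_state)
  pair$student$params <- upd$params
  pair$step <- step + 1L
  pair <- ema_update(pair, ema_cfg)
  list(pair = pair, opt_state = upd$state,
       losses = c(sup = sup_v, dice = dice_v, focal = focal_v, con = con_v,
                  lambda = lam, total = total_loss(sup_v, con_v, lam)))
}
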