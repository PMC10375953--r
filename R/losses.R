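#' Loss configuration
#'
#' Hyper-parameters of the compound supervised loss and the consistency ramp.
#' The supervised loss is `(1 - rho) * dice + rho * focal`; the consistency
#' weight follows a Gaussian ramp from ~0 to `lambda_max` over `ramp_length`
#' steps, restarting at each training round.
#'
#' @param rho Mixing weight in `[0, 1]` between dice and focal loss
#'   (default 0.75, i.e. focal-dominated).
#' @param gamma Focal modulating exponent, `>= 0` (default 2).
#' @param beta Optional per-class weight vector for the focal loss. `NULL`
#'   means uniform weights; the training loop replaces it with normalized
#'   inverse class frequencies when `beta_mode = "inverse_freq"`.
#' @param lambda_max Final consistency weight (default 1). Setting it to 0
#'   disables the consistency term and yields purely supervised training.
#' @param ramp_length Number of steps over which lambda ramps up. `NULL`
#'   defers the choice to the training loop (30% of a round's steps).
#' @param focal_sum Either `"all"` (sum the focal term over all `T`
#'   one-vs-rest components per pixel, the literal reading of the sum over
#'   classes) or `"true_class"` (only the true class term).
#' @return An object of class `loss_config`.
#' @export
loss_config <- function(rho = 0.75, gamma = 2, beta = NULL, lambda_max = 1,
                        ramp_length = NULL, focal_sum = c("all", "true_class")) {
  stopifnot_scalar_prob(rho, "rho")
  if (!(length(gamma) == 1L && is.finite(gamma) && gamma >= 0))
    stop("'gamma' must be a single nonnegative value")
  if (!is.null(beta) && any(beta <= 0)) stop("'beta' weights must be strictly positive")
  if (!(length(lambda_max) == 1L && is.finite(lambda_max) && lambda_max >= 0))
    stop("'lambda_max' must be a single nonnegative value")
  if (!is.null(ramp_length) && !is_count(ramp_length))
    stop("'ramp_length' must be a positive integer")
  structure(list(rho = rho, gamma = gamma, beta = beta, lambda_max = lambda_max,
                 ramp_length = ramp_length, focal_sum = match.arg(focal_sum)),
            class = "loss_config")
}

## Shared entry validation for the supervised losses; returns the kept
## probability and one-hot matrices.
.loss_inputs <- function(pred, truth, n_classes = NULL) {
  P <- as_prob_matrix(pred)
  y <- as_label_vector(truth)
  if (nrow(P) != length(y)) stop("prediction and label shapes disagree")
  check_prob_map(P)
  keep <- y != IGNORE_LABEL
  if (!any(keep)) stop("all pixels are ignored; loss undefined")
  TT <- n_classes %||% ncol(P)
  if (any(y[keep] < 0L | y[keep] >= TT)) stop("label values outside 0..T-1")
  list(P = P[keep, , drop = FALSE], Y = one_hot(y[keep], TT), keep = keep)
}

## Soft-dice loss and its gradient w.r.t. the kept probability matrix.
## Per-class dice over all kept pixels, averaged over classes present in the
## truth; classes absent from the truth are skipped.
.dice_core <- function(P, Y, eps = 1e-6, want_grad = FALSE) {
  present <- which(colSums(Y) > 0)
  num <- 2 * colSums(P * Y)[present]
  den <- colSums(P * P)[present] + colSums(Y)[present] + eps
  loss <- 1 - mean(num / den)
  if (!want_grad) return(list(value = loss))
  G <- matrix(0, nrow(P), ncol(P))
  k <- length(present)
  for (i in seq_along(present)) {
    t <- present[i]
    G[, t] <- -(2 * Y[, t] * den[i] - num[i] * 2 * P[, t]) / (den[i]^2 * k)
  }
  list(value = loss, grad = G)
}

## Focal loss and gradient. h_t = p_t if y_t = 1 else 1 - p_t, clamped before
## the log; per-pixel sum over classes (all or true-class only), weighted by
## beta_t, then averaged over kept pixels.
.focal_core <- function(P, Y, gamma, beta, focal_sum = "all", want_grad = FALSE) {
  TT <- ncol(P)
  if (is.null(beta)) beta <- rep(1, TT)
  if (length(beta) != TT) stop("length of 'beta' must equal the number of classes")
  H <- ifelse(Y == 1, P, 1 - P)
  clamped <- H < 1e-7 | H > 1 - 1e-7
  H <- pmin(pmax(H, 1e-7), 1 - 1e-7)
  terms <- sweep((1 - H)^gamma * (-log(H)), 2L, beta, `*`)
  if (focal_sum == "true_class") terms <- terms * Y
  n <- nrow(P)
  loss <- sum(terms) / n
  if (!want_grad) return(list(value = loss))
  ## d/dh [(1-h)^g (-log h)] = g (1-h)^(g-1) log h - (1-h)^g / h
  dH <- if (gamma == 0) -1 / H else gamma * (1 - H)^(gamma - 1) * log(H) - (1 - H)^gamma / H
  dH[clamped] <- 0  # the clamped loss is locally flat there
  dH <- sweep(dH, 2L, beta, `*`)
  if (focal_sum == "true_class") dH <- dH * Y
  dP <- ifelse(Y == 1, dH, -dH) / n
  list(value = loss, grad = dP)
}

#' Soft-dice loss
#'
#' One minus the mean per-class soft-dice overlap
#' \eqn{2\sum p_t y_t / (\sum p_t^2 + \sum y_t^2 + \epsilon)} between a
#' probability map and a label mask, computed over all non-ignore pixels and
#' averaged over the classes present in the truth.
#'
#' @param pred Probability map: `(H, W, T)` array or `(n_pixels x T)` matrix.
#' @param truth Integer label mask (matrix or vector) with values in
#'   `0..T-1` or [ignore_label()].
#' @param eps Stabilizing constant in the denominator (default `1e-6`).
#' @return A single value in `[0, 1 + eps]`; 0 for a perfect one-hot match.
#' @examples
#' p <- matrix(c(0.8, 0.4, 0.2, 0.6), 2)  # two pixels, two classes
#' dice_loss(p, c(0L, 1L))
#' @export
dice_loss <- function(pred, truth, eps = 1e-6) {
  io <- .loss_inputs(pred, truth)
  .dice_core(io$P, io$Y, eps)$value
}

#' Focal loss
#'
#' Mean over non-ignore pixels of
#' \eqn{\sum_t \beta_t (1 - h_t)^\gamma (-\log h_t)} where
#' \eqn{h_t = p_t} for the true class and \eqn{1 - p_t} otherwise.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` before the logarithm.
#' With `gamma = 0` and unit `beta` this is the one-vs-rest cross-entropy.
#'
#' @inheritParams dice_loss
#' @param config A [loss_config()] supplying `gamma`, `beta` and `focal_sum`.
#' @return A nonnegative scalar.
#' @export
focal_loss <- function(pred, truth, config = loss_config()) {
  io <- .loss_inputs(pred, truth)
  .focal_core(io$P, io$Y, config$gamma, config$beta, config$focal_sum)$value
}

#' Compound supervised loss
#'
#' `(1 - rho) * dice_loss + rho * focal_loss`, the supervised objective used
#' for labeled (and pseudo-labeled) slices.
#'
#' @inheritParams focal_loss
#' @return A nonnegative scalar.
#' @export
supervised_loss <- function(pred, truth, config = loss_config()) {
  (1 - config$rho) * dice_loss(pred, truth) + config$rho * focal_loss(pred, truth, config)
}

## Supervised loss value + gradient w.r.t. the full probability matrix
## (zeros on ignore rows).  Used by the training step.
supervised_loss_grad <- function(pred, truth, config) {
  P <- as_prob_matrix(pred)
  y <- as_label_vector(truth)
  keep <- y != IGNORE_LABEL
  if (!any(keep)) stop("all pixels are ignored; loss undefined")
  Pk <- P[keep, , drop = FALSE]
  Yk <- one_hot(y[keep], ncol(P))
  d <- .dice_core(Pk, Yk, want_grad = TRUE)
  f <- .focal_core(Pk, Yk, config$gamma, config$beta, config$focal_sum, want_grad = TRUE)
  G <- matrix(0, nrow(P), ncol(P))
  G[keep, ] <- (1 - config$rho) * d$grad + config$rho * f$grad
  list(value = (1 - config$rho) * d$value + config$rho * f$value,
       dice = d$value, focal = f$value, grad = G)
}

#' Consistency loss (mean squared error)
#'
#' Mean over pixels and classes of the squared difference between teacher and
#' student probability maps. Symmetric in its arguments and zero iff the maps
#' are equal on the retained pixels.
#'
#' @param teacher_pred,student_pred Probability maps of identical shape.
#' @param mask Optional logical vector/matrix of pixels to retain (e.g. a
#'   non-ignore mask); `NULL` keeps every pixel.
#' @return A nonnegative scalar.
#' @export
consistency_loss <- function(teacher_pred, student_pred, mask = NULL) {
  Tm <- as_prob_matrix(teacher_pred)
  Sm <- as_prob_matrix(student_pred)
  if (!all(dim(Tm) == dim(Sm))) stop("teacher and student maps must share a shape")
  if (!is.null(mask)) {
    mask <- as.logical(as.vector(mask))
    Tm <- Tm[mask, , drop = FALSE]
    Sm <- Sm[mask, , drop = FALSE]
  }
  mean((Tm - Sm)^2)
}

## Consistency loss + gradient w.r.t. the student map (full shape).
consistency_loss_grad <- function(teacher_pred, student_pred, mask = NULL) {
  Tm <- as_prob_matrix(teacher_pred)
  Sm <- as_prob_matrix(student_pred)
  if (!all(dim(Tm) == dim(Sm))) stop("teacher and student maps must share a shape")
  D <- Sm - Tm
  if (!is.null(mask)) {
    mask <- as.logical(as.vector(mask))
    D[!mask, ] <- 0
    n <- sum(mask) * ncol(Sm)
  } else n <- length(Sm)
  if (n == 0) return(list(value = 0, grad = D * 0))
  list(value = sum(D^2) / n, grad = 2 * D / n)
}

#' Consistency weight ramp
#'
#' Gaussian ramp-up of the consistency weight:
#' \eqn{\lambda(s) = \lambda_{max} \exp(-5 (1 - \min(s / L, 1))^2)} with ramp
#' length `L`. Monotone non-decreasing in `s`, reaching `lambda_max` exactly
#' at `s >= L`. The ramp restarts at the beginning of every training round so
#' each round first focuses on the supervised term.
#'
#' @param step Training step within the current round (`>= 0`).
#' @param config A [loss_config()]; its `ramp_length` must be set.
#' @return A value in `[0, lambda_max]`.
#' @export
lambda_schedule <- function(step, config) {
  if (any(step < 0)) stop("'step' must be nonnegative")
  L <- config$ramp_length
  if (is.null(L) || L <= 0) stop("'ramp_length' must be a positive integer")
  t <- pmin(step / L, 1)
  config$lambda_max * exp(-5 * (1 - t)^2)
}

#' Total training loss
#'
#' `sup + lambda * con`: the supervised compound loss plus the ramped
#' consistency term.
#'
#' @param sup Supervised loss value.
#' @param con Consistency loss value.
#' @param lambda Current consistency weight (`>= 0`).
#' @return A scalar.
#' @export
total_loss <- function(sup, con, lambda) {
  if (lambda < 0) stop("'lambda' must be nonnegative")
  sup + lambda * con
}

#' Per-class focal weights from label frequencies
#'
#' Normalized inverse class-frequency weights computed from a set of label
#' masks (ignore pixels excluded), rescaled to mean 1. Classes absent from
#' the masks receive the largest observed weight.
#'
#' @param labels A list of integer label masks.
#' @param n_classes Number of classes `T`.
#' @return A positive weight vector of length `n_classes` with mean 1.
#' @export
class_weights <- function(labels, n_classes) {
  counts <- numeric(n_classes)
  for (lab in labels) {
    y <- as_label_vector(lab)
    y <- y[y != IGNORE_LABEL]
    tab <- tabulate(y + 1L, nbins = n_classes)
    counts <- counts + tab
  }
  if (sum(counts) == 0) return(rep(1, n_classes))
  inv <- ifelse(counts > 0, 1 / counts, NA_real_)
  inv[is.na(inv)] <- max(inv, na.rm = TRUE)
  inv / mean(inv)
}
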