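## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Canonicalize a probability map to an (n_pixels x T) matrix.  Accepts an
## (H, W, T) array or a matrix already in pixel-major form.  Pixel order is
## column-major, matching as.vector() on an H x W label matrix.
as_prob_matrix <- function(pred) {
  if (is.array(pred) && length(dim(pred)) == 3L) {
    d <- dim(pred)
    dim(pred) <- c(d[1L] * d[2L], d[3L])
    return(pred)
  }
  if (is.matrix(pred)) return(pred)
  stop("probability map must be an (H, W, T) array or an (n_pixels x T) matrix")
}

## Canonicalize a label mask to an integer vector.
as_label_vector <- function(truth) {
  if (is.matrix(truth) || is.array(truth)) truth <- as.vector(truth)
  as.integer(truth)
}

check_prob_map <- function(p, tol = 1e-4) {
  if (any(p < -tol) || any(p > 1 + tol))
    stop("probabilities must lie in [0, 1]")
  rs <- rowSums(p)
  if (any(abs(rs - 1) > tol))
    stop("per-pixel class probabilities must sum to 1")
  invisible(TRUE)
}

## One-hot expansion of labels (ignore rows become all-zero).
one_hot <- function(y, n_classes) {
  Y <- matrix(0, length(y), n_classes)
  keep <- which(y != IGNORE_LABEL)
  if (length(keep)) Y[cbind(keep, y[keep] + 1L)] <- 1
  Y
}

## Row-wise maximum of a matrix with few columns.
row_max <- function(m) {
  out <- m[, 1L]
  nc <- ncol(m)
  if (nc > 1L) for (j in 2:nc) out <- pmax(out, m[, j])
  out
}

## Row-wise argmax (1-based); ties go to the lowest index.
row_argmax <- function(m) {
  max.col(m, ties.method = "first")
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && x >= min
}

stopifnot_scalar_prob <- function(x, name) {
  if (!(length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1))
    stop(sprintf("'%s' must be a single value in [0, 1]", name))
}
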