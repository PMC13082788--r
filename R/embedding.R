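# Image-embedding backbone: a fully connected network mapping flattened
# grayscale crops to points in R^M, trained with a double-margin contrastive
# loss. The loss pulls positive pairs until their Euclidean distance falls
# below d_pos (preventing collapse of a fragment to a single point) and pushes
# negative pairs until it exceeds d_neg (preventing unbounded scatter).

#' Double-margin contrastive loss
#'
#' Squared-hinge contrastive loss on a pair's embedding distance `d`:
#' positive pairs contribute `max(0, d - d_pos)^2`, negative pairs
#' `max(0, d_neg - d)^2`. The loss is exactly zero when the margin is
#' satisfied.
#'
#' @param d Non-negative pair distance(s).
#' @param is_positive Logical (recycled): positive or negative pair.
#' @param config A [tracking_config()] supplying `d_pos`, `d_neg`.
#' @return Loss value(s), same length as `d`.
#' @export
contrastive_loss <- function(d, is_positive, config = tracking_config()) {
  if (any(!is.finite(d)) || any(d < 0))
    stop_invalid_input("pair distances must be finite and non-negative")
  is_positive <- rep_len(is_positive, length(d))
  out <- numeric(length(d))
  out[is_positive] <- pmax(0, d[is_positive] - config$d_pos)^2
  out[!is_positive] <- pmax(0, config$d_neg - d[!is_positive])^2
  out
}

# ---- multilayer perceptron ----------------------------------------------

new_embedding_model <- function(input_dim, hidden_dims, output_dim,
                                crop_size, seed = 1L) {
  dims <- c(input_dim, hidden_dims, output_dim)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(dims) - 1L)) {
      W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1L],
                                    sd = sqrt(2 / dims[l])),
                       dims[l], dims[l + 1L])
      b[[l]] <- numeric(dims[l + 1L])
    }
    structure(list(W = W, b = b, dims = dims,
                   crop_size = as.integer(crop_size),
                   output_dim = as.integer(output_dim)),
              class = "pairtrack_model")
  })
}

mlp_forward <- function(model, X, cache = FALSE) {
  K <- length(model$W)
  As <- if (cache) vector("list", K + 1L) else NULL
  A <- X
  if (cache) As[[1L]] <- A
  for (l in seq_len(K)) {
    Z <- A %*% model$W[[l]]
    Z <- sweep(Z, 2L, model$b[[l]], "+")
    A <- if (l < K) pmax(Z, 0) else Z
    if (cache) As[[l + 1L]] <- A
  }
  if (cache) list(out = A, As = As) else A
}

# Gradient of a scalar loss wrt all parameters, given dL/d(output).
mlp_backward <- function(model, As, dOut) {
  K <- length(model$W)
  gW <- vector("list", K); gb <- vector("list", K)
  delta <- dOut
  for (l in seq.int(K, 1L)) {
    gW[[l]] <- crossprod(As[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(model$W[[l]])
      delta <- delta * (As[[l]] > 0)   # ReLU mask (As[[l]] is post-activation)
    }
  }
  list(W = gW, b = gb)
}

adam_state <- function(model) {
  list(mW = lapply(model$W, function(w) w * 0),
       vW = lapply(model$W, function(w) w * 0),
       mb = lapply(model$b, function(b) b * 0),
       vb = lapply(model$b, function(b) b * 0),
       t = 0L)
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (l in seq_along(model$W)) {
    state$mW[[l]] <- beta1 * state$mW[[l]] + (1 - beta1) * grads$W[[l]]
    state$vW[[l]] <- beta2 * state$vW[[l]] + (1 - beta2) * grads$W[[l]]^2
    model$W[[l]] <- model$W[[l]] -
      lr * (state$mW[[l]] / c1) / (sqrt(state$vW[[l]] / c2) + eps)
    state$mb[[l]] <- beta1 * state$mb[[l]] + (1 - beta1) * grads$b[[l]]
    state$vb[[l]] <- beta2 * state$vb[[l]] + (1 - beta2) * grads$b[[l]]^2
    model$b[[l]] <- model$b[[l]] -
      lr * (state$mb[[l]] / c1) / (sqrt(state$vb[[l]] / c2) + eps)
  }
  list(model = model, state = state)
}

#' Embed images into the representation space
#'
#' Deterministic inference: maps each `L x L` grayscale crop (or each row of a
#' pre-flattened matrix) to a point in `R^M`, preserving order.
#'
#' @param model A trained (or freshly initialised) embedding model.
#' @param images A single crop matrix, a list of crop matrices, or an
#'   `n x L^2` numeric matrix of flattened crops.
#' @return An `n x M` matrix of embedding coordinates.
#' @export
embed <- function(model, images) {
  X <- images_to_matrix(images, model$crop_size)
  mlp_forward(model, X)
}

images_to_matrix <- function(images, L) {
  d <- L * L
  if (is.list(images)) {
    bad <- vapply(images, function(im)
      !is.matrix(im) || nrow(im) != L || ncol(im) != L, logical(1))
    if (any(bad))
      stop_invalid_input(sprintf("crops must be %d x %d matrices", L, L))
    X <- do.call(rbind, lapply(images, as.vector))
  } else if (is.matrix(images)) {
    if (ncol(images) == L && nrow(images) == L) {
      X <- matrix(as.vector(images), 1L)
    } else if (ncol(images) == d) {
      X <- images
    } else stop_invalid_input("image matrix has the wrong shape")
  } else stop_invalid_input("images must be a matrix or list of matrices")
  X
}

#' @export
print.pairtrack_model <- function(x, ...) {
  cat(sprintf("Embedding model: %s (crops %dx%d -> R^%d)\n",
              paste(x$dims, collapse = "-"), x$crop_size, x$crop_size,
              x$output_dim))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Single-file JSON checkpoint: layer dimensions, crop size and flattened
#' parameters.
#' @param model A `pairtrack_model`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  obj <- list(dims = model$dims, crop_size = model$crop_size,
              output_dim = model$output_dim,
              W = lapply(model$W, as.vector), b = model$b)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dims <- as.integer(obj$dims)
  W <- lapply(seq_len(length(dims) - 1L), function(l)
    matrix(obj$W[[l]], dims[l], dims[l + 1L]))
  structure(list(W = W, b = lapply(obj$b, as.numeric), dims = dims,
                 crop_size = as.integer(obj$crop_size),
                 output_dim = as.integer(obj$output_dim)),
            class = "pairtrack_model")
}
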