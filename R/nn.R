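## Branched fully-connected neural network: one branch per input signal
## vector, branch outputs concatenated, a fully-connected head, softmax
## output over the five scenario classes. Written directly on BLAS matrix
## operations: forward/backward passes, minibatch training with Adam / SGD /
## RMSprop / AdaDelta, inverted dropout, L1/L2 weight regularization,
## Glorot-normal initialization.

#' Build a branched fully-connected network
#'
#' Each branch maps one input vector through `n_hidden_layers` dense layers
#' of `n_units` with the configured activation, dropout and weight
#' regularization; branch outputs are concatenated and passed through one
#' dense head layer (same width/activation/dropout) and a softmax output
#' layer of 5 units. Weights are Glorot-normal initialized from the seed,
#' biases start at zero.
#'
#' @param input_dims named integer vector: one entry per branch giving its
#'   input length (e.g. from `vapply(assemble_inputs(...), ncol, 1L)`)
#' @param hp an `hr_hyperparams` (see [hyperparams()])
#' @param rng_seed integer seed for the weight initialization
#' @param n_classes number of output classes (default 5)
#' @return object of class `hr_ann`
#' @export
build_branched_ann <- function(input_dims, hp, rng_seed = 1L, n_classes = 5L) {
  if (length(input_dims) == 0) stop("a branched network needs >= 1 branch")
  stopifnot(all(input_dims >= 1))
  nb <- length(input_dims)
  bn <- names(input_dims) %||% paste0("branch", seq_len(nb))
  params <- list()
  with_seed(rng_seed, {
    for (b in seq_len(nb)) {
      fan_in <- input_dims[[b]]
      for (l in seq_len(hp$n_hidden_layers)) {
        params[[sprintf("W_b%d_l%d", b, l)]] <- glorot(fan_in, hp$n_units)
        params[[sprintf("b_b%d_l%d", b, l)]] <- numeric(hp$n_units)
        fan_in <- hp$n_units
      }
    }
    params[["W_head"]] <- glorot(nb * hp$n_units, hp$n_units)
    params[["b_head"]] <- numeric(hp$n_units)
    params[["W_out"]] <- glorot(hp$n_units, n_classes)
    params[["b_out"]] <- numeric(n_classes)
  })
  structure(list(params = params, hp = hp, input_dims = input_dims,
                 branch_names = bn, n_classes = n_classes, trained = FALSE),
            class = "hr_ann")
}

glorot <- function(fan_in, fan_out) {
  matrix(rnorm(fan_in * fan_out, 0, sqrt(2 / (fan_in + fan_out))),
         fan_in, fan_out)
}

#' Number of trainable parameters
#'
#' @param model an `hr_ann`
#' @return integer parameter count
#' @export
n_params <- function(model) {
  sum(vapply(model$params, length, 1L))
}

activate <- function(z, act) {
  switch(act, relu = pmax(z, 0), tanh = tanh(z),
         stop("unknown activation: ", act))
}
activate_grad <- function(a, act) {
  switch(act, relu = (a > 0) * 1, tanh = 1 - a^2)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# forward pass; when training, `masks` holds inverted-dropout masks
nn_forward <- function(model, inputs, masks = NULL) {
  hp <- model$hp
  p <- model$params
  nb <- length(model$input_dims)
  branch_acts <- vector("list", nb)
  cache <- list(branch = vector("list", nb))
  for (b in seq_len(nb)) {
    h <- inputs[[b]]
    layer_cache <- vector("list", hp$n_hidden_layers)
    for (l in seq_len(hp$n_hidden_layers)) {
      z <- h %*% p[[sprintf("W_b%d_l%d", b, l)]]
      z <- sweep_add(z, p[[sprintf("b_b%d_l%d", b, l)]])
      a <- activate(z, hp$activation)
      ad <- if (!is.null(masks)) a * masks$branch[[b]][[l]] else a
      layer_cache[[l]] <- list(input = h, act = a, act_dropped = ad)
      h <- ad
    }
    branch_acts[[b]] <- h
    cache$branch[[b]] <- layer_cache
  }
  concat <- do.call(cbind, branch_acts)
  zh <- sweep_add(concat %*% p$W_head, p$b_head)
  ah <- activate(zh, hp$activation)
  ahd <- if (!is.null(masks)) ah * masks$head else ah
  probs <- softmax_rows(sweep_add(ahd %*% p$W_out, p$b_out))
  cache$concat <- concat
  cache$head_act <- ah
  cache$head_dropped <- ahd
  cache$probs <- probs
  cache
}

sweep_add <- function(m, v) {
  m + rep(v, each = nrow(m))
}

reg_penalty <- function(params, hp) {
  w <- params[startsWith(names(params), "W")]
  lam <- hp$regularization
  if (hp$regularizer == "l2") {
    lam * sum(vapply(w, function(x) sum(x^2), 1))
  } else {
    lam * sum(vapply(w, function(x) sum(abs(x)), 1))
  }
}
reg_grad <- function(W, hp) {
  if (hp$regularizer == "l2") 2 * hp$regularization * W
  else hp$regularization * sign(W)
}

# backward pass: categorical cross-entropy + regularization gradients
nn_backward <- function(model, inputs, y, cache, masks) {
  hp <- model$hp
  p <- model$params
  n <- nrow(y)
  g <- list()
  dZ <- (cache$probs - y) / n
  g$W_out <- crossprod(cache$head_dropped, dZ) + reg_grad(p$W_out, hp)
  g$b_out <- colSums(dZ)
  dAhd <- tcrossprod(dZ, p$W_out)
  dAh <- if (!is.null(masks)) dAhd * masks$head else dAhd
  dZh <- dAh * activate_grad(cache$head_act, hp$activation)
  g$W_head <- crossprod(cache$concat, dZh) + reg_grad(p$W_head, hp)
  g$b_head <- colSums(dZh)
  dConcat <- tcrossprod(dZh, p$W_head)
  nb <- length(model$input_dims)
  for (b in seq_len(nb)) {
    cols <- ((b - 1) * hp$n_units + 1):(b * hp$n_units)
    dH <- dConcat[, cols, drop = FALSE]
    for (l in rev(seq_len(hp$n_hidden_layers))) {
      lc <- cache$branch[[b]][[l]]
      dA <- if (!is.null(masks)) dH * masks$branch[[b]][[l]] else dH
      dZl <- dA * activate_grad(lc$act, hp$activation)
      Wn <- sprintf("W_b%d_l%d", b, l)
      g[[Wn]] <- crossprod(lc$input, dZl) + reg_grad(p[[Wn]], hp)
      g[[sprintf("b_b%d_l%d", b, l)]] <- colSums(dZl)
      if (l > 1) dH <- tcrossprod(dZl, p[[Wn]])
    }
  }
  g
}

draw_masks <- function(model, n) {
  hp <- model$hp
  if (hp$dropout <= 0) return(NULL)
  keep <- 1 - hp$dropout
  nb <- length(model$input_dims)
  list(branch = lapply(seq_len(nb), function(b) {
         lapply(seq_len(hp$n_hidden_layers), function(l) {
           matrix(stats::rbinom(n * hp$n_units, 1, keep) / keep, n, hp$n_units)
         })
       }),
       head = matrix(stats::rbinom(n * hp$n_units, 1, keep) / keep,
                     n, hp$n_units))
}

## Optimizers ----------------------------------------------------------------

make_optimizer <- function(hp) {
  state <- new.env(parent = emptyenv())
  state$t <- 0
  lr <- hp$learning_rate
  switch(hp$optimizer,
    SGD = function(params, grads) {
      for (nm in names(grads)) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
      params
    },
    Adam = {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-7
      function(params, grads) {
        state$t <- state$t + 1
        for (nm in names(grads)) {
          g <- grads[[nm]]
          m <- (state[[paste0("m_", nm)]] %||% 0) * b1 + (1 - b1) * g
          v <- (state[[paste0("v_", nm)]] %||% 0) * b2 + (1 - b2) * g^2
          state[[paste0("m_", nm)]] <- m
          state[[paste0("v_", nm)]] <- v
          mh <- m / (1 - b1^state$t)
          vh <- v / (1 - b2^state$t)
          params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
        }
        params
      }
    },
    RMSprop = {
      rho <- 0.9; eps <- 1e-7
      function(params, grads) {
        for (nm in names(grads)) {
          g <- grads[[nm]]
          acc <- (state[[paste0("a_", nm)]] %||% 0) * rho + (1 - rho) * g^2
          state[[paste0("a_", nm)]] <- acc
          params[[nm]] <- params[[nm]] - lr * g / (sqrt(acc) + eps)
        }
        params
      }
    },
    AdaDelta = {
      rho <- 0.95; eps <- 1e-6
      function(params, grads) {
        for (nm in names(grads)) {
          g <- grads[[nm]]
          ag <- (state[[paste0("ag_", nm)]] %||% 0) * rho + (1 - rho) * g^2
          state[[paste0("ag_", nm)]] <- ag
          ad <- state[[paste0("ad_", nm)]] %||% 0
          step <- -sqrt(ad + eps) / sqrt(ag + eps) * g
          state[[paste0("ad_", nm)]] <- ad * rho + (1 - rho) * step^2
          params[[nm]] <- params[[nm]] + lr * step
        }
        params
      }
    },
    stop("unknown optimizer: ", hp$optimizer))
}

## Training / prediction -----------------------------------------------------

#' Train a branched network
#'
#' Minibatch training for `hp$n_epochs` epochs minimizing categorical
#' cross-entropy plus the weight-regularization penalty. The validation set
#' only monitors convergence (no early stopping; training always runs the
#' full fixed epoch budget). The returned history records per-epoch training
#' loss/accuracy (running means over the minibatches, Keras-style) and
#' validation loss/accuracy.
#'
#' Gradients are clipped to a global L2 norm of `clipnorm` before each
#' optimizer step; at the largest grid learning rates this keeps the fixed
#' 100-epoch run from ending inside a transient divergence spike without
#' altering converged behaviour.
#'
#' @param model an `hr_ann` from [build_branched_ann()]
#' @param x named list of branch input matrices (training set)
#' @param y one-hot label matrix
#' @param x_val,y_val validation inputs/labels (monitoring only); may be NULL
#' @param rng_seed seed for minibatch shuffling and dropout masks
#' @param clipnorm global gradient-norm ceiling (default 1)
#' @param verbose print per-epoch metrics
#' @return list with the trained `model` and `history` (data.frame with
#'   columns epoch, loss, accuracy, val_loss, val_accuracy)
#' @export
train_model <- function(model, x, y, x_val = NULL, y_val = NULL,
                        rng_seed = 1L, clipnorm = 1, verbose = FALSE) {
  hp <- model$hp
  stopifnot(length(x) == length(model$input_dims), is.matrix(y))
  n <- nrow(y)
  if (n < 1) stop("empty training set")
  if (!is.null(y_val) && all(colSums(y) %in% c(0, n))) {
    warning("degenerate training labels: a single class is present")
  }
  opt <- make_optimizer(hp)
  hist <- data.frame(epoch = seq_len(hp$n_epochs), loss = NA_real_,
                     accuracy = NA_real_, val_loss = NA_real_,
                     val_accuracy = NA_real_)
  with_seed(derive_seed(rng_seed, 77), {
    for (ep in seq_len(hp$n_epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1, n, by = hp$batch_size)
      ep_loss <- 0; ep_correct <- 0
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + hp$batch_size - 1, n)]
        xb <- lapply(x, function(m) m[idx, , drop = FALSE])
        yb <- y[idx, , drop = FALSE]
        masks <- draw_masks(model, length(idx))
        cache <- nn_forward(model, xb, masks)
        probs <- cache$probs
        ce <- -mean(log(pmax(probs[yb == 1], 1e-12)))
        loss <- ce + reg_penalty(model$params, hp)
        if (!is.finite(loss)) {
          stop("NaN/Inf loss at epoch ", ep,
               "; training diverged (check learning rate)")
        }
        ep_loss <- ep_loss + loss * length(idx)
        ep_correct <- ep_correct +
          sum(max.col(probs, ties.method = "first") ==
                max.col(yb, ties.method = "first"))
        grads <- nn_backward(model, xb, yb, cache, masks)
        if (is.finite(clipnorm) && clipnorm > 0) {
          gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), 1)))
          if (gn > clipnorm) {
            grads <- lapply(grads, function(g) g * (clipnorm / gn))
          }
        }
        model$params <- opt(model$params, grads)
      }
      hist$loss[ep] <- ep_loss / n
      hist$accuracy[ep] <- ep_correct / n
      if (!is.null(x_val)) {
        vp <- predict_probs(model, x_val)
        hist$val_loss[ep] <- -mean(log(pmax(vp[y_val == 1], 1e-12))) +
          reg_penalty(model$params, hp)
        hist$val_accuracy[ep] <- categorical_accuracy(y_val, vp)
      }
      if (verbose) {
        message(sprintf("epoch %3d loss %.4f acc %.3f val_acc %.3f", ep,
                        hist$loss[ep], hist$accuracy[ep],
                        hist$val_accuracy[ep]))
      }
    }
  })
  model$trained <- TRUE
  list(model = model, history = hist)
}

predict_probs <- function(model, x) {
  nn_forward(model, x, masks = NULL)$probs
}

#' Predict class probabilities
#'
#' Softmax rows (each summing to 1); the predicted class is the argmax with
#' ties broken toward the lowest class index.
#'
#' @param object a trained `hr_ann`
#' @param x named list of branch input matrices matching the architecture
#' @param ... unused
#' @return matrix n x n_classes of probabilities
#' @export
predict.hr_ann <- function(object, x, ...) {
  if (length(x) != length(object$input_dims)) {
    stop("expected ", length(object$input_dims), " branch inputs, got ",
         length(x))
  }
  for (b in seq_along(x)) {
    if (ncol(x[[b]]) != object$input_dims[[b]]) {
      stop("branch ", b, ": input width ", ncol(x[[b]]),
           " does not match architecture width ", object$input_dims[[b]])
    }
  }
  predict_probs(object, x)
}

#' @export
print.hr_ann <- function(x, ...) {
  cat(sprintf("<branched ANN: %d branches, %d hidden layer(s) x %d units, %s, %d params%s>\n",
              length(x$input_dims), x$hp$n_hidden_layers, x$hp$n_units,
              x$hp$activation, n_params(x),
              if (x$trained) ", trained" else ""))
  invisible(x)
}
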