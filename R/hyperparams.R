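## Hyperparameter space, validated hyperparameter sets, random search.

#' The hyperparameter search space
#'
#' The grid investigated for the branched fully-connected networks. The
#' searchable fields have 3*3*2*3*3*4*2*3*2 = 7776 combinations; epoch
#' count, loss, output activation and initializer are fixed. The `extended`
#' flag admits the two off-grid values used by the published best fusion
#' network (learning rate 0.001, batch size 32).
#'
#' @param extended admit the off-grid fusion values
#' @return named list of candidate value vectors
#' @export
hyperparam_space <- function(extended = FALSE) {
  sp <- list(
    n_hidden_layers = c(1L, 2L, 3L),
    n_units = c(32L, 64L, 128L),
    activation = c("relu", "tanh"),
    dropout = c(0.2, 0.3, 0.4),
    learning_rate = c(0.005, 0.01, 0.05),
    optimizer = c("Adam", "SGD", "AdaDelta", "RMSprop"),
    regularizer = c("l1", "l2"),
    regularization = c(0.001, 0.005, 0.01),
    batch_size = c(64L, 128L)
  )
  if (extended) {
    sp$learning_rate <- c(0.001, sp$learning_rate)
    sp$batch_size <- c(32L, sp$batch_size)
  }
  sp
}

#' Construct a validated hyperparameter set
#'
#' Values must come from [hyperparam_space()] (with `extended = TRUE` to
#' admit the off-grid fusion values). Epochs default to the fixed training
#' budget of 100; loss is categorical cross-entropy, output activation
#' softmax, initialization Glorot-normal (all fixed, not searchable).
#'
#' @param n_hidden_layers,n_units,activation,dropout,learning_rate,optimizer,regularizer,regularization,batch_size
#'   searchable fields
#' @param n_epochs fixed training epochs (default 100)
#' @param extended admit off-grid learning rate / batch size values
#' @return object of class `hr_hyperparams`
#' @export
hyperparams <- function(n_hidden_layers = 1L, n_units = 32L,
                        activation = "tanh", dropout = 0.3,
                        learning_rate = 0.005, optimizer = "Adam",
                        regularizer = "l2", regularization = 0.001,
                        batch_size = 64L, n_epochs = 100L,
                        extended = FALSE) {
  sp <- hyperparam_space(extended = extended)
  vals <- list(n_hidden_layers = n_hidden_layers, n_units = n_units,
               activation = activation, dropout = dropout,
               learning_rate = learning_rate, optimizer = optimizer,
               regularizer = regularizer, regularization = regularization,
               batch_size = batch_size)
  for (nm in names(vals)) {
    if (!vals[[nm]] %in% sp[[nm]]) {
      stop("hyperparameter ", nm, " = ", vals[[nm]],
           " is outside the investigated grid",
           if (!extended) " (try extended = TRUE)" else "")
    }
  }
  structure(c(vals, list(n_epochs = as.integer(n_epochs),
                         loss = "categorical_crossentropy",
                         last_activation = "softmax",
                         initializer = "glorot_normal")),
            class = "hr_hyperparams")
}

#' Published best hyperparameter sets per modality
#'
#' The optimized fully-connected configurations found for each input
#' modality: all use a single hidden layer, tanh activation, Adam, and L2
#' regularization 0.001; they differ in width, dropout, learning rate and
#' batch size. Contact and radar models consume FFT half-spectrum inputs
#' only; the fusion model consumes both temporal and FFT inputs. The fusion
#' learning rate (0.001) and batch size (32) sit outside the search grid and
#' are admitted via the extended grid.
#'
#' @param modality `"contact"`, `"radar"`, or `"fusion"`
#' @param n_epochs training epochs (default 100)
#' @return an `hr_hyperparams`
#' @export
published_hyperparams <- function(modality = c("contact", "radar", "fusion"),
                              n_epochs = 100L) {
  modality <- match.arg(modality)
  switch(modality,
    contact = hyperparams(1L, 32L, "tanh", 0.3, 0.005, "Adam", "l2", 0.001,
                          64L, n_epochs),
    radar = hyperparams(1L, 64L, "tanh", 0.3, 0.05, "Adam", "l2", 0.001,
                        128L, n_epochs),
    fusion = hyperparams(1L, 32L, "tanh", 0.4, 0.001, "Adam", "l2", 0.001,
                         32L, n_epochs, extended = TRUE))
}

#' Preferred data type per modality for the published best models
#'
#' @param modality `"contact"`, `"radar"`, or `"fusion"`
#' @return `"frequency"` for contact/radar, `"both"` for fusion
#' @export
published_data_type <- function(modality = c("contact", "radar", "fusion")) {
  modality <- match.arg(modality)
  if (modality == "fusion") "both" else "frequency"
}

#' Draw hyperparameter sets without replacement
#'
#' @param n_draws number of distinct sets to draw
#' @param rng_seed integer seed
#' @param extended extended grid flag
#' @param n_epochs epochs stamped onto each drawn set
#' @return list of `hr_hyperparams`
#' @export
sample_hyperparams <- function(n_draws, rng_seed = 1L, extended = FALSE,
                               n_epochs = 100L) {
  sp <- hyperparam_space(extended = extended)
  sizes <- vapply(sp, length, 1L)
  total <- prod(sizes)
  if (n_draws > total) {
    warning("n_draws ", n_draws, " exceeds the grid size ", total,
            "; capping")
    n_draws <- total
  }
  picks <- with_seed(derive_seed(rng_seed, 5), sample.int(total, n_draws))
  lapply(picks, function(ix) {
    ix <- ix - 1L
    args <- list()
    for (nm in names(sp)) {
      k <- ix %% sizes[[nm]]
      args[[nm]] <- sp[[nm]][k + 1]
      ix <- ix %/% sizes[[nm]]
    }
    do.call(hyperparams, c(args, list(n_epochs = n_epochs,
                                      extended = extended)))
  })
}

#' Random hyperparameter search
#'
#' Draws `n_draws` hyperparameter sets without replacement from the grid,
#' runs the supplied evaluation harness (typically a closure around
#' [run_experiment()] returning the mean CV accuracy) on each, and ranks the
#' sets by mean accuracy. The spread of the top sets indicates how sensitive
#' the architecture is to the exact configuration.
#'
#' @param n_draws number of sets to evaluate
#' @param harness function(hp) -> mean accuracy
#' @param rng_seed integer seed
#' @param extended extended grid flag
#' @param n_epochs epochs per drawn set
#' @return data.frame ranked by decreasing accuracy, with a list-column
#'   `hp`; the top-3 accuracy spread is attached as attribute `top3_spread`
#' @export
random_search <- function(n_draws, harness, rng_seed = 1L, extended = FALSE,
                          n_epochs = 100L) {
  stopifnot(n_draws >= 1)
  hps <- sample_hyperparams(n_draws, rng_seed = rng_seed,
                            extended = extended, n_epochs = n_epochs)
  acc <- vapply(hps, function(hp) as.numeric(harness(hp)), 1)
  ord <- order(acc, decreasing = TRUE)
  out <- data.frame(rank = seq_along(ord), accuracy = acc[ord])
  out$hp <- hps[ord]
  top <- head(out$accuracy, 3)
  attr(out, "top3_spread") <- if (length(top) > 1) max(top) - min(top) else 0
  out
}
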