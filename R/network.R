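# The 3D convolutional block classifier.  Fixed 14-layer stack:
#   Conv3D(2, 8^3) - Conv3D(4, 8^3) - MaxPool(2^3) - Dropout(0.25) -
#   Conv3D(8, 4^3) - Conv3D(16, 4^3) - MaxPool(2^3) -
#   Conv3D(32, 2^3) - Conv3D(64, 2^3) - Dropout(0.25) -
#   Flatten(4096) - Dense(128, ReLU) - Dropout(0.5) - Dense(1, sigmoid)
# All convolutions are same-padded ReLU layers, so the spatial trace is
# 16 -> 16 -> 8 -> 8 -> 4 -> 4 and the flattened feature length entering the
# dense layer is 64 * 4^3 = 4096.  Training minimizes binary cross-entropy
# with Adam; the heavy lifting runs in compiled code.

NET_FILTERS <- c(2L, 4L, 8L, 16L, 32L, 64L)
NET_KERNELS <- c(8L, 8L, 4L, 4L, 2L, 2L)
NET_CHANNELS_IN <- c(4L, 2L, 4L, 8L, 16L, 32L)
NET_SPATIAL <- c(16L, 16L, 8L, 8L, 4L, 4L)

#' Network and training configuration
#'
#' The architecture itself is fixed; the configuration carries the training
#' hyperparameters, none of which change the layer stack.
#'
#' @param dropout three dropout rates: after the first pooling stage, after
#'   the last convolution, and after the dense layer.
#' @param dense width of the dense layer.
#' @param optimizer only "adam" is implemented.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation loss.
#' @param stop_train_acc stop once training accuracy reaches this value
#'   (set above 1 to disable).
#' @param seed RNG seed controlling weight initialization, shuffling and
#'   dropout.
#' @return list of class `network_config`.
#' @export
network_config <- function(dropout = c(0.25, 0.25, 0.5), dense = 128L,
                           optimizer = "adam", learning_rate = 1e-3,
                           batch_size = 32L, epochs = 50L, patience = 10L,
                           stop_train_acc = 1.0, seed = 42L) {
  stopifnot(length(dropout) == 3, all(dropout >= 0 & dropout < 1),
            identical(optimizer, "adam"), learning_rate > 0,
            batch_size >= 1, epochs >= 1)
  if (dense != 128L)
    stop("the architecture fixes the dense width at 128", call. = FALSE)
  structure(list(dropout = dropout, dense = as.integer(dense),
                 optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 stop_train_acc = stop_train_acc, seed = as.integer(seed)),
            class = "network_config")
}

#' Layer-by-layer shape trace of the architecture
#'
#' @return data.frame with one row per layer: kernel, input and output
#'   shapes (channels x spatial).
#' @export
model_shape_trace <- function() {
  shp <- function(c, d) sprintf("%d,(%d,%d,%d)", c, d, d, d)
  data.frame(
    layer = c("Conv3D,ReLU", "Conv3D,ReLU", "MaxPooling3D", "Dropout(0.25)",
              "Conv3D,ReLU", "Conv3D,ReLU", "MaxPooling3D", "Conv3D,ReLU",
              "Conv3D,ReLU", "Dropout(0.25)", "Flatten", "Dense(128),ReLU",
              "Dropout(0.5)", "Dense(1),sigmoid"),
    kernel = c("2,(8,8,8)", "4,(8,8,8)", "(2,2,2)", NA, "8,(4,4,4)",
               "16,(4,4,4)", "(2,2,2)", "32,(2,2,2)", "64,(2,2,2)", NA, NA,
               NA, NA, NA),
    input = c(shp(4, 16), shp(2, 16), shp(4, 16), shp(4, 8), shp(4, 8),
              shp(8, 8), shp(16, 8), shp(16, 4), shp(32, 4), shp(64, 4),
              shp(64, 4), "4096", "128", "128"),
    output = c(shp(2, 16), shp(4, 16), shp(4, 8), shp(4, 8), shp(8, 8),
               shp(16, 8), shp(16, 4), shp(32, 4), shp(64, 4), shp(64, 4),
               "4096", "128", "128", "1"),
    stringsAsFactors = FALSE
  )
}

#' Flattened feature length entering the dense layer
#' @return integer, 64 * 4^3 = 4096.
#' @export
flatten_length <- function() {
  as.integer(NET_FILTERS[6] * NET_SPATIAL[6]^3)
}

#' Trainable parameter count per layer
#'
#' Convolution layers have `(k^3 * c_in + 1) * filters` parameters.
#'
#' @return named integer vector over the eight trainable layers.
#' @export
layer_param_counts <- function() {
  conv <- (NET_KERNELS^3 * NET_CHANNELS_IN + 1L) * NET_FILTERS
  c(setNames(conv, paste0("conv", 1:6)),
    dense1 = (flatten_length() + 1L) * 128L, dense2 = 129L)
}

he_init <- function(nr, nc) matrix(rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)

#' Build an untrained model
#'
#' Initializes weights (He-normal, zero biases) under the configuration
#' seed.
#'
#' @param config a `network_config`.
#' @return object of class `gridpocket_model` with fields `config`,
#'   `weights`, `fingerprint` (shape trace), `trained`, `history`.
#' @export
build_model <- function(config = network_config()) {
  stopifnot(inherits(config, "network_config"))
  w <- with_seed(config$seed, {
    w <- list()
    for (l in 1:6) {
      fanin <- NET_KERNELS[l]^3 * NET_CHANNELS_IN[l]
      w[[paste0("W", l)]] <- he_init(fanin, NET_FILTERS[l])
      w[[paste0("b", l)]] <- rep(0, NET_FILTERS[l])
    }
    w$Wd1 <- he_init(flatten_length(), config$dense)
    w$bd1 <- rep(0, config$dense)
    w$Wd2 <- he_init(config$dense, 1)
    w$bd2 <- 0
    w
  })
  structure(list(config = config, weights = w,
                 fingerprint = model_shape_trace(), trained = FALSE,
                 history = NULL),
            class = "gridpocket_model")
}

#' @export
print.gridpocket_model <- function(x, ...) {
  cat("<gridpocket_model>", if (x$trained) "trained" else "untrained",
      "- 3D CNN,", sum(layer_param_counts()), "parameters\n")
  invisible(x)
}

as_block_tensor <- function(x) {
  if (is.list(x) && !is.array(x)) x <- block_array(x)$x
  d <- dim(x)
  if (length(d) == 4) { dim(x) <- c(d, 1); d <- dim(x) }
  if (length(d) != 5 || !all(d[1:4] == c(BLOCK, BLOCK, BLOCK, 4)))
    stop("blocks must have shape 16x16x16x4", call. = FALSE)
  x
}

#' Train the classifier
#'
#' Minimizes binary cross-entropy with Adam under the configuration seed.
#' When a validation set is given, training stops after `patience` epochs
#' without validation-loss improvement and the best weights are restored.
#'
#' @param model an untrained (or previously trained) `gridpocket_model`.
#' @param x array (16,16,16,4,n) of normalized blocks, or list of
#'   `sample_block`s.
#' @param y binary labels.
#' @param val_x,val_y optional validation set.
#' @param verbose print per-epoch progress?
#' @return the trained model with `history` (per-epoch loss/accuracy).
#' @export
train_model <- function(model, x, y, val_x = NULL, val_y = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "gridpocket_model"))
  x <- as_block_tensor(x)
  n <- dim(x)[5]
  if (n == 0 || length(y) != n) stop("empty or mismatched dataset", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (is.null(val_x)) {
    vx <- numeric(0); vy <- numeric(0)
  } else {
    val_x <- as_block_tensor(val_x)
    vx <- as.numeric(val_x); vy <- as.numeric(val_y)
  }
  cfg <- model$config
  fit <- with_seed(cfg$seed, {
    cnn_train_cpp(model$weights, as.numeric(x), as.numeric(y), vx, vy,
                  cfg$epochs, cfg$batch_size, cfg$learning_rate, 0.9, 0.999,
                  1e-8, cfg$dropout, cfg$patience, cfg$stop_train_acc,
                  verbose)
  })
  model$weights <- fit$weights
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$trained <- TRUE
  model
}

#' Score blocks with the classifier
#'
#' @param model a `gridpocket_model`.
#' @param x array (16,16,16,4,n), a single 4D block, or a list of
#'   `sample_block`s.  An empty list yields an empty numeric vector.
#' @return probabilities in (0, 1), one per block, order preserved.
#' @export
predict_blocks <- function(model, x) {
  stopifnot(inherits(model, "gridpocket_model"))
  if (is.list(x) && !is.array(x) && length(x) == 0) return(numeric(0))
  x <- as_block_tensor(x)
  cnn_forward_cpp(model$weights, as.numeric(x), dim(x)[5])
}

#' Save / load a model
#'
#' Thin RDS wrappers; the architecture fingerprint travels with the weights.
#'
#' @param model a `gridpocket_model`.
#' @param path file path.
#' @return `load_model` returns the model; `save_model` the path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gridpocket_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "gridpocket_model"))
  m
}
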