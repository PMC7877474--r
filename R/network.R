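## CNN / Siamese architectures and the SD-vs-SR generalization experiment.

#' Network architecture and training configuration
#'
#' Defaults follow the simulation protocol: six convolutional layers of
#' four 2x2 channels with stride 1 and ReLU, each followed by 2x2 max
#' pooling with stride 1; two fully connected layers of 128 units with
#' dropout 0.3; a 2-way sigmoid output trained with binary cross-entropy
#' and Adam for up to 70 epochs at batch size 50, stopping early once
#' validation accuracy reaches 90%. Padding ("same" keeps the literal
#' stride-1 pipeline from eroding the 50x80 grid) and pooling stride are
#' overridable.
#'
#' @param n_conv_layers Number of conv+pool blocks (default 6).
#' @param channels Channels per conv layer (default 4).
#' @param fc_units Two fully connected layer sizes (default `c(128, 128)`).
#' @param dropout Dropout rate (default 0.3).
#' @param conv_dropout Apply dropout after every convolutional layer as
#'   well as the fully connected layers (the literal "each layer" reading;
#'   default `TRUE`). `FALSE` restricts dropout to the dense layers.
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param epochs Epoch budget (default 70).
#' @param batch_size Minibatch size (default 50).
#' @param stop_at_val Early-stopping validation-accuracy threshold
#'   (default 0.9).
#' @param val_every Evaluate validation accuracy every this many epochs
#'   (default 1; larger values trade stopping granularity for speed).
#' @param input_h,input_w Input raster size (default 50 x 80).
#' @param padding `"same"` (default) or `"valid"`.
#' @param pool_stride Max-pool stride (default 1; 2 gives the conventional
#'   halving variant).
#' @return A `network_config` list.
#' @export
network_config <- function(n_conv_layers = 6L, channels = 4L,
                           fc_units = c(128L, 128L), dropout = 0.3,
                           conv_dropout = TRUE,
                           learning_rate = 1e-4, epochs = 70L,
                           batch_size = 50L, stop_at_val = 0.9,
                           val_every = 1L,
                           input_h = 50L, input_w = 80L,
                           padding = c("same", "valid"), pool_stride = 1L) {
  padding <- match.arg(padding)
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 channels = as.integer(channels),
                 fc_units = as.integer(fc_units), dropout = dropout,
                 conv_dropout = isTRUE(conv_dropout),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), stop_at_val = stop_at_val,
                 val_every = as.integer(val_every),
                 input_h = as.integer(input_h), input_w = as.integer(input_w),
                 padding = padding, pool_stride = as.integer(pool_stride),
                 siamese = FALSE),
            class = "network_config")
}

#' Build the convolutional classifier
#'
#' Initializes all weights (Glorot-uniform, reproducible from `seed`) for
#' the feedforward CNN that consumes the full two-item 50x80 image. The
#' trainable parameter count is computed at build time.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the weight initialization.
#' @return Object of class `visreason_model` with `config`, `weights`,
#'   `seed`, `param_count`.
#' @export
build_cnn <- function(config = network_config(), seed = 1L) {
  config$siamese <- FALSE
  w <- cpp_nn_init(unclass(config), as.integer(seed))
  structure(list(config = config, weights = w, seed = as.integer(seed),
                 param_count = attr(w, "param_count"), history = NULL),
            class = "visreason_model")
}

#' Build the Siamese (segmentation-oracle) variant
#'
#' Same convolutional trunk as [build_cnn()], applied with shared weights
#' to two images that each show one item alone at its true position; the
#' elementwise difference of the two flattened feature vectors feeds the
#' fully connected classifier. Order-invariance is handled by training on
#' both input orders (see [dataset_arrays()] / [train_model()]).
#'
#' @inheritParams build_cnn
#' @return Object of class `visreason_model`.
#' @export
build_siamese <- function(config = network_config(), seed = 1L) {
  config$siamese <- TRUE
  w <- cpp_nn_init(unclass(config), as.integer(seed))
  structure(list(config = config, weights = w, seed = as.integer(seed),
                 param_count = attr(w, "param_count"), history = NULL),
            class = "visreason_model")
}

#' @export
print.visreason_model <- function(x, ...) {
  cat(sprintf("<visreason_model> %s, %d conv layers, %s trainable parameters\n",
              if (x$config$siamese) "siamese" else "cnn",
              x$config$n_conv_layers, format(x$param_count, big.mark = ",")))
  if (!is.null(x$history))
    cat(sprintf("  trained %d epochs, final val accuracy %.3f\n",
                nrow(x$history), tail(x$history$val_acc, 1)))
  invisible(x)
}

## Images as (HW x n) matrix: column i = as.vector of image i (column-major).
flatten_images <- function(x) {
  n <- dim(x)[1]
  matrix(aperm(x, c(2, 3, 1)), ncol = n)
}

## Standardize train/val data: list(x, y) or list(xa, xb, y) -> matrices.
prep_data <- function(data, siamese, augment_orders = FALSE) {
  if (siamese) {
    Xa <- flatten_images(data$xa); Xb <- flatten_images(data$xb)
    y <- data$y
    if (augment_orders) {  # both presentation orders, same label
      X1 <- cbind(Xa, Xb); X2 <- cbind(Xb, Xa); y <- c(y, y)
      list(X = X1, X2 = X2, y = as.integer(y))
    } else list(X = Xa, X2 = Xb, y = as.integer(y))
  } else list(X = flatten_images(data$x), X2 = NULL, y = as.integer(data$y))
}

#' Train a model with early stopping
#'
#' Runs minibatch Adam up to the configured epoch budget, stopping once
#' validation accuracy reaches `stop_at_val`. Siamese models are trained on
#' both input orders of each pair (the feature difference is signed, so the
#' augmentation teaches order invariance). The per-epoch history (loss,
#' training accuracy, validation accuracy) is attached to the model.
#'
#' @param model A `visreason_model` from [build_cnn()] or [build_siamese()].
#' @param train,val Data lists from [dataset_arrays()] (with `xa`/`xb` for
#'   Siamese models).
#' @param stop_at_val,epochs,learning_rate Optional overrides of the
#'   model's configuration.
#' @return The model with updated `weights` and a `history` data frame.
#' @export
train_model <- function(model, train, val, stop_at_val = NULL, epochs = NULL,
                        learning_rate = NULL) {
  cfg <- model$config
  if (!is.null(stop_at_val)) cfg$stop_at_val <- stop_at_val
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  if (!is.null(learning_rate)) cfg$learning_rate <- learning_rate
  tr <- prep_data(train, cfg$siamese, augment_orders = cfg$siamese)
  va <- prep_data(val, cfg$siamese, augment_orders = FALSE)
  fit <- cpp_nn_train(model$weights, unclass(cfg), tr$X, tr$y, va$X, va$y,
                      tr$X2, va$X2, model$seed)
  model$weights <- fit$weights
  model$config <- cfg
  model$history <- fit$history
  model
}

#' Evaluate a model on a dataset
#'
#' @param model A trained `visreason_model`.
#' @param data Data list from [dataset_arrays()].
#' @return List with `accuracy` and the 2 x n matrix of class probabilities.
#' @export
evaluate_model <- function(model, data) {
  d <- prep_data(data, model$config$siamese, augment_orders = FALSE)
  probs <- cpp_nn_predict(model$weights, unclass(model$config), d$X, d$X2)
  pred <- as.integer(probs[2, ] > probs[1, ])
  list(accuracy = mean(pred == d$y), probs = probs)
}

## Build the three datasets (train/val/test) for one repetition of a task.
make_task_datasets <- function(task, shapes, split, n_train, n_val, n_test,
                               seed, siamese = FALSE) {
  mk <- function(ids, n, s) {
    trials <- generate_dataset(task, n, shapes, ids, seed = s)
    dataset_arrays(trials, shapes, siamese = siamese)
  }
  list(train = mk(split$train_ids, n_train, substream_seed(seed, "train")),
       val = mk(split$train_ids, n_val, substream_seed(seed, "val")),
       test = if (n_test > 0) mk(split$test_ids, n_test,
                                 substream_seed(seed, "test")))
}

#' Run the SD/SR generalization experiment
#'
#' For each requested (task, architecture) pair and each repetition: draw a
#' fresh 30/5 dictionary split, generate fresh 1000-stimulus train /
#' validation / test sets (validation uses training-split shapes at novel
#' placements; test uses the five held-out shapes), initialize a fresh
#' network, train with early stopping, and record final-epoch training
#' accuracy, best validation accuracy and test accuracy. The SR task is
#' learnable and generalizes; the plain CNN on SD fails to generalize
#' (test accuracy near chance) while the Siamese variant generalizes.
#'
#' @param runs Data frame with columns `task` ("SD"/"SR") and `arch`
#'   ("cnn"/"siamese"), one row per condition; default is the three
#'   informative conditions (SR/cnn, SD/cnn, SD/siamese).
#' @param n_reps Repetitions per condition (default 10).
#' @param shapes Dictionary from [enumerate_free_hexominoes()].
#' @param config Base [network_config()]; per-condition epoch budgets can
#'   be supplied via `epochs_by_arch`.
#' @param n_train,n_val,n_test Stimuli per set (default 1000).
#' @param epochs_by_arch Named list of epoch budgets, e.g.
#'   `list(cnn = 70, siamese = 150)` (the Siamese variant takes more
#'   epochs to train).
#' @param seed Master seed; every repetition derives its own substreams.
#' @param min_train_acc Dead-initialization guard: if final training
#'   accuracy stays below this after the full budget, the repetition is
#'   restarted from a shifted seed (the restart rescues optimization
#'   failures of the tiny 4-channel trunk; it cannot create
#'   generalization).
#' @param min_val_acc Optional validation floor (e.g. for the Siamese,
#'   whose protocol trains until validation succeeds): if the best
#'   validation accuracy stays below this, the repetition is restarted.
#'   Validation uses training-split shapes only, so the guard never sees
#'   the held-out test shapes.
#' @param max_restarts Maximum restarts per repetition (default 2).
#' @param probe_epochs Optional probe stage: train this many epochs
#'   first, apply the restart guards, and only continue a healthy run to
#'   the full budget (saves most of a wasted budget on a failed start).
#' @return Object of class `dichotomy_result`: data frame with one row per
#'   (task, arch, rep) plus a `summary()` method giving mean and standard
#'   error.
#' @export
run_dichotomy_experiment <- function(runs = data.frame(
                                       task = c("SR", "SD", "SD"),
                                       arch = c("cnn", "cnn", "siamese")),
                                     n_reps = 10L, shapes, config = network_config(),
                                     n_train = 1000L, n_val = 1000L, n_test = 1000L,
                                     epochs_by_arch = NULL, seed = 1L,
                                     min_train_acc = 0.55, min_val_acc = NULL,
                                     max_restarts = 2L, probe_epochs = NULL) {
  out <- list()
  for (r in seq_len(nrow(runs))) {
    task <- runs$task[r]; arch <- runs$arch[r]
    for (rep in seq_len(n_reps)) {
      rep_seed <- substream_seed(seed, paste(task, arch, rep))
      split <- split_dictionary(shapes, 5L, substream_seed(rep_seed, "split"))
      siam <- arch == "siamese"
      ds <- make_task_datasets(task, shapes, split, n_train, n_val, n_test,
                               rep_seed, siamese = siam)
      ep <- if (!is.null(epochs_by_arch) && !is.null(epochs_by_arch[[arch]]))
        epochs_by_arch[[arch]] else config$epochs
      net_seed <- rep_seed
      restarts <- 0L
      probe <- if (is.null(probe_epochs)) ep else min(probe_epochs, ep)
      repeat {
        model <- if (siam) build_siamese(config, net_seed) else build_cnn(config, net_seed)
        model <- train_model(model, ds$train, ds$val, epochs = probe)
        ## probe-stage guards: dead initialization, or (when a validation
        ## floor applies) training far ahead of a chance-level validation
        dead <- tail(model$history$train_acc, 1) < min_train_acc
        memo <- !is.null(min_val_acc) &&
          max(model$history$val_acc) < 0.55 &&
          tail(model$history$train_acc, 1) > 0.8
        if ((dead || memo) && restarts < max_restarts) {
          restarts <- restarts + 1L
          net_seed <- substream_seed(rep_seed, paste("restart", restarts))
          next
        }
        if (probe < ep &&
            max(model$history$val_acc) < model$config$stop_at_val) {
          h1 <- model$history
          model <- train_model(model, ds$train, ds$val, epochs = ep - probe)
          model$history <- rbind(h1, transform(model$history,
                                               epoch = epoch + nrow(h1)))
        }
        healthy <- tail(model$history$train_acc, 1) >= min_train_acc &&
          (is.null(min_val_acc) || max(model$history$val_acc) >= min_val_acc)
        if (healthy || restarts >= max_restarts) break
        restarts <- restarts + 1L
        net_seed <- substream_seed(rep_seed, paste("restart", restarts))
      }
      test <- evaluate_model(model, ds$test)
      out[[length(out) + 1L]] <- data.frame(
        task = task, arch = arch, rep = rep,
        train_acc = tail(model$history$train_acc, 1),
        best_val_acc = max(model$history$val_acc),
        test_acc = test$accuracy,
        epochs_run = nrow(model$history), restarts = restarts,
        seed = rep_seed)
    }
  }
  structure(do.call(rbind, out), class = c("dichotomy_result", "data.frame"))
}

#' @export
summary.dichotomy_result <- function(object, ...) {
  agg <- function(v) c(mean = mean(v), se = sd(v) / sqrt(length(v)))
  sp <- split(object, paste(object$task, object$arch))
  do.call(rbind, lapply(sp, function(d) {
    data.frame(task = d$task[1], arch = d$arch[1], n_reps = nrow(d),
               train_acc = mean(d$train_acc),
               test_acc = mean(d$test_acc),
               test_se = sd(d$test_acc) / sqrt(nrow(d)))
  }))
}
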