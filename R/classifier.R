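#' Training configuration for the beat-image classifier
#'
#' `architecture` selects one of the built-in presets. `small_cnn` (three
#' 3x3 convolution blocks with 8/16/32 filters, each followed by ReLU and
#' 2x2 max pooling, then a global average pool and a four-way softmax head)
#' is the reference architecture used throughout the tests. `resnet_tl`,
#' `alexnet_tl` and `squeezenet_tl` are presets named after the published
#' networks they stand in for: they run the same engine with larger filter
#' banks, train from random initialisation (no external weights are shipped
#' or downloaded), and report the nominal deep-layer counts of their
#' namesakes (177 / 25 / 68) for bookkeeping parity.
#'
#' @param architecture one of `"small_cnn"`, `"resnet_tl"`, `"alexnet_tl"`,
#'   `"squeezenet_tl"`.
#' @param epochs number of passes over the training set (>= 1).
#' @param batch_size minibatch size.
#' @param learning_rate optimizer step size.
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed integer seed for weight initialisation and batch shuffling.
#' @param split_fraction fraction of each class assigned to training by
#'   [split_half()] callers (0.5 = the half/half protocol).
#' @param balance_to target per-class count for [balance_classes()], or
#'   `"min_class"`.
#' @param image_size image side in pixels fed to the network (must be a
#'   multiple of 8 so three pooling stages divide evenly).
#' @return An object of class `train_config`.
#' @export
train_config <- function(architecture = c("small_cnn", "resnet_tl",
                                          "alexnet_tl", "squeezenet_tl"),
                         epochs = 10L, batch_size = 16L,
                         learning_rate = 3e-3,
                         optimizer = c("adam", "sgd"),
                         seed = 1L, split_fraction = 0.5,
                         balance_to = "min_class",
                         image_size = 64L) {
  architecture <- match.arg(architecture)
  optimizer <- match.arg(optimizer)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop("split_fraction must be in (0, 1)", call. = FALSE)
  }
  if (image_size %% 8L != 0L || image_size < 32L) {
    stop("image_size must be a multiple of 8, >= 32", call. = FALSE)
  }
  structure(list(architecture = architecture, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 seed = as.integer(seed), split_fraction = split_fraction,
                 balance_to = balance_to, image_size = as.integer(image_size)),
            class = "train_config")
}

# preset -> filter bank + nominal published layer count
architecture_preset <- function(architecture) {
  switch(architecture,
    small_cnn     = list(filters = c(8L, 16L, 32L),  deep_layers = 11L),
    resnet_tl     = list(filters = c(16L, 32L, 64L), deep_layers = 177L),
    alexnet_tl    = list(filters = c(12L, 24L, 48L), deep_layers = 25L),
    squeezenet_tl = list(filters = c(8L, 16L, 32L),  deep_layers = 68L),
    stop("unknown architecture: ", architecture, call. = FALSE))
}

#' Downsample every class of a manifest to a common size
#'
#' Sampling is without replacement and deterministic under `seed`. With
#' `n_per_class = "min_class"` every class is reduced to the size of the
#' smallest class (the protocol that turns unbalanced beat counts into a
#' balanced dataset before the half/half split).
#'
#' @param manifest data.frame with at least `path` and `label` columns.
#' @param n_per_class integer target per class, or `"min_class"`.
#' @param seed integer seed.
#' @return The balanced manifest (row order: class blocks in
#'   [beat_classes()] order).
#' @export
#' @examples
#' m <- data.frame(path = as.character(1:12),
#'                 label = rep(beat_classes(), c(5, 3, 2, 2)))
#' table(balance_classes(m, "min_class", seed = 1)$label)
balance_classes <- function(manifest, n_per_class = "min_class", seed = 1L) {
  stopifnot(is.data.frame(manifest), all(c("path", "label") %in% names(manifest)))
  counts <- table(factor(manifest$label, levels = unique(manifest$label)))
  if (identical(n_per_class, "min_class")) n_per_class <- min(counts)
  n_per_class <- as.integer(n_per_class)
  if (any(counts < n_per_class)) {
    small <- names(counts)[counts < n_per_class][1]
    stop("class ", small, " has only ", counts[small],
         " items; cannot sample ", n_per_class, call. = FALSE)
  }
  with_local_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(manifest)), manifest$label),
                          function(i) sort(sample(i, n_per_class))))
  })
  manifest[keep, , drop = FALSE]
}

#' Split a manifest half-and-half per class
#'
#' Each class is shuffled deterministically under `seed`; the training set
#' receives `ceiling(n * fraction)` items and the test set the remainder, so
#' an odd class of 5899 yields 2950 training and 2949 test images. The two
#' halves are disjoint and together restore the input.
#'
#' @param manifest data.frame with `path` and `label`.
#' @param seed integer seed.
#' @param fraction training fraction (default 0.5).
#' @return List with elements `train` and `test`.
#' @export
split_half <- function(manifest, seed = 1L, fraction = 0.5) {
  stopifnot(is.data.frame(manifest), all(c("path", "label") %in% names(manifest)))
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  if (any(table(manifest$label) < 2L)) {
    stop("every class needs at least 2 items to split", call. = FALSE)
  }
  tr_idx <- with_local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(manifest)), manifest$label), function(i) {
      i <- sample(i)
      i[seq_len(ceiling(length(i) * fraction))]
    }))
  })
  tr_idx <- sort(tr_idx)
  list(train = manifest[tr_idx, , drop = FALSE],
       test = manifest[-tr_idx, , drop = FALSE])
}

# Load manifest images into an array(H, W, 1, N), resizing by nearest
# neighbour when the stored size differs from `size`. Images are stored
# trace-dark on a white background; the network consumes them inverted
# (trace = 1, background = 0) so the sparse trace, not the constant
# background, carries the activations.
images_from_manifest <- function(manifest, size) {
  N <- nrow(manifest)
  X <- array(0, c(size, size, 1L, N))
  for (i in seq_len(N)) {
    m <- read_beat_image(manifest$path[i])
    if (nrow(m) != size || ncol(m) != size) {
      ri <- round(seq(1, nrow(m), length.out = size))
      ci <- round(seq(1, ncol(m), length.out = size))
      m <- m[ri, ci]
    }
    X[, , 1L, i] <- 1 - m
  }
  X
}

one_hot <- function(labels, classes) {
  Y <- matrix(0, nrow = length(labels), ncol = length(classes))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Fit the beat-image classifier
#'
#' Trains a convolutional network on the images listed in a labeled
#' manifest, minimising softmax cross-entropy with minibatch Adam (or SGD).
#' All four beat classes must be present: the four-way output head is fixed.
#' Training is deterministic for a given configuration: weights, batch order
#' and hence the final model depend only on `config$seed`.
#'
#' @param manifest data.frame with `path` and `label` columns (as produced
#'   by [build_image_dataset()]).
#' @param config a [train_config()].
#' @param verbose print per-epoch loss/accuracy.
#' @return An object of class `ecg_cnn`: the fitted model, with `history`
#'   (per-epoch loss and training accuracy), usable with [predict()],
#'   [evaluate_classifier()], [save_model()].
#' @export
train_beat_classifier <- function(manifest, config = train_config(),
                                  verbose = FALSE) {
  stopifnot(is.data.frame(manifest), inherits(config, "train_config"))
  if (nrow(manifest) == 0L) stop("empty training manifest", call. = FALSE)
  labels <- as_beat_class(manifest$label)
  missing <- setdiff(beat_classes(), unique(labels))
  if (length(missing) > 0L) {
    stop("training manifest is missing class(es): ",
         paste(missing, collapse = ", "),
         " (the four-class head is fixed)", call. = FALSE)
  }
  preset <- architecture_preset(config$architecture)
  n_blocks <- length(preset$filters)
  classes <- beat_classes()
  X <- images_from_manifest(manifest, config$image_size)
  Y <- one_hot(labels, classes)
  N <- nrow(Y)

  params <- cnn_init(preset$filters, in_channels = 1L,
                     n_classes = length(classes), seed = config$seed)
  state <- adam_init(params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))

  for (ep in seq_len(config$epochs)) {
    ord <- with_local_seed(as.numeric(config$seed) * 1000 + ep, sample.int(N))
    ep_loss <- 0
    n_correct <- 0L
    for (start in seq(1L, N, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, N)]
      lg <- cnn_loss_grad(params, X[, , , idx, drop = FALSE],
                          Y[idx, , drop = FALSE], n_blocks)
      if (config$optimizer == "adam") {
        st <- adam_step(params, lg$grads, state, config$learning_rate)
        params <- st$params
        state <- st$state
      } else {
        params <- sgd_step(params, lg$grads, config$learning_rate)
      }
      ep_loss <- ep_loss + lg$loss * length(idx)
      n_correct <- n_correct +
        sum(max.col(lg$probs, ties.method = "first") ==
              max.col(Y[idx, , drop = FALSE], ties.method = "first"))
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / N,
                                         accuracy = n_correct / N))
    if (verbose) {
      message(sprintf("epoch %d: loss %.4f, train accuracy %.3f",
                      ep, ep_loss / N, n_correct / N))
    }
  }

  structure(list(architecture = config$architecture,
                 deep_layers = preset$deep_layers,
                 filters = preset$filters,
                 image_size = config$image_size,
                 classes = classes,
                 params = params,
                 config = config,
                 history = history,
                 manifest_hash = manifest_hash(manifest)),
            class = "ecg_cnn")
}

manifest_hash <- function(manifest) {
  # order-independent fingerprint of the training membership
  key <- sort(paste(basename(manifest$path), manifest$label, sep = ":"))
  sum(utf8ToInt(paste(key, collapse = "|"))) %% 2147483647
}

#' @export
print.ecg_cnn <- function(x, ...) {
  cat(sprintf("<ecg_cnn> %s (%d nominal deep layers), input %dx%d, classes: %s\n",
              x$architecture, x$deep_layers, x$image_size, x$image_size,
              paste(x$classes, collapse = ", ")))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("trained %d epochs; final loss %.4f, train accuracy %.3f\n",
                last$epoch, last$loss, last$accuracy))
  }
  invisible(x)
}

#' @export
summary.ecg_cnn <- function(object, ...) {
  print(object)
  cat("training history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Predict beat classes for new images
#'
#' @param object an `ecg_cnn` model.
#' @param newdata a manifest data.frame with a `path` column, or a numeric
#'   array `(H, W, 1, N)` of images in `[0, 1]` in rendered polarity (white
#'   background = 1); arrays are inverted internally like manifest images.
#' @param type `"class"` for labels, `"prob"` for the N x 4 probability
#'   matrix.
#' @param ... unused.
#' @export
predict.ecg_cnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (is.data.frame(newdata)) {
    images_from_manifest(newdata, object$image_size)
  } else {
    stopifnot(is.array(newdata), length(dim(newdata)) == 4L)
    1 - newdata
  }
  n_blocks <- length(object$filters)
  N <- dim(X)[4]
  probs <- matrix(0, N, length(object$classes))
  for (start in seq(1L, N, by = 64L)) {
    idx <- start:min(start + 63L, N)
    fw <- cnn_forward(object$params, X[, , , idx, drop = FALSE], n_blocks)
    probs[idx, ] <- fw$probs
  }
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' Evaluate a model on a labeled test manifest
#'
#' @param model an `ecg_cnn`.
#' @param test_manifest data.frame with `path` and `label`; every item must
#'   be labeled.
#' @return A [confusion_table()] (rows = true, columns = predicted).
#' @export
evaluate_classifier <- function(model, test_manifest) {
  stopifnot(inherits(model, "ecg_cnn"), is.data.frame(test_manifest))
  if (anyNA(test_manifest$label)) {
    stop("every test item must be labeled", call. = FALSE)
  }
  true <- as_beat_class(test_manifest$label)
  pred <- predict(model, test_manifest, type = "class")
  confusion_from_labels(true, pred, classes = model$classes)
}

#' Save / load a fitted model
#'
#' The checkpoint is a self-describing RDS: architecture, input size, class
#' order, weights and training history. Reloading reproduces identical
#' predictions.
#'
#' @param model an `ecg_cnn`.
#' @param path checkpoint file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ecg_cnn"))
  saveRDS(c(list(format = "ecgflow_cnn", version = 1L), unclass(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "ecgflow_cnn")) {
    stop("not an ecgflow model checkpoint: ", path, call. = FALSE)
  }
  obj$format <- NULL
  obj$version <- NULL
  structure(obj, class = "ecg_cnn")
}
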