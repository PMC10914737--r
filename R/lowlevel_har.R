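#' Configuration of the low-level activity CNN
#'
#' The smartphone accelerometer network: seven 1-D convolutional layers with
#' either 16 or 32 filters and kernel sizes 5 resp. 3, max pooling of size 2
#' after every second convolution (three pools, 192 -> 24 time steps), two
#' dense layers of 32 and 16 neurons, and a softmax head. Train-time
#' augmentation applies a small random 3-D rotation per window plus additive
#' Gaussian noise; spatial dropout acts on the last convolution's channels and
#' ordinary dropout on the flattened activations.
#'
#' @param filters Seven filter counts, each 16 or 32.
#' @param kernels Seven kernel sizes, each 5 or 3.
#' @param pool_after Logical vector: max-pool (size 2) after this conv layer.
#' @param dense Sizes of the two dense layers.
#' @param n_classes Number of output classes (6 with "on table", 5 when
#'   running is dropped).
#' @param rotation_max_deg Augmentation rotation bound per axis, degrees.
#' @param gauss_noise_std Augmentation noise standard deviation, m/s².
#' @param spatial_dropout,dropout Dropout proportions.
#' @param learning_rate,epochs,batch_size Training hyper-parameters.
#' @param window_s,rate Window length (s) and nominal accelerometer rate (Hz);
#'   their product is the 192-sample input length.
#' @return A list of class `"har_cnn_config"`.
#' @export
har_cnn_config <- function(filters = c(32, 32, 16, 16, 16, 16, 16),
                           kernels = c(5, 5, 3, 3, 3, 3, 3),
                           pool_after = c(FALSE, TRUE, FALSE, TRUE, FALSE,
                                          TRUE, FALSE),
                           dense = c(32, 16),
                           n_classes = 6,
                           rotation_max_deg = 15,
                           gauss_noise_std = 0.1,
                           spatial_dropout = 0.1,
                           dropout = 0.3,
                           learning_rate = 1e-3,
                           epochs = 30,
                           batch_size = 128,
                           window_s = 6,
                           rate = 32) {
  stopifnot(length(filters) == 7, length(kernels) == 7,
            length(pool_after) == 7,
            all(filters %in% c(16, 32)), all(kernels %in% c(3, 5)),
            length(dense) == 2, n_classes >= 2,
            rotation_max_deg >= 0, gauss_noise_std >= 0,
            spatial_dropout >= 0, spatial_dropout < 1,
            dropout >= 0, dropout < 1)
  structure(list(filters = filters, kernels = kernels,
                 pool_after = pool_after, dense = dense,
                 n_classes = n_classes, rotation_max_deg = rotation_max_deg,
                 gauss_noise_std = gauss_noise_std,
                 spatial_dropout = spatial_dropout, dropout = dropout,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, window_s = window_s, rate = rate,
                 input_len = window_s * rate),
            class = "har_cnn_config")
}

#' Randomly rotate an accelerometer window
#'
#' Train-time augmentation simulating small differences in how the phone hangs
#' on its lanyard: one random 3-D rotation (angles uniform in
#' `±max_deg` per axis, composed as X then Y then Z) is applied to every
#' sample of the window. Rotations are isometries, so sample norms are
#' preserved.
#'
#' @param window A numeric `n x 3` matrix of accelerations.
#' @param max_deg Maximum rotation angle per axis in degrees.
#' @param rng_seed Optional seed for reproducible augmentation.
#' @return The rotated `n x 3` matrix.
#' @export
rotate_augment <- function(window, max_deg, rng_seed = NULL) {
  stopifnot(ncol(window) == 3, max_deg >= 0)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (max_deg == 0) return(window)
  window %*% t(random_rotation(max_deg))
}

random_rotation <- function(max_deg) {
  a <- stats::runif(3, -max_deg, max_deg) * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rx %*% Ry %*% Rz
}

#' Build the low-level activity CNN
#'
#' @param cfg A [har_cnn_config()].
#' @param classes Output class names (length `cfg$n_classes`); defaults to the
#'   six low-level classes.
#' @param seed Seed for parameter initialization.
#' @return An untrained model of class `"har_cnn"`.
#' @export
build_har_cnn <- function(cfg = har_cnn_config(),
                          classes = lowlevel_classes()[seq_len(cfg$n_classes)],
                          seed = 1) {
  stopifnot(length(classes) == cfg$n_classes)
  L <- cfg$input_len
  if (L %% 2^sum(cfg$pool_after) != 0) {
    stop("input length must be divisible by 2^(number of pools)",
         call. = FALSE)
  }
  set.seed(seed)
  layers <- list()
  c_in <- 3
  for (i in 1:7) {
    layers[[paste0("conv", i)]] <- conv1d_init(c_in, cfg$filters[i],
                                               cfg$kernels[i])
    c_in <- cfg$filters[i]
    if (cfg$pool_after[i]) L <- L / 2
  }
  flat <- L * c_in
  layers$dense1 <- dense_init(flat, cfg$dense[1])
  layers$dense2 <- dense_init(cfg$dense[1], cfg$dense[2])
  layers$head <- dense_init(cfg$dense[2], cfg$n_classes)
  structure(list(cfg = cfg, classes = classes, layers = layers,
                 flat_dim = flat, trained = FALSE, history = NULL),
            class = "har_cnn")
}

#' @export
print.har_cnn <- function(x, ...) {
  cfg <- x$cfg
  cat("<har_cnn> input", cfg$input_len, "x 3 ->", cfg$n_classes,
      "classes (", paste(x$classes, collapse = ", "), ")\n")
  cat("  conv filters:", paste(cfg$filters, collapse = "/"),
      " kernels:", paste(cfg$kernels, collapse = "/"),
      " pools after:", paste(which(cfg$pool_after), collapse = ","), "\n")
  cat("  dense:", paste(cfg$dense, collapse = " -> "),
      if (x$trained) " [trained]" else " [untrained]", "\n")
  invisible(x)
}

# Forward pass. x: (N, input_len, 3). In training mode applies augmentation
# (rotation + Gaussian noise) and dropout using the current RNG state.
har_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  caches <- list()
  if (training) {
    N <- dim(x)[1]
    if (cfg$rotation_max_deg > 0) {
      for (n in seq_len(N)) {
        x[n, , ] <- matrix(x[n, , ], ncol = 3) %*%
          t(random_rotation(cfg$rotation_max_deg))
      }
    }
    if (cfg$gauss_noise_std > 0) {
      x <- x + array(stats::rnorm(length(x), 0, cfg$gauss_noise_std), dim(x))
    }
  }
  h <- x
  for (i in 1:7) {
    nm <- paste0("conv", i)
    cv <- conv1d_forward(model$layers[[nm]], h)
    caches[[nm]] <- cv$cache
    rl <- relu_forward(cv$y)
    caches[[paste0(nm, "_relu")]] <- rl$cache
    h <- rl$y
    if (cfg$pool_after[i]) {
      mp <- maxpool2_forward(h)
      caches[[paste0(nm, "_pool")]] <- mp$cache
      h <- mp$y
    }
  }
  if (training && cfg$spatial_dropout > 0) {
    d <- dim(h)
    keep <- matrix(stats::rbinom(d[1] * d[3], 1, 1 - cfg$spatial_dropout),
                   d[1], d[3]) / (1 - cfg$spatial_dropout)
    mask <- aperm(array(keep, c(d[1], d[3], d[2])), c(1, 3, 2))
    h <- h * mask
    caches$sdrop <- mask
  }
  flat_dims <- dim(h)
  h <- matrix(h, nrow = flat_dims[1])
  caches$flat_dims <- flat_dims
  if (training && cfg$dropout > 0) {
    mask <- matrix(stats::rbinom(length(h), 1, 1 - cfg$dropout),
                   nrow(h)) / (1 - cfg$dropout)
    h <- h * mask
    caches$drop <- mask
  }
  d1 <- dense_forward(model$layers$dense1, h)
  caches$dense1 <- d1$cache
  r1 <- relu_forward(d1$y)
  caches$dense1_relu <- r1$cache
  d2 <- dense_forward(model$layers$dense2, r1$y)
  caches$dense2 <- d2$cache
  r2 <- relu_forward(d2$y)
  caches$dense2_relu <- r2$cache
  hd <- dense_forward(model$layers$head, r2$y)
  caches$head <- hd$cache
  list(logits = hd$y, caches = caches, training = training)
}

har_backward <- function(model, fw, dlogits) {
  cfg <- model$cfg
  caches <- fw$caches
  grads <- list()
  bk <- dense_backward(model$layers$head, caches$head, dlogits)
  grads[["head.W"]] <- bk$dW; grads[["head.b"]] <- bk$db
  dy <- relu_backward(caches$dense2_relu, bk$dx)
  bk <- dense_backward(model$layers$dense2, caches$dense2, dy)
  grads[["dense2.W"]] <- bk$dW; grads[["dense2.b"]] <- bk$db
  dy <- relu_backward(caches$dense1_relu, bk$dx)
  bk <- dense_backward(model$layers$dense1, caches$dense1, dy)
  grads[["dense1.W"]] <- bk$dW; grads[["dense1.b"]] <- bk$db
  dy <- bk$dx
  if (!is.null(caches$drop)) dy <- dy * caches$drop
  dy <- array(dy, caches$flat_dims)
  if (!is.null(caches$sdrop)) dy <- dy * caches$sdrop
  for (i in 7:1) {
    nm <- paste0("conv", i)
    if (cfg$pool_after[i]) {
      dy <- maxpool2_backward(caches[[paste0(nm, "_pool")]], dy)
    }
    dy <- relu_backward(caches[[paste0(nm, "_relu")]], dy)
    bk <- conv1d_backward(model$layers[[nm]], caches[[nm]], dy)
    grads[[paste0(nm, ".W")]] <- bk$dW
    grads[[paste0(nm, ".b")]] <- bk$db
    dy <- bk$dx
  }
  grads
}

#' Group cross-validation split by participant
#'
#' Keeps `holdout_n` participants apart as a holdout set and partitions the
#' remaining ones into `k` validation folds of near-equal size (for 31
#' participants: holdout 10, validation fold sizes 6/5/5/5). No participant
#' appears in both the train and validation side of a fold.
#'
#' @param participants Character or integer vector of participant ids.
#' @param holdout_n Holdout set size.
#' @param k Number of folds.
#' @param seed Seed controlling the shuffle.
#' @return A list of class `"cv_split"` with `holdout` and `folds` (each fold
#'   a list with `train` and `val`).
#' @export
make_cv_split <- function(participants, holdout_n = 10, k = 4, seed = 1) {
  participants <- unique(participants)
  n <- length(participants)
  if (n < holdout_n + k) {
    stop("need at least holdout_n + k = ", holdout_n + k, " participants, got ",
         n, call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(participants)
  holdout <- shuffled[seq_len(holdout_n)]
  rest <- shuffled[-seq_len(holdout_n)]
  sizes <- rep(floor(length(rest) / k), k)
  extra <- length(rest) - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  folds <- vector("list", k)
  pos <- 0
  for (i in seq_len(k)) {
    val <- rest[pos + seq_len(sizes[i])]
    folds[[i]] <- list(train = setdiff(rest, val), val = val)
    pos <- pos + sizes[i]
  }
  structure(list(holdout = holdout, folds = folds), class = "cv_split")
}

#' @export
print.cv_split <- function(x, ...) {
  cat("<cv_split> holdout:", length(x$holdout), "participants;",
      length(x$folds), "folds with validation sizes",
      paste(vapply(x$folds, function(f) length(f$val), integer(1)),
            collapse = "/"), "\n")
  invisible(x)
}

#' Extract labeled training windows from an accelerometer stream
#'
#' Slices the (grid-regular) accelerometer stream into `window_s`-second
#' windows with `stride_s` stride and attaches to each window the minute label
#' containing its center; windows whose minute is missing are excluded.
#'
#' @param accel Accelerometer [sensor_series()] (resampled to the nominal grid
#'   if needed).
#' @param minute_labels Tibble from [aggregate_to_minutes()] /
#'   [overrule_with_on_table()] / [drop_running()].
#' @param cfg A [har_cnn_config()] (for window length, stride = window/2, and
#'   rate).
#' @param stride_s Window stride in seconds.
#' @return A list with `x` (N x input_len x 3 array), `label` (character) and
#'   `start` (window start times).
#' @export
har_training_windows <- function(accel, minute_labels, cfg = har_cnn_config(),
                                 stride_s = 3) {
  accel <- resample_accel(accel, rate = cfg$rate)
  n <- nrow(accel)
  len <- cfg$input_len
  if (n < len) {
    return(list(x = array(0, c(0, len, 3)), label = character(),
                start = numeric()))
  }
  step_idx <- round(stride_s * cfg$rate)
  starts_idx <- seq(1, n - len + 1, by = step_idx)
  X <- array(0, c(length(starts_idx), len, 3))
  m <- as.matrix(accel[, c("x", "y", "z")])
  for (i in seq_along(starts_idx)) {
    X[i, , ] <- m[starts_idx[i] + 0:(len - 1), ]
  }
  start_t <- accel$t[starts_idx]
  center <- start_t + cfg$window_s / 2
  lab <- minute_labels$label[match(floor(center / 60) * 60,
                                   minute_labels$minute_start)]
  keep <- !is.na(lab)
  list(x = X[keep, , , drop = FALSE], label = lab[keep],
       start = start_t[keep])
}

#' Train the low-level activity CNN
#'
#' Minimizes categorical cross-entropy with per-class inverse-frequency
#' weights using Adam, with rotation + Gaussian-noise augmentation re-drawn
#' every epoch. Classes absent from the training data stay in the output head
#' (with a warning).
#'
#' @param model An untrained [build_har_cnn()] model.
#' @param x `N x input_len x 3` array of windows.
#' @param labels Character vector of window labels (length N).
#' @param epochs,batch_size,learning_rate Override the config values.
#' @param seed Seed for shuffling, augmentation and dropout.
#' @param verbose Print the loss once per epoch.
#' @return The fitted model with a `history` tibble (epoch, loss, accuracy).
#' @export
train_har <- function(model, x, labels, epochs = NULL, batch_size = NULL,
                      learning_rate = NULL, seed = 1, verbose = FALSE) {
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  learning_rate <- learning_rate %||% cfg$learning_rate
  y <- match(labels, model$classes)
  if (anyNA(y)) {
    stop("labels outside the model's class set: ",
         paste(unique(labels[is.na(y)]), collapse = ", "), call. = FALSE)
  }
  counts <- tabulate(y, nbins = length(model$classes))
  if (any(counts == 0)) {
    warning("class(es) absent from training data: ",
            paste(model$classes[counts == 0], collapse = ", "),
            "; kept in the output head")
  }
  class_w <- ifelse(counts > 0, length(y) / (length(model$classes) * counts), 1)
  set.seed(seed)
  opt <- adam_init(collect_params(model$layers))
  N <- dim(x)[1]
  history <- vector("list", epochs)
  if (epochs == 0) {
    model$history <- tibble::tibble(epoch = integer(), loss = numeric(),
                                    accuracy = numeric())
    return(model)
  }
  for (ep in seq_len(epochs)) {
    perm <- sample.int(N)
    total_loss <- 0
    correct <- 0
    for (b0 in seq(1, N, by = batch_size)) {
      idx <- perm[b0:min(b0 + batch_size - 1, N)]
      xb <- x[idx, , , drop = FALSE]
      yb <- y[idx]
      fw <- har_forward(model, xb, training = TRUE)
      sc <- softmax_ce(fw$logits, yb, class_w)
      grads <- har_backward(model, fw, sc$dz)
      params <- collect_params(model$layers)
      upd <- adam_step(opt, params, grads, lr = learning_rate)
      opt <- upd$state
      model$layers <- assign_params(model$layers, upd$params)
      total_loss <- total_loss + sc$loss * length(idx)
      correct <- correct + sum(max.col(sc$p) == yb)
    }
    history[[ep]] <- tibble::tibble(epoch = ep, loss = total_loss / N,
                                    accuracy = correct / N)
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f  acc %.3f", ep, total_loss / N,
                      correct / N))
    }
  }
  model$history <- dplyr::bind_rows(history)
  model$trained <- TRUE
  model
}

#' Predict low-level activity probabilities for an accelerometer stream
#'
#' Slides the model's 6-second window with a 3-second stride over the stream
#' (resampled onto the nominal grid) and returns one probability vector per
#' stride step. Inference is deterministic: augmentation, noise and dropout
#' are disabled.
#'
#' @param model A fitted `"har_cnn"`.
#' @param accel Accelerometer [sensor_series()].
#' @param stride_s Prediction step in seconds.
#' @return A [prob_series()] at `stride_s` step (empty for streams shorter
#'   than one window).
#' @export
predict_probs <- function(model, accel, stride_s = 3) {
  cfg <- model$cfg
  accel <- resample_accel(accel, rate = cfg$rate)
  n <- nrow(accel)
  len <- cfg$input_len
  if (n < len) {
    return(prob_series(numeric(), matrix(0, 0, length(model$classes)),
                       model$classes))
  }
  step_idx <- round(stride_s * cfg$rate)
  starts_idx <- seq(1, n - len + 1, by = step_idx)
  m <- as.matrix(accel[, c("x", "y", "z")])
  X <- array(0, c(length(starts_idx), len, 3))
  for (i in seq_along(starts_idx)) {
    X[i, , ] <- m[starts_idx[i] + 0:(len - 1), ]
  }
  p <- matrix(0, length(starts_idx), length(model$classes))
  chunk <- 512
  for (b0 in seq(1, length(starts_idx), by = chunk)) {
    sel <- b0:min(b0 + chunk - 1, length(starts_idx))
    fw <- har_forward(model, X[sel, , , drop = FALSE], training = FALSE)
    p[sel, ] <- softmax_rows(fw$logits)
  }
  prob_series(accel$t[starts_idx], p, model$classes)
}
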