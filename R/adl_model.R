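#' Configuration of the ADL sequence network
#'
#' The multi-label ADL detector: an LSTM over the 200-step (10-minute, one
#' point per 3 s) feature window returning the full sequence, a skip
#' connection concatenating the LSTM output with the raw input, a pointwise
#' convolution (16 filters, kernel 1, rectifier), max pooling of size 2
#' reducing the time dimension to 100, and a final pointwise convolution with
#' 12 filters (one per ADL) and sigmoid activation — one independent binary
#' classifier per activity every 6 seconds. With `use_lstm = FALSE` the LSTM
#' and the skip connection are dropped, leaving the two pointwise convolutions
#' as a temporal-context-free baseline.
#'
#' @param lstm_units Number of LSTM units.
#' @param dropout Dropout proportion on the first convolution's activations.
#' @param gauss_noise_std Std of Gaussian noise added to the input features
#'   during training.
#' @param l1,l2 Regularization weights on the network's weight matrices.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs (the reference protocol uses 350).
#' @param batch_size Mini-batch size (the reference protocol uses 1024).
#' @param use_lstm `FALSE` gives the no-LSTM baseline.
#' @param threshold Binarization threshold on the sigmoid outputs.
#' @return A list of class `"adl_net_config"`.
#' @export
adl_net_config <- function(lstm_units = 32, dropout = 0.1,
                           gauss_noise_std = 0.05, l1 = 0, l2 = 1e-5,
                           learning_rate = 3e-3, epochs = 350,
                           batch_size = 1024, use_lstm = TRUE,
                           threshold = 0.5) {
  stopifnot(lstm_units >= 1, dropout >= 0, dropout < 1, gauss_noise_std >= 0,
            l1 >= 0, l2 >= 0, learning_rate > 0, epochs >= 0, batch_size >= 1,
            threshold > 0, threshold < 1)
  structure(list(lstm_units = as.integer(lstm_units), dropout = dropout,
                 gauss_noise_std = gauss_noise_std, l1 = l1, l2 = l2,
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), use_lstm = use_lstm,
                 conv1_filters = 16L, conv2_filters = 12L, pool = 2L,
                 threshold = threshold),
            class = "adl_net_config")
}

#' Build the ADL sequence network
#'
#' @param cfg An [adl_net_config()].
#' @param n_features Feature dimension F of the input windows.
#' @param classes Output classes; fixed to the 12-ADL registry.
#' @param seed Seed for parameter initialization.
#' @return An untrained model of class `"adl_net"` mapping
#'   `200 x F -> 100 x 12`.
#' @export
build_adl_network <- function(cfg = adl_net_config(), n_features,
                              classes = adl_registry(), seed = 1) {
  stopifnot(n_features >= 1, length(classes) == cfg$conv2_filters)
  set.seed(seed)
  layers <- list()
  conv1_in <- n_features
  if (cfg$use_lstm) {
    layers$lstm <- lstm_init(n_features, cfg$lstm_units)
    conv1_in <- cfg$lstm_units + n_features # skip connection concatenation
  }
  # kernel-size-1 convolutions are dense maps applied per time step
  layers$conv1 <- dense_init(conv1_in, cfg$conv1_filters)
  layers$conv2 <- dense_init(cfg$conv1_filters, cfg$conv2_filters)
  structure(list(cfg = cfg, classes = classes, n_features = n_features,
                 layers = layers, trained = FALSE, history = NULL),
            class = "adl_net")
}

#' @export
print.adl_net <- function(x, ...) {
  cfg <- x$cfg
  cat("<adl_net>", if (cfg$use_lstm) paste0("LSTM(", cfg$lstm_units,
                                            ") + skip -> ") else "baseline: ",
      "conv(16,k1,relu) -> pool(2) -> conv(12,k1,sigmoid)\n")
  cat("  input: T x", x$n_features, " output: T/2 x", length(x$classes),
      if (x$trained) " [trained]" else " [untrained]", "\n")
  invisible(x)
}

# Forward pass. x: (N, L, F) with L even -> probabilities (N, L/2, 12).
adl_forward <- function(model, x, training = FALSE) {
  cfg <- model$cfg
  caches <- list()
  if (training && cfg$gauss_noise_std > 0) {
    x <- x + array(stats::rnorm(length(x), 0, cfg$gauss_noise_std), dim(x))
  }
  d <- dim(x)
  h <- x
  if (cfg$use_lstm) {
    lf <- lstm_forward(model$layers$lstm, x)
    caches$lstm <- lf$cache
    # skip connection: concatenate LSTM sequence with the raw input features
    h <- array(0, c(d[1], d[2], cfg$lstm_units + d[3]))
    h[, , seq_len(cfg$lstm_units)] <- lf$y
    h[, , cfg$lstm_units + seq_len(d[3])] <- x
  }
  hd <- dim(h)
  h2 <- matrix(h, nrow = hd[1] * hd[2]) # rows: n fastest, then time
  c1 <- dense_forward(model$layers$conv1, h2)
  caches$conv1 <- c1$cache
  r1 <- relu_forward(c1$y)
  caches$relu1 <- r1$cache
  a1 <- r1$y
  if (training && cfg$dropout > 0) {
    mask <- matrix(stats::rbinom(length(a1), 1, 1 - cfg$dropout),
                   nrow(a1)) / (1 - cfg$dropout)
    a1 <- a1 * mask
    caches$drop <- mask
  }
  a1a <- array(a1, c(hd[1], hd[2], cfg$conv1_filters))
  mp <- maxpool2_forward(a1a)
  caches$pool <- mp$cache
  pd <- dim(mp$y)
  p2 <- matrix(mp$y, nrow = pd[1] * pd[2])
  c2 <- dense_forward(model$layers$conv2, p2)
  caches$conv2 <- c2$cache
  z <- array(c2$y, c(pd[1], pd[2], cfg$conv2_filters))
  caches$dims <- list(input = d, concat = hd, pooled = pd)
  list(z = z, probs = sigmoid(z), caches = caches)
}

# Backward pass from dL/dz (gradient w.r.t. the pre-sigmoid output).
adl_backward <- function(model, fw, dz) {
  cfg <- model$cfg
  caches <- fw$caches
  dims <- caches$dims
  grads <- list()
  dz2 <- matrix(dz, nrow = dims$pooled[1] * dims$pooled[2])
  bk <- dense_backward(model$layers$conv2, caches$conv2, dz2)
  grads[["conv2.W"]] <- bk$dW; grads[["conv2.b"]] <- bk$db
  dpool <- array(bk$dx, dims$pooled[1:2] |> c(cfg$conv1_filters))
  da1 <- maxpool2_backward(caches$pool, dpool)
  da1 <- matrix(da1, nrow = dims$concat[1] * dims$concat[2])
  if (!is.null(caches$drop)) da1 <- da1 * caches$drop
  dc1 <- relu_backward(caches$relu1, da1)
  bk <- dense_backward(model$layers$conv1, caches$conv1, dc1)
  grads[["conv1.W"]] <- bk$dW; grads[["conv1.b"]] <- bk$db
  dh <- array(bk$dx, dims$concat)
  if (cfg$use_lstm) {
    dlstm_out <- dh[, , seq_len(cfg$lstm_units), drop = FALSE]
    lb <- lstm_backward(model$layers$lstm, caches$lstm, dlstm_out)
    grads[["lstm.Wx"]] <- lb$dWx
    grads[["lstm.Wh"]] <- lb$dWh
    grads[["lstm.b"]] <- lb$db
  }
  grads
}

#' Pool dense labels onto the network's output grid
#'
#' The labels live on the 3-second feature grid (200 steps per window) while
#' the network predicts every 6 seconds (100 steps). Each output step pools
#' its two constituent label rows: the label is the per-class max (an activity
#' present in either half is present) and the weight is the mean (an output
#' step with one labeled half counts half).
#'
#' @param Y `L x 12` binary label matrix (L even).
#' @param w Length-`L` weight vector.
#' @return A list with `Y` (`L/2 x 12`) and `w` (length `L/2`).
#' @export
pool_labels_to_output_grid <- function(Y, w) {
  L <- nrow(Y)
  if (L %% 2 != 0) stop("label window length must be even", call. = FALSE)
  odd <- seq(1, L, by = 2)
  even <- odd + 1
  list(Y = pmax(Y[odd, , drop = FALSE], Y[even, , drop = FALSE]),
       w = (w[odd] + w[even]) / 2)
}

#' Masked balanced binary cross-entropy
#'
#' The training loss of the ADL network: the mean over the 12 classes of a
#' balanced binary cross-entropy, weighted along the time dimension so that
#' unlabeled steps (weight 0) contribute nothing. For one window,
#' \deqn{loss = \frac{1}{12}\sum_c \frac{\sum_t w_t\,[\,w^+_c Y_{tc}(-\log p_{tc})
#'   + w^-_c (1-Y_{tc})(-\log(1-p_{tc}))\,]}{\max(\sum_t w_t, \epsilon)}}
#' Predictions are clipped to `[eps, 1-eps]`. A window with all-zero weights
#' contributes 0, and perturbing predictions at zero-weight steps leaves the
#' loss bit-identical.
#'
#' @param probs `T x 12` matrix of predicted probabilities (or an
#'   `N x T x 12` array for a batch, in which case the mean over windows is
#'   returned).
#' @param Y Matching binary label matrix/array.
#' @param w Time-weight vector (length T) or `N x T` matrix.
#' @param weights Class-weight tibble from [class_weights()] (columns `w_pos`,
#'   `w_neg`); defaults to all ones.
#' @param eps Clipping constant.
#' @return The scalar loss.
#' @export
masked_balanced_bce <- function(probs, Y, w, weights = NULL, eps = 1e-7) {
  if (anyNA(probs) || anyNA(Y) || anyNA(w)) {
    stop("NaN/NA in loss inputs", call. = FALSE)
  }
  if (length(dim(probs)) == 2) {
    probs <- array(probs, c(1, dim(probs)))
    Y <- array(Y, c(1, dim(Y)))
    w <- matrix(w, nrow = 1)
  }
  d <- dim(probs)
  n_class <- d[3]
  if (is.null(weights)) {
    w_pos <- rep(1, n_class); w_neg <- rep(1, n_class)
  } else {
    w_pos <- weights$w_pos; w_neg <- weights$w_neg
  }
  p <- pmin(pmax(probs, eps), 1 - eps)
  total <- 0
  for (n in seq_len(d[1])) {
    denom <- max(sum(w[n, ]), eps)
    if (sum(w[n, ]) == 0) next # fully unlabeled window contributes 0
    pn <- matrix(p[n, , ], d[2], n_class)
    yn <- matrix(Y[n, , ], d[2], n_class)
    per_class <- colSums(w[n, ] * (yn * sweep(-log(pn), 2, w_pos, "*") +
                                     (1 - yn) * sweep(-log(1 - pn), 2,
                                                      w_neg, "*")))
    total <- total + mean(per_class / denom)
  }
  total / d[1]
}

# Loss + gradient w.r.t. the pre-sigmoid output z, for training.
# probs = sigmoid(z); d(-log p)/dz = p - 1, d(-log(1-p))/dz = p.
masked_bce_grad <- function(probs, Y, w, w_pos, w_neg) {
  d <- dim(probs)
  N <- d[1]
  dz <- array(0, d)
  denom <- pmax(rowSums(w), 1e-7)
  wp <- array(rep(w_pos, each = N * d[2]), d)
  wn <- array(rep(w_neg, each = N * d[2]), d)
  wt <- array(w, d) # recycles (N, T) over classes
  coef <- wt / (N * d[3] * denom) # denom recycles over rows: (N,T,C)
  dz <- coef * (wp * Y * (probs - 1) + wn * (1 - Y) * probs)
  dz
}

#' Train the ADL sequence network
#'
#' Adam on the masked balanced binary cross-entropy, with Gaussian input noise
#' and dropout re-drawn per epoch, plus optional l1/l2 penalties on the weight
#' matrices. Training is deterministic given `seed` (single-threaded BLAS
#' assumed).
#'
#' @param model An untrained [build_adl_network()] model.
#' @param x `N x 200 x F` feature window array.
#' @param Y `N x 200 x 12` dense label array on the 3-second grid.
#' @param w `N x 200` time-weight matrix.
#' @param weights Class weights from [class_weights()]; `NULL` for unweighted.
#' @param epochs,batch_size,learning_rate Override config values.
#' @param seed RNG seed.
#' @param verbose Print per-epoch loss.
#' @return The fitted model with a `history` tibble.
#' @export
train_adl <- function(model, x, Y, w, weights = NULL, epochs = NULL,
                      batch_size = NULL, learning_rate = NULL, seed = 1,
                      verbose = FALSE) {
  cfg <- model$cfg
  epochs <- epochs %||% cfg$epochs
  batch_size <- batch_size %||% cfg$batch_size
  learning_rate <- learning_rate %||% cfg$learning_rate
  N <- dim(x)[1]
  stopifnot(dim(Y)[1] == N, nrow(w) == N, dim(x)[2] %% 2 == 0)
  if (all(w == 0)) stop("all windows fully unlabeled: nothing to train on",
                        call. = FALSE)
  # pool labels 200 -> 100 once
  L_out <- dim(x)[2] / 2
  n_class <- length(model$classes)
  Yp <- array(0, c(N, L_out, n_class))
  wp_mat <- matrix(0, N, L_out)
  for (n in seq_len(N)) {
    pl <- pool_labels_to_output_grid(matrix(Y[n, , ], dim(Y)[2], n_class),
                                     w[n, ])
    Yp[n, , ] <- pl$Y
    wp_mat[n, ] <- pl$w
  }
  if (is.null(weights)) {
    w_pos <- rep(1, n_class); w_neg <- rep(1, n_class)
  } else {
    w_pos <- weights$w_pos; w_neg <- weights$w_neg
  }
  set.seed(seed)
  opt <- adam_init(collect_params(model$layers))
  history <- vector("list", max(epochs, 0))
  if (epochs == 0) {
    model$history <- tibble::tibble(epoch = integer(), loss = numeric())
    return(model)
  }
  weight_keys <- c("conv1.W", "conv2.W", "lstm.Wx", "lstm.Wh")
  for (ep in seq_len(epochs)) {
    perm <- sample.int(N)
    total_loss <- 0
    for (b0 in seq(1, N, by = batch_size)) {
      idx <- perm[b0:min(b0 + batch_size - 1, N)]
      xb <- x[idx, , , drop = FALSE]
      yb <- Yp[idx, , , drop = FALSE]
      wb <- wp_mat[idx, , drop = FALSE]
      fw <- adl_forward(model, xb, training = TRUE)
      loss <- masked_balanced_bce(fw$probs, yb, wb,
                                  weights = tibble::tibble(w_pos = w_pos,
                                                           w_neg = w_neg))
      dz <- masked_bce_grad(fw$probs, yb, wb, w_pos, w_neg)
      grads <- adl_backward(model, fw, dz)
      params <- collect_params(model$layers)
      if (cfg$l1 > 0 || cfg$l2 > 0) {
        for (k in intersect(weight_keys, names(params))) {
          loss <- loss + cfg$l1 * sum(abs(params[[k]])) +
            cfg$l2 * sum(params[[k]]^2)
          grads[[k]] <- grads[[k]] + cfg$l1 * sign(params[[k]]) +
            2 * cfg$l2 * params[[k]]
        }
      }
      upd <- adam_step(opt, params, grads, lr = learning_rate)
      opt <- upd$state
      model$layers <- assign_params(model$layers, upd$params)
      total_loss <- total_loss + loss * length(idx)
    }
    history[[ep]] <- tibble::tibble(epoch = ep, loss = total_loss / N)
    if (verbose) message(sprintf("epoch %d  loss %.5f", ep, total_loss / N))
  }
  model$history <- dplyr::bind_rows(history)
  model$trained <- TRUE
  model
}

#' Predict per-time-step ADL probabilities
#'
#' Forward pass without noise or dropout: `N x 200 x F -> N x 100 x 12`
#' probabilities, one row per 6 seconds.
#'
#' @param model A fitted `"adl_net"`.
#' @param x Feature window array (`N x 200 x F`) or a single `200 x F` matrix.
#' @return An `N x 100 x 12` array (or `100 x 12` matrix for a single window).
#' @export
predict_adl <- function(model, x) {
  single <- length(dim(x)) == 2
  if (single) x <- array(x, c(1, dim(x)))
  out <- adl_forward(model, x, training = FALSE)$probs
  if (single) matrix(out[1, , ], dim(out)[2], dim(out)[3],
                     dimnames = list(NULL, model$classes)) else out
}

#' Predict a whole session, averaging overlapping windows
#'
#' Slides the 10-minute window with a 2-minute stride over the session's
#' feature matrix and averages the probabilities that overlapping windows
#' (up to 5) assign to the same absolute 6-second step.
#'
#' @param model A fitted `"adl_net"`.
#' @param fm A [build_feature_matrix()] result for the session.
#' @param window_s,stride_s Window length and stride in seconds.
#' @return A [prob_series()]-like tibble: column `t` (6-second grid) plus one
#'   probability column per ADL (rows are *not* simplexes — each class is an
#'   independent binary probability). Empty with a warning for sessions
#'   shorter than one window.
#' @export
predict_session <- function(model, fm, window_s = 600, stride_s = 120) {
  wins <- feature_windows(fm, window_s = window_s, stride_s = stride_s)
  n_class <- length(model$classes)
  step_in <- fm$t[2] - fm$t[1]
  step_out <- 2 * step_in
  if (length(wins$starts) == 0) {
    warning("session shorter than one window: empty prediction")
    out <- tibble::as_tibble(matrix(numeric(), 0, n_class,
                                    dimnames = list(NULL, model$classes)))
    return(tibble::add_column(out, t = numeric(), .before = 1))
  }
  probs <- predict_adl(model, wins$x)
  L_out <- dim(probs)[2]
  t_end <- max(wins$starts) + window_s
  grid <- seq(min(wins$starts), t_end - 1e-9, by = step_out)
  acc <- matrix(0, length(grid), n_class)
  cnt <- numeric(length(grid))
  for (i in seq_along(wins$starts)) {
    pos <- round((wins$starts[i] - grid[1]) / step_out)
    rows <- pos + seq_len(L_out)
    acc[rows, ] <- acc[rows, ] + matrix(probs[i, , ], L_out, n_class)
    cnt[rows] <- cnt[rows] + 1
  }
  acc <- acc / pmax(cnt, 1)
  colnames(acc) <- model$classes
  out <- tibble::as_tibble(as.data.frame(acc, check.names = FALSE))
  tibble::add_column(out, t = grid, .before = 1)
}

#' Random hyper-parameter search over the 4-fold participant split
#'
#' Draws `n_trials` configurations from the search space (log-uniform for
#' learning rate, units and regularizers; uniform for dropout and noise),
#' trains on each cross-validation fold and scores by the mean validation
#' masked loss. The full trial log is returned alongside the winning
#' configuration.
#'
#' @param make_data Function `(participant_ids) -> list(x, Y, w)` assembling
#'   the training tensors for a set of participants.
#' @param folds A `"cv_split"` from [make_cv_split()].
#' @param n_trials Number of random configurations.
#' @param n_features Feature dimension.
#' @param epochs Training epochs per trial (keep small for search).
#' @param seed RNG seed.
#' @param space A list of ranges: `lstm_units`, `dropout`, `gauss_noise_std`,
#'   `l1`, `l2`, `learning_rate` (each `c(lo, hi)`).
#' @return A list with `best` (an [adl_net_config()]) and `trials` (a tibble
#'   logging every trial).
#' @export
hyperparam_search <- function(make_data, folds, n_trials, n_features,
                              epochs = 20, seed = 1,
                              space = list(lstm_units = c(16, 256),
                                           dropout = c(0, 0.5),
                                           gauss_noise_std = c(0, 0.5),
                                           l1 = c(1e-7, 1e-2),
                                           l2 = c(1e-7, 1e-2),
                                           learning_rate = c(1e-4, 1e-2))) {
  if (n_trials < 1) stop("n_trials must be >= 1", call. = FALSE)
  set.seed(seed)
  log_unif <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  trials <- vector("list", n_trials)
  configs <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cfg <- adl_net_config(
      lstm_units = round(log_unif(space$lstm_units)),
      dropout = stats::runif(1, space$dropout[1], space$dropout[2]),
      gauss_noise_std = stats::runif(1, space$gauss_noise_std[1],
                                     space$gauss_noise_std[2]),
      l1 = log_unif(space$l1), l2 = log_unif(space$l2),
      learning_rate = log_unif(space$learning_rate),
      epochs = epochs)
    configs[[i]] <- cfg
    val_losses <- numeric(length(folds$folds))
    for (f in seq_along(folds$folds)) {
      fold <- folds$folds[[f]]
      tr <- make_data(fold$train)
      va <- make_data(fold$val)
      cw <- NULL
      model <- build_adl_network(cfg, n_features, seed = seed + i)
      model <- train_adl(model, tr$x, tr$Y, tr$w, weights = tr$weights,
                         epochs = epochs, seed = seed + i)
      pl_Y <- array(0, c(dim(va$x)[1], dim(va$x)[2] / 2, 12))
      pl_w <- matrix(0, dim(va$x)[1], dim(va$x)[2] / 2)
      for (n in seq_len(dim(va$x)[1])) {
        pl <- pool_labels_to_output_grid(matrix(va$Y[n, , ], dim(va$Y)[2], 12),
                                         va$w[n, ])
        pl_Y[n, , ] <- pl$Y
        pl_w[n, ] <- pl$w
      }
      pred <- predict_adl(model, va$x)
      val_losses[f] <- masked_balanced_bce(pred, pl_Y, pl_w,
                                           weights = tr$weights)
    }
    trials[[i]] <- tibble::tibble(
      trial = i, lstm_units = cfg$lstm_units, dropout = cfg$dropout,
      gauss_noise_std = cfg$gauss_noise_std, l1 = cfg$l1, l2 = cfg$l2,
      learning_rate = cfg$learning_rate,
      mean_val_loss = mean(val_losses))
  }
  trials <- dplyr::bind_rows(trials)
  best_i <- which.min(trials$mean_val_loss)
  list(best = configs[[best_i]], trials = trials)
}
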