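#' Assemble ADL training tensors from synthetic sessions
#'
#' For each session, builds the preset's feature matrix on the 3-second grid
#' (using the session's oracle low-level probabilities unless a fitted
#' `"har_cnn"` is supplied), densifies the labels, and slices aligned
#' 10-minute windows with a 2-minute stride. Windows from all sessions are
#' stacked, tagged by participant.
#'
#' @param sessions A list of `"synthetic_session"` objects (or any list whose
#'   elements carry `session`, `oracle_probs` and either `dense` or reported
#'   labels).
#' @param preset One of [feature_presets()].
#' @param labels `"truth"` uses the noiseless script labels; `"reported"`
#'   cleans the self-reported entries with [clean_labels()] first.
#' @param har_model Optional fitted `"har_cnn"` whose predictions replace the
#'   oracle probability stream.
#' @param window_s,stride_s Window length and stride in seconds.
#' @param home A [home_config()].
#' @return A list with `x` (N x 200 x F), `Y` (N x 200 x 12), `w` (N x 200),
#'   `participant` (length N), `starts`, `feature_names` and `weights` (pooled
#'   [class_weights()]).
#' @export
adl_window_data <- function(sessions, preset, labels = c("truth", "reported"),
                            har_model = NULL, window_s = 600, stride_s = 120,
                            home = home_config()) {
  labels <- match.arg(labels)
  xs <- list(); ys <- list(); ws <- list(); pid <- list(); st <- list()
  denses <- list()
  feature_names <- NULL
  for (s in sessions) {
    probs <- if (is.null(har_model)) s$oracle_probs else
      predict_probs(har_model, s$session$streams$accelerometer)
    fm <- build_feature_matrix(s$session, probs, preset, home = home)
    dense <- if (labels == "truth") s$dense else
      densify(clean_labels(s$session$adl_labels), s$session$duration)
    denses <- c(denses, list(dense))
    wins <- feature_windows(fm, window_s = window_s, stride_s = stride_s)
    if (length(wins$starts) == 0) next
    steps <- dim(wins$x)[2]
    n_w <- length(wins$starts)
    Yw <- array(0, c(n_w, steps, ncol(dense$Y)))
    ww <- matrix(0, n_w, steps)
    step_s <- fm$t[2] - fm$t[1]
    for (i in seq_len(n_w)) {
      r0 <- round(wins$starts[i] / step_s)
      rows <- r0 + seq_len(steps)
      Yw[i, , ] <- dense$Y[rows, ]
      ww[i, ] <- dense$w[rows]
    }
    xs <- c(xs, list(wins$x))
    ys <- c(ys, list(Yw))
    ws <- c(ws, list(ww))
    pid <- c(pid, list(rep(s$session$participant_id, n_w)))
    st <- c(st, list(wins$starts))
    feature_names <- fm$feature_names
  }
  if (length(xs) == 0) {
    stop("no session long enough for a single window", call. = FALSE)
  }
  bind3 <- function(lst) {
    n <- sum(vapply(lst, function(a) dim(a)[1], integer(1)))
    d <- dim(lst[[1]])
    out <- array(0, c(n, d[2], d[3]))
    pos <- 0
    for (a in lst) {
      out[pos + seq_len(dim(a)[1]), , ] <- a
      pos <- pos + dim(a)[1]
    }
    out
  }
  list(x = bind3(xs), Y = bind3(ys), w = do.call(rbind, ws),
       participant = unlist(pid), starts = unlist(st),
       feature_names = feature_names, weights = class_weights(denses))
}

#' Evaluate a fitted ADL model on held-out sessions
#'
#' Runs [predict_session()] on each session, pools the ground-truth labels to
#' the 6-second output grid, and computes per-class metrics over the labeled
#' steps plus the flattened joint confusion matrix.
#'
#' @param model A fitted `"adl_net"`.
#' @param sessions List of `"synthetic_session"` objects (held-out
#'   participants).
#' @param preset Feature preset used in training.
#' @param har_model Optional `"har_cnn"` replacing the oracle probabilities.
#' @param threshold Binarization threshold.
#' @param home A [home_config()].
#' @param seed Seed for the flattening's arbitrary-order matching.
#' @return A list with `per_participant` (named list of `"metrics_report"`),
#'   `aggregate` (mean ± sd across participants) and `confusion` (pooled
#'   `"full_confusion"`).
#' @export
evaluate_sessions <- function(model, sessions, preset, har_model = NULL,
                              threshold = NULL, home = home_config(),
                              seed = 1) {
  threshold <- threshold %||% model$cfg$threshold
  reports <- list()
  pairs <- list()
  for (s in sessions) {
    probs <- if (is.null(har_model)) s$oracle_probs else
      predict_probs(har_model, s$session$streams$accelerometer)
    fm <- build_feature_matrix(s$session, probs, preset, home = home)
    pred <- predict_session(model, fm)
    if (nrow(pred) == 0) next
    dense <- s$dense
    L <- 2 * floor(length(dense$t) / 2)
    pl <- pool_labels_to_output_grid(dense$Y[seq_len(L), , drop = FALSE],
                                     dense$w[seq_len(L)])
    n <- min(nrow(pred), nrow(pl$Y))
    pm <- as.matrix(pred[seq_len(n), model$classes])
    Yn <- pl$Y[seq_len(n), , drop = FALSE]
    wn <- pl$w[seq_len(n)]
    colnames(Yn) <- model$classes
    reports[[s$session$participant_id]] <-
      per_class_metrics(Yn, pm, weights = wn, threshold = threshold)
    cm <- flatten_session(pm, Yn, wn, threshold = threshold, seed = seed)
    pairs <- c(pairs, list(cm))
  }
  confusion <- Reduce(`+`, lapply(pairs, unclass))
  confusion <- structure(confusion, class = c("full_confusion", "matrix",
                                              "array"))
  aggregate <- if (length(reports) >= 2)
    aggregate_over_participants(reports) else NULL
  list(per_participant = reports, aggregate = aggregate,
       confusion = confusion)
}

#' End-to-end low-level labeling of one session
#'
#' Reproduces the label-generation chain for the smartphone network: smooth
#' the wrist-worn probability stream, aggregate to minutes, overrule minutes
#' with detected phone-on-table spans, and drop running.
#'
#' @param session A [session_bundle()] with `wearable_probs` and
#'   `accelerometer` streams.
#' @param kernel Smoothing kernel (odd, in 7.5-second steps).
#' @param cfg An [on_table_config()].
#' @param min_fraction Overruling fraction, see [overrule_with_on_table()].
#' @return A minute-label tibble ready for [har_training_windows()].
#' @export
lowlevel_label_chain <- function(session, kernel = 3,
                                 cfg = on_table_config(),
                                 min_fraction = 0.5) {
  wear <- as_prob_series(session$streams$wearable_probs)
  sm <- smooth_predictions(wear, kernel = kernel)
  minutes <- aggregate_to_minutes(sm, t_end = session$duration)
  mask <- detect_on_table(session$streams$accelerometer, cfg = cfg)
  minutes <- overrule_with_on_table(minutes, mask,
                                    min_fraction = min_fraction)
  drop_running(minutes)
}
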