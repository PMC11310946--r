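#' Cut a sample stream into fixed-duration windows
#'
#' Windows start on a regular grid anchored at the first sample. A window is
#' emitted only if at least `min_coverage` of its expected samples are
#' present, so sparse stretches (transmission gaps) do not produce
#' unrepresentative feature vectors.
#'
#' @param samples data.frame with a `timestamp` column (raw or dynamic
#'   stream).
#' @param window_s window duration in seconds (default 5: long enough to
#'   resolve gait and jaw periodicity at >= 10 Hz, and divides the 60-s
#'   energy interval evenly).
#' @param stride_s window spacing in seconds; defaults to `window_s`
#'   (non-overlapping).
#' @param rate_hz nominal sampling rate used to compute the expected sample
#'   count; inferred from timestamps if `NULL`.
#' @param min_coverage minimum fraction of expected samples (default 0.8).
#' @return data.frame of emitted windows: `window_id`, `start`, `end`
#'   (POSIXct), `n_samples`, `coverage`.
#' @export
make_windows <- function(samples, window_s = 5, stride_s = window_s,
                         rate_hz = NULL, min_coverage = 0.8) {
  if (nrow(samples) == 0) {
    return(data.frame(window_id = integer(0),
                      start = samples$timestamp[0], end = samples$timestamp[0],
                      n_samples = integer(0), coverage = numeric(0)))
  }
  t <- as.numeric(samples$timestamp)
  if (is.null(rate_hz)) {
    rate_hz <- if (length(t) >= 2) 1 / stats::median(diff(t)) else 1
  }
  t0 <- t[1]
  span <- t[length(t)] - t0
  n_win <- floor(span / stride_s) + 1
  starts <- t0 + (seq_len(n_win) - 1) * stride_s
  # sample counts per window via binary search on the sorted timestamps;
  # the epsilon absorbs POSIXct double rounding (~2e-7 s at current epochs)
  lo <- findInterval(starts - 1e-6, t) + 1L
  hi <- findInterval(starts + window_s - 1e-6, t)
  n_samples <- pmax(hi - lo + 1L, 0L)
  expected <- window_s * rate_hz
  coverage <- n_samples / expected
  keep <- coverage >= min_coverage
  out <- data.frame(
    window_id = seq_len(n_win)[keep],
    start = as.POSIXct(starts[keep], origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(starts[keep] + window_s, origin = "1970-01-01", tz = "UTC"),
    n_samples = n_samples[keep],
    coverage = pmin(coverage[keep], 1)
  )
  rownames(out) <- NULL
  out
}

#' Extract per-window features for behavior classification
#'
#' For every window: mean, standard deviation, min and max of each raw axis
#' (`ax, ay, az`) and each gravity-free axis (`dx, dy, dz`), the window mean
#' VeDBA and mean ODBA, and the dominant dynamic axis (index of the axis
#' with the largest mean absolute value). Deterministic, and invariant to
#' sample order within a window.
#'
#' @param raw cleaned accelerometry data.frame.
#' @param dyn matching dynamic stream from [remove_gravity()].
#' @param windows window table from [make_windows()].
#' @return data.frame: `window_id` plus 27 numeric feature columns. Windows
#'   with no dynamic samples are dropped.
#' @export
extract_features <- function(raw, dyn, windows) {
  if (nrow(windows) == 0) {
    return(data.frame(window_id = integer(0)))
  }
  stat_block <- function(df, cols, prefix) {
    t <- as.numeric(df$timestamp)
    ws <- as.numeric(windows$start)
    we <- as.numeric(windows$end)
    # assign each sample to a window (windows may be non-contiguous)
    wi <- findInterval(t, ws)
    in_win <- wi >= 1 & t < we[pmax(wi, 1)]
    dt <- data.table(win = windows$window_id[wi[in_win]])
    for (cl in cols) dt[[cl]] <- df[[cl]][in_win]
    long <- dt[, c(lapply(.SD, mean), lapply(.SD, sd),
                   lapply(.SD, min), lapply(.SD, max)),
               by = "win", .SDcols = cols]
    stats_names <- as.vector(t(outer(c("mean", "sd", "min", "max"), cols,
                                     paste, sep = "_")))
    setnames(long, c("win", paste0(prefix, stats_names)))
    long
  }
  raw_f <- stat_block(raw, c("ax", "ay", "az"), "raw_")
  dyn2 <- dyn
  dyn2$vedba_s <- vedba(dyn)
  dyn2$odba_s <- odba(dyn)
  dyn2$adx <- abs(dyn$dx); dyn2$ady <- abs(dyn$dy); dyn2$adz <- abs(dyn$dz)
  dyn_f <- stat_block(dyn2, c("dx", "dy", "dz"), "dyn_")
  t <- as.numeric(dyn2$timestamp)
  ws <- as.numeric(windows$start); we <- as.numeric(windows$end)
  wi <- findInterval(t, ws)
  in_win <- wi >= 1 & t < we[pmax(wi, 1)]
  agg <- data.table(win = windows$window_id[wi[in_win]],
                    v = dyn2$vedba_s[in_win], o = dyn2$odba_s[in_win],
                    adx = dyn2$adx[in_win], ady = dyn2$ady[in_win],
                    adz = dyn2$adz[in_win])
  extra <- agg[, list(mean_vedba = mean(v), mean_odba = mean(o),
                      dominant_axis = which.max(c(mean(adx), mean(ady),
                                                  mean(adz)))),
               by = "win"]
  out <- merge(merge(raw_f, dyn_f, by = "win"), extra, by = "win")
  setnames(out, "win", "window_id")
  out <- as.data.frame(out)
  # a window with samples but zero variance yields sd = NA on length-1 input
  out[is.na(out)] <- 0
  out
}

#' Train the behavior classifier
#'
#' Fits a CART decision tree (default) or a small bagged-forest ensemble over
#' per-window features. Training is reproducible: the same features, labels
#' and seed give an identical model.
#'
#' @param features feature data.frame from [extract_features()] (the
#'   `window_id` column is ignored as a predictor).
#' @param labels character vector of true behaviors, one per feature row.
#' @param method `"tree"` (single CART, default) or `"forest"` (bagged
#'   CART ensemble, majority vote).
#' @param seed RNG seed (only the forest's bootstrap uses randomness, but the
#'   seed is always recorded).
#' @param max_depth,min_split,min_leaf tree growth controls.
#' @param ntree,mtry forest size and features sampled per tree (`mtry`
#'   defaults to `ceiling(sqrt(p))`).
#' @param class_weights optional named vector of per-class case weights
#'   (e.g. to up-weight scarce behaviors); default equal weights.
#' @return a `behavior_model` object.
#' @export
train_behavior_model <- function(features, labels,
                                 method = c("tree", "forest"),
                                 seed = 1L,
                                 max_depth = 12L, min_split = 20L,
                                 min_leaf = 7L,
                                 ntree = 25L, mtry = NULL,
                                 class_weights = NULL) {
  method <- match.arg(method)
  assert_behaviors(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop("training needs at least 2 behavior classes, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  feature_names <- setdiff(names(features), c("window_id", "start", "end"))
  X <- as.matrix(features[, feature_names, drop = FALSE])
  if (nrow(X) != length(labels)) {
    stop("features and labels disagree in length", call. = FALSE)
  }
  y <- match(labels, classes)
  w <- rep(1, length(y))
  if (!is.null(class_weights)) {
    missing_w <- setdiff(classes, names(class_weights))
    if (length(missing_w)) {
      stop("class_weights missing class(es): ",
           paste(missing_w, collapse = ", "), call. = FALSE)
    }
    w <- unname(class_weights[labels])
  }

  fit <- with_local_seed(seed, {
    if (method == "tree") {
      list(cart_fit(X, y, K = length(classes), w = w, max_depth = max_depth,
                    min_split = min_split, min_leaf = min_leaf))
    } else {
      p <- ncol(X)
      if (is.null(mtry)) mtry <- ceiling(sqrt(p))
      lapply(seq_len(ntree), function(b) {
        rows <- sample.int(nrow(X), replace = TRUE)
        feats <- sort(sample.int(p, mtry))
        tr <- cart_fit(X[rows, feats, drop = FALSE], y[rows],
                       K = length(classes), w = w[rows],
                       max_depth = max_depth, min_split = min_split,
                       min_leaf = min_leaf)
        attr(tr, "feats") <- feats
        tr
      })
    }
  })

  counts <- table(factor(labels, levels = classes))
  model <- structure(list(
    method = method, trees = fit, classes = classes,
    feature_names = feature_names,
    class_counts = as.integer(counts),
    seed = seed,
    fingerprint = rlang::hash(list(feature_names, classes, method, seed,
                                   max_depth, min_split, min_leaf, ntree)),
    version = as.character(utils::packageVersion("collarEE"))
  ), class = "behavior_model")
  model
}

#' @export
print.behavior_model <- function(x, ...) {
  cat("<behavior_model> ", x$method,
      if (x$method == "forest") paste0(" (", length(x$trees), " trees)"),
      "\n  classes: ", paste(x$classes, collapse = " "),
      "\n  features: ", length(x$feature_names),
      "\n  fingerprint: ", x$fingerprint, "\n", sep = "")
  invisible(x)
}

#' Predict behaviors for feature windows
#'
#' @param object a `behavior_model`.
#' @param newdata feature data.frame from [extract_features()]; must contain
#'   the model's feature columns.
#' @param ... unused.
#' @return character vector of behavior codes (one per row; a closed world —
#'   only classes seen in training can be emitted).
#' @export
predict.behavior_model <- function(object, newdata, ...) {
  if (nrow(newdata) == 0) return(character(0))
  missing_f <- setdiff(object$feature_names, names(newdata))
  if (length(missing_f)) {
    stop("newdata is missing feature(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  if (object$method == "tree") {
    codes <- cart_predict(object$trees[[1]], X)
  } else {
    K <- length(object$classes)
    votes <- matrix(0L, nrow(X), K)
    for (tr in object$trees) {
      pred <- cart_predict(tr, X[, attr(tr, "feats"), drop = FALSE])
      votes[cbind(seq_len(nrow(X)), pred)] <-
        votes[cbind(seq_len(nrow(X)), pred)] + 1L
    }
    codes <- max.col(votes, ties.method = "first")
  }
  object$classes[codes]
}

#' Classification performance report
#'
#' Confusion matrix plus the per-class and weighted-average metrics used to
#' judge the behavior model: precision, recall, F1 and support per class;
#' accuracy as trace over total. All metrics derive from the confusion
#' matrix alone, so the report is invariant to window order.
#'
#' @param truth character vector of true behaviors.
#' @param predicted character vector of predicted behaviors (same length).
#' @param classes class set for the matrix; defaults to the union observed.
#' @return a `performance_report`: list with `confusion` (true x predicted
#'   counts), `per_class` data.frame, `weighted` averages and `accuracy`.
#' @export
classification_report <- function(truth, predicted, classes = NULL) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(classes)) classes <- sort(union(unique(truth), unique(predicted)))
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  per_class <- data.frame(class = classes, precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1),
                          support = as.integer(support))
  wt <- support / sum(support)
  weighted <- c(precision = sum(wt * prec), recall = sum(wt * rec),
                f1 = sum(wt * f1))
  structure(list(confusion = cm, per_class = per_class, weighted = weighted,
                 accuracy = sum(tp) / sum(cm)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat("accuracy:", round(x$accuracy, 3), "\n")
  print(x$per_class, row.names = FALSE, digits = 3)
  cat("weighted: precision", round(x$weighted["precision"], 3),
      " recall", round(x$weighted["recall"], 3),
      " f1", round(x$weighted["f1"], 3), "\n")
  invisible(x)
}

#' Evaluate a model on labeled windows
#'
#' @inheritParams predict.behavior_model
#' @param model a `behavior_model`.
#' @param features feature data.frame.
#' @param truth true behavior per row.
#' @return a [classification_report()] over the model's class list (plus any
#'   extra classes present in `truth`).
#' @export
evaluate_model <- function(model, features, truth) {
  pred <- predict(model, features)
  classification_report(truth, pred,
                        classes = sort(union(model$classes, unique(truth))))
}

#' Save / load a behavior model
#'
#' Serialized with R's native format; a reloaded model predicts identically
#' (checked via the stored fingerprint).
#'
#' @param model a `behavior_model`.
#' @param path file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "behavior_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "behavior_model")) {
    stop("not a behavior_model file: ", path, call. = FALSE)
  }
  model
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
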