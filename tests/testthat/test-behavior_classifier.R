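test_that("make_windows does the coverage arithmetic", {
  d <- accel_df(rnorm(600))            # 60 s at 10 Hz
  w <- make_windows(d, window_s = 5, stride_s = 5, rate_hz = 10)
  expect_equal(nrow(w), 12)            # 60 s of 10 Hz data, 5 s windows
  expect_true(all(w$n_samples == 50))

  # stream shorter than one window
  expect_equal(nrow(make_windows(accel_df(rnorm(30)), window_s = 5)), 0)

  # a half-empty window is dropped by the 80% rule
  d2 <- accel_df(rnorm(100))
  d2 <- d2[-(55:79), ]                 # knock 50% out of window 2
  w2 <- make_windows(d2, window_s = 5, stride_s = 5, rate_hz = 10)
  expect_false(2 %in% w2$window_id)
  expect_true(1 %in% w2$window_id)
})

test_that("features are deterministic, order-free and collapse for degenerate input", {
  set.seed(23)
  raw <- accel_df(1000 + rnorm(100), rnorm(100), rnorm(100))
  dyn <- remove_gravity(raw)
  w <- make_windows(raw, rate_hz = 10)
  f1 <- extract_features(raw, dyn, w)
  f2 <- extract_features(raw, dyn, w)
  expect_identical(f1, f2)
  expect_equal(ncol(f1), 28)           # window_id + 27 features
  expect_false(anyNA(f1))

  # all-zero dynamic window: dispersion features are zero
  rawc <- accel_df(rep(1000, 100), rep(10, 100), rep(-5, 100))
  dync <- remove_gravity(rawc)
  fc <- extract_features(rawc, dync, make_windows(rawc, rate_hz = 10))
  expect_true(all(fc$dyn_sd_dx == 0 & fc$dyn_max_dz == 0))
  expect_true(all(fc$mean_vedba == 0))
  # constant raw window: sd zero, mean equals the constant
  expect_true(all(fc$raw_sd_ax == 0))
  expect_true(all(fc$raw_mean_ax == 1000))

  # permuting samples within a window leaves order-free features unchanged
  perm <- sample(nrow(dyn))
  dyn_perm <- dyn[perm, ]
  f3 <- extract_features(raw, dyn_perm, w)
  ordered <- names(f1)[!grepl("window_id", names(f1))]
  expect_equal(f3[ordered], f1[ordered], tolerance = 1e-12)
})

test_that("training is reproducible, separable data fits perfectly, and degenerate input errors", {
  set.seed(31)
  n <- 120
  f <- data.frame(a = c(rnorm(n, 0), rnorm(n, 10)),
                  b = c(rnorm(n, 5), rnorm(n, -5)))
  y <- rep(c("L", "W"), each = n)
  m1 <- train_behavior_model(f, y, seed = 5)
  m2 <- train_behavior_model(f, y, seed = 5)
  expect_identical(m1$trees, m2$trees)
  expect_identical(m1$fingerprint, m2$fingerprint)
  rep <- evaluate_model(m1, f, y)
  expect_equal(rep$accuracy, 1.0)

  expect_error(train_behavior_model(f, rep("L", 2 * n)), "at least 2")

  # forest flavor trains and predicts from the same interface
  mf <- train_behavior_model(f, y, method = "forest", seed = 5, ntree = 7)
  expect_gt(evaluate_model(mf, f, y)$accuracy, 0.95)
})

test_that("prediction honors the closed world and empty inputs", {
  set.seed(37)
  f <- data.frame(a = c(rnorm(50, 0), rnorm(50, 10)))
  y <- rep(c("S", "W"), each = 50)
  m <- train_behavior_model(f, y, min_split = 5, min_leaf = 2)
  pred <- predict(m, data.frame(a = rnorm(200, 5)))
  expect_true(all(pred %in% c("S", "W")))    # never emits unseen classes
  expect_identical(predict(m, data.frame(a = numeric(0))), character(0))
  # an exemplar identical to training data predicts its own class
  expect_equal(predict(m, data.frame(a = 10))[1], "W")
  expect_error(predict(m, data.frame(zz = 1)), "missing feature")
})

test_that("model save/load round-trips to identical predictions", {
  set.seed(43)
  f <- data.frame(a = rnorm(100), b = rnorm(100))
  y <- rep(c("L", "R"), 50)
  m <- train_behavior_model(f, y, min_split = 10, min_leaf = 3)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, f), predict(m, f))
  expect_identical(m2$fingerprint, m$fingerprint)
})

test_that("evaluation metrics derive from the confusion matrix", {
  # hand computation for the matrix [[8,2],[3,7]] (rows = truth)
  truth <- c(rep("L", 10), rep("W", 10))
  pred <- c(rep("L", 8), rep("W", 2), rep("L", 3), rep("W", 7))
  r <- classification_report(truth, pred)
  expect_equal(unname(r$confusion["L", "L"]), 8)
  expect_equal(r$per_class$precision[r$per_class$class == "L"], 8 / 11)
  expect_equal(r$per_class$recall[r$per_class$class == "L"], 0.8)
  expect_equal(r$accuracy, 15 / 20)
  # row sums equal supports; accuracy is trace/total
  expect_equal(unname(rowSums(r$confusion)), r$per_class$support)

  # perfect predictions
  rp <- classification_report(truth, truth)
  expect_equal(rp$accuracy, 1)
  expect_true(all(rp$per_class$f1 == 1))

  # all-one-class predictions on balanced two-class data
  r5 <- classification_report(truth, rep("L", 20))
  expect_equal(r5$accuracy, 0.5)

  # invariant to window order
  o <- sample(20)
  expect_equal(classification_report(truth[o], pred[o])$weighted, r$weighted)

  # weighted averages are the support-weighted means
  wts <- r$per_class$support / sum(r$per_class$support)
  expect_equal(unname(r$weighted["f1"]), sum(wts * r$per_class$f1))
  expect_equal(unname(r$weighted["precision"]),
               sum(wts * r$per_class$precision))
})
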