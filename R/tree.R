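# Compact CART classifier (Gini impurity, binary splits) and a small bagged
# ensemble. Written in-package because no tree learner ships with the target
# runtime; the interface is deliberately minimal — the exported surface is
# train_behavior_model() / predict.behavior_model().

# Fit a classification tree.
#   X: numeric matrix (rows = cases, cols = features)
#   y: integer class codes 1..K
#   w: case weights
# Returns a data.frame of nodes: feature/threshold are NA for leaves;
# children indexed by row; pred is the (weighted) majority class.
cart_fit <- function(X, y, K, w = NULL,
                     max_depth = 12L, min_split = 20L, min_leaf = 7L) {
  n <- nrow(X)
  if (is.null(w)) w <- rep(1, n)
  nodes <- new.env(parent = emptyenv())
  nodes$feature <- integer(0)
  nodes$threshold <- numeric(0)
  nodes$left <- integer(0)
  nodes$right <- integer(0)
  nodes$pred <- integer(0)
  nodes$n <- integer(0)

  add_node <- function() {
    i <- length(nodes$feature) + 1L
    nodes$feature[i] <- NA_integer_
    nodes$threshold[i] <- NA_real_
    nodes$left[i] <- NA_integer_
    nodes$right[i] <- NA_integer_
    nodes$pred[i] <- NA_integer_
    nodes$n[i] <- NA_integer_
    i
  }

  grow <- function(idx, depth) {
    me <- add_node()
    wc <- vapply(seq_len(K), function(k) sum(w[idx][y[idx] == k]), 0)
    nodes$pred[me] <- which.max(wc)
    nodes$n[me] <- length(idx)
    # stopping rules
    if (depth >= max_depth || length(idx) < min_split || sum(wc > 0) < 2L) {
      return(me)
    }
    sp <- best_split(X, y, w, idx, K, min_leaf)
    if (is.null(sp)) return(me)
    nodes$feature[me] <- sp$feature
    nodes$threshold[me] <- sp$threshold
    go_left <- X[idx, sp$feature] <= sp$threshold
    nodes$left[me] <- grow(idx[go_left], depth + 1L)
    nodes$right[me] <- grow(idx[!go_left], depth + 1L)
    me
  }
  grow(seq_len(n), 0L)
  data.frame(feature = nodes$feature, threshold = nodes$threshold,
             left = nodes$left, right = nodes$right,
             pred = nodes$pred, n = nodes$n)
}

# Exhaustive best Gini split over all features for one node.
best_split <- function(X, y, w, idx, K, min_leaf) {
  yb <- y[idx]
  wb <- w[idx]
  n <- length(idx)
  tot <- vapply(seq_len(K), function(k) sum(wb[yb == k]), 0)
  wtot <- sum(tot)
  parent_gini <- 1 - sum((tot / wtot)^2)
  best <- NULL
  best_imp <- parent_gini - 1e-9  # require strict improvement

  for (j in seq_len(ncol(X))) {
    x <- X[idx, j]
    o <- order(x)
    xs <- x[o]
    # weighted one-hot cumulative class counts along the sorted order
    cw <- matrix(0, n, K)
    cw[cbind(seq_len(n), yb[o])] <- wb[o]
    cw <- apply(cw, 2, cumsum)
    # candidate cut positions: between distinct consecutive values,
    # honoring the minimum leaf size
    pos <- which(xs[-n] < xs[-1])
    pos <- pos[pos >= min_leaf & (n - pos) >= min_leaf]
    if (!length(pos)) next
    nl <- rowSums(cw)[pos]
    nr <- wtot - nl
    gl <- 1 - rowSums((cw[pos, , drop = FALSE] / nl)^2)
    crw <- matrix(tot, length(pos), K, byrow = TRUE) - cw[pos, , drop = FALSE]
    gr <- 1 - rowSums((crw / nr)^2)
    imp <- (nl * gl + nr * gr) / wtot
    b <- which.min(imp)
    if (imp[b] < best_imp) {
      best_imp <- imp[b]
      best <- list(feature = j,
                   threshold = (xs[pos[b]] + xs[pos[b] + 1]) / 2)
    }
  }
  best
}

# Predict integer class codes for a node table.
cart_predict <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  route <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    f <- tree$feature[node]
    if (is.na(f)) {
      out[idx] <<- tree$pred[node]
      return(invisible(NULL))
    }
    go_left <- X[idx, f] <= tree$threshold[node]
    route(tree$left[node], idx[go_left])
    route(tree$right[node], idx[!go_left])
  }
  route(1L, seq_len(n))
  out
}
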