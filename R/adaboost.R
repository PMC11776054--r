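# Multiclass adaptive boosting (SAMME) over rpart decision stumps.
#
# Stagewise additive boosting: each round fits a depth-limited CART tree
# under the current case weights, then reweights misclassified cases by
# exp(alpha), alpha = learning_rate * (log((1-err)/err) + log(K-1)).
# Class scores at prediction time are normalized sums of stage weights.

fit_adaboost <- function(x, y, n_estimators = 500, learning_rate = 0.05,
                         max_depth = 1, seed = 1) {
  y <- factor(y)
  classes <- levels(y)
  K <- length(classes)
  if (K < 2) abort("Adaptive boosting needs at least 2 classes.")
  n <- nrow(x)
  w <- rep(1 / n, n)
  df <- as.data.frame(x)
  feat_names <- colnames(df)
  df$.y <- y

  stumps <- vector("list", n_estimators)
  alphas <- numeric(n_estimators)
  used <- 0L
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = -1, minsplit = 2,
                               minbucket = 1, xval = 0, maxcompete = 0,
                               maxsurrogate = 0, usesurrogate = 0)
  withr::with_seed(seed, {
    for (m in seq_len(n_estimators)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                          control = ctrl)
      pred <- predict_rpart_class(fit, df, classes)
      miss <- pred != y
      err <- sum(w[miss])
      if (err <= 0) {
        # perfect stage learner: keep it with a large weight and stop
        used <- used + 1L
        stumps[[used]] <- fit
        alphas[used] <- learning_rate * (log(1e10) + log(K - 1))
        break
      }
      if (err >= 1 - 1 / K) {
        # no better than chance under SAMME: stop without this learner
        if (used == 0L) {
          used <- 1L; stumps[[1L]] <- fit; alphas[1L] <- 0
        }
        break
      }
      alpha <- learning_rate * (log((1 - err) / err) + log(K - 1))
      used <- used + 1L
      stumps[[used]] <- fit
      alphas[used] <- alpha
      w <- w * exp(alpha * miss)
      w <- w / sum(w)
    }
  })

  structure(
    list(stumps = stumps[seq_len(used)], alphas = alphas[seq_len(used)],
         classes = classes, feat_names = feat_names,
         n_estimators = n_estimators, learning_rate = learning_rate,
         max_depth = max_depth, seed = seed),
    class = "adaboost_samme"
  )
}

predict_rpart_class <- function(fit, newdata, classes) {
  p <- predict(fit, newdata = newdata, type = "class")
  factor(as.character(p), levels = classes)
}

# class scores: stage-weight vote shares, rows sum to 1
predict_adaboost <- function(object, x) {
  df <- as.data.frame(x)[, object$feat_names, drop = FALSE]
  K <- length(object$classes)
  votes <- matrix(0, nrow = nrow(df), ncol = K,
                  dimnames = list(NULL, object$classes))
  total <- sum(object$alphas)
  for (m in seq_along(object$stumps)) {
    pred <- predict_rpart_class(object$stumps[[m]], df, object$classes)
    votes[cbind(seq_len(nrow(df)), as.integer(pred))] <-
      votes[cbind(seq_len(nrow(df)), as.integer(pred))] + object$alphas[m]
  }
  if (total > 0) {
    prob <- votes / total
  } else {
    prob <- matrix(1 / K, nrow = nrow(df), ncol = K,
                   dimnames = list(NULL, object$classes))
  }
  list(
    class = object$classes[max.col(prob, ties.method = "first")],
    prob = prob
  )
}

# impurity importance: alpha-weighted rpart variable importance, normalized
importance_adaboost <- function(object) {
  imp <- setNames(numeric(length(object$feat_names)), object$feat_names)
  for (m in seq_along(object$stumps)) {
    vi <- object$stumps[[m]]$variable.importance
    if (!is.null(vi)) imp[names(vi)] <- imp[names(vi)] + object$alphas[m] * vi
  }
  imp
}
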