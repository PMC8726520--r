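# Pair classifiers behind one interface: random forest (the production
# model; grid-searched settings num.trees = 100, max.depth = 110),
# AdaBoost, logistic regression and Gaussian naive Bayes as comparators.

#' Classifier specification
#'
#' @param kind One of `"random_forest"`, `"adaboost"`, `"logistic"`,
#'   `"naive_bayes"`.
#' @param num_trees,max_depth Random-forest settings (defaults are the
#'   grid-searched values 100 and 110).
#' @param ada_rounds,ada_depth AdaBoost rounds and base-tree depth.
#' @return A list of settings of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("random_forest", "adaboost", "logistic",
                                     "naive_bayes"),
                            num_trees = 100L, max_depth = 110L,
                            ada_rounds = 50L, ada_depth = 3L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, num_trees = as.integer(num_trees),
                 max_depth = as.integer(max_depth),
                 ada_rounds = as.integer(ada_rounds),
                 ada_depth = as.integer(ada_depth)),
            class = "classifier_spec")
}

#' Train a drug-disease pair classifier
#'
#' @param x Feature matrix (rows = pairs).
#' @param y 0/1 labels; both classes must be present.
#' @param spec A [classifier_spec()].
#' @param seed Integer seed.
#' @return Object of class `dda_classifier` whose [predict()] method
#'   returns scores in \[0, 1\].
#' @export
train_classifier <- function(x, y, spec = classifier_spec(), seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  x <- as.matrix(x)
  fit <- switch(spec$kind,
    random_forest = {
      d <- data.frame(.y = factor(y, levels = c(0L, 1L)), x)
      ranger::ranger(.y ~ ., data = d, num.trees = spec$num_trees,
                     max.depth = spec$max_depth, probability = TRUE,
                     seed = seed, num.threads = 1L)
    },
    adaboost = adaboost_fit(x, y, rounds = spec$ada_rounds,
                            depth = spec$ada_depth, seed = seed),
    logistic = {
      d <- data.frame(.y = y, x)
      suppressWarnings(stats::glm(.y ~ ., data = d, family = stats::binomial()))
    },
    naive_bayes = e1071::naiveBayes(x, factor(y, levels = c(0L, 1L))))
  structure(list(kind = spec$kind, fit = fit, spec = spec,
                 feature_names = colnames(x)),
            class = "dda_classifier")
}

#' @export
print.dda_classifier <- function(x, ...) {
  cat(sprintf("drug-disease pair classifier (%s), %d features\n",
              x$kind, length(x$feature_names)))
  invisible(x)
}

#' Score pairs with a fitted classifier
#'
#' @param object A `dda_classifier`.
#' @param x Feature matrix with the training columns.
#' @param ... Unused.
#' @return Numeric scores in \[0, 1\] (probability of association).
#' @export
predict.dda_classifier <- function(object, x, ...) {
  x <- as.matrix(x)
  colnames(x) <- object$feature_names
  switch(object$kind,
    random_forest = {
      d <- data.frame(x)
      unname(predict(object$fit, d, num.threads = 1L)$predictions[, "1"])
    },
    adaboost = adaboost_score(object$fit, x),
    logistic = {
      d <- data.frame(x)
      unname(predict(object$fit, newdata = d, type = "response"))
    },
    naive_bayes = unname(predict(object$fit, x, type = "raw")[, "1"]))
}

# Discrete AdaBoost (SAMME with two classes) over rpart trees; returns a
# score in [0, 1] by normalizing the weighted vote margin.
adaboost_fit <- function(x, y, rounds = 50L, depth = 3L, seed = 1L) {
  yy <- ifelse(y == 1L, 1, -1)
  n <- length(yy)
  w <- rep(1 / n, n)
  stumps <- vector("list", rounds)
  alphas <- numeric(rounds)
  d <- data.frame(.y = factor(yy, levels = c(-1, 1)), x)
  with_local_seed(seed, {
    for (m in seq_len(rounds)) {
      fit <- rpart::rpart(.y ~ ., data = d, weights = w / mean(w),
                          method = "class",
                          control = rpart::rpart.control(
                            maxdepth = depth, cp = 0, minsplit = 4,
                            xval = 0))
      pred <- as.numeric(as.character(predict(fit, d, type = "class")))
      err <- sum(w[pred != yy]) / sum(w)
      err <- min(max(err, 1e-10), 1 - 1e-10)
      alpha <- 0.5 * log((1 - err) / err)
      w <- w * exp(-alpha * yy * pred)
      w <- w / sum(w)
      stumps[[m]] <- fit
      alphas[m] <- alpha
      if (err >= 0.5) break
    }
  })
  keep <- which(alphas != 0)
  list(trees = stumps[keep], alphas = alphas[keep])
}

adaboost_score <- function(model, x) {
  d <- data.frame(x)
  margin <- numeric(nrow(d))
  for (m in seq_along(model$trees)) {
    pred <- as.numeric(as.character(predict(model$trees[[m]], d,
                                            type = "class")))
    margin <- margin + model$alphas[m] * pred
  }
  total <- sum(abs(model$alphas))
  (margin / total + 1) / 2
}

#' Rank candidate drug-disease pairs by predicted score
#'
#' @param model A fitted `dda_classifier`.
#' @param pairs Data frame `drug`, `disease` of candidates.
#' @param features Feature matrix matching `pairs` row-for-row.
#' @return `pairs` with `score` and `rank` appended, sorted by descending
#'   score; ties broken lexicographically by drug id, then disease id.
#' @export
predict_ranking <- function(model, pairs, features) {
  stopifnot(nrow(pairs) == nrow(features))
  score <- predict(model, features)
  o <- order(-score, pairs$drug, pairs$disease)
  out <- pairs[o, , drop = FALSE]
  out$score <- score[o]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
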