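## Pluggable base learners behind a uniform scorer interface.
##
## fit_scorer(x, y, learner, params)  -> scorer object
## scorer_prob(scorer, x)             -> matrix of class probabilities
##
## Every scorer predicts a probability matrix with one column per class
## level it was trained on.  Degenerate training sets (a single class, or
## too few examples) fall back to a constant-prior scorer so hierarchical
## training never aborts; the model records which nodes fell back.

LEARNERS <- c("random_forest", "adaboost", "logistic_regression", "svm",
              "naive_bayes")

fit_scorer <- function(x, y, learner, params = list()) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) {
    return(constant_scorer(y))
  }
  ## drop zero-variance columns for learners that cannot handle them
  fit <- switch(
    learner,
    random_forest = randomForest::randomForest(
      x = x, y = y,
      ntree = params$ntree %||% 100L,
      mtry = params$mtry %||% max(1L, floor(sqrt(ncol(x))))),
    logistic_regression = fit_multinom(x, y, params),
    svm = e1071::svm(x = x, y = y, probability = TRUE,
                     kernel = params$kernel %||% "radial",
                     cost = params$cost %||% 1),
    naive_bayes = e1071::naiveBayes(x = as.data.frame(x), y = y,
                                    laplace = params$laplace %||% 0),
    adaboost = fit_adaboost(x, y, params),
    stop("unknown base learner: ", learner)
  )
  structure(list(learner = learner, fit = fit, levels = levels(y)),
            class = "te_scorer")
}

constant_scorer <- function(y) {
  y <- as.factor(y)
  prior <- prop.table(table(y))
  structure(list(learner = "constant",
                 fit = as.numeric(prior),
                 levels = names(prior)),
            class = "te_scorer")
}

scorer_prob <- function(scorer, x) {
  lv <- scorer$levels
  n <- nrow(x)
  p <- switch(
    scorer$learner,
    constant = matrix(rep(scorer$fit, each = n), nrow = n,
                      dimnames = list(NULL, lv)),
    random_forest = predict(scorer$fit, x, type = "prob"),
    logistic_regression = predict_multinom(scorer$fit, x, lv),
    svm = {
      pr <- attr(predict(scorer$fit, x, probability = TRUE), "probabilities")
      pr[, lv, drop = FALSE]
    },
    naive_bayes = predict(scorer$fit, as.data.frame(x), type = "raw"),
    adaboost = predict_adaboost(scorer$fit, x, lv),
    stop("unknown scorer type")
  )
  p <- as.matrix(p)[, lv, drop = FALSE]
  p[!is.finite(p)] <- 0
  p
}

## multinomial logistic regression via nnet; covers binary and multiclass
fit_multinom <- function(x, y, params) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- y
  nw <- (ncol(x) + 1L) * nlevels(y) + 10L
  nnet::multinom(.y ~ ., data = df, trace = FALSE,
                 MaxNWts = max(nw, 1000L),
                 maxit = params$maxit %||% 100L,
                 decay = params$decay %||% 1e-4)
}

predict_multinom <- function(fit, x, lv) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  pr <- predict(fit, newdata = df, type = "probs")
  if (is.null(dim(pr))) {
    if (length(lv) == 2L) {
      pr <- cbind(1 - pr, pr)
      colnames(pr) <- lv
    } else {
      pr <- matrix(pr, nrow = 1L, dimnames = list(NULL, names(pr)))
    }
  }
  pr
}

## SAMME boosting on depth-1 rpart trees
fit_adaboost <- function(x, y, params) {
  m_rounds <- params$n_rounds %||% 50L
  maxdepth <- params$maxdepth %||% 1L
  n <- length(y)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- y
  stumps <- list()
  alphas <- numeric(0)
  ctrl <- rpart::rpart.control(maxdepth = maxdepth, cp = 0, minsplit = 2,
                               xval = 0)
  for (m in seq_len(m_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = ctrl)
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K) break
    alpha <- log((1 - err) / max(err, 1e-10)) + log(K - 1)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err < 1e-10) break
  }
  if (length(stumps) == 0L) {  # nothing boostable; weighted prior
    return(list(prior = prop.table(table(y))))
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(fit, x, lv) {
  n <- nrow(x)
  if (!is.null(fit$prior)) {
    return(matrix(rep(as.numeric(fit$prior), each = n), nrow = n,
                  dimnames = list(NULL, names(fit$prior))))
  }
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  scores <- matrix(0, nrow = n, ncol = length(lv),
                   dimnames = list(NULL, lv))
  for (m in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[m]], df, type = "class")
    scores[cbind(seq_len(n), match(as.character(pred), lv))] <-
      scores[cbind(seq_len(n), match(as.character(pred), lv))] +
      fit$alphas[m]
  }
  sweep(scores, 1L, pmax(rowSums(scores), 1e-12), "/")
}
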