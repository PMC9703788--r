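# The five-classifier panel of the patient-versus-patient stage.  Each model
# definition provides fit(X, y, params, positive) -> object and
# predict(object, X) -> list(class = character, score = numeric oriented
# toward the positive class), plus a seeded hyperparameter sampler for the
# optional random-search HPO.  Scores are class probabilities for the
# probabilistic models and signed decision values for the margin models.

model_names <- function() {
  c("RandomForest", "SGD", "Bagging", "GsNB", "PCA+SVM")
}

normalize_model_name <- function(name) {
  key <- tolower(gsub("[^a-z]", "", tolower(name)))
  map <- c(randomforest = "RandomForest", rf = "RandomForest",
           sgd = "SGD",
           bagging = "Bagging", bag = "Bagging",
           gsnb = "GsNB", gnb = "GsNB", naivebayes = "GsNB",
           pcasvm = "PCA+SVM", svm = "PCA+SVM")
  if (!key %in% names(map)) {
    stop("unknown model '", name, "'; choose one of: ",
         paste(model_names(), collapse = ", "))
  }
  unname(map[key])
}

model_def <- function(name) {
  switch(
    name,
    RandomForest = list(
      fit = function(X, y, params, positive) {
        rf_seed <- params$fit_seed %||% 1L
        with_seed(rf_seed, randomForest::randomForest(
          X, y, ntree = params$ntree %||% 200L,
          mtry = params$mtry %||% max(1L, floor(sqrt(ncol(X))))))
      },
      predict = function(m, X, positive) {
        pr <- stats::predict(m, X, type = "prob")[, positive]
        list(class = as.character(stats::predict(m, X)), score = pr)
      },
      sample_params = function() {
        list(ntree = sample(c(100L, 200L, 500L), 1L),
             mtry_frac = stats::runif(1, 0.05, 1))
      },
      resolve_params = function(p, ncol_X) {
        if (!is.null(p$mtry_frac)) {
          p$mtry <- max(1L, floor(p$mtry_frac * ncol_X))
        }
        p
      }),
    SGD = list(
      fit = function(X, y, params, positive) {
        fit_sgd_hinge(X, y, positive,
                      lambda = params$lambda %||% 1e-3,
                      n_epochs = params$n_epochs %||% 30L,
                      seed = params$fit_seed %||% 1L)
      },
      predict = function(m, X, positive) predict_sgd_hinge(m, X),
      sample_params = function() {
        list(lambda = 10^stats::runif(1, -5, -1),
             n_epochs = sample(c(10L, 30L, 60L), 1L))
      },
      resolve_params = function(p, ncol_X) p),
    Bagging = list(
      fit = function(X, y, params, positive) {
        fit_bagged_trees(X, y, n_bag = params$n_bag %||% 25L,
                         minsplit = params$minsplit %||% 5L,
                         seed = params$fit_seed %||% 1L)
      },
      predict = function(m, X, positive) predict_bagged_trees(m, X, positive),
      sample_params = function() {
        list(n_bag = sample(c(10L, 25L, 50L), 1L),
             minsplit = sample(c(2L, 5L, 10L), 1L))
      },
      resolve_params = function(p, ncol_X) p),
    GsNB = list(
      fit = function(X, y, params, positive) {
        e1071::naiveBayes(X, y)
      },
      predict = function(m, X, positive) {
        pr <- stats::predict(m, X, type = "raw")[, positive]
        cls <- as.character(stats::predict(m, X, type = "class"))
        list(class = cls, score = pr)
      },
      sample_params = function() list(),
      resolve_params = function(p, ncol_X) p),
    `PCA+SVM` = list(
      fit = function(X, y, params, positive) {
        fit_pca_svm(X, y, variance_retained = params$variance %||% 0.8,
                    cost = params$cost %||% 1)
      },
      predict = function(m, X, positive) predict_pca_svm(m, X, positive),
      sample_params = function() {
        list(cost = 10^stats::runif(1, -2, 2))
      },
      resolve_params = function(p, ncol_X) p),
    stop("unknown model: ", name))
}

# --- linear SVM after fold-fitted scaling and PCA ------------------------

fit_pca_svm <- function(X, y, variance_retained = 0.8, cost = 1) {
  sc <- fold_scaler(X)
  Z <- apply_scaler(sc, X)
  V <- pca_basis(Z, variance_retained)
  fit <- fit_linear_svm(Z %*% V, droplevels(y), cost = cost)
  list(scaler = sc, basis = V, svm = fit)
}

predict_pca_svm <- function(m, X, positive) {
  Z <- apply_scaler(m$scaler, X) %*% m$basis
  dec <- svm_decision(m$svm, Z)
  score <- if (m$svm$pos == positive) dec else -dec
  list(class = ifelse(dec > 0, m$svm$pos, m$svm$neg), score = score)
}

# --- linear hinge-loss classifier trained by stochastic gradient descent --
# Pegasos-style updates with an offset schedule eta_t = 1 / (lambda * t + 1)
# (bounded first steps), deterministic given the shuffling seed; features
# are standardised internally.

fit_sgd_hinge <- function(X, y, positive, lambda = 1e-3, n_epochs = 30L,
                          seed = 1L) {
  sc <- fold_scaler(X)
  Z <- apply_scaler(sc, X)
  yy <- ifelse(as.character(y) == positive, 1, -1)
  neg_label <- setdiff(unique(as.character(y)), positive)[1]
  n <- nrow(Z)
  w <- numeric(ncol(Z))
  b <- 0
  t <- 0
  with_seed(seed, {
    for (ep in seq_len(n_epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1
        eta <- 1 / (lambda * t + 1)
        margin <- yy[i] * (sum(w * Z[i, ]) + b)
        w <- (1 - eta * lambda) * w
        if (margin < 1) {
          w <- w + eta * yy[i] * Z[i, ]
          b <- b + eta * yy[i]
        }
      }
    }
  })
  list(scaler = sc, w = w, b = b, positive = positive, negative = neg_label)
}

predict_sgd_hinge <- function(m, X) {
  Z <- apply_scaler(m$scaler, X)
  score <- as.numeric(Z %*% m$w) + m$b
  list(class = ifelse(score > 0, m$positive, m$negative), score = score)
}

# --- bootstrap-aggregated decision trees ----------------------------------

fit_bagged_trees <- function(X, y, n_bag = 25L, minsplit = 5L, seed = 1L) {
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(X)))
  df$.y <- factor(y)
  n <- nrow(df)
  trees <- with_seed(seed, {
    lapply(seq_len(n_bag), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      rpart::rpart(.y ~ ., data = df[idx, , drop = FALSE],
                   method = "class",
                   control = rpart::rpart.control(minsplit = minsplit,
                                                  cp = 0.01, xval = 0L))
    })
  })
  list(trees = trees, levels = levels(df$.y), ncol = ncol(X))
}

predict_bagged_trees <- function(m, X, positive) {
  df <- as.data.frame(X)
  names(df) <- paste0("V", seq_len(ncol(X)))
  probs <- vapply(m$trees, function(tr) {
    stats::predict(tr, df, type = "prob")[, positive]
  }, numeric(nrow(df)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  score <- rowMeans(probs)
  other <- setdiff(m$levels, positive)[1]
  list(class = ifelse(score > 0.5, positive, other), score = score)
}
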