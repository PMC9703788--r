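#' Stratified cross-validation folds
#'
#' Deals the subjects of each class, in seeded shuffled order, round-robin
#' into `k` folds, so fold class proportions are as balanced as the counts
#' allow and the assignment is reproducible.
#'
#' @param y factor (or coercible) of class labels.
#' @param k number of folds; must not exceed the smallest class size.
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids in `1:k`, one per subject.
#' @export
make_folds <- function(y, k, seed = 1L) {
  y <- factor(y)
  k <- as.integer(k)
  if (k < 2L) stop("need at least 2 folds")
  if (min(table(y)) < k) {
    stop("smallest class (", min(table(y)), ") is smaller than k = ", k)
  }
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

# Linear SVM fit returning a closure-free decision structure; prediction is
# done from the primal weights directly (identical to predict.svm for the
# linear kernel, but far cheaper in tight loops).
fit_linear_svm <- function(X, y, cost = 1) {
  m <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- t(m$coefs) %*% m$SV
  list(w = as.numeric(w), rho = m$rho,
       pos = m$levels[m$labels[1]], neg = m$levels[m$labels[2]])
}

svm_decision <- function(fit, X) {
  as.numeric(X %*% fit$w) - fit$rho
}

svm_predict <- function(fit, X) {
  ifelse(svm_decision(fit, X) > 0, fit$pos, fit$neg)
}

# Training-fold standardisation: center/scale by training statistics,
# constant features get unit scale.
fold_scaler <- function(Xtr) {
  mu <- colMeans(Xtr)
  sd <- sqrt(colMeans(sweep(Xtr, 2L, mu)^2))
  sd[sd < .Machine$double.eps] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(sc, X) {
  sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, "/")
}

# PCA basis retaining the smallest number of components whose cumulative
# explained variance reaches `variance_retained` (always at least one).
pca_basis <- function(Xs, variance_retained) {
  sv <- svd(Xs, nu = 0L)
  ev <- sv$d^2
  tot <- sum(ev)
  ncomp <- if (tot <= .Machine$double.eps) 1L else {
    which(cumsum(ev) / tot >= variance_retained - 1e-12)[1L]
  }
  sv$v[, seq_len(max(ncomp, 1L)), drop = FALSE]
}

#' Cross-validated PCA+SVM decoding accuracy
#'
#' The classifier protocol shared by the searchlight and the sub-cluster
#' stability stages: within each fold, features are standardised using
#' training-fold statistics, projected onto the principal components fitted
#' on the training rows only (keeping the smallest number of components
#' reaching the requested explained variance), and a linear support vector
#' machine is trained on the projected training rows.  Accuracy is the mean
#' over folds of the fraction of correct test-row predictions.
#'
#' @param X numeric `subjects x features` matrix.
#' @param y two-level factor of class labels.
#' @param fold_id integer fold assignment from [make_folds()].
#' @param variance_retained fraction of variance the PCA keeps (default 0.8).
#' @param cost linear-SVM regularisation parameter C (default 1).
#' @param pca_leaky if `TRUE`, scaling and PCA are fitted once on all rows
#'   before splitting (the information-leaking shortcut some pipelines use);
#'   default `FALSE` keeps all fitting inside training folds.
#' @return mean cross-validated accuracy in `[0, 1]`.
#' @export
cv_pca_svm <- function(X, y, fold_id, variance_retained = 0.8, cost = 1,
                       pca_leaky = FALSE) {
  y <- factor(y)
  if (nlevels(droplevels(y)) != 2L) stop("need exactly two classes")
  k <- max(fold_id)
  acc <- numeric(k)
  if (pca_leaky) {
    sc <- fold_scaler(X)
    Z_all <- apply_scaler(sc, X)
    V <- pca_basis(Z_all, variance_retained)
    Z_all <- Z_all %*% V
  }
  for (f in seq_len(k)) {
    te <- fold_id == f
    if (pca_leaky) {
      Ztr <- Z_all[!te, , drop = FALSE]
      Zte <- Z_all[te, , drop = FALSE]
    } else {
      sc <- fold_scaler(X[!te, , drop = FALSE])
      Ztr <- apply_scaler(sc, X[!te, , drop = FALSE])
      Zte <- apply_scaler(sc, X[te, , drop = FALSE])
      V <- pca_basis(Ztr, variance_retained)
      Ztr <- Ztr %*% V
      Zte <- Zte %*% V
    }
    fit <- fit_linear_svm(Ztr, droplevels(y[!te]), cost = cost)
    acc[f] <- mean(svm_predict(fit, Zte) == as.character(y[te]))
  }
  mean(acc)
}
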