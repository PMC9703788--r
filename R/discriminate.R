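#' Evaluation protocol for the patient-versus-patient stage
#'
#' Stratified fivefold cross-validation repeated over ten independently
#' reshuffled iterations, optionally with seeded random-search
#' hyperparameter optimisation nested inside the training folds.
#'
#' @param n_folds folds per iteration (default 5).
#' @param n_iterations independent CV repetitions (default 10).
#' @param hpo `"none"` (fixed defaults) or `"random"` (nested seeded random
#'   search).
#' @param hpo_budget candidate draws per random search (default 10).
#' @param seed master seed for fold reshuffles, HPO draws and any
#'   stochastic fits.
#' @return list of class `eval_protocol`.
#' @export
eval_protocol <- function(n_folds = 5L, n_iterations = 10L,
                          hpo = c("none", "random"), hpo_budget = 10L,
                          seed = 1L) {
  hpo <- match.arg(hpo)
  stopifnot(n_folds >= 2L, n_iterations >= 1L)
  structure(list(n_folds = as.integer(n_folds),
                 n_iterations = as.integer(n_iterations),
                 hpo = hpo, hpo_budget = as.integer(hpo_budget),
                 seed = as.integer(seed)),
            class = "eval_protocol")
}

#' Classify two patient groups and evaluate with the full metric set
#'
#' Runs one classifier of the panel (random forest, linear SGD, bagged
#' trees, Gaussian naive Bayes, or PCA+SVM) under the repeated stratified
#' CV protocol.  Within each fold all fitting — scaling, PCA, tree growing,
#' and any hyperparameter search — sees training rows only.  Per iteration,
#' test predictions are pooled across folds and summarised as sensitivity,
#' specificity, balanced accuracy (their arithmetic mean) and rank AUC;
#' the report carries the per-iteration values and their mean and standard
#' deviation.
#'
#' @param X numeric `subjects x features` matrix.
#' @param y two-level labels (e.g. ET / PD).
#' @param model one of `"RandomForest"`, `"SGD"`, `"Bagging"`, `"GsNB"`,
#'   `"PCA+SVM"` (short aliases such as `"rf"`, `"pca_svm"` are accepted).
#' @param protocol an [eval_protocol()].
#' @param positive the positive-class label (defaults to `"ET"` when
#'   present, otherwise the first factor level).
#' @return list of class `classifier_eval` with `model`, `positive`,
#'   `per_iteration` (data frame of sensitivity / specificity / accuracy /
#'   auc per iteration), `summary` (mean and sd of each metric), and `roc`
#'   (threshold-sweep points over all pooled scores).
#' @export
classify_groups <- function(X, y, model, protocol = eval_protocol(),
                            positive = NULL) {
  model <- normalize_model_name(model)
  y <- factor(as.character(y))
  if (nlevels(y) != 2L) stop("need exactly two classes")
  if (min(table(y)) < protocol$n_folds) {
    stop("smallest class is below n_folds = ", protocol$n_folds)
  }
  if (is.null(positive)) {
    positive <- if ("ET" %in% levels(y)) "ET" else levels(y)[1]
  }
  def <- model_def(model)
  iter_seeds <- derive_seeds(protocol$seed, protocol$n_iterations)

  per_iter <- vector("list", protocol$n_iterations)
  all_scores <- numeric(0)
  all_labels <- character(0)
  for (it in seq_len(protocol$n_iterations)) {
    fold_id <- make_folds(y, protocol$n_folds, iter_seeds[it])
    pred <- character(length(y))
    score <- numeric(length(y))
    fold_seeds <- derive_seeds(iter_seeds[it], protocol$n_folds)
    for (f in seq_len(protocol$n_folds)) {
      te <- fold_id == f
      params <- select_params(def, X[!te, , drop = FALSE], y[!te], positive,
                              protocol, fold_seeds[f])
      params$fit_seed <- fold_seeds[f]
      params <- def$resolve_params(params, ncol(X))
      m <- def$fit(X[!te, , drop = FALSE], droplevels(y[!te]), params,
                   positive)
      pr <- def$predict(m, X[te, , drop = FALSE], positive)
      pred[te] <- pr$class
      score[te] <- pr$score
    }
    rates <- confusion_rates(pred, y, positive)
    per_iter[[it]] <- data.frame(
      iteration = it,
      sensitivity = rates[["sensitivity"]],
      specificity = rates[["specificity"]],
      accuracy = balanced_accuracy(rates[["sensitivity"]],
                                   rates[["specificity"]]),
      auc = auc_rank(score, y, positive))
    all_scores <- c(all_scores, score)
    all_labels <- c(all_labels, as.character(y))
  }
  per_iter <- do.call(rbind, per_iter)
  summ <- data.frame(
    metric = c("sensitivity", "specificity", "accuracy", "auc"),
    mean = c(mean(per_iter$sensitivity), mean(per_iter$specificity),
             mean(per_iter$accuracy), mean(per_iter$auc)),
    sd = c(stats::sd(per_iter$sensitivity), stats::sd(per_iter$specificity),
           stats::sd(per_iter$accuracy), stats::sd(per_iter$auc)))
  structure(list(model = model, positive = positive,
                 per_iteration = per_iter, summary = summ,
                 roc = roc_curve(all_scores, all_labels, positive)),
            class = "classifier_eval")
}

#' @export
print.classifier_eval <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<classifier_eval> %s (positive = %s)\n  ACC %.1f%%  SEN %.1f%%  SPE %.1f%%  AUC %.3f\n",
    x$model, x$positive,
    s$mean[s$metric == "accuracy"], s$mean[s$metric == "sensitivity"],
    s$mean[s$metric == "specificity"], s$mean[s$metric == "auc"]))
  invisible(x)
}

# Nested random-search HPO on the training rows only: each candidate is
# scored by inner 3-fold CV balanced accuracy; ties keep the earlier draw.
select_params <- function(def, Xtr, ytr, positive, protocol, seed) {
  if (protocol$hpo == "none") return(list())
  cands <- with_seed(seed, {
    lapply(seq_len(protocol$hpo_budget), function(i) def$sample_params())
  })
  cands <- Filter(length, cands)
  if (!length(cands)) return(list())
  inner_k <- min(3L, min(table(droplevels(ytr))))
  if (inner_k < 2L) return(cands[[1]])
  fold_id <- make_folds(droplevels(ytr), inner_k, seed)
  best <- NULL
  best_score <- -Inf
  for (p in cands) {
    p2 <- def$resolve_params(p, ncol(Xtr))
    p2$fit_seed <- seed
    accs <- numeric(inner_k)
    for (f in seq_len(inner_k)) {
      te <- fold_id == f
      m <- def$fit(Xtr[!te, , drop = FALSE], droplevels(ytr[!te]), p2,
                   positive)
      pr <- def$predict(m, Xtr[te, , drop = FALSE], positive)
      rates <- tryCatch(confusion_rates(pr$class, ytr[te], positive),
                        error = function(e) c(sensitivity = NA,
                                              specificity = NA))
      accs[f] <- if (anyNA(rates)) mean(pr$class == as.character(ytr[te]))
                 else balanced_accuracy(rates[["sensitivity"]],
                                        rates[["specificity"]]) / 100
    }
    if (mean(accs) > best_score) {
      best_score <- mean(accs)
      best <- p
    }
  }
  best
}

#' Compare direct and framework-based classification
#'
#' Runs the five-classifier panel on (a) all in-mask smoothed GM voxels
#' ("direct") and (b) the biomarker-mask voxels selected by the stability
#' stage ("framework"), and reports balanced accuracy, sensitivity,
#' specificity and AUC per model and condition — the head-to-head table of
#' the classification stage.
#'
#' @param coh a [cohort()]; only the two `groups` are used.
#' @param biomarker_mask logical 3D array from [select_biomarkers()] /
#'   [find_biomarkers()]; must be nonempty.
#' @param protocol an [eval_protocol()].
#' @param models character vector of panel models (default all five).
#' @param groups the two labels to classify (default ET vs PD).
#' @param positive positive-class label (default `groups[1]`).
#' @return data frame with one row per model x condition: `model`,
#'   `condition` (`direct` / `framework`), `n_features`, `acc`, `sen`,
#'   `spe` (percent), `auc`.
#' @export
compare_direct_vs_framework <- function(coh, biomarker_mask,
                                        protocol = eval_protocol(),
                                        models = model_names(),
                                        groups = c("ET", "PD"),
                                        positive = groups[1]) {
  if (!any(biomarker_mask)) stop("biomarker mask is empty")
  two <- subset_cohort(coh, groups)
  y <- droplevels(two$groups)
  X_direct <- build_feature_matrix(two, two$mask)$X
  X_frame <- build_feature_matrix(two, biomarker_mask & two$mask)$X
  rows <- list()
  for (model in vapply(models, normalize_model_name, "")) {
    for (cond in c("direct", "framework")) {
      X <- if (cond == "direct") X_direct else X_frame
      ev <- classify_groups(X, y, model, protocol, positive = positive)
      s <- ev$summary
      rows[[length(rows) + 1L]] <- data.frame(
        model = model, condition = cond, n_features = ncol(X),
        acc = s$mean[s$metric == "accuracy"],
        sen = s$mean[s$metric == "sensitivity"],
        spe = s$mean[s$metric == "specificity"],
        auc = s$mean[s$metric == "auc"],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
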