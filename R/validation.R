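# Outcome validation: gradient-boosting models checking (a) that the
# representative subgraphs predict phenotype membership and (b) that
# phenotypes carry prognostic information on 30-day mortality, benchmarked
# against mean 7-day SOFA and the Elixhauser index. Metrics follow the
# study's table layout: accuracy, precision, recall, F-score and ROC-AUC
# per split (and per class, one-vs-rest, for the multiclass model).

#' Binary classification metrics from probabilities
#'
#' Accuracy, precision, recall, F-score at the 0.5 threshold, plus
#' ROC-AUC. Precision is reported as 0 when no positive prediction is
#' made; AUC is `NA` when only one class is present.
#'
#' @param truth logical (or 0/1) vector.
#' @param prob predicted probability of the positive class.
#' @param threshold classification threshold.
#' @return named numeric vector `accuracy`, `precision`, `recall`,
#'   `f_score`, `auc`.
#' @export
#' @examples
#' binary_metrics(c(TRUE, TRUE, FALSE, FALSE), c(0.9, 0.4, 0.6, 0.1))
binary_metrics <- function(truth, prob, threshold = 0.5) {
  truth <- as.logical(truth)
  pred <- prob >= threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  accuracy <- mean(pred == truth)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f_score <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  auc <- if (length(unique(truth)) < 2) NA_real_ else
    as.numeric(pROC::auc(pROC::roc(response = truth, predictor = prob,
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  c(accuracy = accuracy, precision = precision, recall = recall,
    f_score = f_score, auc = auc)
}

#' Build a feature set for outcome validation
#'
#' `representative_subgraphs`: the count-matrix columns restricted to the
#' union of the per-component representative sets. `mean_sofa_7d`: one
#' column, the mean of each patient's daily SOFA totals over days 1-7
#' (observed days only). `elixhauser_index`: one column of weighted
#' comorbidity-flag sums.
#'
#' @param name one of `"representative_subgraphs"`, `"mean_sofa_7d"`,
#'   `"elixhauser_index"`.
#' @param artifacts list carrying the needed inputs: `matrix` (count
#'   matrix structure) and `representatives` (list of sets) for subgraphs;
#'   `sofa` (daily table) for SOFA; `comorbidities` (+ optional `weights`)
#'   for Elixhauser.
#' @param patients patient universe defining row order.
#' @return list of class `feature_set`: `name`, `matrix` (patients x
#'   features, dense).
#' @export
build_features <- function(name, artifacts, patients) {
  mat <- switch(name,
    representative_subgraphs = {
      ids <- unique(unlist(lapply(artifacts$representatives, function(s) {
        if (is.data.frame(s)) s$subgraph else s
      })))
      counts <- artifacts$matrix$counts
      ids <- intersect(ids, colnames(counts))
      m <- as.matrix(counts[match(patients, artifacts$matrix$patients), ids,
                            drop = FALSE])
      rownames(m) <- patients
      m
    },
    mean_sofa_7d = {
      sofa <- artifacts$sofa
      sofa <- sofa[sofa$day >= 1 & sofa$day <= 7, ]
      mu <- tapply(sofa$total, sofa$patient_id, mean)
      m <- matrix(as.numeric(mu[patients]), ncol = 1,
                  dimnames = list(patients, "mean_sofa_7d"))
      m
    },
    elixhauser_index = {
      weights <- artifacts$weights
      if (is.null(weights)) weights <- elixhauser_registry()
      idx <- elixhauser_score(artifacts$comorbidities, weights)
      m <- matrix(idx[match(patients, artifacts$comorbidities$patient_id)],
                  ncol = 1, dimnames = list(patients, "elixhauser_index"))
      m
    },
    stop("unknown feature set name: ", name)
  )
  if (anyNA(mat)) stop("feature set '", name, "' has missing values for some patients")
  structure(list(name = name, matrix = mat), class = "feature_set")
}

# seeded xgboost fit; nthread = 1 keeps results reproducible
.fit_gbm <- function(X, y, objective, num_class = NULL, nrounds = 300,
                     max_depth = 3, eta = 0.1, seed = 1L) {
  params <- list(objective = objective, max_depth = max_depth, eta = eta,
                 nthread = 1, seed = seed)
  if (!is.null(num_class)) params$num_class <- num_class
  dtrain <- xgboost::xgb.DMatrix(data = X, label = y)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

.predict_prob <- function(model, X, k = NULL) {
  p <- stats::predict(model, xgboost::xgb.DMatrix(X))
  if (!is.null(k) && is.null(dim(p))) p <- matrix(p, ncol = k, byrow = TRUE)
  p
}

#' Gradient-boosting membership classifier
#'
#' Multiclass GBM predicting phenotype membership from a feature set, with
#' per-class one-vs-rest metrics on a refreshed train/test split.
#'
#' @param features a `feature_set` (typically representative subgraph
#'   counts).
#' @param labels integer phenotype labels named by patient id.
#' @param split list with `train`/`test` id vectors (e.g.
#'   [split_cohort()]).
#' @param nrounds,max_depth,eta GBM hyperparameters.
#' @param seed integer seed.
#' @return list with `model`, `metrics` (data.frame `measure`, `split`,
#'   `class`, `value`; overall accuracy rows use class `"overall"`), and
#'   `split`.
#' @export
train_membership_classifier <- function(features, labels, split,
                                        nrounds = 300, max_depth = 3,
                                        eta = 0.1, seed = 1L) {
  X <- features$matrix
  lab <- labels[rownames(X)]
  classes <- sort(unique(lab[!is.na(lab)]))
  k <- length(classes)
  tr <- intersect(split$train, rownames(X))
  te <- intersect(split$test, rownames(X))
  ytr <- match(lab[tr], classes) - 1L
  if (length(unique(ytr)) < 2) stop("need at least 2 classes in the training split")
  if (length(unique(ytr)) < k) stop("class absent from the training split")
  model <- .fit_gbm(X[tr, , drop = FALSE], ytr, "multi:softprob",
                    num_class = k, nrounds = nrounds, max_depth = max_depth,
                    eta = eta, seed = seed)
  rows <- list()
  for (sp in c("train", "test")) {
    ids <- if (sp == "train") tr else te
    P <- .predict_prob(model, X[ids, , drop = FALSE], k = k)
    truth <- lab[ids]
    pred_class <- classes[max.col(P, ties.method = "first")]
    rows[[length(rows) + 1]] <- data.frame(
      measure = "accuracy", split = sp, class = "overall",
      value = mean(pred_class == truth))
    for (ci in seq_len(k)) {
      m <- binary_metrics(truth == classes[ci], P[, ci])
      rows[[length(rows) + 1]] <- data.frame(
        measure = c("precision", "recall", "f_score", "auc"), split = sp,
        class = as.character(classes[ci]),
        value = as.numeric(m[c("precision", "recall", "f_score", "auc")]))
    }
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(model = model, metrics = metrics, split = split)
}

#' Gradient-boosting 30-day mortality model
#'
#' Binary GBM on a feature set with train/test accuracy, precision,
#' recall, F-score and ROC-AUC.
#'
#' @param features a `feature_set`.
#' @param outcomes logical 30-day mortality flags named by patient id.
#' @inheritParams train_membership_classifier
#' @return list with `model`, `metrics` (data.frame `measure`, `split`,
#'   `value`), `feature_name`, `split`.
#' @export
train_mortality_model <- function(features, outcomes, split, nrounds = 300,
                                  max_depth = 3, eta = 0.1, seed = 1L) {
  X <- features$matrix
  y <- stats::setNames(as.logical(outcomes[rownames(X)]), rownames(X))
  tr <- intersect(split$train, rownames(X))
  te <- intersect(split$test, rownames(X))
  if (length(unique(y[tr])) < 2) stop("both outcome classes must be present in the training split")
  model <- .fit_gbm(X[tr, , drop = FALSE], as.numeric(y[tr]),
                    "binary:logistic", nrounds = nrounds,
                    max_depth = max_depth, eta = eta, seed = seed)
  rows <- lapply(c("train", "test"), function(sp) {
    ids <- if (sp == "train") tr else te
    p <- .predict_prob(model, X[ids, , drop = FALSE])
    m <- binary_metrics(y[ids], p)
    data.frame(measure = names(m), split = sp, value = as.numeric(m))
  })
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  list(model = model, metrics = metrics, feature_name = features$name,
       split = split)
}

#' Compare mortality models across feature sets
#'
#' Orders the models by test AUC and flags whether the subgraph-based
#' features rank first, mirroring the benchmark comparison of the
#' phenotyping study (subgraphs > SOFA > Elixhauser).
#'
#' @param models named list of [train_mortality_model()] results, all fit
#'   on the same split.
#' @return list with `table` (data.frame `feature_set`, `test_accuracy`,
#'   `test_auc`, ordered by AUC descending), `subgraphs_first` (logical;
#'   `NA` when the top is tied) and `tie` flag.
#' @export
compare_benchmarks <- function(models) {
  splits <- lapply(models, function(m) m$split)
  ref <- splits[[1]]
  same <- vapply(splits, function(s) identical(s$train, ref$train) &&
                   identical(s$test, ref$test), logical(1))
  if (!all(same)) stop("all models must be evaluated on the same split")
  tab <- do.call(rbind, lapply(names(models), function(nm) {
    met <- models[[nm]]$metrics
    data.frame(feature_set = models[[nm]]$feature_name,
               test_accuracy = met$value[met$measure == "accuracy" & met$split == "test"],
               test_auc = met$value[met$measure == "auc" & met$split == "test"])
  }))
  tab <- tab[order(-tab$test_auc), , drop = FALSE]
  rownames(tab) <- NULL
  tie <- nrow(tab) > 1 && tab$test_auc[1] == tab$test_auc[2]
  list(table = tab,
       subgraphs_first = if (tie) NA else
         tab$feature_set[1] == "representative_subgraphs",
       tie = tie)
}
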