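test_that("binary metrics reproduce hand-computed confusion arithmetic", {
  truth <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE)
  prob <- c(0.9, 0.8, 0.7, 0.4, 0.6, 0.3, 0.2, 0.1, 0.55, 0.45)
  # by hand at 0.5: TP 4 (0.9 0.8 0.7 0.55), FP 1 (0.6), FN 1 (0.4), TN 4;
  # AUC: 22 of 25 positive-negative pairs correctly ordered
  m <- binary_metrics(truth, prob)
  expect_equal(unname(m["accuracy"]), 0.8)
  expect_equal(unname(m["precision"]), 0.8)
  expect_equal(unname(m["recall"]), 0.8)
  expect_equal(unname(m["f_score"]), 0.8)
  expect_equal(unname(m["auc"]), 22 / 25)
  # degenerate edges: no positive predictions, single-class truth
  m0 <- binary_metrics(c(TRUE, FALSE), c(0.1, 0.2))
  expect_equal(unname(m0["precision"]), 0)
  expect_equal(unname(m0["recall"]), 0)
  expect_true(is.na(binary_metrics(c(TRUE, TRUE), c(0.9, 0.8))["auc"]))
})

test_that("perfect and reversed rankings bracket the AUC range", {
  truth <- rep(c(TRUE, FALSE), each = 5)
  expect_equal(unname(binary_metrics(truth, c(6:10, 1:5) / 10)["auc"]), 1)
  expect_equal(unname(binary_metrics(truth, c(1:5, 6:10) / 10)["auc"]), 0)
})

toy_artifacts <- function() {
  pats <- c("A", "B", "C")
  counts <- Matrix::sparseMatrix(
    i = c(1, 1, 2, 3), j = c(1, 2, 2, 3), x = c(2, 1, 4, 5),
    dims = c(3, 3), dimnames = list(pats, c("hr:1,1", "hr:2,2", "rr:0,0")))
  list(
    matrix = list(counts = counts, patients = pats),
    representatives = list(c("hr:1,1"), c("rr:0,0")),
    sofa = data.frame(patient_id = rep(pats, each = 7), day = rep(1:7, 3),
                      total = rep(8, 21)),
    comorbidities = data.frame(
      patient_id = pats,
      matrix(0L, 3, 30, dimnames = list(NULL, elixhauser_registry()$category)),
      check.names = FALSE)
  )
}

test_that("feature sets are assembled per contract", {
  arts <- toy_artifacts()
  pats <- c("A", "B", "C")
  fs <- build_features("representative_subgraphs", arts, pats)
  expect_equal(colnames(fs$matrix), c("hr:1,1", "rr:0,0"))
  expect_equal(unname(fs$matrix["A", "hr:1,1"]), 2)
  fsofa <- build_features("mean_sofa_7d", arts, pats)
  expect_equal(unname(fsofa$matrix[, 1]), rep(8, 3))
  felix <- build_features("elixhauser_index", arts, pats)
  expect_equal(unname(felix$matrix[, 1]), rep(0, 3))
  expect_error(build_features("nope", arts, pats), "unknown")
})

sep_cohort <- function(n = 120, seed = 1) {
  # three linearly separable feature clusters with matching labels
  set.seed(seed)
  g <- sample(1:3, n, replace = TRUE)
  X <- cbind(g == 1, g == 2, g == 3) * 5 + matrix(rnorm(n * 3, sd = 0.3), n, 3)
  rownames(X) <- sprintf("P%03d", 1:n)
  colnames(X) <- c("f1", "f2", "f3")
  list(X = X, g = setNames(g, rownames(X)))
}

test_that("the membership classifier nails separable features and tracks layout", {
  sc <- sep_cohort()
  fs <- structure(list(name = "representative_subgraphs", matrix = sc$X),
                  class = "feature_set")
  split <- list(train = rownames(sc$X)[1:90], test = rownames(sc$X)[91:120])
  res <- train_membership_classifier(fs, sc$g, split, nrounds = 50, seed = 1)
  met <- res$metrics
  acc <- met$value[met$measure == "accuracy" & met$split == "test"]
  expect_gte(acc, 0.95)
  # layout: overall accuracy + 4 measures x k classes, per split
  expect_setequal(unique(met$split), c("train", "test"))
  expect_setequal(unique(met$class), c("overall", "1", "2", "3"))
  expect_true(all(met$value >= 0 & met$value <= 1))
  # a class missing from train errors
  g_bad <- sc$g; g_bad[split$train] <- ifelse(sc$g[split$train] == 3, 2,
                                              sc$g[split$train])
  expect_error(train_membership_classifier(fs, g_bad, split, nrounds = 5),
               "class")
})

test_that("shuffled labels yield chance-level per-class AUC", {
  sc <- sep_cohort(n = 200, seed = 2)
  set.seed(99)
  g_shuf <- setNames(sample(sc$g), names(sc$g))
  fs <- structure(list(name = "representative_subgraphs", matrix = sc$X),
                  class = "feature_set")
  split <- list(train = rownames(sc$X)[1:150], test = rownames(sc$X)[151:200])
  res <- train_membership_classifier(fs, g_shuf, split, nrounds = 50, seed = 1)
  aucs <- with(res$metrics, value[measure == "auc" & split == "test"])
  expect_true(all(abs(aucs - 0.5) < 0.25))
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("the mortality model recovers a deterministic outcome and stays at chance on noise", {
  set.seed(4)
  n <- 150
  X <- cbind(risk = rnorm(n), junk = rnorm(n))
  rownames(X) <- sprintf("P%03d", 1:n)
  y <- setNames(X[, "risk"] > 0, rownames(X))
  fs <- structure(list(name = "mean_sofa_7d", matrix = X), class = "feature_set")
  split <- list(train = rownames(X)[1:110], test = rownames(X)[111:150])
  res <- train_mortality_model(fs, y, split, nrounds = 100, seed = 1)
  expect_gte(res$metrics$value[res$metrics$measure == "auc" &
                                 res$metrics$split == "test"], 0.95)
  y_null <- setNames(sample(c(TRUE, FALSE), n, replace = TRUE), rownames(X))
  res0 <- train_mortality_model(fs, y_null, split, nrounds = 100, seed = 1)
  expect_lt(abs(res0$metrics$value[res0$metrics$measure == "auc" &
                                     res0$metrics$split == "test"] - 0.5), 0.25)
  expect_error(train_mortality_model(fs, setNames(rep(TRUE, n), rownames(X)),
                                     split), "classes")
})

test_that("benchmark comparison orders by test AUC and flags ties and split mismatches", {
  mk <- function(name, auc, split) {
    list(metrics = data.frame(measure = c("accuracy", "auc", "accuracy", "auc"),
                              split = c("train", "train", "test", "test"),
                              value = c(0.9, 0.9, 0.8, auc)),
         feature_name = name, split = split)
  }
  sp <- list(train = c("A", "B"), test = c("C"))
  cmp <- compare_benchmarks(list(
    subgraphs = mk("representative_subgraphs", 0.681, sp),
    sofa = mk("mean_sofa_7d", 0.560, sp),
    elix = mk("elixhauser_index", 0.507, sp)))
  expect_equal(cmp$table$feature_set,
               c("representative_subgraphs", "mean_sofa_7d", "elixhauser_index"))
  expect_true(cmp$subgraphs_first)
  tie <- compare_benchmarks(list(a = mk("mean_sofa_7d", 0.6, sp),
                                 b = mk("elixhauser_index", 0.6, sp)))
  expect_true(tie$tie)
  expect_true(is.na(tie$subgraphs_first))
  sp2 <- list(train = c("A", "C"), test = c("B"))
  expect_error(compare_benchmarks(list(a = mk("mean_sofa_7d", 0.6, sp),
                                       b = mk("elixhauser_index", 0.5, sp2))),
               "same split")
})
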