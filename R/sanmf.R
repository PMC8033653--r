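# The core estimator: consensus NMF phenotyping over a patient x subgraph
# count matrix, returned as a classed model object with the usual
# accessor/method surface.

#' Subgraph-augmented NMF phenotyping
#'
#' Fits the phenotyping model to a patient-by-subgraph count matrix:
#' `n_runs` seeded NMF restarts yield a consensus co-clustering matrix and
#' its cophenetic correlation (cluster stability); the restart with the
#' lowest Frobenius objective is kept as the final fit, providing the
#' patient-group coefficient matrix `W` and trend-group coefficient matrix
#' `H`, and each patient is assigned to the component with their largest
#' `W` coefficient.
#'
#' @param X nonnegative patient x subgraph matrix (dense or sparse), rows
#'   named by patient id, columns by subgraph id; or the count-matrix
#'   structure returned by [assemble_matrix()].
#' @param k number of phenotypes (components).
#' @param n_runs consensus restarts.
#' @param max_iter,tol optimizer controls, see [fit_nmf()].
#' @param seed integer seed; restart r uses `seed + r`.
#' @return Object of class `sanmf`: list with `W`, `H`, `k`, `assignment`
#'   (integer labels named by patient), `consensus`, `cophenetic_rho`,
#'   `objective`, `trace`, `subgraphs` (metadata when available), `call`.
#' @seealso [select_representatives()], [consensus_cophenetic()],
#'   [select_hyperparameters()]
#' @export
#' @examples
#' X <- rbind(matrix(rpois(60, 5), 10, 6), matrix(0, 10, 6))
#' X <- cbind(X, rbind(matrix(0, 10, 6), matrix(rpois(60, 5), 10, 6)))
#' rownames(X) <- sprintf("P%02d", 1:20)
#' colnames(X) <- sprintf("hr:%d,%d", 1:12, 2:13)
#' fit <- sanmf(X, k = 2, n_runs = 5, seed = 1)
#' table(fit$assignment)
sanmf <- function(X, k = 3, n_runs = 30, max_iter = 200, tol = 1e-5,
                  seed = 1L) {
  cl <- match.call()
  subgraphs <- NULL
  if (is.list(X) && !is.null(X$counts)) {
    subgraphs <- X$subgraphs
    X <- X$counts
  }
  cc <- consensus_cophenetic(X, k, n_runs = n_runs, seed = seed,
                             max_iter = max_iter, tol = tol)
  fit <- cc$best_fit
  rownames(fit$W) <- rownames(X)
  colnames(fit$H) <- colnames(X)
  assignment <- assign_membership(fit$W)
  structure(list(
    W = fit$W, H = fit$H, k = as.integer(k),
    assignment = assignment, consensus = cc$consensus,
    cophenetic_rho = cc$cophenetic_rho,
    objective = fit$objective, trace = fit$trace,
    n_runs = n_runs, seed = seed, subgraphs = subgraphs, call = cl
  ), class = "sanmf")
}

#' @method print sanmf
#' @export
print.sanmf <- function(x, ...) {
  cat("Subgraph-augmented NMF phenotyping\n")
  cat(sprintf("  %d patients x %d subgraphs, k = %d\n",
              nrow(x$W), ncol(x$H), x$k))
  cat(sprintf("  cophenetic correlation: %.3f (%d consensus runs)\n",
              x$cophenetic_rho, x$n_runs))
  tb <- table(factor(x$assignment, levels = seq_len(x$k)))
  cat("  phenotype sizes:", paste(tb, collapse = " / "))
  nu <- attr(x$assignment, "n_unassigned")
  if (!is.null(nu) && nu > 0) cat("  (", nu, "unassigned )")
  cat("\n")
  invisible(x)
}

#' @method summary sanmf
#' @export
summary.sanmf <- function(object, top_n = 5, ...) {
  tb <- table(factor(object$assignment, levels = seq_len(object$k)))
  top <- lapply(seq_len(object$k), function(i) {
    ord <- order(object$H[i, ], decreasing = TRUE)[seq_len(min(top_n, ncol(object$H)))]
    data.frame(component = i, subgraph = colnames(object$H)[ord],
               coefficient = object$H[i, ord], row.names = NULL)
  })
  out <- list(k = object$k, sizes = as.integer(tb),
              cophenetic_rho = object$cophenetic_rho,
              objective = object$objective,
              distinctiveness = if (object$k >= 2) distinctiveness(object$H) else NA_real_,
              top_subgraphs = do.call(rbind, top))
  class(out) <- "summary.sanmf"
  out
}

#' @method print summary.sanmf
#' @export
print.summary.sanmf <- function(x, ...) {
  cat("sanmf fit: k =", x$k, "\n")
  cat("phenotype sizes:", paste(x$sizes, collapse = " / "), "\n")
  cat(sprintf("cophenetic rho %.3f | distinctiveness %.3f | objective %.4g\n",
              x$cophenetic_rho, x$distinctiveness, x$objective))
  cat("top subgraphs per component:\n")
  print(x$top_subgraphs, digits = 3)
  invisible(x)
}

#' @method coef sanmf
#' @export
coef.sanmf <- function(object, which = c("H", "W"), ...) {
  which <- match.arg(which)
  object[[which]]
}

#' @method fitted sanmf
#' @export
fitted.sanmf <- function(object, ...) object$W %*% object$H

#' @method residuals sanmf
#' @export
residuals.sanmf <- function(object, X, ...) {
  if (inherits(X, "Matrix")) X <- as.matrix(X)
  X - fitted(object)
}

#' Project new patients onto a fitted phenotyping model
#'
#' Holds `H` fixed and estimates nonnegative coefficients for the new
#' rows by multiplicative updates, then assigns memberships by row
#' argmax. Columns of `newdata` are aligned to the model's subgraph
#' vocabulary by name; unseen subgraphs are ignored and missing ones
#' treated as zero counts.
#'
#' @param object a `sanmf` fit.
#' @param newdata new patient x subgraph matrix with column names.
#' @param max_iter,seed optimizer controls.
#' @param ... unused.
#' @return list with `W` (new coefficients) and `assignment`.
#' @export
predict.sanmf <- function(object, newdata, max_iter = 200, seed = 1L, ...) {
  if (is.list(newdata) && !is.null(newdata$counts)) newdata <- newdata$counts
  if (inherits(newdata, "Matrix")) newdata <- as.matrix(newdata)
  vocab <- colnames(object$H)
  Xn <- matrix(0, nrow(newdata), length(vocab),
               dimnames = list(rownames(newdata), vocab))
  shared <- intersect(colnames(newdata), vocab)
  Xn[, shared] <- newdata[, shared]
  H <- object$H
  eps <- 1e-10
  set.seed(seed)
  W <- matrix(stats::runif(nrow(Xn) * object$k, eps, 1), nrow(Xn), object$k)
  for (i in seq_len(max_iter)) {
    W <- W * (Xn %*% t(H)) / (W %*% tcrossprod(H) + eps)
  }
  rownames(W) <- rownames(Xn)
  list(W = W, assignment = assign_membership(W))
}

#' Plot a fitted phenotyping model
#'
#' Two base-graphics panels: the objective trace of the final fit and an
#' image of the consensus matrix with patients ordered by phenotype.
#'
#' @param x a `sanmf` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.sanmf <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$trace, type = "l", xlab = "iteration",
                 ylab = "0.5 ||X - WH||_F^2", main = "NMF objective")
  ord <- order(x$assignment)
  graphics::image(x$consensus[ord, ord], axes = FALSE,
                  main = sprintf("consensus (rho = %.3f)", x$cophenetic_rho),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Write model artifacts as plain text
#'
#' W and H as CSV, the configuration and summary scalars as JSON.
#'
#' @param object a `sanmf` fit.
#' @param dir output directory.
#' @export
write_sanmf <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(patient_id = rownames(object$W), object$W,
                              assignment = object$assignment,
                              check.names = FALSE),
                   file.path(dir, "W.csv"), row.names = FALSE)
  utils::write.csv(data.frame(subgraph = colnames(object$H), t(object$H),
                              check.names = FALSE),
                   file.path(dir, "H.csv"), row.names = FALSE)
  jsonlite::write_json(list(k = object$k, n_runs = object$n_runs,
                            seed = object$seed,
                            cophenetic_rho = object$cophenetic_rho,
                            objective = object$objective),
                       file.path(dir, "model.json"), auto_unbox = TRUE)
  invisible(dir)
}
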