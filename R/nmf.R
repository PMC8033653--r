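# Nonnegative matrix factorization with the Frobenius objective, consensus
# clustering across seeded restarts, cophenetic-correlation stability, a
# distinctiveness score over top-coefficient subgraph sets, and grid-based
# hyperparameter selection. The factorization uses multiplicative updates,
# whose Frobenius objective is non-increasing at every step.

#' NMF configuration
#'
#' @param k number of components (>= 2 for phenotyping use; k = 1 allowed
#'   for factorization alone).
#' @param max_iter iteration cap.
#' @param tol relative objective-decrease tolerance for early stopping.
#' @param n_consensus_runs restarts used for the consensus matrix.
#' @param seed integer seed for the random initialization.
#' @return list of class `nmf_config`.
#' @export
nmf_config <- function(k = 3, max_iter = 200, tol = 1e-5,
                       n_consensus_runs = 30, seed = 1L) {
  stopifnot(k >= 1, max_iter >= 1, tol > 0, n_consensus_runs >= 1)
  structure(list(k = as.integer(k), max_iter = as.integer(max_iter),
                 tol = tol, n_consensus_runs = as.integer(n_consensus_runs),
                 seed = as.integer(seed)), class = "nmf_config")
}

#' Fit a nonnegative matrix factorization
#'
#' Factorizes `X ~ W %*% H` with `W, H >= 0` by multiplicative updates on
#' the Frobenius objective `0.5 * ||X - WH||_F^2`. The objective is
#' recorded after every iteration and is non-increasing; iteration stops
#' when the relative decrease falls below `tol` or at `max_iter`.
#'
#' @param X nonnegative numeric matrix (dense or `Matrix` sparse; no
#'   all-zero matrix).
#' @param k rank.
#' @param max_iter,tol,seed see [nmf_config()].
#' @return list with `W` (n x k), `H` (k x m), `objective` (final value)
#'   and `trace` (per-iteration objective).
#' @export
#' @examples
#' X <- outer(c(1, 2, 3), c(2, 1, 4))
#' f <- fit_nmf(X, k = 1, max_iter = 500, tol = 1e-12)
#' norm(X - f$W %*% f$H, "F") / norm(X, "F") < 1e-6
fit_nmf <- function(X, k, max_iter = 200, tol = 1e-5, seed = 1L) {
  # sparse X is kept sparse: the updates only need X through crossprod
  # and %*%, and the objective through the trace identity
  # ||X - WH||^2 = ||X||^2 - 2<W'X, H> + <W'W, HH'>
  sparse <- inherits(X, "Matrix")
  if (!sparse) X <- as.matrix(X)
  xmin <- min(X)
  if (xmin < 0) {
    neg <- which(as.matrix(X) < 0, arr.ind = TRUE)
    stop(sprintf("X must be nonnegative; first negative entry at (%d, %d)",
                 neg[1, 1], neg[1, 2]))
  }
  normX2 <- sum(X^2)
  if (normX2 == 0) stop("X must not be the all-zero matrix")
  n <- nrow(X); m <- ncol(X)
  eps <- 1e-10
  set.seed(seed)
  scale0 <- sqrt(mean(X) / k)
  W <- matrix(stats::runif(n * k, eps, 1), n, k) * scale0
  H <- matrix(stats::runif(k * m, eps, 1), k, m) * scale0
  trace <- numeric(max_iter)
  prev <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    W <- W * as.matrix(X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    WtX <- as.matrix(crossprod(W, X))
    WtW <- crossprod(W)
    H <- H * WtX / (WtW %*% H + eps)
    cur <- max(0, 0.5 * (normX2 - 2 * sum(WtX * H) + sum(WtW * tcrossprod(H))))
    trace[it] <- cur
    if (is.finite(prev) && prev - cur >= 0 &&
        (prev - cur) <= tol * max(prev, eps)) break
    prev <- cur
  }
  list(W = W, H = H, objective = trace[it], trace = trace[seq_len(it)])
}

#' Stratified train/test split by mortality
#'
#' Splits patients at `ratio` into train and test, stratified by the
#' 30-day mortality flag. Per-stratum train sizes are apportioned by
#' largest remainder so that `|train| = round(ratio * n)` exactly; the
#' mortality rates of the two halves then differ by at most one patient
#' per stratum.
#'
#' @param patient_id character vector.
#' @param mortality logical vector, both classes present.
#' @param ratio train fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `test` id vectors.
#' @export
split_cohort <- function(patient_id, mortality, ratio = 0.8, seed = 1L) {
  stopifnot(length(patient_id) == length(mortality))
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie strictly between 0 and 1")
  strata <- split(patient_id, mortality)
  if (length(strata) < 2) stop("both mortality classes must be present")
  if (any(lengths(strata) < 2)) stop("each mortality stratum needs at least 2 patients")
  n <- length(patient_id)
  n_train <- round(ratio * n)
  target <- ratio * lengths(strata)
  base <- floor(target)
  rem <- n_train - sum(base)
  if (rem > 0) {
    ord <- order(target - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  } else if (rem < 0) {
    ord <- order(target - base)
    base[ord[seq_len(-rem)]] <- base[ord[seq_len(-rem)]] - 1
  }
  set.seed(seed)
  train <- unlist(lapply(seq_along(strata), function(s) {
    ids <- strata[[s]]
    sample(ids, base[s])
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(patient_id, train)))
}

#' Assign phenotype membership from W
#'
#' Each patient is labelled with the component holding their largest
#' patient-group coefficient; ties break toward the lowest component
#' index. All-zero rows are reported as unassigned (`NA`) with their count
#' in the `"n_unassigned"` attribute.
#'
#' @param W patient-by-component coefficient matrix.
#' @return integer labels (named by rownames of `W` when present) with
#'   attribute `n_unassigned`.
#' @export
assign_membership <- function(W) {
  lab <- apply(W, 1, which.max)          # which.max breaks ties low
  zero <- rowSums(W) == 0
  lab[zero] <- NA_integer_
  lab <- as.integer(lab)
  names(lab) <- rownames(W)
  attr(lab, "n_unassigned") <- sum(zero)
  lab
}

#' Consensus matrix and cophenetic correlation
#'
#' Runs [fit_nmf()] `n_runs` times with distinct seeded initializations;
#' each run's connectivity matrix marks pairs of patients sharing the same
#' W row-argmax, and the consensus is their mean. The cophenetic
#' correlation is the Pearson correlation between the consensus
#' dissimilarities `1 - consensus` and the cophenetic distances of their
#' average-linkage hierarchical clustering; a perfectly stable (zero
#' variance) consensus is reported as 1.
#'
#' @param X nonnegative matrix.
#' @param k rank.
#' @param n_runs number of restarts (>= 2).
#' @param seed base seed; run r uses `seed + r`.
#' @param max_iter,tol passed to [fit_nmf()].
#' @return list with `consensus` (n x n), `cophenetic_rho`.
#' @export
consensus_cophenetic <- function(X, k, n_runs = 30, seed = 1L,
                                 max_iter = 200, tol = 1e-5) {
  stopifnot(n_runs >= 2)
  n <- nrow(X)
  consensus <- matrix(0, n, n)
  best <- NULL
  for (r in seq_len(n_runs)) {
    fit <- fit_nmf(X, k, max_iter = max_iter, tol = tol, seed = seed + r)
    lab <- apply(fit$W, 1, which.max)
    conn <- outer(lab, lab, "==") * 1
    consensus <- consensus + conn
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  consensus <- consensus / n_runs
  diag(consensus) <- 1
  d <- stats::as.dist(1 - consensus)
  rho <- if (stats::sd(d) == 0) {
    1
  } else {
    coph <- stats::cophenetic(stats::hclust(d, method = "average"))
    suppressWarnings(stats::cor(d, coph))
  }
  if (is.na(rho)) rho <- 1  # degenerate tree distances
  list(consensus = consensus, cophenetic_rho = rho, best_fit = best)
}

#' Distinctiveness of component subgraph distributions
#'
#' One minus the mean pairwise Jaccard overlap of the components' top-n
#' subgraph sets (by H coefficient); 1 means fully distinct top sets.
#' When H has fewer than `top_n` columns all columns are used.
#'
#' @param H component-by-subgraph coefficient matrix, `k >= 2` rows.
#' @param top_n set size per component.
#' @return real in `[0, 1]`.
#' @export
distinctiveness <- function(H, top_n = 100) {
  k <- nrow(H)
  stopifnot(k >= 2)
  n_use <- min(top_n, ncol(H))
  sets <- lapply(seq_len(k), function(i) order(H[i, ], decreasing = TRUE)[seq_len(n_use)])
  pairs <- utils::combn(k, 2)
  jac <- apply(pairs, 2, function(p) {
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    length(intersect(a, b)) / length(union(a, b))
  })
  1 - mean(jac)
}

#' Select mining/factorization hyperparameters on the training split
#'
#' Evaluates every grid cell (time interval x minimum support x k) on the
#' training matrix: the count matrix is re-mined per (interval, support),
#' then each k is scored by consensus cophenetic correlation (primary) with
#' distinctiveness as the tie-breaker. Cells yielding an empty subgraph
#' vocabulary score `-Inf`.
#'
#' @param matrix_builder function `(interval, support) ->` count-matrix
#'   structure (as from [assemble_matrix()]) for the training patients.
#' @param intervals,supports,ks grid axes.
#' @param n_runs,seed,max_iter,tol consensus parameters.
#' @param top_n distinctiveness set size.
#' @return list with `best` (interval, support, k) and `scores`
#'   (data.frame of the full grid).
#' @export
select_hyperparameters <- function(matrix_builder, intervals = c(6, 24),
                                   supports = c(5, 15, 25, 50, 100),
                                   ks = 2:6, n_runs = 30, seed = 1L,
                                   max_iter = 200, tol = 1e-5, top_n = 100) {
  stopifnot(length(intervals) > 0, length(supports) > 0, length(ks) > 0)
  rows <- list()
  for (iv in intervals) {
    for (sp in supports) {
      mat <- matrix_builder(iv, sp)
      for (k in ks) {
        if (is.null(mat) || ncol(mat$counts) == 0) {
          message("grid cell (interval=", iv, ", support=", sp,
                  ") yielded no subgraphs; scored -Inf")
          rows[[length(rows) + 1]] <- data.frame(
            interval = iv, support = sp, k = k,
            cophenetic_rho = -Inf, distinctiveness = NA_real_)
          next
        }
        cc <- consensus_cophenetic(mat$counts, k, n_runs = n_runs,
                                   seed = seed, max_iter = max_iter, tol = tol)
        rows[[length(rows) + 1]] <- data.frame(
          interval = iv, support = sp, k = k,
          cophenetic_rho = cc$cophenetic_rho,
          distinctiveness = distinctiveness(cc$best_fit$H, top_n = top_n))
      }
    }
  }
  scores <- do.call(rbind, rows)
  ord <- order(-scores$cophenetic_rho, -scores$distinctiveness,
               scores$interval, scores$support, scores$k)
  best <- scores[ord[1], c("interval", "support", "k")]
  list(best = as.list(best), scores = scores)
}

#' Refit the selected configuration on the held-out split
#'
#' Compares consensus stability between splits and rank-correlates the H
#' weights of subgraphs shared by both vocabularies (components matched
#' greedily by that correlation).
#'
#' @param fit_train a fitted `sanmf` object (training split).
#' @param X_test test count matrix (columns named by subgraph id).
#' @param n_runs,seed,max_iter,tol consensus parameters for the test refit.
#' @return list with `rho_train`, `rho_test`, `rho_diff`,
#'   `h_rank_correlation` (NA with a flag when no subgraphs are shared),
#'   `n_shared`.
#' @export
refit_validation <- function(fit_train, X_test, n_runs = 30, seed = 1L,
                             max_iter = 200, tol = 1e-5) {
  k <- fit_train$k
  cc <- consensus_cophenetic(X_test, k, n_runs = n_runs, seed = seed,
                             max_iter = max_iter, tol = tol)
  ft <- cc$best_fit
  shared <- intersect(colnames(fit_train$H), colnames(X_test))
  if (length(shared) < 2) {
    warning("no (or <2) shared subgraphs between splits; H rank correlation undefined")
    hcor <- NA_real_
  } else {
    Ht <- fit_train$H[, shared, drop = FALSE]
    He <- ft$H[, match(shared, colnames(X_test)), drop = FALSE]
    # greedy component matching by Spearman correlation
    cmat <- matrix(NA_real_, k, k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      cmat[i, j] <- suppressWarnings(stats::cor(Ht[i, ], He[j, ], method = "spearman"))
    }
    cmat[is.na(cmat)] <- -Inf
    picked <- numeric(0)
    used <- rep(FALSE, k)
    for (i in seq_len(k)) {
      j <- which.max(ifelse(used, -Inf, cmat[i, ]))
      used[j] <- TRUE
      picked <- c(picked, cmat[i, j])
    }
    hcor <- mean(picked[is.finite(picked)])
  }
  list(rho_train = fit_train$cophenetic_rho, rho_test = cc$cophenetic_rho,
       rho_diff = fit_train$cophenetic_rho - cc$cophenetic_rho,
       h_rank_correlation = hcor, n_shared = length(shared))
}
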