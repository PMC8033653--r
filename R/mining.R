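# Frequent subgraph mining on chain graphs. Because each time series graph
# is a linear chain of levels, subgraph mining reduces to contiguous
# subsequence mining: patterns are runs of 2-6 consecutive levels. Mining
# proceeds length by length with the anti-monotone prune (a pattern can be
# frequent only if its length-(l-1) prefix and suffix are), support counts
# distinct chains (one chain per patient per variable, so chain support
# equals patient support) and per-patient feature values count occurrences,
# overlapping occurrences included.

pattern_id <- function(variable, levels) {
  paste0(variable, ":", paste(levels, collapse = ","))
}

parse_pattern_id <- function(id) {
  sp <- strsplit(id, ":", fixed = TRUE)[[1]]
  list(variable = sp[1],
       levels = as.integer(strsplit(sp[2], ",", fixed = TRUE)[[1]]))
}

#' Count occurrences of a pattern in a chain
#'
#' Number of start positions where the pattern matches the chain exactly;
#' overlapping occurrences all count. Direction matters (no reversal).
#'
#' @param chain integer vector of levels.
#' @param pattern integer vector, length at least 1.
#' @return nonnegative integer count.
#' @export
#' @examples
#' enumerate_occurrences(c(1, 1, 1), c(1, 1))  # 2
enumerate_occurrences <- function(chain, pattern) {
  lp <- length(pattern)
  stopifnot(lp >= 1)
  lc <- length(chain)
  if (lp > lc) return(0L)
  n <- 0L
  for (s in seq_len(lc - lp + 1)) {
    if (all(chain[s:(s + lp - 1)] == pattern)) n <- n + 1L
  }
  n
}

# string keys for all length-l windows of every chain (rows of `chains`);
# returns data.frame(chain = row index, key = "l1,l2,...") with one row per
# window position
.window_keys <- function(chains, l) {
  nw <- ncol(chains)
  if (l > nw || nrow(chains) == 0) {
    return(data.frame(chain = integer(0), key = character(0)))
  }
  starts <- seq_len(nw - l + 1)
  keys <- character(0)
  chain_ix <- integer(0)
  for (s in starts) {
    block <- chains[, s:(s + l - 1), drop = FALSE]
    k <- do.call(paste, c(as.data.frame(block), sep = ","))
    keys <- c(keys, k)
    chain_ix <- c(chain_ix, seq_len(nrow(chains)))
  }
  data.frame(chain = chain_ix, key = keys, stringsAsFactors = FALSE)
}

#' Mine frequent contiguous patterns from one variable's corpus
#'
#' Returns exactly the patterns of length `min_size`..`max_size` contained
#' in at least `min_support` distinct chains, with document-frequency
#' supports and per-chain occurrence counts.
#'
#' @param corpus list with `patients` (character) and `chains` (integer
#'   matrix, one chain per row), as built by [build_corpora()].
#' @param variable variable name used in canonical pattern ids.
#' @param min_support minimum number of distinct chains containing a
#'   pattern.
#' @param min_size,max_size pattern length bounds (nodes).
#' @return list with `patterns` (data.frame `id`, `variable`, `levels`
#'   (comma string), `size`, `support`) and `counts` (data.frame
#'   `patient_id`, `id`, `count` of occurrences).
#' @export
mine_corpus <- function(corpus, variable = "var", min_support = 5,
                        min_size = 2, max_size = 6) {
  stopifnot(min_support >= 1, min_size >= 1, min_size <= max_size)
  chains <- corpus$chains
  empty <- list(
    patterns = data.frame(id = character(0), variable = character(0),
                          levels = character(0), size = integer(0),
                          support = integer(0), stringsAsFactors = FALSE),
    counts = data.frame(patient_id = character(0), id = character(0),
                        count = integer(0), stringsAsFactors = FALSE)
  )
  if (nrow(chains) == 0) return(empty)
  pat_rows <- list()
  cnt_rows <- list()
  prev_frequent <- NULL  # frequent keys of length l-1, for the prune
  for (l in seq_len(max_size)) {
    if (l > ncol(chains)) break
    wk <- .window_keys(chains, l)
    if (l > 1 && !is.null(prev_frequent)) {
      # anti-monotone prune: both the (l-1)-prefix and (l-1)-suffix of a
      # frequent pattern must themselves be frequent
      pre <- sub(",[^,]*$", "", wk$key)
      suf <- sub("^[^,]*,", "", wk$key)
      ok_key <- unique(wk$key[pre %in% prev_frequent & suf %in% prev_frequent])
      wk <- wk[wk$key %in% ok_key, , drop = FALSE]
    }
    if (nrow(wk) == 0) { prev_frequent <- character(0); next }
    support <- tapply(wk$chain, wk$key, function(ix) length(unique(ix)))
    freq <- names(support)[support >= min_support]
    prev_frequent <- freq
    if (l < min_size || length(freq) == 0) next
    sup <- as.integer(support[freq])
    pat_rows[[length(pat_rows) + 1]] <- data.frame(
      id = paste0(variable, ":", freq), variable = variable, levels = freq,
      size = l, support = sup, stringsAsFactors = FALSE
    )
    wf <- wk[wk$key %in% freq, , drop = FALSE]
    agg <- stats::aggregate(list(count = rep(1L, nrow(wf))),
                            by = list(chain = wf$chain, key = wf$key), FUN = sum)
    cnt_rows[[length(cnt_rows) + 1]] <- data.frame(
      patient_id = corpus$patients[agg$chain],
      id = paste0(variable, ":", agg$key),
      count = as.integer(agg$count), stringsAsFactors = FALSE
    )
  }
  if (length(pat_rows) == 0) return(empty)
  list(patterns = do.call(rbind, pat_rows),
       counts = do.call(rbind, cnt_rows))
}

# TRUE iff `a` occurs as a contiguous run inside `b` (strictly shorter)
.is_subpattern <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (la >= lb) return(FALSE)
  for (s in seq_len(lb - la + 1)) {
    if (all(b[s:(s + la - 1)] == a)) return(TRUE)
  }
  FALSE
}

#' Patient-level subsumption removal
#'
#' For each patient independently, zero the count of every pattern that is
#' a contiguous sub-pattern (same variable) of some larger pattern also
#' present for that patient. Maximality is judged against the original
#' presence set, not the progressively zeroed one; the operation is
#' idempotent. Columns whose total count drops to zero across all patients
#' are removed, and the number dropped is recorded in the `"n_dropped"`
#' attribute.
#'
#' @param mat a subgraph count matrix as returned by [assemble_matrix()]
#'   (list with sparse `counts`, `subgraphs`, `patients`).
#' @return The same structure with subsumed counts zeroed and empty
#'   columns dropped.
#' @export
remove_subsumed <- function(mat) {
  counts <- mat$counts
  info <- mat$subgraphs
  lev <- lapply(strsplit(info$levels, ",", fixed = TRUE), as.integer)
  sizes <- lengths(lev)
  tm <- methods::as(counts, "TsparseMatrix")
  nz_by_patient <- split(tm@j + 1L, tm@i + 1L)  # column indices per row
  zeros <- vector("list", length(nz_by_patient))
  zi <- 0L
  for (pi_chr in names(nz_by_patient)) {
    pi <- as.integer(pi_chr)
    cols <- nz_by_patient[[pi_chr]]
    if (length(cols) < 2) next
    byvar <- split(cols, info$variable[cols])
    dead <- integer(0)
    for (vc in byvar) {
      if (length(vc) < 2) next
      for (a in vc) {
        larger <- vc[sizes[vc] > sizes[a]]
        for (b in larger) {
          if (.is_subpattern(lev[[a]], lev[[b]])) {
            dead[length(dead) + 1L] <- a
            break
          }
        }
      }
    }
    if (length(dead) > 0) {
      zi <- zi + 1L
      zeros[[zi]] <- cbind(pi, dead)
    }
  }
  if (zi > 0) {
    zz <- do.call(rbind, zeros[seq_len(zi)])
    counts[zz] <- 0
  }
  counts <- Matrix::drop0(counts)
  col_tot <- Matrix::colSums(counts)
  drop <- col_tot == 0
  out <- list(counts = counts[, !drop, drop = FALSE],
              subgraphs = info[!drop, , drop = FALSE],
              patients = mat$patients)
  rownames(out$subgraphs) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Assemble the patient-by-subgraph count matrix
#'
#' Mines every variable's corpus, column-concatenates the per-variable
#' results over a common patient universe (patients absent from every
#' corpus keep an all-zero row), and applies patient-level subsumption
#' removal. Bookkeeping (`n_mined`, `n_dropped`, `n_retained`) is attached
#' as attributes; mined − dropped = retained.
#'
#' @param corpora named list of corpora from [build_corpora()].
#' @param patients the full patient universe (row order of the matrix).
#' @param min_support,min_size,max_size mining parameters.
#' @return list with `counts` (sparse patients x subgraphs matrix),
#'   `subgraphs` (metadata data.frame incl. `support`), `patients`;
#'   attributes `n_mined`, `n_dropped`, `n_retained`.
#' @export
assemble_matrix <- function(corpora, patients, min_support = 5,
                            min_size = 2, max_size = 6) {
  all_pat <- list(); all_cnt <- list()
  for (v in names(corpora)) {
    res <- mine_corpus(corpora[[v]], variable = v, min_support = min_support,
                       min_size = min_size, max_size = max_size)
    if (nrow(res$patterns) > 0) {
      all_pat[[v]] <- res$patterns
      all_cnt[[v]] <- res$counts
    }
  }
  info <- if (length(all_pat)) do.call(rbind, all_pat) else
    data.frame(id = character(0), variable = character(0),
               levels = character(0), size = integer(0),
               support = integer(0), stringsAsFactors = FALSE)
  rownames(info) <- NULL
  if (anyDuplicated(info$id)) stop("internal error: duplicate canonical subgraph ids")
  cnt <- if (length(all_cnt)) do.call(rbind, all_cnt) else
    data.frame(patient_id = character(0), id = character(0), count = integer(0))
  ri <- match(cnt$patient_id, patients)
  if (anyNA(ri)) stop("count rows reference patients outside the universe")
  ci <- match(cnt$id, info$id)
  counts <- Matrix::sparseMatrix(i = ri, j = ci, x = cnt$count,
                                 dims = c(length(patients), nrow(info)),
                                 dimnames = list(patients, info$id))
  mat <- list(counts = counts, subgraphs = info, patients = patients)
  n_mined <- nrow(info)
  out <- remove_subsumed(mat)
  attr(out, "n_mined") <- n_mined
  attr(out, "n_retained") <- nrow(out$subgraphs)
  out
}

#' Write a subgraph count matrix as MatrixMarket + sidecar CSVs
#'
#' @param mat matrix structure from [assemble_matrix()].
#' @param dir output directory.
#' @export
write_count_matrix <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(mat$counts, file.path(dir, "counts.mtx"))
  utils::write.csv(data.frame(patient_id = mat$patients),
                   file.path(dir, "rows.csv"), row.names = FALSE)
  utils::write.csv(mat$subgraphs, file.path(dir, "columns.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "counts.mtx")), "CsparseMatrix")
  patients <- utils::read.csv(file.path(dir, "rows.csv"),
                              stringsAsFactors = FALSE)$patient_id
  subgraphs <- utils::read.csv(file.path(dir, "columns.csv"),
                               stringsAsFactors = FALSE)
  dimnames(counts) <- list(patients, subgraphs$id)
  list(counts = counts, subgraphs = subgraphs, patients = patients)
}
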