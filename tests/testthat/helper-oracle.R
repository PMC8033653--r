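# Independent brute-force oracle for contiguous-pattern mining, used to
# cross-check mine_corpus. Deliberately takes a different route: per-chain
# exhaustive substring enumeration with its own matcher, no pruning, no
# shared helpers from the package.

oracle_count_occurrences <- function(chain, pattern) {
  lp <- length(pattern); lc <- length(chain)
  if (lp > lc) return(0L)
  hits <- 0L
  for (s in 1:(lc - lp + 1)) {
    match <- TRUE
    for (j in 1:lp) {
      if (chain[s + j - 1] != pattern[j]) { match <- FALSE; break }
    }
    if (match) hits <- hits + 1L
  }
  hits
}

oracle_mine <- function(corpus, min_support, min_size = 2, max_size = 6) {
  chains <- corpus$chains
  n <- nrow(chains)
  # candidate vocabulary: every contiguous subsequence of every chain
  cand <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    len <- ncol(chains)
    for (l in min_size:min(max_size, len)) {
      for (s in 1:(len - l + 1)) {
        key <- paste(chains[i, s:(s + l - 1)], collapse = ",")
        if (is.null(cand[[key]])) cand[[key]] <- chains[i, s:(s + l - 1)]
      }
    }
  }
  pat <- ls(cand)
  support <- integer(length(pat))
  counts <- list()
  for (pi in seq_along(pat)) {
    pv <- cand[[pat[pi]]]
    occ <- vapply(seq_len(n), function(i) oracle_count_occurrences(chains[i, ], pv),
                  integer(1))
    support[pi] <- sum(occ > 0)
    counts[[pi]] <- occ
  }
  keep <- support >= min_support
  cnt <- do.call(rbind, lapply(which(keep), function(pi) {
    occ <- counts[[pi]]
    nz <- which(occ > 0)
    data.frame(patient_id = corpus$patients[nz], levels = pat[pi],
               count = occ[nz], stringsAsFactors = FALSE)
  }))
  if (is.null(cnt)) {
    cnt <- data.frame(patient_id = character(0), levels = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  }
  list(
    patterns = data.frame(levels = pat[keep], support = support[keep],
                          stringsAsFactors = FALSE),
    counts = cnt
  )
}

random_corpus <- function(n_chains, len = 12, lev = -2:2, seed = 1) {
  set.seed(seed)
  list(patients = sprintf("P%03d", seq_len(n_chains)),
       chains = matrix(sample(lev, n_chains * len, replace = TRUE),
                       n_chains, len))
}

# canonicalized comparison frames for implementation-vs-oracle equality
mined_as_frame <- function(res) {
  p <- res$patterns[order(res$patterns$levels), c("levels", "support")]
  rownames(p) <- NULL
  cn <- res$counts
  cn$levels <- sub("^[^:]*:", "", cn$id %||% cn$levels)
  cn <- cn[order(cn$patient_id, cn$levels), c("patient_id", "levels", "count")]
  rownames(cn) <- NULL
  list(patterns = p, counts = cn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
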