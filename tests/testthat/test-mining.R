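test_that("occurrence counting slides with overlap and respects direction", {
  expect_equal(enumerate_occurrences(c(1, 1, 1), c(1, 1)), 2L)
  expect_equal(enumerate_occurrences(c(0, 1, 2), c(2, 1)), 0L)
  expect_equal(enumerate_occurrences(c(0, 1, 2), c(0, 1, 2)), 1L)
  expect_equal(enumerate_occurrences(c(1, 2), c(1, 2, 3)), 0L)
})

test_that("mine_corpus returns exactly the frequent contiguous patterns", {
  corp <- list(patients = c("a", "b", "c"),
               chains = rbind(c(1, 1, 2), c(1, 1, 3), c(1, 1, 2)))
  res <- mine_corpus(corp, variable = "hr", min_support = 2)
  got <- setNames(res$patterns$support, res$patterns$levels)
  expect_equal(got[order(names(got))],
               c("1,1" = 3L, "1,1,2" = 2L, "1,2" = 2L))
  # per-patient occurrence counts
  cn <- res$counts
  expect_equal(cn$count[cn$patient_id == "a" & cn$id == "hr:1,1"], 1L)
  expect_false("hr:1,3" %in% res$patterns$id)     # support 1 pruned
  expect_false("hr:1" %in% res$patterns$id)       # singletons below min_size
  # raising support empties the result
  expect_equal(nrow(mine_corpus(corp, min_support = 4)$patterns), 0)
  empty <- mine_corpus(list(patients = character(0),
                            chains = matrix(integer(0), 0, 12)),
                       min_support = 1)
  expect_equal(nrow(empty$patterns), 0)
})

test_that("mining matches the brute-force oracle on random corpora", {
  for (i in 1:20) {
    corp <- random_corpus(n_chains = sample(3:25, 1), seed = 1000 + i)
    ms <- sample(c(1, 2, 3, 5), 1)
    impl <- mined_as_frame(mine_corpus(corp, variable = "v", min_support = ms))
    orac <- mined_as_frame(oracle_mine(corp, min_support = ms))
    expect_identical(impl$patterns, orac$patterns)
    expect_identical(impl$counts, orac$counts)
  }
})

test_that("support is anti-monotone in pattern extension", {
  corp <- random_corpus(30, seed = 99)
  res <- mine_corpus(corp, variable = "v", min_support = 1)
  sup <- setNames(res$patterns$support, res$patterns$levels)
  for (lvs in names(sup)) {
    parts <- as.integer(strsplit(lvs, ",")[[1]])
    if (length(parts) <= 2) next
    pre <- paste(parts[-length(parts)], collapse = ",")
    suf <- paste(parts[-1], collapse = ",")
    expect_lte(sup[[lvs]], sup[[pre]])
    expect_lte(sup[[lvs]], sup[[suf]])
  }
})

make_mat <- function(counts_df, patients) {
  # small helper: build the matrix structure from a tidy (patient, id, count)
  ids <- unique(counts_df$id)
  info <- data.frame(
    id = ids, variable = sub(":.*", "", ids),
    levels = sub("^[^:]*:", "", ids),
    size = lengths(strsplit(sub("^[^:]*:", "", ids), ",")),
    support = as.integer(table(counts_df$id)[ids]), stringsAsFactors = FALSE)
  m <- Matrix::sparseMatrix(
    i = match(counts_df$patient_id, patients),
    j = match(counts_df$id, ids),
    x = counts_df$count, dims = c(length(patients), length(ids)),
    dimnames = list(patients, ids))
  list(counts = m, subgraphs = info, patients = patients)
}

test_that("subsumption zeroes contained patterns per patient, per variable", {
  df <- data.frame(patient_id = c("A", "A", "B", "B"),
                   id = c("hr:1,1", "hr:1,1,2", "hr:1,1", "rr:1,1,2"),
                   count = c(2, 1, 2, 1), stringsAsFactors = FALSE)
  out <- remove_subsumed(make_mat(df, c("A", "B")))
  # A's (1,1) is inside A's (1,1,2) -> zeroed; B's (1,1) survives because
  # the larger pattern lives in another variable
  expect_equal(unname(out$counts["A", "hr:1,1"]), 0)
  expect_equal(unname(out$counts["A", "hr:1,1,2"]), 1)
  expect_equal(unname(out$counts["B", "hr:1,1"]), 2)
  expect_equal(unname(out$counts["B", "rr:1,1,2"]), 1)
  expect_equal(attr(out, "n_dropped"), 0)  # hr:1,1 kept: B still counts it
})

test_that("subsumption judges against the original presence set and is idempotent", {
  # chain (1,1,1,2): patterns (1,1) in (1,1,1) in (1,1,1,2); all zeroed
  # except the largest even though (1,1,1) is itself zeroed
  df <- data.frame(patient_id = "A",
                   id = c("hr:1,1", "hr:1,1,1", "hr:1,1,1,2"),
                   count = c(2, 1, 1), stringsAsFactors = FALSE)
  out <- remove_subsumed(make_mat(df, "A"))
  expect_equal(colnames(out$counts), "hr:1,1,1,2")
  expect_equal(attr(out, "n_dropped"), 2)
  again <- remove_subsumed(out)
  expect_equal(as.matrix(again$counts), as.matrix(out$counts))
  expect_equal(attr(again, "n_dropped"), 0)
})

test_that("assembly concatenates variables, keeps empty patients, balances books", {
  corp <- list(
    hr = list(patients = c("A", "B"), chains = rbind(c(1L, 1L, 2L, 0L),
                                                     c(1L, 1L, 2L, 0L))),
    rr = list(patients = "A", chains = rbind(c(0L, 0L, 3L, 3L))))
  mat <- assemble_matrix(corp, patients = c("A", "B", "C"), min_support = 1,
                         min_size = 2, max_size = 3)
  expect_equal(nrow(mat$counts), 3)
  expect_equal(sum(mat$counts["C", ]), 0)     # patient kept as all-zero row
  expect_true(all(c("hr", "rr") %in% mat$subgraphs$variable))
  expect_equal(attr(mat, "n_mined") - attr(mat, "n_dropped"),
               attr(mat, "n_retained"))
})

test_that("after removal no patient holds a pattern nested in another (property)", {
  for (i in 1:10) {
    corp <- random_corpus(12, seed = 2000 + i)
    mat <- assemble_matrix(list(v = corp), patients = corp$patients,
                           min_support = 2)
    lev <- lapply(strsplit(mat$subgraphs$levels, ","), as.integer)
    cm <- as.matrix(mat$counts)
    for (p in seq_len(nrow(cm))) {
      nz <- which(cm[p, ] > 0)
      if (length(nz) < 2) next
      for (a in nz) for (b in nz) {
        if (length(lev[[a]]) >= length(lev[[b]])) next
        contained <- any(vapply(
          seq_len(length(lev[[b]]) - length(lev[[a]]) + 1),
          function(s) all(lev[[b]][s:(s + length(lev[[a]]) - 1)] == lev[[a]]),
          logical(1)))
        expect_false(contained)
      }
    }
  }
})

test_that("raising min_support never adds patterns", {
  corp <- random_corpus(25, seed = 5)
  prev <- mine_corpus(corp, variable = "v", min_support = 1)$patterns$id
  for (ms in c(2, 3, 5, 8)) {
    cur <- mine_corpus(corp, variable = "v", min_support = ms)$patterns$id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("count matrices round-trip through MatrixMarket + CSV", {
  corp <- random_corpus(8, seed = 77)
  mat <- assemble_matrix(list(v = corp), patients = corp$patients,
                         min_support = 2)
  dir <- withr::local_tempdir()
  write_count_matrix(mat, dir)
  back <- read_count_matrix(dir)
  expect_equal(as.matrix(back$counts), as.matrix(mat$counts))
  expect_equal(back$subgraphs, mat$subgraphs)
})
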