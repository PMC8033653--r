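# Representative trend selection: each phenotype's trend group is
# summarized by the subgraphs ranked in its top-n H coefficients or with a
# coefficient strictly above a threshold, plus exclusivity bookkeeping and
# step-plot rendering of the selected level patterns.

#' Select representative subgraphs per trend group
#'
#' Per component, the union of (a) the `top_n` subgraphs by H coefficient
#' — coefficient ties at the rank boundary are all included — and (b) every
#' subgraph with coefficient strictly greater than `threshold`.
#'
#' @param H component x subgraph coefficient matrix with column names, or
#'   a `sanmf` fit.
#' @param top_n rank cut per component.
#' @param threshold strict coefficient cut.
#' @return list of data.frames (one per component) with columns `subgraph`,
#'   `coefficient`, sorted by coefficient descending.
#' @export
select_representatives <- function(H, top_n = 100, threshold = 1.0) {
  if (inherits(H, "sanmf")) H <- H$H
  if (is.null(colnames(H))) colnames(H) <- paste0("s", seq_len(ncol(H)))
  lapply(seq_len(nrow(H)), function(i) {
    co <- H[i, ]
    ord <- order(co, decreasing = TRUE)
    n_use <- min(top_n, length(co))
    cut <- co[ord[n_use]]
    sel <- co > threshold | co >= cut   # >= cut pulls in boundary ties
    df <- data.frame(subgraph = colnames(H)[sel], coefficient = co[sel],
                     row.names = NULL, stringsAsFactors = FALSE)
    df[order(df$coefficient, decreasing = TRUE), , drop = FALSE]
  })
}

#' Exclusivity summary of representative sets
#'
#' @param sets list of per-component representative data.frames (from
#'   [select_representatives()]) or character vectors of subgraph ids.
#' @return list with `n_unique` (size of the union), `n_exclusive`
#'   (subgraphs appearing in exactly one component's set), `per_component`
#'   (set sizes) and `exclusive` (per-subgraph logical, named).
#' @export
#' @examples
#' exclusivity_summary(list(c("a", "b"), c("b", "c"), c("c", "d")))$n_exclusive
exclusivity_summary <- function(sets) {
  ids <- lapply(sets, function(s) if (is.data.frame(s)) s$subgraph else s)
  stopifnot(length(ids) >= 2)
  all_ids <- unlist(ids, use.names = FALSE)
  tab <- table(all_ids)
  list(n_unique = length(tab),
       n_exclusive = sum(tab == 1),
       per_component = lengths(ids),
       exclusive = stats::setNames(as.vector(tab == 1), names(tab)))
}

#' Render a trend group's representative patterns as step plots
#'
#' One panel per pattern (capped at `max_panels`): the integer level run
#' drawn as a step polyline over its window span.
#'
#' @param set data.frame with a `subgraph` column of canonical ids
#'   (`"variable:l1,l2,..."`), or a character vector of ids.
#' @param path output file (PNG).
#' @param max_panels cap on plotted patterns.
#' @return The path invisibly, or `NULL` (with a warning) for an empty set.
#' @export
render_trend_panel <- function(set, path, max_panels = 25) {
  ids <- if (is.data.frame(set)) set$subgraph else set
  if (length(ids) == 0) {
    warning("empty representative set; no figure written")
    return(invisible(NULL))
  }
  ids <- ids[seq_len(min(length(ids), max_panels))]
  pats <- lapply(ids, parse_pattern_id)
  nc <- ceiling(sqrt(length(pats)))
  nr <- ceiling(length(pats) / nc)
  grDevices::png(path, width = 220 * nc, height = 180 * nr)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(2.5, 2.5, 2, 0.5),
                      mgp = c(1.5, 0.5, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  for (p in pats) {
    lv <- p$levels
    graphics::plot(seq_along(lv), lv, type = "s", ylim = c(-4, 4),
                   xlab = "window", ylab = "level", main = p$variable,
                   cex.main = 0.9, col = "steelblue", lwd = 2)
    graphics::points(seq_along(lv), lv, pch = 16, col = "steelblue")
    graphics::abline(h = 0, lty = 3, col = "grey")
  }
  invisible(path)
}

#' Write representative sets as CSV
#'
#' @param sets list from [select_representatives()].
#' @param subgraph_info optional metadata data.frame (`id`, `variable`,
#'   `levels`, `support`).
#' @param path CSV path.
#' @export
write_representatives <- function(sets, path, subgraph_info = NULL) {
  excl <- exclusivity_summary(sets)$exclusive
  rows <- do.call(rbind, lapply(seq_along(sets), function(i) {
    df <- sets[[i]]
    data.frame(component = i, subgraph = df$subgraph,
               coefficient = df$coefficient,
               exclusive = excl[df$subgraph], row.names = NULL)
  }))
  if (!is.null(subgraph_info)) {
    m <- match(rows$subgraph, subgraph_info$id)
    rows$variable <- subgraph_info$variable[m]
    rows$levels <- subgraph_info$levels[m]
    rows$support <- subgraph_info$support[m]
  }
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
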