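# Preprocessing: irregular records -> per-patient, per-variable integer
# level sequences ("time series graphs"). Steps: cohort-window filter,
# measurable-range outlier removal, window aggregation + linear
# interpolation onto a uniform grid, cohort-wide z-scoring with rounding,
# and assembly of one corpus of level chains per variable.

#' Filter patients by suspicion-to-admission window
#'
#' Keeps exactly the patients whose suspicion-of-infection time lies within
#' a closed +/- 24 h window of ICU admission. Patients with a missing
#' timestamp are excluded with a warning, not an error.
#'
#' @param admissions data.frame with columns `patient_id`, `t_icu`,
#'   `t_suspicion` (same time units).
#' @param window half-width of the closed window, hours.
#' @return character vector of included patient ids.
#' @export
filter_cohort_window <- function(admissions, window = 24) {
  miss <- is.na(admissions$t_icu) | is.na(admissions$t_suspicion)
  if (any(miss)) {
    warning(sum(miss), " patient(s) excluded for missing admission/suspicion timestamps")
  }
  ok <- !miss & abs(admissions$t_suspicion - admissions$t_icu) <= window
  admissions$patient_id[ok]
}

#' Remove physiologically implausible records
#'
#' A record survives iff `lo <= value <= hi` for its variable's
#' measurable range. Removal counts per variable are attached as the
#' `"removed"` attribute.
#'
#' @param records data.frame with columns `patient_id`, `variable`, `t`,
#'   `value`.
#' @param ranges data.frame with columns `variable`, `lo`, `hi`; must cover
#'   every variable present in `records`.
#' @return The surviving records, with attribute `removed` (named integer
#'   vector of per-variable removal counts).
#' @export
#' @examples
#' r <- data.frame(patient_id = "P1", variable = "resp_rate",
#'                 t = 1, value = 2355555)
#' nrow(filter_outliers(r, measurable_ranges()))  # 0
filter_outliers <- function(records, ranges = measurable_ranges()) {
  if (nrow(records) == 0) {
    out <- records
    attr(out, "removed") <- integer(0)
    return(out)
  }
  idx <- match(records$variable, ranges$variable)
  if (anyNA(idx)) {
    stop("measurable range missing for variable(s): ",
         paste(unique(records$variable[is.na(idx)]), collapse = ", "))
  }
  keep <- records$value >= ranges$lo[idx] & records$value <= ranges$hi[idx]
  removed <- tapply(!keep, records$variable, sum)
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed[removed > 0]
  out
}

# core single-series interpolation used by interpolate_all(); exported for
# direct use on one patient-variable series
#' Interpolate one irregular series onto uniform windows
#'
#' Windows are half-open `[w*interval, (w+1)*interval)`, 0-based; a record
#' at exactly the horizon is discarded. Windows holding at least one record
#' take the mean of their records; empty interior windows are linearly
#' interpolated between the nearest populated windows; empty leading and
#' trailing windows take the nearest populated window's value.
#'
#' @param t,value record times (hours) and values for one patient-variable.
#' @param interval window width in hours (6 or 24).
#' @param horizon total span in hours (72).
#' @return list with `values` (length `horizon/interval`) and
#'   `observed_mask`, or `NULL` when no record falls in `[0, horizon)`.
#' @export
#' @examples
#' interpolate_series(c(1, 13), c(80, 90))$values[1:4]  # 80 85 90 90
interpolate_series <- function(t, value, interval = 6, horizon = 72) {
  nw <- n_windows(interval, horizon)
  keep <- t >= 0 & t < horizon & is.finite(value)
  t <- t[keep]; value <- value[keep]
  if (length(t) == 0) return(NULL)
  w <- floor(t / interval) + 1L
  means <- tapply(value, factor(w, levels = seq_len(nw)), mean)
  mask <- !is.na(means)
  pop <- which(mask)
  vals <- if (length(pop) == 1) {
    rep(means[pop], nw)
  } else {
    stats::approx(pop, means[pop], xout = seq_len(nw), rule = 2)$y
  }
  list(values = as.numeric(vals), observed_mask = as.logical(mask))
}

#' Interpolate every patient-variable series in a record table
#'
#' @param records cleaned record table.
#' @inheritParams interpolate_series
#' @return data.frame with one row per (patient, variable, window):
#'   columns `patient_id`, `variable`, `window` (1-based), `value`,
#'   `observed`.
#' @export
interpolate_all <- function(records, interval = 6, horizon = 72) {
  nw <- n_windows(interval, horizon)
  key <- interaction(records$patient_id, records$variable, drop = TRUE, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(records)), key), function(ix) {
    s <- interpolate_series(records$t[ix], records$value[ix], interval, horizon)
    if (is.null(s)) return(NULL)
    data.frame(patient_id = records$patient_id[ix[1]],
               variable = records$variable[ix[1]],
               window = seq_len(nw), value = s$values,
               observed = s$observed_mask, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Cohort-wide variable statistics over interpolated values
#'
#' Mean and SD (n-1 denominator) per variable over all patients and all
#' windows of the interpolated series. Variables with zero variance are
#' dropped with a warning.
#'
#' @param interp output of [interpolate_all()].
#' @return data.frame with columns `variable`, `mean`, `sd`.
#' @export
compute_stats <- function(interp) {
  mu <- tapply(interp$value, interp$variable, mean)
  sd_ <- tapply(interp$value, interp$variable, stats::sd)
  out <- data.frame(variable = names(mu), mean = as.numeric(mu),
                    sd = as.numeric(sd_), stringsAsFactors = FALSE)
  degenerate <- is.na(out$sd) | out$sd == 0
  if (any(degenerate)) {
    warning("dropping constant variable(s): ",
            paste(out$variable[degenerate], collapse = ", "))
    out <- out[!degenerate, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# round half away from zero (round() in R rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Discretize interpolated values into integer z-score levels
#'
#' Each value is standardized with its variable's cohort-wide mean and SD,
#' rounded half-away-from-zero, and clipped to `[-clip, clip]`.
#'
#' @param interp output of [interpolate_all()].
#' @param stats data.frame `variable`, `mean`, `sd` (from [compute_stats()]
#'   or supplied externally, e.g. registry statistics).
#' @param clip maximum absolute level.
#' @return data.frame `patient_id`, `variable`, `window`, `level`.
#' @export
#' @examples
#' interp <- data.frame(patient_id = "P1", variable = "heart_rate",
#'                      window = 1, value = 107.4, observed = TRUE)
#' st <- data.frame(variable = "heart_rate", mean = 88.4, sd = 19.0)
#' discretize_levels(interp, st)$level  # 1
discretize_levels <- function(interp, stats, clip = 4) {
  idx <- match(interp$variable, stats$variable)
  keep <- !is.na(idx)
  if (all(!keep)) stop("no variable in `interp` has statistics in `stats`")
  if (anyNA(idx) && !any(keep)) stop("statistics missing for all variables")
  interp <- interp[keep, , drop = FALSE]
  idx <- idx[keep]
  z <- (interp$value - stats$mean[idx]) / stats$sd[idx]
  lev <- pmin(pmax(round_half_away(z), -clip), clip)
  out <- data.frame(patient_id = interp$patient_id, variable = interp$variable,
                    window = interp$window, level = as.integer(lev),
                    stringsAsFactors = FALSE)
  out
}

#' Assemble per-variable corpora of level chains
#'
#' One corpus per variable; each patient contributes at most one chain
#' (its full level sequence) per corpus.
#'
#' @param levels output of [discretize_levels()].
#' @param variables the full variable universe (absent variables yield
#'   empty corpora).
#' @param nw chain length (windows per series).
#' @return named list of corpora; each corpus is a list with `patients`
#'   (character) and `chains` (integer matrix, one chain per row).
#' @export
build_corpora <- function(levels, variables = variable_registry()$variable,
                          nw = 12) {
  out <- stats::setNames(vector("list", length(variables)), variables)
  for (v in variables) {
    sub <- levels[levels$variable == v, , drop = FALSE]
    if (nrow(sub) == 0) {
      out[[v]] <- list(patients = character(0),
                       chains = matrix(integer(0), 0, nw))
      next
    }
    pats <- sort(unique(sub$patient_id))
    m <- matrix(NA_integer_, length(pats), nw)
    m[cbind(match(sub$patient_id, pats), sub$window)] <- sub$level
    if (anyNA(m)) stop("incomplete level sequence for variable ", v)
    out[[v]] <- list(patients = pats, chains = m)
  }
  out
}

#' Write / read level sequences as tidy CSV
#'
#' Round-trip serialization of the discretized level table.
#'
#' @param levels the level table ([discretize_levels()] output).
#' @param path CSV path.
#' @export
write_levels <- function(levels, path) {
  utils::write.csv(levels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_levels
#' @export
read_levels <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(patient_id = "character",
                                 variable = "character",
                                 window = "integer", level = "integer"))
}

#' Write corpora as JSON lines (one chain per line)
#'
#' @param corpora output of [build_corpora()].
#' @param path output file.
#' @export
write_corpora <- function(corpora, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (v in names(corpora)) {
    cp <- corpora[[v]]
    for (i in seq_along(cp$patients)) {
      writeLines(jsonlite::toJSON(list(variable = v,
                                       patient_id = cp$patients[i],
                                       levels = cp$chains[i, ]),
                                  auto_unbox = TRUE), con)
    }
  }
  invisible(path)
}

#' Run the full preprocessing stage
#'
#' Outlier filter, interpolation, z-scoring, discretization, corpora.
#'
#' @param records raw record table.
#' @param ranges measurable-range table.
#' @param interval window width (6 or 24 h).
#' @param clip level clip bound.
#' @param stats optional externally supplied variable statistics; computed
#'   cohort-wide over interpolated values when `NULL`.
#' @return list with `levels`, `corpora`, `stats`, `n_removed`.
#' @export
prep_stage <- function(records, ranges = measurable_ranges(), interval = 6,
                       clip = 4, stats = NULL) {
  clean <- filter_outliers(records, ranges)
  interp <- interpolate_all(clean, interval = interval)
  if (is.null(stats)) stats <- compute_stats(interp)
  levels <- discretize_levels(interp, stats, clip = clip)
  corpora <- build_corpora(levels, variables = ranges$variable,
                           nw = n_windows(interval))
  list(levels = levels, corpora = corpora, stats = stats,
       n_removed = sum(attr(clean, "removed")))
}
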