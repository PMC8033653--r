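# Subgroup profiling: demographics/outcome tables, 7-day SOFA
# trajectories with organ subscores, comorbidity incidence tables with the
# 10%-maximum-subgroup filter, between-subgroup hypothesis tests, and the
# Elixhauser comorbidity index.

.mean_sd <- function(x) c(mean = mean(x), sd = stats::sd(x))

#' BMI stratum labels
#'
#' Underweight `< 18.5 <=` healthy `< 25 <=` overweight `< 30 <=` obese.
#'
#' @param bmi numeric vector (kg/m^2).
#' @return factor with levels underweight/healthy/overweight/obese.
#' @export
bmi_stratum <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
      labels = c("underweight", "healthy", "overweight", "obese"))
}

#' Demographics and outcome table by subgroup
#'
#' Per subgroup and overall: n; mean +/- SD for age, weight, BMI, ICU
#' length of stay, Elixhauser index and day-1 SOFA; percentages for sex,
#' ethnicity, BMI strata and the two mortality outcomes.
#'
#' @param outcomes patient outcome data.frame (`patient_id`, `age`, `sex`,
#'   `weight`, `bmi`, `ethnicity`, `icu_los`, `day1_sofa`,
#'   `elixhauser_index`, `mortality_30d`, `mortality_inhosp`).
#' @param assignment integer subgroup labels named by patient id.
#' @return data.frame with one row per statistic and one column per
#'   subgroup plus `overall`; `statistic`/`unit` columns describe rows.
#' @export
demographics_table <- function(outcomes, assignment) {
  ids <- names(assignment)[!is.na(assignment)]
  missing <- setdiff(ids, outcomes$patient_id)
  if (length(missing) > 0) {
    stop("labelled patients missing outcome rows: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  oc <- outcomes[match(ids, outcomes$patient_id), ]
  grp <- assignment[ids]
  groups <- sort(unique(grp))
  cols <- c(paste0("subgroup_", groups), "overall")
  pick <- c(lapply(groups, function(g) oc[grp == g, , drop = FALSE]),
            list(oc))
  row_ms <- function(stat, vals) {
    data.frame(statistic = stat, unit = "mean_sd",
               as.list(stats::setNames(vals, cols)), check.names = FALSE)
  }
  rows <- list()
  rows$n <- data.frame(statistic = "n", unit = "count",
                       as.list(stats::setNames(vapply(pick, nrow, 0), cols)),
                       check.names = FALSE)
  for (v in c("age", "weight", "bmi", "icu_los", "elixhauser_index", "day1_sofa")) {
    ms <- vapply(pick, function(d) .mean_sd(d[[v]]), numeric(2))
    rows[[paste0(v, "_mean")]] <- row_ms(paste0(v, "_mean"), ms["mean", ])
    rows[[paste0(v, "_sd")]] <- row_ms(paste0(v, "_sd"), ms["sd", ])
  }
  pct_rows <- function(label, fn) {
    data.frame(statistic = label, unit = "percent",
               as.list(stats::setNames(vapply(pick, fn, 0) * 100, cols)),
               check.names = FALSE)
  }
  rows$male <- pct_rows("sex_male", function(d) mean(d$sex == "male"))
  rows$female <- pct_rows("sex_female", function(d) mean(d$sex == "female"))
  for (s in levels(bmi_stratum(1))) {
    rows[[paste0("bmi_", s)]] <-
      pct_rows(paste0("bmi_", s), function(d) mean(bmi_stratum(d$bmi) == s))
  }
  for (e in sort(unique(oc$ethnicity))) {
    rows[[paste0("eth_", e)]] <-
      pct_rows(paste0("ethnicity_", e), function(d) mean(d$ethnicity == e))
  }
  rows$m30 <- pct_rows("mortality_30d", function(d) mean(d$mortality_30d))
  rows$minh <- pct_rows("mortality_inhosp", function(d) mean(d$mortality_inhosp))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 7-day SOFA trajectory by subgroup
#'
#' Mean daily SOFA total and mean subscores per subgroup for days 1-7,
#' averaging over the patients observed on each day (patients contribute
#' only their observed days).
#'
#' @param sofa daily SOFA data.frame (`patient_id`, `day`, the six
#'   subscores, `total`).
#' @param assignment labels named by patient id.
#' @return data.frame `subgroup`, `day`, `total` and the six subscore
#'   means.
#' @export
sofa_trend <- function(sofa, assignment) {
  if (any(sofa$day < 1 | sofa$day > 7)) stop("SOFA days must lie in 1..7")
  subs <- c("respiration", "coagulation", "liver", "cardiovascular", "cns", "renal")
  bad <- sofa$total != rowSums(sofa[, subs])
  if (any(bad)) stop("SOFA total != sum of subscores for ", sum(bad), " row(s)")
  grp <- assignment[sofa$patient_id]
  keep <- !is.na(grp)
  sofa <- sofa[keep, ]; grp <- grp[keep]
  out <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    sg <- sofa[grp == g, ]
    agg <- stats::aggregate(sg[, c("total", subs)], by = list(day = sg$day), mean)
    data.frame(subgroup = g, agg)
  }))
  rownames(out) <- NULL
  out
}

#' Comorbidity incidence table
#'
#' Per-category, per-subgroup incidence percentages. Categories are
#' retained when their maximum subgroup incidence reaches `min_incidence`
#' (closed boundary) and sorted by whole-cohort incidence descending.
#'
#' @param flags comorbidity data.frame: `patient_id` plus 30 0/1 columns.
#' @param assignment labels named by patient id.
#' @param min_incidence retention threshold on the max subgroup incidence
#'   (proportion).
#' @return data.frame `category`, `cohort_pct`, one `subgroup_g` column
#'   per subgroup.
#' @export
comorbidity_incidence <- function(flags, assignment, min_incidence = 0.10) {
  cats <- setdiff(colnames(flags), "patient_id")
  grp <- assignment[flags$patient_id]
  keep <- !is.na(grp)
  fl <- flags[keep, cats, drop = FALSE]; grp <- grp[keep]
  groups <- sort(unique(grp))
  inc <- vapply(groups, function(g) colMeans(fl[grp == g, , drop = FALSE]),
                numeric(length(cats)))
  cohort <- colMeans(fl)
  retain <- apply(inc, 1, max) >= min_incidence
  out <- data.frame(category = cats, cohort_pct = 100 * cohort,
                    100 * inc, check.names = FALSE)
  colnames(out)[-(1:2)] <- paste0("subgroup_", groups)
  out <- out[retain, , drop = FALSE]
  out <- out[order(-out$cohort_pct, out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Between-subgroup hypothesis tests
#'
#' Continuous variables: Welch one-way ANOVA across subgroups plus
#' pairwise Welch t-tests. Proportions: chi-square test of independence.
#' Decisions at `alpha` with no multiplicity correction by default
#' (`p_adjust = "holm"` available for the pairwise battery).
#'
#' @param values named list; each element either a numeric vector
#'   (continuous) or a logical/0-1 vector (proportion), aligned with
#'   `assignment` by name or position.
#' @param assignment labels (same length/order as each element of
#'   `values`).
#' @param alpha significance level.
#' @param p_adjust `"none"` or `"holm"` for the pairwise t-tests.
#' @return data.frame `variable`, `test`, `comparison`, `statistic`, `p`,
#'   `reject`.
#' @export
subgroup_tests <- function(values, assignment, alpha = 0.05,
                           p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  grp <- factor(assignment)
  if (nlevels(grp) < 2) stop("need at least 2 subgroups")
  rows <- list()
  for (nm in names(values)) {
    x <- values[[nm]]
    if (is.logical(x) || all(x %in% c(0, 1, NA))) {
      tab <- table(grp, factor(as.integer(x), levels = 0:1))
      tst <- suppressWarnings(stats::chisq.test(tab))
      rows[[length(rows) + 1]] <- data.frame(
        variable = nm, test = "chi_square", comparison = "all",
        statistic = unname(tst$statistic), p = tst$p.value,
        reject = tst$p.value < alpha)
    } else {
      within_var <- tapply(x, grp, stats::var)
      grp_means <- tapply(x, grp, mean)
      if (all(within_var == 0, na.rm = TRUE) &&
          max(grp_means) - min(grp_means) < 1e-12) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = nm, test = "welch_anova", comparison = "all",
          statistic = 0, p = 1, reject = FALSE)
        next
      }
      av <- stats::oneway.test(x ~ grp, var.equal = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        variable = nm, test = "welch_anova", comparison = "all",
        statistic = unname(av$statistic), p = av$p.value,
        reject = av$p.value < alpha)
      pair <- utils::combn(levels(grp), 2)
      praw <- numeric(ncol(pair)); stat <- numeric(ncol(pair))
      for (j in seq_len(ncol(pair))) {
        tt <- stats::t.test(x[grp == pair[1, j]], x[grp == pair[2, j]])
        praw[j] <- tt$p.value; stat[j] <- unname(tt$statistic)
      }
      padj <- stats::p.adjust(praw, method = p_adjust)
      rows[[length(rows) + 1]] <- data.frame(
        variable = nm, test = "welch_t", comparison = paste(pair[1, ], pair[2, ], sep = "_vs_"),
        statistic = stat, p = padj, reject = padj < alpha)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Elixhauser comorbidity index
#'
#' Weighted sum of comorbidity flags; default van Walraven weights from
#' [elixhauser_registry()].
#'
#' @param flags data.frame with `patient_id` and the 30 category columns.
#' @param weights data.frame `category`, `weight` covering every flag
#'   column.
#' @return numeric index named by patient id.
#' @export
#' @examples
#' fl <- data.frame(patient_id = "P1",
#'                  matrix(0, 1, 30,
#'                         dimnames = list(NULL, elixhauser_registry()$category)),
#'                  check.names = FALSE)
#' elixhauser_score(fl)  # 0
elixhauser_score <- function(flags, weights = elixhauser_registry()) {
  cats <- setdiff(colnames(flags), "patient_id")
  idx <- match(cats, weights$category)
  if (anyNA(idx)) {
    stop("weight table missing categories: ",
         paste(cats[is.na(idx)], collapse = ", "))
  }
  w <- weights$weight[idx]
  score <- as.numeric(as.matrix(flags[, cats, drop = FALSE]) %*% w)
  stats::setNames(score, flags$patient_id)
}

#' Full subgroup profile report
#'
#' @param outcomes,sofa,flags cohort tables.
#' @param assignment subgroup labels named by patient id.
#' @param alpha significance level for the test battery.
#' @return list with `demographics`, `sofa_trend`, `comorbidities`,
#'   `tests`.
#' @export
profile_subgroups <- function(outcomes, sofa, flags, assignment,
                              alpha = 0.05) {
  ids <- names(assignment)[!is.na(assignment)]
  oc <- outcomes[match(ids, outcomes$patient_id), ]
  grp <- assignment[ids]
  tests <- subgroup_tests(
    list(age = oc$age, weight = oc$weight, bmi = oc$bmi,
         icu_los = oc$icu_los, elixhauser_index = oc$elixhauser_index,
         day1_sofa = as.numeric(oc$day1_sofa),
         mortality_30d = oc$mortality_30d,
         mortality_inhosp = oc$mortality_inhosp,
         sex_male = oc$sex == "male"),
    grp, alpha = alpha)
  list(demographics = demographics_table(outcomes, assignment),
       sofa_trend = sofa_trend(sofa, assignment),
       comorbidities = comorbidity_incidence(flags, assignment),
       tests = tests)
}
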