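# Synthetic cohort generator: plants latent trend-group structure in the
# 34-variable physiological panel, with irregular Poisson-process sampling
# and group-linked mortality, SOFA trajectories and comorbidity prevalences.
# Ground-truth group labels are returned for recovery testing.

#' Construct a cohort specification
#'
#' Bundles and validates every parameter of the synthetic cohort generator.
#' The defaults describe a three-group cohort on the scale of the
#' physiological registry; [make_paperlike_spec()] supplies a fully
#' parameterized study-like specification.
#'
#' @param n_patients number of patients (positive integer).
#' @param n_groups number of latent trend groups.
#' @param group_proportions simplex vector of length `n_groups`.
#' @param archetype function `f(group, variable, w)` returning the z-scale
#'   trend value of `variable` for members of `group` at window indices `w`
#'   (0-based, vectorized over `w`).
#' @param noise_sd measurement noise SD on the z scale.
#' @param sampling_rate expected measurements per variable per 72 h.
#' @param missing_variable_prob probability a patient-variable series is
#'   entirely absent.
#' @param mortality_logit per-group logit of 30-day mortality.
#' @param sofa_day1_mean per-group mean day-1 SOFA total.
#' @param sofa_slope per-group SOFA change per day (points/day).
#' @param sofa_subscore_weights `n_groups` x 6 matrix of nonnegative weights
#'   (rows sum to 1) splitting the SOFA total across the six organ
#'   subscores.
#' @param comorbidity_prevalence `n_groups` x 30 matrix of per-category
#'   prevalences in `[0, 1]`, columns in [elixhauser_registry()] order.
#' @param variable_stats data.frame with columns `variable`, `mean`, `sd`
#'   (natural units); defaults to the registry panel statistics.
#' @param demographics optional list of per-group demographic parameters
#'   (see [make_paperlike_spec()] for the shape); a generic default is used
#'   when omitted.
#' @param seed integer seed; the generator is bit-reproducible given the
#'   spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients,
                        n_groups = 3,
                        group_proportions = rep(1 / n_groups, n_groups),
                        archetype = function(group, variable, w) rep(0, length(w)),
                        noise_sd = 0.5,
                        sampling_rate = 24,
                        missing_variable_prob = 0.05,
                        mortality_logit = rep(stats::qlogis(0.18), n_groups),
                        sofa_day1_mean = rep(7, n_groups),
                        sofa_slope = rep(-0.3, n_groups),
                        sofa_subscore_weights = NULL,
                        comorbidity_prevalence = NULL,
                        variable_stats = variable_registry()[, c("variable", "mean", "sd")],
                        demographics = NULL,
                        seed = 1L) {
  if (is.null(sofa_subscore_weights)) {
    sofa_subscore_weights <- matrix(1 / 6, n_groups, 6)
  }
  if (is.null(comorbidity_prevalence)) {
    comorbidity_prevalence <- matrix(0.1, n_groups, 30)
  }
  spec <- structure(list(
    n_patients = as.integer(n_patients), n_groups = as.integer(n_groups),
    group_proportions = group_proportions, archetype = archetype,
    noise_sd = noise_sd, sampling_rate = sampling_rate,
    missing_variable_prob = missing_variable_prob,
    mortality_logit = mortality_logit, sofa_day1_mean = sofa_day1_mean,
    sofa_slope = sofa_slope, sofa_subscore_weights = sofa_subscore_weights,
    comorbidity_prevalence = comorbidity_prevalence,
    variable_stats = variable_stats, demographics = demographics,
    seed = as.integer(seed)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (!is.numeric(spec$n_patients) || spec$n_patients < 1) {
    stop("cohort_spec invariant violated: n_patients must be a positive integer")
  }
  p <- spec$group_proportions
  if (length(p) != spec$n_groups || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("cohort_spec invariant violated: group_proportions must be nonnegative and sum to 1 (length n_groups)")
  }
  vs <- spec$variable_stats
  if (nrow(vs) != 34 || any(vs$sd <= 0)) {
    stop("cohort_spec invariant violated: variable registry must have exactly 34 entries with sd > 0")
  }
  cp <- spec$comorbidity_prevalence
  if (!is.matrix(cp) || nrow(cp) != spec$n_groups || ncol(cp) != 30 ||
      any(cp < 0) || any(cp > 1)) {
    stop("cohort_spec invariant violated: comorbidity_prevalence must be n_groups x 30 with entries in [0,1]")
  }
  if (spec$noise_sd < 0) {
    stop("cohort_spec invariant violated: noise_sd must be nonnegative")
  }
  if (spec$sampling_rate <= 0) {
    stop("cohort_spec invariant violated: sampling_rate must be positive")
  }
  if (spec$missing_variable_prob < 0 || spec$missing_variable_prob > 1) {
    stop("cohort_spec invariant violated: missing_variable_prob must lie in [0,1]")
  }
  w <- spec$sofa_subscore_weights
  if (!is.matrix(w) || nrow(w) != spec$n_groups || ncol(w) != 6 ||
      any(w < 0) || any(abs(rowSums(w) - 1) > 1e-9)) {
    stop("cohort_spec invariant violated: sofa_subscore_weights rows must be length-6 simplex vectors")
  }
  invisible(spec)
}

#' Study-like cohort specification
#'
#' A ready-made three-group specification mirroring the structure of the
#' sepsis phenotyping study: group proportions 0.21/0.35/0.44, 30-day
#' mortality rates 17%/28%/10%, registry (panel) variable statistics, and
#' hand-designed trend archetypes. The three groups follow one-period
#' trajectory shapes at equally spaced phases over the 72-h horizon
#' (deteriorate-then-recover, late deterioration, and the recovering
#' mirror; amplitude 1.2 z-units, alternate variables sign-flipped), so
#' the shapes are mutually equidistant and every variable separates all
#' three phenotypes. Group-linked SOFA trajectories, subscore-dominance
#' profiles, comorbidity prevalences and demographics complete the
#' study-like structure.
#'
#' @param n_patients cohort size (must be at least 3).
#' @param seed integer seed stored in the spec.
#' @return A `cohort_spec`.
#' @export
#' @examples
#' spec <- make_paperlike_spec(100, seed = 1)
#' spec$group_proportions
make_paperlike_spec <- function(n_patients, seed = 1L) {
  if (n_patients < 3) stop("n_patients must be at least n_groups (3)")
  reg <- variable_registry()
  vars <- reg$variable
  # Every variable trends in every group, with one-period trajectory
  # shapes at three equally spaced phases (z amplitude 1.2): deteriorate-
  # then-recover, late deterioration, and the recovering mirror. The three
  # shapes are mutually equidistant in L2, so no pair of phenotypes is
  # closer than any other — the three-distinct-stable-clusters regime the
  # factorization assumes. Alternate variables flip sign (some variables
  # fall while others rise in the same patient), which shifts all three
  # phases by half a period and preserves the equidistance.
  flip <- stats::setNames(rep_len(c(0, pi), length(vars)), vars)
  archetype <- function(group, variable, w) {
    phase <- 2 * pi * (group - 1) / 3 + flip[[variable]]
    1.2 * cos(2 * pi * w / 11 - phase)
  }
  subw <- rbind(
    c(0.15, 0.10, 0.05, 0.25, 0.10, 0.35),  # renal/cardiovascular dominant
    c(0.15, 0.10, 0.15, 0.25, 0.05, 0.30),  # adds hepatic burden
    c(0.15, 0.10, 0.05, 0.15, 0.35, 0.20)   # neurologic dominant
  )
  ereg <- elixhauser_registry()$category
  prev <- matrix(0.05, 3, 30, dimnames = list(NULL, ereg))
  tab4 <- list(
    hypertension = c(0.6987, 0.6518, 0.4858),
    fluid_electrolyte = c(0.4212, 0.6194, 0.3536),
    cardiac_arrhythmias = c(0.3859, 0.3713, 0.2247),
    congestive_heart_failure = c(0.3235, 0.3060, 0.1495),
    deficiency_anemias = c(0.2291, 0.2898, 0.2136),
    diabetes_uncomplicated = c(0.2808, 0.2574, 0.1657),
    chronic_pulmonary = c(0.2340, 0.2102, 0.2049),
    renal_failure = c(0.2808, 0.2888, 0.0680),
    coagulopathy = c(0.0993, 0.2957, 0.1195),
    neurologic_disease = c(0.1511, 0.1321, 0.2176),
    hypothyroidism = c(0.1535, 0.1326, 0.1072),
    depression = c(0.1166, 0.1297, 0.1404),
    liver_disease = c(0.0616, 0.1744, 0.0949),
    valvular_disease = c(0.1182, 0.1302, 0.0724),
    alcohol_abuse = c(0.0608, 0.1061, 0.1286),
    peripheral_vascular = c(0.1133, 0.1203, 0.0542),
    pulmonary_circulation = c(0.0985, 0.1110, 0.0629)
  )
  for (cat in names(tab4)) prev[, cat] <- tab4[[cat]]
  demographics <- list(
    age_mean = c(73.12, 67.91, 59.92), age_sd = c(14.56, 16.27, 18.24),
    male_prob = c(0.590, 0.603, 0.504),
    weight_mean = c(84.25, 83.01, 79.37), weight_sd = c(35.08, 24.32, 25.54),
    bmi_mean = c(29.36, 29.48, 28.36), bmi_sd = c(8.73, 8.73, 8.73),
    los_mean = c(3.14, 6.23, 4.21),
    ethnicity_prob = rbind(
      c(asian = 0.0238, black = 0.0961, white = 0.7668, hispanic = 0.0140, other = 0.0993),
      c(asian = 0.0295, black = 0.0864, white = 0.7215, hispanic = 0.0309, other = 0.1317),
      c(asian = 0.0356, black = 0.0823, white = 0.7108, hispanic = 0.0427, other = 0.1286)
    ),
    inhosp_given_30d = c(0.71, 0.87, 0.72)
  )
  cohort_spec(
    n_patients = n_patients, n_groups = 3,
    group_proportions = c(0.21, 0.35, 0.44),
    archetype = archetype, noise_sd = 0.5, sampling_rate = 24,
    missing_variable_prob = 0.05,
    mortality_logit = stats::qlogis(c(0.17, 0.28, 0.10)),
    sofa_day1_mean = c(6.5, 8.7, 6.5),
    sofa_slope = c(-0.25, -0.10, -0.55),
    sofa_subscore_weights = subw,
    comorbidity_prevalence = prev,
    demographics = demographics,
    seed = seed
  )
}

# split an integer total across 6 subscores proportionally to `weights`,
# rounding by largest remainder while preserving the total, each subscore
# capped at 4 (feasible because total <= 24)
allocate_subscores <- function(total, weights) {
  total <- max(0L, min(24L, as.integer(total)))
  target <- total * weights / sum(weights)
  base <- floor(target)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(target - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  # repair any cap violations by shifting excess to subscores with headroom
  over <- which(base > 4)
  while (length(over) > 0) {
    i <- over[1]
    excess <- base[i] - 4
    base[i] <- 4
    room <- which(base < 4)
    for (j in room) {
      give <- min(excess, 4 - base[j])
      base[j] <- base[j] + give
      excess <- excess - give
      if (excess == 0) break
    }
    over <- which(base > 4)
  }
  as.integer(base)
}

#' Generate a synthetic cohort
#'
#' Realizes a [cohort_spec()]: assigns each patient a latent trend group,
#' samples irregular measurement times per variable from a Poisson process
#' over the 72-h horizon, evaluates the group archetype (z scale) at each
#' record's window, maps to natural units through the variable statistics
#' and adds Gaussian noise, and draws outcomes, daily SOFA totals with
#' subscore splits, comorbidity flags and demographics from the group-linked
#' distributions.
#'
#' @param spec a validated `cohort_spec`.
#' @return An object of class `synthetic_cohort`: a list with data.frames
#'   `records` (`patient_id`, `variable`, `t`, `value`), `patients`
#'   (demographics and outcomes), `sofa` (daily subscores and totals, days
#'   1–7), `comorbidities` (30 0/1 flags), and `truth` (named integer vector
#'   of group labels).
#' @export
#' @examples
#' co <- generate_cohort(make_paperlike_spec(20, seed = 7))
#' table(co$truth)
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  n <- spec$n_patients
  ids <- sprintf("P%04d", seq_len(n))
  grp <- sample.int(spec$n_groups, n, replace = TRUE, prob = spec$group_proportions)
  names(grp) <- ids

  vs <- spec$variable_stats
  vars <- vs$variable
  # --- physiological records -------------------------------------------
  present <- matrix(stats::runif(n * length(vars)) >= spec$missing_variable_prob,
                    n, length(vars))
  counts <- matrix(stats::rpois(n * length(vars), spec$sampling_rate),
                   n, length(vars))
  counts[!present] <- 0L
  total <- sum(counts)
  rec_pat <- rep(rep(ids, length(vars)), as.vector(counts))
  rec_var <- rep(rep(vars, each = n), as.vector(counts))
  rec_grp <- rep(rep(grp, length(vars)), as.vector(counts))
  t <- stats::runif(total, 0, 72)
  w <- pmin(floor(t / 6), 11)
  z <- numeric(total)
  for (g in seq_len(spec$n_groups)) {
    for (v in vars) {
      sel <- rec_grp == g & rec_var == v
      if (any(sel)) z[sel] <- spec$archetype(g, v, w[sel])
    }
  }
  if (spec$noise_sd > 0) z <- z + stats::rnorm(total, 0, spec$noise_sd)
  mu <- vs$mean[match(rec_var, vars)]
  sig <- vs$sd[match(rec_var, vars)]
  records <- data.frame(patient_id = rec_pat, variable = rec_var,
                        t = t, value = mu + sig * z,
                        stringsAsFactors = FALSE)
  o <- order(records$patient_id, records$variable, records$t)
  records <- records[o, , drop = FALSE]
  rownames(records) <- NULL

  # --- SOFA -------------------------------------------------------------
  sofa <- do.call(rbind, lapply(seq_len(n), function(i) {
    g <- grp[i]
    day <- 1:7
    mean_tot <- spec$sofa_day1_mean[g] + spec$sofa_slope[g] * (day - 1)
    tot <- pmax(0, pmin(24, round(stats::rnorm(7, mean_tot, 1.5))))
    subs <- t(vapply(tot, allocate_subscores, integer(6),
                     weights = spec$sofa_subscore_weights[g, ]))
    data.frame(patient_id = ids[i], day = day,
               respiration = subs[, 1], coagulation = subs[, 2],
               liver = subs[, 3], cardiovascular = subs[, 4],
               cns = subs[, 5], renal = subs[, 6],
               total = rowSums(subs), stringsAsFactors = FALSE)
  }))
  rownames(sofa) <- NULL

  # --- comorbidities ----------------------------------------------------
  ereg <- elixhauser_registry()
  flags <- matrix(0L, n, 30, dimnames = list(NULL, ereg$category))
  for (g in seq_len(spec$n_groups)) {
    gi <- which(grp == g)
    if (length(gi) == 0) next
    p <- spec$comorbidity_prevalence[g, ]
    draws <- matrix(stats::runif(length(gi) * 30), length(gi), 30)
    flags[gi, ] <- 1L * (draws < matrix(p, length(gi), 30, byrow = TRUE))
  }
  comorbidities <- data.frame(patient_id = ids, flags,
                              stringsAsFactors = FALSE, check.names = FALSE)

  # --- demographics and outcomes ---------------------------------------
  dg <- spec$demographics
  if (is.null(dg)) {
    k <- spec$n_groups
    dg <- list(age_mean = rep(65, k), age_sd = rep(17, k),
               male_prob = rep(0.55, k),
               weight_mean = rep(82, k), weight_sd = rep(27, k),
               bmi_mean = rep(29, k), bmi_sd = rep(8.7, k),
               los_mean = rep(4.7, k),
               ethnicity_prob = matrix(c(0.03, 0.09, 0.73, 0.03, 0.12), k, 5,
                                       byrow = TRUE,
                                       dimnames = list(NULL, c("asian", "black", "white", "hispanic", "other"))),
               inhosp_given_30d = rep(0.8, k))
  }
  eth_levels <- colnames(dg$ethnicity_prob)
  age <- pmax(18, stats::rnorm(n, dg$age_mean[grp], dg$age_sd[grp]))
  sex <- ifelse(stats::runif(n) < dg$male_prob[grp], "male", "female")
  weight <- pmax(30, stats::rnorm(n, dg$weight_mean[grp], dg$weight_sd[grp]))
  bmi <- pmax(12, stats::rnorm(n, dg$bmi_mean[grp], dg$bmi_sd[grp]))
  los <- stats::rgamma(n, shape = 1.2, scale = dg$los_mean[grp] / 1.2)
  eth <- vapply(seq_len(n), function(i) {
    sample(eth_levels, 1, prob = dg$ethnicity_prob[grp[i], ])
  }, character(1))
  mort30 <- stats::runif(n) < stats::plogis(spec$mortality_logit[grp])
  mort_inhosp <- mort30 & (stats::runif(n) < dg$inhosp_given_30d[grp])
  day1 <- sofa$total[sofa$day == 1][match(ids, sofa$patient_id[sofa$day == 1])]
  elix <- as.numeric(flags %*% ereg$weight)
  patients <- data.frame(
    patient_id = ids, age = age, sex = sex, weight = weight, bmi = bmi,
    ethnicity = eth, icu_los = los, day1_sofa = as.integer(day1),
    elixhauser_index = elix, mortality_30d = mort30,
    mortality_inhosp = mort_inhosp, stringsAsFactors = FALSE
  )

  structure(list(records = records, patients = patients, sofa = sofa,
                 comorbidities = comorbidities, truth = grp, spec = spec),
            class = "synthetic_cohort")
}

#' @method print synthetic_cohort
#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic ICU cohort:", nrow(x$patients), "patients,",
      nrow(x$records), "records,", length(unique(x$records$variable)),
      "variables\n")
  cat("Group sizes:", paste(table(x$truth), collapse = " / "), "\n")
  cat("30-day mortality:",
      sprintf("%.1f%%", 100 * mean(x$patients$mortality_30d)), "\n")
  invisible(x)
}

#' Write or read a cohort as plain-text files
#'
#' `write_cohort()` writes the four tables as CSV (`records.csv`,
#' `patients.csv`, `sofa.csv`, `comorbidities.csv`) plus the ground-truth
#' labels as JSON (`truth.json`); `read_cohort()` restores the same
#' structure.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort()` the directory invisibly; `read_cohort()` a
#'   `synthetic_cohort` (without the generating spec).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$records, file.path(dir, "records.csv"), row.names = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"), row.names = FALSE)
  utils::write.csv(cohort$sofa, file.path(dir, "sofa.csv"), row.names = FALSE)
  utils::write.csv(cohort$comorbidities, file.path(dir, "comorbidities.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(cohort$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  truth <- unlist(jsonlite::read_json(file.path(dir, "truth.json")))
  structure(list(
    records = utils::read.csv(file.path(dir, "records.csv"), stringsAsFactors = FALSE),
    patients = utils::read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE),
    sofa = utils::read.csv(file.path(dir, "sofa.csv"), stringsAsFactors = FALSE),
    comorbidities = utils::read.csv(file.path(dir, "comorbidities.csv"),
                                    stringsAsFactors = FALSE, check.names = FALSE),
    truth = truth, spec = NULL
  ), class = "synthetic_cohort")
}
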