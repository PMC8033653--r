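ten_patients <- function() {
  data.frame(
    patient_id = sprintf("P%02d", 1:10),
    age = c(60, 70, 50, 55, 65, 80, 75, 40, 45, 62),
    sex = c(rep("male", 6), rep("female", 4)),
    weight = c(80, 90, 70, 75, 85, 95, 88, 60, 66, 82),
    bmi = c(24.9, 25.0, 18.4, 18.5, 30.0, 29.9, 31, 22, 27, 26),
    ethnicity = c(rep("white", 7), rep("black", 3)),
    icu_los = c(2, 3, 4, 5, 6, 2, 3, 4, 5, 6),
    day1_sofa = c(6, 8, 5, 7, 9, 10, 6, 4, 5, 7),
    elixhauser_index = c(0, 5, 3, 7, 2, 9, 4, 1, 0, 6),
    mortality_30d = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE,
                      FALSE, FALSE),
    mortality_inhosp = c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE,
                         FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

test_that("demographics arithmetic matches hand computation", {
  oc <- ten_patients()
  grp <- setNames(rep(1:2, each = 5), oc$patient_id)
  tab <- demographics_table(oc, grp)
  pick <- function(stat, col) tab[tab$statistic == stat, col]
  # subgroup of two patients aged 60 and 70: mean 65, sd sqrt(50)
  grp2 <- setNames(c(1, 1), c("P01", "P02"))
  tab2 <- demographics_table(oc[1:2, ], grp2)
  expect_equal(tab2[tab2$statistic == "age_mean", "subgroup_1"], 65)
  expect_equal(tab2[tab2$statistic == "age_sd", "subgroup_1"], sqrt(50))
  expect_equal(tab2[tab2$statistic == "sex_male", "subgroup_1"], 100)
  expect_equal(tab2[tab2$statistic == "sex_female", "subgroup_1"], 0)
  # full table: n sums to cohort, percentage blocks sum to 100
  expect_equal(sum(unlist(tab[tab$statistic == "n",
                              c("subgroup_1", "subgroup_2")])), 10)
  sex_block <- tab[tab$statistic %in% c("sex_male", "sex_female"), "overall"]
  expect_equal(sum(sex_block), 100)
  bmi_block <- tab[grepl("^bmi_(under|healthy|over|obese)", tab$statistic), "overall"]
  expect_equal(sum(bmi_block), 100)
  # labelled patient without an outcome row errors with the id
  expect_error(demographics_table(oc[-1, ], grp), "P01")
})

test_that("BMI strata boundaries are half-open at 18.5 / 25 / 30", {
  expect_equal(as.character(bmi_stratum(c(18.4, 18.5, 24.9, 25.0, 29.9, 30.0))),
               c("underweight", "healthy", "healthy", "overweight",
                 "overweight", "obese"))
})

test_that("SOFA trends average observed days per subgroup", {
  subs <- c("respiration", "coagulation", "liver", "cardiovascular", "cns", "renal")
  mk <- function(id, day, total) {
    alloc <- c(rep(floor(total / 6), 5), total - 5 * floor(total / 6))
    out <- data.frame(patient_id = id, day = day)
    out[subs] <- as.list(alloc)
    out$total <- total
    out
  }
  sofa <- rbind(mk("A", 1, 6), mk("B", 1, 10), mk("A", 2, 8), mk("B", 2, 8))
  grp <- setNames(c(1, 1), c("A", "B"))
  tr <- sofa_trend(sofa, grp)
  expect_equal(tr$total[tr$day == 1], 8)       # (6 + 10) / 2
  expect_equal(tr$total[tr$day == 2], 8)
  bad <- sofa; bad$day[1] <- 8
  expect_error(sofa_trend(bad, grp), "1..7")
  bad2 <- sofa; bad2$total[1] <- 5
  expect_error(sofa_trend(bad2, grp), "subscores")
})

test_that("generator SOFA slopes are recovered from the daily means", {
  spec <- cohort_spec(500, n_groups = 1, group_proportions = 1,
                      sampling_rate = 0.5, missing_variable_prob = 0.9,
                      mortality_logit = qlogis(0.2),
                      sofa_day1_mean = 9, sofa_slope = -0.5, seed = 31)
  co <- generate_cohort(spec)
  grp <- setNames(rep(1L, 500), co$patients$patient_id)
  tr <- sofa_trend(co$sofa, grp)
  slope <- coef(lm(total ~ day, tr))[["day"]]
  expect_lt(abs(slope - (-0.5)), 0.1)
})

test_that("comorbidity incidence filters on max subgroup incidence and sorts", {
  set.seed(1)
  ids <- sprintf("P%03d", 1:300)
  grp <- setNames(rep(1:3, each = 100), ids)
  flags <- data.frame(patient_id = ids, check.names = FALSE)
  flags[["common"]] <- rep(1L, 300)                       # 100% everywhere
  flags[["rare"]] <- c(rep(1L, 8), rep(0L, 92),           # 8% / 9% / 7%
                       rep(1L, 9), rep(0L, 91),
                       rep(1L, 7), rep(0L, 93))
  flags[["boundary"]] <- c(rep(1L, 10), rep(0L, 90),      # exactly 10% in g1
                           rep(0L, 200))
  flags[["absent"]] <- rep(0L, 300)
  inc <- comorbidity_incidence(flags, grp, min_incidence = 0.10)
  expect_setequal(inc$category, c("common", "boundary"))  # rare + absent out
  expect_equal(inc$category[1], "common")                 # sorted by cohort %
  expect_equal(inc[inc$category == "boundary", "subgroup_1"], 10)
})

test_that("hypothesis tests reject real separation and keep the null", {
  set.seed(5)
  grp <- rep(1:2, each = 200)
  sep <- c(rnorm(200, 60, 15), rnorm(200, 73, 15))
  same <- rep(rnorm(200), 2)
  res <- subgroup_tests(list(sep = sep, same = same, flag = rep(c(0, 1), 200)),
                        grp)
  expect_true(res$reject[res$variable == "sep" & res$test == "welch_anova"])
  expect_false(res$reject[res$variable == "same" & res$test == "welch_anova"])
  expect_equal(res$test[res$variable == "flag"], "chi_square")
  # degenerate: zero variance, equal means -> p = 1, no error
  cst <- subgroup_tests(list(x = rep(5, 400)), grp)
  expect_equal(cst$p[cst$test == "welch_anova"], 1)
  expect_false(cst$reject[1])
  # pairwise battery present for continuous variables
  expect_equal(sum(res$variable == "sep" & res$test == "welch_t"), 1)
})

test_that("the Elixhauser index is the weighted flag sum", {
  cats <- elixhauser_registry()$category
  fl <- data.frame(patient_id = c("A", "B", "C"),
                   matrix(0L, 3, 30, dimnames = list(NULL, cats)),
                   check.names = FALSE)
  fl[2, "congestive_heart_failure"] <- 1L
  fl[3, "congestive_heart_failure"] <- 1L
  fl[3, "coagulopathy"] <- 1L
  sc <- elixhauser_score(fl)
  expect_equal(unname(sc), c(0, 7, 10))   # vW: CHF 7, coagulopathy 3
  expect_error(elixhauser_score(fl, weights = elixhauser_registry()[1:5, ]),
               "missing")
})

test_that("the full profile report is internally consistent on a generated cohort", {
  co <- generate_cohort(make_paperlike_spec(80, seed = 13))
  rep_ <- profile_subgroups(co$patients, co$sofa, co$comorbidities, co$truth)
  n_row <- rep_$demographics[rep_$demographics$statistic == "n", ]
  expect_equal(sum(unlist(n_row[grep("subgroup", names(n_row))])), 80)
  expect_true(all(rep_$comorbidities$cohort_pct >= 0 &
                    rep_$comorbidities$cohort_pct <= 100))
  expect_true(all(rep_$sofa_trend$day %in% 1:7))
  expect_true(all(c("welch_anova", "chi_square") %in% rep_$tests$test))
})
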