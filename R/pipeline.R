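# End-to-end orchestration: simulate/ingest -> preprocess -> mine ->
# (optional tuning) -> factorize -> representatives -> validate -> profile,
# driven by one validated configuration with a master seed feeding named
# per-stage substreams, and a run manifest with artifact hashes.

#' Default pipeline configuration
#'
#' Returns the full configuration list with study defaults: 6-h windows,
#' minimum support 5, subgraph sizes 2-6, level clip 4, k = 3, 80:20
#' mortality-stratified split. Override any field via `...` or by editing
#' the returned list; [run_pipeline()] validates it.
#'
#' @param ... named overrides.
#' @return named list of class `run_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_patients = 300, seed = 1L, cohort_dir = NULL, out_dir = NULL,
    interval = 6, min_support = 5, min_size = 2, max_size = 6, clip = 4,
    k = 3, tune = FALSE, k_grid = 2:6, tune_intervals = c(6, 24),
    tune_supports = c(5, 15, 25, 50, 100),
    n_runs = 30, max_iter = 200, tol = 1e-5,
    top_n = 100, threshold = 1.0, split_ratio = 0.8,
    nrounds = 300, max_depth = 3, eta = 0.1,
    stages = c("simulate", "prep", "mine", "factorize", "represent",
               "validate", "profile")
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys override [pipeline_config()] defaults.
#' @return `run_config` list.
#' @export
read_config <- function(path) {
  over <- yaml::read_yaml(path)
  do.call(pipeline_config, over)
}

validate_config <- function(cfg) {
  if (cfg$min_support < 1) stop("config invalid: min_support must be >= 1")
  if (cfg$min_size < 1 || cfg$min_size > cfg$max_size) {
    stop("config invalid: need 1 <= min_size <= max_size")
  }
  if (!cfg$interval %in% c(6, 24)) stop("config invalid: interval must be 6 or 24")
  if (cfg$k < 2) stop("config invalid: k must be >= 2")
  if (cfg$split_ratio <= 0 || cfg$split_ratio >= 1) {
    stop("config invalid: split_ratio must lie in (0, 1)")
  }
  if (cfg$clip < 1) stop("config invalid: clip must be >= 1")
  if (is.null(cfg$cohort_dir) && (is.null(cfg$n_patients) || cfg$n_patients < 3)) {
    stop("config invalid: n_patients must be >= 3 when simulating")
  }
  invisible(cfg)
}

# named per-stage substreams derived from the master seed (kept < 2^31)
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, split = 23L, nmf = 37L, tune = 41L,
               validate_split = 53L, membership = 61L, mortality = 71L)
  (as.integer(seed) * 101L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full phenotyping pipeline
#'
#' Executes the enabled stages in fixed order on a synthetic or ingested
#' cohort; every source of randomness derives from `config$seed` through
#' named substreams, so identical configurations reproduce identical
#' artifacts. A manifest (configuration snapshot, per-stage counts,
#' artifact hashes) is written to `out_dir` even when a stage fails, with
#' the failed stage recorded.
#'
#' @param config a `run_config` from [pipeline_config()] /
#'   [read_config()].
#' @return list with the stage artifacts (`cohort`, `prep`, `matrix`,
#'   `tuning`, `fit`, `representatives`, `validation`, `profile`) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("sanmf_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config), "archetype")],
                   stages = list(), failed_stage = NULL,
                   version = as.character(utils::packageVersion("sanmf")))
  res <- list()
  current_stage <- NA_character_
  finish <- function() {
    files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    files <- setdiff(files, file.path(out_dir, "manifest.json"))
    hashes <- tools::md5sum(files)
    names(hashes) <- substring(names(hashes), nchar(out_dir) + 2)
    manifest$artifact_hashes <<- as.list(hashes)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    current_stage <<- stage
    fn()
  }
  tryCatch({
    run("simulate", function() {
      if (!is.null(config$cohort_dir)) {
        res$cohort <<- read_cohort(config$cohort_dir)
      } else {
        spec <- make_paperlike_spec(config$n_patients,
                                    seed = stage_seed(config$seed, "simulate"))
        res$cohort <<- generate_cohort(spec)
      }
      write_cohort(res$cohort, file.path(out_dir, "cohort"))
      manifest$stages$simulate <<- list(
        n_patients = nrow(res$cohort$patients),
        n_records = nrow(res$cohort$records))
    })
    run("prep", function() {
      res$prep <<- prep_stage(res$cohort$records, interval = config$interval,
                              clip = config$clip)
      write_levels(res$prep$levels, file.path(out_dir, "levels.csv"))
      manifest$stages$prep <<- list(
        n_chains = nrow(unique(res$prep$levels[, c("patient_id", "variable")])),
        n_outliers_removed = res$prep$n_removed)
    })
    run("mine", function() {
      res$matrix <<- assemble_matrix(
        res$prep$corpora, patients = res$cohort$patients$patient_id,
        min_support = config$min_support, min_size = config$min_size,
        max_size = config$max_size)
      write_count_matrix(res$matrix, file.path(out_dir, "matrix"))
      manifest$stages$mine <<- list(
        n_mined = attr(res$matrix, "n_mined"),
        n_dropped = attr(res$matrix, "n_dropped"),
        n_retained = attr(res$matrix, "n_retained"))
    })
    if (isTRUE(config$tune) && "factorize" %in% config$stages) {
      current_stage <- "tune"
      mort <- stats::setNames(res$cohort$patients$mortality_30d,
                              res$cohort$patients$patient_id)
      split <- split_cohort(res$cohort$patients$patient_id, mort,
                            ratio = config$split_ratio,
                            seed = stage_seed(config$seed, "split"))
      builder <- function(interval, support) {
        pr <- if (interval == config$interval) res$prep else
          prep_stage(res$cohort$records, interval = interval, clip = config$clip)
        corp <- lapply(pr$corpora, function(cp) {
          keep <- cp$patients %in% split$train
          list(patients = cp$patients[keep], chains = cp$chains[keep, , drop = FALSE])
        })
        assemble_matrix(corp, patients = split$train, min_support = support,
                        min_size = config$min_size, max_size = config$max_size)
      }
      res$tuning <- select_hyperparameters(
        builder, intervals = config$tune_intervals,
        supports = config$tune_supports, ks = config$k_grid,
        n_runs = config$n_runs, seed = stage_seed(config$seed, "tune"),
        max_iter = config$max_iter, tol = config$tol, top_n = config$top_n)
      utils::write.csv(res$tuning$scores, file.path(out_dir, "tuning.csv"),
                       row.names = FALSE)
      manifest$stages$tune <- res$tuning$best
    }
    run("factorize", function() {
      res$fit <<- sanmf(res$matrix, k = config$k, n_runs = config$n_runs,
                        max_iter = config$max_iter, tol = config$tol,
                        seed = stage_seed(config$seed, "nmf"))
      write_sanmf(res$fit, file.path(out_dir, "model"))
      manifest$stages$factorize <<- list(
        cophenetic_rho = res$fit$cophenetic_rho,
        objective = res$fit$objective,
        sizes = as.integer(table(factor(res$fit$assignment,
                                        levels = seq_len(config$k)))))
    })
    run("represent", function() {
      res$representatives <<- select_representatives(
        res$fit, top_n = config$top_n, threshold = config$threshold)
      write_representatives(res$representatives,
                            file.path(out_dir, "representatives.csv"),
                            subgraph_info = res$matrix$subgraphs)
      ex <- exclusivity_summary(res$representatives)
      manifest$stages$represent <<- list(n_unique = ex$n_unique,
                                         n_exclusive = ex$n_exclusive)
    })
    run("validate", function() {
      pats <- res$cohort$patients
      mort <- stats::setNames(pats$mortality_30d, pats$patient_id)
      split <- split_cohort(pats$patient_id, mort, ratio = config$split_ratio,
                            seed = stage_seed(config$seed, "validate_split"))
      arts <- list(matrix = res$matrix,
                   representatives = res$representatives,
                   sofa = res$cohort$sofa,
                   comorbidities = res$cohort$comorbidities)
      fs_sub <- build_features("representative_subgraphs", arts, pats$patient_id)
      fs_sofa <- build_features("mean_sofa_7d", arts, pats$patient_id)
      fs_elix <- build_features("elixhauser_index", arts, pats$patient_id)
      memb <- train_membership_classifier(
        fs_sub, res$fit$assignment, split, nrounds = config$nrounds,
        max_depth = config$max_depth, eta = config$eta,
        seed = stage_seed(config$seed, "membership"))
      mm <- lapply(list(subgraphs = fs_sub, sofa = fs_sofa, elixhauser = fs_elix),
                   function(fs) train_mortality_model(
                     fs, mort, split, nrounds = config$nrounds,
                     max_depth = config$max_depth, eta = config$eta,
                     seed = stage_seed(config$seed, "mortality")))
      bench <- compare_benchmarks(mm)
      res$validation <<- list(split = split, membership = memb,
                              mortality = mm, benchmark = bench)
      utils::write.csv(memb$metrics, file.path(out_dir, "membership_metrics.csv"),
                       row.names = FALSE)
      utils::write.csv(bench$table, file.path(out_dir, "mortality_benchmark.csv"),
                       row.names = FALSE)
      acc <- memb$metrics
      manifest$stages$validate <<- list(
        membership_test_accuracy =
          acc$value[acc$measure == "accuracy" & acc$split == "test"],
        mortality_test_auc = stats::setNames(
          as.list(bench$table$test_auc), bench$table$feature_set),
        subgraphs_first = bench$subgraphs_first)
    })
    run("profile", function() {
      res$profile <<- profile_subgroups(res$cohort$patients, res$cohort$sofa,
                                        res$cohort$comorbidities,
                                        res$fit$assignment)
      utils::write.csv(res$profile$demographics,
                       file.path(out_dir, "demographics.csv"), row.names = FALSE)
      utils::write.csv(res$profile$sofa_trend,
                       file.path(out_dir, "sofa_trend.csv"), row.names = FALSE)
      utils::write.csv(res$profile$comorbidities,
                       file.path(out_dir, "comorbidities.csv"), row.names = FALSE)
      utils::write.csv(res$profile$tests,
                       file.path(out_dir, "tests.csv"), row.names = FALSE)
      manifest$stages$profile <<- list(
        n_comorbidity_categories = nrow(res$profile$comorbidities))
    })
  }, error = function(e) {
    manifest$failed_stage <<- current_stage
    finish()
    stop("pipeline stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  finish()
  res$manifest <- manifest
  res$out_dir <- out_dir
  res
}
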