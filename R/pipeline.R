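default_config <- function() {
  list(
    n_disease = 20L, n_control = 20L, dims = c(6L, 7L, 6L),
    n_informative = 20L, effect_size = 0.3, noise_sd = 0.05,
    baseline_smoothness = 2, layout = "blob",
    cohort_seed = 1L, split_seed = 2L, survey_seed = 3L,
    tol = 1e-12, g = 10L, extremum_tol = 1e-9,
    ratios = c(6, 2, 2), allow_custom_split = FALSE,
    n_surveys = 200L, n_repetitions = 10L,
    baseline_columns = "selected",
    models = c("linear", "lasso", "pls", "svm", "rs_svm"),
    cohort_path = NULL, out = "rssvm-run")
}

#' Validate and complete a pipeline configuration
#'
#' Fills documented defaults into a raw configuration (an R list or
#' a YAML file path) and checks cross-field constraints; every
#' violation is reported with the offending field named. All
#' randomness in a run flows from the three named seeds
#' (cohort_seed, split_seed, survey_seed).
#'
#' @param raw named list of overrides, or path to a YAML file;
#'   \code{NULL} or an empty file yields all defaults.
#' @return a validated \code{run_config} list.
#' @export
validate_config <- function(raw = NULL) {
  if (is.character(raw) && length(raw) == 1L) {
    if (!file.exists(raw)) stop("config file not found: ", raw)
    raw <- yaml::read_yaml(raw)
  }
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a named list or YAML file")
  unknown <- setdiff(names(raw), names(default_config()))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(default_config(), raw)
  chk <- function(ok, field, msg)
    if (!ok) stop("config field '", field, "': ", msg)
  chk(length(cfg$dims) == 3 && all(cfg$dims >= 1), "dims",
      "must be three positive integers")
  chk(cfg$n_disease >= 1 && cfg$n_control >= 1, "n_disease/n_control",
      "must be at least 1")
  chk(cfg$n_informative >= 0 &&
        cfg$n_informative <= prod(cfg$dims), "n_informative",
      "must be between 0 and the voxel count")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be nonnegative")
  for (s in c("cohort_seed", "split_seed", "survey_seed"))
    chk(is.numeric(cfg[[s]]) && cfg[[s]] >= 0, s,
        "must be a nonnegative integer")
  chk(cfg$tol >= 0, "tol", "must be nonnegative")
  chk(cfg$g >= 1, "g", "must be at least 1")
  chk(cfg$n_surveys >= 1, "n_surveys", "must be at least 1")
  chk(cfg$n_repetitions >= 1, "n_repetitions", "must be at least 1")
  if (!isTRUE(cfg$allow_custom_split))
    chk(length(cfg$ratios) == 3 && all(cfg$ratios == c(6, 2, 2)),
        "ratios", "must be (6, 2, 2) unless allow_custom_split is set")
  chk(cfg$baseline_columns %in% c("selected", "all"),
      "baseline_columns", "must be 'selected' or 'all'")
  if (!is.null(cfg$cohort_path))
    chk(dir.exists(cfg$cohort_path), "cohort_path",
        paste0("directory does not exist: ", cfg$cohort_path))
  structure(cfg, class = "run_config")
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

#' Run the full pipeline: simulate, prep, bounds, select, compare
#'
#' Chains every stage -- cohort simulation (or loading), group
#' matrices and voxel-pair deletion, similarity bounds, the
#' random-survey SVM selection, and the five-model repeated
#' comparison -- writing each intermediate artifact plus a
#' provenance manifest into one run directory. Re-running with an
#' identical configuration reproduces every numeric output.
#'
#' @param config a \code{run_config} from [validate_config()] (a raw
#'   list is validated first).
#' @return the run directory path, invisibly; artifacts: cohort/,
#'   pairs.tsv, bounds.json, result.json, history.tsv, metrics.tsv,
#'   accuracy_curves.tsv, roc.tsv, auc.json, manifest.json.
#' @export
full_run <- function(config = list()) {
  cfg <- if (inherits(config, "run_config")) config
         else validate_config(config)
  out <- cfg$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))

  cohort <- stage("simulate", {
    if (!is.null(cfg$cohort_path)) load_cohort(cfg$cohort_path)
    else {
      co <- generate_cohort(cfg$n_disease, cfg$n_control, cfg$dims,
                            cfg$n_informative, cfg$effect_size,
                            cfg$noise_sd, cfg$baseline_smoothness,
                            cfg$layout, seed = cfg$cohort_seed)
      save_cohort(co, file.path(out, "cohort"))
      co
    }
  })
  prep <- stage("prep", {
    gm <- compute_group_matrices(cohort)
    pairs <- build_voxel_pairs(gm$M, gm$N, tol = cfg$tol)
    write_tsv(as.data.frame(pairs), file.path(out, "pairs.tsv"))
    list(pairs = pairs,
         features = assemble_feature_matrix(cohort, pairs))
  })
  bounds <- stage("bounds", {
    b <- feature_count_bounds(
      block_similarity(prep$pairs, g = min(cfg$g, nrow(prep$pairs))),
      extremum_tol = cfg$extremum_tol)
    jsonlite::write_json(
      list(c_max = b$c_max, c_min = b$c_min,
           extremum_tol = b$extremum_tol, g = b$g,
           n_voxels = b$n_voxels, swapped = b$swapped),
      file.path(out, "bounds.json"), auto_unbox = TRUE, digits = NA)
    b
  })
  rs <- stage("select", {
    split <- split_dataset(length(prep$features$y), prep$features$y,
                           ratios = cfg$ratios, seed = cfg$split_seed)
    res <- run_rs_svm(prep$features, bounds, split,
                      n_surveys = cfg$n_surveys,
                      seed = cfg$survey_seed)
    write_tsv(res$history, file.path(out, "history.tsv"))
    jsonlite::write_json(
      list(R = res$best$survey$R, l = res$best$survey$l,
           voxel_index = res$best$voxel_index,
           best_params = as.list(res$best$best_params),
           val_accuracy = res$best$val_accuracy,
           test_accuracy = res$best$test_accuracy,
           split_seed = cfg$split_seed, survey_seed = cfg$survey_seed),
      file.path(out, "result.json"), auto_unbox = TRUE, digits = NA)
    res
  })
  cmp <- stage("evaluate", {
    rep <- compare_models(prep$features, bounds, models = cfg$models,
                          n_repetitions = cfg$n_repetitions,
                          seed = cfg$split_seed,
                          n_surveys = cfg$n_surveys,
                          baseline_columns = cfg$baseline_columns)
    write_tsv(rep$metrics, file.path(out, "metrics.tsv"))
    acc <- rep$accuracy[rep$accuracy$split == "test",
                        c("repetition", "model", "accuracy")]
    write_tsv(acc, file.path(out, "accuracy_curves.tsv"))
    write_tsv(rep$roc, file.path(out, "roc.tsv"))
    jsonlite::write_json(as.list(rep$auc), file.path(out, "auc.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })
  manifest <- list(
    package = "rssvm",
    version = as.character(utils::packageVersion("rssvm")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(cfg),
    seeds = list(cohort = cfg$cohort_seed, split = cfg$split_seed,
                 survey = cfg$survey_seed))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
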