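#' Assemble an end-to-end run configuration
#'
#' Collects every knob of the simulate / extract / evaluate /
#' filter-report pipeline into one serializable object. All randomness
#' downstream derives per-stage sub-seeds from the single global `seed`
#' (the stage name is hashed into the stream), so individual stages are
#' independently reproducible. Numeric scalars are stored as doubles so
#' a configuration survives a JSON/YAML round trip unchanged.
#'
#' @param plate A [plate_config()] or a list of overrides for one.
#' @param features List: `n_shells`, `cutoff`, `window`, `log_power`.
#' @param task_id Classification task (1 or 2).
#' @param day Acquisition day evaluated/filtered; `NULL` = latest
#'   configured day.
#' @param classifier List: `n_pc`, `ntree`, `threshold`, `scale`.
#' @param cv List: `n_folds`, `n_repeats`.
#' @param stages Character subset of
#'   `c("simulate", "extract", "evaluate", "filter_report")`, executed in
#'   that order.
#' @param write_images Write rendered frames as PNG files (default
#'   `FALSE`: frames are kept in memory for the extract stage only).
#' @param seed Global integer seed.
#' @return A list of class `"run_config"`.
#' @examples
#' cfg <- run_config(plate = list(n_wells = 8, image_height = 64,
#'                                image_width = 64))
#' cfg$task_id
#' @export
run_config <- function(plate = list(),
                       features = list(),
                       task_id = 2,
                       day = NULL,
                       classifier = list(),
                       cv = list(),
                       stages = c("simulate", "extract", "evaluate",
                                  "filter_report"),
                       write_images = FALSE,
                       seed = 1) {
  if (inherits(plate, "plate_config")) plate <- unclass(plate)
  plate_cfg <- do.call(plate_config, plate)
  feat <- utils::modifyList(list(n_shells = 100, cutoff = 30,
                                 window = FALSE, log_power = FALSE), features)
  clf <- utils::modifyList(list(n_pc = 10, ntree = 100, threshold = 0.5,
                                scale = FALSE), classifier)
  cvv <- utils::modifyList(list(n_folds = 4, n_repeats = 50), cv)
  bad <- setdiff(stages, c("simulate", "extract", "evaluate", "filter_report"))
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  cfg <- list(plate = normalize_numeric(unclass(plate_cfg)),
              features = normalize_numeric(feat),
              task_id = as.numeric(task_id),
              day = if (is.null(day)) NULL else as.numeric(day),
              classifier = normalize_numeric(clf),
              cv = normalize_numeric(cvv),
              stages = stages,
              write_images = isTRUE(write_images),
              seed = as.numeric(seed))
  class(cfg) <- "run_config"
  cfg
}

# Coerce all numeric leaves of a nested list to double so that a
# serialize/parse cycle (which may re-type integers) is the identity.
normalize_numeric <- function(x) {
  if (is.list(x)) return(lapply(x, normalize_numeric))
  if (is.numeric(x)) return(as.numeric(x))
  x
}

#' Read and write run configurations
#'
#' Serialization round trip for [run_config()] objects: JSON (`.json`)
#' or YAML (`.yml`/`.yaml`), chosen by file extension.
#' `read_run_config(write_run_config(cfg, path))` reproduces `cfg`
#' exactly.
#'
#' @param config A [run_config()].
#' @param path File path ending in `.json`, `.yml` or `.yaml`.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  ext <- tolower(tools::file_ext(path))
  payload <- unclass(config)
  if (ext == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(payload, path)
  } else stopf("unsupported config extension '.%s' (use json/yml/yaml)", ext)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else stopf("unsupported config extension '.%s' (use json/yml/yaml)", ext)
  run_config(plate = raw$plate,
             features = raw$features,
             task_id = raw$task_id,
             day = raw$day,
             classifier = raw$classifier,
             cv = raw$cv,
             stages = unlist(raw$stages),
             write_images = isTRUE(raw$write_images),
             seed = raw$seed)
}

#' Run the pipeline end to end
#'
#' Executes the selected stages in order — simulate (synthetic plate),
#' extract (spectral feature table), evaluate (repeated well-grouped CV
#' for the configured task and day), filter_report (pooled out-of-fold
#' filter metrics) — writing each stage's outputs under `out_dir` and a
#' `manifest.json` recording the configuration, per-stage seeds, and an
#' MD5 content hash of every output file. A failed stage halts all
#' downstream stages; the manifest records the failure point.
#'
#' Rerunning with the same configuration and output directory reproduces
#' every output bitwise.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results
#'   (`dataset`, `features`, `cv`, `filter_report`) and the `manifest`.
#' @examples
#' \donttest{
#' cfg <- run_config(plate = list(n_wells = 8, acquisition_days = c(14, 38),
#'                                positions_per_well = 2,
#'                                image_height = 64, image_width = 64),
#'                   cv = list(n_repeats = 2))
#' res <- run_pipeline(cfg, out_dir = tempfile("run"))
#' names(res$manifest$outputs)
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  manifest <- list(package_version = as.character(utils::packageVersion("myospect")),
                   config = unclass(config),
                   seeds = list(),
                   outputs = list(),
                   status = "running", failed_stage = NULL)
  results <- list()
  outputs <- character(0)
  record <- function(path) outputs <<- c(outputs, path)
  finish <- function(status, failed = NULL) {
    manifest$status <<- status
    manifest$failed_stage <<- failed
    manifest$outputs <<- as.list(tools::md5sum(outputs))
    path <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  task <- task_spec(config$task_id)
  day <- if (is.null(config$day)) max(config$plate$acquisition_days)
         else config$day
  stages <- config$stages
  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      finish("failed", failed = name)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  run_stage("simulate", function() {
    seed <- derive_seed(config$seed, "simulate")
    manifest$seeds$simulate <<- seed
    plate <- do.call(plate_config,
                     utils::modifyList(config$plate, list(seed = seed)))
    img_dir <- if (config$write_images) file.path(out_dir, "images") else NULL
    results$dataset <<- generate_dataset(plate, dir = img_dir)
    path <- file.path(out_dir, "outcomes.csv")
    utils::write.csv(results$dataset$outcomes, path, row.names = FALSE)
    record(path)
    if (config$write_images) {
      record(file.path(img_dir, "metadata.csv"))
      record(results$dataset$metadata$file_path)
    }
  })

  run_stage("extract", function() {
    if (is.null(results$dataset))
      stopf("extract requires the simulate stage (or pre-rendered images)")
    src <- if (is.null(results$dataset$images))
      results$dataset$metadata$file_path else results$dataset
    meta <- if (is.character(src)) results$dataset$metadata else NULL
    results$features <<- batch_extract(src, metadata = meta,
                                       n_shells = config$features$n_shells,
                                       window = config$features$window,
                                       log_power = config$features$log_power)
    path <- file.path(out_dir, "features.csv")
    utils::write.csv(results$features, path, row.names = FALSE)
    record(path)
  })

  run_stage("evaluate", function() {
    if (is.null(results$features)) stopf("evaluate requires the extract stage")
    seed <- derive_seed(config$seed, "evaluate")
    manifest$seeds$evaluate <<- seed
    cv <- repeated_cv(results$features, results$dataset$outcomes, task,
                      day = day,
                      n_folds = config$cv$n_folds,
                      n_repeats = config$cv$n_repeats,
                      seed = seed,
                      n_pc = config$classifier$n_pc,
                      ntree = config$classifier$ntree,
                      scale = config$classifier$scale)
    results$cv <<- cv
    long <- file.path(out_dir, "cv_folds.csv")
    utils::write.csv(cv$folds, long, row.names = FALSE)
    record(long)
    summ <- data.frame(task = task$task_id, day = day,
                       n_repeats = cv$n_repeats, n_folds = cv$n_folds,
                       median_avg_auc = stats::median(cv$avg_auc),
                       mean_avg_auc = mean(cv$avg_auc),
                       q25 = stats::quantile(cv$avg_auc, 0.25),
                       q75 = stats::quantile(cv$avg_auc, 0.75))
    spath <- file.path(out_dir, "cv_summary.csv")
    utils::write.csv(summ, spath, row.names = FALSE)
    record(spath)
  })

  run_stage("filter_report", function() {
    if (is.null(results$features))
      stopf("filter_report requires the extract stage")
    seed <- derive_seed(config$seed, "filter")
    manifest$seeds$filter_report <<- seed
    fr <- oof_filter_report(results$features, results$dataset$outcomes, task,
                            day = day,
                            n_folds = config$cv$n_folds,
                            seed = seed,
                            threshold = config$classifier$threshold,
                            n_pc = config$classifier$n_pc,
                            ntree = config$classifier$ntree,
                            scale = config$classifier$scale)
    results$filter_report <<- fr
    path <- file.path(out_dir, "filter_report.json")
    payload <- unclass(fr)
    payload$task <- unclass(payload$task)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    record(path)
    wpath <- file.path(out_dir, "filter_report.txt")
    writeLines(waffle_text(fr), wpath)
    record(wpath)
  })

  finish("complete")
  results$manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                          simplifyVector = TRUE)
  invisible(results)
}

# Text waffle summary: 100 squares per pool, '#' = task-positive share.
waffle_text <- function(fr) {
  pool_grid <- function(label, prop) {
    n_pos <- round(100 * prop)
    cells <- c(rep("#", n_pos), rep(".", 100 - n_pos))
    rows <- apply(matrix(cells, nrow = 10, byrow = TRUE), 1, paste,
                  collapse = "")
    c(sprintf("%s (%.1f%% positive):", label, 100 * prop), rows, "")
  }
  c(sprintf("Task %d filter waffle (each square = 1%% of the pool)",
            fr$task$task_id),
    "",
    pool_grid("Input", fr$impurity_before),
    pool_grid("Retained pool", fr$impurity_after),
    sprintf("impurity change %.3f, p = %.3g", fr$impurity_change, fr$p_value))
}
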