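# Pipeline driver: a declarative run configuration (YAML-compatible) and
# the simulate / preprocess / train / evaluate / ablate commands tying the
# modules together, with a provenance record per run.

#' Run configuration
#'
#' All pipeline defaults in one declarative object: the study protocol's
#' hyperparameters (30 epochs, batch 256, learning rate 0.001, weight decay
#' 0.0005, dropout 0.5), 200 ms / 50 ms windows, the 10-500 Hz band-pass and
#' the {1,3,4,6}/{2,5} repetition split.
#'
#' @param source `"synthetic"` (generate sessions in-package) or
#'   `"fixtures"` (read `.mat` files from `fixtures_dir`).
#' @param synthetic list of [synthetic_config()] arguments.
#' @param fixtures_dir directory of `.mat` session files when
#'   `source = "fixtures"`.
#' @param window_T_ms,window_S_ms sliding-window length and step (ms).
#' @param filter_order,filter_band_hz band-pass parameters.
#' @param preset model preset, `"small"` (default) or `"full"`.
#' @param dropout,use_attention model head options.
#' @param train list of [train_config()] overrides.
#' @param train_reps,test_reps,include_rest split options.
#' @param out_dir artifact directory.
#' @param seed master seed for the run.
#' @param verbose print progress?
#' @return object of class `run_config`.
#' @export
run_config <- function(source = c("synthetic", "fixtures"),
                       synthetic = list(preset = "desk"), fixtures_dir = NULL,
                       window_T_ms = 200, window_S_ms = 50,
                       filter_order = 4, filter_band_hz = c(10, 500),
                       preset = c("small", "full"), dropout = 0.5,
                       use_attention = TRUE, train = list(),
                       train_reps = c(1, 3, 4, 6), test_reps = c(2, 5),
                       include_rest = FALSE, out_dir = "emgfuse-out",
                       seed = 1, verbose = FALSE) {
  source <- match.arg(source)
  preset <- match.arg(preset)
  if (source == "fixtures" && is.null(fixtures_dir))
    abort_arg("config field 'fixtures_dir' is required when source = 'fixtures'")
  structure(list(source = source, synthetic = synthetic,
                 fixtures_dir = fixtures_dir,
                 window_T_ms = window_T_ms, window_S_ms = window_S_ms,
                 filter_order = filter_order, filter_band_hz = filter_band_hz,
                 preset = preset, dropout = dropout,
                 use_attention = isTRUE(use_attention), train = train,
                 train_reps = train_reps, test_reps = test_reps,
                 include_rest = isTRUE(include_rest),
                 out_dir = out_dir, seed = as.integer(seed),
                 verbose = isTRUE(verbose)), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Unknown top-level fields raise an error naming the first offending field.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file's values.
#' @return a [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) abort_arg("config file '%s' does not exist", path)
  vals <- yaml::read_yaml(path) %||% list()
  vals[names(overrides)] <- overrides
  allowed <- names(formals(run_config))
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0) abort_arg("unknown config field '%s'", bad[1])
  do.call(run_config, vals)
}

.cfg_synth <- function(config) {
  args <- config$synthetic %||% list()
  args$seed <- args$seed %||% config$seed
  do.call(synthetic_config, args)
}

.cfg_sessions <- function(config) {
  if (config$source == "synthetic") {
    sc <- .cfg_synth(config)
    lapply(seq_len(sc$n_subjects), function(i)
      generate_session(sc, sprintf("S%02d", i)))
  } else {
    files <- sort(list.files(config$fixtures_dir, pattern = "\\.mat$",
                             full.names = TRUE))
    if (length(files) == 0)
      abort_arg("no .mat fixtures found in '%s'", config$fixtures_dir)
    lapply(files, read_session)
  }
}

.cfg_train <- function(config) {
  args <- config$train %||% list()
  args$seed <- args$seed %||% config$seed
  args$dropout <- args$dropout %||% config$dropout
  args$verbose <- args$verbose %||% config$verbose
  do.call(train_config, args)
}

.cfg_preprocess <- function(config, session) {
  preprocess_session(
    session,
    filter_spec(config$filter_order, config$filter_band_hz),
    window_spec(config$window_T_ms, config$window_S_ms, session$sampling_rate_hz),
    config$train_reps, config$test_reps, config$include_rest)
}

write_provenance <- function(config, command, extra = list()) {
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  rec <- c(list(command = command,
                package = "emgfuse",
                version = as.character(utils::packageVersion("emgfuse")),
                seed = config$seed,
                config_md5 = unname(tools::md5sum(cfg_path)),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
           extra)
  jsonlite::write_json(rec, file.path(config$out_dir,
                                      sprintf("provenance-%s.json", command)),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}

#' Run a pipeline command
#'
#' \describe{
#'   \item{`simulate`}{generate synthetic sessions and write one DB2-layout
#'     `.mat` fixture per subject under `out_dir/fixtures/`.}
#'   \item{`preprocess`}{filter, normalize and segment every session into
#'     paired window sets (`out_dir/windows/subjectXX.rds`).}
#'   \item{`train`}{train the configured model per subject; writes
#'     checkpoints and history tables.}
#'   \item{`evaluate`}{evaluate saved checkpoints on the test partitions;
#'     writes per-subject accuracies, the summed confusion matrix and a
#'     plain-text summary.}
#'   \item{`ablate`}{run [run_ablation()] over the configured conditions.}
#' }
#' Every command writes a provenance record (config hash, seed, package
#' version) to `out_dir`.
#'
#' @param command one of `"simulate"`, `"preprocess"`, `"train"`,
#'   `"evaluate"`, `"ablate"`.
#' @param config a [run_config()].
#' @param conditions ablation conditions (for `"ablate"`).
#' @return invisibly, a list of the artifact paths written.
#' @export
run_command <- function(command = c("simulate", "preprocess", "train",
                                    "evaluate", "ablate"),
                        config = run_config(), conditions = c("emg-only",
                                                              "acc-only", "fused")) {
  command <- match.arg(command)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)

  if (command == "simulate") {
    fdir <- file.path(config$out_dir, "fixtures")
    dir.create(fdir, showWarnings = FALSE)
    sc <- .cfg_synth(config)
    for (i in seq_len(sc$n_subjects)) {
      sid <- sprintf("S%02d", i)
      path <- file.path(fdir, paste0(sid, ".mat"))
      write_fixture(generate_session(sc, sid), path)
      artifacts <- c(artifacts, path)
    }
  } else if (command == "preprocess") {
    wdir <- file.path(config$out_dir, "windows")
    dir.create(wdir, showWarnings = FALSE)
    for (s in .cfg_sessions(config)) {
      pp <- .cfg_preprocess(config, s)
      path <- file.path(wdir, paste0(s$subject_id, ".rds"))
      saveRDS(pp, path)
      artifacts <- c(artifacts, path)
    }
  } else if (command == "train") {
    wdir <- file.path(config$out_dir, "windows")
    files <- sort(list.files(wdir, pattern = "\\.rds$", full.names = TRUE))
    if (length(files) == 0)
      abort_arg("no preprocessed windows found at '%s'; run 'preprocess' first", wdir)
    mdir <- file.path(config$out_dir, "models")
    dir.create(mdir, showWarnings = FALSE)
    cfg <- .cfg_train(config)
    for (f in files) {
      pp <- readRDS(f)
      if (length(pp$train$labels) == 0)
        abort_arg("'%s' contains no training windows", f)
      sid <- sub("\\.rds$", "", basename(f))
      n_classes <- length(unique(pp$train$labels))
      spec <- two_stream_spec(c(12, pp$window$L, 1), c(36, pp$window$L, 1),
                              n_classes, config$preset, config$dropout,
                              config$use_attention)
      fit <- train_model(spec, pp$train, cfg)
      ck <- file.path(mdir, paste0(sid, ".rds"))
      save_checkpoint(fit$model, ck)
      hist_path <- file.path(mdir, paste0(sid, "-history.csv"))
      write.csv(fit$history, hist_path, row.names = FALSE)
      artifacts <- c(artifacts, ck, hist_path)
    }
  } else if (command == "evaluate") {
    wdir <- file.path(config$out_dir, "windows")
    mdir <- file.path(config$out_dir, "models")
    files <- sort(list.files(mdir, pattern = "\\.rds$", full.names = TRUE))
    if (length(files) == 0)
      abort_arg("no model checkpoints found at '%s'; run 'train' first", mdir)
    accs <- numeric(0); conf <- NULL
    for (f in files) {
      sid <- sub("\\.rds$", "", basename(f))
      wfile <- file.path(wdir, paste0(sid, ".rds"))
      if (!file.exists(wfile))
        abort_arg("missing preprocessed windows '%s' for checkpoint '%s'", wfile, f)
      pp <- readRDS(wfile)
      model <- load_checkpoint(f)
      ev <- evaluate_model(model, pp$test)
      accs[sid] <- ev$accuracy
      conf <- if (is.null(conf)) ev$confusion else conf + ev$confusion
    }
    rep <- eval_report(accs, confusion = conf)
    acc_path <- file.path(config$out_dir, "per_subject_accuracy.csv")
    write.csv(data.frame(subject = names(accs), accuracy = unname(accs)),
              acc_path, row.names = FALSE)
    conf_path <- file.path(config$out_dir, "confusion.csv")
    write.csv(conf, conf_path)
    sum_path <- file.path(config$out_dir, "summary.txt")
    writeLines(c(sprintf("subjects: %d", length(accs)),
                 sprintf("overall accuracy: %.6f", rep$overall_acc),
                 sprintf("%s: %.6f", names(accs), accs)), sum_path)
    artifacts <- c(artifacts, acc_path, conf_path, sum_path)
  } else if (command == "ablate") {
    sessions <- .cfg_sessions(config)
    rep <- run_ablation(sessions, conditions,
                        window_T_ms = config$window_T_ms,
                        config = .cfg_train(config),
                        seeds = config$seed, preset = config$preset,
                        filter = filter_spec(config$filter_order, config$filter_band_hz),
                        S_ms = config$window_S_ms,
                        train_reps = config$train_reps, test_reps = config$test_reps)
    ab_path <- file.path(config$out_dir, "ablation.csv")
    write.csv(rep$ablation_table, ab_path, row.names = FALSE)
    grid_path <- file.path(config$out_dir, "ablation_per_subject.csv")
    write.csv(attr(rep, "per_subject_grid"), grid_path, row.names = FALSE)
    artifacts <- c(artifacts, ab_path, grid_path)
  }

  write_provenance(config, command, list(artifacts = artifacts))
  invisible(list(artifacts = artifacts,
                 provenance = file.path(config$out_dir,
                                        sprintf("provenance-%s.json", command))))
}
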