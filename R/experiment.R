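#' Configuration of a repeated-training experiment
#'
#' Bundles every setting of the end-to-end pipeline: simulator, labeling,
#' network, number of independent training repetitions, split fractions and
#' the evaluation protocol. Protocol `"split"` (default) evaluates each
#' repetition on its own held-out test split; `"paper_protocol"` evaluates
#' each repetition on the full labeled set, so the per-class supports equal
#' the full class counts and `total_tests = n_repetitions * n`.
#'
#' @param n Dataset size.
#' @param class_mix Class proportions (Good, Fair, Bad).
#' @param acq,pfgse_cfg,oxidation_params Simulator settings, see
#'   [generate_dataset()].
#' @param policy Labeling policy, see [classify_oxidation()].
#' @param model A [model_config()].
#' @param n_repetitions Number of independently seeded training sessions.
#' @param split Named fractions (train, validation, test) summing to 1.
#' @param protocol `"split"` or `"paper_protocol"`.
#' @param seed Master seed; every repetition seed derives from it.
#' @return An object of class `"experiment_config"`.
#' @export
experiment_config <- function(n = 390L,
                              class_mix = c(Good = 126, Fair = 77,
                                            Bad = 187),
                              acq = acquisition_config(),
                              pfgse_cfg = pfgse_config(),
                              oxidation_params = default_oxidation_params(),
                              policy = "worst_case",
                              model = model_config(),
                              n_repetitions = 30L,
                              split = c(train = 0.70, validation = 0.15,
                                        test = 0.15),
                              protocol = c("split", "paper_protocol"),
                              seed = 1L) {
  protocol <- match.arg(protocol)
  n_repetitions <- as.integer(n_repetitions)
  if (n_repetitions < 1) stop_invalid("n_repetitions must be >= 1")
  if (abs(sum(split) - 1) > 1e-6)
    stop_invalid("split fractions must sum to 1")
  structure(list(n = as.integer(n), class_mix = class_mix, acq = acq,
                 pfgse_cfg = pfgse_cfg, oxidation_params = oxidation_params,
                 policy = policy, model = model,
                 n_repetitions = n_repetitions, split = split,
                 protocol = protocol, seed = as.integer(seed)),
            class = "experiment_config")
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  writeLines(msg, con)
}

#' Run a repeated-training experiment
#'
#' Fig-4-style experiment driver: generates one labeled synthetic dataset,
#' audits label consistency, then runs `n_repetitions` training sessions,
#' each with its own derived seed, its own stratified split and its own
#' randomly initialized network, evaluates each per the configured protocol,
#' and aggregates the reports. All artifacts (per-repetition history and
#' report, aggregate table CSV, structured log, run manifest with seeds and
#' checksums) are written under `out_dir`.
#'
#' @param cfg An [experiment_config()].
#' @param out_dir Output directory (created; must be writable).
#' @param keep_models Save the trained weights of every repetition (default
#'   FALSE: only histories and reports are kept).
#' @return Invisibly, a list with `dataset`, `reports`, `aggregate`, `seeds`,
#'   and `paths` of the written artifacts.
#' @export
run_experiment <- function(cfg, out_dir, keep_models = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory ", out_dir)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  log_line(con, "oxirelax ", as.character(packageVersion("oxirelax")),
           " run_experiment, master seed ", cfg$seed)

  set.seed(cfg$seed)
  data_seed <- sample.int(.Machine$integer.max - 1L, 1)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_repetitions)
  log_line(con, "dataset seed ", data_seed, "; repetition seeds ",
           paste(rep_seeds, collapse = ","))

  ds <- generate_dataset(cfg$n, cfg$class_mix, cfg$acq, cfg$pfgse_cfg,
                         cfg$oxidation_params, policy = cfg$policy,
                         seed = data_seed)
  # label-consistency audit: stored class must re-derive from chemistry
  audit <- classify_oxidation(ds$manifest$d_m2_per_s,
                              ds$manifest$pv_mmol_per_kg,
                              policy = cfg$policy)
  if (!all(as.character(audit) == ds$manifest$class))
    stop("label audit failed: stored classes do not re-derive from chemistry")
  log_line(con, "dataset of ", cfg$n, " samples generated; label audit OK")

  y <- ds$manifest$class
  X <- preprocess_input(ds, cfg$model$target_len)
  reports <- vector("list", cfg$n_repetitions)
  paths <- list(log = log_path)
  for (r in seq_len(cfg$n_repetitions)) {
    rs <- rep_seeds[r]
    set.seed(rs)
    idx <- stratified_split(y, cfg$split)
    fit <- oxinet(X[c(idx$train, idx$validation), , drop = FALSE],
                  y[c(idx$train, idx$validation)], config = cfg$model,
                  validation = seq_along(idx$validation) +
                    length(idx$train),
                  seed = rs)
    eval_idx <- if (cfg$protocol == "paper_protocol") seq_along(y)
                else idx$test
    pred <- predict(fit, X[eval_idx, , drop = FALSE])
    reports[[r]] <- eval_report(y[eval_idx], pred)
    rep_dir <- file.path(out_dir, sprintf("rep%02d", r))
    dir.create(rep_dir, showWarnings = FALSE)
    write.csv(fit$history, file.path(rep_dir, "history.csv"),
              row.names = FALSE)
    rep_json <- file.path(rep_dir, "report.json")
    jsonlite::write_json(
      list(seed = rs, accuracy = reports[[r]]$accuracy,
           weighted = as.list(reports[[r]]$weighted),
           per_class = reports[[r]]$per_class,
           confusion = unclass(reports[[r]]$confusion)),
      rep_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (keep_models) save_oxinet(fit, file.path(rep_dir, "model"))
    log_line(con, sprintf(
      "repetition %d (seed %d): accuracy %.4f, weighted F1 %.4f",
      r, rs, reports[[r]]$accuracy, reports[[r]]$weighted["f1"]))
  }
  agg <- aggregate_repetitions(reports)
  paths$aggregate_csv <- file.path(out_dir, "aggregate_table.csv")
  report_table(agg, paths$aggregate_csv)
  paths$aggregate_json <- file.path(out_dir, "aggregate.json")
  jsonlite::write_json(
    list(n_repetitions = agg$n_repetitions, total_tests = agg$total_tests,
         support = as.list(agg$support), per_class = agg$per_class,
         overall_weighted = agg$overall_weighted,
         overall_micro = as.list(agg$overall_micro)),
    paths$aggregate_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "run_manifest.json"))
  manifest <- data.frame(path = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  paths$run_manifest <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(
    list(package_version = as.character(packageVersion("oxirelax")),
         master_seed = cfg$seed, data_seed = data_seed,
         repetition_seeds = rep_seeds, protocol = cfg$protocol,
         n = cfg$n, n_repetitions = cfg$n_repetitions,
         config_hash = unname(tools::md5sum(paths$aggregate_csv)),
         artifacts = manifest),
    paths$run_manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(con, "aggregate written; total tests ", agg$total_tests)
  invisible(list(dataset = ds, reports = reports, aggregate = agg,
                 seeds = list(master = cfg$seed, data = data_seed,
                              repetitions = rep_seeds),
                 paths = paths))
}

#' Classify a single curve file with a saved model
#'
#' Reads a two-column curve file, runs the trained network, and returns (and
#' optionally writes) the JSON verdict: sample id, predicted class and its
#' softmax probability, and the model version.
#'
#' @param curve_file Path to a `time_s,amplitude` CSV.
#' @param model_dir A [save_oxinet()] artifact directory, or an `"oxinet"`.
#' @param out Optional path to write the JSON verdict to.
#' @return The verdict as a named list (invisibly when `out` is given).
#' @export
classify_workflow <- function(curve_file, model_dir, out = NULL) {
  curve <- read_curve(curve_file)
  model <- if (inherits(model_dir, "oxinet")) model_dir
           else load_oxinet(model_dir)
  v <- predict(model, curve, type = "both")
  verdict <- list(sample_id = sub("\\.[^.]*$", "", basename(curve_file)),
                  class = as.character(v$class[1]),
                  probability = v$probability[1],
                  model_version = model$package_version)
  if (!is.null(out)) {
    jsonlite::write_json(verdict, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(verdict))
  }
  verdict
}
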