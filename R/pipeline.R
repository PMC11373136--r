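# Pipeline plumbing: a declarative spec (scaling -> optional feature
# selection -> model), re-fittable inside cross-validation folds so no
# preprocessing leaks, plus the end-to-end run_pipeline() driver consumed by
# the command-line wrapper.

#' Declare an ensemble to be fitted later
#'
#' Same arguments as [tox_ensemble()] minus the data; used inside
#' [pipeline_spec()] so cross-validation can refit the ensemble per fold.
#'
#' @param strategy,members,voting_mode,n_bootstrap,k_oof,seed see
#'   [tox_ensemble()].
#' @return an `ensemble_spec`.
#' @export
ensemble_spec <- function(strategy = "voting", members = NULL,
                          voting_mode = "soft", n_bootstrap = 5, k_oof = 5,
                          seed = 1) {
  structure(list(strategy = strategy, members = members,
                 voting_mode = voting_mode, n_bootstrap = n_bootstrap,
                 k_oof = k_oof, seed = seed), class = "ensemble_spec")
}

#' Declare a modelling pipeline
#'
#' @param model a `base_model_config` or an [ensemble_spec()].
#' @param scale fit and apply a min-max scaler on the training rows
#'   (default TRUE; fingerprints are unaffected by it).
#' @param selection NULL, or a list with optional `ranker`, `step_size`,
#'   `evaluator` controlling in-pipeline sequential feature elimination.
#' @return a `pipeline_spec`.
#' @export
pipeline_spec <- function(model, scale = TRUE, selection = NULL) {
  if (!inherits(model, "base_model_config") && !inherits(model, "ensemble_spec"))
    abort("model must be a base_model_config or ensemble_spec", "config_error")
  structure(list(model = model, scale = scale, selection = selection),
            class = "pipeline_spec")
}

.fit_pipeline <- function(spec, x, y, seed = 1) {
  stopifnot(inherits(spec, "pipeline_spec"))
  scaler <- NULL
  if (isTRUE(spec$scale)) {
    scaler <- fit_minmax(x)
    x <- apply_minmax(scaler, x)
  }
  selected <- NULL
  if (!is.null(spec$selection)) {
    sel <- spec$selection
    ranking <- rank_features(x, y, ranker = sel$ranker %||% "embedded_forest",
                             seed = seed)
    trace <- sequential_elimination(
      x, y, ranking, step_size = sel$step_size,
      evaluator = sel$evaluator %||% base_model("rf", seed = seed), seed = seed)
    selected <- select_optimal_subset(trace)
    x <- x[, selected, drop = FALSE]
  }
  model <- spec$model
  fit <- if (inherits(model, "base_model_config")) {
    fit_base_model(model, x, y)
  } else {
    members <- model$members %||% default_members(seed = model$seed)
    tox_ensemble(x, y, strategy = model$strategy, members = members,
                 voting_mode = model$voting_mode,
                 n_bootstrap = model$n_bootstrap, k_oof = model$k_oof,
                 seed = model$seed)
  }
  structure(list(fit = fit, scaler = scaler, selected = selected),
            class = "fitted_pipeline")
}

.predict_pipeline <- function(fp, x) {
  if (!is.null(fp$scaler)) x <- apply_minmax(fp$scaler, x)
  if (!is.null(fp$selected)) x <- x[, fp$selected, drop = FALSE]
  predict(fp$fit, x)
}

#' Read a pipeline run configuration
#'
#' YAML with blocks: `input` (path + format + column names, or
#' `synthetic: smiles` with generator arguments), `features` (kind, radius,
#' n_bits, scale), `selection` (enabled, ranker, step_size), `ensemble`
#' (strategy, mode, members, include_mlp, include_rnn), `evaluation`
#' (test_fraction, k_folds, n_repeats), `seed`, `output_dir`.
#'
#' @param path YAML file path.
#' @return the configuration list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' Execute the full workflow
#'
#' curate -> featurize -> split -> (select) -> fit ensemble -> evaluate,
#' writing all artifacts (resolved config, curated records + curation log,
#' selected features, ensemble manifest, metrics JSON/CSV, ROC points, run
#' log) into the output directory.
#'
#' @param config a `run_config` (or path to one).
#' @return invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  seed <- config$seed %||% 1
  out_dir <- config$output_dir %||% "hepatens_run"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out_dir, "run_log.txt")
  say <- function(...) cat(sprintf(...), "\n", sep = "", file = logf, append = TRUE)
  say("hepatens run, seed %d, started %s", seed, format(Sys.time()))
  yaml::write_yaml(unclass(config), file.path(out_dir, "resolved_config.yaml"))

  # stage 1: input + curation
  input <- config$input %||% list()
  rows <- if (identical(input$synthetic, "smiles")) {
    rule_labeled_smiles(n_molecules = input$n_molecules %||% 500,
                        label_noise = input$label_noise %||% 0, seed = seed)
  } else if (!is.null(input$path)) {
    read_compound_table(input$path, format = input$format,
                        smiles_col = input$smiles_col %||% "smiles",
                        label_col = input$label_col %||% "label")
  } else abort("config$input needs a path or synthetic generator", "config_error")
  curated <- curate_compounds(rows)
  write_curated(curated, file.path(out_dir, "curated.csv"),
                file.path(out_dir, "curation_log.csv"))
  say("curated: %d records, %d exclusions", nrow(curated$records),
      nrow(curated$curation_log))

  # stage 2: featurization
  feats <- config$features %||% list()
  kind <- feats$kind %||% "circular_fingerprints"
  x <- switch(kind,
    circular_fingerprints = morgan_fingerprints(curated,
                                                radius = feats$radius %||% 2,
                                                n_bits = feats$n_bits %||% 2048),
    combined_descriptors = combine_features(
      clean_features(compute_descriptors(curated, "physchem_descriptors")),
      clean_features(compute_descriptors(curated, "extended_descriptors"))),
    clean_features(compute_descriptors(curated, kind)))
  y <- curated$records$label
  say("features: %s, %d x %d", kind, nrow(x), ncol(x))

  # stage 3: split + pipeline spec
  ens <- config$ensemble %||% list()
  sel_cfg <- config$selection %||% list()
  selection <- if (isTRUE(sel_cfg$enabled))
    list(ranker = sel_cfg$ranker, step_size = sel_cfg$step_size) else NULL
  espec <- ensemble_spec(
    strategy = ens$strategy %||% "voting",
    members = default_members(seed = seed,
                              include_rnn = ens$include_rnn %||% TRUE,
                              include_mlp = ens$include_mlp %||% FALSE),
    voting_mode = ens$mode %||% "soft",
    n_bootstrap = ens$n_bootstrap %||% 5, k_oof = ens$k_oof %||% 5,
    seed = seed)
  pspec <- pipeline_spec(espec, scale = feats$scale %||% TRUE,
                         selection = selection)
  evalb <- config$evaluation %||% list()
  sp <- stratified_split(y, evalb$test_fraction %||% 0.2, seed = seed)

  # stage 4: fit
  fp <- .fit_pipeline(pspec, x[sp$train_idx, , drop = FALSE], y[sp$train_idx],
                      seed = seed)
  if (!is.null(fp$selected))
    writeLines(fp$selected, file.path(out_dir, "selected_features.txt"))
  manifest <- list(strategy = espec$strategy, mode = espec$voting_mode,
                   members = vapply(espec$members, function(m) m$algorithm,
                                    character(1)),
                   n_features = if (is.null(fp$selected)) ncol(x)
                                else length(fp$selected),
                   seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "ensemble_manifest.json"),
                       auto_unbox = TRUE)

  # stage 5: evaluate on the held-out rows
  p <- .predict_pipeline(fp, x[sp$test_idx, , drop = FALSE])
  y_te <- y[sp$test_idx]
  met <- classification_metrics(confusion_counts(y_te, predict_label(p)),
                                scores = p, y_true = y_te)
  jsonlite::write_json(met, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(met), file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(roc_curve(y_te, p), file.path(out_dir, "roc.csv"),
                   row.names = FALSE)
  say("holdout metrics: accuracy %.4f, auc %.4f", met$accuracy, met$auc)
  say("finished %s", format(Sys.time()))
  invisible(out_dir)
}
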