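#' Read and write the epoch container
#'
#' The container is a single RDS file (R's native serialized format, which
#' round-trips every double bit-exactly) holding the feature matrix,
#' labels, channel names, time-point count and, when present, the
#' per-stimulus trial/epoch/code table of a speller session. Labels stored
#' as `{1, 0}` are recoded to `{+1, -1}` on read, with a note.
#'
#' @param data An [epoch_dataset()].
#' @param path File path (conventionally `.rds`).
#' @param trials Optional per-stimulus tibble (`trial`, `epoch`, `code`,
#'   ...) stored alongside.
#' @param targets Optional per-trial attended characters.
#' @return `read_epoch_container()` returns a list with elements `data`,
#'   `trials` (possibly `NULL`) and `targets`.
#' @export
write_epoch_container <- function(data, path, trials = NULL, targets = NULL) {
  stopifnot(inherits(data, "epoch_dataset"))
  saveRDS(list(
    format = "p300bsbl-epochs", version = 1L,
    features = data$features, labels = data$labels,
    channel_names = data$channel_names, n_time = data$n_time,
    trials = trials, targets = targets
  ), path)
  invisible(path)
}

#' @rdname write_epoch_container
#' @export
read_epoch_container <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("cannot read epoch container '%s': %s", path, conditionMessage(e)))
  })
  if (!is.list(obj) || !identical(obj$format, "p300bsbl-epochs")) {
    abort("not a p300bsbl epoch container.")
  }
  if (!identical(obj$version, 1L)) {
    abort(sprintf("unsupported container version %s.", format(obj$version)))
  }
  if (all(obj$labels %in% c(0, 1))) {
    inform("labels coded {1,0} recoded to {+1,-1}.")
  }
  list(
    data = epoch_dataset(obj$features, obj$labels, obj$channel_names, obj$n_time),
    trials = obj$trials, targets = obj$targets
  )
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors the arguments of [run_experiment()]: top-level `seed`,
#' `mode` (`"auto"` or `"fixed_m"`), `m`, `n_epochs_used`, `out_dir`,
#' `regions` (builtin scheme name or region-file path), plus nested `fit`
#' (fields of [fit_config()]) and `sim` (fields of [p300_sim_spec()]) or
#' `data` (path to an epoch container). See
#' `system.file("extdata", "example-config.yaml", package = "p300bsbl")`
#' for a commented example.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list suitable for [run_experiment()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file '%s' not found.", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(cfg$data) && !file.exists(cfg$data)) {
    abort(sprintf("config stage: data container '%s' not found.", cfg$data))
  }
  cfg
}

#' Run a complete channel-selection experiment
#'
#' Executes the full pipeline: obtain labelled epochs (simulate a speller
#' session, or load an epoch container), fit the block-sparse model on the
#' training characters, select channels (automatically or a fixed number),
#' train the BLDA classifier on the selected channels, decode the test
#' characters and report accuracy. When simulating, the training session
#' uses `seed` and the test session `seed + 1`. Outputs (selection table,
#' EM trace, JSON summary stamped with the seed and a config hash) are
#' written to `out_dir` when given; reruns with an identical config
#' reproduce identical summaries.
#'
#' @param config Named list as produced by [read_run_config()]: fields
#'   `seed`, `mode`, `m`, `n_epochs_used`, `out_dir`, `regions`, `fit`,
#'   and either `sim` or `data`.
#' @return A list with `selection`, `fit`, `model`, `decoded`, `summary`
#'   (the summary is also what lands in `summary.json`).
#' @export
run_experiment <- function(config = list()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s': %s", name, conditionMessage(e)))
    })
  }
  seed <- as.integer(config[["seed"]] %||% 1L)
  mode <- config[["mode"]] %||% "auto"
  if (!mode %in% c("auto", "fixed_m")) abort("mode must be 'auto' or 'fixed_m'.")

  fitcfg <- stage("config", do.call(fit_config, c(config[["fit"]], list(seed = seed))))

  sess <- stage("data", {
    if (!is.null(config[["data"]])) {
      cont <- read_epoch_container(config[["data"]])
      if (is.null(cont$trials)) abort("container lacks the trial table needed for decoding.")
      list(train = cont, test = NULL)
    } else {
      simargs <- config[["sim"]] %||% list()
      train <- gen_p300_session(do.call(p300_sim_spec, c(simargs, list(seed = seed))))
      test <- gen_p300_session(do.call(p300_sim_spec, c(simargs, list(seed = seed + 1L))))
      list(train = list(data = train$data, trials = train$trials, targets = train$targets),
           test = list(data = test$data, trials = test$trials, targets = test$targets),
           layout = train$layout)
    }
  })
  if (is.null(sess$test)) {
    abort("stage 'data': running from a container needs both train and test sets; simulate instead.")
  }

  train <- sess$train
  regions <- stage("regions", {
    rg <- config[["regions"]] %||% "cap59"
    if (rg %in% c("cap59", "cap64")) builtin_region_map(rg)
    else load_region_map(rg, train$data$channel_names)
  })

  fit <- stage("fit", em_fit(train$data, regions, fitcfg))
  selection <- stage("select", select_auto(fit))
  channels <- stage("select", {
    if (mode == "fixed_m") {
      if (is.null(config[["m"]])) abort("mode 'fixed_m' needs `m`.")
      select_top_m(selection, config[["m"]])
    } else selection$selected
  })

  keep_cols <- unlist(lapply(channels, function(b) block_cols(train$data$structure, b)))
  model <- stage("train", blda_fit(train$data$features[, keep_cols, drop = FALSE],
                                   train$data$labels))
  decoded <- stage("evaluate", {
    sc <- blda_score(model, sess$test$data$features[, keep_cols, drop = FALSE])
    decode_characters(sc, sess$test$trials, sess$layout %||% speller_layout(),
                      config[["n_epochs_used"]])
  })
  acc <- stage("evaluate", accuracy(decoded$predicted, sess$test$targets))

  summary <- list(
    seed = seed, mode = mode,
    config_hash = rlang::hash(config),
    n_channels_selected = length(channels),
    selected_channels = train$data$channel_names[channels],
    accuracy_pct = acc,
    n_test_characters = length(sess$test$targets),
    em_iterations = fit$n_iter, em_converged = fit$converged,
    sigma2 = fit$sigma2, tau = fitcfg$tau, b_mode = fitcfg$b_mode
  )

  if (!is.null(config[["out_dir"]])) {
    stage("write", {
      dir.create(config[["out_dir"]], recursive = TRUE, showWarnings = FALSE)
      write_selection(selection, file.path(config[["out_dir"]], "selection.csv"),
                      file.path(config[["out_dir"]], "selected_channels.txt"))
      tr <- fit$trace
      tr$pruned <- vapply(tr$pruned, paste, "", collapse = ";")
      tr$gamma <- NULL
      write.csv(tr, file.path(config[["out_dir"]], "trace.csv"), row.names = FALSE)
      jsonlite::write_json(summary, file.path(config[["out_dir"]], "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  invisible(list(selection = selection, fit = fit, model = model,
                 decoded = decoded, summary = summary))
}
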