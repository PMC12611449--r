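#' Pipeline configuration
#'
#' Everything needed for an end-to-end run: generator parameters, the
#' analysis window and channel mode, normalization mode, model and alarm
#' settings, surrogate count and the master seed (every random draw in the
#' run flows from it).
#'
#' @param gen a `spes_gen_params` object.
#' @param window one of the [window_presets()] ids.
#' @param channel_mode "top1", "top5" or "all".
#' @param norm_mode "retrospective_interictal" or "prospective_first2h".
#' @param preprocess a `spes_preprocess_config`.
#' @param model a `spes_model_spec`.
#' @param grid a `spes_alarm_grid`.
#' @param n_surrogates shuffles per patient in the chance-level estimate.
#' @param seed master seed; defaults to the generator seed.
#' @return list of class `spes_run_config`.
#' @export
run_config <- function(gen = generator_params(),
                       window = "post_first_4000_4980",
                       channel_mode = "top5",
                       norm_mode = "retrospective_interictal",
                       preprocess = preprocess_config(),
                       model = model_spec(),
                       grid = alarm_grid(),
                       n_surrogates = 100,
                       seed = gen$seed) {
  stopifnot(window %in% window_presets()$id,
            channel_mode %in% c("top1", "top5", "all"),
            norm_mode %in% c("retrospective_interictal",
                             "prospective_first2h"))
  structure(list(gen = gen, window = window, channel_mode = channel_mode,
                 norm_mode = norm_mode, preprocess = preprocess,
                 model = model, grid = grid, n_surrogates = n_surrogates,
                 seed = as.integer(seed)),
            class = "spes_run_config")
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(cfg, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Featurize and normalize one patient end to end
#'
#' Preprocess the recording, build the feature table for the configured
#' window/channel mode and normalize it. Raises a `spescast_skip` condition
#' (caught by [run_pipeline()]) when prospective normalization is
#' infeasible for the patient.
#'
#' @param patient list with recording, schedule and seizure.
#' @param cfg a `spes_run_config`.
#' @return list(table, stats, epochs_meta).
#' @export
featurize_one <- function(patient, cfg) {
  epochs <- preprocess_patient(patient$recording, patient$schedule,
                               cfg$preprocess)
  tbl <- featurize_patient(epochs, window = cfg$window,
                           channel_mode = cfg$channel_mode,
                           onset_s = patient$seizure$onset_s)
  z <- znormalize(tbl, cfg$norm_mode)
  list(table = z$table, stats = z$stats,
       epochs_meta = list(n_epochs = length(epochs$valid),
                          n_rejected = sum(!epochs$valid),
                          n_dropped = epochs$n_dropped,
                          channels = attr(tbl, "channels")))
}

#' Run the full pipeline: simulate, preprocess, featurize, forecast, evaluate
#'
#' Generates the synthetic cohort, preprocesses every patient, extracts and
#' normalizes features, fits the leave-one-patient-out logistic forecaster,
#' grid-searches the alarm parameters on training folds and evaluates every
#' held-out patient against the 100-shuffle chance level. Patients for whom
#' the configured normalization mode is infeasible (prospective mode with
#' fewer than 5 h of pre-seizure data) are skipped from testing with a
#' logged reason; they still serve as training data in the remaining folds
#' under retrospective normalization. Fully reproducible given the seed.
#'
#' @param cfg a `spes_run_config`.
#' @param cohort optionally, a pre-generated cohort (list of patients); by
#'   default the cohort is generated from `cfg$gen`.
#' @return a `spes_eval_report` with extra elements `skipped` (data.frame of
#'   skipped patients and reasons), `per_patient_meta`, and `config_hash`.
#' @export
run_pipeline <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "spes_run_config"))
  n_patients <- if (is.null(cohort)) cfg$gen$n_patients else length(cohort)
  if (is.null(cohort) && n_patients < 2)
    stop("a cohort needs at least 2 patients (leave-one-patient-out)",
         call. = FALSE)

  tables <- list(); train_tables <- list(); meta <- list()
  onsets <- numeric(0)
  skipped <- data.frame(patient_id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_patients)) {
    # generate on demand: one continuous recording in memory at a time
    pat <- if (is.null(cohort)) generate_patient(cfg$gen, i) else
      cohort[[i]]
    id <- pat$patient_id
    onsets[id] <- pat$seizure$onset_s
    res <- tryCatch(featurize_one(pat, cfg),
                    spescast_skip = function(c) c)
    if (inherits(res, "spescast_skip")) {
      message(sprintf("%s: %s", id, conditionMessage(res)))
      skipped <- rbind(skipped,
                       data.frame(patient_id = id,
                                  reason = conditionMessage(res),
                                  stringsAsFactors = FALSE))
      # still usable for training under retrospective normalization
      cfg_retro <- cfg; cfg_retro$norm_mode <- "retrospective_interictal"
      res <- featurize_one(pat, cfg_retro)
      train_tables[[id]] <- res$table
      meta[[id]] <- res$epochs_meta
    } else {
      tables[[id]] <- res$table
      train_tables[[id]] <- res$table
      meta[[id]] <- res$epochs_meta
    }
    rm(pat, res); gc(FALSE)
  }
  if (length(tables) < 1)
    stop("no testable patients after normalization-mode screening",
         call. = FALSE)

  loso <- fit_loso_mixed(tables, train_tables, cfg$model)
  report <- evaluate_cohort(loso, onsets, cfg$grid,
                            n_surrogates = cfg$n_surrogates,
                            seed = cfg$seed)
  report$skipped <- skipped
  report$per_patient_meta <- meta
  report$config_hash <- config_hash(cfg)
  report
}

# LOSO where the tested patients may be a subset of the training pool
# (prospective mode skips short-pre-seizure patients from testing only)
fit_loso_mixed <- function(test_tables, train_tables, spec) {
  if (length(train_tables) < 2)
    stop("LOSO needs at least 2 patients", call. = FALSE)
  series <- list(); models <- list()
  for (id in names(test_tables)) {
    pool <- train_tables[setdiff(names(train_tables), id)]
    train <- do.call(rbind, lapply(pool, function(tb) {
      rows <- tb$valid & tb$label %in% c("preictal", "interictal")
      tb[rows, c(FEATURE_COLS, "label")]
    }))
    y <- as.integer(train$label == "preictal")
    if (length(unique(y)) < 2)
      stop(sprintf("training fold for held-out patient %s has a single label",
                   id), call. = FALSE)
    model <- fit_logistic(as.matrix(train[, FEATURE_COLS]), y, spec)
    models[[id]] <- model
    series[[id]] <- predict_single(model, test_tables[[id]], id)
  }
  list(series = series, models = models)
}
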