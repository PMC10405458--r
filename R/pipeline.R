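#' Assemble a full pipeline configuration
#'
#' One nested configuration drives every stage; all randomness flows from
#' the single master `seed`. Section defaults mirror the study protocol
#' (38 subjects of which 8 are reserved for adaptation, an 8:2
#' cross-validation/test split of the rest, 4-fold CV, forgetting rate 0.2,
#' 200 iterations, patience 8) and can be overridden per section.
#'
#' @param seed master integer seed.
#' @param n_adapt number of subjects reserved for incremental adaptation.
#' @param simulation,preprocess,features,selection,model named lists of
#'   overrides for the per-stage defaults.
#' @param output_dir default output directory for [run_simulate()] etc.
#' @return a `pipeline_config` nested list.
#' @export
pipeline_config <- function(seed = 1L, n_adapt = 8,
                            simulation = list(), preprocess = list(),
                            features = list(), selection = list(),
                            model = list(), output_dir = NULL) {
  base <- list(
    seed = as.integer(seed),
    n_adapt = as.integer(n_adapt),
    output_dir = output_dir,
    simulation = as.list(simulation_config(seed = seed)),
    preprocess = list(lowpass_cutoff = 6, smooth_window_s = 0.25, min_cycle_s = 0.4),
    features = list(window_s = 5, stride_s = 0.5),
    selection = list(threshold = 0.3, k = 100, latent_dim = 20,
                     ae_epochs = 200, ae_lr = 0.01),
    model = unclass(training_config(seed = seed))
  )
  for (sec in c("simulation", "preprocess", "features", "selection", "model")) {
    ov <- get(sec)
    if (length(ov)) base[[sec]] <- utils::modifyList(base[[sec]], ov)
  }
  base$simulation$seed <- base$seed
  base$model$seed <- base$seed
  structure(base, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips losslessly; every run echoes its configuration next to its
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config` returns the `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, c(
    list(seed = cfg$seed, n_adapt = cfg$n_adapt, output_dir = cfg$output_dir),
    lapply(cfg[c("simulation", "preprocess", "features", "selection", "model")],
           identity)))
}

sim_config_of <- function(config) do.call(simulation_config, config$simulation)

#' Simulate a cohort and write it to disk
#'
#' @param config a [pipeline_config()].
#' @param dir output directory (defaults to `config$output_dir`).
#' @param force overwrite an existing non-empty directory.
#' @return the manifest, invisibly.
#' @export
run_simulate <- function(config, dir = config$output_dir, force = FALSE) {
  stopifnot(!is.null(dir))
  scfg <- sim_config_of(config)
  cohort <- generate_cohort(scfg)
  manifest <- write_cohort(cohort, dir, scfg, force = force)
  write_config(config, file.path(dir, "config_echo.yaml"))
  invisible(manifest)
}

# Condition one trial end-to-end: band decomposition, feature battery, and
# staircase targets read at the window-end times.
extract_trial <- function(trial, config) {
  decomp <- decompose_trial(trial$recording)
  plan <- windowing_plan(config$features$window_s, config$features$stride_s)
  fm <- build_feature_matrix(decomp, plan)
  gait <- preprocess_gait(trial$gait,
                          cutoff = config$preprocess$lowpass_cutoff,
                          window_s = config$preprocess$smooth_window_s,
                          min_cycle_s = config$preprocess$min_cycle_s)
  list(values = fm$values, index = fm$index, target_times = fm$target_times,
       speed = window_targets(gait, fm$target_times, "speed"),
       step = window_targets(gait, fm$target_times, "step"),
       mode = trial$mode)
}

# Stack the mode-matched trials of the given subjects into one dataset.
assemble_dataset <- function(extracted, subjects, target) {
  mode <- if (target == "speed") "speed" else "stride"
  rows <- list(); metas <- list(); ys <- list()
  for (sid in subjects) {
    ex <- extracted[[as.character(sid)]][[mode]]
    if (is.null(ex)) next
    rows[[length(rows) + 1]] <- ex$values
    ys[[length(ys) + 1]] <- if (target == "speed") ex$speed else ex$step
    metas[[length(metas) + 1]] <- data.frame(
      subject = sid, trial = paste0(sid, ".", mode), time = ex$target_times)
  }
  list(features = do.call(rbind, rows), target = do.call(c, ys),
       meta = do.call(rbind, metas))
}

#' Run the full fitting pipeline on a cohort
#'
#' Preprocesses every trial, extracts the structured feature battery,
#' reserves `n_adapt` subjects for adaptation, splits the remainder into
#' cross-validation and test subjects (`split_ratio`), fits the hybrid
#' selection and autoencoder reduction on cross-validation rows only, trains
#' one LSTM per gait parameter with subject-wise CV, and evaluates on the
#' held-out test subjects. All learned transforms are fitted on training
#' rows and applied frozen elsewhere.
#'
#' @param cohort a [generate_cohort()] result (or [read_cohort()] output).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory for `metrics.json` + config echo.
#' @return a `pipeline_fit`: per-target models, reducers, score tables,
#'   fold/test metrics, subject splits and the feature count.
#' @export
run_fit <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  ids <- vapply(cohort, function(s) s$subject_id, numeric(1))
  extracted <- lapply(cohort, function(s) lapply(s$trials, extract_trial, config = config))
  names(extracted) <- as.character(ids)
  n_feat <- ncol(extracted[[1]][[1]]$values)
  message("extracted ", n_feat, " features per window from ",
          length(ids), " subjects")

  splits <- with_seed(derive_seed(config$seed, "split"), {
    perm <- sample(ids)
    n_ad <- min(config$n_adapt, length(ids) - config$model$folds)
    adapt <- if (n_ad > 0) perm[seq_len(n_ad)] else numeric(0)
    rest <- sort(setdiff(perm, adapt))
    n_cv <- max(config$model$folds, round(config$model$split_ratio * length(rest)))
    cvs <- sort(sample(rest, min(n_cv, length(rest))))
    list(cv = cvs, test = sort(setdiff(rest, cvs)), adapt = sort(adapt))
  })
  message("subject split: ", length(splits$cv), " cross-validation, ",
          length(splits$test), " test, ", length(splits$adapt), " adaptation")

  fit_target <- function(target) {
    ds <- assemble_dataset(extracted, splits$cv, target)
    ok <- is.finite(ds$target)
    sel <- score_features(ds$features[ok, , drop = FALSE], ds$target[ok],
                          threshold = config$selection$threshold,
                          k = config$selection$k,
                          seed = derive_seed(config$seed, "select", target))
    message(target, ": ", sum(sel$scores$retained), " features pass the ",
            config$selection$threshold, " screen; top ", length(sel$selected),
            " selected")
    ae <- fit_autoencoder(ds$features[ok, sel$selected, drop = FALSE],
                          latent_dim = min(config$selection$latent_dim,
                                           length(sel$selected) - 1),
                          seed = derive_seed(config$seed, "ae", target),
                          epochs = config$selection$ae_epochs,
                          lr = config$selection$ae_lr)
    reducer <- list(selected = sel$selected, autoencoder = ae)
    codes <- encode(ae, ds$features[, sel$selected, drop = FALSE])
    tcfg <- do.call(training_config, config$model)
    model <- train_cv(codes, ds$target, ds$meta, tcfg)
    test_eval <- NULL
    if (length(splits$test)) {
      tds <- assemble_dataset(extracted, splits$test, target)
      tcodes <- encode(ae, tds$features[, sel$selected, drop = FALSE])
      pred <- predict(model, tcodes, tds$meta)
      okt <- is.finite(tds$target)
      test_eval <- evaluate_predictions(pred[okt], tds$target[okt])
    }
    list(model = model, reducer = reducer, scores = sel$scores,
         test_eval = test_eval)
  }
  speed <- fit_target("speed")
  step <- fit_target("step")

  metrics <- list(
    n_features = n_feat,
    splits = splits,
    speed = list(cv_rmse_relative = mean(speed$model$fold_metrics$rmse_relative),
                 cv_r_squared = mean(speed$model$fold_metrics$r_squared),
                 fold_metrics = speed$model$fold_metrics[, 1:5],
                 test_rmse_relative = speed$test_eval$rmse_relative,
                 test_r_squared = speed$test_eval$r_squared),
    step = list(cv_rmse_relative = mean(step$model$fold_metrics$rmse_relative),
                cv_r_squared = mean(step$model$fold_metrics$r_squared),
                fold_metrics = step$model$fold_metrics[, 1:5],
                test_rmse_relative = step$test_eval$rmse_relative,
                test_r_squared = step$test_eval$r_squared))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
    write_config(config, file.path(out_dir, "config_echo.yaml"))
  }
  structure(list(speed = speed, step = step, metrics = metrics,
                 splits = splits, config = config, extracted = extracted),
            class = "pipeline_fit")
}

#' Adapt the fitted models to held-out subjects
#'
#' For each adaptation subject and each gait parameter, transforms the
#' subject's rows through the frozen selection + autoencoder, runs the
#' R-squared-gated incremental update, and aggregates the before/after
#' deltas into a cohort report.
#'
#' @param fit a [run_fit()] result.
#' @param cohort the cohort the fit came from (or new subjects).
#' @param subject_ids subjects to adapt on; defaults to the fit's reserved
#'   adaptation split.
#' @param out_dir optional directory for `adaptation.json`.
#' @return list with per-target adaptation records and
#'   [adaptation_report()] summaries.
#' @export
run_adapt <- function(fit, cohort, subject_ids = fit$splits$adapt, out_dir = NULL) {
  if (!length(subject_ids)) {
    res <- list(speed = list(), step = list(), report = NULL,
                note = "no adaptation subjects")
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(list(note = res$note),
                           file.path(out_dir, "adaptation.json"),
                           auto_unbox = TRUE, pretty = TRUE)
    }
    return(res)
  }
  ids <- vapply(cohort, function(s) s$subject_id, numeric(1))
  config <- fit$config
  adapt_target <- function(target) {
    part <- fit[[target]]
    lapply(subject_ids, function(sid) {
      subj <- cohort[[which(ids == sid)]]
      ex_all <- if (!is.null(fit$extracted[[as.character(sid)]]))
        fit$extracted[[as.character(sid)]]
      else lapply(subj$trials, extract_trial, config = config)
      ds <- assemble_dataset(stats::setNames(list(ex_all), as.character(sid)),
                             sid, target)
      codes <- encode(part$reducer$autoencoder,
                      ds$features[, part$reducer$selected, drop = FALSE])
      upd <- adaptive_update(part$model, codes, ds$target, ds$meta)
      upd$subject <- sid
      upd
    })
  }
  speed_upd <- adapt_target("speed")
  step_upd <- adapt_target("step")
  report <- list(
    speed = adaptation_report(speed_upd, speed_upd),
    step = adaptation_report(step_upd, step_upd))
  out <- list(speed = speed_upd, step = step_upd, report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    slim <- list(
      speed = report$speed[c("per_subject", "mean_delta_rmse", "mean_delta_r2")],
      step = report$step[c("per_subject", "mean_delta_rmse", "mean_delta_r2")])
    jsonlite::write_json(slim, file.path(out_dir, "adaptation.json"),
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
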