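# Experiment driver wiring the modules into the full workflow:
# series -> lag windows -> chronological split -> metaheuristic-tuned RNN
# -> held-out evaluation -> multi-run statistics -> attribution.

#' Experiment configuration
#'
#' @param series Optional list of `heart_rate_series` to tune on; when
#'   `NULL`, data are generated from `generator`.
#' @param generator A [generator_config()] used when `series` is `NULL`.
#' @param lags Window length (default 15).
#' @param fractions Chronological split fractions (default 70/10/20).
#' @param variants Character vector of optimizer variants to run; the first
#'   is the control for the statistical comparison.
#' @param optimizer An [optimizer_config()] (its `variant` field is
#'   overridden per run).
#' @param gcfg A [gipso_config()].
#' @param space A `search_space` (default [default_space()]).
#' @param repeats Independent tuning runs per variant (default 30).
#' @param base_seed Base integer seed; run r uses `base_seed + r` for the
#'   optimizer while the data seed and the model-training seed stay fixed,
#'   so runs are paired across variants.
#' @param epoch_cap Optional ceiling applied to decoded epoch counts (for
#'   reduced-budget runs); `NULL` leaves them untouched.
#' @param refit Refit the winning hyperparameters on train+validation
#'   before the single test evaluation (default `TRUE`); otherwise the
#'   tuning-time model is reused.
#' @param output_dir Optional directory; when given, all tables and traces
#'   are written there as CSV.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(series = NULL, generator = generator_config(),
                              lags = 15L, fractions = c(0.7, 0.1, 0.2),
                              variants = c("gipso", "pso"),
                              optimizer = optimizer_config(),
                              gcfg = gipso_config(),
                              space = default_space(),
                              repeats = 30L, base_seed = 1L,
                              epoch_cap = NULL, refit = TRUE,
                              output_dir = NULL) {
  stopifnot(repeats >= 1, length(variants) >= 1,
            all(variants %in% c("gipso", "pso", "ga")))
  structure(list(series = series, generator = generator, lags = as.integer(lags),
                 fractions = fractions, variants = variants,
                 optimizer = optimizer, gcfg = gcfg, space = space,
                 repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed),
                 epoch_cap = epoch_cap, refit = isTRUE(refit),
                 output_dir = output_dir),
            class = "experiment_config")
}

#' Load an experiment configuration from YAML
#'
#' Recognized top-level keys mirror the [experiment_config()] arguments
#' (`lags`, `fractions`, `variants`, `repeats`, `base_seed`, `refit`,
#' `output_dir`, `csv_path` for input data, nested `optimizer`, `gipso`,
#' `generator` and `search_space` blocks).
#'
#' @param path Path to a YAML file.
#' @return An `experiment_config`.
#' @export
experiment_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  opt_args <- y$optimizer %||% list()
  gen_args <- y$generator %||% list()
  gip_args <- y$gipso %||% list()
  experiment_config(
    series = if (!is.null(y$csv_path)) read_series_csv(y$csv_path),
    generator = do.call(generator_config, gen_args),
    lags = y$lags %||% 15L,
    fractions = unlist(y$fractions %||% c(0.7, 0.1, 0.2)),
    variants = unlist(y$variants %||% c("gipso", "pso")),
    optimizer = do.call(optimizer_config, opt_args),
    gcfg = do.call(gipso_config, gip_args),
    space = space_from_config(path),
    repeats = y$repeats %||% 30L,
    base_seed = y$base_seed %||% 1L,
    epoch_cap = y$epoch_cap,
    refit = y$refit %||% TRUE,
    output_dir = y$output_dir
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run seeded code without disturbing the caller's random stream.
with_isolated_rng <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

apply_epoch_cap <- function(hp, cap) {
  if (is.null(cap) || hp$epochs <= cap) return(hp)
  hyperparameter_set(hp$learning_rate, hp$dropout, cap, hp$num_layers,
                     hp$neurons)
}

#' Validation error-rate objective for hyperparameter tuning
#'
#' Decodes the position, builds and trains the classifier, and returns the
#' validation error rate (1 - accuracy) with the validation Cohen's kappa
#' attached as attribute `"kappa"` (the tracked indicator). Training
#' failures are penalized with the worst possible fitness 1.0 and a
#' warning. Training runs under an isolated random stream seeded with
#' `seed`, so the fitness is a deterministic function of the position and
#' the caller's stream is untouched.
#'
#' @param position Real vector in the search space.
#' @param space The `search_space`.
#' @param train_set,val_set Chronological `windowed_dataset` splits.
#' @param seed Integer seed for weight initialization and training.
#' @param lags Window length.
#' @param epoch_cap Optional ceiling on decoded epochs.
#' @return The error rate, with attribute `kappa`.
#' @export
tuning_objective <- function(position, space, train_set, val_set, seed,
                             lags = 15L, epoch_cap = NULL) {
  hp <- decode_position(position, space)
  hp <- apply_epoch_cap(hp, epoch_cap)
  out <- tryCatch(
    with_isolated_rng(seed, {
      model <- build_rnn(hp, lags = lags)
      run <- rnn_train(model, train_set, val_set, hp)
      pred <- predict(run$model, val_set$X)
      cm <- confusion_matrix(val_set$y, pred)
      err <- error_rate(cm)
      kap <- tryCatch(cohen_kappa(cm), error = function(e) NA_real_)
      structure(err, kappa = kap)
    }),
    error = function(e) {
      warning("training failed (", conditionMessage(e),
              "); assigning worst fitness 1.0", call. = FALSE)
      structure(1.0, kappa = NA_real_)
    }
  )
  out
}

#' Run the full tuning experiment
#'
#' For each optimizer variant and each of `repeats` runs (run r seeded
#' `base_seed + r`), searches the hyperparameter space by minimizing the
#' validation error rate; the winning hyperparameters of each variant's
#' best run are refit on train+validation (when `refit`) and evaluated
#' exactly once on the held-out final test windows. Produces per-variant
#' run collections, objective/indicator summary tables, per-variant test
#' reports, Shapiro-Wilk and Wilcoxon comparisons against the first
#' (control) variant, and a per-lag attribution summary for the overall
#' best model. With `cfg$output_dir` set, every table is also written as
#' CSV.
#'
#' @param cfg An [experiment_config()].
#' @return An `experiment_result` list; `test_evaluations` records how many
#'   times the reserved test windows were touched (once per variant).
#' @export
run_experiment <- function(cfg) {
  series <- cfg$series %||%
    generate_synthetic_series(cfg$generator, seed = cfg$base_seed)
  ds <- make_windows(series, lags = cfg$lags)
  splits <- chronological_split(ds, cfg$fractions)
  train_set <- splits$train
  val_set <- splits$val

  # reserved test windows live behind an access-counting guard
  guard <- new.env(parent = emptyenv())
  guard$accesses <- 0L
  guard$data <- splits$test
  test_data <- function() {
    guard$accesses <- guard$accesses + 1L
    guard$data
  }

  model_seed <- cfg$base_seed
  objective <- function(position) {
    tuning_objective(position, cfg$space, train_set, val_set,
                     seed = model_seed, lags = cfg$lags,
                     epoch_cap = cfg$epoch_cap)
  }

  collections <- list()
  reports <- list()
  best_rows <- list()
  traces <- list()
  trainings_per_run <- c()
  for (variant in cfg$variants) {
    ocfg <- cfg$optimizer
    ocfg$variant <- variant
    run_best <- numeric(cfg$repeats)
    run_kappa <- numeric(cfg$repeats)
    run_seeds <- cfg$base_seed + seq_len(cfg$repeats)
    run_hps <- vector("list", cfg$repeats)
    for (r in seq_len(cfg$repeats)) {
      res <- optimize_swarm(objective, cfg$space, ocfg, cfg$gcfg,
                            seed = run_seeds[r])
      run_best[r] <- res$best_fitness
      run_kappa[r] <- res$best_attributes$kappa %||% NA_real_
      run_hps[[r]] <- decode_position(res$best_position, cfg$space)
      trainings_per_run <- c(trainings_per_run, res$evaluations_used)
      traces[[length(traces) + 1L]] <- data.frame(
        variant = variant, run = r,
        iteration = seq_along(res$trace) - 1L,
        best_fitness = res$trace)
    }
    collections[[variant]] <- run_collection(
      algorithm = variant, objective = run_best, indicator = run_kappa,
      seeds = run_seeds, best_hyperparameters = run_hps)

    best_run <- which.min(run_best)
    hp <- apply_epoch_cap(run_hps[[best_run]], cfg$epoch_cap)
    final_model <- with_isolated_rng(model_seed, {
      if (cfg$refit) {
        trainval <- structure(list(X = rbind(train_set$X, val_set$X),
                                   y = c(train_set$y, val_set$y),
                                   lags = ds$lags),
                              class = "windowed_dataset")
        rnn_train(build_rnn(hp, lags = cfg$lags), trainval, val_set, hp)$model
      } else {
        rnn_train(build_rnn(hp, lags = cfg$lags), train_set, val_set, hp)$model
      }
    })
    test_set <- test_data()
    pred <- predict(final_model, test_set$X)
    cm <- confusion_matrix(test_set$y, pred)
    # a degenerate final model (single-class predictions) keeps its error
    # rate but has undefined per-class precision and kappa
    reports[[variant]] <- list(
      model = final_model, cm = cm,
      report = tryCatch(classification_report(cm), error = function(e) NULL),
      kappa = tryCatch(cohen_kappa(cm), error = function(e) NA_real_),
      error = error_rate(cm),
      hyperparameters = hp)
    best_rows[[variant]] <- data.frame(
      method = variant, learning_rate = hp$learning_rate,
      dropout = hp$dropout, epochs = hp$epochs, layers = hp$num_layers,
      neurons = paste(hp$neurons, collapse = "/"))
  }

  obj_table <- summary_table(collections, "objective")
  ind_table <- summary_table(collections, "indicator")
  stats <- if (length(cfg$variants) > 1) {
    compare_algorithms(collections[[cfg$variants[1]]],
                       unname(collections[cfg$variants[-1]]))
  }

  best_variant <- cfg$variants[which.min(vapply(reports, `[[`, numeric(1),
                                                "error"))]
  best_model <- reports[[best_variant]]$model
  bg_idx <- with_isolated_rng(model_seed,
    sample.int(nrow(train_set$X), min(100L, nrow(train_set$X))))
  sample_idx <- seq_len(min(25L, nrow(guard$data$X)))
  attribution <- feature_importance(
    best_model, train_set$X[bg_idx, , drop = FALSE],
    guard$data$X[sample_idx, , drop = FALSE],
    n_coalitions = 20L, seed = model_seed)

  result <- structure(list(
    collections = collections, reports = reports,
    objective_summary = obj_table, indicator_summary = ind_table,
    best_hyperparameters = do.call(rbind, best_rows),
    stats = stats, attribution = attribution,
    best_variant = best_variant,
    traces = do.call(rbind, traces),
    trainings_per_run = trainings_per_run,
    test_evaluations = guard$accesses,
    splits = list(train = train_set, val = val_set)
  ), class = "experiment_result")

  if (!is.null(cfg$output_dir)) write_experiment(result, cfg$output_dir)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("tuning experiment over variants:",
      paste(names(x$collections), collapse = ", "), "\n")
  cat("objective (validation error) summary:\n")
  print(x$objective_summary, row.names = FALSE)
  cat(sprintf("best variant on test: %s (error %.6f, kappa %.6f)\n",
              x$best_variant, x$reports[[x$best_variant]]$error,
              x$reports[[x$best_variant]]$kappa))
  invisible(x)
}

write_experiment <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(result$objective_summary, "summary_objective.csv")
  w(result$indicator_summary, "summary_indicator.csv")
  w(result$best_hyperparameters, "best_hyperparameters.csv")
  w(result$traces, "traces.csv")
  for (v in names(result$reports)) {
    if (!is.null(result$reports[[v]]$report)) {
      write_report_csv(result$reports[[v]]$report,
                       file.path(dir, paste0("report_", v, ".csv")))
    }
  }
  if (!is.null(result$stats)) {
    w(result$stats$shapiro, "shapiro.csv")
    w(result$stats$wilcoxon, "wilcoxon.csv")
  }
  write_attribution_csv(result$attribution, file.path(dir, "attribution.csv"))
  invisible(dir)
}
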