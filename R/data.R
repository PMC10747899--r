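# Heart-rate series handling: CSV in/out, a synthetic arrhythmia-series
# generator, lag-window construction, and chronological splitting.

#' Construct a labeled heart-rate series
#'
#' @param values Numeric beats-per-minute values at fixed 0.5 s intervals.
#' @param labels Integer 0/1 per step (1 = anomalous).
#' @param series_id Identifier.
#' @return A `heart_rate_series` object.
#' @export
heart_rate_series <- function(values, labels, series_id = "series_1") {
  if (length(values) != length(labels)) {
    stop("values and labels must have equal length")
  }
  if (!all(labels %in% c(0, 1))) {
    bad <- which(!(labels %in% c(0, 1)))[1]
    stop(sprintf("non-binary label %s at row %d", labels[bad], bad))
  }
  structure(list(values = as.numeric(values),
                 labels = as.integer(labels),
                 series_id = as.character(series_id)),
            class = "heart_rate_series")
}

#' @export
print.heart_rate_series <- function(x, ...) {
  cat(sprintf("heart-rate series '%s': %d steps (0.5 s), %.1f%% anomalous\n",
              x$series_id, length(x$values), 100 * mean(x$labels)))
  invisible(x)
}

#' Read labeled heart-rate series from CSV
#'
#' Expects a header with columns `value` and `label` and an optional
#' `series_id` column; one series object is returned per distinct id, in
#' order of first appearance.
#'
#' @param path Path to the CSV file.
#' @return A list of `heart_rate_series`.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("value", "label") %in% names(df))) {
    stop("CSV must have columns 'value' and 'label'")
  }
  if (!all(df$label %in% c(0, 1))) {
    bad <- which(!(df$label %in% c(0, 1)))[1]
    stop(sprintf("non-binary label %s at row %d", df$label[bad], bad))
  }
  if (is.null(df$series_id)) df$series_id <- "series_1"
  ids <- unique(df$series_id)
  lapply(ids, function(id) {
    sub <- df[df$series_id == id, ]
    heart_rate_series(sub$value, sub$label, id)
  })
}

#' Write heart-rate series to CSV
#'
#' @param series A list of `heart_rate_series` (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "heart_rate_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(series_id = s$series_id, value = s$values, label = s$labels)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Synthetic-series generator configuration
#'
#' The generator emulates an ambulatory heart-rate recording: a first-order
#' autoregressive process around a resting baseline with Gaussian noise, on
#' which contiguous arrhythmic episodes are overlaid. Episode boundaries
#' follow a two-state Markov chain whose stay probabilities are set so that
#' the stationary anomalous fraction equals `anomalous_fraction_target` and
#' the expected number of episodes per series is `anomaly_segment_rate`
#' (episode onsets are then approximately Poisson). Anomalous steps add
#' `anomaly_mean_shift` to the level and inflate the innovation standard
#' deviation by `anomaly_extra_sd`.
#'
#' Defaults mirror the heavily imbalanced monitoring data the harness is
#' aimed at: 1800 steps at 0.5 s (15 min), resting baseline 80 bpm, an 85%
#' anomalous target so test splits carry roughly 15% normal windows, and
#' roughly 20 episodes per series (mean arrhythmic run of about 75 steps,
#' i.e. ~40 s), short enough that every chronological split sees both
#' classes. AR persistence 0.8 keeps the within-state spread well below the
#' episode level shift, so the anomaly is learnable from a lag window.
#'
#' @param n_series Number of independent series.
#' @param length Steps per series (default 1800, i.e. 15 min at 0.5 s).
#' @param baseline_hr Resting heart-rate level in bpm.
#' @param ar_coefficient AR(1) coefficient in (0, 1).
#' @param noise_sd Innovation standard deviation during normal activity (bpm).
#' @param anomaly_segment_rate Expected anomalous episodes per series.
#' @param anomaly_mean_shift Added bpm level during episodes.
#' @param anomaly_extra_sd Additional innovation sd during episodes (bpm).
#' @param anomalous_fraction_target Stationary fraction of anomalous steps.
#' @return A `generator_config` object.
#' @export
generator_config <- function(n_series = 1L, length = 1800L, baseline_hr = 80,
                             ar_coefficient = 0.8, noise_sd = 1.5,
                             anomaly_segment_rate = 20, anomaly_mean_shift = 25,
                             anomaly_extra_sd = 6,
                             anomalous_fraction_target = 0.85) {
  stopifnot(n_series >= 1, length >= 2, baseline_hr > 0,
            ar_coefficient > 0, ar_coefficient < 1, noise_sd > 0,
            anomaly_segment_rate >= 0, anomaly_extra_sd >= 0,
            anomalous_fraction_target > 0, anomalous_fraction_target < 1)
  structure(list(n_series = as.integer(n_series), length = as.integer(length),
                 baseline_hr = baseline_hr, ar_coefficient = ar_coefficient,
                 noise_sd = noise_sd,
                 anomaly_segment_rate = anomaly_segment_rate,
                 anomaly_mean_shift = anomaly_mean_shift,
                 anomaly_extra_sd = anomaly_extra_sd,
                 anomalous_fraction_target = anomalous_fraction_target),
            class = "generator_config")
}

# Two-state label chain: stationary anomalous fraction = target, expected
# episode count per series = rate.
label_chain_probs <- function(cfg) {
  target <- cfg$anomalous_fraction_target
  # onset probability normal -> anomalous; expected episodes =
  # length * P(normal) * p01
  p01 <- min(1, cfg$anomaly_segment_rate / (cfg$length * (1 - target)))
  p10 <- p01 * (1 - target) / target
  list(p01 = p01, p10 = min(1, p10))
}

#' Generate synthetic labeled heart-rate series
#'
#' @param cfg A [generator_config()].
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return A list of `heart_rate_series` of length `cfg$n_series`.
#' @examples
#' s <- generate_synthetic_series(generator_config(n_series = 1), seed = 1)
#' mean(s[[1]]$labels)
#' @export
generate_synthetic_series <- function(cfg = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- label_chain_probs(cfg)
  lapply(seq_len(cfg$n_series), function(k) {
    n <- cfg$length
    labels <- integer(n)
    if (cfg$anomaly_segment_rate > 0) {
      state <- as.integer(stats::runif(1) < cfg$anomalous_fraction_target)
      u <- stats::runif(n)
      for (t in seq_len(n)) {
        labels[t] <- state
        state <- if (state == 0L) {
          as.integer(u[t] < pr$p01)
        } else {
          1L - as.integer(u[t] < pr$p10)
        }
      }
    }
    sd_t <- cfg$noise_sd + labels * cfg$anomaly_extra_sd
    level <- cfg$baseline_hr + labels * cfg$anomaly_mean_shift
    eps <- stats::rnorm(n, 0, sd_t)
    values <- numeric(n)
    prev_dev <- 0
    for (t in seq_len(n)) {
      dev <- cfg$ar_coefficient * prev_dev + eps[t]
      values[t] <- level[t] + dev
      prev_dev <- dev
    }
    heart_rate_series(values, labels, sprintf("synthetic_%d", k))
  })
}

#' Build a lag-window matrix from one or more series
#'
#' The window for step `t` holds the `lags` preceding values
#' (`values[t - lags .. t - 1]`) and predicts the label at step `t`, so each
#' series of length `n` yields `n - lags` windows. Windows never span series
#' boundaries.
#'
#' @param series A `heart_rate_series` or a list of them.
#' @param lags Window length (default 15).
#' @return A `windowed_dataset` with matrix `X` (`n` rows by `lags`
#'   columns, oldest lag first), label vector `y` and `lags`.
#' @export
make_windows <- function(series, lags = 15L) {
  if (inherits(series, "heart_rate_series")) series <- list(series)
  lags <- as.integer(lags)
  parts <- lapply(series, function(s) {
    n <- length(s$values)
    if (n < lags + 1L) {
      stop(sprintf("series '%s' has %d steps; need at least lags + 1 = %d",
                   s$series_id, n, lags + 1L))
    }
    m <- n - lags
    X <- matrix(NA_real_, nrow = m, ncol = lags)
    for (j in seq_len(lags)) X[, j] <- s$values[j:(j + m - 1L)]
    list(X = X, y = s$labels[(lags + 1L):n])
  })
  structure(list(X = do.call(rbind, lapply(parts, `[[`, "X")),
                 y = do.call(c, lapply(parts, `[[`, "y")),
                 lags = lags),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("windowed dataset: %d windows of %d lags, %.1f%% anomalous\n",
              nrow(x$X), x$lags, 100 * mean(x$y)))
  invisible(x)
}

subset_windows <- function(ds, idx) {
  structure(list(X = ds$X[idx, , drop = FALSE], y = ds$y[idx], lags = ds$lags),
            class = "windowed_dataset")
}

#' Chronological train/validation/test split
#'
#' Contiguous, order-preserving split: the first fraction trains, the next
#' validates, and the final windows are reserved for testing. Train and
#' validation sizes are floored; the remainder goes to test.
#'
#' @param ds A `windowed_dataset`.
#' @param fractions Numeric triple summing to 1 (default `c(0.7, 0.1, 0.2)`).
#' @return A list with `windowed_dataset` elements `train`, `val`, `test`.
#' @export
chronological_split <- function(ds, fractions = c(0.7, 0.1, 0.2)) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three numbers summing to 1")
  }
  n <- nrow(ds$X)
  n_train <- floor(fractions[1] * n)
  n_val <- floor(fractions[2] * n)
  list(train = subset_windows(ds, seq_len(n_train)),
       val = subset_windows(ds, n_train + seq_len(n_val)),
       test = subset_windows(ds, (n_train + n_val + 1L):n))
}
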