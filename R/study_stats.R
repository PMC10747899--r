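# Multi-run comparison protocol: per-algorithm samples over repeated
# independent tuning runs, six-number summaries, Shapiro-Wilk normality
# screening at alpha = 0.05, and a Wilcoxon signed-rank comparison against
# the control optimizer (exact by sign-assignment enumeration for small n,
# tie-corrected normal approximation otherwise).

#' Collect per-run outcomes for one algorithm
#'
#' @param algorithm Label for the optimizer.
#' @param objective Numeric vector of per-run best objective values.
#' @param indicator Optional numeric vector of per-run best indicator values.
#' @param seeds Optional integer vector of per-run seeds (must be distinct).
#' @param best_hyperparameters Optional list of winning hyperparameter sets.
#' @return A `run_collection`.
#' @export
run_collection <- function(algorithm, objective, indicator = NULL,
                           seeds = NULL, best_hyperparameters = NULL) {
  stopifnot(length(objective) >= 1)
  if (!is.null(seeds) && anyDuplicated(seeds)) {
    stop("per-run seeds must be distinct")
  }
  structure(list(algorithm = algorithm, objective = as.numeric(objective),
                 indicator = indicator, seeds = seeds,
                 best_hyperparameters = best_hyperparameters),
            class = "run_collection")
}

#' Six-number summary of a run sample
#'
#' Best, worst, mean, median, sample standard deviation (denominator
#' `n - 1`) and variance. `direction = "min"` treats small values as best
#' (objective samples); `"max"` treats large values as best (indicator
#' samples).
#'
#' @param sample Numeric vector (or a `run_collection`, whose objective
#'   sample is used).
#' @param direction `"min"` or `"max"`.
#' @return A one-row data frame with columns best, worst, mean, median,
#'   std, var.
#' @export
summarize_runs <- function(sample, direction = c("min", "max")) {
  direction <- match.arg(direction)
  if (inherits(sample, "run_collection")) sample <- sample$objective
  if (length(sample) == 0) stop("empty sample")
  s <- if (length(sample) > 1) stats::sd(sample) else 0
  data.frame(
    best = if (direction == "min") min(sample) else max(sample),
    worst = if (direction == "min") max(sample) else min(sample),
    mean = mean(sample),
    median = stats::median(sample),
    std = s,
    var = s^2
  )
}

#' Shapiro-Wilk normality screen
#'
#' Returns the p-value of the normality null; values below 0.05 flag a
#' non-normal sample, gating the choice of the nonparametric comparison.
#'
#' @param sample Numeric vector, `3 <= n <= 5000`, not constant.
#' @return The p-value.
#' @export
shapiro_wilk <- function(sample) {
  if (length(sample) < 3) stop("Shapiro-Wilk needs at least 3 observations")
  if (length(unique(sample)) == 1) {
    stop("Shapiro-Wilk undefined for a constant sample")
  }
  stats::shapiro.test(sample)$p.value
}

# Exact null distribution of the signed-rank statistic with midranks:
# convolution over doubled ranks so all support points are integers.
signed_rank_exact_p <- function(ranks, W) {
  dr <- as.integer(round(2 * ranks))
  total <- sum(dr)
  probs <- c(1, numeric(total))
  for (d in dr) {
    shifted <- c(numeric(d), probs[seq_len(total + 1 - d)])
    probs <- 0.5 * probs + 0.5 * shifted
  }
  w2 <- as.integer(round(2 * W))
  p_le <- sum(probs[seq_len(w2 + 1L)])
  p_ge <- sum(probs[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired run samples
#'
#' Two-sided test on paired differences `control - other`. Zero differences
#' are dropped; absolute differences are midranked. For `n <= exact_limit`
#' nonzero pairs, the p-value is exact over all `2^n` sign assignments
#' (computed by convolution, ties handled by midranks); beyond that, the
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param control_sample,other_sample Equal-length paired numeric vectors
#'   (run i of the control paired with run i of the comparator).
#' @param exact_limit Largest n for the exact distribution (default 25).
#' @return The two-sided p-value.
#' @export
wilcoxon_signed_rank <- function(control_sample, other_sample,
                                 exact_limit = 25L) {
  if (length(control_sample) != length(other_sample)) {
    stop("paired samples must have equal length")
  }
  d <- control_sample - other_sample
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    return(signed_rank_exact_p(r, W))
  }
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- sign(W - mu) * 0.5
  z <- (W - mu - cc) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Summary table over several run collections
#'
#' @param collections List of `run_collection` objects.
#' @param metric `"objective"` (best = min) or `"indicator"` (best = max).
#' @return A data frame, one row per algorithm, with the six summary
#'   columns.
#' @export
summary_table <- function(collections, metric = c("objective", "indicator")) {
  metric <- match.arg(metric)
  direction <- if (metric == "objective") "min" else "max"
  rows <- lapply(collections, function(rc) {
    x <- if (metric == "objective") rc$objective else rc$indicator
    cbind(data.frame(method = rc$algorithm), summarize_runs(x, direction))
  })
  do.call(rbind, rows)
}

#' Compare a control optimizer against competitors
#'
#' Runs the Shapiro-Wilk screen on every algorithm's objective sample and
#' the Wilcoxon signed-rank test of the control against each competitor on
#' paired runs.
#'
#' @param control A `run_collection` for the control algorithm.
#' @param others List of `run_collection` objects to compare against.
#' @param alpha Significance threshold for the normality screen (default
#'   0.05).
#' @return A list with data frames `shapiro` (method, p_value, normal) and
#'   `wilcoxon` (method, p_value).
#' @export
compare_algorithms <- function(control, others, alpha = 0.05) {
  all_rc <- c(list(control), others)
  shapiro <- data.frame(
    method = vapply(all_rc, `[[`, character(1), "algorithm"),
    p_value = vapply(all_rc, function(rc) {
      tryCatch(shapiro_wilk(rc$objective), error = function(e) NA_real_)
    }, numeric(1))
  )
  shapiro$normal <- shapiro$p_value >= alpha
  wilcoxon <- data.frame(
    method = vapply(others, `[[`, character(1), "algorithm"),
    p_value = vapply(others, function(rc) {
      tryCatch(wilcoxon_signed_rank(control$objective, rc$objective),
               error = function(e) NA_real_)
    }, numeric(1))
  )
  list(shapiro = shapiro, wilcoxon = wilcoxon)
}
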