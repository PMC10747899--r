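# Shared fixtures built in code.

# A small, clearly separable windowed dataset: the label is 1 when the mean
# of the window's last three values exceeds the threshold by a margin.
separable_windows <- function(n = 300, lags = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * lags, mean = 0, sd = 1), n, lags)
  shift <- rep(c(0, 3), length.out = n)
  X <- X + shift
  structure(list(X = X, y = as.integer(shift > 0), lags = lags),
            class = "windowed_dataset")
}

random_confusion <- function(seed) {
  set.seed(seed)
  cm_from_counts(tn = sample(1:200, 1), fp = sample(1:50, 1),
                 fn = sample(1:50, 1), tp = sample(1:200, 1))
}

# Independent signed-rank oracle: enumerate every sign assignment.
wilcoxon_brute_force <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  p_le <- mean(Ws <= W + 1e-9)
  p_ge <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}
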