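# Independent brute-force oracles: explicit loops and two-pass formulas,
# deliberately naive, used only to cross-check the vectorized implementation.

pearson_loop <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (t in seq_len(n)) {
    num <- num + (x[t] - mx) * (y[t] - my)
    dx <- dx + (x[t] - mx)^2
    dy <- dy + (y[t] - my)^2
  }
  num / sqrt(dx * dy)
}

var_loop <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- sum(x) / n
  s <- 0
  for (i in seq_len(n)) s <- s + (x[i] - m)^2
  s / (n - 1)
}

# Variance components of a 2-session fisher panel, element by element.
variance_components_loop <- function(fisher) {
  I <- dim(fisher)[1]; V <- dim(fisher)[3]
  var_U <- var_V <- var_X <- numeric(V)
  for (v in seq_len(V)) {
    d <- numeric(I)
    for (i in seq_len(I)) d[i] <- fisher[i, 2, v] - fisher[i, 1, v]
    var_U[v] <- 0.5 * var_loop(d)
    var_V[v] <- 0.5 * (var_loop(fisher[, 1, v]) + var_loop(fisher[, 2, v]))
    var_X[v] <- max(var_V[v] - var_U[v], 0)
  }
  list(var_U = var_U, var_V = var_V, var_X = var_X)
}

mse_loop <- function(pred, obs) {
  I <- nrow(pred)
  out <- numeric(I)
  for (i in seq_len(I)) {
    s <- 0; n <- 0
    for (v in seq_len(ncol(pred))) {
      if (!is.na(pred[i, v]) && !is.na(obs[i, v])) {
        s <- s + (pred[i, v] - obs[i, v])^2
        n <- n + 1
      }
    }
    out[i] <- s / n
  }
  out
}

# Small deterministic fisher panel straight from given session matrices.
make_fisher_panel <- function(v1, v2) {
  I <- nrow(v1); V <- ncol(v1)
  p <- array(NA_real_, c(I, 2, V),
             dimnames = list(subject = sprintf("sub%02d", seq_len(I)),
                             session = c("1", "2"), voxel = NULL))
  p[, 1, ] <- v1; p[, 2, ] <- v2
  class(p) <- c("fisher_panel", class(p))
  p
}

new_est_for_test <- function(m) {
  structure(list(method = "test", fisher = m, correlation = tanh(m)),
            class = "estimator_result")
}

# Random time-series panel for oracle comparisons.
make_random_ts_panel <- function(I, J, V, T, seed = 1) {
  set.seed(seed)
  p <- array(rnorm(I * J * V * T), c(I, J, V, T),
             dimnames = list(subject = sprintf("sub%02d", seq_len(I)),
                             session = as.character(seq_len(J)),
                             voxel = NULL, time = NULL))
  class(p) <- c("ts_panel", class(p))
  p
}
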