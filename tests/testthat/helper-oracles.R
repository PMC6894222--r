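# Independent oracles, deliberately naive: brute-force normal equations,
# exhaustive average-rank Spearman, and exact permutation p-values. They
# never call the package's fitting code.

ols_normal_equations <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}

average_ranks <- function(v) {
  # explicit average-rank computation (no rank() call)
  n <- length(v)
  out <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(v < v[i])
    ties <- sum(v == v[i])
    out[i] <- less + (ties + 1) / 2
  }
  out
}

spearman_exhaustive <- function(x, y) {
  rx <- average_ranks(x)
  ry <- average_ranks(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}

# Exact two-sided permutation p for Spearman's r, feasible for n <= 10
spearman_perm_p <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 10)
  r_obs <- spearman_exhaustive(x, y)
  perms <- perm_matrix(n)
  count <- 0L
  for (k in seq_len(nrow(perms))) {
    r <- spearman_exhaustive(x, y[perms[k, ]])
    if (abs(r) >= abs(r_obs) - 1e-12) count <- count + 1L
  }
  count / nrow(perms)
}

perm_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_matrix(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

# tiny complete cohort builders used across test files
tiny_config <- function(...) {
  arthrism_config(n_per_group = c(naive = 2, cfa = 2, cia = 3, cia_mtx = 3),
                  n_experiments = 1, seed = 123, ...)
}

noiseless_params <- function(slopes = NULL) {
  p <- default_modality_params()
  for (m in names(p)) p[[m]]$noise_sd <- 0
  if (!is.null(slopes))
    for (m in names(slopes)) p[[m]]$true_slope <- slopes[[m]]
  p
}
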