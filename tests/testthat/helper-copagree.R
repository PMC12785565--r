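# Shared fixtures and independent oracles, built in code.

# Independent covariance-form CCC oracle (Lin's original definition),
# kept deliberately separate from the package's moments-form implementation.
ccc_cov_form <- function(s, p) {
  2 * stats::cov(s, p) /
    (stats::var(s) + stats::var(p) + (mean(s) - mean(p))^2)
}

# Naive loop oracle for the CoP weighted vector summation.
cop_loop_oracle <- function(u, positions) {
  num <- c(0, 0); den <- 0
  for (i in 1:6) {
    num <- num + u[i] * positions[i, ]
    den <- den + u[i]
  }
  unname(num / den)
}

# Build an aligned_pair from two raw vectors (centres them as align_cop would).
make_pair <- function(s, p, dt = 0.01, axis = "x") {
  aligned_pair(time = dt * seq_along(s), sock = s - mean(s),
               platform = p - mean(p), axis = axis,
               mu_sock = mean(s), mu_platform = mean(p))
}

# A centred pair with exact Pearson correlation `rho`, equal SDs and zero
# means (so CCC = rho exactly): orthonormalised basis vectors recombined.
make_exact_rho_pair <- function(rho, n, seed = 1) {
  set.seed(seed)
  a <- rnorm(n); b <- rnorm(n)
  a <- a - mean(a)
  b <- b - mean(b)
  b <- b - a * sum(a * b) / sum(a * a)   # orthogonal to a
  a <- a / sd(a)
  b <- b / sd(b)
  list(platform = a, sock = rho * a + sqrt(1 - rho^2) * b)
}

# Short conductance series with a configurable low-load window.
make_marker_series <- function(rate = 100, total_dur = 12,
                               windows = list(c(2, 5)), high = 10, low = 0.05) {
  t <- seq(0, total_dur, by = 1 / rate)
  u <- matrix(high / 6, length(t), 6)
  for (w in windows) {
    sel <- t >= w[1] & t < w[2]
    u[sel, ] <- low / 6
  }
  conductance_series(t, u)
}
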