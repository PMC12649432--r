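# Independent oracles and fixture builders shared across the suite.

# Brute-force I-DT oracle: the same greedy contract as the production
# scanner, but written naively -- the dispersion of every candidate window
# is recomputed from scratch with range(), and the gap rule is applied by
# explicit lookup. Used to verify the compiled scanner.
idt_oracle <- function(trace, dispersion_deg = 1.0, min_duration_ms = 100,
                       gap_tolerance_ms = 75) {
  keep <- which(trace$valid)
  out <- NULL
  if (length(keep) == 0) {
    return(data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0), cx_deg = numeric(0),
                      cy_deg = numeric(0), n_samples = integer(0)))
  }
  t <- trace$t_ms[keep]
  x <- trace$x_deg[keep]
  y <- trace$y_deg[keep]
  n <- length(t)
  disp <- function(i, j) {
    max(diff(range(x[i:j])), diff(range(y[i:j])))
  }
  i <- 1L
  while (i <= n) {
    j <- i
    while (j + 1L <= n &&
           (t[j + 1L] - t[j]) <= gap_tolerance_ms &&
           disp(i, j + 1L) <= dispersion_deg) {
      j <- j + 1L
    }
    if (t[j] - t[i] >= min_duration_ms) {
      out <- rbind(out, data.frame(
        onset_ms = t[i], offset_ms = t[j], duration_ms = t[j] - t[i],
        cx_deg = mean(x[i:j]), cy_deg = mean(y[i:j]),
        n_samples = j - i + 1L))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (is.null(out)) {
    data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
               duration_ms = numeric(0), cx_deg = numeric(0),
               cy_deg = numeric(0), n_samples = integer(0))
  } else {
    out
  }
}

# Random gaze trace mixing stationary plateaus, drifting stretches,
# signal loss and dropped samples; exercises gap bridging and boundary
# cases of the scanner.
random_trace <- function(max_samples = 200) {
  n <- sample(10:max_samples, 1)
  dt <- 1000 / 60
  t <- cumsum(c(0, dt * (1 + 4 * (runif(n - 1) < 0.05))))
  x <- numeric(n)
  y <- numeric(n)
  i <- 1
  px <- 0
  py <- 0
  while (i <= n) {
    len <- min(sample(1:40, 1), n - i + 1)
    if (runif(1) < 0.6) {           # plateau
      x[i:(i + len - 1)] <- px + rnorm(len, 0, 0.15)
      y[i:(i + len - 1)] <- py + rnorm(len, 0, 0.15)
    } else {                        # drift / jump
      px <- px + runif(1, -6, 6)
      py <- py + runif(1, -5, 5)
      x[i:(i + len - 1)] <- seq(px - 2, px, length.out = len) +
        rnorm(len, 0, 0.3)
      y[i:(i + len - 1)] <- py + rnorm(len, 0, 0.3)
    }
    i <- i + len
  }
  valid <- runif(n) > 0.1
  if (!any(valid)) valid[1] <- TRUE
  x[!valid] <- NA
  y[!valid] <- NA
  gaze_trace(t, x, y, valid)
}

# Direct eigen-solution CCA oracle: square roots of the eigenvalues of
# Sxx^-1 Sxy Syy^-1 Syx, the textbook definition.
cca_oracle <- function(X, Y) {
  X <- scale(as.matrix(X))
  Y <- scale(as.matrix(Y))
  Sxx <- stats::cov(X)
  Syy <- stats::cov(Y)
  Sxy <- stats::cov(X, Y)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  ev <- sort(Re(eigen(M)$values), decreasing = TRUE)
  sqrt(pmax(pmin(ev[seq_len(min(ncol(X), ncol(Y)))], 1), 0))
}

# Sample matrices whose population canonical correlations are `rhos`:
# block covariance [[I, D], [D, I]] with D = diag(rhos).
sample_canonical_pair <- function(n, p, q, rhos) {
  s <- min(p, q)
  D <- matrix(0, p, q)
  diag(D)[seq_along(rhos)] <- rhos
  Sigma <- rbind(cbind(diag(p), D), cbind(t(D), diag(q)))
  L <- chol(Sigma)
  Z <- matrix(rnorm(n * (p + q)), n) %*% L
  list(X = Z[, 1:p, drop = FALSE], Y = Z[, (p + 1):(p + q), drop = FALSE])
}

# Uniform 60 Hz trace at a fixed position (with optional jitter).
constant_trace <- function(n = 31, pos = c(0, 0), rate = 60) {
  t <- (seq_len(n) - 1) * 1000 / rate
  gaze_trace(t, rep(pos[1], n), rep(pos[2], n))
}
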