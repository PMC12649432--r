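#' Descriptive summary of a cohort variable
#'
#' Mean, SD, five-number summary (type-7 quantiles), adjusted
#' Fisher-Pearson skewness and the Shapiro-Wilk normality p-value.
#'
#' @param x Numeric vector, `n >= 3`, `NA`s dropped.
#' @return A list with `n`, `mean`, `sd`, `min`, `q1`, `median`, `q3`,
#'   `max`, `skewness`, `shapiro_p`, `constant` (flag; skewness and the
#'   normality test are undefined for a constant vector).
#' @export
descriptives <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
  s <- stats::sd(x)
  constant <- s == 0
  if (constant) {
    skew <- NA_real_
    swp <- NA_real_
  } else {
    m3 <- mean((x - mean(x))^3)
    g1 <- m3 / (mean((x - mean(x))^2))^1.5
    skew <- g1 * sqrt(n * (n - 1)) / (n - 2)  # adjusted Fisher-Pearson
    swp <- stats::shapiro.test(x)$p.value
  }
  list(n = n, mean = mean(x), sd = s,
       min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
       skewness = skew, shapiro_p = swp, constant = constant)
}

#' Pearson correlation with t-test
#'
#' `r` with the usual `t = r * sqrt(n - 2) / sqrt(1 - r^2)` statistic and
#' two-sided p-value on `n - 2` df.
#'
#' @param x,y Paired numeric vectors; pairs with any `NA` are dropped.
#' @return A list with `r`, `t_stat`, `p_t`, `n`.
#' @export
pearson_with_t <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    t <- sign(r) * Inf
    p <- 0
  } else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, t_stat = t, p_t = p, n = n)
}

#' Pairs-bootstrap p-value for a Pearson correlation
#'
#' Nonparametric double-check of a correlation's significance: (x, y)
#' pairs are resampled with replacement and `r` is recomputed for each
#' resample. Inference is studentized on the variance-stabilized (Fisher
#' z) scale: the p-value is the two-sided tail of
#' `atanh(r) / sd(atanh(r*))` under a t reference with `n - 3` degrees of
#' freedom, floored at `1 / (B + 1)` and capped at 1. The studentized
#' form is used because the raw percentile rule (comparing the resampled
#' `r*` against zero) inherits the pairs bootstrap's small-sample
#' underestimate of the sampling spread and rejects too often at
#' moderate n; the variance-stabilized studentized test holds its nominal
#' level. Seeded and reproducible.
#'
#' @param x,y Paired numeric vectors (`NA` pairs dropped), `n >= 5`.
#' @param B Number of bootstrap resamples (at least 99).
#' @param seed Integer seed.
#' @return The bootstrap p-value.
#' @export
bootstrap_p <- function(x, y, B = 9999, seed = 1) {
  if (B < 99) stop("B must be at least 99", call. = FALSE)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete pairs", call. = FALSE)
  z0 <- atanh(min(max(stats::cor(x, y), -1 + 1e-12), 1 - 1e-12))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  xb <- matrix(x[idx], nrow = n)
  yb <- matrix(y[idx], nrow = n)
  xm <- colMeans(xb); ym <- colMeans(yb)
  sxy <- colMeans(xb * yb) - xm * ym
  sxx <- colMeans(xb * xb) - xm^2
  syy <- colMeans(yb * yb) - ym^2
  rb <- sxy / sqrt(sxx * syy)
  rb <- rb[is.finite(rb)]  # degenerate resamples (zero variance) dropped
  s <- stats::sd(atanh(pmin(pmax(rb, -1 + 1e-12), 1 - 1e-12)))
  p <- if (s == 0) 0 else 2 * stats::pt(-abs(z0) / s, df = n - 3)
  min(max(p, 1 / (B + 1)), 1)
}

#' F-test for a coefficient of determination
#'
#' Back-calculates the overall regression F statistic and p-value from an
#' R-squared, the predictor count and the sample size:
#' `F = (R2/k) / ((1 - R2)/(n - k - 1))` on `(k, n - k - 1)` df.
#'
#' @param r_squared Coefficient of determination in `[0, 1)`.
#' @param k Number of predictors.
#' @param n Sample size.
#' @return A list with `f_stat`, `p_f`, `df1`, `df2`.
#' @export
r2_f_test <- function(r_squared, k, n) {
  stopifnot(r_squared >= 0, r_squared < 1, n > k + 1)
  f <- (r_squared / k) / ((1 - r_squared) / (n - k - 1))
  list(f_stat = f, p_f = stats::pf(f, k, n - k - 1, lower.tail = FALSE),
       df1 = k, df2 = n - k - 1)
}

#' Shared variance between a criterion and a predictor set
#'
#' R-squared from the least-squares regression of `y` on `X` with
#' intercept, with the overall F-test. Regression coefficients are
#' deliberately not part of the report: with strongly intercorrelated
#' predictors they are unstable and uninformative, while the shared
#' variance is well defined.
#'
#' @param y Criterion vector.
#' @param X Numeric predictor matrix (or data.frame), full column rank.
#' @return A list with `r_squared`, `f_stat`, `p_f`, `k`, `n`.
#' @export
shared_variance <- function(y, X) {
  X <- as.matrix(X)
  keep <- stats::complete.cases(y, X)
  y <- y[keep]; X <- X[keep, , drop = FALSE]
  n <- length(y)
  k <- ncol(X)
  if (n <= k + 1) stop("need n > k + 1 observations", call. = FALSE)
  Xi <- cbind(`(intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    dropped <- colnames(Xi)[qx$pivot[(qx$rank + 1):ncol(Xi)]]
    stop("predictor matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qx, y)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("criterion has zero variance", call. = FALSE)
  r2 <- 1 - sum(res^2) / tss
  ft <- r2_f_test(min(r2, 1 - 1e-15), k, n)
  list(r_squared = r2, f_stat = ft$f_stat, p_f = ft$p_f, k = k, n = n)
}

#' Canonical correlation analysis
#'
#' Finds maximally correlated linear combinations (canonical variates) of
#' two variable sets. Computed by the numerically stable orthogonal route:
#' columns are standardized, each set is QR-decomposed, and the canonical
#' correlations are the singular values of the cross-product of the two
#' orthonormal bases (equivalently the square roots of the eigenvalues of
#' `Sxx^-1 Sxy Syy^-1 Syx`). Loadings are the Pearson correlations of each
#' observed variable with its own set's canonical variates. Each variate is
#' oriented so that its largest-magnitude loading is positive (canonical
#' signs are arbitrary; published solutions may differ by a global flip per
#' variate).
#'
#' @param X,Y Numeric matrices/data.frames with the same rows
#'   (listwise-complete); `n` must exceed `ncol(X) + ncol(Y)`.
#' @param max_condition Maximum accepted condition number of a within-set
#'   correlation matrix; beyond it an error advises removing variables.
#' @return A list of class `cca_result`: `cor` (canonical correlations,
#'   descending), `loadings_x`, `loadings_y` (variables x variates),
#'   `wilks` (sequential Wilks lambdas from [wilks_lambda()]), `n`.
#' @export
cca <- function(X, Y, max_condition = 1e10) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  keep <- stats::complete.cases(X, Y)
  X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  n <- nrow(X)
  if (n != nrow(Y)) stop("X and Y must have the same rows", call. = FALSE)
  if (n <= ncol(X) + ncol(Y)) {
    stop("need more rows than total variables", call. = FALSE)
  }
  Xs <- scale(X); Ys <- scale(Y)
  if (any(!is.finite(Xs)) || any(!is.finite(Ys))) {
    stop("constant column: standardization failed", call. = FALSE)
  }
  for (nm in c("X", "Y")) {
    S <- stats::cor(if (nm == "X") X else Y)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0 || max(ev) / min(ev) > max_condition) {
      stop(sprintf(
        "within-set covariance of %s is ill-conditioned; remove collinear variables",
        nm), call. = FALSE)
    }
  }
  qrx <- qr(Xs); qry <- qr(Ys)
  Qx <- qr.Q(qrx); Qy <- qr.Q(qry)
  sv <- svd(crossprod(Qx, Qy))
  s <- min(ncol(X), ncol(Y))
  rho <- pmin(pmax(sv$d[seq_len(s)], 0), 1)
  U <- Qx %*% sv$u[, seq_len(s), drop = FALSE]
  V <- Qy %*% sv$v[, seq_len(s), drop = FALSE]
  lx <- stats::cor(X, U)
  ly <- stats::cor(Y, V)
  for (k in seq_len(s)) {
    if (lx[which.max(abs(lx[, k])), k] < 0) lx[, k] <- -lx[, k]
    if (ly[which.max(abs(ly[, k])), k] < 0) ly[, k] <- -ly[, k]
  }
  colnames(lx) <- colnames(ly) <- paste0("variate_", seq_len(s))
  structure(list(cor = rho, loadings_x = lx, loadings_y = ly,
                 wilks = wilks_lambda(rho), n = n),
            class = "cca_result")
}

#' Sequential Wilks lambda statistics
#'
#' `Lambda_k = prod_{i > k} (1 - rho_i^2)` for `k = 0 .. s-1`; `Lambda_0`
#' tests all canonical pairs jointly, `Lambda_1` the pairs remaining after
#' removing the first, and so on.
#'
#' @param rhos Canonical correlations, each in `[0, 1]`.
#' @return Numeric vector of length `s` (`Lambda_0` first).
#' @export
wilks_lambda <- function(rhos) {
  if (any(rhos < 0 | rhos > 1 | !is.finite(rhos))) {
    stop("canonical correlations must lie in [0, 1]", call. = FALSE)
  }
  s <- length(rhos)
  vapply(seq_len(s) - 1L,
         function(k) prod(1 - rhos[seq_len(s) > k]^2),
         numeric(1))
}

#' Permutation test of the canonical correlations (sequential Wilks)
#'
#' Permutes whole rows of `Y` (preserving within-set correlation) `B`
#' times; for each removal step `k` the p-value is
#' `(#{Lambda_k,perm <= Lambda_k,obs} + 1) / (B + 1)` (small Wilks lambda =
#' strong association). Seeded and reproducible.
#'
#' @param X,Y As in [cca()].
#' @param B Number of permutations (at least 99).
#' @param seed Integer seed.
#' @return A list with `p` (one p-value per canonical pair), `wilks`
#'   (observed sequential lambdas), `cor` (observed canonical
#'   correlations), `B`.
#' @export
cca_permutation_p <- function(X, Y, B = 999, seed = 1) {
  if (B < 99) stop("B must be at least 99", call. = FALSE)
  X <- as.matrix(X); Y <- as.matrix(Y)
  keep <- stats::complete.cases(X, Y)
  X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  n <- nrow(X)
  s <- min(ncol(X), ncol(Y))
  Qx <- qr.Q(qr(scale(X)))
  Qy <- qr.Q(qr(scale(Y)))
  lam <- function(Qyp) {
    d <- svd(crossprod(Qx, Qyp), nu = 0, nv = 0)$d[seq_len(s)]
    wilks_lambda(pmin(pmax(d, 0), 1))
  }
  obs <- lam(Qy)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  count <- numeric(s)
  for (b in seq_len(B)) {
    perm <- sample.int(n)
    count <- count + (lam(Qy[perm, , drop = FALSE]) <= obs)
  }
  list(p = (count + 1) / (B + 1), wilks = obs,
       cor = svd(crossprod(Qx, Qy), nu = 0, nv = 0)$d[seq_len(s)], B = B)
}
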