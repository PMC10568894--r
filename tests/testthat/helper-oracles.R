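# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the local-regression oracle builds the smoother matrix
# explicitly from the tricube weighted least-squares definition, and the
# bootstrap oracle enumerates every resample.

# Exhaustive pairs-bootstrap mean correlation for n pairs (n^n resamples),
# excluding degenerate resamples where either coordinate is constant.
enumerate_mean_correlation <- function(x, y) {
  n <- length(x)
  idx <- do.call(expand.grid, rep(list(seq_len(n)), n))
  rs <- apply(idx, 1, function(ii) {
    xs <- x[ii]
    ys <- y[ii]
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      return(NA_real_)
    }
    stats::cor(xs, ys)
  })
  mean(rs, na.rm = TRUE)
}

# Local weighted polynomial regression via explicit hat-matrix rows:
# for each target point, tricube weights over the floor(span * n) nearest
# neighbours, weighted least squares of the given degree, hat row
# l_i = e1' (X'WX)^-1 X'W. Standard errors follow Cleveland & Grosse:
# delta1 = n - 2 tr(L) + tr(L L'), s = sqrt(RSS / delta1),
# se_i = s * ||l_i||.
reference_local_regression <- function(y, x = seq_along(y), span = 0.17, degree = 2) {
  n <- length(y)
  q <- max(degree + 1L, min(n, floor(span * n)))
  L <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    dq <- sort(d)[q]
    w <- numeric(n)
    inside <- d < dq | (d <= dq & dq == 0)
    w[d <= dq] <- (1 - pmin(d[d <= dq] / max(dq, .Machine$double.eps), 1)^3)^3
    X <- outer(x - x[i], 0:degree, `^`)
    WX <- w * X
    A <- crossprod(X, WX)
    li <- solve(A, t(WX))[1, ]
    L[i, ] <- li
  }
  fitted <- as.numeric(L %*% y)
  res <- y - fitted
  delta1 <- n - 2 * sum(diag(L)) + sum(L * L)
  s <- sqrt(sum(res^2) / delta1)
  se <- s * sqrt(rowSums(L^2))
  list(fitted = fitted, se = se, s = s, delta1 = delta1, L = L)
}
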