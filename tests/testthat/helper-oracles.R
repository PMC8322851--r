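# Independent brute-force oracles, deliberately written as plain loops.

naive_feature_oracle <- function(x) {
  n <- length(x)
  mav <- 0; ss <- 0; mx <- -Inf
  for (xi in x) {
    mav <- mav + abs(xi); ss <- ss + xi^2
    if (xi > mx) mx <- xi
  }
  mc <- 0; mac <- 0; zc <- 0
  for (i in 1:(n - 1)) {
    mc <- mc + (x[i + 1] - x[i])
    mac <- mac + abs(x[i + 1] - x[i])
    if (x[i] * x[i + 1] < 0) zc <- zc + 1
  }
  m <- sum(x) / n
  v <- 0
  for (xi in x) v <- v + (xi - m)^2
  c(mav = mav / n, rms = sqrt(ss / n), mc = mc / n, mac = mac / n,
    max = mx, zc = zc, var = v / (n - 1))
}

# AR(3) oracle: an independent Yule-Walker solver (Levinson recursion via
# stats::ar.yw on the non-demeaned series)
arc_oracle <- function(x) {
  as.numeric(stats::ar.yw(x, aic = FALSE, order.max = 3, demean = FALSE)$ar)
}

# exhaustive two-sided permutation p-value by direct enumeration
perm_oracle <- function(a, b) {
  pooled <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  combos <- utils::combn(length(pooled), length(a))
  stats <- apply(combos, 2, function(idx) {
    abs(mean(pooled[idx]) - mean(pooled[-idx]))
  })
  mean(stats >= obs - 1e-12)
}
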