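# independent oracles used across test files

# sorted-order linear-interpolation percentile at position 1 + q(n-1)/100
oracle_percentile <- function(v, q) {
  s <- sort(v)
  n <- length(s)
  pos <- 1 + q * (n - 1) / 100
  lo <- floor(pos); hi <- ceiling(pos)
  s[lo] + (pos - lo) * (s[hi] - s[lo])
}

# pooled-variance two-sample t statistic and two-sided p, by the formula
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tt <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, p = 2 * pt(-abs(tt), df = n1 + n2 - 2))
}

# Jarque-Bera statistic from population moments, by the formula
oracle_jb <- function(v) {
  n <- length(v)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  s <- mean((v - m)^3) / m2^1.5
  k <- mean((v - m)^4) / m2^2
  n / 6 * (s^2 + (k - 3)^2 / 4)
}

# curvature score by explicit 2x2 covariance eigen-decomposition
oracle_curvature <- function(x, y) {
  xc <- x - mean(x); yc <- y - mean(y)
  cxx <- mean(xc^2); cyy <- mean(yc^2); cxy <- mean(xc * yc)
  tr <- cxx + cyy
  disc <- sqrt((cxx - cyy)^2 + 4 * cxy^2)
  lam_min <- (tr - disc) / 2
  lam_min / tr
}

groups_all <- c("crystalloid", "crystalloid_dextrose", "crystalloid_albumin")

baseline_state_for_test <- function(p) hemobia:::baseline_state(p)
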