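# Independent oracles used to verify the statistical primitives. Each is a
# different computational route from the implementation it checks.

# Exact multi-set intersection distribution by enumeration of
# membership-cell counts with multinomial weights (supports m = 2 or 3
# sets). Returns P(intersection = k) for k = 0..min(sizes).
oracle_multiset_pmf <- function(n, sizes) {
  m <- length(sizes)
  stopifnot(m %in% c(2, 3))
  log_total <- sum(lchoose(n, sizes))
  kmax <- min(sizes)
  if (m == 2) {
    a <- 0:kmax
    x1 <- sizes[1] - a
    x2 <- sizes[2] - a
    x0 <- n - sizes[1] - sizes[2] + a
    ok <- x1 >= 0 & x2 >= 0 & x0 >= 0
    lw <- lfactorial(n) - (lfactorial(a) + lfactorial(x1) +
                             lfactorial(x2) + lfactorial(x0)) - log_total
    out <- numeric(kmax + 1)
    out[a[ok] + 1] <- exp(lw[ok])
    return(out)
  }
  s <- sizes
  grid <- expand.grid(a = 0:min(s), x12 = 0:min(s[1], s[2]),
                      x13 = 0:min(s[1], s[3]), x23 = 0:min(s[2], s[3]))
  x1 <- s[1] - grid$a - grid$x12 - grid$x13
  x2 <- s[2] - grid$a - grid$x12 - grid$x23
  x3 <- s[3] - grid$a - grid$x13 - grid$x23
  used <- grid$a + grid$x12 + grid$x13 + grid$x23 + x1 + x2 + x3
  x0 <- n - used
  ok <- x1 >= 0 & x2 >= 0 & x3 >= 0 & x0 >= 0
  lw <- lfactorial(n) -
    (lfactorial(grid$a) + lfactorial(grid$x12) + lfactorial(grid$x13) +
       lfactorial(grid$x23) + lfactorial(x1) + lfactorial(x2) +
       lfactorial(x3) + lfactorial(x0)) - log_total
  agg <- tapply(exp(lw[ok]), grid$a[ok], sum)
  out <- numeric(kmax + 1)
  out[as.integer(names(agg)) + 1] <- agg
  out
}

oracle_multiset_pvalue <- function(n, sizes, k) {
  pmf <- oracle_multiset_pmf(n, sizes)
  sum(pmf[(k + 1):length(pmf)])
}

# Two-sided Fisher p by explicit hypergeometric enumeration from binomial
# coefficients ("probability at most that of the observed table").
oracle_fisher_two_sided <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; c1 <- a + c; n <- m1 + m2
  lo <- max(0, c1 - m2); hi <- min(c1, m1)
  x <- lo:hi
  probs <- exp(lchoose(m1, x) + lchoose(m2, c1 - x) - lchoose(n, c1))
  p_obs <- probs[x == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Pearson chi-square from the expected-count formula.
oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# Welch t and Satterthwaite df from the closed form.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Holm step-down adjustment by direct computation.
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Benjamini-Hochberg step-up adjustment by direct computation.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(n / (n - seq_len(n) + 1) * p[o]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Spearman's rho with average ranks, from the Pearson correlation of ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Closed-form Wright-Fisher endpoint variance after t generations.
oracle_wf_variance <- function(p0, ne, t) {
  p0 * (1 - p0) * (1 - (1 - 1 / (2 * ne))^t)
}
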