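# Independent oracles, written from the textbook definitions and kept free
# of the package's own code paths.

# Welch two-sample t-test: statistic, Welch-Satterthwaite df, two-sided p.
welch_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(y) - mean(x)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

# Benjamini-Hochberg step-up by brute force: q_i = min_{j: p_(j) >= p_(i)}
# of p_(j) * m / rank_j, capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Pearson correlation with the closed-form t = r * sqrt((n-2)/(1-r^2)).
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), n - 2))
}

# ---- exact big-integer arithmetic (base 1e4 limbs, little-endian) --------

big_from_int <- function(n) {
  stopifnot(n >= 0, n < 1e4)
  as.integer(n)
}

big_norm <- function(b) {
  carry <- 0
  out <- integer(0)
  for (i in seq_along(b)) {
    v <- b[i] + carry
    out[i] <- v %% 1e4
    carry <- v %/% 1e4
  }
  while (carry > 0) {
    out <- c(out, carry %% 1e4)
    carry <- carry %/% 1e4
  }
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_mul_small <- function(b, k) big_norm(b * k)

# exact school division by a small integer (must divide exactly when used
# for binomial coefficients)
big_div_small <- function(b, k) {
  out <- integer(length(b))
  rem <- 0
  for (i in rev(seq_along(b))) {
    cur <- rem * 1e4 + b[i]
    out[i] <- cur %/% k
    rem <- cur %% k
  }
  stopifnot(rem == 0)
  while (length(out) > 1 && out[length(out)] == 0) out <- out[-length(out)]
  out
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_norm(c(a, integer(n - length(a))) + c(b, integer(n - length(b))))
}

# limbwise products stay far below 2^53, so one final normalization is exact
big_mul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  big_norm(out)
}

# C(n, k) as a bignum via exact multiply/divide
big_choose <- function(n, k) {
  if (k < 0 || k > n) return(big_from_int(0))
  k <- min(k, n - k)
  res <- big_from_int(1)
  for (i in seq_len(k)) {
    res <- big_mul_small(res, n - k + i)
    res <- big_div_small(res, i)
  }
  res
}

# bignum -> (mantissa in [1, 1e4), exponent in limbs)
big_to_mant_exp <- function(b) {
  nl <- length(b)
  top <- b[max(1, nl - 3):nl]
  mant <- sum(top * 1e4^(seq_along(top) - 1)) / 1e4^(length(top) - 1)
  list(mant = mant, exp = nl - 1)
}

big_ratio <- function(num, den) {
  if (length(num) == 1 && num == 0) return(0)
  a <- big_to_mant_exp(num)
  b <- big_to_mant_exp(den)
  (a$mant / b$mant) * 1e4^(a$exp - b$exp)
}

# Upper-tail hypergeometric P(X >= k) with K marked genes, universe N,
# query n, by exact combinatorial summation.
hyper_tail_oracle <- function(k, K, N, n) {
  num <- big_from_int(0)
  for (j in seq(max(k, 0), min(K, n))) {
    num <- big_add(num, big_mul(big_choose(K, j), big_choose(N - K, n - j)))
  }
  big_ratio(num, big_choose(N, n))
}
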