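# Independently coded brute-force references. These deliberately avoid the
# package's vectorized implementations: plain loops and textbook formulas
# only, so agreement is a genuine dual-route check.

oracle_indices <- function(x) {
  x <- x[x > 0]
  p <- x / sum(x)
  S <- 0L; H <- 0; sum2 <- 0; pmax <- 0
  for (pi in p) {
    S <- S + 1L
    H <- H - pi * log(pi)
    sum2 <- sum2 + pi * pi
    if (pi > pmax) pmax <- pi
  }
  c(S = S, H = H, D1 = 1 - sum2, D2 = 1 / sum2, BP = pmax,
    E = (1 / sum2) / S)
}

oracle_hill <- function(x, a) {
  x <- x[x > 0]
  p <- x / sum(x)
  if (is.infinite(a)) return(1 / max(p))
  if (abs(a - 1) < 1e-9) {
    H <- 0
    for (pi in p) H <- H - pi * log(pi)
    return(exp(H))
  }
  s <- 0
  for (pi in p) s <- s + pi^a
  s^(1 / (1 - a))
}

oracle_richness <- function(pres) {
  pres <- pres[, colSums(pres) > 0, drop = FALSE]
  N <- nrow(pres)
  f <- colSums(pres)
  S_obs <- length(f)
  q1 <- sum(f == 1)
  q2 <- sum(f == 2)
  chao <- if (q2 > 0) {
    S_obs + (N - 1) / N * q1^2 / (2 * q2)
  } else {
    S_obs + (N - 1) / N * q1 * (q1 - 1) / 2
  }
  c(chao = chao,
    jackknife1 = S_obs + q1 * (N - 1) / N,
    bootstrap = S_obs + sum((1 - f / N)^N))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(-abs(tstat), n - 2))
}

oracle_ols <- function(y, x) {
  n <- length(y)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  rss <- sum((y - a - b * x)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  Fstat <- r2 / (1 - r2) * (n - 2)
  c(F = Fstat, p = stats::pf(Fstat, 1, n - 2, lower.tail = FALSE),
    r = sign(b) * sqrt(r2))
}

# correlation matrix built element-by-element, then a plain symmetric
# eigendecomposition (the package goes through SVD of the scaled data)
oracle_cor_eigenvalues <- function(X) {
  m <- ncol(X)
  R <- diag(m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i != j) R[i, j] <- unname(oracle_pearson(X[, i], X[, j])["r"])
    }
  }
  eigen(R, symmetric = TRUE)$values
}

random_abundance <- function(S = NULL) {
  if (is.null(S)) S <- sample(2:40, 1)
  stats::rgamma(S, shape = stats::runif(1, 0.3, 2))
}
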