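# small fixture builders shared across the suite

# random regression problem with named predictors
rand_problem <- function(n, p, seed, beta = NULL, noise_sd = 0.3) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  if (is.null(beta)) beta <- rnorm(p)
  y <- drop(x %*% beta) + rnorm(n, sd = noise_sd)
  list(x = x, y = y, beta = beta)
}

# centered columns, mutually orthogonal, each with unit sample SD,
# so autoscaling leaves the matrix proportionally unchanged
orthonormal_x <- function(n, p, seed) {
  set.seed(seed)
  m <- scale(matrix(rnorm(n * (p + 1)), n, p + 1), scale = FALSE)
  q <- qr.Q(qr(m))[, seq_len(p), drop = FALSE]
  q <- sweep(q, 2, apply(q, 2, sd), "/")
  colnames(q) <- paste0("v", seq_len(p))
  q
}

# wine_dataset with given stratum counts and random chemistry
strata_dataset <- function(counts, p = 3, seed = 1) {
  set.seed(seed)
  labels <- names(counts)
  stratum <- rep(labels, counts)
  n <- length(stratum)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  wine_dataset(sprintf("s%03d", seq_len(n)), stratum, x, rnorm(n, 3, 1))
}

# the study design: 12 strata, 110 samples
design_counts <- function() {
  c(AGL = 10, CAN = 9, COR = 7, MON = 9, NEB = 11, NER = 3,
    PRI = 11, RAB = 10, SAG = 10, SAR = 12, SAT = 7, TER = 11)
}

# independent brute force for Cook's distance: delete one sample, refit
# the score regression, and measure the shift in all fitted values
cooks_brute <- function(x, y, ncomp) {
  fit <- spi_pls(x, y, ncomp = ncomp)
  scores <- fit$scores
  n <- nrow(scores); pprime <- ncol(scores) + 1
  lmf <- stats::lm(y ~ scores)
  yhat <- stats::fitted(lmf)
  s2 <- sum(stats::residuals(lmf)^2) / (n - pprime)
  vapply(seq_len(n), function(i) {
    cf <- stats::coef(stats::lm(y[-i] ~ scores[-i, , drop = FALSE]))
    yhat_i <- drop(cbind(1, scores) %*% cf)
    sum((yhat - yhat_i)^2) / (pprime * s2)
  }, numeric(1))
}

# OLS coefficients on autoscaled data: the full-rank PLS oracle
ols_scaled <- function(x, y) {
  xs <- scale(x)
  ys <- drop(scale(y))
  unname(drop(solve(crossprod(xs), crossprod(xs, ys))))
}
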