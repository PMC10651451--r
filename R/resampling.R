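#' Repeated randomized k-fold cross-validation of a PLS1 model
#'
#' Runs `reps` repetitions of random `k`-fold cross-validation. Folds are
#' re-randomized every repetition; every sample is held out exactly once per
#' repetition. By default the autoscaling is refit inside each training
#' segment so no held-out statistic ever leaks into the fit
#' (`scale_in_cv = FALSE` reproduces the variant that scales once on the
#' full training set before segmenting). Held-out predictions are pooled
#' across all repetitions: `RMSEcv(A)` is the root of the pooled mean
#' squared held-out error using `A` components and
#' `R2cv(A) = 1 - MSEcv(A) / Var_n(y)`. Per-segment scaled coefficient sets
#' are retained for jack-knife significance.
#'
#' @param x numeric predictor matrix.
#' @param y numeric response (raw units).
#' @param ncomp_max largest component count evaluated; clamped to
#'   `min(n - ceiling(n/k) - 1, p)` so every segment can support it.
#' @param k number of folds (2..n).
#' @param reps number of repetitions.
#' @param seed integer seed controlling the fold randomization.
#' @param scale_in_cv logical; refit autoscaling per training segment
#'   (default `TRUE`).
#' @return An object of class `pls_cv`: list with `RMSEcv` and `R2cv`
#'   (length `ncomp_max`), `pred` (n x ncomp_max x reps held-out
#'   predictions, raw units), `seg_coefs` (p x ncomp_max x k*reps scaled
#'   coefficient sets, segment index varying fold fastest), `fold_rep` /
#'   `fold_id` bookkeeping, `ncomp_best = which.min(RMSEcv)` and the
#'   configuration.
#' @export
pls_cv <- function(x, y, ncomp_max, k = 8, reps = 10, seed = 1L,
                   scale_in_cv = TRUE) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of samples")
  a_cap <- min(n - ceiling(n / k) - 1, p)
  if (a_cap < 1) stop("too few samples per segment for even one component")
  ncomp_max <- as.integer(min(ncomp_max, a_cap))

  full_scaler <- if (!scale_in_cv) fit_scaler(x, y)
  pred <- array(NA_real_, c(n, ncomp_max, reps))
  seg_coefs <- array(NA_real_, c(p, ncomp_max, k * reps),
                     dimnames = list(colnames(x), NULL, NULL))
  folds <- matrix(NA_integer_, n, reps)

  with_seed(seed, {
    for (r in seq_len(reps)) {
      fold <- sample(rep(seq_len(k), length.out = n))
      folds[, r] <- fold
      for (m in seq_len(k)) {
        hold <- fold == m
        xt <- x[!hold, , drop = FALSE]; yt <- y[!hold]
        scaler <- if (scale_in_cv) fit_scaler(xt, yt) else full_scaler
        sc <- apply_scaler(scaler, xt, yt)
        core <- nipals_pls1(sc$x, sc$y, ncomp_max)
        xs_hold <- apply_scaler(scaler, x = x[hold, , drop = FALSE])
        seg <- (r - 1L) * k + m
        for (a in seq_len(ncomp_max)) {
          a_use <- min(a, max(core$ncomp, 1L))
          b <- if (core$ncomp == 0L) numeric(p) else {
            Wa <- core$W[, seq_len(a_use), drop = FALSE]
            Pa <- core$P[, seq_len(a_use), drop = FALSE]
            drop(Wa %*% solve(crossprod(Pa, Wa), core$q[seq_len(a_use)]))
          }
          seg_coefs[, a, seg] <- b
          pred[hold, a, r] <- invert_scaler(scaler, y = drop(xs_hold %*% b))
        }
      }
    }
  })

  err2 <- sweep(pred, 1, y, FUN = function(p, y) (y - p)^2)
  msecv <- apply(err2, 2, mean)          # pooled over samples and reps
  var_n <- mean((y - mean(y))^2)
  structure(
    list(RMSEcv = sqrt(msecv), R2cv = 1 - msecv / var_n,
         ncomp_best = which.min(sqrt(msecv)),
         pred = pred, seg_coefs = seg_coefs, folds = folds,
         y = y, k = k, reps = reps, ncomp_max = ncomp_max,
         scale_in_cv = scale_in_cv, seed = seed),
    class = "pls_cv"
  )
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("Repeated %d-fold CV, %d repetition(s), up to %d component(s)\n",
              x$k, x$reps, x$ncomp_max))
  tab <- data.frame(ncomp = seq_len(x$ncomp_max),
                    RMSEcv = x$RMSEcv, R2cv = x$R2cv)
  print(tab, row.names = FALSE, digits = 4)
  cat("RMSEcv minimum at", x$ncomp_best, "component(s)\n")
  invisible(x)
}

#' Jack-knife significance of PLS regression coefficients
#'
#' Estimates the uncertainty of each scaled-unit regression coefficient from
#' the spread of the cross-validation segment models (Martens' jack-knife).
#' Within repetition r with folds m = 1..k:
#' \deqn{s_{j,r}^2 = \frac{k-1}{k} \sum_m (b_j - b_j^{(m)})^2,}
#' where `b_j` is the full-model coefficient; variances are averaged over
#' repetitions, \eqn{t_j = b_j / s_j} is referred to a Student t
#' distribution with `df = k - 1`, and the two-sided p-value and the
#' `1 - alpha_level` confidence interval follow. A degenerate `s_j = 0`
#' (all segment models identical) yields p = 0 for a nonzero coefficient
#' and p = 1 otherwise.
#'
#' @param cv a [pls_cv()] result holding segment coefficients.
#' @param b_full full-model scaled coefficients (`coef(fit, type =
#'   "scaled")`), same predictors as the CV.
#' @param ncomp component count at which coefficients are compared.
#' @param alpha_level significance level for the confidence interval.
#' @return An object of class `spi_jackknife`: data.frame with one row per
#'   variable — `variable`, `coef`, `se`, `t`, `df`, `p_value`, `ci_lo`,
#'   `ci_hi`.
#' @export
jackknife_significance <- function(cv, b_full, ncomp = cv$ncomp_best,
                                   alpha_level = 0.05) {
  stopifnot(inherits(cv, "pls_cv"))
  if (ncomp < 1 || ncomp > cv$ncomp_max)
    stop("ncomp not available in this CV result")
  p <- dim(cv$seg_coefs)[1]
  if (length(b_full) != p) stop("b_full length does not match CV predictors")
  k <- cv$k
  segb <- cv$seg_coefs[, ncomp, , drop = TRUE]      # p x (k*reps)
  segb <- matrix(segb, nrow = p)
  s2_rep <- vapply(seq_len(cv$reps), function(r) {
    cols <- (r - 1L) * k + seq_len(k)
    dev2 <- (segb[, cols, drop = FALSE] - b_full)^2
    (k - 1) / k * rowSums(dev2)
  }, numeric(p))
  s2 <- rowMeans(matrix(s2_rep, nrow = p))
  se <- sqrt(s2)
  df <- k - 1
  tstat <- ifelse(se > 0, b_full / se,
                  ifelse(b_full != 0, Inf, 0))
  pval <- ifelse(se > 0, 2 * stats::pt(-abs(b_full / se), df),
                 ifelse(b_full != 0, 0, 1))
  tcrit <- stats::qt(1 - alpha_level / 2, df)
  nm <- dimnames(cv$seg_coefs)[[1]] %||% names(b_full) %||%
    paste0("V", seq_len(p))
  out <- data.frame(
    variable = nm, coef = unname(b_full), se = se, t = tstat,
    df = df, p_value = pval,
    ci_lo = unname(b_full) - tcrit * se,
    ci_hi = unname(b_full) + tcrit * se,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("spi_jackknife", "data.frame")
  out
}

#' Randomized permutation test for the number of PLS components
#'
#' Tests each latent component against the null hypothesis of no
#' predictor-response association. The statistic of component a is the
#' absolute covariance of its score pair,
#' \eqn{c_a = |t_a' u_a|}, with `t_a` the X-score and `u_a` the response
#' residual entering component a (after a-1 deflations). The null
#' distribution is built by refitting the model on `nperm` random
#' permutations of the response; the significance is the exceedance
#' fraction with the add-one rule,
#' \eqn{\alpha_a = (1 + \#\{c^{null}_a \ge c_a\}) / (nperm + 1)},
#' so it is never exactly zero. Components a permuted response explains as
#' well as the real one are non-significant (high alpha).
#'
#' @param x numeric predictor matrix.
#' @param y numeric response.
#' @param ncomp_max number of components tested.
#' @param nperm number of permutations (>= 99).
#' @param seed integer seed for the permutations.
#' @return An object of class `spi_randtest`: list with `table`
#'   (data.frame `ncomp`, `statistic`, `alpha`), `null` (nperm x ncomp_max
#'   matrix of null statistics) and the configuration.
#' @seealso [select_ncomp()]
#' @export
randomization_test <- function(x, y, ncomp_max, nperm = 1000, seed = 1L) {
  x <- as.matrix(x); y <- as.numeric(y)
  if (nperm < 99) stop("nperm must be at least 99")
  if (ncomp_max < 1) stop("ncomp_max must be at least 1")
  if (stats::sd(y) == 0) stop("constant response")
  ncomp_max <- as.integer(min(ncomp_max, nrow(x) - 1, ncol(x)))
  scaler <- fit_scaler(x, y)
  sc <- apply_scaler(scaler, x, y)
  c_obs <- score_cov_stats(sc$x, sc$y, ncomp_max)
  null <- with_seed(seed, {
    draws <- vapply(seq_len(nperm), function(i) {
      score_cov_stats(sc$x, sample(sc$y), ncomp_max)
    }, numeric(ncomp_max))
    # vapply collapses to a vector when ncomp_max == 1
    t(matrix(draws, nrow = ncomp_max, ncol = nperm))
  })
  alpha <- vapply(seq_len(ncomp_max), function(a) {
    (1 + sum(null[, a] >= c_obs[a])) / (nperm + 1)
  }, numeric(1))
  structure(
    list(table = data.frame(ncomp = seq_len(ncomp_max),
                            statistic = c_obs, alpha = alpha),
         null = null, nperm = nperm, seed = seed),
    class = "spi_randtest"
  )
}

# |t_a' u_a| per component; u_a is the deflated response entering step a.
# Since q_a = t_a'u_a / (t_a't_a), the statistic is |q_a| * t_a't_a.
# Components the fit cannot extract get statistic 0.
score_cov_stats <- function(xs, ys, ncomp_max) {
  core <- nipals_pls1(xs, ys, ncomp_max)
  out <- numeric(ncomp_max)
  if (core$ncomp >= 1) {
    tt <- colSums(core$scores^2)
    out[seq_len(core$ncomp)] <- abs(core$q) * tt
  }
  out
}

#' @export
print.spi_randtest <- function(x, ...) {
  cat(sprintf("Randomized component test, %d permutations\n", x$nperm))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Number of significant components from a randomization test
#'
#' Returns the largest A such that components 1..A all have
#' `alpha <= alpha_crit`; 0 when even the first component is
#' non-significant.
#'
#' @param rt an [randomization_test()] result.
#' @param alpha_crit critical alpha (default 0.05).
#' @return Integer component count (possibly 0).
#' @export
select_ncomp <- function(rt, alpha_crit = 0.05) {
  stopifnot(inherits(rt, "spi_randtest"))
  ok <- rt$table$alpha <= alpha_crit
  if (!ok[1]) return(0L)
  bad <- which(!ok)
  if (!length(bad)) nrow(rt$table) else as.integer(bad[1] - 1L)
}
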