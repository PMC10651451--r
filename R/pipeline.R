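#' Pipeline configuration
#'
#' Tunable parameters of [run_spi_pipeline()], with the calibration
#' defaults: 70/30 stratified split, 8-fold cross-validation with 10
#' repetitions, 1000 permutations, VIP threshold 1.0, first-pass p
#' threshold 0.1, backward-elimination p threshold 0.05, critical alpha
#' 0.05, Cook's rule 4/n.
#'
#' @param train_frac training fraction of the stratified split.
#' @param k,reps cross-validation folds and repetitions.
#' @param nperm permutations of the randomized component test.
#' @param vip_threshold VIP score below which a variable is a removal
#'   candidate in the first filter.
#' @param p_stage1 jack-knife p-value above which a variable is a removal
#'   candidate in the first filter.
#' @param p_stage2 significance level of the backward elimination.
#' @param alpha_crit critical alpha of the randomized component test.
#' @param outlier_rule Cook's-distance flag rule ([flag_outliers()]).
#' @param stage1_rule `"and"`: remove iff (VIP < threshold AND
#'   p > threshold); `"or"`: remove iff either condition holds (i.e. keep
#'   only variables that are both important and significant).
#' @param scale_in_cv refit autoscaling per CV segment.
#' @param max_components largest component count explored.
#' @param seed integer master seed.
#' @return A validated list of class `spi_config`.
#' @export
pipeline_config <- function(train_frac = 0.7, k = 8, reps = 10,
                            nperm = 1000, vip_threshold = 1.0,
                            p_stage1 = 0.1, p_stage2 = 0.05,
                            alpha_crit = 0.05, outlier_rule = "4/n",
                            stage1_rule = c("and", "or"),
                            scale_in_cv = TRUE, max_components = 10,
                            seed = 1L) {
  stage1_rule <- match.arg(stage1_rule)
  stopifnot(train_frac > 0, train_frac < 1, k >= 2, reps >= 1, nperm >= 99)
  structure(
    list(train_frac = train_frac, k = k, reps = reps, nperm = nperm,
         vip_threshold = vip_threshold, p_stage1 = p_stage1,
         p_stage2 = p_stage2, alpha_crit = alpha_crit,
         outlier_rule = outlier_rule, stage1_rule = stage1_rule,
         scale_in_cv = scale_in_cv,
         max_components = as.integer(max_components),
         seed = as.integer(seed)),
    class = "spi_config"
  )
}

#' First variable filter: VIP score and jack-knife significance
#'
#' Under the default `"and"` rule a variable is removed only when it is
#' both unimportant (VIP < `vip_threshold`) and non-significant
#' (p > `p_threshold`); a variable strong on either count survives. The
#' `"or"` rule removes a variable when either condition holds.
#'
#' @param vip named VIP scores (from [vip()]).
#' @param jack an [jackknife_significance()] result covering the same
#'   variables.
#' @param vip_threshold VIP cut (default 1.0).
#' @param p_threshold p-value cut (default 0.1).
#' @param rule `"and"` (default) or `"or"`.
#' @return List with `kept` and `removed` character vectors (`removed`
#'   carries the rule as an attribute).
#' @export
stage1_filter <- function(vip, jack, vip_threshold = 1.0,
                          p_threshold = 0.1, rule = c("and", "or")) {
  rule <- match.arg(rule)
  stopifnot(inherits(jack, "spi_jackknife"))
  vars <- names(vip)
  if (!setequal(vars, jack$variable))
    stop("vip and jack-knife results cover different variables")
  p <- jack$p_value[match(vars, jack$variable)]
  low_vip <- vip < vip_threshold
  high_p <- p > p_threshold
  drop <- if (rule == "and") low_vip & high_p else low_vip | high_p
  if (all(drop))
    stop("first filter removed every variable; relax vip_threshold or ",
         "p_threshold")
  removed <- vars[drop]
  attr(removed, "rule") <- rule
  list(kept = vars[!drop], removed = removed)
}

#' Backward elimination by jack-knife significance
#'
#' Starting from the given variable set, repeatedly refits the model
#' (component count at the cross-validation RMSE minimum), recomputes
#' jack-knife p-values, and removes the single variable with the largest
#' p-value above `p_threshold` (exact ties: first in column order), until
#' every remaining coefficient is significant.
#'
#' @param x predictor matrix (training, candidate variables as columns).
#' @param y response.
#' @param p_threshold significance level (default 0.05).
#' @param config an [pipeline_config()] supplying k, reps, seed,
#'   scale_in_cv and max_components.
#' @return List with `kept` (character), `trace` (data.frame: one row per
#'   removal — `step`, `variable_removed`, `p_removed`, `model_size_after`,
#'   `ncomp_used`, `RMSEcv_before`), `cv` and `fit` for the final set.
#' @export
stage2_backward <- function(x, y, p_threshold = 0.05,
                            config = pipeline_config()) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least 2 variables to eliminate from")
  vars <- colnames(x)
  trace <- list()
  step <- 0L
  repeat {
    xk <- x[, vars, drop = FALSE]
    cv <- pls_cv(xk, y, config$max_components, k = config$k,
                 reps = config$reps, seed = config$seed,
                 scale_in_cv = config$scale_in_cv)
    a <- cv$ncomp_best
    fit <- spi_pls(xk, y, ncomp = a)
    a <- fit$ncomp
    jack <- jackknife_significance(cv, coef(fit, ncomp = a,
                                            type = "scaled"), ncomp = a)
    insig <- jack$p_value > p_threshold
    if (!any(insig)) break
    worst <- which(jack$p_value == max(jack$p_value[insig]) & insig)[1]
    victim <- jack$variable[worst]
    if (length(vars) == 1L)
      stop("backward elimination removed every variable")
    step <- step + 1L
    trace[[step]] <- data.frame(
      step = step, variable_removed = victim,
      p_removed = jack$p_value[worst],
      model_size_after = length(vars) - 1L,
      ncomp_used = a, RMSEcv_before = cv$RMSEcv[a],
      stringsAsFactors = FALSE
    )
    vars <- setdiff(vars, victim)
    if (length(vars) < 2) {
      # single survivor: keep it only if it is itself significant
      xk <- x[, vars, drop = FALSE]
      cv <- pls_cv(xk, y, 1, k = config$k, reps = config$reps,
                   seed = config$seed, scale_in_cv = config$scale_in_cv)
      fit <- spi_pls(xk, y, ncomp = 1)
      jack <- jackknife_significance(cv, coef(fit, 1, type = "scaled"), 1)
      if (jack$p_value[1] > p_threshold)
        stop("backward elimination removed every variable")
      break
    }
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), variable_removed = character(),
               p_removed = numeric(), model_size_after = integer(),
               ncomp_used = integer(), RMSEcv_before = numeric())
  list(kept = vars, trace = trace, cv = cv, fit = fit)
}

#' Run the full SPI calibration pipeline
#'
#' Orchestrates the staged model sequence:
#' \enumerate{
#'   \item stratified 70/30 split (test partition untouched until the end);
#'   \item `m0`: PLS on all variables, component count at the CV RMSE
#'     minimum;
#'   \item Cook's-distance screening on the score regression, flagged
#'     training samples removed;
#'   \item `m1`: refit on the cleaned training set;
#'   \item variable selection: VIP + jack-knife first filter, then
#'     backward elimination at `p_stage2`;
#'   \item `m2`: refit on the selected variables;
#'   \item randomized component test and overfitting control; the final
#'     component count is the smaller of the largest significant and the
#'     largest admissible count;
#'   \item `m3`: final model, then a single evaluation pass over the test
#'     partition for every stage model.
#' }
#' When the randomized test finds no significant component (or no
#' component count passes the overfitting control), no final model is
#' fitted and `status` records the refusal.
#'
#' @param dataset a [wine_dataset].
#' @param config an [pipeline_config()].
#' @return An object of class `spi_pipeline`: list with `summary` (stage x
#'   metric data.frame in the style of a calibration report), `split`,
#'   `outliers` (report + flagged ids), `stage1` (filter record), `trace`
#'   (backward-elimination trace), `randtest`, `overfit`, `models` (the
#'   per-stage `spi_pls` fits), `final_model`, `test_eval` (per-stratum
#'   RMSE of the final model), `status` and `config`.
#' @export
run_spi_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "wine_dataset"))
  split <- stratified_split(dataset, config$train_frac, seed = config$seed)
  train <- split$train
  test_checksum <- dataset_checksum(split$test)

  # m0: all samples, all variables
  cv0 <- pls_cv(train$x, train$y, config$max_components, k = config$k,
                reps = config$reps, seed = config$seed,
                scale_in_cv = config$scale_in_cv)
  fit0 <- spi_pls(train$x, train$y, ncomp = cv0$ncomp_best)

  # Cook's screening at the pilot component count
  cooks <- pls_cooks(train$x, train$y, ncomp = cv0$ncomp_best,
                     sample_id = train$sample_id)
  flagged <- flag_outliers(cooks, rule = config$outlier_rule)
  train1 <- subset_samples(train, !(train$sample_id %in% flagged))

  # m1: outliers removed
  cv1 <- pls_cv(train1$x, train1$y, config$max_components, k = config$k,
                reps = config$reps, seed = config$seed,
                scale_in_cv = config$scale_in_cv)
  fit1 <- spi_pls(train1$x, train1$y, ncomp = cv1$ncomp_best)

  # variable selection
  jack1 <- jackknife_significance(
    cv1, coef(fit1, ncomp = fit1$ncomp, type = "scaled"),
    ncomp = fit1$ncomp
  )
  s1 <- stage1_filter(vip(fit1, fit1$ncomp), jack1,
                      vip_threshold = config$vip_threshold,
                      p_threshold = config$p_stage1,
                      rule = config$stage1_rule)
  s2 <- tryCatch(
    stage2_backward(train1$x[, s1$kept, drop = FALSE], train1$y,
                    p_threshold = config$p_stage2, config = config),
    error = function(e) e
  )

  if (inherits(s2, "error")) {
    # nothing survives significance-based selection: report the refusal,
    # with the randomized test on the first-filter set as evidence
    rt <- randomization_test(train1$x[, s1$kept, drop = FALSE], train1$y,
                             ncomp_max = cv1$ncomp_max,
                             nperm = config$nperm, seed = config$seed)
    s2 <- list(kept = character(0),
               trace = data.frame(), cv = NULL, fit = NULL)
    cv2 <- fit2 <- fit3 <- ovf <- NULL
    a_sig <- select_ncomp(rt, alpha_crit = config$alpha_crit)
    a_adm <- 0L
    a_final <- 0L
    status <- "no significant model: backward elimination removed every variable"
  } else {
    # m2: selected variables
    cv2 <- s2$cv
    fit2 <- s2$fit

    # component significance and overfitting control
    rt <- randomization_test(train1$x[, s2$kept, drop = FALSE], train1$y,
                             ncomp_max = cv2$ncomp_max, nperm = config$nperm,
                             seed = config$seed)
    a_sig <- select_ncomp(rt, alpha_crit = config$alpha_crit)
    fit2_full <- spi_pls(train1$x[, s2$kept, drop = FALSE], train1$y,
                         ncomp = cv2$ncomp_max)
    cal2 <- summary(fit2_full)$per_component
    ovf <- overfit_report(cal2, cv2)
    a_adm <- if (length(ovf$admissible_ncomp)) max(ovf$admissible_ncomp)
             else 0L

    status <- "ok"
    fit3 <- NULL
    a_final <- min(a_sig, a_adm)
    if (a_sig == 0L) {
      status <- "no significant model: first component fails the randomized test"
    } else if (a_adm == 0L) {
      status <- "no admissible model: every component count fails the overfitting control"
    } else {
      fit3 <- spi_pls(train1$x[, s2$kept, drop = FALSE], train1$y,
                      ncomp = a_final)
    }
  }

  # single evaluation pass over the untouched test partition
  stopifnot(identical(dataset_checksum(split$test), test_checksum))
  models <- list(m0 = fit0, m1 = fit1, m2 = fit2, m3 = fit3)
  cvs <- list(m0 = cv0, m1 = cv1, m2 = cv2,
              m3 = if (!is.null(fit3)) cv2)
  summary_tab <- do.call(rbind, lapply(names(models), function(st) {
    f <- models[[st]]
    if (is.null(f)) return(NULL)
    a <- if (st == "m3") a_final else f$ncomp
    cal <- r2_rmse(f$y, predict(f, f$x, ncomp = a))
    cvr <- cvs[[st]]
    tst <- r2_rmse(split$test$y, predict(f, split$test, ncomp = a))
    data.frame(model = st, n_samples = f$n, n_variables = f$p, ncomp = a,
               R2cal = cal$R2, R2cv = cvr$R2cv[a], RMSEcal = cal$RMSE,
               RMSEcv = cvr$RMSEcv[a], R2test = tst$R2, RMSEtest = tst$RMSE,
               stringsAsFactors = FALSE)
  }))
  test_eval <- if (!is.null(fit3))
    evaluate_on_test(fit3, split$test, ncomp = a_final)

  structure(
    list(summary = summary_tab, split = split,
         outliers = list(report = cooks, flagged = flagged,
                         rule = config$outlier_rule),
         stage1 = s1, trace = s2$trace, randtest = rt, overfit = ovf,
         ncomp_significant = a_sig, ncomp_admissible = a_adm,
         models = models, final_model = fit3, final_ncomp =
           if (!is.null(fit3)) a_final else NA_integer_,
         selected_variables = s2$kept,
         test_eval = test_eval, status = status, config = config),
    class = "spi_pipeline"
  )
}

dataset_checksum <- function(dataset) {
  c(n = length(dataset$y), sum_y = sum(dataset$y), sum_x = sum(dataset$x),
    id = sum(utf8ToInt(paste(dataset$sample_id, collapse = ""))))
}

#' @export
print.spi_pipeline <- function(x, ...) {
  cat("SPI calibration pipeline\n")
  cat(sprintf("  split: %d train / %d test; %d outlier(s) removed (%s)\n",
              length(x$split$train$y), length(x$split$test$y),
              length(x$outliers$flagged), x$outliers$rule))
  cat(sprintf("  selection: %d -> %d variables; %d significant / %d admissible component(s)\n",
              x$models$m1$p, length(x$selected_variables),
              x$ncomp_significant, x$ncomp_admissible))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE, digits = 3)
  if (x$status != "ok") cat("  status:", x$status, "\n")
  invisible(x)
}

#' Evaluate a fitted model on a held-out test set
#'
#' @param model an `spi_pls` fit (or any object with a `predict` method
#'   over the test predictors).
#' @param test a [wine_dataset] held out from all training decisions.
#' @param ncomp component count for prediction (spi_pls models).
#' @return List with `metrics` (`R2`, `RMSE`) and `per_stratum`
#'   (data.frame `stratum`, `n`, `RMSE`; for a single-sample stratum the
#'   RMSE is that sample's absolute error).
#' @export
evaluate_on_test <- function(model, test, ncomp = NULL) {
  stopifnot(inherits(test, "wine_dataset"))
  yh <- if (inherits(model, "spi_pls"))
    predict(model, test, ncomp = ncomp %||% model$ncomp)
  else predict(model, test)
  m <- r2_rmse(test$y, yh)
  err2 <- (test$y - yh)^2
  strata <- unique(test$stratum)
  per <- data.frame(
    stratum = strata,
    n = vapply(strata, function(s) sum(test$stratum == s), integer(1)),
    RMSE = vapply(strata, function(s)
      sqrt(mean(err2[test$stratum == s])), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(metrics = m, per_stratum = per)
}
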