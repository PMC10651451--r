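#' Study-design stratum counts
#'
#' The default sampling design of the generator: 12 variety-x-region strata
#' of Italian mono-varietal red wines, 110 samples in total.
#'
#' @return data.frame with `label` and `count`.
#' @export
default_strata <- function() {
  data.frame(
    label = c("AGL", "CAN", "COR", "MON", "NEB", "NER",
              "PRI", "RAB", "SAG", "SAR", "SAT", "TER"),
    count = c(10L, 9L, 7L, 9L, 11L, 3L, 11L, 10L, 10L, 12L, 7L, 11L),
    stringsAsFactors = FALSE
  )
}

#' Default per-stratum SPI levels
#'
#' Stratum mean SPI values (g/L GAE) used by the generator, spanning the
#' roughly 1.7-5.9 g/L range that separates low-astringency (e.g. Corvina,
#' Nerello Mascalese) from high-astringency (Aglianico, Sagrantino) wines.
#'
#' @return Named numeric vector, one mean per stratum label.
#' @export
default_stratum_means <- function() {
  c(AGL = 5.9, CAN = 4.0, COR = 1.7, MON = 3.6, NEB = 4.5, NER = 1.7,
    PRI = 3.2, RAB = 5.1, SAG = 5.8, SAR = 3.5, SAT = 3.4, TER = 2.9)
}

# 52 physico-chemical parameter names; the first 19 are the active set
default_predictor_names <- function() {
  c("procyanidin_B1", "epicatechin_terminal", "total_aldehydes",
    "protein_content", "vanillin_assay", "abs_520nm", "polysaccharides",
    "epigallocatechin_phl", "tartaric_acid", "volatile_acidity",
    "titratable_acidity", "catechin_terminal", "proanthocyanidin_assay",
    "pH", "tannin_fe_anthocyanin", "buffer_capacity",
    "epigallocatechin_gallate_phl", "catechin_epicatechin_phl", "tannin_fe",
    "alcohol", "mDP", "mDP_normalized", "total_anthocyanins",
    "free_anthocyanins", "polymeric_pigments_small",
    "polymeric_pigments_large", "malic_acid", "lactic_acid", "citric_acid",
    "succinic_acid", "acetaldehyde", "abs_420nm", "abs_620nm",
    "color_intensity", "hue", "total_phenols", "total_flavonoids",
    "procyanidin_B2", "procyanidin_B3", "procyanidin_B4", "procyanidin_C1",
    "catechin_free", "epicatechin_free", "gallic_acid", "caffeic_acid",
    "coumaric_acid", "quercetin", "glycerol", "reducing_sugars",
    "potassium", "calcium", "dry_extract")
}

#' Default active variable set
#'
#' The 19 active predictors of the generator's sparse linear response, with
#' standardized true coefficients (SPI g/L GAE per predictor SD): 12
#' positive and 7 negative signs, magnitudes descending with the variable's
#' importance rank. Effect sizes are benchmark-design choices: the weakest
#' active is still detectable at the default calibration size (n around 72).
#'
#' @return data.frame with `name` and `beta`.
#' @export
default_active_set <- function() {
  name <- default_predictor_names()[1:19]
  sign <- c(+1, -1, -1, -1, +1, +1, -1, -1, +1, +1,
            +1, +1, +1, -1, -1, +1, +1, +1, +1)
  magnitude <- seq(0.55, 0.35, length.out = 19)
  data.frame(name = name, beta = sign * magnitude,
             stringsAsFactors = FALSE)
}

#' Configuration for the synthetic wine-chemistry generator
#'
#' Defines the study conditions the generator emulates: stratum counts, a
#' block-correlated predictor matrix built from a latent-factor model, a
#' sparse linear SPI response with stratum-level mean shifts, measurement
#' noise calibrated to a target population R-squared, and a small fraction
#' of injected response outliers.
#'
#' @param strata data.frame with `label`, `count`.
#' @param n_predictors number of physico-chemical parameters.
#' @param n_latent_factors number of latent blocks behind the predictor
#'   correlation (must be < total sample count).
#' @param block_loading loading of each predictor on its block factor, in
#'   (0, 1); within-block correlation is `block_loading^2`.
#' @param active_set data.frame `name`, `beta`: the true standardized
#'   coefficients (response units per predictor SD).
#' @param stratum_means named vector of per-stratum SPI means (g/L GAE).
#' @param predictor_means,predictor_sds target column means/SDs for the
#'   affine mapping to measurement units (recycled to `n_predictors`).
#' @param noise_sd residual SPI noise SD (g/L GAE), or `NULL` to solve it
#'   from `target_r2`.
#' @param target_r2 population R-squared (fraction of SPI variance
#'   explainable from the predictors alone) used when `noise_sd` is `NULL`.
#' @param outlier_fraction fraction of samples displaced in y, in [0, 0.5).
#' @param outlier_shift_sds displacement magnitude in response SDs.
#' @param seed integer seed.
#' @return An object of class `synth_config` (validated list).
#' @export
synth_config <- function(strata = default_strata(),
                         n_predictors = 52L,
                         n_latent_factors = 5L,
                         block_loading = 0.75,
                         active_set = default_active_set(),
                         stratum_means = default_stratum_means(),
                         predictor_means = 5,
                         predictor_sds = 2,
                         noise_sd = NULL,
                         target_r2 = 0.65,
                         outlier_fraction = 5 / 110,
                         outlier_shift_sds = 6,
                         seed = 1L) {
  stopifnot(is.data.frame(strata), all(c("label", "count") %in% names(strata)))
  if (any(strata$count < 1)) stop("stratum counts must be positive")
  n <- sum(strata$count)
  if (n <= n_latent_factors)
    stop("total sample count must exceed n_latent_factors")
  pn <- default_predictor_names()
  if (n_predictors <= length(pn)) pn <- pn[seq_len(n_predictors)]
  else pn <- c(pn, paste0("param_", seq_len(n_predictors - length(pn))))
  missing <- setdiff(active_set$name, pn)
  if (length(missing))
    stop("active variables not among predictors: ",
         paste(missing, collapse = ", "))
  missing_strata <- setdiff(strata$label, names(stratum_means))
  if (length(missing_strata))
    stop("stratum_means missing for: ",
         paste(missing_strata, collapse = ", "))
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  if (outlier_fraction < 0 || outlier_fraction >= 0.5)
    stop("outlier_fraction must lie in [0, 0.5)")
  if (block_loading <= 0 || block_loading >= 1)
    stop("block_loading must lie in (0, 1)")
  structure(
    list(strata = strata, n_predictors = as.integer(n_predictors),
         n_latent_factors = as.integer(n_latent_factors),
         block_loading = block_loading,
         active_set = active_set,
         stratum_means = stratum_means[strata$label],
         predictor_names = pn,
         predictor_means = rep_len(predictor_means, n_predictors),
         predictor_sds = rep_len(predictor_sds, n_predictors),
         noise_sd = noise_sd, target_r2 = target_r2,
         outlier_fraction = outlier_fraction,
         outlier_shift_sds = outlier_shift_sds,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# round-robin block membership of each predictor
block_of <- function(config) {
  (seq_len(config$n_predictors) - 1L) %% config$n_latent_factors + 1L
}

# variance of the standardized linear signal beta' R beta under the implied
# block-equicorrelation structure
signal_variance <- function(config) {
  blocks <- block_of(config)
  beta <- stats::setNames(rep(0, config$n_predictors),
                          config$predictor_names)
  beta[config$active_set$name] <- config$active_set$beta
  rho <- config$block_loading^2
  v <- sum(beta^2)
  for (b in unique(blocks)) {
    bb <- beta[blocks == b]
    v <- v + rho * (sum(bb)^2 - sum(bb^2))
  }
  v
}

# between-stratum variance of the configured SPI means, count-weighted
shift_variance <- function(config) {
  w <- config$strata$count / sum(config$strata$count)
  m <- config$stratum_means
  sum(w * (m - sum(w * m))^2)
}

# noise SD: configured, or solved so that the population R2 (predictor
# signal over total variance) equals target_r2
resolve_noise_sd <- function(config) {
  if (!is.null(config$noise_sd)) return(config$noise_sd)
  vs <- signal_variance(config)
  vshift <- shift_variance(config)
  noise_var <- vs * (1 - config$target_r2) / config$target_r2 - vshift
  if (noise_var < 0)
    stop("target_r2 unattainable: stratum-shift variance (",
         round(vshift, 3), ") already exceeds the allowed noise budget")
  sqrt(noise_var)
}

#' Generate a synthetic stratified wine-chemistry dataset
#'
#' Predictors are drawn from a latent-factor model
#' `X = L Lambda' + E` (standard normal factor scores `L`, block-structured
#' loadings so predictors form correlated groups, independent unique
#' noise), then affine-mapped to the configured column means/SDs. The
#' response is `y = stratum mean + sum over actives of beta_j z_j + eps`
#' with `z_j` the standardized predictor and
#' `eps ~ N(0, noise_sd^2)`; configured outliers are then injected with
#' [inject_outliers()]. Byte-identical output for identical config + seed.
#'
#' The ground truth records the standardized true coefficients, the
#' injected outlier indices and the population R-squared
#' `Var(signal) / (Var(signal) + Var(shift) + noise_sd^2)` — the share of
#' total SPI variance a predictor-only model can explain, stratum shifts
#' being invisible to it by construction.
#'
#' @param config a [synth_config()].
#' @return List with `dataset` (a [wine_dataset]) and `truth` (class
#'   `synth_truth`: `true_coefficients` over all predictors,
#'   `active` names, `outlier_indices`, `population_R2`, `noise_sd`,
#'   `signal_variance`, `shift_variance`).
#' @export
generate_wine_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- sum(config$strata$count)
  p <- config$n_predictors
  kf <- config$n_latent_factors
  lambda <- config$block_loading
  blocks <- block_of(config)
  noise_sd <- resolve_noise_sd(config)

  beta <- stats::setNames(rep(0, p), config$predictor_names)
  beta[config$active_set$name] <- config$active_set$beta
  stratum <- rep(config$strata$label, config$strata$count)

  out <- with_seed(config$seed, {
    L <- matrix(stats::rnorm(n * kf), n, kf)
    E <- matrix(stats::rnorm(n * p, sd = sqrt(1 - lambda^2)), n, p)
    Z <- L[, blocks, drop = FALSE] * lambda + E   # unit-variance columns
    eps <- stats::rnorm(n, sd = noise_sd)
    list(Z = Z, eps = eps)
  })
  colnames(out$Z) <- config$predictor_names
  x <- sweep(sweep(out$Z, 2, config$predictor_sds, "*"),
             2, config$predictor_means, "+")
  y <- config$stratum_means[stratum] + drop(out$Z %*% beta) + out$eps

  ids <- unlist(lapply(seq_len(nrow(config$strata)), function(i) {
    sprintf("%s_%02d", config$strata$label[i],
            seq_len(config$strata$count[i]))
  }))
  ds <- wine_dataset(ids, stratum, x, unname(y))

  outlier_idx <- integer(0)
  if (config$outlier_fraction > 0) {
    inj <- inject_outliers(ds, config$outlier_fraction,
                           config$outlier_shift_sds,
                           seed = config$seed + 1L)
    ds <- inj$dataset
    outlier_idx <- inj$indices
  }

  vs <- signal_variance(config)
  vshift <- shift_variance(config)
  truth <- structure(
    list(true_coefficients = beta,
         active = config$active_set$name,
         outlier_indices = outlier_idx,
         population_R2 = vs / (vs + vshift + noise_sd^2),
         noise_sd = noise_sd,
         signal_variance = vs, shift_variance = vshift,
         seed = config$seed),
    class = "synth_truth"
  )
  list(dataset = ds, truth = truth)
}

#' Inject response outliers into a dataset
#'
#' Displaces the SPI of `ceiling(fraction * n)` randomly chosen samples by
#' `shift_sds` response standard deviations (random sign), leaving the
#' predictors untouched — the influence pattern Cook's distance screening
#' is designed to catch. The input dataset is not modified.
#'
#' @param dataset a [wine_dataset].
#' @param fraction fraction of samples to displace, in [0, 0.5).
#' @param shift_sds displacement in SD(y) units (> 0).
#' @param seed integer seed.
#' @return List with `dataset` (modified copy) and `indices` (displaced
#'   sample indices, increasing).
#' @export
inject_outliers <- function(dataset, fraction, shift_sds, seed = 1L) {
  stopifnot(inherits(dataset, "wine_dataset"))
  if (fraction < 0 || fraction >= 0.5)
    stop("fraction must lie in [0, 0.5)")
  n <- length(dataset$y)
  n_out <- ceiling(fraction * n)
  if (n_out == 0)
    return(list(dataset = dataset, indices = integer(0)))
  shift <- shift_sds * stats::sd(dataset$y)
  picks <- with_seed(seed, {
    idx <- sort(sample_exact(seq_len(n), n_out))
    list(idx = idx, sign = sample(c(-1, 1), n_out, replace = TRUE))
  })
  y2 <- dataset$y
  y2[picks$idx] <- y2[picks$idx] + picks$sign * shift
  list(dataset = wine_dataset(dataset$sample_id, dataset$stratum,
                              dataset$x, y2),
       indices = picks$idx)
}

#' @export
print.synth_truth <- function(x, ...) {
  cat("Synthetic ground truth:", length(x$active), "active variables,",
      length(x$outlier_indices), "injected outlier(s)\n")
  cat(sprintf("  population R2 = %.3f (noise SD %.3f g/L GAE)\n",
              x$population_R2, x$noise_sd))
  invisible(x)
}
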