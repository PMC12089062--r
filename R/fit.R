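#' Fit the integrated living-squirrel cline model
#'
#' Posterior sampling for the 10-parameter integrated model (abundance
#' cline, melanism cline, per-morph quadratic-temperature detection) given
#' point counts and camera histories. The ten parameters are proposed as a
#' single adaptive block so that proposals learn the strong posterior
#' correlation between abundance and detection intercepts; each morph's
#' marginal likelihood term is cached and only recomputed when a parameter
#' it depends on moves.
#'
#' @param data A `squirrel_survey_data` list (see
#'   [simulate_observations()] or [read_survey_tables()]).
#' @param config An [mcmc_config()].
#' @param priors A [prior_spec()] in the order of
#'   [default_living_priors()].
#' @param map_init Initialize chains by jittering around the posterior mode
#'   and seed the proposal covariance with the Laplace approximation
#'   (see [map_laplace()]); `FALSE` falls back to prior draws.
#' @param n_max_floor,tail_tol Latent-sum truncation controls; see
#'   [site_marginal_loglik()].
#' @param n_max_cap Hard ceiling on the latent sum used during sampling;
#'   ample for any abundance the priors allow, and protects against
#'   pathological early-adaptation proposals.
#' @return A `posterior_samples` object carrying the dataset's distance and
#'   temperature standardizers.
#' @export
fit_living_model <- function(data, config = mcmc_config(),
                             priors = default_living_priors(),
                             map_init = TRUE,
                             n_max_floor = 50L, tail_tol = 1e-12,
                             n_max_cap = 500L) {
  stopifnot(inherits(data, "squirrel_survey_data"))
  d <- data$sites$dist_std
  n_sites <- nrow(data$sites)
  counts <- dplyr::arrange(data$counts, .data$site)
  cams <- dplyr::arrange(data$cameras, .data$site)
  # offset vectors (site-sorted records) for the grouped likelihood entry
  cnt_off <- c(0L, cumsum(tabulate(counts$site, n_sites)))
  cam_off <- c(0L, cumsum(tabulate(cams$site, n_sites)))
  cnt_mel <- as.numeric(counts$count_melanic)
  cnt_gray <- as.numeric(counts$count_gray)
  det_mel <- as.integer(cams$det_melanic)
  det_gray <- as.integer(cams$det_gray)
  t_cnt <- counts$temp_std
  t2_cnt <- t_cnt^2
  t_cam <- cams$temp_std
  t2_cam <- t_cam^2

  morph_ll <- function(theta, morph, cap = n_max_cap) {
    lambda <- exp(theta[1] + theta[2] * d)
    p_mel <- invlogit(theta[3] + theta[4] * d)
    if (morph == "melanic") {
      lam <- lambda * p_mel
      a <- theta[5:7]; cnt <- cnt_mel; det <- det_mel
    } else {
      lam <- lambda * (1 - p_mel)
      a <- theta[8:10]; cnt <- cnt_gray; det <- det_gray
    }
    .morph_loglik_fit_cpp(lam, cnt_off, cnt, t_cnt, t2_cnt,
                          cam_off, det, t_cam, t2_cam,
                          a[1], a[2], a[3],
                          as.integer(n_max_floor), tail_tol,
                          as.integer(cap))
  }
  # cache each morph's term keyed on the sub-vector it depends on
  key_mel <- NULL; val_mel <- NULL
  key_gray <- NULL; val_gray <- NULL
  loglik <- function(theta) {
    km <- theta[c(1:4, 5:7)]
    if (is.null(key_mel) || !identical(km, key_mel)) {
      val_mel <<- morph_ll(theta, "melanic")
      key_mel <<- km
    }
    kg <- theta[c(1:4, 8:10)]
    if (is.null(key_gray) || !identical(kg, key_gray)) {
      val_gray <<- morph_ll(theta, "gray")
      key_gray <<- kg
    }
    val_mel + val_gray
  }
  # the mode search only needs the objective to locate optima, so it runs
  # with looser truncation (tail 1e-8, floor 20, ceiling 150); mode
  # locations are insensitive to truncation error at that level, and the
  # sampler itself always uses the strict rule
  map_ll_one <- function(theta, morph) {
    lambda <- exp(theta[1] + theta[2] * d)
    p_mel <- invlogit(theta[3] + theta[4] * d)
    if (morph == "melanic") {
      lam <- lambda * p_mel
      a <- theta[5:7]; cnt <- cnt_mel; det <- det_mel
    } else {
      lam <- lambda * (1 - p_mel)
      a <- theta[8:10]; cnt <- cnt_gray; det <- det_gray
    }
    .morph_loglik_fit_cpp(lam, cnt_off, cnt, t_cnt, t2_cnt,
                          cam_off, det, t_cam, t2_cam,
                          a[1], a[2], a[3], 20L, 1e-8, 150L)
  }
  map_loglik <- function(theta) {
    map_ll_one(theta, "melanic") + map_ll_one(theta, "gray")
  }
  fit <- run_with_laplace(loglik, priors, config, map_init,
                          map_loglik = map_loglik)
  fit$standardizers <- data$standardizers
  fit$model <- "living_cline"
  fit
}

#' Fit the DOR melanism cline model
#'
#' Bayesian logistic regression of road-killed squirrel morph on
#' standardized distance to the city center (see [dor_model_loglik()]).
#'
#' @param records DOR records (see [simulate_dor_records()] or
#'   [read_survey_tables()]); distance is re-standardized within the
#'   records if a `dist_std` column is absent.
#' @param config An [mcmc_config()].
#' @param priors A [prior_spec()] with rows `alpha_D`, `beta_D`.
#' @param map_init See [fit_living_model()].
#' @return A `posterior_samples` object carrying the records' distance
#'   standardizer.
#' @export
fit_dor_model <- function(records, config = mcmc_config(),
                          priors = default_dor_priors(), map_init = TRUE) {
  if (is.null(records$dist_std)) {
    std <- standardize(records$distance_km)
    records$dist_std <- std$values
    standardizer <- list(mean = std$mean, sd = std$sd)
  } else {
    standardizer <- attr(records, "standardizer") %||%
      standardize(records$distance_km)[c("mean", "sd")]
  }
  loglik <- function(theta) {
    dor_model_loglik(list(alpha_D = theta[1], beta_D = theta[2]), records)
  }
  fit <- run_with_laplace(loglik, priors, config, map_init)
  fit$standardizers <- list(distance = standardizer)
  fit$model <- "dor_cline"
  fit
}

# shared fitting path: multi-start Laplace approximation drives chain
# initialization (chains distributed across the discovered modes), the
# proposal covariance, and the mode-jumping mixture proposal. Covariance
# re-estimation during adaptation needs a long adaptation phase to be
# stable, so it is enabled only when one is configured.
run_with_laplace <- function(loglik, priors, config, map_init,
                             n_starts = 12, map_loglik = loglik) {
  if (!map_init) return(sample_posterior(loglik, priors, config))
  seeds <- derive_seeds(sum(config$seeds) %% 1000000L + 1L, 2)
  map <- map_laplace(map_loglik, priors, seed = seeds[1],
                     n_starts = n_starts)
  log_prior <- log_prior_fn(priors)
  logpost <- function(th) loglik(th) + log_prior(th)
  k <- length(map$modes)
  init <- matrix(NA_real_, config$n_chains, length(map$mode))
  for (ch in seq_len(config$n_chains)) {
    m <- map$modes[[(ch - 1L) %% k + 1L]]
    init[ch, ] <- laplace_inits(m, logpost, 1L,
                                seed = seeds[2] %% 1000000L + ch)
  }
  sample_posterior(loglik, priors, config, init = init, init_cov = map$cov,
                   adapt_cov = config$n_adapt >= 2500,
                   jump = if (k > 1) map$modes else NULL)
}
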