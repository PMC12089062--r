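#' Per-survey individual detection probability
#'
#' Detection of a single squirrel during one survey occasion (or camera day)
#' is modeled on the logit scale as quadratic in standardized mean daily
#' temperature, with morph-specific coefficients:
#' `logit p = a0 + a1 * t + a2 * t^2`.
#'
#' @param coefs Length-3 numeric `(a0, a1, a2)`, or a list with elements
#'   `det_melanic`/`det_gray` (e.g. [truth_params()]) combined with `morph`.
#' @param temp_std Standardized temperature, vectorized.
#' @param morph `"melanic"` or `"gray"`, used only when `coefs` is a list.
#' @return Probabilities in (0, 1), same length as `temp_std`.
#' @examples
#' detection_probability(c(-1.53, -0.019, -0.39), 0)
#' @export
detection_probability <- function(coefs, temp_std, morph = NULL) {
  if (is.list(coefs)) {
    if (is.null(morph)) abort("Supply `morph` when `coefs` is a list.")
    morph <- match.arg(morph, c("melanic", "gray"))
    coefs <- if (morph == "melanic") coefs$det_melanic else coefs$det_gray
  }
  if (length(coefs) != 3L || !all(is.finite(coefs))) {
    abort("`coefs` must be 3 finite numbers (a0, a1, a2).")
  }
  invlogit(coefs[1] + coefs[2] * temp_std + coefs[3] * temp_std^2)
}

#' Probability of detecting at least one of N individuals
#'
#' With per-individual detection probability `p` and `N` independent
#' individuals present, the chance that a survey or camera day records the
#' morph at all is `1 - (1 - p)^N`. Vectorized over both arguments.
#'
#' @param p Individual detection probability in \[0, 1\].
#' @param N Nonnegative integer abundance.
#' @return Probability; 0 whenever `N = 0`.
#' @examples
#' prob_at_least_one(0.5, 2)  # 0.75
#' @export
prob_at_least_one <- function(p, N) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("`p` must lie in [0, 1].")
  if (any(N < 0, na.rm = TRUE)) abort("`N` must be nonnegative.")
  1 - (1 - p)^N
}

#' Marginal log-likelihood of one morph at one site
#'
#' Sums the latent morph abundance `N ~ Poisson(lambda)` out of the joint
#' observation likelihood: repeated point counts `c_j ~ Binomial(N, p_j)`
#' and daily camera detections `d ~ Bernoulli(1 - (1 - p_d)^N)`. The sum
#' runs from the largest observed count (below which the likelihood is
#' zero) to the smallest `N` whose Poisson upper tail is under `tail_tol`
#' (never below `n_max_floor`), so the truncation error is negligible
#' relative to the retained mass.
#'
#' @param lambda Expected abundance of the morph at the site (> 0).
#' @param counts Integer point counts across surveys (possibly empty).
#' @param p_count Per-survey individual detection probabilities, same
#'   length as `counts`.
#' @param detections Binary camera-day detections (possibly empty).
#' @param p_detect Per-day individual detection probabilities.
#' @param n_max Optional hard truncation point; must be at least the
#'   maximum observed count. Default: automatic tail rule.
#' @param n_max_floor,tail_tol Automatic truncation controls.
#' @return The log marginal likelihood (finite unless the data are
#'   impossible under the parameters).
#' @export
site_marginal_loglik <- function(lambda, counts, p_count,
                                 detections = integer(0),
                                 p_detect = numeric(0),
                                 n_max = NULL, n_max_floor = 50L,
                                 tail_tol = 1e-12) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !(lambda > 0)) {
    abort("`lambda` must be a single positive number.")
  }
  counts <- as.numeric(counts)
  detections <- as.integer(detections)
  if (length(counts) != length(p_count)) {
    abort("`counts` and `p_count` lengths differ.")
  }
  if (length(detections) != length(p_detect)) {
    abort("`detections` and `p_detect` lengths differ.")
  }
  if (length(counts) && (any(counts < 0) || any(counts != round(counts)))) {
    abort("`counts` must be nonnegative integers.")
  }
  if (length(detections) && !all(detections %in% c(0L, 1L))) {
    abort("`detections` must be binary.")
  }
  cap <- -1L
  if (!is.null(n_max)) {
    cap <- as.integer(n_max)
    if (length(counts) && cap < max(counts)) {
      abort("`n_max` is below the maximum observed count.")
    }
  }
  .morph_loglik_cpp(lambda,
                    rep(1L, length(counts)), counts, as.numeric(p_count),
                    rep(1L, length(detections)), detections,
                    as.numeric(p_detect),
                    as.integer(n_max_floor), tail_tol, cap, TRUE)
}

#' Living-squirrel cline model parameters
#'
#' Parameter container for the integrated point-count + camera model: the
#' abundance cline (`beta0_N`, `beta1_N`, log scale), the melanism cline
#' (`beta0_M`, `beta1_M`, logit scale), and per-morph quadratic-temperature
#' detection coefficients.
#'
#' @inheritParams truth_params
#' @return A named list of class `living_model_params`.
#' @export
living_model_params <- function(beta0_N, beta1_N, beta0_M, beta1_M,
                                det_melanic, det_gray) {
  coefs <- c(beta0_N, beta1_N, beta0_M, beta1_M, det_melanic, det_gray)
  if (length(coefs) != 10L || !all(is.finite(coefs))) {
    abort("All 10 coefficients must be finite.")
  }
  structure(list(beta0_N = beta0_N, beta1_N = beta1_N,
                 beta0_M = beta0_M, beta1_M = beta1_M,
                 det_melanic = as.numeric(det_melanic),
                 det_gray = as.numeric(det_gray)),
            class = "living_model_params")
}

#' Integrated log-likelihood of the living-squirrel data
#'
#' Total log-likelihood of point counts and camera histories across sites
#' and morphs. Latent morph abundances are marginalized analytically using
#' the Poisson thinning identity: if `N_total ~ Poisson(lambda)` is split
#' `Binomial(N_total, p_mel)`, then the morph counts are independent
#' Poissons with means `lambda * p_mel` and `lambda * (1 - p_mel)`, so each
#' site-by-morph term is a one-dimensional marginal (see
#' [site_marginal_loglik()]). Sites without cameras contribute count terms
#' only.
#'
#' @param params A [living_model_params()] (a [truth_params()] also works).
#' @param data A `squirrel_survey_data` list (see [simulate_observations()]).
#' @param n_max,n_max_floor,tail_tol Truncation controls, passed through.
#' @return The total log-likelihood.
#' @export
living_model_loglik <- function(params, data, n_max = NULL,
                                n_max_floor = 50L, tail_tol = 1e-12) {
  stopifnot(is.list(params), is.list(data))
  d <- data$sites$dist_std
  lambda <- exp(params$beta0_N + params$beta1_N * d)
  p_mel <- invlogit(params$beta0_M + params$beta1_M * d)
  cap <- if (is.null(n_max)) -1L else as.integer(n_max)
  counts <- data$counts
  cams <- data$cameras
  ll <- 0
  for (morph in c("melanic", "gray")) {
    lam <- if (morph == "melanic") lambda * p_mel else lambda * (1 - p_mel)
    a <- if (morph == "melanic") params$det_melanic else params$det_gray
    p_cnt <- detection_probability(a, counts$temp_std)
    p_cam <- detection_probability(a, cams$temp_std)
    cnt_col <- paste0("count_", morph)
    det_col <- paste0("det_", morph)
    ll <- ll + .morph_loglik_cpp(
      lam,
      as.integer(counts$site), as.numeric(counts[[cnt_col]]), p_cnt,
      as.integer(cams$site), as.integer(cams[[det_col]]), p_cam,
      as.integer(n_max_floor), tail_tol, cap, TRUE
    )
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}

#' Log-likelihood of the DOR melanism cline
#'
#' Bernoulli log-likelihood of road-killed squirrel morphs under
#' `logit P(melanic) = alpha_D + beta_D * dist_std`.
#'
#' @param params Named list with `alpha_D` and `beta_D`.
#' @param records Data frame of DOR records with columns `dist_std` and
#'   `morph` (1 = melanic, 0 = gray); see [simulate_dor_records()].
#' @return The log-likelihood.
#' @export
dor_model_loglik <- function(params, records) {
  if (is.null(records) || nrow(records) == 0L) {
    abort("`records` must contain at least one DOR observation.")
  }
  if (!all(records$morph %in% c(0, 1))) abort("`morph` must be binary.")
  eta <- params$alpha_D + params$beta_D * records$dist_std
  # log Bernoulli via plogis log.p: stable for large |eta|
  sum(stats::plogis(ifelse(records$morph == 1, eta, -eta), log.p = TRUE))
}
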