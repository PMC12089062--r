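#' Simulate site network and latent morph abundances
#'
#' Draws site locations uniformly over the study distance range, standardizes
#' distance, and generates latent abundances from the hierarchical cline
#' model: total abundance is Poisson with a log-linear distance cline, and
#' the melanic share of each site's squirrels is Binomial with a logit-linear
#' distance cline.
#'
#' @param truth A [truth_params()] object.
#' @param n_sites Number of survey sites (>= 2).
#' @param seed Integer seed; the same seed reproduces the landscape exactly.
#' @return A tibble with one row per site: `site`, `distance_km`, `dist_std`,
#'   `lambda` (expected total abundance), `p_melanic` (expected melanic
#'   share), and latent counts `N_total`, `N_melanic`, `N_gray`. The distance
#'   standardizer is attached as attribute `"standardizer"`.
#' @examples
#' land <- simulate_squirrel_landscape(truth_params(), n_sites = 41, seed = 1)
#' head(land)
#' @export
simulate_squirrel_landscape <- function(truth, n_sites, seed) {
  stopifnot(inherits(truth, "truth_params"))
  if (!is.numeric(n_sites) || n_sites < 2) {
    abort("`n_sites` must be >= 2 (distance standardization needs spread).")
  }
  n_sites <- as.integer(n_sites)
  rng <- truth$distance_range_km
  withr::with_seed(as.integer(seed), {
    distance_km <- runif(n_sites, rng[1], rng[2])
    std <- standardize(distance_km)
    lambda <- exp(truth$beta0_N + truth$beta1_N * std$values)
    p_mel <- invlogit(truth$beta0_M + truth$beta1_M * std$values)
    N_total <- rpois(n_sites, lambda)
    N_mel <- rbinom(n_sites, N_total, p_mel)
  })
  out <- tibble::tibble(
    site = seq_len(n_sites),
    distance_km = distance_km,
    dist_std = std$values,
    lambda = lambda,
    p_melanic = p_mel,
    N_total = N_total,
    N_melanic = N_mel,
    N_gray = N_total - N_mel
  )
  attr(out, "standardizer") <- list(mean = std$mean, sd = std$sd)
  out
}

#' Survey and camera-trap design for synthetic observations
#'
#' Builds the occasion structure (which sites get how many point-count
#' surveys and camera days, and at what temperature) that
#' [simulate_observations()] fills with data. Defaults mirror the field
#' design the model was developed for: every site gets point counts
#' (default 5 surveys, the study median), and a subset of sites also runs a
#' camera trap (default 263 days, the study median). Temperatures follow a
#' seasonal sinusoid plus Gaussian noise and are standardized pooled across
#' all point-count and camera occasions.
#'
#' @param n_sites Number of sites.
#' @param camera_sites Integer site ids with cameras. Default: a seeded
#'   random subset of `round(n_sites * 24 / 41)` sites (the study's camera
#'   share).
#' @param n_surveys Point-count surveys per site; scalar or length
#'   `n_sites`.
#' @param n_camera_days Camera days per camera site; scalar or one value per
#'   camera site.
#' @param seed Integer seed.
#' @param temp_mean,temp_amplitude,temp_sd Seasonal temperature model
#'   (degrees C): mean level, annual sinusoid amplitude, day-to-day SD.
#' @return A list of class `survey_design`: tibbles `counts` (site, survey,
#'   temp, temp_std) and `cameras` (site, day, temp, temp_std), the vector
#'   `camera_sites`, and `temp_standardizer`.
#' @export
survey_design <- function(n_sites, camera_sites = NULL, n_surveys = 5L,
                          n_camera_days = 263L, seed = 1L,
                          temp_mean = 8, temp_amplitude = 10, temp_sd = 3) {
  n_sites <- as.integer(n_sites)
  stopifnot(n_sites >= 1)
  withr::with_seed(as.integer(seed), {
    if (is.null(camera_sites)) {
      n_cam <- max(0L, round(n_sites * 24 / 41))
      camera_sites <- sort(sample.int(n_sites, n_cam))
    } else {
      camera_sites <- sort(as.integer(camera_sites))
      if (length(camera_sites) &&
          (min(camera_sites) < 1 || max(camera_sites) > n_sites)) {
        abort("`camera_sites` must be site ids in 1..n_sites.")
      }
    }
    n_surveys <- rep_len(as.integer(n_surveys), n_sites)
    if (any(n_surveys < 1)) abort("Every site needs >= 1 point-count survey.")
    n_camera_days <- rep_len(as.integer(n_camera_days), length(camera_sites))

    season <- function(day) {
      temp_mean + temp_amplitude * cos(2 * pi * (day - 200) / 365) +
        rnorm(length(day), 0, temp_sd)
    }
    counts <- tibble::tibble(
      site = rep(seq_len(n_sites), n_surveys),
      survey = unlist(lapply(n_surveys, seq_len), use.names = FALSE)
    )
    counts$temp <- season(sample.int(365, nrow(counts), replace = TRUE))
    cameras <- tibble::tibble(
      site = rep(camera_sites, n_camera_days),
      day = unlist(lapply(n_camera_days, seq_len), use.names = FALSE)
    )
    if (nrow(cameras)) {
      start <- rep(sample.int(365, length(camera_sites), replace = TRUE),
                   n_camera_days)
      cameras$temp <- season((start + cameras$day - 1L) %% 365L + 1L)
    } else {
      cameras$temp <- numeric(0)
    }
  })
  pooled <- standardize(c(counts$temp, cameras$temp))
  counts$temp_std <- pooled$values[seq_len(nrow(counts))]
  cameras$temp_std <- pooled$values[nrow(counts) + seq_len(nrow(cameras))]
  structure(
    list(counts = counts, cameras = cameras, camera_sites = camera_sites,
         temp_standardizer = list(mean = pooled$mean, sd = pooled$sd)),
    class = "survey_design"
  )
}

#' Simulate point counts and camera-trap detection histories
#'
#' Fills a [survey_design()] with morph-specific observations conditional on
#' the latent abundances of a simulated landscape. Point counts are
#' `Binomial(N_k, p)` per survey; daily camera detections are
#' `Bernoulli(1 - (1 - p)^N_k)`, the probability of photographing at least
#' one of the `N_k` individuals of morph `k`. Individual detection
#' probability `p` is quadratic in standardized temperature on the logit
#' scale, with morph-specific coefficients.
#'
#' @param truth A [truth_params()] object (detection coefficients are used).
#' @param landscape Output of [simulate_squirrel_landscape()].
#' @param design A [survey_design()] for the same number of sites.
#' @param seed Integer seed.
#' @return A list of class `squirrel_survey_data` with tibbles `sites`
#'   (site, distance_km, dist_std, camera), `counts` (site, survey, temp,
#'   temp_std, count_melanic, count_gray), `cameras` (site, day, temp,
#'   temp_std, det_melanic, det_gray), the latent truth tibble `latent`,
#'   and `standardizers` (distance and temperature constants).
#' @export
simulate_observations <- function(truth, landscape, design, seed) {
  stopifnot(inherits(truth, "truth_params"), inherits(design, "survey_design"))
  n_sites <- nrow(landscape)
  if (max(design$counts$site) > n_sites ||
      (nrow(design$cameras) && max(design$cameras$site) > n_sites)) {
    abort("Design refers to sites missing from the landscape.")
  }
  counts <- design$counts
  cameras <- design$cameras
  N_mel <- landscape$N_melanic[counts$site]
  N_gray <- landscape$N_gray[counts$site]
  p_cnt_mel <- detection_probability(truth$det_melanic, counts$temp_std)
  p_cnt_gray <- detection_probability(truth$det_gray, counts$temp_std)
  withr::with_seed(as.integer(seed), {
    counts$count_melanic <- rbinom(nrow(counts), N_mel, p_cnt_mel)
    counts$count_gray <- rbinom(nrow(counts), N_gray, p_cnt_gray)
    if (nrow(cameras)) {
      Nc_mel <- landscape$N_melanic[cameras$site]
      Nc_gray <- landscape$N_gray[cameras$site]
      p_cam_mel <- detection_probability(truth$det_melanic, cameras$temp_std)
      p_cam_gray <- detection_probability(truth$det_gray, cameras$temp_std)
      cameras$det_melanic <- rbinom(nrow(cameras), 1L,
                                    prob_at_least_one(p_cam_mel, Nc_mel))
      cameras$det_gray <- rbinom(nrow(cameras), 1L,
                                 prob_at_least_one(p_cam_gray, Nc_gray))
    } else {
      cameras$det_melanic <- integer(0)
      cameras$det_gray <- integer(0)
    }
  })
  sites <- tibble::tibble(
    site = landscape$site,
    distance_km = landscape$distance_km,
    dist_std = landscape$dist_std,
    camera = landscape$site %in% design$camera_sites
  )
  structure(
    list(sites = sites, counts = counts, cameras = cameras,
         latent = landscape,
         standardizers = list(
           distance = attr(landscape, "standardizer"),
           temperature = design$temp_standardizer
         )),
    class = "squirrel_survey_data"
  )
}

#' One-call synthetic living-squirrel survey
#'
#' Convenience wrapper chaining [simulate_squirrel_landscape()],
#' [survey_design()] and [simulate_observations()] from a single seed.
#'
#' @inheritParams simulate_squirrel_landscape
#' @param ... Passed to [survey_design()].
#' @return A `squirrel_survey_data` list; see [simulate_observations()].
#' @export
simulate_squirrel_surveys <- function(truth, n_sites = 41, seed = 1, ...) {
  seeds <- derive_seeds(seed, 3)
  land <- simulate_squirrel_landscape(truth, n_sites, seeds[1])
  des <- survey_design(n_sites, seed = seeds[2], ...)
  simulate_observations(truth, land, des, seeds[3])
}

#' @export
print.squirrel_survey_data <- function(x, ...) {
  cat(sprintf(
    "Synthetic squirrel survey data: %d sites (%d with cameras), %d point-count records, %d camera days\n",
    nrow(x$sites), sum(x$sites$camera), nrow(x$counts), nrow(x$cameras)))
  invisible(x)
}

#' Simulate dead-on-road (DOR) records
#'
#' Samples carcass locations uniformly over the study distance range and
#' assigns each a color morph from the DOR melanism cline:
#' `morph ~ Bernoulli(invlogit(alpha_D + beta_D * dist_std))`, where
#' distance is standardized within the DOR sample (each dataset carries its
#' own standardizer, as in fitting).
#'
#' @param truth A [truth_params()] object.
#' @param n_records Number of road-killed squirrels (>= 1).
#' @param seed Integer seed.
#' @return A tibble with `distance_km`, `dist_std`, and `morph` (1 =
#'   melanic, 0 = gray), with the distance standardizer attached as
#'   attribute `"standardizer"`.
#' @examples
#' dor <- simulate_dor_records(truth_params(), n_records = 141, seed = 7)
#' mean(dor$morph)
#' @export
simulate_dor_records <- function(truth, n_records, seed) {
  stopifnot(inherits(truth, "truth_params"))
  if (!is.numeric(n_records) || n_records < 1) {
    abort("`n_records` must be >= 1.")
  }
  n_records <- as.integer(n_records)
  rng <- truth$distance_range_km
  withr::with_seed(as.integer(seed), {
    distance_km <- runif(n_records, rng[1], rng[2])
    if (n_records >= 2) {
      std <- standardize(distance_km)
    } else {
      std <- list(values = 0, mean = distance_km, sd = 1)
    }
    p <- invlogit(truth$alpha_D + truth$beta_D * std$values)
    morph <- rbinom(n_records, 1L, p)
  })
  out <- tibble::tibble(distance_km = distance_km, dist_std = std$values,
                        morph = morph)
  attr(out, "standardizer") <- list(mean = std$mean, sd = std$sd)
  out
}

#' Build a 2x2 morph-by-status contingency table
#'
#' Assembles the dead/alive by melanic/gray table used for the
#' citizen-science photo analysis from classification totals per morph.
#'
#' @param total_melanic,total_gray Total classified squirrels per morph.
#' @param dead_melanic,dead_gray Of those, the number photographed dead on
#'   a road.
#' @return An integer matrix of class `contingency_2x2` with rows
#'   `dead`/`alive` and columns `melanic`/`gray`.
#' @examples
#' make_citizen_table(12705, 174, 96025, 1581)
#' @export
make_citizen_table <- function(total_melanic, dead_melanic,
                               total_gray, dead_gray) {
  vals <- c(total_melanic, dead_melanic, total_gray, dead_gray)
  if (any(!is.finite(vals)) || any(vals < 0) ||
      any(vals != round(vals))) {
    abort("Counts must be nonnegative integers.")
  }
  if (dead_melanic > total_melanic || dead_gray > total_gray) {
    abort("Dead counts cannot exceed totals.")
  }
  tab <- matrix(
    c(dead_melanic, total_melanic - dead_melanic,
      dead_gray, total_gray - dead_gray),
    nrow = 2, ncol = 2,
    dimnames = list(status = c("dead", "alive"),
                    morph = c("melanic", "gray"))
  )
  structure(tab, class = c("contingency_2x2", class(tab)))
}
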