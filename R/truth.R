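#' Generating parameters for synthetic squirrel survey data
#'
#' Bundles the coefficients of the three living-squirrel submodels (total
#' abundance, proportion melanic, per-morph detection) and the dead-on-road
#' (DOR) melanism cline, together with the distance range of the study
#' gradient. These are the "truth" that [simulate_squirrel_landscape()],
#' [simulate_observations()] and [simulate_dor_records()] draw from, and the
#' quantities parameter-recovery tests try to get back.
#'
#' All slope coefficients are per SD of standardized distance (or
#' temperature); intercepts are at the standardized mean. The defaults are
#' an urban melanism cline on a ~1-11 km gradient: total abundance declines
#' away from the city center, melanism declines faster among living squirrels
#' than among road-killed ones, and the melanic morph has a lower per-survey
#' detection probability than the gray morph.
#'
#' @param beta0_N,beta1_N Log-scale intercept and distance slope of expected
#'   total squirrel abundance per site.
#' @param beta0_M,beta1_M Logit-scale intercept and distance slope of the
#'   proportion melanic among living squirrels.
#' @param det_melanic,det_gray Length-3 numeric vectors `(a0, a1, a2)`:
#'   logit-scale intercept, linear and quadratic standardized-temperature
#'   coefficients of per-survey individual detection probability.
#' @param alpha_D,beta_D Logit-scale intercept and distance slope of the
#'   probability that a road-killed squirrel is melanic.
#' @param distance_range_km Length-2 numeric `(min, max)` distance to the
#'   city center, km.
#' @return An object of class `truth_params` (a named list).
#' @examples
#' truth <- truth_params()
#' truth$beta1_M
#' @export
truth_params <- function(beta0_N = 2.58, beta1_N = -0.62,
                         beta0_M = -0.85, beta1_M = -0.80,
                         det_melanic = c(-2.16, -0.058, -0.34),
                         det_gray = c(-1.53, -0.019, -0.39),
                         alpha_D = -1.36, beta_D = -0.22,
                         distance_range_km = c(0.93, 11.3)) {
  coefs <- c(beta0_N, beta1_N, beta0_M, beta1_M,
             det_melanic, det_gray, alpha_D, beta_D)
  if (!all(is.finite(coefs))) abort("All coefficients must be finite.")
  if (length(det_melanic) != 3L || length(det_gray) != 3L) {
    abort("Detection coefficient vectors must have length 3 (a0, a1, a2).")
  }
  if (length(distance_range_km) != 2L ||
      !all(is.finite(distance_range_km)) ||
      distance_range_km[1] >= distance_range_km[2] ||
      distance_range_km[1] <= 0) {
    abort("`distance_range_km` must be positive with min < max.")
  }
  structure(
    list(beta0_N = beta0_N, beta1_N = beta1_N,
         beta0_M = beta0_M, beta1_M = beta1_M,
         det_melanic = as.numeric(det_melanic),
         det_gray = as.numeric(det_gray),
         alpha_D = alpha_D, beta_D = beta_D,
         distance_range_km = as.numeric(distance_range_km)),
    class = "truth_params"
  )
}

#' @export
print.truth_params <- function(x, ...) {
  cat("Generating parameters (truth) for synthetic surveys\n")
  cat(sprintf("  abundance:     log lambda = %.3f %+.3f * dist_std\n",
              x$beta0_N, x$beta1_N))
  cat(sprintf("  melanism:      logit p    = %.3f %+.3f * dist_std\n",
              x$beta0_M, x$beta1_M))
  cat(sprintf("  DOR melanism:  logit p    = %.3f %+.3f * dist_std\n",
              x$alpha_D, x$beta_D))
  cat(sprintf("  detection (melanic): a = (%.3f, %.3f, %.3f)\n",
              x$det_melanic[1], x$det_melanic[2], x$det_melanic[3]))
  cat(sprintf("  detection (gray):    a = (%.3f, %.3f, %.3f)\n",
              x$det_gray[1], x$det_gray[2], x$det_gray[3]))
  cat(sprintf("  distance range: %.2f-%.2f km\n",
              x$distance_range_km[1], x$distance_range_km[2]))
  invisible(x)
}
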