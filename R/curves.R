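#' Proportion melanic along the distance gradient
#'
#' Evaluates the logit-linear melanism cline
#' `invlogit(beta0 + beta1 * dist_std)` on a grid of raw distances, using
#' the standardization constants of the fit that produced the
#' coefficients.
#'
#' @param beta0,beta1 Logit-scale intercept and slope (per SD of distance).
#' @param distance_km Numeric grid of distances, km.
#' @param standardizer List with `mean` and `sd` of distance from the
#'   fitting dataset.
#' @return Proportions in (0, 1), one per grid point.
#' @examples
#' melanism_cline(-0.85, -0.80, c(1, 5, 10),
#'                standardizer = list(mean = 6, sd = 3))
#' @export
melanism_cline <- function(beta0, beta1, distance_km, standardizer) {
  if (missing(standardizer) || is.null(standardizer)) {
    abort("`standardizer` (distance mean/sd of the fit) is required.")
  }
  invlogit(beta0 + beta1 * apply_standardizer(distance_km, standardizer))
}

#' Default evaluation grid over the study gradient
#'
#' @param n Number of points.
#' @param range_km Distance range, km.
#' @return Evenly spaced distances.
#' @export
distance_grid <- function(n = 100, range_km = c(0.93, 11.3)) {
  seq(range_km[1], range_km[2], length.out = n)
}

new_cline_curve <- function(distance_km, mean, lower95, upper95, kind) {
  out <- tibble::tibble(distance_km = distance_km, mean = mean,
                        lower95 = lower95, upper95 = upper95)
  class(out) <- c(kind, "cline_curve", class(out))
  out
}

summarize_curve_draws <- function(curves, distance_km, kind) {
  # curves: draws x grid matrix
  q <- apply(curves, 2, quantile, probs = c(0.025, 0.975), names = FALSE,
             type = 7)
  new_cline_curve(distance_km, colMeans(curves), q[1, ], q[2, ], kind)
}

posterior_pair <- function(samples, names) {
  found <- intersect(names, samples$parameters)
  if (length(found) != 2) {
    abort(paste0("Posterior lacks parameters: ",
                 paste(setdiff(names, found), collapse = ", ")))
  }
  d <- dim(samples$draws)
  if (d[1] * d[2] == 0) abort("Posterior has no draws.")
  cbind(as.vector(samples$draws[, , names[1]]),
        as.vector(samples$draws[, , names[2]]))
}

#' Living and DOR cline curves and their posterior difference
#'
#' For each posterior draw, evaluates the living-squirrel melanism cline
#' and the DOR melanism cline over a distance grid and takes their
#' pointwise difference (living minus DOR); the draws are then summarized
#' by the mean and 2.5%/97.5% quantiles at each grid point. A positive
#' difference means the melanic morph is underrepresented among road-killed
#' squirrels relative to the living population at that distance.
#'
#' The two models are fit to independent datasets, so any pairing of their
#' draws is valid; draws are pooled across chains, truncated to the shorter
#' of the two posteriors, and paired by index, which is reproducible. Each
#' curve uses its own fit's distance standardizer.
#'
#' @param post_living `posterior_samples` from [fit_living_model()] (needs
#'   `beta0_M`, `beta1_M` and a distance standardizer).
#' @param post_dor `posterior_samples` from [fit_dor_model()] (needs
#'   `alpha_D`, `beta_D` and a distance standardizer).
#' @param distance_km Evaluation grid; default [distance_grid()].
#' @return A list of class `cline_contrast` with elements `living`, `dor`
#'   (class `morph_cline_curve`) and `difference` (class
#'   `difference_curve`), each a tibble `distance_km`, `mean`, `lower95`,
#'   `upper95`.
#' @export
cline_difference_curves <- function(post_living, post_dor,
                                    distance_km = distance_grid()) {
  stopifnot(inherits(post_living, "posterior_samples"),
            inherits(post_dor, "posterior_samples"))
  std_l <- post_living$standardizers$distance
  std_d <- post_dor$standardizers$distance
  if (is.null(std_l) || is.null(std_d)) {
    abort("Both posteriors must carry a distance standardizer.")
  }
  z_out <- abs(apply_standardizer(distance_km, std_l)) > 4 |
    abs(apply_standardizer(distance_km, std_d)) > 4
  if (any(z_out)) {
    warn("Distance grid extends far beyond the fitted data (|z| > 4); the cline is extrapolated there.")
  }
  b_liv <- posterior_pair(post_living, c("beta0_M", "beta1_M"))
  b_dor <- posterior_pair(post_dor, c("alpha_D", "beta_D"))
  n <- min(nrow(b_liv), nrow(b_dor))
  b_liv <- b_liv[seq_len(n), , drop = FALSE]
  b_dor <- b_dor[seq_len(n), , drop = FALSE]
  z_l <- apply_standardizer(distance_km, std_l)
  z_d <- apply_standardizer(distance_km, std_d)
  # draws x grid
  liv <- invlogit(outer(b_liv[, 1], rep(1, length(z_l))) +
                    outer(b_liv[, 2], z_l))
  dor <- invlogit(outer(b_dor[, 1], rep(1, length(z_d))) +
                    outer(b_dor[, 2], z_d))
  structure(
    list(
      living = summarize_curve_draws(liv, distance_km, "morph_cline_curve"),
      dor = summarize_curve_draws(dor, distance_km, "morph_cline_curve"),
      difference = summarize_curve_draws(liv - dor, distance_km,
                                         "difference_curve")
    ),
    class = "cline_contrast"
  )
}

#' @export
print.cline_contrast <- function(x, ...) {
  cat("Cline contrast (living vs. DOR proportion melanic)\n")
  rng <- range(x$difference$distance_km)
  cat(sprintf("  grid: %d points over %.2f-%.2f km\n",
              nrow(x$difference), rng[1], rng[2]))
  i <- 1L
  cat(sprintf("  difference at %.2f km: %.3f [%.3f, %.3f]\n",
              x$difference$distance_km[i], x$difference$mean[i],
              x$difference$lower95[i], x$difference$upper95[i]))
  invisible(x)
}
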