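# degenerate posterior helper: every draw equals `values`
point_mass_posterior <- function(values, n_draws = 50, n_chains = 2,
                                 standardizer = list(mean = 6, sd = 3)) {
  npar <- length(values)
  arr <- array(rep(values, each = n_draws * n_chains),
               dim = c(n_draws, n_chains, npar),
               dimnames = list(NULL, NULL, names(values)))
  structure(list(draws = arr, parameters = names(values),
                 config = NULL, priors = NULL,
                 standardizers = list(distance = standardizer)),
            class = "posterior_samples")
}

test_that("melanism cline evaluates the logit-linear curve on the raw grid", {
  std <- list(mean = 6, sd = 3)
  # at the mean distance the standardized coordinate is 0
  expect_equal(melanism_cline(-0.85, -0.80, 6, std), plogis(-0.85))
  expect_equal(round(melanism_cline(-0.85, 0, 6, std), 3), 0.299)
  # flat slope: constant curve
  expect_equal(melanism_cline(0.2, 0, c(1, 5, 11), std),
               rep(plogis(0.2), 3))
  # negative slope: strictly decreasing
  curve <- melanism_cline(-0.5, -0.9, seq(1, 11, length.out = 50), std)
  expect_true(all(diff(curve) < 0))
  expect_true(all(curve > 0 & curve < 1))
  expect_error(melanism_cline(0, 1, 1:3), "standardizer")
})

test_that("identical degenerate posteriors give an identically zero difference", {
  std <- list(mean = 6, sd = 3)
  liv <- point_mass_posterior(c(beta0_M = -0.6, beta1_M = -0.8),
                              standardizer = std)
  dor <- point_mass_posterior(c(alpha_D = -0.6, beta_D = -0.8),
                              standardizer = std)
  ctr <- cline_difference_curves(liv, dor, distance_km = seq(1, 11, 0.5))
  expect_equal(ctr$difference$mean, rep(0, nrow(ctr$difference)))
  expect_equal(ctr$difference$lower95, ctr$difference$upper95)
  expect_equal(ctr$difference$lower95, rep(0, nrow(ctr$difference)))
})

test_that("point-mass posteriors reproduce the closed-form invlogit difference", {
  std_l <- list(mean = 5, sd = 2.5)
  std_d <- list(mean = 7, sd = 3.5)
  liv <- point_mass_posterior(c(beta0_M = -0.4, beta1_M = -1.1),
                              standardizer = std_l)
  dor <- point_mass_posterior(c(alpha_D = -1.3, beta_D = -0.2),
                              standardizer = std_d)
  grid <- seq(1, 11, length.out = 21)
  ctr <- cline_difference_curves(liv, dor, grid)
  want <- plogis(-0.4 - 1.1 * (grid - 5) / 2.5) -
    plogis(-1.3 - 0.2 * (grid - 7) / 3.5)
  expect_equal(ctr$difference$mean, want, tolerance = 1e-12)
  expect_equal(ctr$living$mean, plogis(-0.4 - 1.1 * (grid - 5) / 2.5),
               tolerance = 1e-12)
})

test_that("random posteriors keep interval ordering and [0,1] bounds", {
  withr::with_seed(6, {
    n <- 200
    arr_l <- array(c(rnorm(n, -0.5, 0.4), rnorm(n, -0.8, 0.3)),
                   dim = c(n / 2, 2, 2),
                   dimnames = list(NULL, NULL, c("beta0_M", "beta1_M")))
    arr_d <- array(c(rnorm(n, -1.2, 0.4), rnorm(n, -0.2, 0.3)),
                   dim = c(n / 2, 2, 2),
                   dimnames = list(NULL, NULL, c("alpha_D", "beta_D")))
  })
  std <- list(mean = 6, sd = 3)
  liv <- structure(list(draws = arr_l, parameters = c("beta0_M", "beta1_M"),
                        standardizers = list(distance = std)),
                   class = "posterior_samples")
  dor <- structure(list(draws = arr_d, parameters = c("alpha_D", "beta_D"),
                        standardizers = list(distance = std)),
                   class = "posterior_samples")
  ctr <- cline_difference_curves(liv, dor)
  for (part in ctr[c("living", "dor")]) {
    expect_true(all(part$lower95 <= part$mean & part$mean <= part$upper95))
    expect_true(all(part$lower95 >= 0 & part$upper95 <= 1))
  }
  dd <- ctr$difference
  expect_true(all(dd$lower95 <= dd$mean & dd$mean <= dd$upper95))
  expect_true(all(dd$lower95 >= -1 & dd$upper95 <= 1))
  # grid far outside the data support warns about extrapolation
  expect_warning(cline_difference_curves(liv, dor, distance_km = c(2, 90)),
                 "extrapolated")
})

test_that("missing parameters or standardizers are reported", {
  liv <- point_mass_posterior(c(beta0_M = 0, beta1_M = 0))
  bad <- point_mass_posterior(c(foo = 1, bar = 2))
  expect_error(cline_difference_curves(liv, bad), "alpha_D")
  nostd <- point_mass_posterior(c(alpha_D = 0, beta_D = 0))
  nostd$standardizers <- NULL
  expect_error(cline_difference_curves(liv, nostd), "standardizer")
})

test_that("curves serialize to CSV and JSON", {
  curve <- structure(
    tibble::tibble(distance_km = c(1, 2), mean = c(0.3, 0.2),
                   lower95 = c(0.2, 0.1), upper95 = c(0.4, 0.35)),
    class = c("morph_cline_curve", "cline_curve", class(tibble::tibble())))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_curve(curve, p1)
  write_curve(curve, p2)
  back <- read.csv(p1)
  expect_equal(back$mean, curve$mean)
  expect_equal(jsonlite::read_json(p2, simplifyVector = TRUE)$upper95,
               curve$upper95)
})
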