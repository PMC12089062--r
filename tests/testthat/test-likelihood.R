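test_that("detection probability follows the quadratic-temperature logit", {
  expect_equal(detection_probability(c(0, 0, 0), 2.7), 0.5)
  # a published-style gray intercept at mean temperature
  expect_equal(detection_probability(c(-1.53, -0.019, -0.39), 0),
               plogis(-1.53))
  # even in temperature when the linear term is 0
  a <- c(-0.7, 0, -0.3)
  tt <- seq(-2, 2, 0.25)
  expect_equal(detection_probability(a, tt), detection_probability(a, -tt))
  # morph selection from a parameter list
  truth <- truth_params()
  expect_equal(detection_probability(truth, 0.5, morph = "gray"),
               detection_probability(truth$det_gray, 0.5))
  expect_error(detection_probability(c(1, 2), 0), "a0, a1, a2")
})

test_that("site marginal log-likelihood equals brute-force enumeration", {
  # small site: 2 surveys, 3 camera days
  a <- c(-0.4, 0.1, -0.2)
  p_c <- detection_probability(a, c(-0.5, 1.2))
  p_d <- detection_probability(a, c(0.3, -1, 0.8))
  cases <- list(
    list(lambda = 2, counts = c(1L, 0L), dets = c(1L, 0L, 1L)),
    list(lambda = 0.4, counts = c(0L, 0L), dets = c(0L, 0L, 0L)),
    list(lambda = 7.5, counts = c(3L, 5L), dets = c(1L, 1L, 1L)),
    list(lambda = 2, counts = c(2L, 1L), dets = integer(0))
  )
  for (cs in cases) {
    pd <- if (length(cs$dets)) p_d else numeric(0)
    expect_equal(
      site_marginal_loglik(cs$lambda, cs$counts, p_c, cs$dets, pd),
      brute_marginal(cs$lambda, cs$counts, p_c, cs$dets, pd),
      tolerance = 1e-10
    )
  }
})

test_that("truncation point does not matter once the Poisson tail is negligible", {
  p_c <- c(0.3, 0.45)
  base <- site_marginal_loglik(3, c(2L, 1L), p_c, n_max = 60)
  expect_equal(site_marginal_loglik(3, c(2L, 1L), p_c, n_max = 120), base,
               tolerance = 1e-10)
  expect_equal(site_marginal_loglik(3, c(2L, 1L), p_c), base,
               tolerance = 1e-10)
  expect_error(site_marginal_loglik(3, c(2L, 5L), p_c, n_max = 3), "n_max")
  expect_error(site_marginal_loglik(-1, c(0L), 0.5), "lambda")
})

test_that("empty site log-likelihood tends to 0 as lambda tends to 0", {
  p <- c(0.4, 0.4)
  ll <- site_marginal_loglik(1e-10, c(0L, 0L), p, c(0L, 0L), p)
  expect_gt(ll, -1e-9)
  expect_lte(ll, 0)
})

test_that("integrated likelihood sums site-by-morph marginals and is exchangeable", {
  params <- tiny_params()
  dat <- tiny_survey_data()
  ll <- living_model_loglik(params, dat)
  # oracle: per-site brute-force products under the thinning factorization
  d <- dat$sites$dist_std
  lam_tot <- exp(params$beta0_N + params$beta1_N * d)
  p_mel <- plogis(params$beta0_M + params$beta1_M * d)
  oracle <- 0
  for (i in 1:3) {
    cn <- dat$counts[dat$counts$site == i, ]
    cm <- dat$cameras[dat$cameras$site == i, ]
    for (morph in c("melanic", "gray")) {
      lam <- if (morph == "melanic") lam_tot[i] * p_mel[i] else
        lam_tot[i] * (1 - p_mel[i])
      a <- if (morph == "melanic") params$det_melanic else params$det_gray
      oracle <- oracle + brute_marginal(
        lam, cn[[paste0("count_", morph)]],
        detection_probability(a, cn$temp_std),
        cm[[paste0("det_", morph)]],
        detection_probability(a, cm$temp_std))
    }
  }
  expect_equal(ll, oracle, tolerance = 1e-10)

  # permuting record order changes nothing
  perm <- dat
  perm$counts <- perm$counts[sample(nrow(perm$counts)), ]
  perm$cameras <- perm$cameras[rev(seq_len(nrow(perm$cameras))), ]
  perm$sites <- perm$sites[c(3, 1, 2), ]
  # sites table order feeds lambda by site id, so keep ids aligned
  perm$sites <- perm$sites[order(perm$sites$site), ]
  expect_equal(living_model_loglik(params, perm), ll, tolerance = 1e-12)

  # a single-site dataset equals that site's marginal
  one <- dat
  one$sites <- dat$sites[1, ]
  one$counts <- dat$counts[dat$counts$site == 1, ]
  one$cameras <- dat$cameras[dat$cameras$site == 1, ]
  lam1_mel <- lam_tot[1] * p_mel[1]
  lam1_gray <- lam_tot[1] * (1 - p_mel[1])
  cn <- one$counts; cm <- one$cameras
  expected <- brute_marginal(lam1_mel, cn$count_melanic,
                             detection_probability(params$det_melanic, cn$temp_std),
                             cm$det_melanic,
                             detection_probability(params$det_melanic, cm$temp_std)) +
    brute_marginal(lam1_gray, cn$count_gray,
                   detection_probability(params$det_gray, cn$temp_std),
                   cm$det_gray,
                   detection_probability(params$det_gray, cm$temp_std))
  expect_equal(living_model_loglik(params, one), expected, tolerance = 1e-10)
})

test_that("thinning factorization equals the joint Poisson-Binomial marginal", {
  # 2-site toy: independent-morph-Poisson total loglik must equal the joint
  # Poisson(N_total) -> Binomial(split) formulation marginalized over both
  # latent abundances
  params <- tiny_params()
  dat <- tiny_survey_data()
  dat$sites <- dat$sites[1:2, ]
  dat$counts <- dat$counts[dat$counts$site <= 2, ]
  dat$cameras <- dat$cameras[dat$cameras$site <= 2, ]
  d <- dat$sites$dist_std
  lam_tot <- exp(params$beta0_N + params$beta1_N * d)
  p_mel <- plogis(params$beta0_M + params$beta1_M * d)
  joint <- 0
  for (i in 1:2) {
    cn <- dat$counts[dat$counts$site == i, ]
    cm <- dat$cameras[dat$cameras$site == i, ]
    joint <- joint + brute_joint_split(
      lam_tot[i], p_mel[i],
      obs_mel = list(counts = cn$count_melanic,
                     p_count = detection_probability(params$det_melanic, cn$temp_std),
                     detections = cm$det_melanic,
                     p_detect = detection_probability(params$det_melanic, cm$temp_std)),
      obs_gray = list(counts = cn$count_gray,
                      p_count = detection_probability(params$det_gray, cn$temp_std),
                      detections = cm$det_gray,
                      p_detect = detection_probability(params$det_gray, cm$temp_std)),
      n_top = 120)
  }
  expect_equal(living_model_loglik(params, dat), joint, tolerance = 1e-8)
})

test_that("DOR log-likelihood matches direct summation and its symmetries", {
  rec <- tibble::tibble(dist_std = c(-1.2, -0.3, 0, 0.8, 1.5),
                        morph = c(1, 1, 0, 0, 1))
  pars <- list(alpha_D = -0.9, beta_D = -0.4)
  p <- plogis(pars$alpha_D + pars$beta_D * rec$dist_std)
  by_hand <- sum(log(ifelse(rec$morph == 1, p, 1 - p)))
  expect_equal(dor_model_loglik(pars, rec), by_hand, tolerance = 1e-12)

  # label symmetry: swapping morphs and negating coefficients is invariant
  flipped <- rec
  flipped$morph <- 1 - rec$morph
  expect_equal(dor_model_loglik(list(alpha_D = 0.9, beta_D = 0.4), flipped),
               dor_model_loglik(pars, rec), tolerance = 1e-12)

  # all-melanic data: likelihood tends to 1 as the intercept grows
  allm <- tibble::tibble(dist_std = rnorm(4), morph = rep(1, 4))
  expect_gt(dor_model_loglik(list(alpha_D = 40, beta_D = 0), allm), -1e-9)
  expect_error(dor_model_loglik(pars, allm[0, ]), "at least one")
})

test_that("the grouped fitting path matches the general likelihood entry", {
  truth <- truth_params()
  dat <- simulate_squirrel_surveys(truth, 12, seed = 31, n_camera_days = 40)
  th <- c(2.1, -0.55, -0.7, -0.85, -2.1, -0.06, -0.33, -1.5, -0.02, -0.38)
  ref <- living_model_loglik(
    living_model_params(th[1], th[2], th[3], th[4], th[5:7], th[8:10]), dat)
  cnt <- dplyr::arrange(dat$counts, site)
  cam <- dplyr::arrange(dat$cameras, site)
  n_sites <- nrow(dat$sites)
  cnt_off <- c(0L, cumsum(tabulate(cnt$site, n_sites)))
  cam_off <- c(0L, cumsum(tabulate(cam$site, n_sites)))
  d <- dat$sites$dist_std
  lam <- exp(th[1] + th[2] * d)
  pm <- plogis(th[3] + th[4] * d)
  fast <- roadcline:::.morph_loglik_fit_cpp(
    lam * pm, cnt_off, as.numeric(cnt$count_melanic),
    cnt$temp_std, cnt$temp_std^2, cam_off, as.integer(cam$det_melanic),
    cam$temp_std, cam$temp_std^2, th[5], th[6], th[7], 50L, 1e-12, 500L) +
    roadcline:::.morph_loglik_fit_cpp(
      lam * (1 - pm), cnt_off, as.numeric(cnt$count_gray),
      cnt$temp_std, cnt$temp_std^2, cam_off, as.integer(cam$det_gray),
      cam$temp_std, cam$temp_std^2, th[8], th[9], th[10], 50L, 1e-12, 500L)
  expect_equal(fast, ref, tolerance = 1e-12)
})
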