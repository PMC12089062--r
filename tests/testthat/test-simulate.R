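test_that("landscape simulation respects the distance range and cline structure", {
  truth <- truth_params()
  land <- simulate_squirrel_landscape(truth, n_sites = 41, seed = 7)
  expect_equal(nrow(land), 41)
  expect_true(all(land$distance_km >= 0.93 & land$distance_km <= 11.3))
  expect_true(all(land$N_melanic >= 0 & land$N_melanic <= land$N_total))
  expect_equal(mean(land$dist_std), 0, tolerance = 1e-12)
  expect_equal(sd(land$dist_std), 1, tolerance = 1e-12)
  # identical seeds: bit-identical output
  expect_identical(land, simulate_squirrel_landscape(truth, 41, seed = 7))
  expect_false(identical(land,
                         simulate_squirrel_landscape(truth, 41, seed = 8)))
  expect_error(simulate_squirrel_landscape(truth, 1, seed = 1), "n_sites")
})

test_that("flat clines produce no distance trend and the Poisson mean is right", {
  truth <- truth_params(beta0_N = 2.58, beta1_N = 0, beta0_M = -0.85,
                        beta1_M = 0)
  land <- simulate_squirrel_landscape(truth, n_sites = 10000, seed = 21)
  # E[N_total] = exp(2.58) at every site; sample mean within 2 SE
  mu <- exp(2.58)
  se <- sqrt(mu / nrow(land))
  expect_lt(abs(mean(land$N_total) - mu), 2 * se)
  # no trend: regression slope of N_total on distance within MC error of 0
  sl <- coef(summary(lm(N_total ~ dist_std, data = land)))["dist_std", ]
  expect_lt(abs(sl["Estimate"]), 3 * sl["Std. Error"])
  slm <- coef(summary(lm(I(N_melanic / pmax(N_total, 1)) ~ dist_std,
                         data = land)))["dist_std", ]
  expect_lt(abs(slm["Estimate"]), 3 * slm["Std. Error"])
})

test_that("two-stage Poisson/Binomial generation equals independent Poisson morphs", {
  # Poisson thinning: N_melanic should be Poisson(lambda * p_mel)
  truth <- truth_params(beta1_N = 0, beta1_M = 0)
  land <- simulate_squirrel_landscape(truth, n_sites = 20000, seed = 33)
  lam_mel <- exp(truth$beta0_N) * plogis(truth$beta0_M)
  ks <- 0:max(land$N_melanic)
  p_expect <- dpois(ks, lam_mel)
  # pool the tail so expected counts stay reasonable
  cut <- max(which(p_expect * nrow(land) >= 5))
  obs <- tabulate(land$N_melanic + 1L, nbins = length(ks))
  obs_b <- c(obs[1:cut], sum(obs[-(1:cut)]))
  p_b <- c(p_expect[1:cut], 1 - sum(p_expect[1:cut]))
  gof <- suppressWarnings(chisq.test(obs_b, p = p_b))
  expect_gt(gof$p.value, 0.01)
})

test_that("observation simulation matches its conditional distributions", {
  truth <- truth_params()
  land <- simulate_squirrel_landscape(truth, n_sites = 12, seed = 5)
  des <- survey_design(12, camera_sites = 1:6, n_surveys = 4,
                       n_camera_days = 30, seed = 6)
  obs <- simulate_observations(truth, land, des, seed = 9)
  expect_s3_class(obs$counts, "tbl_df")
  expect_true(all(obs$counts$count_melanic <= land$N_melanic[obs$counts$site]))
  expect_true(all(obs$cameras$det_melanic %in% 0:1))
  # sites without cameras have no camera records
  expect_true(all(obs$cameras$site %in% 1:6))
  # empty site: all observations zero for that morph
  empty <- land$site[land$N_melanic == 0]
  if (length(empty)) {
    expect_true(all(obs$counts$count_melanic[obs$counts$site %in% empty] == 0))
    expect_true(all(obs$cameras$det_melanic[obs$cameras$site %in% empty] == 0))
  }
  # pooled temperature standardization
  tt <- c(obs$counts$temp_std, obs$cameras$temp_std)
  expect_equal(mean(tt), 0, tolerance = 1e-10)
  expect_equal(sd(tt), 1, tolerance = 1e-10)
  expect_identical(obs, simulate_observations(truth, land, des, seed = 9))
})

test_that("perfect detection returns the latent state exactly", {
  truth <- truth_params(det_melanic = c(40, 0, 0), det_gray = c(40, 0, 0))
  land <- simulate_squirrel_landscape(truth, n_sites = 8, seed = 15)
  des <- survey_design(8, camera_sites = 1:4, n_surveys = 3,
                       n_camera_days = 10, seed = 2)
  obs <- simulate_observations(truth, land, des, seed = 4)
  expect_true(all(obs$counts$count_melanic ==
                    land$N_melanic[obs$counts$site]))
  expect_true(all(obs$counts$count_gray == land$N_gray[obs$counts$site]))
  occupied <- obs$cameras$site[land$N_gray[obs$cameras$site] > 0]
  expect_true(all(obs$cameras$det_gray[land$N_gray[obs$cameras$site] > 0] == 1))
})

test_that("camera detection frequency matches 1 - (1 - p)^N", {
  # closed form: p = 0.3, N = 2 -> p* = 0.51; check by moment at scale
  n_days <- 100000
  withr::with_seed(99, {
    det <- rbinom(n_days, 1, prob_at_least_one(0.3, 2))
  })
  p_star <- 1 - 0.7^2
  se <- sqrt(p_star * (1 - p_star) / n_days)
  expect_lt(abs(mean(det) - p_star), 3 * se)
  expect_equal(prob_at_least_one(0.5, 1), 0.5)
  expect_equal(prob_at_least_one(0.5, 2), 0.75)
  expect_equal(prob_at_least_one(0.9, 0), 0)
  # monotone in both arguments
  ps <- seq(0, 1, 0.1)
  expect_true(all(diff(prob_at_least_one(ps, 3)) >= 0))
  expect_true(all(diff(prob_at_least_one(0.4, 0:10)) >= 0))
})

test_that("DOR simulation reproduces its Bernoulli cline", {
  truth <- truth_params()
  dor <- simulate_dor_records(truth, n_records = 141, seed = 12)
  expect_equal(nrow(dor), 141)
  expect_true(all(dor$morph %in% 0:1))
  expect_true(all(dor$distance_km >= 0.93 & dor$distance_km <= 11.3))
  expect_identical(dor, simulate_dor_records(truth, 141, seed = 12))

  # constant cline: melanic fraction within 3 MC SE of plogis(alpha_D)
  t0 <- truth_params(alpha_D = qlogis(0.2), beta_D = 0)
  big <- simulate_dor_records(t0, 50000, seed = 13)
  se <- sqrt(0.2 * 0.8 / 50000)
  expect_lt(abs(mean(big$morph) - 0.2), 3 * se)

  # slope recovery by ordinary logistic regression at large n
  t1 <- truth_params(beta_D = -0.22)
  big1 <- simulate_dor_records(t1, 20000, seed = 14)
  fit <- glm(morph ~ dist_std, family = binomial, data = big1)
  est <- coef(summary(fit))["dist_std", ]
  expect_lt(abs(est["Estimate"] - (-0.22)), 3 * est["Std. Error"])
})

test_that("citizen table construction preserves margins and validates input", {
  tab <- make_citizen_table(12705, 174, 96025, 1581)
  expect_equal(sum(tab), 108730)
  expect_equal(unname(tab["dead", ]), c(174, 1581))
  expect_equal(unname(tab["alive", ]), c(12531, 94444))
  z <- make_citizen_table(10, 0, 10, 0)
  expect_equal(unname(z["dead", ]), c(0, 0))
  expect_error(make_citizen_table(10, 11, 10, 0), "exceed")
  expect_error(make_citizen_table(10, -1, 10, 0), "nonnegative")
})

test_that("count moments match N * p at each design point", {
  truth <- truth_params(det_melanic = c(-0.5, 0.2, -0.3),
                        det_gray = c(-1, 0, -0.2))
  land <- simulate_squirrel_landscape(truth, n_sites = 4, seed = 3)
  des <- survey_design(4, camera_sites = integer(0), n_surveys = 2000,
                       seed = 8)
  obs <- simulate_observations(truth, land, des, seed = 10)
  by_site <- split(obs$counts, obs$counts$site)
  for (s in names(by_site)) {
    df <- by_site[[s]]
    p <- detection_probability(truth$det_melanic, df$temp_std)
    mu <- land$N_melanic[as.integer(s)] * mean(p)
    if (mu == 0) next
    se <- sd(df$count_melanic) / sqrt(nrow(df))
    expect_lt(abs(mean(df$count_melanic) - mu), 3 * se + 1e-9)
  }
})
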