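test_that("standardize centers, scales, round-trips and is affine invariant", {
  s <- standardize(c(1, 2, 3))
  expect_equal(s$values, c(-1, 0, 1))
  expect_equal(s$mean, 2)
  expect_equal(s$sd, 1)

  x <- c(3.2, -1.5, 8, 0.4, 2.2)
  st <- standardize(x)
  expect_equal(mean(st$values), 0, tolerance = 1e-12)
  expect_equal(sd(st$values), 1, tolerance = 1e-12)
  back <- st$values * st$sd + st$mean
  expect_equal(back, x, tolerance = 1e-12)
  expect_equal(apply_standardizer(x, st), st$values, tolerance = 1e-12)

  # affine transforms with positive slope leave the standardized vector alone
  aff <- standardize(2.5 * x - 7)
  expect_equal(aff$values, st$values, tolerance = 1e-12)

  expect_error(standardize(rep(1, 5)), "constant")
  expect_error(standardize(3), "length")
})

test_that("prior spec validates and evaluates with Jacobians", {
  expect_error(prior_spec("a", "normal", 0, -1), "SD")
  expect_error(prior_spec("a", "uniform", 2, 1), "bounds")
  expect_error(prior_spec(c("a", "a")), "unique")
  pr <- default_living_priors()
  expect_equal(nrow(pr), 10)
  lp <- roadcline:::log_prior_fn(pr)
  theta <- rep(0.3, 10)
  # exp-scale uniform: density 1/100 on the natural scale times Jacobian
  by_hand <- log(1 / 100) + 0.3 +                  # beta0_N ~ U(0,100) on exp
    sum(dnorm(rep(0.3, 6), 0, 10, log = TRUE)) +   # six normal slopes
    3 * (log(dunif(plogis(0.3))) + log(plogis(0.3)) + log(1 - plogis(0.3)))
  expect_equal(lp(theta), by_hand, tolerance = 1e-12)
  # outside a uniform's support the log prior is -Inf
  theta_bad <- theta
  theta_bad[1] <- log(101)
  expect_equal(lp(theta_bad), -Inf)
})

test_that("the default protocol retains 1100 draws per chain", {
  cfg <- mcmc_config()
  expect_equal(cfg$n_chains, 3)
  expect_equal(cfg$n_retained, 1100)
  expect_error(mcmc_config(n_iter = 100, n_burnin = 100), "n_burnin")
  expect_error(mcmc_config(seeds = c(1, 1, 1)), "distinct")
})

test_that("sampler reproduces a conjugate normal posterior and is seed-stable", {
  withr::with_seed(42, y <- rnorm(20, 1.5, 1))
  # known variance 1, prior mu ~ N(0, 2): closed-form posterior
  prior_sd <- 2
  post_var <- 1 / (length(y) + 1 / prior_sd^2)
  post_mean <- post_var * sum(y)
  loglik <- function(th) sum(dnorm(y, th, 1, log = TRUE))
  pr <- prior_spec("mu", "normal", 0, prior_sd)
  cfg <- mcmc_config(n_chains = 3, n_adapt = 1000, n_iter = 4000,
                     n_burnin = 500, thin = 2, seed = 9)
  fit <- sample_posterior(loglik, pr, cfg)
  draws <- as.vector(fit$draws)
  n_eff_guess <- length(draws) / 10          # conservative for a random walk
  mc_se <- sqrt(post_var / n_eff_guess)
  expect_lt(abs(mean(draws) - post_mean), 3 * mc_se)
  expect_equal(sd(draws), sqrt(post_var), tolerance = 0.15)
  expect_lt(gelman_rubin(fit), 1.05)

  # identical seeds => identical draws; different seeds differ
  fit2 <- sample_posterior(loglik, pr, cfg)
  expect_identical(fit$draws, fit2$draws)
  cfg3 <- mcmc_config(n_chains = 3, n_adapt = 1000, n_iter = 4000,
                      n_burnin = 500, thin = 2, seed = 10)
  fit3 <- sample_posterior(loglik, pr, cfg3)
  expect_false(identical(fit$draws, fit3$draws))
})

test_that("split-chain R-hat matches the hand-evaluated formula", {
  # 2 chains x 4 draws, hand computation with split halves
  m <- cbind(c(1, 2, 3, 4), c(2, 2, 4, 5))
  # split into 4 half-chains of length 2
  halves <- list(c(1, 2), c(3, 4), c(2, 2), c(4, 5))
  n <- 2
  W <- mean(sapply(halves, var))
  B <- n * var(sapply(halves, mean))
  expect_equal(gelman_rubin(m),
               sqrt(((n - 1) / n * W + B / n) / W), tolerance = 1e-12)

  # copies of one stationary stream: R-hat ~ 1
  withr::with_seed(3, x <- rnorm(1000))
  expect_lt(gelman_rubin(cbind(x, x)), 1.01)

  # wildly separated chains: clear divergence
  withr::with_seed(4, {
    far <- cbind(rnorm(200, 0, 1), rnorm(200, 100, 1))
  })
  expect_gt(gelman_rubin(far), 10)
  expect_error(gelman_rubin(matrix(1:10, ncol = 1)), "2 chains")
})

test_that("posterior summaries use pooled draws and type-7 quantiles", {
  mk <- function(draws_vec) {
    arr <- array(draws_vec, dim = c(length(draws_vec), 1, 1),
                 dimnames = list(NULL, NULL, "x"))
    structure(list(draws = arr, parameters = "x",
                   config = NULL, priors = NULL),
              class = "posterior_samples")
  }
  s <- posterior_summary(mk(c(-1, 1)))
  expect_equal(s$mean, 0)
  # draws 1..1000: type-7 quantiles interpolate to 25.975 and 975.025
  s2 <- posterior_summary(mk(1:1000))
  expect_equal(s2$lower95, 25.975)
  expect_equal(s2$upper95, 975.025)
  s3 <- posterior_summary(mk(rep(3.7, 50)))
  expect_equal(unlist(s3[, c("mean", "lower95", "upper95")]),
               c(mean = 3.7, lower95 = 3.7, upper95 = 3.7))
})

test_that("long-format draws carry chain and iteration labels", {
  pr <- prior_spec(c("a", "b"), "normal", 0, 1)
  cfg <- mcmc_config(n_chains = 2, n_adapt = 100, n_iter = 200,
                     n_burnin = 100, thin = 5, seed = 2)
  fit <- sample_posterior(function(th) 0, pr, cfg)
  df <- as_draws_df(fit)
  expect_equal(nrow(df), 20 * 2 * 2)
  expect_setequal(unique(df$parameter), c("a", "b"))
  expect_equal(max(df$iteration), cfg$n_retained)
  expect_false(anyNA(df$value))
})
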