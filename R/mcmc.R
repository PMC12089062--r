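#' Prior specification
#'
#' One row per parameter. A prior is either `normal(p1 = mean, p2 = sd)` or
#' `uniform(p1 = lower, p2 = upper)`, placed on a named `scale` of the
#' working parameter: `"identity"`, `"exp"` (the prior constrains
#' `exp(theta)`, e.g. a mean abundance), or `"invlogit"` (the prior
#' constrains `plogis(theta)`, e.g. a mean probability). Log-Jacobians are
#' handled internally, so the sampler always works on the unconstrained
#' scale.
#'
#' @param parameter Character vector of parameter names.
#' @param dist `"normal"` or `"uniform"`, recycled.
#' @param p1,p2 Distribution parameters, recycled.
#' @param scale `"identity"`, `"exp"`, or `"invlogit"`, recycled.
#' @return A tibble of class `prior_spec`.
#' @examples
#' prior_spec("slope", "normal", 0, 10)
#' @export
prior_spec <- function(parameter, dist = "normal", p1 = 0, p2 = 10,
                       scale = "identity") {
  n <- length(parameter)
  out <- tibble::tibble(
    parameter = as.character(parameter),
    dist = rep_len(dist, n), p1 = rep_len(p1, n), p2 = rep_len(p2, n),
    scale = rep_len(scale, n)
  )
  if (anyDuplicated(out$parameter)) abort("Parameter names must be unique.")
  if (!all(out$dist %in% c("normal", "uniform"))) {
    abort("`dist` must be \"normal\" or \"uniform\".")
  }
  if (!all(out$scale %in% c("identity", "exp", "invlogit"))) {
    abort("`scale` must be identity, exp, or invlogit.")
  }
  bad <- (out$dist == "normal" & out$p2 <= 0) |
    (out$dist == "uniform" & out$p1 >= out$p2)
  if (any(bad)) abort("Normal SDs must be positive; uniform bounds ordered.")
  class(out) <- c("prior_spec", class(out))
  out
}

#' Default priors for the living-squirrel model
#'
#' Weakly informative defaults: Normal(0, 10) on all slope and curvature
#' coefficients; Uniform(0, 100) on mean site abundance `exp(beta0_N)`;
#' Uniform(0, 1) on mean proportion melanic `plogis(beta0_M)` and on the
#' mean detection probability of each morph.
#'
#' @return A [prior_spec()] with 10 rows in the sampler's parameter order.
#' @export
default_living_priors <- function() {
  out <- dplyr::bind_rows(
    prior_spec("beta0_N", "uniform", 0, 100, scale = "exp"),
    prior_spec("beta1_N", "normal", 0, 10),
    prior_spec("beta0_M", "uniform", 0, 1, scale = "invlogit"),
    prior_spec("beta1_M", "normal", 0, 10),
    prior_spec("a0_melanic", "uniform", 0, 1, scale = "invlogit"),
    prior_spec(c("a1_melanic", "a2_melanic"), "normal", 0, 10),
    prior_spec("a0_gray", "uniform", 0, 1, scale = "invlogit"),
    prior_spec(c("a1_gray", "a2_gray"), "normal", 0, 10)
  )
  class(out) <- c("prior_spec", class(tibble::tibble()))
  out
}

#' Default priors for the DOR cline model
#'
#' Normal(0, 10) on both logistic regression coefficients.
#'
#' @return A [prior_spec()] with rows `alpha_D`, `beta_D`.
#' @export
default_dor_priors <- function() {
  prior_spec(c("alpha_D", "beta_D"), "normal", 0, 10)
}

log_prior_fn <- function(priors) {
  dist <- priors$dist; p1 <- priors$p1; p2 <- priors$p2; scale <- priors$scale
  function(theta) {
    x <- theta
    jac <- numeric(length(theta))
    ie <- scale == "exp"
    il <- scale == "invlogit"
    if (any(ie)) {
      x[ie] <- exp(theta[ie])
      jac[ie] <- theta[ie]
    }
    if (any(il)) {
      p <- invlogit(theta[il])
      x[il] <- p
      jac[il] <- log(p) + log1p(-p)
    }
    lp <- numeric(length(theta))
    nn <- dist == "normal"
    lp[nn] <- stats::dnorm(x[nn], p1[nn], p2[nn], log = TRUE)
    lp[!nn] <- stats::dunif(x[!nn], p1[!nn], p2[!nn], log = TRUE)
    sum(lp + jac)
  }
}

# initial working-scale draw; normal priors are shrunk (sd capped at 1) so
# retries rarely start in absurd regions of a Normal(0, 10) prior
draw_init <- function(priors) {
  n <- nrow(priors)
  theta <- numeric(n)
  for (j in seq_len(n)) {
    if (priors$dist[j] == "normal") {
      v <- rnorm(1, priors$p1[j], min(priors$p2[j], 1))
    } else {
      lo <- priors$p1[j]; hi <- priors$p2[j]
      pad <- 0.05 * (hi - lo)
      v <- runif(1, lo + pad, hi - pad)
    }
    theta[j] <- switch(priors$scale[j],
      identity = v,
      exp = log(max(v, 1e-8)),
      invlogit = logit(min(max(v, 1e-8), 1 - 1e-8))
    )
  }
  theta
}

#' Posterior modes and Laplace approximation
#'
#' Maximizes the log-posterior from several prior draws (Nelder-Mead, then
#' a BFGS polish) and clusters the optima: hierarchical models of this
#' kind can have several near-equivalent modes (e.g. a higher-abundance /
#' lower-detectability explanation of the same data), and knowing them all
#' matters for sampling. Each distinct mode gets an inverse-Hessian
#' covariance ([stats::optimHess()]) and a Laplace mass weight
#' proportional to `exp(logpost) * sqrt(det cov)`. Used to initialize MCMC
#' chains, to seed the proposal covariance, and to build the mode-jumping
#' mixture proposal of [sample_posterior()].
#'
#' @param loglik Log-likelihood function of the working-scale parameters.
#' @param priors A [prior_spec()].
#' @param seed Integer seed for the optimizer starts.
#' @param n_starts Number of prior draws to start the coarse basin search
#'   from.
#' @param maxit Nelder-Mead iteration cap for the polish stage.
#' @param polish_maxit BFGS polish iteration cap per start.
#' @param dedup_tol Euclidean distance below which two optima are the same
#'   mode.
#' @param keep_within Discard modes more than this many log-posterior
#'   units below the best.
#' @return A list with `mode`, `cov`, `logpost` (the best mode) and
#'   `modes`, a list of all retained modes, each with `mode`, `cov`,
#'   `logpost`, and normalized Laplace `weight`.
#' @export
map_laplace <- function(loglik, priors, seed = 1, n_starts = 12,
                        maxit = 400, polish_maxit = 40, dedup_tol = 0.1,
                        keep_within = 10) {
  log_prior <- log_prior_fn(priors)
  neg <- function(th) {
    v <- tryCatch(loglik(th) + log_prior(th), error = function(e) -Inf)
    if (!is.finite(v)) 1e10 else -v
  }
  optima <- list()
  withr::with_seed(as.integer(seed), {
    # phase 1: many cheap simplex runs to locate basins
    coarse <- list()
    for (s in seq_len(n_starts)) {
      start <- draw_init(priors)
      if (neg(start) >= 1e10) next
      fit <- tryCatch(
        stats::optim(start, neg, method = "Nelder-Mead",
                     control = list(maxit = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      dup <- FALSE
      for (m in coarse) {
        if (sqrt(sum((m$par - fit$par)^2)) < 0.3) {
          dup <- TRUE
          if (fit$value < m$value) { m$par <- fit$par; m$value <- fit$value }
          break
        }
      }
      if (!dup) coarse[[length(coarse) + 1L]] <- fit
    }
    # phase 2: refine one representative per basin (simplex only; the
    # quasi-Newton polish happens once per distinct optimum at the end)
    add_optimum <- function(start, nm_iter) {
      fit <- tryCatch(
        stats::optim(start, neg, method = "Nelder-Mead",
                     control = list(maxit = nm_iter)),
        error = function(e) NULL)
      if (is.null(fit)) return(invisible(NULL))
      for (i in seq_along(optima)) {
        if (sqrt(sum((optima[[i]]$par - fit$par)^2)) < dedup_tol) {
          if (fit$value < optima[[i]]$value) optima[[i]] <<- fit
          return(invisible(NULL))
        }
      }
      optima[[length(optima) + 1L]] <<- fit
      invisible(NULL)
    }
    coarse <- coarse[order(vapply(coarse, function(m) m$value, numeric(1)))]
    for (cf in head(coarse, 5)) add_optimum(cf$par, maxit)
    # phase 3: probe for reflection modes of the weakly identified
    # probability intercepts, restarting from the best mode with each such
    # coordinate shifted
    if (length(optima)) {
      best0 <- optima[[which.min(vapply(optima, function(m) m$value,
                                        numeric(1)))]]
      probe_idx <- which(priors$scale == "invlogit")
      for (j in probe_idx) {
        for (shift in c(-0.7, 0.7)) {
          st <- best0$par
          st[j] <- st[j] + shift
          add_optimum(st, 150)
        }
      }
    }
    # final polish of each distinct optimum near the best, then
    # re-deduplicate
    vals <- vapply(optima, function(m) m$value, numeric(1))
    polished <- optima[vals <= min(vals) + keep_within]
    optima <- list()
    for (m in polished) {
      fit <- tryCatch(
        stats::optim(m$par, neg, method = "BFGS",
                     control = list(maxit = polish_maxit)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$value < m$value) m <- fit
      dup <- FALSE
      for (i in seq_along(optima)) {
        if (sqrt(sum((optima[[i]]$par - m$par)^2)) < dedup_tol) {
          dup <- TRUE
          if (m$value < optima[[i]]$value) optima[[i]] <- m
          break
        }
      }
      if (!dup) optima[[length(optima) + 1L]] <- m
    }
  })
  if (!length(optima)) abort("Posterior mode search failed from all starts.")
  best_val <- min(vapply(optima, function(m) m$value, numeric(1)))
  optima <- Filter(function(m) m$value <= best_val + keep_within, optima)
  modes <- lapply(optima, function(m) {
    H <- tryCatch(stats::optimHess(m$par, neg), error = function(e) NULL)
    if (is.null(H)) H <- diag(length(m$par))
    ev <- eigen((H + t(H)) / 2, symmetric = TRUE)
    vals <- pmax(ev$values, max(abs(ev$values)) * 1e-8, 1e-8)
    list(mode = m$par, cov = ev$vectors %*% (t(ev$vectors) / vals),
         logpost = -m$value, half_logdet_cov = -0.5 * sum(log(vals)))
  })
  lw <- vapply(modes, function(m) m$logpost + m$half_logdet_cov, numeric(1))
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  ord <- order(vapply(modes, function(m) -m$logpost, numeric(1)))
  modes <- modes[ord]
  w <- w[ord]
  for (i in seq_along(modes)) modes[[i]]$weight <- w[i]
  c(modes[[1]][c("mode", "cov", "logpost")], list(modes = modes))
}

# precompute Cholesky factors and normalizing constants for the Gaussian
# mixture built on the discovered modes. Each mode contributes two
# components, at the Laplace scale and at 3x that scale, so the proposal
# has a sharp core plus heavy tails that keep ridge extensions beyond the
# local Laplace width proposable. Mode weights are floored so no
# discovered mode is starved.
prepare_jump <- function(modes, scales = c(1, 3), scale_probs = c(0.7, 0.3)) {
  w <- vapply(modes, `[[`, 1, "weight")
  w <- pmax(w, 0.1)
  w <- w / sum(w)
  out <- list()
  for (i in seq_along(modes)) {
    m <- modes[[i]]
    d <- length(m$mode)
    U1 <- chol(m$cov + diag(d) * 1e-10)
    for (k in seq_along(scales)) {
      U <- scales[k] * U1
      out[[length(out) + 1L]] <- list(
        mean = m$mode, U = U, weight = w[i] * scale_probs[k],
        log_norm = -0.5 * d * log(2 * pi) - sum(log(diag(U))))
    }
  }
  out
}

jump_draw <- function(jump) {
  i <- sample.int(length(jump), 1, prob = vapply(jump, `[[`, 1, "weight"))
  m <- jump[[i]]
  m$mean + drop(rnorm(length(m$mean)) %*% m$U)
}

jump_logdens <- function(jump, x) {
  comp <- vapply(jump, function(m) {
    y <- backsolve(m$U, x - m$mean, transpose = TRUE)
    log(m$weight) + m$log_norm - 0.5 * sum(y^2)
  }, numeric(1))
  mx <- max(comp)
  mx + log(sum(exp(comp - mx)))
}

# n_chains starting points jittered around the Laplace mode; retries shrink
# the jitter if it lands on a non-finite posterior
laplace_inits <- function(map, logpost, n_chains, seed, jitter = 1) {
  npar <- length(map$mode)
  L <- chol(map$cov + diag(npar) * 1e-10)
  init <- matrix(NA_real_, n_chains, npar)
  withr::with_seed(as.integer(seed), {
    for (ch in seq_len(n_chains)) {
      fac <- jitter
      for (try in 1:20) {
        cand <- map$mode + fac * drop(rnorm(npar) %*% L)
        if (is.finite(logpost(cand))) break
        fac <- fac / 2
      }
      init[ch, ] <- cand
    }
  })
  init
}

#' MCMC protocol configuration
#'
#' Chains, adaptation length, sampling length, burn-in, thinning, and
#' per-chain seeds. The default mirrors a common field protocol: 3 chains,
#' 20,000 adaptation iterations, then 12,000 iterations with the first
#' 1,000 discarded as burn-in and the rest thinned by 10, retaining
#' `ceiling((n_iter - n_burnin) / thin)` = 1,100 draws per chain (3,300
#' total).
#'
#' @param n_chains Number of chains (>= 1; >= 2 for convergence checks).
#' @param n_adapt Adaptation iterations (proposal tuning only, discarded).
#' @param n_iter Post-adaptation iterations per chain.
#' @param n_burnin Iterations discarded after adaptation (< `n_iter`).
#' @param thin Keep every `thin`-th post-burn-in iteration.
#' @param seed Single integer from which distinct per-chain seeds are
#'   derived; alternatively give `seeds` directly.
#' @param seeds Optional integer vector, one distinct seed per chain.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_adapt = 20000, n_iter = 12000,
                        n_burnin = 1000, thin = 10, seed = 1, seeds = NULL) {
  if (n_burnin >= n_iter) abort("`n_burnin` must be < `n_iter`.")
  if (thin < 1) abort("`thin` must be >= 1.")
  if (is.null(seeds)) seeds <- derive_seeds(seed, n_chains)
  seeds <- as.integer(seeds)
  if (length(seeds) != n_chains || anyDuplicated(seeds)) {
    abort("Need one distinct seed per chain.")
  }
  structure(
    list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
         n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
         thin = as.integer(thin), seeds = seeds,
         n_retained = as.integer(ceiling((n_iter - n_burnin) / thin))),
    class = "mcmc_config"
  )
}

#' Adaptive random-walk Metropolis sampler
#'
#' Samples the posterior implied by `loglik` plus `priors` with blocked
#' Gaussian random-walk proposals. During the adaptation phase each block
#' learns both a scalar step size (Robbins-Monro updates toward roughly
#' 23% acceptance, inside the 20-45% band that keeps random walks
#' efficient) and the empirical covariance of the chain so far, so
#' proposals follow the posterior's correlation structure
#' (Haario-style adaptive Metropolis). Both are frozen when adaptation
#' ends, so the recorded chain is a valid Markov chain satisfying detailed
#' balance. Identical seeds give identical draws.
#'
#' @param loglik Function of the working-scale parameter vector returning a
#'   scalar log-likelihood (may be `-Inf`).
#' @param priors A [prior_spec()]; row order defines the parameter order.
#' @param config An [mcmc_config()].
#' @param blocks List of integer index vectors partitioning the parameters
#'   into proposal blocks. Default: one block with all parameters.
#' @param init Optional numeric matrix (`n_chains` x `n_par`) of
#'   working-scale starting values; default draws from the priors with up
#'   to 100 retries per chain until the log-posterior is finite.
#' @param init_scale Initial proposal SD (used until enough history exists
#'   to estimate a covariance).
#' @param init_cov Optional initial proposal covariance (a matrix for a
#'   single block, or a list of matrices matching `blocks`), e.g. a
#'   Laplace approximation; refined during adaptation.
#' @param adapt_cov Re-estimate the proposal covariance from the chain
#'   history during adaptation. Disable to keep `init_cov` fixed (only the
#'   scalar step size is then tuned), which is more stable when a good
#'   covariance is already known.
#' @param jump Optional mode-jumping mixture: the `modes` element of
#'   [map_laplace()]. When given, a fraction `jump_prob` of iterations
#'   propose an independent draw from the Gaussian mixture over the
#'   discovered posterior modes (Metropolis-Hastings corrected with the
#'   mixture density), letting chains hop between well-separated modes
#'   that a random walk crosses only rarely.
#' @param jump_prob Probability of a mode-jump proposal per iteration.
#' @return A `posterior_samples` object: `draws` is an array
#'   `(iteration, chain, parameter)`; also carries the config, priors,
#'   per-block acceptance rates, and (when set by fitting wrappers) the
#'   covariate standardizers.
#' @export
sample_posterior <- function(loglik, priors, config, blocks = NULL,
                             init = NULL, init_scale = 0.1,
                             init_cov = NULL, adapt_cov = TRUE,
                             jump = NULL, jump_prob = 0.1) {
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "mcmc_config"))
  npar <- nrow(priors)
  pnames <- priors$parameter
  if (is.null(blocks)) blocks <- list(seq_len(npar))
  if (!setequal(unlist(blocks), seq_len(npar))) {
    abort("`blocks` must partition the parameter indices.")
  }
  log_prior <- log_prior_fn(priors)
  if (!is.null(jump)) jump <- prepare_jump(jump)
  n_keep <- config$n_retained
  draws <- array(NA_real_, dim = c(n_keep, config$n_chains, npar),
                 dimnames = list(NULL, NULL, pnames))
  accept <- matrix(NA_real_, config$n_chains, length(blocks))
  jump_accept <- rep(NA_real_, config$n_chains)
  target_acc <- 0.234

  for (ch in seq_len(config$n_chains)) {
    withr::with_seed(config$seeds[ch], {
      if (is.null(init)) {
        theta <- NULL
        for (try in seq_len(100L)) {
          cand <- draw_init(priors)
          lp <- loglik(cand) + log_prior(cand)
          if (is.finite(lp)) { theta <- cand; break }
        }
        if (is.null(theta)) {
          abort("Could not find a finite starting point in 100 prior draws.")
        }
      } else {
        theta <- init[ch, ]
        lp <- loglik(theta) + log_prior(theta)
        if (!is.finite(lp)) abort("Supplied init has non-finite posterior.")
      }
      nb <- length(blocks)
      log_sig <- rep(log(init_scale), nb)
      # running moments of the chain, per block (Welford)
      mu <- lapply(blocks, function(idx) theta[idx])
      M2 <- lapply(blocks, function(idx) {
        d <- length(idx); matrix(0, d, d)
      })
      n_hist <- 0L
      # proposal square roots: exp(log_sig) * chol(2.38^2/d * Cov)
      if (!is.null(init_cov) && is.matrix(init_cov)) {
        if (length(blocks) != 1L) {
          abort("Give `init_cov` as a list when using multiple blocks.")
        }
        init_cov <- list(init_cov)
      }
      prop_sqrt <- lapply(seq_along(blocks), function(b) {
        d <- length(blocks[[b]])
        if (!is.null(init_cov)) {
          C <- init_cov[[b]] + diag(d) * 1e-10
          (2.38 / sqrt(d)) * chol(C)
        } else {
          diag(d) * (2.38 / sqrt(d))
        }
      })
      refresh_sqrt <- function(b) {
        d <- length(blocks[[b]])
        C <- M2[[b]] / max(n_hist - 1L, 1L)
        C <- C + diag(d) * (1e-8 + 1e-6 * mean(diag(C)))
        ch_ok <- tryCatch(chol(C), error = function(e) NULL)
        if (!is.null(ch_ok)) prop_sqrt[[b]] <<- (2.38 / sqrt(d)) * ch_ok
      }
      acc_n <- integer(nb)
      prop_n <- integer(nb)
      jmp_n <- 0L
      jmp_a <- 0L
      batch <- 0L
      keep_row <- 0L
      total <- config$n_adapt + config$n_iter
      for (it in seq_len(total)) {
        adapting <- it <= config$n_adapt
        if (!is.null(jump) && runif(1) < jump_prob) {
          # independence proposal from the mode mixture
          jmp_n <- jmp_n + 1L
          cand <- jump_draw(jump)
          lp_cand <- loglik(cand) + log_prior(cand)
          if (is.finite(lp_cand)) {
            ratio <- (lp_cand - jump_logdens(jump, cand)) -
              (lp - jump_logdens(jump, theta))
            if (log(runif(1)) < ratio) {
              theta <- cand
              lp <- lp_cand
              jmp_a <- jmp_a + 1L
            }
          }
        }
        for (b in seq_len(nb)) {
          idx <- blocks[[b]]
          cand <- theta
          cand[idx] <- cand[idx] +
            exp(log_sig[b]) * drop(rnorm(length(idx)) %*% prop_sqrt[[b]])
          lp_cand <- loglik(cand) + log_prior(cand)
          if (is.finite(lp_cand) && log(runif(1)) < lp_cand - lp) {
            theta <- cand
            lp <- lp_cand
            acc_n[b] <- acc_n[b] + 1L
          }
          prop_n[b] <- prop_n[b] + 1L
        }
        if (adapting) {
          n_hist <- n_hist + 1L
          for (b in seq_len(nb)) {
            x <- theta[blocks[[b]]]
            delta <- x - mu[[b]]
            mu[[b]] <- mu[[b]] + delta / n_hist
            M2[[b]] <- M2[[b]] + tcrossprod(delta, x - mu[[b]])
          }
          if (it %% 50L == 0L) {
            batch <- batch + 1L
            rate <- acc_n / pmax(prop_n, 1L)
            step <- min(0.5, 5 / sqrt(batch))
            log_sig <- log_sig + step * (rate - target_acc)
            acc_n[] <- 0L
            prop_n[] <- 0L
            if (adapt_cov && n_hist >= 100L) {
              for (b in seq_len(nb)) refresh_sqrt(b)
            }
          }
        }
        if (!adapting) {
          post_it <- it - config$n_adapt
          if (post_it > config$n_burnin &&
              (post_it - config$n_burnin - 1L) %% config$thin == 0L) {
            keep_row <- keep_row + 1L
            draws[keep_row, ch, ] <- theta
          }
        }
      }
      accept[ch, ] <- acc_n / pmax(prop_n, 1L)
      jump_accept[ch] <- if (jmp_n > 0) jmp_a / jmp_n else NA_real_
    })
  }
  structure(
    list(draws = draws, parameters = pnames, config = config,
         priors = priors, blocks = blocks, acceptance = accept,
         jump_acceptance = jump_accept, standardizers = NULL),
    class = "posterior_samples"
  )
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior samples: %d parameters, %d chains x %d draws\n",
              d[3], d[2], d[1]))
  print(posterior_summary(x), ...)
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic (split-chain R-hat)
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain drift also registers as non-convergence. Values
#' near 1 indicate convergence; the conventional acceptance threshold used
#' throughout this package is R-hat < 1.1.
#'
#' @param samples A `posterior_samples` object, or a numeric matrix of one
#'   parameter's draws with one column per chain.
#' @param split Halve each chain before computing the statistic (default
#'   `TRUE`).
#' @return Named numeric vector of R-hat values (one per parameter).
#' @export
gelman_rubin <- function(samples, split = TRUE) {
  rhat_matrix <- function(m) {
    if (ncol(m) < 2) abort("R-hat needs at least 2 chains.")
    if (split) {
      n_half <- floor(nrow(m) / 2)
      m <- cbind(m[seq_len(n_half), , drop = FALSE],
                 m[nrow(m) - n_half + seq_len(n_half), , drop = FALSE])
    }
    n <- nrow(m); k <- ncol(m)
    if (k < 2) abort("R-hat needs at least 2 chains.")
    if (n < 2) abort("R-hat needs at least 2 draws per half-chain.")
    W <- mean(apply(m, 2, var))
    B <- n * var(colMeans(m))
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }
  if (is.matrix(samples)) return(rhat_matrix(samples))
  stopifnot(inherits(samples, "posterior_samples"))
  if (dim(samples$draws)[2] < 2) abort("R-hat needs at least 2 chains.")
  out <- vapply(seq_along(samples$parameters),
                function(j) rhat_matrix(samples$draws[, , j, drop = TRUE]),
                numeric(1))
  setNames(out, samples$parameters)
}

#' Posterior means and 95% credible intervals
#'
#' Pools draws across chains and reports the mean and the 2.5% / 97.5%
#' quantiles per parameter. Quantiles use linear interpolation between
#' order statistics (R's default type 7 rule).
#'
#' @param samples A `posterior_samples` object.
#' @param probs Two quantile probabilities; default `c(0.025, 0.975)`.
#' @return A tibble: `parameter`, `mean`, `lower95`, `upper95`.
#' @export
posterior_summary <- function(samples, probs = c(0.025, 0.975)) {
  stopifnot(inherits(samples, "posterior_samples"), length(probs) == 2)
  rows <- lapply(seq_along(samples$parameters), function(j) {
    x <- as.vector(samples$draws[, , j])
    q <- quantile(x, probs, names = FALSE, type = 7)
    tibble::tibble(parameter = samples$parameters[j], mean = mean(x),
                   lower95 = q[1], upper95 = q[2])
  })
  dplyr::bind_rows(rows)
}

#' @method tidy posterior_samples
#' @export
tidy.posterior_samples <- function(x, ...) {
  out <- posterior_summary(x)
  out$rhat <- if (dim(x$draws)[2] >= 2) unname(gelman_rubin(x)) else NA_real_
  out
}

#' @method glance posterior_samples
#' @export
glance.posterior_samples <- function(x, ...) {
  tibble::tibble(
    n_parameters = length(x$parameters),
    n_chains = dim(x$draws)[2],
    n_draws_per_chain = dim(x$draws)[1],
    max_rhat = if (dim(x$draws)[2] >= 2) max(gelman_rubin(x)) else NA_real_
  )
}

#' Posterior draws in long format
#'
#' @param x A `posterior_samples` object.
#' @param ... Unused.
#' @return A tibble with columns `chain`, `iteration`, `parameter`, `value`.
#' @export
as_draws_df <- function(x, ...) {
  stopifnot(inherits(x, "posterior_samples"))
  d <- dim(x$draws)
  tibble::tibble(
    chain = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(x$parameters, each = d[1] * d[2]),
    value = as.vector(x$draws)
  )
}
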