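#' Generating truth for synthetic road-mortality risk data
#'
#' Structural equations over the nodes of a causal DAG, plus the logistic
#' outcome model for mortality risk. Each non-outcome node is either
#' Gaussian on a working ("latent") scale — the log for positive
#' multiplicative covariates, the logit for proportions — or Bernoulli;
#' its observed column is the back-transformed latent. The outcome's
#' linear predictor uses each parent on the scale a regression would use
#' it: the log for `exp`-transformed covariates, the observed value
#' otherwise.
#'
#' The defaults encode an urbanization cascade consistent with
#' [default_squirrel_dag()]: population density falls with distance to the
#' city center and drives building density, speed limits and traffic;
#' forest cover falls with building density and drives fragmentation,
#' crossings and morph abundance; fragmentation drives habitat split.
#'
#' @param outcome Named numeric vector: `intercept` plus one coefficient
#'   per parent of the outcome node (`speed`, `traffic`, `crossings`,
#'   `habitat_split`, `morph_abundance` by default). Coefficients for
#'   log-scale covariates (e.g. `traffic`) are per log unit.
#' @param nodes Optional replacement list of node specifications; each
#'   element is a list with `parents` (character), `coefs` (numeric, one
#'   per parent, applied on the parents' working scale), `intercept`,
#'   `sd` (Gaussian nodes), `dist` (`"gaussian"` or `"bernoulli"`), and
#'   `transform` (`"identity"`, `"exp"`, `"invlogit"`).
#' @param observed Columns reported in the dataset.
#' @return A list of class `risk_truth`.
#' @export
risk_truth <- function(outcome = c(intercept = -8.2, speed = 0.04,
                                   traffic = 0.5, crossings = 0.6,
                                   habitat_split = 1.5,
                                   morph_abundance = 0.5),
                       nodes = NULL,
                       observed = c("speed", "traffic", "crossings",
                                    "habitat_split", "pop_density",
                                    "forest_cover", "fragmentation")) {
  if (is.null(nodes)) nodes <- default_risk_nodes()
  if (!"intercept" %in% names(outcome)) abort("`outcome` needs an intercept.")
  miss <- setdiff(setdiff(names(outcome), "intercept"), names(nodes))
  if (length(miss)) {
    abort(paste0("Outcome coefficients for unknown nodes: ",
                 paste(miss, collapse = ", ")))
  }
  edges <- do.call(rbind, lapply(names(nodes), function(nm) {
    pa <- nodes[[nm]]$parents
    if (length(pa)) data.frame(parent = pa, child = nm) else NULL
  }))
  out_edges <- data.frame(parent = setdiff(names(outcome), "intercept"),
                          child = "mortality")
  dag <- causal_dag(rbind(edges, out_edges), nodes = names(nodes))
  structure(list(nodes = nodes, outcome = outcome, observed = observed,
                 dag = dag),
            class = "risk_truth")
}

default_risk_nodes <- function() {
  node <- function(parents = character(0), coefs = numeric(0),
                   intercept = 0, sd = 1, dist = "gaussian",
                   transform = "identity") {
    list(parents = parents, coefs = coefs, intercept = intercept, sd = sd,
         dist = dist, transform = transform)
  }
  list(
    # distance to city center, km, uniform over the study gradient
    distance = node(intercept = mean(c(0.93, 11.3)),
                    sd = diff(c(0.93, 11.3)) / sqrt(12)),
    # people per km^2 on the log scale; denser near the center
    pop_density = node("distance", coefs = -0.25, intercept = 7.5, sd = 0.6,
                       transform = "exp"),
    building_density = node("pop_density", coefs = 0.8, intercept = -4.8,
                            sd = 0.45),
    # proportion forest on the logit scale; falls with building density
    forest_cover = node("building_density", coefs = -0.9, intercept = -0.4,
                        sd = 0.5, transform = "invlogit"),
    # disjunct core areas on the log scale; rises as forest thins
    fragmentation = node("forest_cover", coefs = -0.6, intercept = 2.5,
                         sd = 0.5, transform = "exp"),
    morph_abundance = node(c("forest_cover", "pop_density"),
                           coefs = c(0.6, 0.3), intercept = -1.8, sd = 0.5),
    # posted speed, mph; slower where population is dense
    speed = node("pop_density", coefs = -5, intercept = 72, sd = 4),
    # AADT on the log scale
    traffic = node("pop_density", coefs = 0.9, intercept = 2.6, sd = 0.7,
                   transform = "exp"),
    crossings = node(c("building_density", "forest_cover"),
                     coefs = c(0.6, 0.7), dist = "bernoulli"),
    habitat_split = node("fragmentation", coefs = 1.0, intercept = -3.5,
                         sd = 0.6, transform = "invlogit")
  )
}

# working ("latent") value of each node, simulated parent-first
simulate_sem_pool <- function(truth, n) {
  nodes <- truth$nodes
  ord <- topological_order(truth$dag)
  ord <- ord[ord %in% names(nodes)]
  latent <- list()
  for (nm in ord) {
    nd <- nodes[[nm]]
    lp <- rep(nd$intercept, n)
    if (length(nd$parents)) {
      for (i in seq_along(nd$parents)) {
        lp <- lp + nd$coefs[i] * latent[[nd$parents[i]]]
      }
    }
    latent[[nm]] <- if (identical(nd$dist, "bernoulli")) {
      rbinom(n, 1L, invlogit(lp))
    } else {
      lp + rnorm(n, 0, nd$sd)
    }
  }
  latent
}

risk_input_value <- function(truth, nm, latent) {
  nd <- truth$nodes[[nm]]
  switch(nd$transform,
    exp = latent[[nm]],                 # regression uses the log scale
    invlogit = invlogit(latent[[nm]]),  # regression uses the proportion
    identity = latent[[nm]]
  )
}

observed_value <- function(truth, nm, latent) {
  nd <- truth$nodes[[nm]]
  switch(nd$transform,
    exp = exp(latent[[nm]]),
    invlogit = invlogit(latent[[nm]]),
    identity = latent[[nm]]
  )
}

#' Simulate a road-mortality risk dataset
#'
#' Generates covariates parent-first along the structural equations of a
#' [risk_truth()] and draws the binary outcome (1 = DOR location, 0 =
#' reference) from the logistic outcome model. With `balanced = TRUE`
#' (default, mirroring a matched case-reference design) a large population
#' pool is simulated and `n_per_group` cases and references are sampled
#' from it, so the returned data have equal group sizes by construction;
#' with `balanced = FALSE` a simple random sample of `2 * n_per_group`
#' locations is returned with the population prevalence.
#'
#' @param truth A [risk_truth()].
#' @param n_per_group Locations per outcome class (>= 10).
#' @param seed Integer seed.
#' @param balanced Case-reference balancing flag (see above).
#' @return A tibble with `outcome` and the observed covariate columns;
#'   attribute `"truth"` carries the generator.
#' @examples
#' risk <- simulate_risk_dataset(risk_truth(), n_per_group = 141, seed = 3)
#' table(risk$outcome)
#' @export
simulate_risk_dataset <- function(truth = risk_truth(), n_per_group, seed,
                                  balanced = TRUE) {
  stopifnot(inherits(truth, "risk_truth"))
  if (!is.numeric(n_per_group) || n_per_group < 10) {
    abort("`n_per_group` must be >= 10.")
  }
  n_per_group <- as.integer(n_per_group)
  out_coef <- truth$outcome
  parents <- setdiff(names(out_coef), "intercept")
  withr::with_seed(as.integer(seed), {
    n_pool <- if (balanced) max(60L * n_per_group, 5000L) else 2L * n_per_group
    for (attempt in 1:4) {
      latent <- simulate_sem_pool(truth, n_pool)
      lp <- rep(out_coef[["intercept"]], n_pool)
      for (nm in parents) {
        lp <- lp + out_coef[[nm]] * risk_input_value(truth, nm, latent)
      }
      y <- rbinom(n_pool, 1L, invlogit(lp))
      if (!balanced || (sum(y == 1L) >= n_per_group &&
                        sum(y == 0L) >= n_per_group)) break
      n_pool <- n_pool * 4L
    }
    if (balanced) {
      if (sum(y == 1L) < n_per_group || sum(y == 0L) < n_per_group) {
        abort("Could not realize enough cases/references; outcome model too extreme.")
      }
      idx <- c(sample(which(y == 1L), n_per_group),
               sample(which(y == 0L), n_per_group))
    } else {
      idx <- seq_len(n_pool)
    }
  })
  cols <- lapply(truth$observed, function(nm) observed_value(truth, nm, latent)[idx])
  names(cols) <- truth$observed
  out <- tibble::as_tibble(c(list(outcome = y[idx]), cols))
  attr(out, "truth") <- truth
  attr(out, "balanced") <- balanced
  out
}
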