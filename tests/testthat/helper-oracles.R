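# Independent oracles used across tests. These stay deliberately naive:
# direct summation / enumeration, no shared code with the implementation.

# brute-force marginal over latent N for one morph at one site
brute_marginal <- function(lambda, counts, p_count, detections = integer(0),
                           p_detect = numeric(0), n_top = 400) {
  total <- 0
  for (N in 0:n_top) {
    term <- dpois(N, lambda)
    if (length(counts)) term <- term * prod(dbinom(counts, N, p_count))
    if (length(detections)) {
      pstar <- 1 - (1 - p_detect)^N
      term <- term * prod(dbinom(detections, 1, pstar))
    }
    total <- total + term
  }
  log(total)
}

# joint Poisson(N_total) -> Binomial(split) marginalization over BOTH latents
brute_joint_split <- function(lambda_tot, p_mel, obs_mel, obs_gray,
                              n_top = 150) {
  # obs_*: list(counts, p_count, detections, p_detect)
  lik_given_N <- function(obs, N) {
    term <- 1
    if (length(obs$counts)) term <- prod(dbinom(obs$counts, N, obs$p_count))
    if (length(obs$detections)) {
      pstar <- 1 - (1 - obs$p_detect)^N
      term <- term * prod(dbinom(obs$detections, 1, pstar))
    }
    term
  }
  total <- 0
  for (Ntot in 0:n_top) {
    for (Nmel in 0:Ntot) {
      total <- total + dpois(Ntot, lambda_tot) *
        dbinom(Nmel, Ntot, p_mel) *
        lik_given_N(obs_mel, Nmel) * lik_given_N(obs_gray, Ntot - Nmel)
    }
  }
  log(total)
}

# path-enumeration d-separation oracle (independent of the moralization
# algorithm): enumerates every simple undirected path and applies the
# chain/fork/collider blocking rules directly
oracle_d_separated <- function(dag, X, Y, Z) {
  edges <- as.data.frame(dag$edges)
  nbrs <- function(v) unique(c(edges$child[edges$parent == v],
                               edges$parent[edges$child == v]))
  is_parent <- function(a, b) any(edges$parent == a & edges$child == b)
  desc <- function(v) {
    out <- character(0); frontier <- v
    while (length(frontier)) {
      nxt <- setdiff(unique(edges$child[edges$parent %in% frontier]), out)
      out <- c(out, nxt); frontier <- nxt
    }
    out
  }
  path_open <- function(path) {
    if (length(path) <= 2) return(TRUE)
    for (i in 2:(length(path) - 1)) {
      v <- path[i]
      collider <- is_parent(path[i - 1], v) && is_parent(path[i + 1], v)
      if (collider) {
        if (!(v %in% Z) && !length(intersect(c(v, desc(v)), Z))) return(FALSE)
      } else {
        if (v %in% Z) return(FALSE)
      }
    }
    TRUE
  }
  found_open <- FALSE
  walk <- function(path, target) {
    v <- path[length(path)]
    if (v == target) {
      if (path_open(path)) found_open <<- TRUE
      return()
    }
    for (w in setdiff(nbrs(v), path)) {
      if (!found_open) walk(c(path, w), target)
    }
  }
  for (x in X) for (y in Y) if (!found_open) walk(x, y)
  !found_open
}

# random DAG on n nodes: edges only from lower to higher label
random_dag <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    nodes <- LETTERS[seq_len(n)]
    pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(pairs)) < p_edge
    if (!any(keep)) keep[sample.int(nrow(pairs), 1)] <- TRUE
    causal_dag(data.frame(parent = nodes[pairs[keep, 1]],
                          child = nodes[pairs[keep, 2]]),
               nodes = nodes)
  })
}

# small survey dataset built by hand (no simulator) for likelihood tests
tiny_survey_data <- function() {
  sites <- tibble::tibble(site = 1:3,
                          distance_km = c(1.5, 5, 10),
                          dist_std = standardize(c(1.5, 5, 10))$values,
                          camera = c(TRUE, TRUE, FALSE))
  counts <- tibble::tibble(
    site = c(1L, 1L, 2L, 2L, 3L),
    survey = c(1L, 2L, 1L, 2L, 1L),
    temp = c(10, 12, 8, 15, 11),
    temp_std = c(-0.3, 0.2, -0.8, 1.1, 0),
    count_melanic = c(2L, 1L, 0L, 1L, 0L),
    count_gray = c(1L, 3L, 2L, 0L, 1L)
  )
  cameras <- tibble::tibble(
    site = c(1L, 1L, 1L, 2L, 2L),
    day = c(1L, 2L, 3L, 1L, 2L),
    temp = c(9, 14, 10, 7, 13),
    temp_std = c(-0.5, 0.9, -0.2, -1.2, 0.6),
    det_melanic = c(1L, 0L, 1L, 0L, 0L),
    det_gray = c(1L, 1L, 0L, 1L, 0L)
  )
  structure(
    list(sites = sites, counts = counts, cameras = cameras, latent = NULL,
         standardizers = list(
           distance = list(mean = mean(sites$distance_km),
                           sd = sd(sites$distance_km)),
           temperature = list(mean = 11, sd = 2.5))),
    class = "squirrel_survey_data"
  )
}

tiny_params <- function() {
  living_model_params(beta0_N = 1.1, beta1_N = -0.4,
                      beta0_M = -0.5, beta1_M = -0.7,
                      det_melanic = c(-0.8, 0.1, -0.25),
                      det_gray = c(-0.4, -0.05, -0.3))
}
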