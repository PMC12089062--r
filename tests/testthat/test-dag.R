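test_that("DAG construction validates structure", {
  dag <- causal_dag(data.frame(parent = c("A", "B"), child = c("B", "C")))
  expect_setequal(dag$nodes, c("A", "B", "C"))
  expect_error(causal_dag(data.frame(parent = c("A", "B"),
                                     child = c("B", "A"))), "cycle")
  expect_error(causal_dag(data.frame(parent = "A", child = "A")), "Self-loop")
  expect_equal(dag_descendants(dag, "A"), c("B", "C"))
  expect_equal(dag_ancestors(dag, "C"), c("A", "B"))
  expect_error(dag_ancestors(dag, "Z"), "Unknown")
})

test_that("d-separation handles chains, forks and colliders", {
  chain <- causal_dag(data.frame(parent = c("A", "B"), child = c("B", "C")))
  expect_true(d_separated(chain, "A", "C", "B"))
  expect_false(d_separated(chain, "A", "C"))

  fork <- causal_dag(data.frame(parent = c("B", "B"), child = c("A", "C")))
  expect_true(d_separated(fork, "A", "C", "B"))
  expect_false(d_separated(fork, "A", "C"))

  collider <- causal_dag(data.frame(parent = c("A", "C"), child = c("B", "B")))
  expect_true(d_separated(collider, "A", "C"))
  expect_false(d_separated(collider, "A", "C", "B"))

  # conditioning on a collider's descendant also opens the path
  cd <- causal_dag(data.frame(parent = c("A", "C", "B"),
                              child = c("B", "B", "D")))
  expect_false(d_separated(cd, "A", "C", "D"))
  expect_error(d_separated(chain, "A", "A"), "disjoint")
})

test_that("d-separation agrees with path-enumeration oracle on random DAGs", {
  for (rep in 1:25) {
    dag <- random_dag(n = sample(4:6, 1), p_edge = 0.4, seed = 100 + rep)
    nodes <- dag$nodes
    withr::with_seed(200 + rep, {
      xy <- sample(nodes, 2)
      rest <- setdiff(nodes, xy)
      z <- if (length(rest)) {
        sample(rest, sample(0:length(rest), 1))
      } else {
        character(0)
      }
    })
    expect_equal(
      d_separated(dag, xy[1], xy[2], z),
      oracle_d_separated(dag, xy[1], xy[2], z),
      info = sprintf("rep %d: %s _||_ %s | {%s}", rep, xy[1], xy[2],
                     paste(z, collapse = ","))
    )
  }
})

test_that("backdoor sets match brute-force enumeration on random DAGs", {
  # oracle: test every subset of non-descendants via the oracle d-separation
  # in the graph with the exposure's outgoing edges removed
  oracle_backdoor <- function(dag, x, y) {
    desc <- dag_descendants(dag, x, include_self = TRUE)
    pool <- sort(setdiff(dag$nodes, c(desc, y)))
    e <- dag$edges[dag$edges$parent != x, ]
    bd <- structure(list(nodes = dag$nodes, edges = e), class = "causal_dag")
    valid <- list()
    sizes <- 0:length(pool)
    for (k in sizes) {
      combos <- if (k == 0) list(character(0)) else
        utils::combn(pool, k, simplify = FALSE)
      for (z in combos) {
        if (any(vapply(valid, function(v) all(v %in% z), logical(1)))) next
        if (oracle_d_separated(bd, x, y, z)) valid[[length(valid) + 1]] <- z
      }
    }
    valid
  }
  for (rep in 1:12) {
    dag <- random_dag(n = sample(4:6, 1), p_edge = 0.45, seed = 300 + rep)
    withr::with_seed(400 + rep, xy <- sample(dag$nodes, 2))
    got <- backdoor_sets(dag, xy[1], xy[2])
    want <- oracle_backdoor(dag, xy[1], xy[2])
    expect_equal(got, want,
                 info = sprintf("rep %d: %s -> %s", rep, xy[1], xy[2]))
  }
  # chain: no backdoor path, empty set is the unique minimal set
  chain <- causal_dag(data.frame(parent = c("A", "B"), child = c("B", "C")))
  expect_equal(backdoor_sets(chain, "A", "C"), list(character(0)))
})

test_that("the default study DAG yields the expected adjustment structure", {
  dag <- default_squirrel_dag()
  expect_true("pop_density" %in% dag$nodes)
  sets_speed <- backdoor_sets(dag, "speed", "mortality")
  expect_true(any(vapply(sets_speed, identical, logical(1),
                         y = "pop_density")))
  # speed's adjustment goes through population density alone
  expect_identical(sets_speed[[1]], "pop_density")

  # adjustment covariates observable in a risk dataset, per exposure
  observed <- c("speed", "traffic", "crossings", "habitat_split",
                "pop_density", "forest_cover", "fragmentation")
  chosen <- lapply(c("speed", "traffic", "crossings", "habitat_split"),
                   function(ex) {
                     sets <- backdoor_sets(dag, ex, "mortality")
                     usable <- Filter(function(z) all(z %in% observed), sets)
                     usable[[1]]
                   })
  expect_true(all(unlist(chosen) %in%
                    c("pop_density", "forest_cover", "fragmentation")))
})

test_that("DAG round-trips through its CSV form", {
  dag <- default_squirrel_dag()
  path <- withr::local_tempfile(fileext = ".csv")
  write_dag_csv(dag, path)
  back <- read_dag_csv(path)
  expect_equal(back$nodes, dag$nodes)
  expect_equal(dplyr::arrange(back$edges, parent, child),
               dplyr::arrange(dag$edges, parent, child))
})
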