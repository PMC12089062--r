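#' Construct a causal DAG
#'
#' A directed acyclic graph given as a parent -> child edge list.
#' Acyclicity is verified by topological sort at construction.
#'
#' @param edges Two-column data frame (`parent`, `child`), or a character
#'   matrix with two columns.
#' @param nodes Optional character vector of node names (to include
#'   isolated nodes); defaults to the names appearing in `edges`.
#' @return An object of class `causal_dag` with elements `nodes` (sorted)
#'   and `edges` (tibble `parent`, `child`).
#' @examples
#' dag <- causal_dag(data.frame(parent = c("A", "B"), child = c("B", "C")))
#' d_separated(dag, "A", "C", "B")
#' @export
causal_dag <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) abort("`edges` needs columns parent and child.")
  names(edges)[1:2] <- c("parent", "child")
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  if (any(edges$parent == edges$child)) abort("Self-loops are not allowed.")
  edges <- unique(edges[, c("parent", "child")])
  nodes <- sort(unique(c(nodes, edges$parent, edges$child)))
  if (length(nodes) == 0) abort("DAG must have at least one node.")
  dag <- structure(
    list(nodes = nodes, edges = tibble::as_tibble(edges)),
    class = "causal_dag"
  )
  if (is.null(topological_order(dag))) {
    abort("Edge list contains a directed cycle.")
  }
  dag
}

#' @export
print.causal_dag <- function(x, ...) {
  cat(sprintf("Causal DAG: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges))) {
    cat(sprintf("  %s -> %s\n", x$edges$parent[i], x$edges$child[i]))
  }
  invisible(x)
}

# Kahn's algorithm; NULL if cyclic
topological_order <- function(dag) {
  nodes <- dag$nodes
  indeg <- setNames(integer(length(nodes)), nodes)
  for (ch in dag$edges$child) indeg[ch] <- indeg[ch] + 1L
  order <- character(0)
  queue <- names(indeg)[indeg == 0L]
  while (length(queue)) {
    n <- queue[1]; queue <- queue[-1]
    order <- c(order, n)
    ch <- dag$edges$child[dag$edges$parent == n]
    for (c0 in ch) {
      indeg[c0] <- indeg[c0] - 1L
      if (indeg[c0] == 0L) queue <- c(queue, c0)
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

parents_of <- function(dag, node) dag$edges$parent[dag$edges$child == node]
children_of <- function(dag, node) dag$edges$child[dag$edges$parent == node]

#' Ancestors or descendants of a node set
#'
#' @param dag A [causal_dag()].
#' @param nodes Character vector of node names.
#' @param include_self Include the query nodes themselves.
#' @return Sorted character vector.
#' @export
dag_ancestors <- function(dag, nodes, include_self = FALSE) {
  reach(dag, nodes, parents_of, include_self)
}

#' @rdname dag_ancestors
#' @export
dag_descendants <- function(dag, nodes, include_self = FALSE) {
  reach(dag, nodes, children_of, include_self)
}

reach <- function(dag, nodes, step, include_self) {
  check_nodes(dag, nodes)
  seen <- character(0)
  frontier <- nodes
  while (length(frontier)) {
    nxt <- unique(unlist(lapply(frontier, step, dag = dag)))
    nxt <- setdiff(nxt, c(seen, nodes))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(if (include_self) unique(c(seen, nodes)) else seen)
}

check_nodes <- function(dag, nodes) {
  unknown <- setdiff(nodes, dag$nodes)
  if (length(unknown)) {
    abort(paste0("Unknown node(s): ", paste(unknown, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Test d-separation
#'
#' Returns `TRUE` iff every path between `X` and `Y` is blocked given `Z`
#' under the standard d-separation semantics (chains and forks are blocked
#' by conditioning; colliders are blocked unless the collider or one of its
#' descendants is conditioned on). Implemented via the moralized ancestral
#' graph: `X` and `Y` are d-separated by `Z` iff they are disconnected in
#' the moralization of the subgraph induced by the ancestors of
#' `X Y Z`, after removing `Z`.
#'
#' @param dag A [causal_dag()].
#' @param X,Y,Z Character vectors of node names; `Z` may be empty. The
#'   three sets must be disjoint.
#' @return Logical scalar.
#' @export
d_separated <- function(dag, X, Y, Z = character(0)) {
  stopifnot(inherits(dag, "causal_dag"))
  check_nodes(dag, c(X, Y, Z))
  if (length(intersect(X, Y)) || length(intersect(X, Z)) ||
      length(intersect(Y, Z))) {
    abort("X, Y and Z must be disjoint.")
  }
  anc <- dag_ancestors(dag, unique(c(X, Y, Z)), include_self = TRUE)
  e <- dag$edges[dag$edges$parent %in% anc & dag$edges$child %in% anc, ]
  # undirected adjacency: original edges plus marriages of co-parents
  adj <- lapply(setNames(vector("list", length(anc)), anc), function(x) character(0))
  add_edge <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (i in seq_len(nrow(e))) add_edge(e$parent[i], e$child[i])
  for (v in anc) {
    pa <- intersect(parents_of(dag, v), anc)
    if (length(pa) > 1) {
      for (i in seq_len(length(pa) - 1)) {
        for (j in seq(i + 1, length(pa))) add_edge(pa[i], pa[j])
      }
    }
  }
  keep <- setdiff(anc, Z)
  seen <- X <- intersect(X, keep)
  frontier <- X
  Y <- intersect(Y, keep)
  while (length(frontier)) {
    nxt <- setdiff(intersect(unique(unlist(adj[frontier])), keep), seen)
    if (length(intersect(nxt, Y))) return(FALSE)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  TRUE
}

#' Minimal backdoor adjustment sets
#'
#' Enumerates all minimal sets `Z` of non-descendants of `exposure` that
#' block every backdoor path from `exposure` to `outcome` (the backdoor
#' criterion): `Z` is valid iff exposure and outcome are d-separated by `Z`
#' in the graph with the exposure's outgoing edges removed. Subsets of the
#' candidate nodes are enumerated exhaustively, so this is intended for
#' the moderate-sized DAGs typical of applied causal analyses.
#'
#' @param dag A [causal_dag()].
#' @param exposure,outcome Node names.
#' @param candidates Optional restriction of the nodes allowed in
#'   adjustment sets (e.g. the observed covariates). Default: all nodes
#'   except exposure, outcome, and descendants of exposure.
#' @return A list of character vectors (each sorted), ordered by size and
#'   then lexicographically; `list(character(0))` when no adjustment is
#'   needed, `list()` when no valid set exists within the candidates.
#' @export
backdoor_sets <- function(dag, exposure, outcome, candidates = NULL) {
  stopifnot(inherits(dag, "causal_dag"))
  check_nodes(dag, c(exposure, outcome))
  if (identical(exposure, outcome)) abort("exposure must differ from outcome.")
  desc <- dag_descendants(dag, exposure, include_self = TRUE)
  pool <- setdiff(dag$nodes, c(desc, outcome))
  if (!is.null(candidates)) {
    check_nodes(dag, candidates)
    pool <- intersect(pool, candidates)
  }
  pool <- sort(pool)
  if (length(pool) > 20) {
    abort("Too many candidate nodes for exhaustive enumeration (> 20).")
  }
  # backdoor graph: drop exposure's outgoing edges
  e <- dag$edges[dag$edges$parent != exposure, ]
  bd_dag <- structure(list(nodes = dag$nodes, edges = e),
                      class = "causal_dag")
  valid <- list()
  is_superset_of_valid <- function(z) {
    any(vapply(valid, function(v) all(v %in% z), logical(1)))
  }
  for (size in 0:length(pool)) {
    combos <- if (size == 0) list(character(0)) else {
      cm <- utils::combn(pool, size, simplify = FALSE)
      cm[order(vapply(cm, paste, character(1), collapse = "\r"))]
    }
    for (z in combos) {
      if (is_superset_of_valid(z)) next  # not minimal
      if (d_separated(bd_dag, exposure, outcome, z)) {
        valid[[length(valid) + 1L]] <- z
      }
    }
  }
  valid
}

#' Default causal DAG for squirrel road-mortality risk
#'
#' The hypothesized causal structure linking urbanization to road and
#' landscape features and on to morph-specific road mortality risk.
#' Urbanization is a cascade from distance to the city center through human
#' population density, building density, forest cover and forest
#' fragmentation, which also drive local morph abundance; population
#' density sets speed limits and traffic volume, building density and
#' forest cover supply above-ground crossing structures (utility lines,
#' overhanging branches), fragmentation drives habitat split; and
#' mortality risk responds directly to speed, traffic, crossings, habitat
#' split and morph abundance. This edge list is a reconstruction from the
#' study-system literature and is deliberately editable: pass your own
#' edge list to [causal_dag()] (or edit a two-column CSV and use
#' [read_dag_csv()]) to encode different hypotheses.
#'
#' @return A [causal_dag()].
#' @export
default_squirrel_dag <- function() {
  causal_dag(data.frame(
    parent = c("distance",
               "pop_density", "pop_density", "pop_density", "pop_density",
               "building_density", "building_density",
               "forest_cover", "forest_cover", "forest_cover",
               "fragmentation",
               "speed", "traffic", "crossings", "habitat_split",
               "morph_abundance"),
    child = c("pop_density",
              "building_density", "morph_abundance", "speed", "traffic",
              "forest_cover", "crossings",
              "fragmentation", "morph_abundance", "crossings",
              "habitat_split",
              "mortality", "mortality", "mortality", "mortality",
              "mortality")
  ))
}

#' Read / write a DAG as a two-column CSV
#'
#' @param path File path; the CSV has columns `parent`, `child`.
#' @return `read_dag_csv()` returns a [causal_dag()]; `write_dag_csv()`
#'   returns `path` invisibly.
#' @export
read_dag_csv <- function(path) {
  causal_dag(read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_dag_csv
#' @param dag A [causal_dag()].
#' @export
write_dag_csv <- function(dag, path) {
  write.csv(as.data.frame(dag$edges), path, row.names = FALSE)
  invisible(path)
}
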