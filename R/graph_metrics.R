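as_igraph <- function(graph) {
  if (inherits(graph, "igraph")) return(graph)
  adj <- if (inherits(graph, "fc_graph")) graph$adjacency else graph
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Nodal clustering coefficient
#'
#' For each node, the fraction of its neighbour pairs that are themselves
#' connected: `NCp(i) = 2 T(i) / (k_i (k_i - 1))` with `T(i)` the number of
#' triangles through `i`; nodes of degree < 2 score 0.
#'
#' @param graph An `fc_graph` or binary adjacency matrix.
#' @return Numeric vector in `[0, 1]`, one value per node.
#' @export
nodal_clustering <- function(graph) {
  g <- as_igraph(graph)
  ncp <- igraph::transitivity(g, type = "local", isolates = "zero")
  ncp[!is.finite(ncp)] <- 0
  ncp
}

#' Nodal local efficiency
#'
#' Global efficiency of the subgraph induced by a node's neighbours (the
#' node itself removed): the efficiency of communication among its
#' neighbours if the node fails. Nodes of degree < 2 score 0.
#'
#' @inheritParams nodal_clustering
#' @return Numeric vector in `[0, 1]`, one value per node.
#' @export
nodal_local_efficiency <- function(graph) {
  g <- as_igraph(graph)
  n <- igraph::vcount(g)
  vapply(seq_len(n), function(i) {
    nb <- as.integer(igraph::neighbors(g, i))
    if (length(nb) < 2) return(0)
    sub <- igraph::induced_subgraph(g, nb)
    efficiency_of(sub)
  }, numeric(1))
}

efficiency_of <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Characteristic path length
#'
#' Mean shortest-path distance between node pairs. Three conventions for
#' disconnected graphs:
#' * `"reachable"` (default): arithmetic mean over reachable pairs only,
#'   with the number of unreachable pairs attached as attribute
#'   `n_unreachable`; a graph with no edges returns `NA`.
#' * `"harmonic"`: harmonic mean over all pairs, unreachable pairs
#'   contributing `1/d = 0` -- i.e. the reciprocal of global efficiency,
#'   the convention common in network toolboxes, which grows (rather than
#'   collapses) as a graph fragments; `Inf` on an empty graph.
#' * `"inf"`: any unreachable pair makes `Lp` infinite.
#'
#' @inheritParams nodal_clustering
#' @param disconnected `"reachable"`, `"harmonic"` or `"inf"`.
#' @return A length-1 numeric (possibly `NA`/`Inf`), with attribute
#'   `n_unreachable`.
#' @export
characteristic_path_length <- function(graph,
                                       disconnected = c("reachable",
                                                        "harmonic", "inf")) {
  disconnected <- match.arg(disconnected)
  g <- as_igraph(graph)
  if (igraph::vcount(g) < 2) abort("need at least 2 nodes")
  d <- igraph::distances(g)
  ut <- d[upper.tri(d)]
  unreach <- sum(!is.finite(ut))
  lp <- switch(disconnected,
    reachable = if (all(!is.finite(ut))) NA_real_ else
      mean(ut[is.finite(ut)]),
    harmonic = {
      inv <- 1 / ut
      inv[!is.finite(inv)] <- 0
      if (mean(inv) == 0) Inf else 1 / mean(inv)
    },
    inf = if (unreach > 0) Inf else mean(ut))
  attr(lp, "n_unreachable") <- unreach
  lp
}

#' Global efficiency
#'
#' Mean inverse shortest-path distance over distinct node pairs, with
#' `1/Inf = 0` for unreachable pairs; the inverse of the harmonic mean
#' shortest path.
#'
#' @inheritParams nodal_clustering
#' @return A number in `[0, 1]`.
#' @export
global_efficiency <- function(graph) {
  g <- as_igraph(graph)
  if (igraph::vcount(g) < 2) abort("need at least 2 nodes")
  efficiency_of(g)
}

#' Degree-preserving random null ensemble
#'
#' `M` Maslov-Sneppen double-edge-swap randomizations of the graph, each
#' preserving the exact degree sequence; reproducible under `seed`. Graphs
#' admitting no swap (e.g. stars) are returned as unchanged copies with a
#' warning.
#'
#' @inheritParams nodal_clustering
#' @param M Number of null graphs.
#' @param seed Integer seed.
#' @param niter_per_edge Swap attempts per edge.
#' @return List of `M` igraph objects.
#' @export
random_null_ensemble <- function(graph, M = 100, seed = 1,
                                 niter_per_edge = 10) {
  g <- as_igraph(graph)
  ne <- igraph::ecount(g)
  if (ne < 1) abort("graph has no edges")
  nulls <- withr::with_seed(seed, {
    lapply(seq_len(M), function(k) {
      igraph::rewire(g, igraph::keeping_degseq(niter = niter_per_edge * ne))
    })
  })
  if (M >= 2) {
    a0 <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    changed <- FALSE
    for (h in nulls) {
      if (!identical(igraph::as_adjacency_matrix(h, sparse = FALSE), a0)) {
        changed <- TRUE
        break
      }
    }
    if (!changed) {
      warn("degree-preserving rewiring left the graph unchanged (no valid swaps)")
    }
  }
  nulls
}

#' Small-worldness
#'
#' `sigma = (Cp / <Cp_rand>) / (Lp / <Lp_rand>)` against a degree-matched
#' null ensemble: a small-world graph keeps the clustering of a lattice
#' (`Cp >> Cp_rand`) at near-random path length (`Lp ~ Lp_rand`), so
#' `sigma > 1`.
#'
#' @inheritParams nodal_clustering
#' @param nulls List of null graphs (see [random_null_ensemble()]).
#' @return A length-1 numeric (`NA` if undefined).
#' @export
small_worldness <- function(graph, nulls) {
  cp <- mean(nodal_clustering(graph))
  lp <- as.numeric(characteristic_path_length(graph))
  cp_r <- mean(vapply(nulls, function(h) mean(nodal_clustering(h)),
                      numeric(1)))
  lp_r <- mean(vapply(nulls, function(h) {
    as.numeric(characteristic_path_length(h))
  }, numeric(1)))
  if (!is.finite(cp) || !is.finite(lp) || !is.finite(cp_r) ||
      !is.finite(lp_r) || cp_r == 0 || lp_r == 0 || lp == 0) {
    return(NA_real_)
  }
  (cp / cp_r) / (lp / lp_r)
}

#' Global metrics of one binary graph
#'
#' @inheritParams nodal_clustering
#' @param nulls Optional null ensemble for small-worldness.
#' @param lp_convention Disconnected-graph convention for `lp`, see
#'   [characteristic_path_length()].
#' @return A one-row tibble: `cp`, `lp`, `eg`, `eloc`, `sigma`,
#'   `n_unreachable`.
#' @export
global_metrics <- function(graph, nulls = NULL,
                           lp_convention = "reachable") {
  ncp <- nodal_clustering(graph)
  nle <- nodal_local_efficiency(graph)
  lp <- characteristic_path_length(graph, disconnected = lp_convention)
  tibble(
    cp = mean(ncp),
    lp = as.numeric(lp),
    eg = global_efficiency(graph),
    eloc = mean(nle),
    sigma = if (is.null(nulls)) NA_real_ else small_worldness(graph, nulls),
    n_unreachable = attr(lp, "n_unreachable"))
}

#' Area under a metric-versus-threshold curve
#'
#' Trapezoidal quadrature over the threshold grid (default); a left
#' rectangle-sum alternative is available for parity with other toolboxes.
#'
#' @param taus Threshold grid (ascending).
#' @param values Metric values at each threshold.
#' @param rule `"trapezoid"` or `"rectangle"`.
#' @return The area (length-1 numeric).
#' @export
auc_threshold <- function(taus, values, rule = c("trapezoid", "rectangle")) {
  rule <- match.arg(rule)
  stopifnot(length(taus) == length(values), length(taus) >= 2)
  dt <- diff(taus)
  if (rule == "trapezoid") {
    sum(dt * (head(values, -1) + tail(values, -1)) / 2)
  } else {
    sum(dt * head(values, -1))
  }
}

#' Metric curves and AUCs across the threshold sweep
#'
#' Evaluates the global metrics (Cp, Lp, Eg, Eloc and optionally
#' small-worldness) and the nodal metrics (NCp, NLe) on the binary graph at
#' every threshold, and summarizes each curve by its area under the curve
#' over the sweep. Metrics undefined at a threshold (e.g. Lp on an empty
#' graph) contribute 0 to the curve, with a warning, rather than aborting
#' the sweep.
#'
#' @param conn An `fc_conn` (or symmetric matrix).
#' @param taus Threshold grid.
#' @param null_M Nulls per threshold for small-worldness; `0` skips sigma.
#' @param seed Seed for the null ensembles.
#' @inheritParams threshold_graph
#' @param lp_convention Disconnected-graph convention for the Lp curve
#'   (default `"harmonic"`: on the fragmenting sparse graphs of a threshold
#'   sweep the reachable-pairs average collapses, while the harmonic form
#'   keeps growing, matching common toolbox behaviour); see
#'   [characteristic_path_length()]. Under the harmonic convention the Lp
#'   curve is additionally bounded at the node count -- the harmonic mean
#'   distance of any connected graph is below it, so larger values only
#'   signal fragmentation -- and an empty graph contributes the bound (a
#'   graph with no edges has the worst possible integration, not path
#'   length zero). Small-worldness always uses the reachable-pairs form
#'   for graph and nulls alike.
#' @param auc_rule Quadrature rule, see [auc_threshold()].
#' @return A list of class `fc_curves` with tibbles `global` (threshold,
#'   metric, value), `global_auc` (metric, auc), `nodal` (node, threshold,
#'   metric, value) and `nodal_auc` (node, metric, auc).
#' @export
metric_curves <- function(conn, taus = seq(0.40, 0.90, by = 0.05),
                          null_M = 100, seed = 1, scale = c("r", "z"),
                          lp_convention = "harmonic",
                          auc_rule = "trapezoid") {
  scale <- match.arg(scale)
  glob <- list(); nod <- list()
  undefined <- 0L
  for (k in seq_along(taus)) {
    g <- threshold_graph(conn, taus[k], scale)
    nulls <- NULL
    if (null_M > 0 && sum(g$adjacency) > 0) {
      nulls <- random_null_ensemble(g, M = null_M, seed = seed + k)
    }
    gm <- global_metrics(g, nulls, lp_convention = lp_convention)
    if (lp_convention == "harmonic") {
      nv <- nrow(g$adjacency)
      gm$lp <- if (is.finite(gm$lp)) min(gm$lp, nv) else nv
    } else if (!is.finite(gm$lp)) {
      gm$lp <- 0
      undefined <- undefined + 1L
    }
    if (!is.finite(gm$sigma)) gm$sigma <- 0
    glob[[k]] <- tibble(
      threshold = taus[k],
      metric = c("cp", "lp", "eg", "eloc", "sigma"),
      value = c(gm$cp, gm$lp, gm$eg, gm$eloc, gm$sigma))
    nod[[k]] <- tibble(
      node = rep(g$nodes, 2),
      threshold = taus[k],
      metric = rep(c("ncp", "nle"), each = length(g$nodes)),
      value = c(nodal_clustering(g), nodal_local_efficiency(g)))
  }
  if (undefined > 0) {
    warn(sprintf("metric undefined at %d threshold(s); contributed 0 to curves",
                 undefined))
  }
  global <- bind_rows(glob)
  nodal <- bind_rows(nod)
  if (null_M == 0) global <- filter(global, .data$metric != "sigma")
  global_auc <- global %>%
    group_by(.data$metric) %>%
    summarise(auc = auc_threshold(.data$threshold, .data$value, auc_rule),
              .groups = "drop")
  nodal_auc <- nodal %>%
    group_by(.data$node, .data$metric) %>%
    summarise(auc = auc_threshold(.data$threshold, .data$value, auc_rule),
              .groups = "drop")
  structure(list(global = global, global_auc = global_auc, nodal = nodal,
                 nodal_auc = nodal_auc, taus = taus),
            class = "fc_curves")
}

#' Average nodal AUCs within each hemisphere-by-region group
#'
#' @param nodal_auc Tibble with columns `node`, `metric`, `auc` (see
#'   [metric_curves()]).
#' @param atlas An `fc_atlas` covering the nodes.
#' @return A tibble: `region` (e.g. `L_FPA`), `metric`, `value` (mean AUC
#'   over the region's channels).
#' @export
roi_average <- function(nodal_auc, atlas) {
  regions <- atlas_regions(atlas)
  missing_nodes <- setdiff(unique(nodal_auc$node), regions$channel)
  if (length(missing_nodes)) {
    abort(sprintf("atlas does not cover node(s): %s",
                  paste(missing_nodes, collapse = ", ")))
  }
  joined <- nodal_auc %>%
    left_join(regions[, c("channel", "region")],
              by = c(node = "channel"))
  empty <- setdiff(unique(regions$region), unique(joined$region))
  if (length(empty)) {
    abort(sprintf("region(s) without any node: %s",
                  paste(empty, collapse = ", ")))
  }
  joined %>%
    group_by(.data$region, .data$metric) %>%
    summarise(value = mean(.data$auc), .groups = "drop")
}
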