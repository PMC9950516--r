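#' Pearson correlation matrix across channels
#'
#' Full-series Pearson correlations between every pair of HbO channel
#' traces. Channels with zero variance get `NA` rows/columns and a warning;
#' the policy for carrying them further (zeroed, no edges) is applied by
#' [build_connectivity()].
#'
#' @param hbo Channels-by-samples numeric matrix, or an `fc_hemo` object
#'   (its HbO plane is used).
#' @return Symmetric correlation matrix with unit diagonal (dimension =
#'   number of channels).
#' @export
correlation_matrix <- function(hbo) {
  if (inherits(hbo, "fc_hemo")) hbo <- hbo_matrix(hbo)
  if (ncol(hbo) < 3) abort("need at least 3 samples for correlation")
  v <- apply(hbo, 1, var)
  bad <- which(v == 0 | !is.finite(v))
  r <- unname(suppressWarnings(cor(t(hbo))))
  if (length(bad)) {
    warn(sprintf("zero-variance channel(s): %s",
                 paste(bad, collapse = ", ")))
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
  }
  diag(r) <- 1
  attr(r, "zero_variance") <- bad
  r
}

#' Remove the midline channels from a channel-space matrix
#'
#' Drops the rows/columns of channels labelled `midline` in the atlas
#' (channels 25, 28 and 29 in the packaged atlas), preserving the order of
#' the remaining channels; a 53-channel matrix becomes the 50-node lateral
#' matrix used for network analysis.
#'
#' @param mat Square channel-space matrix (rows/cols in channel order).
#' @param atlas An `fc_atlas` table covering the matrix's channels.
#' @return The reduced matrix, with `nodes` attribute holding the retained
#'   channel indices.
#' @export
drop_midline <- function(mat, atlas) {
  if (nrow(mat) != ncol(mat)) abort("matrix must be square")
  if (nrow(mat) != nrow(atlas)) {
    abort(sprintf("matrix has %d channels but atlas covers %d",
                  nrow(mat), nrow(atlas)))
  }
  keep <- atlas$channel[atlas$hemisphere != "midline"]
  out <- mat[keep, keep, drop = FALSE]
  attr(out, "nodes") <- keep
  out
}

#' Fisher r-to-z transform with negative rectification
#'
#' `z = arctanh(r)` for positive correlations; zero and negative
#' correlations are set to 0 (network analysis is confined to positive
#' coupling, whose interpretation is unambiguous). Off-diagonal `r = 1`
#' (duplicate traces) is clamped to `arctanh(1 - 1e-7)` with a warning; the
#' diagonal is set to 0 (self-coupling is not an edge).
#'
#' @param r_matrix Symmetric correlation matrix (`|r| <= 1`).
#' @return The rectified z matrix (non-negative, zero diagonal).
#' @export
fisher_z_rectify <- function(r_matrix) {
  r <- r_matrix
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    abort("correlation entries must satisfy |r| <= 1")
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 0
  if (any(r >= 1 - 1e-12, na.rm = TRUE)) {
    warn("off-diagonal r = 1 clamped to arctanh(1 - 1e-7)")
    r[r > 1 - 1e-7] <- 1 - 1e-7
  }
  z <- ifelse(r > 0, atanh(r), 0)
  z[is.na(z)] <- 0
  z
}

#' Build a subject's 50-node connectivity matrix
#'
#' Composition of [correlation_matrix()], [drop_midline()] and
#' [fisher_z_rectify()]: Pearson r over the retained HbO series, midline
#' channels removed, Fisher z with negative rectification. Zero-variance
#' channels have their rows/columns zeroed (no edges) and are reported in
#' the `flagged_channels` field.
#'
#' @param hbo Channels-by-samples HbO matrix or `fc_hemo`.
#' @param atlas An `fc_atlas` covering the channels.
#' @return An object of class `fc_conn`: `nodes` (channel indices), `r`
#'   (with `NA` for flagged channels replaced by 0), `z`, and
#'   `flagged_channels`.
#' @export
build_connectivity <- function(hbo, atlas) {
  r_full <- correlation_matrix(hbo)
  bad <- attr(r_full, "zero_variance")
  r <- drop_midline(r_full, atlas)
  nodes <- attr(r, "nodes")
  flagged <- intersect(nodes, bad)
  z <- fisher_z_rectify(r)
  r[is.na(r)] <- 0
  diag(r) <- 1
  structure(
    list(nodes = nodes, r = r, z = z, flagged_channels = flagged),
    class = "fc_conn")
}

#' @export
print.fc_conn <- function(x, ...) {
  cat(sprintf("<fc_conn> %d nodes; mean off-diagonal r = %.3f\n",
              length(x$nodes),
              mean(x$r[upper.tri(x$r)])))
  invisible(x)
}

#' Threshold a connectivity matrix into a binary graph
#'
#' An undirected edge joins nodes whose connection strength is strictly
#' larger than the threshold. Thresholds are applied on the correlation (r)
#' scale by default; the Fisher-z matrix can be selected for toolbox
#' parity.
#'
#' @param conn An `fc_conn`, or a symmetric numeric matrix.
#' @param tau Threshold in `[0, 1)`.
#' @param scale `"r"` (default) or `"z"`: which matrix the threshold is
#'   applied to when `conn` is an `fc_conn`.
#' @return An `fc_graph`: binary symmetric `adjacency` with zero diagonal,
#'   plus `tau` and `nodes`.
#' @export
threshold_graph <- function(conn, tau, scale = c("r", "z")) {
  scale <- match.arg(scale)
  if (tau < 0 || tau >= 1) abort("tau must be in [0, 1)")
  if (inherits(conn, "fc_conn")) {
    mat <- if (scale == "r") conn$r else conn$z
    nodes <- conn$nodes
  } else {
    mat <- conn
    nodes <- attr(conn, "nodes") %||% seq_len(nrow(conn))
  }
  adj <- (mat > tau) * 1L
  diag(adj) <- 0L
  adj <- pmax(adj, t(adj))  # symmetry guard
  structure(list(adjacency = adj, tau = tau, nodes = nodes),
            class = "fc_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Edge counts across the threshold sweep
#'
#' Number of suprathreshold edges at each threshold (default 0.40 to 0.90
#' in steps of 0.05), plus their arithmetic mean, which serves as the
#' subject's total-edge summary.
#'
#' @param conn An `fc_conn` or symmetric matrix.
#' @param taus Ascending threshold vector.
#' @inheritParams threshold_graph
#' @return A tibble with columns `threshold` and `n_edges`; the mean count
#'   is attached as attribute `mean_edges`.
#' @export
edge_profile <- function(conn, taus = seq(0.40, 0.90, by = 0.05),
                         scale = c("r", "z")) {
  scale <- match.arg(scale)
  if (is.unsorted(taus, strictly = TRUE)) {
    abort("taus must be strictly ascending")
  }
  counts <- vapply(taus, function(tau) {
    g <- threshold_graph(conn, tau, scale)
    sum(g$adjacency[upper.tri(g$adjacency)])
  }, numeric(1))
  out <- tibble(threshold = taus, n_edges = counts)
  attr(out, "mean_edges") <- mean(counts)
  out
}

#' Element-wise mean of a group's Fisher-z matrices
#'
#' @param matrices List of `fc_conn` objects (or plain matrices) sharing a
#'   node set.
#' @return The mean z matrix (attribute `nodes` preserved).
#' @export
group_mean_matrix <- function(matrices) {
  if (!length(matrices)) abort("empty matrix list")
  get_z <- function(m) if (inherits(m, "fc_conn")) m$z else m
  get_nodes <- function(m) {
    if (inherits(m, "fc_conn")) m$nodes else seq_len(nrow(m))
  }
  nodes <- get_nodes(matrices[[1]])
  zs <- lapply(matrices, function(m) {
    if (!identical(get_nodes(m), nodes)) abort("node sets differ")
    get_z(m)
  })
  out <- Reduce(`+`, zs) / length(zs)
  attr(out, "nodes") <- nodes
  out
}

#' Long (tidy) edge table of a connectivity matrix
#'
#' @param x An `fc_conn`.
#' @param ... Unused.
#' @return A tibble with one row per unordered node pair: `node_i`,
#'   `node_j`, `r`, `z`.
#' @method tidy fc_conn
#' @export
tidy.fc_conn <- function(x, ...) {
  ut <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    node_i = x$nodes[ut[, 1]], node_j = x$nodes[ut[, 2]],
    r = x$r[ut], z = x$z[ut])
}
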