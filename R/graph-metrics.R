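#' Density thresholding, conventional graph attributes and rewiring nulls
#'
#' Functional networks are binarized by proportional density thresholding:
#' the strongest fraction `density` of positive connections become edges, so
#' graphs of equal size stay comparable across subjects. Five conventional
#' attributes are computed on the binary graph — two integration measures
#' (characteristic path length, inverted for reporting, and global
#' efficiency) and three segregation measures (modularity, clustering
#' coefficient, transitivity) — and each is normalized against a null
#' distribution from degree-preserving random rewiring.
#'
#' @name graph_metrics
NULL

#' Construct a binary graph
#'
#' @param adjacency symmetric 0/1 matrix with a zero diagonal.
#' @param node_labels optional node names.
#' @return a `binary_graph`: list with `adjacency`, `node_labels` and the
#'   achieved edge `density` 2|E| / (n (n - 1)).
#' @export
binary_graph <- function(adjacency, node_labels = NULL) {
  a <- as.matrix(adjacency)
  if (nrow(a) != ncol(a)) stop("adjacency must be square")
  if (!all(a %in% c(0, 1))) stop("adjacency must be 0/1")
  if (any(diag(a) != 0)) stop("adjacency must have a zero diagonal")
  if (!identical(a, t(a))) stop("adjacency must be symmetric")
  storage.mode(a) <- "integer"
  n <- nrow(a)
  if (is.null(node_labels)) {
    node_labels <- rownames(a)
    if (is.null(node_labels)) node_labels <- sprintf("R%03d", seq_len(n))
  }
  dimnames(a) <- list(node_labels, node_labels)
  structure(
    list(adjacency = a, node_labels = node_labels,
         density = sum(a) / (n * (n - 1))),
    class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges, density %.4f\n",
              length(x$node_labels), sum(x$adjacency) / 2L, x$density))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Proportional density threshold of a connectivity matrix
#'
#' Keeps the `floor(density * n(n-1)/2)` largest positive off-diagonal
#' weights as edges of an unweighted graph. Negative weights are never
#' candidates: edge-strength ordering across mixed signs is ill-defined.
#' Ties are broken by lexicographic (row, column) node-index order so the
#' edge set is a deterministic function of the input. If fewer positive
#' weights exist than requested, all positive edges are kept and a warning
#' records the shortfall.
#'
#' The edge set is monotone in `density`: a lower-density graph is always a
#' subgraph of a higher-density one for the same input.
#'
#' @param c an `fc_matrix` (either scale; atanh is monotone so the ranking
#'   is the same).
#' @param density target edge density in (0, 1].
#' @return a `binary_graph` with the achieved density recorded.
#' @export
threshold_by_density <- function(c, density) {
  stopifnot(is.numeric(density), length(density) == 1L,
            density > 0, density <= 1)
  m <- as.matrix(unclass(c))
  n <- nrow(m)
  ut <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[ut]
  pos <- w > 0
  ut <- ut[pos, , drop = FALSE]
  w <- w[pos]
  m_req <- floor(density * n * (n - 1) / 2)
  ord <- order(-w, ut[, 1L], ut[, 2L])
  n_keep <- min(m_req, length(w))
  if (length(w) < m_req)
    warning(sprintf(
      "only %d positive weights available for %d requested edges; keeping all",
      length(w), m_req))
  keep <- ut[ord[seq_len(n_keep)], , drop = FALSE]
  a <- matrix(0L, n, n)
  a[keep] <- 1L
  a <- a + t(a)
  dimnames(a) <- dimnames(m)
  binary_graph(a)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes that
#' are reachable from one another. Unreachable pairs are excluded from the
#' mean rather than failing the computation: proportionally thresholded
#' functional graphs at low density are routinely disconnected.
#'
#' @param g a `binary_graph` with at least one edge.
#' @return mean geodesic length (>= 1).
#' @export
characteristic_path_length <- function(g) {
  if (sum(g$adjacency) == 0L)
    stop("characteristic path length is undefined on an edgeless graph")
  d <- igraph::distances(as_igraph(g))
  diag(d) <- NA
  finite <- d[is.finite(d) & !is.na(d)]
  mean(finite)
}

#' Global efficiency
#'
#' Mean of 1/d(i, j) over all ordered pairs of distinct nodes, with
#' unreachable pairs contributing 0 — the integration measure that stays
#' defined on disconnected graphs.
#'
#' @param g a `binary_graph`.
#' @return efficiency in [0, 1].
#' @export
global_efficiency <- function(g) {
  n <- length(g$node_labels)
  if (n < 2L) stop("global efficiency needs at least 2 nodes")
  d <- igraph::distances(as_igraph(g))
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Mean clustering coefficient
#'
#' Average over nodes of C_i = 2 t_i / (k_i (k_i - 1)), where t_i counts
#' triangles through node i and k_i its degree; nodes with degree < 2 are
#' assigned C_i = 0.
#'
#' @param g a `binary_graph`.
#' @return mean local clustering in [0, 1].
#' @export
clustering_coefficient <- function(g) {
  a <- g$adjacency
  k <- rowSums(a)
  tri <- diag(a %*% a %*% a) / 2
  ci <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  mean(ci)
}

#' Transitivity (global clustering)
#'
#' 3 x (number of triangles) / (number of connected triples).
#'
#' @param g a `binary_graph` with at least one path of length two.
#' @return transitivity in [0, 1].
#' @export
transitivity_coefficient <- function(g) {
  a <- g$adjacency
  k <- rowSums(a)
  triples <- sum(k * (k - 1) / 2)
  if (triples == 0)
    stop("transitivity is undefined: the graph has no connected triple")
  tri_per_node <- diag(a %*% a %*% a) / 2
  sum(tri_per_node) / triples  # = 3 * n_triangles / n_triples
}

#' Louvain modularity with random restarts
#'
#' Greedy multi-level community detection, repeated `n_restarts` times with
#' a freshly randomized node order; the partition with the highest
#' Newman-Girvan Q (resolution 1) is returned. Restarting guards against
#' the algorithm's order dependence, which the single-run variant leaves
#' uncontrolled.
#'
#' @param g a `binary_graph` with at least one edge.
#' @param seed optional integer seed for the restart randomization.
#' @param n_restarts number of randomized runs (default 10).
#' @return a list of class `fc_partition`: `assignment` (named integer
#'   community ids) and `q_value`.
#' @export
modularity_louvain <- function(g, seed = NULL, n_restarts = 10L) {
  if (sum(g$adjacency) == 0L)
    stop("modularity is undefined on an edgeless graph")
  if (!is.null(seed)) set.seed(seed)
  ig <- as_igraph(g)
  n <- igraph::vcount(ig)
  best_q <- -Inf
  best_member <- NULL
  for (r in seq_len(n_restarts)) {
    perm <- sample.int(n)
    igp <- igraph::permute(ig, perm)
    cl <- igraph::cluster_louvain(igp)
    member <- igraph::membership(cl)[perm]  # back to original order
    q <- igraph::modularity(ig, member)
    if (q > best_q) {
      best_q <- q
      best_member <- member
    }
  }
  assignment <- as.integer(best_member)
  names(assignment) <- g$node_labels
  structure(list(assignment = assignment, q_value = best_q),
            class = "fc_partition")
}

#' Modularity Q of a given assignment
#'
#' Newman-Girvan modularity of an arbitrary node-to-community assignment,
#' for checking planted partitions against detected ones.
#'
#' @param g a `binary_graph`.
#' @param assignment integer/factor community ids, one per node.
#' @return Q value.
#' @export
modularity_q <- function(g, assignment) {
  igraph::modularity(as_igraph(g), as.integer(as.factor(assignment)))
}

#' Degree-preserving rewiring null ensemble
#'
#' Produces `n_iter` random graphs by double-edge swaps that exactly
#' preserve every node's degree while avoiding self-loops and multi-edges.
#' Graphs admitting no valid swap (a star, for instance) come back as
#' unchanged copies and the ensemble is flagged degenerate.
#'
#' @param g a `binary_graph` with at least 2 edges.
#' @param n_iter ensemble size (default 100).
#' @param swaps_per_edge attempted swaps per edge per null graph
#'   (default 10).
#' @param seed optional integer seed.
#' @return list of `binary_graph` nulls; attribute `degenerate` is TRUE
#'   when no null differs from the input.
#' @export
rewire_null <- function(g, n_iter = 100L, swaps_per_edge = 10L, seed = NULL) {
  m <- sum(g$adjacency) / 2L
  if (m < 2L) stop("rewiring needs at least 2 edges")
  if (!is.null(seed)) set.seed(seed)
  ig <- as_igraph(g)
  niter <- as.integer(swaps_per_edge * m)
  nulls <- vector("list", n_iter)
  changed <- FALSE
  for (i in seq_len(n_iter)) {
    rg <- igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                                    niter = niter))
    a <- as.matrix(igraph::as_adjacency_matrix(rg, sparse = FALSE))
    dimnames(a) <- dimnames(g$adjacency)
    if (!changed && !identical(a, matrix(as.numeric(g$adjacency),
                                         nrow(a), ncol(a),
                                         dimnames = dimnames(a))))
      changed <- TRUE
    nulls[[i]] <- binary_graph(a)
  }
  if (!changed)
    message("rewiring null is degenerate: no valid degree-preserving swap")
  attr(nulls, "degenerate") <- !changed
  nulls
}

raw_attributes <- function(g, seed = NULL, n_restarts = 10L) {
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  cpl <- safe(characteristic_path_length(g))
  c(char_path_length = cpl,
    inv_char_path_length = if (is.na(cpl)) NA_real_ else 1 / cpl,
    global_efficiency = safe(global_efficiency(g)),
    modularity = safe(modularity_louvain(g, seed = seed,
                                         n_restarts = n_restarts)$q_value),
    clustering_coefficient = safe(clustering_coefficient(g)),
    transitivity = safe(transitivity_coefficient(g)))
}

#' Null-normalized attribute profile across density thresholds
#'
#' For each requested density the connectivity matrix is thresholded, the
#' five attributes are computed on the binary graph, and each is normalized
#' against the mean of its null distribution over `n_null` rewired graphs:
#' `normalized = raw / null_mean`, except for the characteristic path
#' length, which is inverted so that lower values represent worse function
#' — its normalized value is `mean(null CPL) / raw CPL`, making all five
#' normalized attributes concordant (larger = more favourable topology).
#' Attributes undefined on a given graph (an edgeless graph's path length,
#' say) are recorded as `NA`, never silently zeroed.
#'
#' @param c an `fc_matrix`.
#' @param densities density thresholds, each in (0, 1].
#' @param n_null null-ensemble size per density (default 100).
#' @param seed optional integer seed governing rewiring and Louvain
#'   restarts.
#' @param swaps_per_edge rewiring intensity, see [rewire_null()].
#' @param n_restarts Louvain restarts, see [modularity_louvain()].
#' @return an `attribute_profile`: data frame with columns `density`,
#'   `attribute`, `raw`, `null_mean`, `null_sd`, `normalized`; attributes
#'   `densities` and `n_null`.
#' @export
attribute_profile <- function(c, densities = c(0.05, 0.10, 0.15, 0.20),
                              n_null = 100L, seed = NULL,
                              swaps_per_edge = 10L, n_restarts = 10L) {
  stopifnot(length(densities) >= 1L, all(densities > 0), all(densities <= 1))
  if (!is.null(seed)) set.seed(seed)
  attrs <- c("inv_char_path_length", "global_efficiency", "modularity",
             "clustering_coefficient", "transitivity")
  rows <- list()
  for (d in densities) {
    g <- threshold_by_density(c, d)
    raw <- raw_attributes(g, n_restarts = n_restarts)
    nulls <- rewire_null(g, n_iter = n_null, swaps_per_edge = swaps_per_edge)
    null_vals <- vapply(nulls, raw_attributes, raw,
                        n_restarts = n_restarts)
    null_mean <- rowMeans(null_vals, na.rm = TRUE)
    null_sd <- apply(null_vals, 1L, stats::sd, na.rm = TRUE)
    normalized <- raw[attrs] / null_mean[attrs]
    # inverted path length: normalized = null-mean CPL / raw CPL
    normalized["inv_char_path_length"] <-
      null_mean["char_path_length"] / raw["char_path_length"]
    rows[[length(rows) + 1L]] <- data.frame(
      density = d, attribute = attrs, raw = unname(raw[attrs]),
      null_mean = unname(null_mean[attrs]),
      null_sd = unname(null_sd[attrs]),
      normalized = unname(normalized[attrs]),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "densities") <- densities
  attr(out, "n_null") <- as.integer(n_null)
  class(out) <- c("attribute_profile", class(out))
  out
}

#' Write an attribute profile as JSON
#'
#' @param profile an `attribute_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  jsonlite::write_json(
    list(densities = attr(profile, "densities"),
         n_null = attr(profile, "n_null"),
         values = as.data.frame(unclass(profile))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
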