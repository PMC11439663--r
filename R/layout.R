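#' Spring-embedded (force-directed) network layout
#'
#' Fruchterman-Reingold-style embedding for qualitative inspection of
#' network composition: attractive forces act along edges, repulsive forces
#' between all node pairs, and nodes move until the displacement becomes
#' negligible under a linear cooling schedule. Isolated nodes receive
#' coordinates like any other node and render as dots without lines.
#'
#' @name graph_layout
NULL

#' Compute a spring-embedded layout
#'
#' Starts from a seeded uniform random placement on the unit square and
#' iterates: repulsion k^2/d between every pair, attraction d^2/k along
#' every edge, per-step displacement capped by a temperature that cools
#' linearly from 0.1 to 0. Stops early once the largest displacement falls
#' below `tol` (in layout-scale units). The optimal-distance constant is
#' k = 1/sqrt(n).
#'
#' @param g a `binary_graph`.
#' @param seed optional integer seed for the initial placement.
#' @param iterations iteration budget (default 500).
#' @param tol early-stop displacement threshold (default 1e-4).
#' @return a `layout_coordinates` list: `positions` (n x 2 matrix, node
#'   labels as rownames), `iterations_run`, `seed`, and `energy_trace` (one
#'   potential value per iteration, for convergence diagnostics).
#' @export
spring_layout <- function(g, seed = NULL, iterations = 500L, tol = 1e-4) {
  n <- length(g$node_labels)
  stopifnot(n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  pos <- matrix(stats::runif(2L * n), n, 2L,
                dimnames = list(g$node_labels, c("x", "y")))
  if (n == 1L)
    return(structure(list(positions = pos, iterations_run = 0L,
                          seed = seed, energy_trace = numeric(0)),
                     class = "layout_coordinates"))
  a <- g$adjacency
  k <- 1 / sqrt(n)
  t0 <- 0.1
  eps <- 1e-9
  energy <- numeric(iterations)
  it_run <- 0L
  for (it in seq_len(iterations)) {
    dx <- outer(pos[, 1L], pos[, 1L], "-")
    dy <- outer(pos[, 2L], pos[, 2L], "-")
    d <- sqrt(dx^2 + dy^2)
    d[d < eps] <- eps
    # repulsion from every other node, attraction along edges
    rep_f <- k^2 / d^2          # force magnitude / distance
    att_f <- a * d / k          # d^2/k along unit vector -> a * d / k
    diag(rep_f) <- 0
    diag(att_f) <- 0
    fx <- rowSums(dx * (rep_f - att_f))
    fy <- rowSums(dy * (rep_f - att_f))
    disp <- sqrt(fx^2 + fy^2)
    temp <- t0 * (1 - (it - 1) / iterations)
    scale <- pmin(disp, temp) / pmax(disp, eps)
    pos[, 1L] <- pos[, 1L] + fx * scale
    pos[, 2L] <- pos[, 2L] + fy * scale
    # potential: attractive d^3/(3k) on edges minus k^2 log d repulsion
    dxn <- outer(pos[, 1L], pos[, 1L], "-")
    dyn <- outer(pos[, 2L], pos[, 2L], "-")
    dn <- sqrt(dxn^2 + dyn^2)
    dn[dn < eps] <- eps
    ut <- upper.tri(dn)
    energy[it] <- sum((a * dn^3 / (3 * k))[ut]) - sum(k^2 * log(dn[ut]))
    it_run <- it
    if (max(pmin(disp, temp)) < tol) break
  }
  structure(list(positions = pos, iterations_run = it_run, seed = seed,
                 energy_trace = energy[seq_len(it_run)]),
            class = "layout_coordinates")
}

network_palette <- function(labels) {
  base <- c(VN = "#781286", SMN = "#4682B4", DAN = "#00760E",
            VAN = "#C43AFA", LN = "#DCF8A4", FPN = "#E69422",
            DMN = "#CD3E4E", subcortical = "#7F7F7F",
            cerebellum = "#66401f", brainstem = "#000000")
  extra <- setdiff(labels, names(base))
  if (length(extra)) {
    more <- grDevices::hcl.colors(max(3L, length(extra)), "Dark 3")
    base <- c(base, stats::setNames(more[seq_along(extra)], extra))
  }
  base[labels]
}

#' Render a spring-embedded network figure
#'
#' Draws edges as line segments and nodes as dots coloured by canonical
#' network, with a legend of the labels present and a caption line stating
#' the density at which the graph was thresholded. SVG and PDF output are
#' selected by file extension; SVG output is byte-stable for fixed inputs.
#'
#' @param g a `binary_graph`.
#' @param layout a `layout_coordinates` covering g's nodes.
#' @param partition a `canonical_partition` labelling g's nodes.
#' @param file output path ending in `.svg` or `.pdf`.
#' @param density_note density to report in the caption (defaults to the
#'   achieved density of `g`).
#' @return the file path, invisibly.
#' @export
render_network_plot <- function(g, layout, partition, file,
                                density_note = g$density) {
  pos <- layout$positions
  if (!all(g$node_labels %in% rownames(pos)))
    stop("layout does not cover all graph nodes")
  pos <- pos[g$node_labels, , drop = FALSE]
  nets <- partition$network[match(g$node_labels, partition$node)]
  if (anyNA(nets))
    stop("nodes missing a network label: ",
         paste(g$node_labels[is.na(nets)][1:5], collapse = ", "))
  unknown <- setdiff(unique(nets), CANONICAL_NETWORKS)
  if (length(unknown))
    stop("unknown network label(s): ", paste(unknown, collapse = ", "),
         " for nodes ",
         paste(g$node_labels[nets %in% unknown][1:5], collapse = ", "))
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         svg = grDevices::svg(file, width = 7, height = 7),
         pdf = grDevices::pdf(file, width = 7, height = 7),
         stop("unsupported figure format: .", ext))
  on.exit(grDevices::dev.off())
  present <- intersect(CANONICAL_NETWORKS, unique(nets))
  cols <- network_palette(present)
  graphics::par(mar = c(3, 1, 1, 1))
  graphics::plot(pos, type = "n", axes = FALSE, xlab = "", ylab = "",
                 asp = 1)
  ed <- which(upper.tri(g$adjacency) & g$adjacency == 1L, arr.ind = TRUE)
  if (nrow(ed))
    graphics::segments(pos[ed[, 1L], 1L], pos[ed[, 1L], 2L],
                       pos[ed[, 2L], 1L], pos[ed[, 2L], 2L],
                       col = "grey70", lwd = 0.5)
  graphics::points(pos, pch = 21, bg = cols[nets], col = "grey20",
                   cex = 1.1)
  graphics::legend("topleft", legend = present, pt.bg = cols,
                   pch = 21, bty = "n", cex = 0.8)
  graphics::mtext(sprintf("network density = %.3f", density_note),
                  side = 1, line = 1, cex = 0.8)
  invisible(file)
}

#' Export layout coordinates as CSV
#'
#' @param layout a `layout_coordinates`.
#' @param path output path.
#' @export
write_layout <- function(layout, path) {
  df <- data.frame(node = rownames(layout$positions),
                   x = layout$positions[, 1L],
                   y = layout$positions[, 2L], row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
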