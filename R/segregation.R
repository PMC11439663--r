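#' System segregation of canonical resting-state networks
#'
#' System segregation quantifies a network module's functional isolation:
#'
#'   SysSeg = (Zw - Zb) / Zw
#'
#' where Zw is the mean Fisher z-transformed connectivity over node pairs
#' within the same module and Zb the mean over pairs linking that module to
#' the other modules under analysis. It is computed on the full z matrix
#' (no thresholding) per canonical network and pooled across all of them.
#'
#' @name system_segregation_module
NULL

#' Canonical network labels
#'
#' The seven cortical resting-state systems plus the three non-cortical
#' pools carried through the parcellation.
#' @export
CANONICAL_NETWORKS <- c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN",
                        "subcortical", "cerebellum", "brainstem")

#' Seven cortical analysis networks
#' @export
CORTICAL_NETWORKS <- c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN")

#' Construct a canonical node-to-network partition
#'
#' @param node character vector of node labels.
#' @param network network label per node, from [CANONICAL_NETWORKS] (other
#'   labels are allowed but flagged when plotting).
#' @param analysis_set networks entering the segregation analysis; defaults
#'   to the seven cortical systems.
#' @return a data frame of class `canonical_partition` with columns `node`
#'   and `network` and attribute `analysis_set`.
#' @export
canonical_partition <- function(node, network,
                                analysis_set = CORTICAL_NETWORKS) {
  stopifnot(length(node) == length(network), !anyDuplicated(node))
  network <- as.character(network)
  analysis_set <- intersect(analysis_set, unique(network))
  if (length(analysis_set) == 0L)
    stop("analysis_set contains no network present in the partition")
  sizes <- table(network)[analysis_set]
  if (any(sizes < 2L))
    stop("every analysis network needs at least 2 nodes; too small: ",
         paste(analysis_set[sizes < 2L], collapse = ", "))
  structure(data.frame(node = as.character(node), network = network,
                       stringsAsFactors = FALSE),
            analysis_set = analysis_set,
            class = c("canonical_partition", "data.frame"))
}

#' Read a canonical partition from a two-column table
#'
#' @param path path to a delimited file with columns node, network (header
#'   optional, detected from the first line).
#' @param analysis_set see [canonical_partition()].
#' @param sep field separator.
#' @return a `canonical_partition`.
#' @export
read_partition <- function(path, analysis_set = CORTICAL_NETWORKS,
                           sep = "\t") {
  first <- strsplit(readLines(path, n = 1L), sep)[[1L]]
  header <- identical(tolower(first[1L]), "node")
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE)
  canonical_partition(df[[1L]], df[[2L]], analysis_set = analysis_set)
}

#' Write a canonical partition
#' @param p a `canonical_partition`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_partition <- function(p, path, sep = "\t") {
  utils::write.table(as.data.frame(unclass(p))[, c("node", "network")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

seg_summary <- function(zw_vals, zb_vals) {
  zw <- if (length(zw_vals)) mean(zw_vals) else NA_real_
  zb <- if (length(zb_vals)) mean(zb_vals) else NA_real_
  sysseg <- if (!is.na(zw) && !is.na(zb) && zw > 0) (zw - zb) / zw
            else NA_real_
  list(sysseg = sysseg, z_within_mean = zw, z_between_mean = zb,
       n_within_pairs = length(zw_vals), n_between_pairs = length(zb_vals))
}

#' System segregation per canonical network and overall
#'
#' For each network in the analysis set, `z_within_mean` averages the
#' retained z values over unordered within-network pairs and
#' `z_between_mean` over pairs linking that network to the other analysis
#' networks; `sysseg = (Zw - Zb) / Zw`. Negative z values are excluded from
#' both means by default, following the segregation literature in which
#' anticorrelations carry no within/between meaning; set
#' `exclude_negative = FALSE` to keep them. The overall value pools pairs
#' across the analysis set (every cross-network pair counted once) rather
#' than averaging the per-network ratios; `overall_method = "mean_networks"`
#' selects the alternative.
#'
#' A network whose within-mean is non-positive, or whose inclusion set is
#' empty, gets `NA` with the reason recorded — never a spurious ratio.
#'
#' @param c an `fc_matrix` on the `fisher_z` scale.
#' @param p a `canonical_partition` covering the matrix nodes.
#' @param exclude_negative drop pairs with z < 0 from both means
#'   (default TRUE).
#' @param between_includes_nonanalysis if TRUE, between-network pairs also
#'   reach into non-analysis pools (subcortical/cerebellum/brainstem);
#'   default FALSE.
#' @param overall_method `"pooled"` (default) or `"mean_networks"`.
#' @return a `segregation_result`: list with `per_network` (data frame) and
#'   `overall` (one-row data frame).
#' @export
system_segregation <- function(c, p, exclude_negative = TRUE,
                               between_includes_nonanalysis = FALSE,
                               overall_method = c("pooled",
                                                  "mean_networks")) {
  overall_method <- match.arg(overall_method)
  if (fc_scale(c) != "fisher_z")
    stop("system segregation requires a Fisher z-scale matrix; ",
         "apply fisher_z() first")
  z <- as.matrix(unclass(c))
  labels <- rownames(z)
  idx <- match(p$node, labels)
  if (anyNA(idx))
    stop("partition nodes missing from the matrix: ",
         paste(p$node[is.na(idx)][1:5], collapse = ", "))
  member <- character(nrow(z))
  member[idx] <- p$network
  if (any(member == "")) stop("matrix nodes missing from the partition")
  analysis_set <- attr(p, "analysis_set")

  include <- function(vals) if (exclude_negative) vals[vals >= 0] else vals
  pick_within <- function(m) {
    i <- which(member == m)
    z[i, i][upper.tri(z[i, i])]
  }
  pick_between <- function(m) {
    i <- which(member == m)
    others <- if (between_includes_nonanalysis) {
      which(member != m)
    } else {
      which(member %in% setdiff(analysis_set, m))
    }
    as.vector(z[i, others, drop = FALSE])
  }

  per <- lapply(analysis_set, function(m) {
    s <- seg_summary(include(pick_within(m)), include(pick_between(m)))
    cbind(data.frame(network = m, stringsAsFactors = FALSE),
          as.data.frame(s))
  })
  per <- do.call(rbind, per)

  if (overall_method == "pooled") {
    all_within <- unlist(lapply(analysis_set, pick_within))
    ai <- which(member %in% analysis_set)
    zb_pairs <- z[ai, ai]
    diff_net <- outer(member[ai], member[ai], "!=")
    all_between <- zb_pairs[upper.tri(zb_pairs) & diff_net]
    if (between_includes_nonanalysis) {
      out_idx <- which(!(member %in% analysis_set))
      if (length(out_idx))
        all_between <- c(all_between,
                         as.vector(z[ai, out_idx, drop = FALSE]))
    }
    overall <- as.data.frame(seg_summary(include(all_within),
                                         include(all_between)))
  } else {
    overall <- data.frame(sysseg = mean(per$sysseg, na.rm = TRUE),
                          z_within_mean = NA_real_,
                          z_between_mean = NA_real_,
                          n_within_pairs = sum(per$n_within_pairs),
                          n_between_pairs = sum(per$n_between_pairs))
  }
  overall <- cbind(data.frame(network = "overall",
                              stringsAsFactors = FALSE), overall)
  structure(list(per_network = per, overall = overall),
            exclude_negative = exclude_negative,
            overall_method = overall_method,
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat("<segregation_result>\n")
  print(rbind(x$per_network, x$overall), row.names = FALSE)
  invisible(x)
}

#' Tidy table of segregation results across subjects
#'
#' @param results named list of `segregation_result` objects (names =
#'   subject ids).
#' @return data frame with columns `subject`, `network`, `sysseg`.
#' @export
segregation_table <- function(results) {
  stopifnot(length(results) >= 1L)
  out <- lapply(names(results), function(id) {
    r <- results[[id]]
    tab <- rbind(r$per_network, r$overall)
    data.frame(subject = id, network = tab$network, sysseg = tab$sysseg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
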