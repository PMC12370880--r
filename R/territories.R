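#' Assign tissue territories
#'
#' Territories are large-scale, spatially contiguous tissue domains. Labels
#' can come from an upstream territory-detection pipeline via the cell table
#' (\code{source = "provided"}, the preferred route), or from a built-in
#' fallback: k-means on the expression embedding followed by a spatial split,
#' so that one expression cluster spanning disconnected regions is divided
#' into one territory per connected component of the Delaunay graph.
#'
#' @param d a \code{spatial_dataset}.
#' @param source \code{"provided"} (use \code{d$territory_labels}) or
#'   \code{"fallback"}.
#' @param embedding cell-level \code{signal_matrix} (required for fallback).
#' @param k number of expression clusters for the fallback (default 5).
#' @param seed RNG seed for the fallback k-means.
#' @param prune_quantile Delaunay edge pruning quantile for the spatial split.
#' @return \code{d} with \code{territory_labels} set.
#' @export
assign_territories <- function(d, source = c("provided", "fallback"),
                               embedding = NULL, k = 5, seed = 42,
                               prune_quantile = 0.99) {
  source <- match.arg(source)
  if (source == "provided") {
    if (is.null(d$territory_labels)) {
      stop("no territory labels present; use source = 'fallback' or supply them")
    }
    return(d)
  }
  if (is.null(embedding) || !inherits(embedding, "signal_matrix")) {
    stop("fallback territory detection requires an embedding signal_matrix")
  }
  km <- withr::with_seed(seed,
    kmeans(t(embedding$values), centers = k, nstart = 10, iter.max = 50))
  clusters <- km$cluster
  xy <- as.matrix(d$coords[, c("x", "y")])
  adj <- delaunay_adjacency(xy, prune_quantile)
  labels <- character(length(clusters))
  for (cl in sort(unique(clusters))) {
    idx <- which(clusters == cl)
    sub <- igraph::graph_from_data_frame(
      d = subgraph_edges(adj, idx),
      directed = FALSE,
      vertices = data.frame(name = as.character(idx))
    )
    comp <- igraph::components(sub)$membership
    comp <- comp[as.character(idx)]
    if (max(comp) == 1L) {
      labels[idx] <- as.character(cl)
    } else {
      labels[idx] <- paste(cl, comp, sep = ".")
    }
  }
  d$territory_labels <- labels
  d
}

# Edge data frame of the induced subgraph on `idx` (vertex names are the
# original indices as strings).
subgraph_edges <- function(adj, idx) {
  keep <- logical(length(adj))
  keep[idx] <- TRUE
  from <- integer(0)
  to <- integer(0)
  for (i in idx) {
    nb <- adj[[i]]
    nb <- nb[keep[nb] & nb > i]
    from <- c(from, rep.int(i, length(nb)))
    to <- c(to, nb)
  }
  data.frame(from = as.character(from), to = as.character(to))
}

#' Territory-level expression signal
#'
#' Column \code{c} of the result is the mean of the base signal over every
#' cell sharing \code{c}'s territory, so the signal is block-constant within
#' territories.
#'
#' @param d a \code{spatial_dataset} with \code{territory_labels}.
#' @param base a cell-level \code{signal_matrix} over the same cells.
#' @return A territory-level \code{signal_matrix}.
#' @export
territory_signal <- function(d, base) {
  if (is.null(d$territory_labels)) stop("territory labels are required")
  if (anyNA(d$territory_labels)) {
    stop("missing territory label for cells: ",
         paste(head(d$barcodes[is.na(d$territory_labels)], 5), collapse = ", "))
  }
  if (!inherits(base, "signal_matrix") || base$level != "cell") {
    stop("base must be a cell-level signal_matrix")
  }
  f <- factor(d$territory_labels)
  # group means, then broadcast back to cells
  group_means <- sapply(levels(f), function(l) {
    rowMeans(base$values[, f == l, drop = FALSE])
  })
  if (is.null(dim(group_means))) {
    group_means <- matrix(group_means, ncol = length(levels(f)),
                          dimnames = list(rownames(base$values), levels(f)))
  }
  vals <- group_means[, as.character(f), drop = FALSE]
  colnames(vals) <- colnames(base$values)
  signal_matrix(vals, level = "territory")
}
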