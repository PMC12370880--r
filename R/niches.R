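#' Extract spatial niches
#'
#' A niche is the set of spatial neighbors of a cell, defined by one of three
#' methods: \code{knn} (the k nearest neighbors), \code{graph} (all cells
#' within a given graph depth on the Delaunay triangulation, the dual of the
#' Voronoi tessellation), or \code{radius} (all cells within a distance of the
#' center). Neighbor sets are stored excluding the center cell; whether the
#' center participates in the niche mean is controlled by
#' \code{include_center} (default \code{TRUE}).
#'
#' Delaunay adjacency is pruned of unusually long boundary edges (longer than
#' the \code{prune_quantile} of all edge lengths) to avoid spurious
#' long-range adjacency at the convex hull.
#'
#' @param d a \code{spatial_dataset}.
#' @param method \code{"knn"}, \code{"graph"} or \code{"radius"}.
#' @param k neighbor count for \code{knn} (default 6).
#' @param depth graph depth for \code{graph} (default 1).
#' @param radius search radius, in coordinate units, for \code{radius}.
#' @param include_center include the center cell in its own niche mean.
#' @param prune_quantile Delaunay edge-length pruning quantile (default 0.99).
#' @return A \code{niche_assignment}: per-cell integer neighbor index lists.
#' @export
extract_niches <- function(d, method = c("knn", "graph", "radius"),
                           k = 6, depth = 1, radius = NULL,
                           include_center = TRUE, prune_quantile = 0.99) {
  method <- match.arg(method)
  xy <- as.matrix(d$coords[, c("x", "y")])
  n <- nrow(xy)
  if (method == "knn") {
    idx <- knn_indices(xy, k)
    neighbors <- lapply(seq_len(n), function(i) idx[i, ])
    parameter <- c(k = k)
  } else if (method == "graph") {
    if (depth < 1) stop("depth must be a positive integer")
    adj <- delaunay_adjacency(xy, prune_quantile)
    neighbors <- lapply(seq_len(n), function(i) graph_ball(adj, i, depth))
    parameter <- c(depth = depth)
  } else {
    if (is.null(radius) || radius <= 0) stop("radius must be positive")
    nn <- RANN::nn2(xy, searchtype = "radius", radius = radius, k = n)
    neighbors <- lapply(seq_len(n), function(i) {
      row <- nn$nn.idx[i, ]
      row[row != 0L & row != i]
    })
    parameter <- c(radius = radius)
  }
  structure(list(method = method, parameter = parameter,
                 neighbors = neighbors, include_center = include_center,
                 barcodes = d$barcodes),
            class = "niche_assignment")
}

#' @export
print.niche_assignment <- function(x, ...) {
  cat("niche_assignment (", x$method, ", ",
      paste(names(x$parameter), x$parameter, sep = "=", collapse = ", "),
      "): ", length(x$neighbors), " cells, mean niche size ",
      round(mean(lengths(x$neighbors)), 2), "\n", sep = "")
  invisible(x)
}

# Delaunay adjacency list from deldir, with long-edge pruning.
delaunay_adjacency <- function(xy, prune_quantile = 0.99) {
  dd <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
  seg <- dd$delsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  keep <- len <= quantile(len, prune_quantile)
  seg <- seg[keep, , drop = FALSE]
  adj <- vector("list", nrow(xy))
  for (i in seq_len(nrow(seg))) {
    a <- seg$ind1[i]; b <- seg$ind2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  lapply(adj, unique)
}

# All vertices within `depth` hops of `start` on an adjacency list,
# excluding the start vertex itself.
graph_ball <- function(adj, start, depth) {
  visited <- start
  frontier <- start
  for (step in seq_len(depth)) {
    frontier <- setdiff(unique(unlist(adj[frontier])), visited)
    if (length(frontier) == 0L) break
    visited <- c(visited, frontier)
  }
  setdiff(visited, start)
}

#' Niche-level expression signal
#'
#' Replaces each cell's signal with the mean signal over its niche: column
#' \code{c} of the result is the mean of the base columns over the neighbors
#' of \code{c} (plus the center itself when the niche assignment was built
#' with \code{include_center = TRUE}).
#'
#' @param niches a \code{niche_assignment}.
#' @param base a cell-level \code{signal_matrix} over the same cells.
#' @param fallback_to_cell if a niche is empty and the center is excluded,
#'   use the cell's own signal instead of erroring.
#' @return A niche-level \code{signal_matrix}.
#' @export
niche_signal <- function(niches, base, fallback_to_cell = FALSE) {
  if (!inherits(base, "signal_matrix") || base$level != "cell") {
    stop("base must be a cell-level signal_matrix")
  }
  n <- ncol(base$values)
  if (length(niches$neighbors) != n) {
    stop("niche assignment and signal cover different cell sets")
  }
  members <- lapply(seq_len(n), function(i) {
    mem <- niches$neighbors[[i]]
    if (niches$include_center) mem <- c(i, mem)
    mem
  })
  empty <- lengths(members) == 0L
  if (any(empty)) {
    if (!fallback_to_cell) {
      stop("empty niche for cells: ",
           paste(head(niches$barcodes[empty], 5), collapse = ", "),
           " (set fallback_to_cell = TRUE to use the cell's own signal)")
    }
    members[empty] <- as.list(which(empty))
  }
  # sparse averaging operator: A[c', c] = 1/|N(c)| for c' in N(c)
  sizes <- lengths(members)
  A <- Matrix::sparseMatrix(
    i = unlist(members),
    j = rep.int(seq_len(n), sizes),
    x = rep.int(1 / sizes, sizes),
    dims = c(n, n)
  )
  vals <- as.matrix(base$values %*% A)
  dimnames(vals) <- dimnames(base$values)
  signal_matrix(vals, level = "niche")
}

#' Per-cell niche label multisets
#'
#' The cell-type labels found in each cell's niche (center included when the
#' assignment says so), used for composition scoring and evaluation.
#'
#' @param d a \code{spatial_dataset} with \code{cell_labels}.
#' @param niches a \code{niche_assignment} over the same cells.
#' @return A list of character vectors, one multiset per cell.
#' @export
niche_label_sets <- function(d, niches) {
  if (is.null(d$cell_labels)) stop("cell_labels are required")
  lapply(seq_along(niches$neighbors), function(i) {
    mem <- niches$neighbors[[i]]
    if (niches$include_center) mem <- c(i, mem)
    d$cell_labels[mem]
  })
}
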