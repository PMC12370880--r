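#' Construct a signal matrix
#'
#' A \code{signal_matrix} holds a features x cells real matrix carrying the
#' expression signal used for similarity scoring, at one of three spatial
#' scales: the cell itself, its niche (neighborhood mean), or its territory
#' (domain mean).
#'
#' @param values features x cells numeric matrix with feature rownames and
#'   barcode colnames.
#' @param level one of \code{"cell"}, \code{"niche"}, \code{"territory"}.
#' @return A \code{signal_matrix}.
#' @export
signal_matrix <- function(values, level = c("cell", "niche", "territory")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("signal values must carry feature rownames and barcode colnames")
  }
  if (!all(is.finite(values))) stop("signal values must be finite")
  structure(list(level = level, values = values,
                 feature_ids = rownames(values)),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix (", x$level, "): ", nrow(x$values), " features x ",
      ncol(x$values), " cells\n", sep = "")
  invisible(x)
}

#' Normalize counts
#'
#' \code{lognorm} scales each cell's counts to the median library size of the
#' sample and applies \code{log1p}. \code{tfidf} computes term-frequency
#' (counts over library size) weighted by inverse document frequency
#' \code{log(1 + n_cells / (1 + n_cells_expressing))}, the usual choice for
#' sparse accessibility-like data.
#'
#' @param d a \code{spatial_dataset}.
#' @param method \code{"lognorm"} (default) or \code{"tfidf"}.
#' @return \code{d} with the \code{normalized} layer set.
#' @export
normalize_counts <- function(d, method = c("lognorm", "tfidf")) {
  method <- match.arg(method)
  counts <- as.matrix(d$counts)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("all-zero cells cannot be normalized: ",
         paste(head(colnames(counts)[lib == 0], 5), collapse = ", "))
  }
  if (method == "lognorm") {
    target <- stats::median(lib)
    norm <- log1p(sweep(counts, 2, lib / target, "/"))
  } else {
    tf <- sweep(counts, 2, lib, "/")
    idf <- log(1 + ncol(counts) / (1 + rowSums(counts > 0)))
    norm <- tf * idf
  }
  d$normalized <- norm
  d
}

#' Select highly variable features
#'
#' Genes are ranked by a dispersion statistic (variance over mean) computed on
#' the normalized layer; the top \code{n} gene identifiers are returned. Ties
#' are broken by gene identifier so the selection is deterministic.
#'
#' @param d a \code{spatial_dataset} with a normalized layer.
#' @param n number of genes to keep (default 2000).
#' @return Character vector of \code{n} gene identifiers.
#' @export
select_variable_features <- function(d, n = 2000) {
  if (is.null(d$normalized)) stop("run normalize_counts() first")
  if (n > nrow(d$normalized)) {
    stop("n (", n, ") exceeds the number of genes (", nrow(d$normalized), ")")
  }
  m <- rowMeans(d$normalized)
  v <- apply(d$normalized, 1, var)
  disp <- ifelse(m > 0, v / m, 0)
  ord <- order(-disp, rownames(d$normalized))
  rownames(d$normalized)[ord][seq_len(n)]
}

#' Cell-level expression signal
#'
#' Extracts the per-cell expression signal (normalized values over a feature
#' set) as a \code{signal_matrix} at cell level.
#'
#' @param d a \code{spatial_dataset} with a normalized layer.
#' @param features gene identifiers to use; default all genes.
#' @return A cell-level \code{signal_matrix}.
#' @export
cell_signal <- function(d, features = NULL) {
  if (is.null(d$normalized)) stop("run normalize_counts() first")
  features <- features %||% rownames(d$normalized)
  missing <- setdiff(features, rownames(d$normalized))
  if (length(missing)) {
    stop("features not present: ", paste(head(missing, 5), collapse = ", "))
  }
  signal_matrix(d$normalized[features, , drop = FALSE], level = "cell")
}

#' Principal-component embedding of the expression signal
#'
#' Centers the selected features across cells and computes principal-component
#' scores, returned as a dims x cells cell-level signal. Embedding dimensions
#' are named \code{PC1..PCdims}.
#'
#' @param d a \code{spatial_dataset} with a normalized layer.
#' @param dims number of components (default 30).
#' @param features feature subset (default all genes).
#' @return A cell-level \code{signal_matrix} of PC scores.
#' @export
compute_embedding <- function(d, dims = 30, features = NULL) {
  sig <- cell_signal(d, features)
  nf <- nrow(sig$values)
  nc <- ncol(sig$values)
  if (dims > min(nf, nc)) {
    stop("dims (", dims, ") exceeds min(features, cells) = ", min(nf, nc))
  }
  pc <- prcomp(t(sig$values), center = TRUE, scale. = FALSE, rank. = dims)
  scores <- t(pc$x)
  if (nrow(scores) < dims) {  # rank-deficient input: pad with zero scores
    pad <- matrix(0, dims - nrow(scores), ncol(scores))
    scores <- rbind(scores, pad)
  }
  rownames(scores) <- paste0("PC", seq_len(dims))
  colnames(scores) <- colnames(sig$values)
  signal_matrix(scores, level = "cell")
}
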