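#' Similarity matrices and the cost stack
#'
#' The mapping cost between a query cell i and a reference cell j is the
#' unweighted sum of reciprocals of similarity scores,
#' \code{C_ij = sum_k (1 - S_ij^(k))}, over any combination of named
#' similarity matrices. Correlation-based metrics (feature, niche, territory)
#' keep their natural [-1, 1] range, so a single correlation metric can
#' contribute up to 2 to the cost; composition lies in [0, 1] and label
#' agreement in {0, 1}.
#'
#' @name cost_stack
NULL

new_similarity <- function(metric, scores, declared_range) {
  structure(list(metric = metric, scores = scores,
                 declared_range = declared_range),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix (", x$metric, "): ", nrow(x$scores), " query x ",
      ncol(x$scores), " reference, range [",
      paste(signif(range(x$scores), 3), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

# Pearson correlation between every query column and every reference column
# over the intersection of their feature ids. Zero-variance columns get
# similarity 0 (with a warning) rather than NaN.
pearson_similarity <- function(q, r, metric) {
  shared <- intersect(q$feature_ids, r$feature_ids)
  if (length(shared) < 2L) {
    stop("need at least 2 shared features to correlate (got ", length(shared), ")")
  }
  qm <- q$values[shared, , drop = FALSE]
  rm_ <- r$values[shared, , drop = FALSE]
  qv <- apply(qm, 2, var)
  rv <- apply(rm_, 2, var)
  scores <- suppressWarnings(cor(qm, rm_))
  if (any(qv == 0) || any(rv == 0)) {
    warning(sum(qv == 0) + sum(rv == 0),
            " zero-variance signal column(s); their similarities set to 0")
    scores[qv == 0, ] <- 0
    scores[, rv == 0] <- 0
  }
  scores <- pmin(pmax(scores, -1), 1)  # guard fp overshoot
  dimnames(scores) <- list(colnames(qm), colnames(rm_))
  new_similarity(metric, scores, c(-1, 1))
}

#' Cell (feature) expression similarity
#'
#' Pearson correlation between the expression signals of each potential cell
#' pair, computed over the intersection of the two signals' feature sets.
#'
#' @param q,r cell-level \code{signal_matrix} objects for query and reference.
#' @return A \code{similarity_matrix} (metric \code{"feature"}, range [-1, 1]).
#' @export
feature_similarity <- function(q, r) pearson_similarity(q, r, "feature")

#' Niche expression similarity
#'
#' As \code{\link{feature_similarity}}, applied to niche-level signals
#' (neighborhood mean expression).
#'
#' @param qn,rn niche-level \code{signal_matrix} objects.
#' @return A \code{similarity_matrix} (metric \code{"niche"}).
#' @export
niche_similarity <- function(qn, rn) {
  if (qn$level != "niche" || rn$level != "niche") {
    stop("niche_similarity expects niche-level signals")
  }
  out <- pearson_similarity(qn, rn, "niche")
  out
}

#' Territory expression similarity
#'
#' As \code{\link{feature_similarity}}, applied to territory-level signals
#' (domain mean expression); scores depend only on the (query territory,
#' reference territory) pair, so the matrix is block-constant.
#'
#' @param qt,rt territory-level \code{signal_matrix} objects.
#' @return A \code{similarity_matrix} (metric \code{"territory"}).
#' @export
territory_similarity <- function(qt, rt) {
  if (qt$level != "territory" || rt$level != "territory") {
    stop("territory_similarity expects territory-level signals")
  }
  pearson_similarity(qt, rt, "territory")
}

#' Niche cell-type composition similarity
#'
#' Frequency-aware Jaccard index between the cell-type label multisets of the
#' two cells' niches: repeated labels are disambiguated (A, A.1, A.2, ...)
#' before the set operations, which equals the multiset Jaccard index.
#'
#' @param q,r \code{spatial_dataset}s with \code{cell_labels}.
#' @param qn,rn \code{niche_assignment}s for query and reference.
#' @return A \code{similarity_matrix} (metric \code{"composition"}, range [0, 1]).
#' @export
composition_similarity <- function(q, r, qn, rn) {
  if (is.null(q$cell_labels) || is.null(r$cell_labels)) {
    stop("cell_labels are required for composition similarity")
  }
  qsets <- niche_label_sets(q, qn)
  rsets <- niche_label_sets(r, rn)
  vocab <- union(unique(q$cell_labels), unique(r$cell_labels))
  qc <- label_count_matrix(qsets, vocab)
  rc <- label_count_matrix(rsets, vocab)
  scores <- pairwise_multiset_jaccard(qc, rc)
  dimnames(scores) <- list(q$barcodes, r$barcodes)
  new_similarity("composition", scores, c(0, 1))
}

#' Cell-type label agreement
#'
#' Indicator matrix: 1 where the query and reference cells carry the same
#' cell-type label, 0 otherwise.
#'
#' @param q,r \code{spatial_dataset}s with \code{cell_labels}.
#' @return A \code{similarity_matrix} (metric \code{"label"}, range \{0, 1\}).
#' @export
label_similarity <- function(q, r) {
  if (is.null(q$cell_labels) || is.null(r$cell_labels)) {
    stop("cell_labels are required for label similarity")
  }
  scores <- outer(q$cell_labels, r$cell_labels, "==") * 1
  dimnames(scores) <- list(q$barcodes, r$barcodes)
  new_similarity("label", scores, c(0, 1))
}

#' Wrap a user-supplied similarity matrix
#'
#' Entry point for custom, context-specific similarity scores; the matrix is
#' used in the cost sum exactly like the built-in metrics.
#'
#' @param scores query x reference numeric matrix with barcode dimnames.
#' @param declared_range the score range, default \code{c(-1, 1)}.
#' @param metric name for the metric (default \code{"custom"}).
#' @return A \code{similarity_matrix}.
#' @export
custom_similarity <- function(scores, declared_range = c(-1, 1),
                              metric = "custom") {
  if (anyNA(scores)) stop("custom similarity scores must not contain NA")
  new_similarity(metric, as.matrix(scores), declared_range)
}

#' Build a cost stack from named similarity matrices
#'
#' Sums the reciprocals of all provided similarity matrices into the total
#' cost, \code{C_ij = sum_k (1 - S_ij^(k))}; matrices are never weighted.
#'
#' @param matrices list of \code{similarity_matrix} objects (named by metric
#'   if unnamed).
#' @return A \code{cost_stack} with elements \code{matrices},
#'   \code{total_cost}, \code{active_query} (initially all query cells),
#'   \code{query_ids}, \code{ref_ids}.
#' @export
build_cost_stack <- function(matrices) {
  if (length(matrices) == 0L) stop("at least one similarity matrix is required")
  if (is.null(names(matrices)) || any(names(matrices) == "")) {
    names(matrices) <- vapply(matrices, function(m) m$metric, character(1))
  }
  dims <- vapply(matrices, function(m) dim(m$scores), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all similarity matrices must share query x reference dimensions")
  }
  total <- 0
  for (m in matrices) total <- total + (1 - m$scores)
  qn <- rownames(matrices[[1]]$scores)
  rn <- colnames(matrices[[1]]$scores)
  structure(list(matrices = matrices, total_cost = total,
                 active_query = seq_len(nrow(total)),
                 query_ids = qn, ref_ids = rn),
            class = "cost_stack")
}

#' @export
print.cost_stack <- function(x, ...) {
  cat("cost_stack: ", length(x$matrices), " metric(s) [",
      paste(names(x$matrices), collapse = ", "), "], ",
      nrow(x$total_cost), " query x ", ncol(x$total_cost), " reference, ",
      length(x$active_query), " active query cells\n", sep = "")
  invisible(x)
}

#' Filter query cells before mapping
#'
#' Two independent filters, both acting on query cells only. The score
#' threshold keeps a query cell if it has at least one reference match whose
#' similarity exceeds \code{threshold} in any correlation/Jaccard metric
#' (feature, niche, territory, composition, custom); the label indicator is
#' not thresholded. The label filter drops query cells whose label matches no
#' reference cell at all (row sum of the indicator is zero).
#'
#' @param stack a \code{cost_stack}.
#' @param threshold similarity threshold (default 0.9); \code{NULL} disables.
#' @param use_label_filter drop label-orphan query cells (default FALSE).
#' @return The stack with \code{active_query} restricted.
#' @export
filter_candidates <- function(stack, threshold = 0.9, use_label_filter = FALSE) {
  keep <- rep(TRUE, length(stack$query_ids))
  if (!is.null(threshold)) {
    scored <- stack$matrices[names(stack$matrices) != "label"]
    if (length(scored)) {
      any_above <- rep(FALSE, length(keep))
      for (m in scored) {
        any_above <- any_above | (apply(m$scores, 1, max) > threshold)
      }
      keep <- keep & any_above
    }
  }
  if (use_label_filter && "label" %in% names(stack$matrices)) {
    keep <- keep & (rowSums(stack$matrices[["label"]]$scores) > 0)
  }
  if (!any(keep)) stop("all query cells removed by filtering")
  stack$active_query <- unname(which(keep))
  stack
}

#' Interpretability diagnostics for a cost stack
#'
#' For each metric: the coefficient of variation (sd over mean) of its cost
#' contribution \code{1 - S} across all candidate pairs, a measure of its
#' discriminative power, and the mean proportion of contribution (POC) across
#' mapped pairs, where a pair's POC for metric k is
#' \code{(1 - S_ij^(k)) / C_ij}. Pairs with zero total cost have undefined
#' POC and are excluded, with the count reported.
#'
#' @param stack a \code{cost_stack}.
#' @param mapping a \code{mapping_result} produced from this stack.
#' @return data frame with columns \code{metric}, \code{cv}, \code{mean_poc},
#'   \code{n_pairs}, \code{n_zero_cost}.
#' @export
cost_diagnostics <- function(stack, mapping) {
  qi <- match(mapping$query_barcode, stack$query_ids)
  ri <- match(mapping$ref_barcode, stack$ref_ids)
  if (anyNA(qi) || anyNA(ri)) stop("mapping does not match this cost stack")
  pair_idx <- cbind(qi, ri)
  total <- stack$total_cost[pair_idx]
  ok <- total > 0
  n_zero <- sum(!ok)
  out <- lapply(names(stack$matrices), function(met) {
    contrib_mat <- 1 - stack$matrices[[met]]$scores
    contrib <- contrib_mat[pair_idx]
    data.frame(metric = met,
               cv = sd(contrib_mat) / mean(contrib_mat),
               mean_poc = mean(contrib[ok] / total[ok]),
               n_pairs = sum(ok),
               n_zero_cost = n_zero)
  })
  do.call(rbind, out)
}

#' Per-pair proportions of contribution
#'
#' @param stack a \code{cost_stack}.
#' @param mapping a \code{mapping_result}.
#' @return matrix of POC values (pairs x metrics); rows with zero total cost
#'   are NA.
#' @export
poc_matrix <- function(stack, mapping) {
  qi <- match(mapping$query_barcode, stack$query_ids)
  ri <- match(mapping$ref_barcode, stack$ref_ids)
  pair_idx <- cbind(qi, ri)
  total <- stack$total_cost[pair_idx]
  poc <- sapply(stack$matrices, function(m) (1 - m$scores)[pair_idx] / total)
  if (is.null(dim(poc))) poc <- matrix(poc, nrow = 1,
                                       dimnames = list(NULL, names(stack$matrices)))
  poc[total <= 0, ] <- NA_real_
  poc
}

#' Parse a cost-configuration letter string
#'
#' Configurations are written with the one-letter metric codes \code{f}
#' (feature/cell), \code{n} (niche), \code{c} (composition), \code{t}
#' (territory), \code{y} (cell-type label); e.g. \code{"fnct"}.
#'
#' @param config letter string.
#' @return character vector of metric names.
#' @export
parse_cost_config <- function(config) {
  letters_map <- c(f = "feature", n = "niche", c = "composition",
                   t = "territory", y = "label")
  ch <- strsplit(config, "")[[1]]
  bad <- setdiff(ch, names(letters_map))
  if (length(bad)) stop("unknown metric letter(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(ch)) stop("duplicate metric letters in '", config, "'")
  unname(letters_map[ch])
}

#' The benchmark cost-matrix configurations
#'
#' The 14 combinations used to benchmark mapping performance, from single
#' metrics up to the full stack.
#'
#' @return character vector of 14 configuration strings.
#' @export
cost_configurations <- function() {
  c("f", "n", "t", "c",
    "fn", "fny", "fc", "ft", "nt", "nc",
    "fnt", "fnc", "fnct", "fncty")
}
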