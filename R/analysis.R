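#' Adjusted Rand index
#'
#' Chance-corrected agreement between two labelings of the same items, from
#' the contingency-table closed form under the permutation model.
#'
#' @param labels_a,labels_b equal-length label vectors.
#' @return A number in \code{[-1, 1]}; 1 for identical partitions, about 0 at
#'   chance level.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors must have equal length")
  }
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)  # degenerate partitions agree by chance
  (sum_ij - expected) / (max_index - expected)
}

#' Neighborhood Jaccard scores of mapped pairs
#'
#' For every mapped pair, the frequency-aware Jaccard index between the
#' cell-type label multiset of the query cell's k nearest neighbors (in the
#' query sample) and that of its matched reference cell (in the reference
#' sample). Measures how well the mapping preserves spatial context.
#'
#' @param result a \code{mapping_result}.
#' @param q,r query and reference \code{spatial_dataset}s with
#'   \code{cell_labels}.
#' @param k neighbors (default 6), matching the interaction-label convention
#'   (center cell excluded).
#' @return Numeric vector of per-pair scores in \code{[0, 1]}.
#' @export
interaction_jaccard <- function(result, q, r, k = 6) {
  if (is.null(q$cell_labels) || is.null(r$cell_labels)) {
    stop("both datasets must carry cell_labels")
  }
  qidx <- knn_indices(as.matrix(q$coords[, c("x", "y")]), k)
  ridx <- knn_indices(as.matrix(r$coords[, c("x", "y")]), k)
  vocab <- union(unique(q$cell_labels), unique(r$cell_labels))
  qsets <- lapply(seq_len(nrow(qidx)), function(i) q$cell_labels[qidx[i, ]])
  rsets <- lapply(seq_len(nrow(ridx)), function(i) r$cell_labels[ridx[i, ]])
  qc <- label_count_matrix(qsets, vocab)
  rc <- label_count_matrix(rsets, vocab)
  qi <- match(result$query_barcode, q$barcodes)
  ri <- match(result$ref_barcode, r$barcodes)
  if (anyNA(qi) || anyNA(ri)) stop("mapping barcodes not found in datasets")
  inter <- rowSums(pmin(qc[qi, , drop = FALSE], rc[ri, , drop = FALSE]))
  uni <- rowSums(pmax(qc[qi, , drop = FALSE], rc[ri, , drop = FALSE]))
  score <- inter / uni
  score[uni == 0] <- 1
  score
}

#' Evaluate a mapping against ground-truth labels
#'
#' Computes the adjusted Rand index between the cell-type labels of mapped
#' query and reference cells, and the per-pair neighborhood Jaccard scores.
#'
#' @inheritParams interaction_jaccard
#' @return List with \code{ari}, \code{interaction_jaccard} (per-pair),
#'   \code{mean_jaccard} and \code{n_pairs}.
#' @export
evaluate_mapping <- function(result, q, r, k = 6) {
  qi <- match(result$query_barcode, q$barcodes)
  ri <- match(result$ref_barcode, r$barcodes)
  ari <- adjusted_rand_index(q$cell_labels[qi], r$cell_labels[ri])
  ji <- interaction_jaccard(result, q, r, k = k)
  list(ari = ari, interaction_jaccard = ji,
       mean_jaccard = mean(ji), n_pairs = nrow(result))
}

#' Cluster query cells by co-mapping
#'
#' Query cells that preferentially map to the same set of reference cells are
#' grouped together: for each query cell the reference candidates are ranked
#' by ascending mapping cost (best match first) and the top \code{top_n}
#' reference identifiers form its candidate set; the distance between two
#' query cells is 1 minus the Jaccard index of their candidate sets;
#' average-linkage hierarchical clustering is cut at \code{k} clusters or
#' height \code{h}.
#'
#' @param stack a \code{cost_stack} providing per-query candidate costs.
#' @param top_n candidate-set size (default 30); cells with fewer candidates
#'   use all of them.
#' @param k number of clusters (mutually exclusive with \code{h}).
#' @param h cut height in \code{[0, 1]}.
#' @param query_subset optional barcodes restricting the query cells used.
#' @return List with \code{clusters} (named integer vector), \code{hclust},
#'   and the \code{distance} matrix.
#' @export
co_mapping_clusters <- function(stack, top_n = 30, k = NULL, h = NULL,
                                query_subset = NULL) {
  ids <- stack$query_ids[stack$active_query]
  if (!is.null(query_subset)) ids <- intersect(ids, query_subset)
  if (length(ids) < 2L) stop("need at least two query cells to cluster")
  n_top <- min(top_n, length(stack$ref_ids))
  top_sets <- lapply(ids, function(q) {
    costs <- stack$total_cost[q, ]
    stack$ref_ids[order(costs)][seq_len(n_top)]
  })
  n <- length(ids)
  J <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(top_sets[[i]], top_sets[[j]]))
      J[i, j] <- J[j, i] <- inter / (2 * n_top - inter)
    }
  }
  d <- as.dist(1 - J)
  hc <- hclust(d, method = "average")
  clusters <- if (!is.null(k)) cutree(hc, k = k)
              else if (!is.null(h)) cutree(hc, h = h)
              else cutree(hc, k = min(5, n))
  names(clusters) <- ids
  dm <- as.matrix(d)
  dimnames(dm) <- list(ids, ids)
  list(clusters = clusters, hclust = hc, distance = dm)
}

#' Cluster samples by mean mapping cost
#'
#' Uses a samples x samples matrix of mean mapping costs (entry i,j = mean
#' cost of mapping sample i onto sample j) directly as the clustering
#' distance: the matrix is symmetrized by averaging the two directions,
#' self-mapping entries are ignored, and average-linkage hierarchical
#' clustering is cut at height \code{h}.
#'
#' @param cost_matrix square numeric matrix of mean mapping costs.
#' @param h cut height (default 0.5).
#' @return List with \code{clusters} (named integer vector) and \code{hclust}.
#' @export
cluster_samples <- function(cost_matrix, h = 0.5) {
  cost_matrix <- as.matrix(cost_matrix)
  if (nrow(cost_matrix) != ncol(cost_matrix)) {
    stop("cost matrix must be square (samples x samples)")
  }
  sym <- (cost_matrix + t(cost_matrix)) / 2
  diag(sym) <- 0
  hc <- hclust(as.dist(sym), method = "average")
  clusters <- cutree(hc, h = h)
  names(clusters) <- rownames(cost_matrix) %||%
    paste0("sample_", seq_len(nrow(cost_matrix)))
  list(clusters = clusters, hclust = hc)
}

#' Rank-sum differential expression between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test per gene on the normalized layer, with
#' Benjamini-Hochberg correction and a significance flag at adjusted
#' p < 0.05.
#'
#' @param d a \code{spatial_dataset} with a normalized layer (may hold
#'   integrated counts from several samples).
#' @param group_a,group_b barcode vectors (each of at least 2 cells).
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @return data frame with columns \code{gene}, \code{statistic},
#'   \code{log_fc}, \code{p}, \code{p_adj}, \code{significant}, ordered by
#'   adjusted p-value.
#' @export
differential_expression <- function(d, group_a, group_b, alpha = 0.05) {
  if (is.null(d$normalized)) stop("run normalize_counts() first")
  ia <- match(group_a, d$barcodes)
  ib <- match(group_b, d$barcodes)
  if (anyNA(ia) || anyNA(ib)) stop("unknown barcodes in group definition")
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("both groups need at least 2 cells")
  }
  a <- d$normalized[, ia, drop = FALSE]
  b <- d$normalized[, ib, drop = FALSE]
  res <- t(vapply(seq_len(nrow(a)), function(g) {
    wt <- suppressWarnings(wilcox.test(a[g, ], b[g, ]))
    c(statistic = unname(wt$statistic), p = wt$p.value)
  }, c(statistic = 0, p = 0)))
  p <- res[, "p"]
  p[is.na(p)] <- 1  # constant genes carry no evidence
  out <- data.frame(gene = rownames(d$normalized),
                    statistic = res[, "statistic"],
                    log_fc = rowMeans(a) - rowMeans(b),
                    p = p,
                    p_adj = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_adj < alpha
  out[order(out$p_adj, out$p), ]
}
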