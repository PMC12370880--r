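#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dist prcomp kmeans hclust cutree as.dist sd
#'   wilcox.test p.adjust rgamma rpois rlnorm runif quantile var setNames
#' @importFrom utils head read.table write.table
#' @importFrom methods as
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frequency-aware Jaccard index between two label multisets
#'
#' Repeated labels are disambiguated before the set operations: the second
#' occurrence of label \code{A} is treated as \code{A.1}, the third as
#' \code{A.2}, and so on. The resulting index equals the multiset Jaccard
#' index: the sum over labels of the smaller occurrence count divided by the
#' sum of the larger occurrence count.
#'
#' @param a,b character vectors of labels (multisets; order irrelevant).
#' @return A number in \code{[0, 1]}. Two empty multisets score 1.
#' @examples
#' freq_aware_jaccard(c("A", "A", "B"), c("A", "B", "B")) # 0.5
#' @export
freq_aware_jaccard <- function(a, b) {
  if (length(a) == 0L && length(b) == 0L) return(1)
  ta <- table(a)
  tb <- table(b)
  labs <- union(names(ta), names(tb))
  ca <- as.integer(ta[labs])
  cb <- as.integer(tb[labs])
  ca[is.na(ca)] <- 0L
  cb[is.na(cb)] <- 0L
  sum(pmin(ca, cb)) / sum(pmax(ca, cb))
}

# Disambiguate repeated labels: A, A, B -> A, A.1, B. Used where the
# uniquified sets themselves are needed (documentation/tests); numeric
# scoring goes through the equivalent count formulation.
uniquify_labels <- function(x) {
  if (length(x) == 0L) return(character(0))
  idx <- stats::ave(seq_along(x), x, FUN = seq_along) - 1L
  ifelse(idx == 0L, x, paste(x, idx, sep = "."))
}

# Occurrence-count matrix (rows = cells, cols = label vocabulary) from a
# list of per-cell label multisets.
label_count_matrix <- function(label_sets, vocab) {
  m <- matrix(0L, nrow = length(label_sets), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(label_sets)) {
    tt <- table(label_sets[[i]])
    m[i, names(tt)] <- as.integer(tt)
  }
  m
}

# Pairwise multiset Jaccard between the rows of two occurrence-count
# matrices sharing the same vocabulary columns.
pairwise_multiset_jaccard <- function(qc, rc) {
  stopifnot(ncol(qc) == ncol(rc))
  inter <- matrix(0, nrow(qc), nrow(rc))
  uni <- matrix(0, nrow(qc), nrow(rc))
  for (l in seq_len(ncol(qc))) {
    ql <- qc[, l]
    rl <- rc[, l]
    inter <- inter + outer(ql, rl, pmin)
    uni <- uni + outer(ql, rl, pmax)
  }
  out <- inter / uni
  out[uni == 0] <- 1  # two empty multisets are identical
  out
}

# k nearest neighbours (self excluded) as an n x k index matrix.
knn_indices <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) {
    stop("k (", k, ") must be smaller than the number of cells (", n, ")")
  }
  nn <- RANN::nn2(coords, k = k + 1L)$nn.idx
  idx <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    row <- nn[i, ]
    row <- row[row != i]
    idx[i, ] <- row[seq_len(k)]
  }
  idx
}
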