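#' Build a cost stack between two prepared samples
#'
#' Convenience constructor running the preprocessing needed by the requested
#' metric letters and assembling the similarity matrices: \code{f} feature
#' (cell expression), \code{n} niche, \code{c} composition, \code{t}
#' territory, \code{y} cell-type label. Expression signals use the top
#' variable genes of each sample's normalized layer; similarity is computed
#' over the feature intersection.
#'
#' @param query,ref \code{spatial_dataset}s with counts (and labels where the
#'   metrics require them).
#' @param metrics configuration letter string (default \code{"fn"}).
#' @param n_features variable genes per dataset (default 2000, capped at the
#'   gene count).
#' @param normalization \code{"lognorm"} or \code{"tfidf"}.
#' @param niche_method,niche_k,niche_depth,niche_radius niche definition
#'   passed to \code{\link{extract_niches}}.
#' @param territory_k fallback territory count if labels are absent.
#' @param seed seed for the fallback territory detection.
#' @return A \code{cost_stack}.
#' @export
build_sample_stack <- function(query, ref, metrics = "fn",
                               n_features = 2000,
                               normalization = c("lognorm", "tfidf"),
                               niche_method = c("knn", "graph", "radius"),
                               niche_k = 6, niche_depth = 1,
                               niche_radius = NULL,
                               territory_k = 5, seed = 42) {
  normalization <- match.arg(normalization)
  niche_method <- match.arg(niche_method)
  wanted <- parse_cost_config(metrics)
  if (is.null(query$normalized)) query <- normalize_counts(query, normalization)
  if (is.null(ref$normalized)) ref <- normalize_counts(ref, normalization)
  nf_q <- min(n_features, nrow(query$normalized))
  nf_r <- min(n_features, nrow(ref$normalized))
  qsig <- cell_signal(query, select_variable_features(query, nf_q))
  rsig <- cell_signal(ref, select_variable_features(ref, nf_r))
  mats <- list()
  if ("feature" %in% wanted) {
    mats$feature <- feature_similarity(qsig, rsig)
  }
  need_niche <- any(c("niche", "composition") %in% wanted)
  if (need_niche) {
    qn <- extract_niches(query, niche_method, k = niche_k,
                         depth = niche_depth, radius = niche_radius)
    rn <- extract_niches(ref, niche_method, k = niche_k,
                         depth = niche_depth, radius = niche_radius)
  }
  if ("niche" %in% wanted) {
    mats$niche <- niche_similarity(niche_signal(qn, qsig),
                                   niche_signal(rn, rsig))
  }
  if ("composition" %in% wanted) {
    mats$composition <- composition_similarity(query, ref, qn, rn)
  }
  if ("territory" %in% wanted) {
    get_territories <- function(d, sig) {
      if (!is.null(d$territory_labels)) return(d)
      emb <- compute_embedding(d, dims = min(30, nrow(sig$values) - 1,
                                             ncol(sig$values) - 1),
                               features = sig$feature_ids)
      assign_territories(d, "fallback", embedding = emb, k = territory_k,
                         seed = seed)
    }
    query <- get_territories(query, qsig)
    ref <- get_territories(ref, rsig)
    mats$territory <- territory_similarity(territory_signal(query, qsig),
                                           territory_signal(ref, rsig))
  }
  if ("label" %in% wanted) {
    mats$label <- label_similarity(query, ref)
  }
  build_cost_stack(mats[wanted])
}

#' Map one sample onto another
#'
#' End-to-end pipeline: normalization, variable-feature selection, niche and
#' territory signal extraction as required by the metric configuration, cost
#' stack construction, candidate filtering, and batched assignment across
#' epochs.
#'
#' @inheritParams build_sample_stack
#' @param threshold similarity filter threshold (default 0.9; \code{NULL}
#'   disables).
#' @param filter_labels drop query cells whose label is absent from the
#'   reference (default FALSE).
#' @param batch_size,epochs,seed,one_to_one passed to \code{\link{map_cells}}.
#' @param verbose print per-epoch mean retained cost.
#' @return List of class \code{sample_mapping} with elements \code{mapping}
#'   (a \code{mapping_result}) and \code{stack} (the \code{cost_stack}).
#' @export
map_samples <- function(query, ref, metrics = "fn", n_features = 2000,
                        normalization = "lognorm",
                        niche_method = "knn", niche_k = 6, niche_depth = 1,
                        niche_radius = NULL, territory_k = 5,
                        threshold = 0.9, filter_labels = FALSE,
                        batch_size = 1000, epochs = 25, seed = 42,
                        one_to_one = FALSE, verbose = FALSE) {
  stack <- build_sample_stack(query, ref, metrics = metrics,
                              n_features = n_features,
                              normalization = normalization,
                              niche_method = niche_method, niche_k = niche_k,
                              niche_depth = niche_depth,
                              niche_radius = niche_radius,
                              territory_k = territory_k, seed = seed)
  stack <- filter_candidates(stack, threshold = threshold,
                             use_label_filter = filter_labels)
  mapping <- map_cells(stack, batch_size = batch_size, epochs = epochs,
                       seed = seed, one_to_one = one_to_one,
                       verbose = verbose)
  structure(list(mapping = mapping, stack = stack,
                 query_id = query$sample_id, ref_id = ref$sample_id),
            class = "sample_mapping")
}

#' @export
print.sample_mapping <- function(x, ...) {
  cat("sample_mapping: ", x$query_id, " -> ", x$ref_id, "\n", sep = "")
  print(x$mapping)
  invisible(x)
}

#' Enumerate all-vs-all mapping events
#'
#' Ordered (query, reference) sample pairs over a collection, excluding
#' self-mapping: n samples yield n * (n - 1) events.
#'
#' @param datasets list of \code{spatial_dataset}s (or sample ids).
#' @return data frame with columns \code{query} and \code{ref}.
#' @export
enumerate_mapping_events <- function(datasets) {
  ids <- vapply(datasets, function(d) {
    if (inherits(d, "spatial_dataset")) d$sample_id else as.character(d)
  }, character(1))
  grid <- expand.grid(query = ids, ref = ids, stringsAsFactors = FALSE)
  grid[grid$query != grid$ref, c("query", "ref")]
}
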