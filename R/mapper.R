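#' Solve a linear assignment problem
#'
#' Finds the one-to-one row-to-column assignment minimizing the total cost,
#' using the Jonker-Volgenant/Hungarian family solver from \pkg{clue}. The
#' matrix may be rectangular with no more rows than columns; every row is
#' assigned to a distinct column.
#'
#' @param cost finite numeric cost matrix (rows <= columns).
#' @return Integer vector: \code{result[i]} is the column assigned to row i.
#' @export
solve_lap <- function(cost) {
  cost <- as.matrix(cost)
  if (!all(is.finite(cost))) stop("cost matrix must be finite")
  if (nrow(cost) > ncol(cost)) {
    stop("cost matrix must have no more rows than columns (pad first)")
  }
  lo <- min(cost)
  if (lo < 0) cost <- cost - lo  # constant shift leaves the argmin unchanged
  as.integer(clue::solve_LSAP(cost, maximum = FALSE))
}

#' Draw matched batches of reference and query cells
#'
#' Cells are sampled without replacement so the larger of the two sets is
#' partitioned across batches and every cell is eventually selected. When one
#' set is smaller, it is padded by cyclic repetition of a shuffled copy of
#' itself, so padded entries are always duplicates of real identifiers; a
#' query cell can then meet a reference more than once, producing many-to-one
#' matches naturally. Batch contents are deterministic given the seed.
#'
#' @param ref_ids,query_ids character vectors of cell identifiers.
#' @param batch_size requested batch size B.
#' @param seed integer seed for the shuffles.
#' @return List of batches, each a list with elements \code{ref} and
#'   \code{query} of equal length.
#' @export
make_batches <- function(ref_ids, query_ids, batch_size, seed = 42) {
  if (length(ref_ids) == 0L || length(query_ids) == 0L) {
    stop("both id sets must be non-empty")
  }
  withr::with_seed(seed, {
    q <- sample(query_ids)
    r <- sample(ref_ids)
  })
  n <- max(length(q), length(r))
  pad_cyclic <- function(x, n) x[((seq_len(n) - 1L) %% length(x)) + 1L]
  q_full <- pad_cyclic(q, n)
  r_full <- pad_cyclic(r, n)
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) {
    idx <- s:min(s + batch_size - 1L, n)
    list(ref = r_full[idx], query = q_full[idx])
  })
}

#' Map cells between samples by batched assignment
#'
#' Runs the epoch/batch mapping loop over a precomputed \code{cost_stack}:
#' at each epoch, fresh random batches are drawn (epoch e uses
#' \code{seed + e}), the per-batch cost submatrix is sliced from the full
#' stack, the assignment problem is solved, and each query cell's retained
#' pair is replaced only when the new pair costs strictly less. The output
#' lists every active query cell with its best reference match, the total
#' cost, the per-metric similarity scores and the epoch at which the pair was
#' retained. When a single batch covers both cell sets the epoch loop stops
#' after the first epoch, since every further epoch would re-solve the
#' identical assignment problem.
#'
#' @param stack a (optionally filtered) \code{cost_stack}.
#' @param batch_size batch size B (default 1000).
#' @param epochs number of epochs (default 25).
#' @param seed integer seed driving batch sampling.
#' @param one_to_one apply \code{\link{filter_one_to_one}} before returning.
#' @param verbose print the mean retained cost per epoch.
#' @param return_history attach a query x epoch matrix of retained costs as
#'   the \code{"history"} attribute of the result.
#' @return A \code{mapping_result} data frame with columns
#'   \code{query_barcode}, \code{ref_barcode}, \code{total_cost},
#'   \code{epoch}, and one \code{score_<metric>} column per stack metric.
#' @export
map_cells <- function(stack, batch_size = 1000, epochs = 25, seed = 42,
                      one_to_one = FALSE, verbose = FALSE,
                      return_history = FALSE) {
  if (!inherits(stack, "cost_stack")) stop("stack must be a cost_stack")
  if (batch_size < 1 || epochs < 1) stop("batch_size and epochs must be >= 1")
  query_ids <- stack$query_ids[stack$active_query]
  if (length(query_ids) == 0L) stop("no active query cells to map")
  ref_ids <- stack$ref_ids
  best_cost <- setNames(rep(Inf, length(query_ids)), query_ids)
  best_ref <- setNames(rep(NA_character_, length(query_ids)), query_ids)
  best_epoch <- setNames(rep(NA_integer_, length(query_ids)), query_ids)
  history <- if (return_history) {
    matrix(NA_real_, length(query_ids), epochs,
           dimnames = list(query_ids, NULL))
  }
  for (e in seq_len(epochs)) {
    batches <- make_batches(ref_ids, query_ids, batch_size, seed = seed + e)
    for (b in batches) {
      sub <- stack$total_cost[b$query, b$ref, drop = FALSE]
      assign <- solve_lap(sub)
      cost <- sub[cbind(seq_along(assign), assign)]
      matched_ref <- b$ref[assign]
      # strict improvement only; ties keep the earlier epoch's pair
      qpos <- match(b$query, query_ids)
      if (anyDuplicated(qpos)) {
        # padded (duplicated) query entries must be applied sequentially
        for (i in seq_along(qpos)) {
          p <- qpos[i]
          if (cost[i] < best_cost[p]) {
            best_cost[p] <- cost[i]
            best_ref[p] <- matched_ref[i]
            best_epoch[p] <- e
          }
        }
      } else {
        better <- cost < best_cost[qpos]
        upd <- qpos[better]
        best_cost[upd] <- cost[better]
        best_ref[upd] <- matched_ref[better]
        best_epoch[upd] <- e
      }
    }
    if (return_history) history[, e] <- best_cost
    if (verbose) {
      message("epoch ", e, ": mean retained cost ",
              signif(mean(best_cost[is.finite(best_cost)]), 5))
    }
    if (batch_size >= max(length(query_ids), length(ref_ids))) {
      # a single batch already covers both sets: every further epoch
      # re-solves the identical assignment problem, so stop early
      if (return_history && e < epochs) {
        history[, (e + 1):epochs] <- best_cost
      }
      break
    }
  }
  result <- data.frame(query_barcode = query_ids,
                       ref_barcode = unname(best_ref),
                       total_cost = unname(best_cost),
                       epoch = unname(best_epoch),
                       stringsAsFactors = FALSE)
  qi <- match(result$query_barcode, stack$query_ids)
  ri <- match(result$ref_barcode, stack$ref_ids)
  for (met in names(stack$matrices)) {
    result[[paste0("score_", met)]] <- stack$matrices[[met]]$scores[cbind(qi, ri)]
  }
  rownames(result) <- NULL
  class(result) <- c("mapping_result", "data.frame")
  attr(result, "config") <- list(batch_size = batch_size, epochs = epochs,
                                 seed = seed,
                                 metrics = names(stack$matrices))
  if (return_history) attr(result, "history") <- history
  if (one_to_one) result <- filter_one_to_one(result)
  result
}

#' Reduce a mapping to one-to-one pairs
#'
#' Greedy retention by ascending cost: pairs are visited cheapest first and
#' kept only if neither their query nor their reference identifier has been
#' used yet.
#'
#' @param result a \code{mapping_result}.
#' @return The filtered \code{mapping_result}.
#' @export
filter_one_to_one <- function(result) {
  if (nrow(result) == 0L) stop("empty mapping result")
  ord <- order(result$total_cost)
  keep <- logical(nrow(result))
  used_q <- character(0)
  used_r <- character(0)
  for (i in ord) {
    q <- result$query_barcode[i]
    r <- result$ref_barcode[i]
    if (!(q %in% used_q) && !(r %in% used_r)) {
      keep[i] <- TRUE
      used_q <- c(used_q, q)
      used_r <- c(used_r, r)
    }
  }
  out <- result[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- attr(result, "config")
  class(out) <- c("mapping_result", "data.frame")
  out
}

#' @export
print.mapping_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("mapping_result: ", nrow(x), " pairs",
      if (!is.null(cfg)) paste0(" [metrics: ",
                                paste(cfg$metrics, collapse = ", "),
                                "; epochs: ", cfg$epochs, "]"),
      "\n", sep = "")
  if (nrow(x)) {
    cat("  mean total cost: ", signif(mean(x$total_cost), 5), "\n", sep = "")
    print(utils::head(as.data.frame(x), 4))
    if (nrow(x) > 4) cat("  ... ", nrow(x) - 4, " more pairs\n", sep = "")
  }
  invisible(x)
}
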