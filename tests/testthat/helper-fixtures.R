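# Fixtures built in code; sizes kept small so the whole suite stays fast.

# Random dataset with labels on a jittered grid; distinct expression per cell.
make_toy_dataset <- function(n_cells = 40, n_genes = 25, seed = 1,
                             sample_id = "toy", n_types = 3) {
  withr::with_seed(seed, {
    counts <- matrix(rpois(n_genes * n_cells, lambda = 5), n_genes, n_cells,
                     dimnames = list(paste0("g", seq_len(n_genes)),
                                     paste0("c", seq_len(n_cells))))
    coords <- data.frame(barcode = colnames(counts),
                         x = runif(n_cells), y = runif(n_cells))
    labels <- sample(LETTERS[seq_len(n_types)], n_cells, replace = TRUE)
  })
  spatial_dataset(counts, coords, sample_id = sample_id, cell_labels = labels)
}

# Deterministic signal matrix from a matrix literal.
make_signal <- function(values, level = "cell") {
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("g", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  }
  signal_matrix(values, level = level)
}

# All permutations of 1..n (for the brute-force assignment oracle).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Brute-force minimum assignment cost over all permutations.
brute_force_lap <- function(cost) {
  perms <- all_perms(nrow(cost))
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    tot <- sum(cost[cbind(seq_len(ncol(perms)), perms[i, ])])
    if (tot < best) best <- tot
  }
  best
}
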