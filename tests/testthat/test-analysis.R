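test_that("adjusted Rand index matches its closed form and known anchors", {
  a <- c("x", "x", "y", "y", "z")
  expect_equal(adjusted_rand_index(a, a), 1)
  # relabeling leaves the index unchanged
  b <- c("1", "1", "2", "2", "3")
  expect_equal(adjusted_rand_index(a, b), 1)
  # one-class labeling vs a balanced split sits at chance level
  expect_equal(adjusted_rand_index(rep("u", 6), rep(c("p", "q"), 3)), 0)
  expect_error(adjusted_rand_index(a, a[-1]), "equal length")

  skip_if_not_installed("mclust")
  withr::with_seed(80, {
    for (i in 1:5) {
      l1 <- sample(letters[1:4], 50, replace = TRUE)
      l2 <- sample(letters[1:3], 50, replace = TRUE)
      expect_equal(adjusted_rand_index(l1, l2),
                   mclust::adjustedRandIndex(l1, l2), tolerance = 1e-12)
    }
  })
})

test_that("interaction Jaccard is 1 for identity self-mapping and 0 for disjoint labels", {
  d <- make_toy_dataset(n_cells = 30, seed = 81)
  self_map <- data.frame(query_barcode = d$barcodes,
                         ref_barcode = d$barcodes,
                         total_cost = 0, epoch = 1L)
  class(self_map) <- c("mapping_result", "data.frame")
  ji <- interaction_jaccard(self_map, d, d, k = 6)
  expect_equal(ji, rep(1, 30))

  r <- d
  r$cell_labels <- rep("ZZZ", 30)
  ji0 <- interaction_jaccard(self_map, d, r, k = 6)
  expect_equal(ji0, rep(0, 30))
})

test_that("interaction Jaccard matches hand-computed uniquified sets on a toy", {
  # query: 5 cells on a line, labels A A B B C; k = 2
  mk <- function(labels, xs, id) {
    n <- length(labels)
    counts <- matrix(1L, 2, n,
                     dimnames = list(c("g1", "g2"), paste0(id, 1:n)))
    spatial_dataset(counts,
                    data.frame(barcode = paste0(id, 1:n), x = xs, y = 0),
                    cell_labels = labels, sample_id = id)
  }
  q <- mk(c("A", "A", "B", "B", "C"), 1:5, "q")
  r <- mk(c("A", "B", "B", "C", "C"), 1:5, "r")
  mapping <- data.frame(query_barcode = c("q2", "q3"),
                        ref_barcode = c("r2", "r4"),
                        total_cost = 0, epoch = 1L)
  class(mapping) <- c("mapping_result", "data.frame")
  ji <- interaction_jaccard(mapping, q, r, k = 2)
  # q2 neighbors {q1, q3} -> {A, B}; r2 neighbors {r1, r3} -> {A, B} -> J = 1
  # q3 neighbors {q2, q4} -> {A, B}; r4 neighbors {r3, r5} -> {B, C} -> 1/3
  expect_equal(ji, c(1, 1 / 3), tolerance = 1e-12)
})

test_that("co-mapping clustering groups queries by shared candidate sets", {
  # planted two-block structure: queries 1..6 prefer refs 1..8,
  # queries 7..12 prefer refs 9..16
  nq <- 12; nr <- 16
  withr::with_seed(83, {
    scores <- matrix(runif(nq * nr, 0, 0.2), nq, nr)
    scores[1:6, 1:8] <- scores[1:6, 1:8] + 0.7
    scores[7:12, 9:16] <- scores[7:12, 9:16] + 0.7
  })
  dimnames(scores) <- list(paste0("q", 1:nq), paste0("r", 1:nr))
  stack <- build_cost_stack(list(
    feature = custom_similarity(scores, c(0, 1), "feature")))
  cm <- co_mapping_clusters(stack, top_n = 8, k = 2)
  expect_length(unique(cm$clusters[1:6]), 1)
  expect_length(unique(cm$clusters[7:12]), 1)
  expect_false(cm$clusters[1] == cm$clusters[12])

  # identical top sets -> distance 0; disjoint -> distance 1
  expect_equal(cm$distance["q1", "q1"], 0)
  expect_equal(max(cm$distance), 1)
  expect_equal(cm$distance, t(cm$distance))
  expect_error(co_mapping_clusters(stack, query_subset = "q1"), "at least two")
})

test_that("sample clustering cuts the symmetrized cost dendrogram at h", {
  m <- matrix(1, 4, 4)
  m[1:2, 1:2] <- 0.1; m[3:4, 3:4] <- 0.1
  rownames(m) <- colnames(m) <- paste0("s", 1:4)
  out <- cluster_samples(m, h = 0.5)
  expect_equal(length(unique(out$clusters)), 2)
  expect_equal(out$clusters[["s1"]], out$clusters[["s2"]])
  expect_false(out$clusters[["s1"]] == out$clusters[["s3"]])

  flat <- matrix(0.3, 3, 3); diag(flat) <- 0
  expect_equal(length(unique(cluster_samples(flat, h = 0.5)$clusters)), 1)

  # hand-built linkage: merge heights follow average-linkage arithmetic
  m3 <- matrix(c(0, 0.2, 1.0,
                 0.2, 0, 0.8,
                 1.0, 0.8, 0), 3, 3, byrow = TRUE)
  hc <- cluster_samples(m3, h = 0.5)$hclust
  expect_equal(hc$height, c(0.2, 0.9), tolerance = 1e-12)

  expect_error(cluster_samples(matrix(0, 2, 3)), "square")
})

test_that("rank-sum differential expression recovers planted effects only", {
  withr::with_seed(85, {
    counts <- matrix(rpois(30 * 100, 10), 30, 100)
  })
  dimnames(counts) <- list(paste0("g", 1:30), paste0("c", 1:100))
  d <- spatial_dataset(counts, data.frame(barcode = colnames(counts),
                                          x = 1:100, y = 1))
  d <- normalize_counts(d)
  # plant the effect on the normalized scale so library-size renormalization
  # does not smear it across the other genes
  d$normalized[5, 1:50] <- d$normalized[5, 1:50] + 2
  res <- differential_expression(d, paste0("c", 1:50), paste0("c", 51:100))
  expect_true(res$significant[res$gene == "g5"])
  expect_lt(sum(res$significant), 4)  # planted gene, not the flat ones

  # identical groups (copied cells): nothing significant
  d2 <- d
  d2$normalized[, 51:100] <- d2$normalized[, 1:50]
  res2 <- differential_expression(d2, paste0("c", 1:50), paste0("c", 51:100))
  expect_false(any(res2$significant))

  expect_error(differential_expression(d, "c1", paste0("c", 3:9)), "at least 2")
})

test_that("rank-sum p-values match exact enumeration on a 4v4 toy", {
  a <- c(1.1, 2.3, 3.7, 5.2)
  b <- c(0.4, 0.9, 6.1, 7.5)
  # exact two-sided p by enumerating all C(8,4) group assignments
  pooled <- c(a, b)
  u_obs <- sum(rank(pooled)[1:4]) - 4 * 5 / 2
  combs <- utils::combn(8, 4)
  us <- apply(combs, 2, function(ix) sum(rank(pooled)[ix]) - 10)
  p_exact <- mean(abs(us - 8) >= abs(u_obs - 8))  # center = n1*n2/2 = 8
  counts <- matrix(1L, 1, 8, dimnames = list("g1", paste0("c", 1:8)))
  d <- spatial_dataset(counts, data.frame(barcode = colnames(counts),
                                          x = 1:8, y = 1))
  d$normalized <- matrix(pooled, 1, 8, dimnames = dimnames(counts))
  res <- differential_expression(d, paste0("c", 1:4), paste0("c", 5:8))
  expect_equal(res$p, p_exact, tolerance = 1e-12)
})

test_that("BH-adjusted p-values are monotone in raw p-value rank", {
  withr::with_seed(86, {
    counts <- matrix(rpois(20 * 40, 8), 20, 40)
  })
  dimnames(counts) <- list(paste0("g", 1:20), paste0("c", 1:40))
  d <- spatial_dataset(counts, data.frame(barcode = colnames(counts),
                                          x = 1:40, y = 1))
  d <- normalize_counts(d)
  res <- differential_expression(d, paste0("c", 1:20), paste0("c", 21:40))
  ord <- order(res$p)
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
})
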