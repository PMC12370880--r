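test_that("feature similarity is the Pearson correlation over shared features", {
  q <- make_signal(cbind(a = c(1, 2, 3), b = c(3, 2, 1)))
  r <- make_signal(cbind(u = c(1, 2, 3), v = c(2, 1, 0)))
  s <- feature_similarity(q, r)
  expect_equal(unname(s$scores["a", "u"]), 1)   # identical
  expect_equal(unname(s$scores["a", "v"]), -1)  # negated after centering
  expect_equal(s$declared_range, c(-1, 1))

  # textbook two-pass formula oracle
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  q2 <- make_signal(matrix(x, 3, 1, dimnames = list(paste0("g", 1:3), "a")))
  r2 <- make_signal(matrix(y, 3, 1, dimnames = list(paste0("g", 1:3), "u")))
  expect_equal(unname(feature_similarity(q2, r2)$scores[1, 1]), oracle,
               tolerance = 1e-12)

  # shared-feature intersection and the minimum-feature guard
  r3 <- make_signal(matrix(rnorm(4), 1, 4,
                           dimnames = list("g1", paste0("u", 1:4))))
  expect_error(feature_similarity(q, r3), "shared features")
})

test_that("zero-variance signal columns score 0 with a warning", {
  q <- make_signal(cbind(flat = c(2, 2, 2), live = c(1, 2, 3)))
  r <- make_signal(cbind(u = c(3, 1, 2)))
  expect_warning(s <- feature_similarity(q, r), "zero-variance")
  expect_equal(unname(s$scores["flat", "u"]), 0)
  expect_false(anyNA(s$scores))
})

test_that("niche similarity equals feature similarity of niche signals", {
  d <- make_toy_dataset(n_cells = 18, n_genes = 10, seed = 31, sample_id = "q")
  e <- make_toy_dataset(n_cells = 15, n_genes = 10, seed = 32, sample_id = "r")
  d <- normalize_counts(d); e <- normalize_counts(e)
  dn <- extract_niches(d, "knn", k = 4)
  en <- extract_niches(e, "knn", k = 4)
  qs <- niche_signal(dn, cell_signal(d))
  rs <- niche_signal(en, cell_signal(e))
  s1 <- niche_similarity(qs, rs)
  s2 <- pearson_oracle <- feature_similarity(
    make_signal(qs$values), make_signal(rs$values))
  expect_equal(s1$scores, s2$scores, tolerance = 1e-12)
  expect_identical(s1$metric, "niche")
  expect_error(niche_similarity(cell_signal(d), rs), "niche-level")
})

test_that("territory similarity is block-constant over territory pairs", {
  d <- make_toy_dataset(n_cells = 12, n_genes = 8, seed = 33)
  e <- make_toy_dataset(n_cells = 10, n_genes = 8, seed = 34)
  d <- normalize_counts(d); e <- normalize_counts(e)
  d$territory_labels <- rep(c("T1", "T2"), 6)
  e$territory_labels <- rep(c("U1", "U2"), 5)
  s <- territory_similarity(territory_signal(d, cell_signal(d)),
                            territory_signal(e, cell_signal(e)))
  # score depends only on the (territory_q, territory_r) pair
  for (tq in c("T1", "T2")) for (tr in c("U1", "U2")) {
    block <- s$scores[d$territory_labels == tq, e$territory_labels == tr]
    expect_lt(diff(range(block)), 1e-12)
  }
})

test_that("frequency-aware Jaccard follows the uniquification rule", {
  expect_equal(freq_aware_jaccard(c("A", "B"), c("A", "B")), 1)
  expect_equal(freq_aware_jaccard(c("A"), c("B")), 0)
  # the worked rule: {A,A,B} vs {A,B,B} -> {A,A.1,B} vs {A,B,B.1} -> 2/4
  expect_equal(freq_aware_jaccard(c("A", "A", "B"), c("A", "B", "B")), 0.5)
  # explicit uniquified-set oracle
  u1 <- spatmatch:::uniquify_labels(c("A", "A", "B"))
  u2 <- spatmatch:::uniquify_labels(c("A", "B", "B"))
  expect_equal(length(intersect(u1, u2)) / length(union(u1, u2)), 0.5)
  expect_identical(u1, c("A", "A.1", "B"))
})

test_that("composition similarity scores niche label multisets pairwise", {
  mk <- function(labels, id) {
    n <- length(labels)
    counts <- matrix(1L, 2, n,
                     dimnames = list(c("g1", "g2"), paste0(id, 1:n)))
    spatial_dataset(counts,
                    data.frame(barcode = paste0(id, 1:n),
                               x = seq_len(n), y = 0),
                    cell_labels = labels, sample_id = id)
  }
  q <- mk(c("A", "A", "B"), "q")
  r <- mk(c("A", "B", "B"), "r")
  # k = 2 niches with center: each cell's niche is the whole line of 3 cells
  qn <- extract_niches(q, "knn", k = 2)
  rn <- extract_niches(r, "knn", k = 2)
  s <- composition_similarity(q, r, qn, rn)
  expect_true(all(abs(s$scores - 0.5) < 1e-12))
  expect_equal(s$declared_range, c(0, 1))
  q$cell_labels <- NULL
  expect_error(composition_similarity(q, r, qn, rn), "cell_labels")
})

test_that("label similarity is the outer equality indicator", {
  q <- make_toy_dataset(n_cells = 9, seed = 35)
  r <- make_toy_dataset(n_cells = 7, seed = 36)
  s <- label_similarity(q, r)
  oracle <- outer(q$cell_labels, r$cell_labels, "==") * 1
  expect_equal(unname(s$scores), unname(oracle))
  expect_true(all(s$scores %in% c(0, 1)))
})

test_that("the cost stack sums reciprocals without weighting", {
  mk_sim <- function(val, metric) {
    spatmatch:::new_similarity(metric,
      matrix(val, 2, 2, dimnames = list(c("q1", "q2"), c("r1", "r2"))),
      c(-1, 1))
  }
  stack <- build_cost_stack(list(feature = mk_sim(1, "feature"),
                                 niche = mk_sim(1, "niche")))
  expect_equal(unname(stack$total_cost), matrix(0, 2, 2))

  stack2 <- build_cost_stack(list(a = mk_sim(0, "feature"),
                                  b = mk_sim(0, "niche"),
                                  c = mk_sim(0, "territory")))
  expect_equal(unname(stack2$total_cost), matrix(3, 2, 2))

  stack3 <- build_cost_stack(list(feature = mk_sim(0.4, "feature"),
                                  label = mk_sim(1, "label")))
  expect_equal(unname(stack3$total_cost), matrix(0.6, 2, 2), tolerance = 1e-12)

  bad <- spatmatch:::new_similarity("feature", matrix(0, 3, 2), c(-1, 1))
  expect_error(build_cost_stack(list(bad, mk_sim(0, "niche"))), "dimensions")
  expect_error(build_cost_stack(list()), "at least one")

  # recomputing the total from the stored matrices reproduces it exactly
  total <- Reduce(`+`, lapply(stack3$matrices, function(m) 1 - m$scores))
  expect_equal(total, stack3$total_cost, tolerance = 1e-12)
})

test_that("candidate filtering matches the row-maximum rule", {
  scores <- matrix(c(0.95, 0.2, 0.5,
                     0.85, 0.3, 0.91,
                     0.1, 0.2, 0.3), 3, 3, byrow = TRUE,
                   dimnames = list(paste0("q", 1:3), paste0("r", 1:3)))
  sim <- spatmatch:::new_similarity("feature", scores, c(-1, 1))
  labels <- spatmatch:::new_similarity("label",
    matrix(c(1, 1, 1, 0, 0, 0, 1, 1, 1), 3, 3, byrow = TRUE,
           dimnames = dimnames(scores)), c(0, 1))
  stack <- build_cost_stack(list(feature = sim, label = labels))

  # threshold below every score removes nothing
  all_kept <- filter_candidates(stack, threshold = 0)
  expect_equal(all_kept$active_query, 1:3)

  # row-max oracle at 0.9: q3 has no score above threshold
  kept <- filter_candidates(stack, threshold = 0.9)
  expect_equal(kept$active_query, unname(which(apply(scores, 1, max) > 0.9)))

  # label filter drops query cells whose label matches nothing (q2)
  lab_kept <- filter_candidates(stack, threshold = NULL,
                                use_label_filter = TRUE)
  expect_equal(lab_kept$active_query, c(1L, 3L))

  expect_error(filter_candidates(stack, threshold = 0.99), "all query cells")
})

test_that("cost diagnostics report CV and normalized contributions", {
  mk_sim <- function(vals, metric, range = c(-1, 1)) {
    spatmatch:::new_similarity(metric,
      matrix(vals, 2, 2, dimnames = list(c("q1", "q2"), c("r1", "r2"))),
      range)
  }
  # contributions 0.3 and 0.1 -> POC 0.75 / 0.25
  stack <- build_cost_stack(list(a = mk_sim(0.7, "feature"),
                                 b = mk_sim(0.9, "niche")))
  mapping <- data.frame(query_barcode = c("q1", "q2"),
                        ref_barcode = c("r1", "r2"),
                        total_cost = 0.4, epoch = 1L)
  class(mapping) <- c("mapping_result", "data.frame")
  diag <- cost_diagnostics(stack, mapping)
  expect_equal(diag$mean_poc, c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(diag$cv, c(0, 0))  # constant matrices

  # single-metric stack: POC is 1 everywhere
  stack1 <- build_cost_stack(list(a = mk_sim(c(0.7, 0.2, 0.3, 0.5), "feature")))
  diag1 <- cost_diagnostics(stack1, mapping)
  expect_equal(diag1$mean_poc, 1)

  # POC rows sum to 1 whenever the total cost is positive
  poc <- poc_matrix(stack, mapping)
  expect_equal(unname(rowSums(poc)), c(1, 1), tolerance = 1e-9)
})

test_that("metric letter strings parse to the benchmark configurations", {
  expect_equal(parse_cost_config("fnct"),
               c("feature", "niche", "composition", "territory"))
  expect_equal(parse_cost_config("y"), "label")
  expect_error(parse_cost_config("fx"), "unknown")
  expect_error(parse_cost_config("ff"), "duplicate")
  cfgs <- cost_configurations()
  expect_length(cfgs, 14)
  expect_false(anyDuplicated(cfgs) > 0)
  for (cf in cfgs) expect_silent(parse_cost_config(cf))
})

test_that("similarity matrices respect their declared ranges on random data", {
  q <- make_toy_dataset(n_cells = 14, n_genes = 12, seed = 41, sample_id = "q")
  r <- make_toy_dataset(n_cells = 11, n_genes = 12, seed = 42, sample_id = "r")
  q <- normalize_counts(q); r <- normalize_counts(r)
  qn <- extract_niches(q, "knn", k = 3)
  rn <- extract_niches(r, "knn", k = 3)
  mats <- list(
    feature_similarity(cell_signal(q), cell_signal(r)),
    niche_similarity(niche_signal(qn, cell_signal(q)),
                     niche_signal(rn, cell_signal(r))),
    composition_similarity(q, r, qn, rn),
    label_similarity(q, r)
  )
  for (m in mats) {
    expect_true(all(m$scores >= m$declared_range[1] - 1e-12))
    expect_true(all(m$scores <= m$declared_range[2] + 1e-12))
    expect_false(anyNA(m$scores))
  }
})
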