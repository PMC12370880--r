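#' Configure a synthetic spatial regime
#'
#' Defines one of five ground-truth spatial regimes used for benchmarking
#' cell mapping. Each sample places \code{n_cells} uniform points in the unit
#' square and assigns them to a background and territory/layer regions by
#' geometry:
#' \describe{
#'   \item{circle}{5 circular territories of random size at random positions
#'     (overlaps allowed, latest-drawn wins); each contains 2 cell types; all
#'     5 territories are guaranteed present in every sample.}
#'   \item{layer}{1 circular territory divided into 5 concentric layers;
#'     background and each layer hold 2 cell types.}
#'   \item{dropped}{2 circular territories with 1-3 layers each (drawn per
#'     sample); background and each layer hold 1-2 cell types, so regions are
#'     not necessarily shared across samples.}
#'   \item{random_one, random_two}{1-3 territories of random shape (circle,
#'     rod, or chaos map) with 0-4 layers; regions hold at most one
#'     (random_one) or at most two (random_two) cell types.}
#' }
#' Counts are drawn from a gamma-Poisson (negative binomial) model shared per
#' cell type across all of a regime's samples. Differential expression
#' between territory-scale populations occurs with probability
#' \code{de_prob_territory} and between layers (and types within a layer)
#' with probability \code{de_prob_layer}.
#'
#' @param regime one of \code{"circle"}, \code{"layer"}, \code{"dropped"},
#'   \code{"random_one"}, \code{"random_two"}.
#' @param n_samples samples per regime (default 12).
#' @param n_cells cells per sample (default 5000).
#' @param n_genes genes (default 2000).
#' @param de_prob_territory probability a gene is differentially expressed
#'   between territory-scale cell populations (default 0.5).
#' @param de_prob_layer probability of differential expression between layers
#'   and between types within a layer (default 0.05).
#' @param seed integer seed; all layouts and counts derive from it.
#' @param radius_range circle radius range as a fraction of the unit square.
#' @param dispersion gamma-Poisson dispersion (default 0.3).
#' @param mean_meanlog,mean_sdlog log-normal parameters of the per-gene
#'   baseline means (defaults log(0.5) and 1).
#' @param de_fold_sdlog log-normal sd of differential fold-changes (default 0.5).
#' @param interaction_k neighbors used for interaction labels (default 6).
#' @return A \code{regime_config} list.
#' @export
regime_config <- function(regime = c("circle", "layer", "dropped",
                                     "random_one", "random_two"),
                          n_samples = 12, n_cells = 5000, n_genes = 2000,
                          de_prob_territory = 0.5, de_prob_layer = 0.05,
                          seed = 1, radius_range = c(0.05, 0.2),
                          dispersion = 0.3, mean_meanlog = log(0.5),
                          mean_sdlog = 1, de_fold_sdlog = 0.5,
                          interaction_k = 6) {
  regime <- match.arg(regime)
  stopifnot(n_samples >= 1, n_cells >= 1, n_genes >= 1,
            de_prob_territory >= 0, de_prob_territory <= 1,
            de_prob_layer >= 0, de_prob_layer <= 1)
  structure(list(regime = regime, n_samples = n_samples, n_cells = n_cells,
                 n_genes = n_genes, de_prob_territory = de_prob_territory,
                 de_prob_layer = de_prob_layer, seed = as.integer(seed),
                 radius_range = radius_range, dispersion = dispersion,
                 mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
                 de_fold_sdlog = de_fold_sdlog, interaction_k = interaction_k),
            class = "regime_config")
}

# deterministic per-sample sub-seed, kept inside 32-bit integer range
layout_seed <- function(seed, sample_index, salt = 0L) {
  as.integer((as.numeric(seed) * 7919 + sample_index * 131071 + salt) %%
               2147483647)
}

#' Shared cell-type count models for a regime
#'
#' Builds the full cell-type vocabulary of the regime and one gamma-Poisson
#' model per type: per-gene baseline means drawn log-normal, multiplied by
#' fold-changes that differ from 1 only at genes selected as differentially
#' expressed for that type. Territory-scale fold-changes are drawn with
#' probability \code{de_prob_territory}; layer-scale and within-layer
#' fold-changes with probability \code{de_prob_layer}, composed
#' multiplicatively. Models are deterministic given the config seed and are
#' reused by every sample of the regime, so cells of the same type are
#' exchangeable across samples.
#'
#' @param cfg a \code{regime_config}.
#' @return List with \code{baseline} (per-gene means) and \code{folds}
#'   (genes x types fold-change matrix).
#' @export
build_type_models <- function(cfg) {
  vocab <- regime_vocabulary(cfg$regime)
  withr::with_seed(layout_seed(cfg$seed, 0L), {
    baseline <- rlnorm(cfg$n_genes, cfg$mean_meanlog, cfg$mean_sdlog)
    draw_fold <- function(p) {
      de <- runif(cfg$n_genes) < p
      fold <- rep(1, cfg$n_genes)
      fold[de] <- rlnorm(sum(de), 0, cfg$de_fold_sdlog)
      fold
    }
    folds <- matrix(1, cfg$n_genes, length(vocab$types),
                    dimnames = list(paste0("gene_", seq_len(cfg$n_genes)),
                                    vocab$types))
    for (grp in unique(vocab$territory_group)) {
      grp_fold <- if (grp == "baseline") rep(1, cfg$n_genes)
                  else draw_fold(cfg$de_prob_territory)
      members <- vocab$types[vocab$territory_group == grp]
      for (ty in members) folds[, ty] <- grp_fold
    }
    for (grp in unique(vocab$layer_group)) {
      if (is.na(grp)) next
      members <- vocab$types[!is.na(vocab$layer_group) &
                               vocab$layer_group == grp]
      layer_fold <- draw_fold(cfg$de_prob_layer)
      for (ty in members) folds[, ty] <- folds[, ty] * layer_fold
    }
    for (ty in vocab$types[vocab$within_scale == "territory"]) {
      folds[, ty] <- folds[, ty] * draw_fold(cfg$de_prob_territory)
    }
    for (ty in vocab$types[vocab$within_scale == "layer"]) {
      folds[, ty] <- folds[, ty] * draw_fold(cfg$de_prob_layer)
    }
  })
  list(baseline = baseline, folds = folds, types = vocab$types)
}

# Full cell-type vocabulary per regime with the grouping used to compose
# fold-changes: territory_group shares a territory-scale fold, layer_group a
# layer-scale fold, within_scale sets the DE probability of the type's own
# fold ("territory" = de_prob_territory, "layer" = de_prob_layer,
# "none" = no extra fold).
regime_vocabulary <- function(regime) {
  mk <- function(types, territory_group, layer_group, within_scale) {
    data.frame(types = types, territory_group = territory_group,
               layer_group = layer_group, within_scale = within_scale,
               stringsAsFactors = FALSE)
  }
  v <- switch(regime,
    circle = {
      ty <- c("bg", paste0("circle_", rep(1:5, each = 2), "_", c("A", "B")))
      mk(ty,
         territory_group = c("baseline", rep("baseline", 10)),
         layer_group = NA_character_,
         within_scale = c("none", rep("territory", 10)))
    },
    layer = {
      ty <- c("bg_A", "bg_B",
              paste0("layer_", rep(1:5, each = 2), "_", c("A", "B")))
      mk(ty,
         territory_group = c("bg", "bg", rep("circle_1", 10)),
         layer_group = c(NA, NA, paste0("layer_", rep(1:5, each = 2))),
         within_scale = c("territory", "territory", rep("layer", 10)))
    },
    dropped = {
      ty <- c("bg_A", "bg_B")
      tg <- c("bg", "bg")
      lg <- c(NA_character_, NA_character_)
      for (ter in 1:2) for (l in 1:3) {
        ty <- c(ty, paste0("ter", ter, "_layer", l, "_", c("A", "B")))
        tg <- c(tg, rep(paste0("ter", ter), 2))
        lg <- c(lg, rep(paste0("ter", ter, "_layer", l), 2))
      }
      mk(ty, tg, lg,
         within_scale = c("territory", "territory",
                          rep("layer", length(ty) - 2)))
    },
    {
      # random_one / random_two share a vocabulary: up to 3 territories,
      # layers 0-4 (0 = undivided), up to 2 types per region
      ty <- c("bg_A", "bg_B")
      tg <- c("bg", "bg")
      lg <- c(NA_character_, NA_character_)
      for (ter in 1:3) for (l in 0:4) {
        ty <- c(ty, paste0("ter", ter, "_layer", l, "_", c("A", "B")))
        tg <- c(tg, rep(paste0("ter", ter), 2))
        lg <- c(lg, rep(paste0("ter", ter, "_layer", l), 2))
      }
      mk(ty, tg, lg,
         within_scale = c("territory", "territory",
                          rep("layer", length(ty) - 2)))
    }
  )
  v
}

#' Generate the spatial layout of one synthetic sample
#'
#' Places \code{n_cells} uniform points in the unit square and assigns
#' territory, layer and cell-type labels according to the regime geometry.
#' Overlapping territories resolve membership in favor of the latest-drawn
#' territory. The circle regime redraws its geometry until all 5 territories
#' contain at least one cell.
#'
#' @param cfg a \code{regime_config}.
#' @param sample_index sample number (1-based); layouts are deterministic
#'   given \code{cfg$seed} and the index.
#' @return data frame with columns \code{barcode}, \code{x}, \code{y},
#'   \code{territory}, \code{cell_labels}.
#' @export
generate_layout <- function(cfg, sample_index) {
  withr::with_seed(layout_seed(cfg$seed, sample_index), {
    n <- cfg$n_cells
    xy <- cbind(x = runif(n), y = runif(n))
    territory <- rep("background", n)
    cell_labels <- rep(NA_character_, n)
    rr <- cfg$radius_range
    draw_circle <- function() {
      r <- runif(1, rr[1], rr[2])
      c(cx = runif(1, r, 1 - r), cy = runif(1, r, 1 - r), r = r)
    }
    assign_two_types <- function(idx, names2) {
      sample(names2, length(idx), replace = TRUE)
    }
    if (cfg$regime == "circle") {
      for (try in 1:200) {
        territory <- rep("background", n)
        circles <- replicate(5, draw_circle())
        for (k in 1:5) {
          d2 <- (xy[, 1] - circles["cx", k])^2 + (xy[, 2] - circles["cy", k])^2
          territory[d2 <= circles["r", k]^2] <- paste0("circle_", k)
        }
        if (all(paste0("circle_", 1:5) %in% territory)) break
      }
      cell_labels <- rep("bg", n)
      for (k in 1:5) {
        idx <- which(territory == paste0("circle_", k))
        cell_labels[idx] <-
          assign_two_types(idx, paste0("circle_", k, "_", c("A", "B")))
      }
    } else if (cfg$regime == "layer") {
      r <- runif(1, 0.25, 0.4)
      cx <- runif(1, r, 1 - r); cy <- runif(1, r, 1 - r)
      d <- sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2)
      inside <- d <= r
      territory[inside] <- "circle_1"
      layer <- pmin(ceiling(d / r * 5), 5)
      cell_labels <- assign_two_types(seq_len(n), c("bg_A", "bg_B"))
      for (l in 1:5) {
        idx <- which(inside & layer == l)
        cell_labels[idx] <-
          assign_two_types(idx, paste0("layer_", l, "_", c("A", "B")))
      }
    } else if (cfg$regime == "dropped") {
      cell_labels <- character(n)
      bg_types <- paste0("bg_", head(c("A", "B"), sample(1:2, 1)))
      lay <- rep(NA_integer_, n)
      circles <- replicate(2, draw_circle())
      n_layers <- sample(1:3, 2, replace = TRUE)
      for (ter in 1:2) {
        d <- sqrt((xy[, 1] - circles["cx", ter])^2 +
                    (xy[, 2] - circles["cy", ter])^2)
        inside <- d <= circles["r", ter]
        territory[inside] <- paste0("ter", ter)
        lay[inside] <- pmin(ceiling(d[inside] / circles["r", ter] *
                                      n_layers[ter]), n_layers[ter])
      }
      cell_labels <- sample(bg_types, n, replace = TRUE)
      for (ter in 1:2) for (l in seq_len(n_layers[ter])) {
        idx <- which(territory == paste0("ter", ter) & lay == l)
        if (!length(idx)) next
        types <- paste0("ter", ter, "_layer", l, "_",
                        head(c("A", "B"), sample(1:2, 1)))
        cell_labels[idx] <- sample(types, length(idx), replace = TRUE)
      }
    } else {
      # random_one / random_two
      max_types <- if (cfg$regime == "random_one") 1L else 2L
      n_ter <- sample(1:3, 1)
      n_bg_types <- if (max_types == 1L) 1L else sample(1:2, 1)
      cell_labels <- sample(paste0("bg_", head(c("A", "B"), n_bg_types)),
                            n, replace = TRUE)
      lay <- rep(NA_integer_, n)
      for (ter in seq_len(n_ter)) {
        shape <- sample(c("circle", "rod", "chaos"), 1)
        n_layers <- sample(0:4, 1)
        memb <- territory_membership(xy, shape, rr)
        inside <- memb$inside
        if (!any(inside)) next
        territory[inside] <- paste0("ter", ter)
        if (n_layers > 0) {
          band <- pmin(ceiling(memb$depth[inside] * n_layers), n_layers)
          band[band < 1] <- 1L
          lay[inside] <- band
        } else {
          lay[inside] <- 0L
        }
        for (l in unique(lay[inside])) {
          idx <- which(territory == paste0("ter", ter) & lay == l)
          k_types <- if (max_types == 1L) 1L else sample(1:2, 1)
          types <- paste0("ter", ter, "_layer", l, "_",
                          head(c("A", "B"), k_types))
          cell_labels[idx] <- sample(types, length(idx), replace = TRUE)
        }
      }
    }
    data.frame(barcode = sprintf("cell_%04d_%05d", sample_index, seq_len(n)),
               x = xy[, 1], y = xy[, 2],
               territory = territory, cell_labels = cell_labels,
               stringsAsFactors = FALSE)
  })
}

# Membership test for the random-regime shapes. Returns a logical `inside`
# vector and a `depth` in [0, 1] (relative distance from the shape core,
# used to carve layers).
territory_membership <- function(xy, shape, radius_range) {
  n <- nrow(xy)
  if (shape == "circle") {
    r <- runif(1, radius_range[1], radius_range[2])
    cx <- runif(1, r, 1 - r); cy <- runif(1, r, 1 - r)
    d <- sqrt((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2)
    list(inside = d <= r, depth = pmin(d / r, 1))
  } else if (shape == "rod") {
    # capsule: segment of random orientation with semicircular caps
    half_len <- runif(1, 0.1, 0.25)
    width <- runif(1, 0.03, 0.08)
    theta <- runif(1, 0, pi)
    cx <- runif(1, 0.25, 0.75); cy <- runif(1, 0.25, 0.75)
    ax <- cx - half_len * cos(theta); ay <- cy - half_len * sin(theta)
    bx <- cx + half_len * cos(theta); by <- cy + half_len * sin(theta)
    vx <- bx - ax; vy <- by - ay
    tt <- pmin(pmax(((xy[, 1] - ax) * vx + (xy[, 2] - ay) * vy) /
                      (vx^2 + vy^2), 0), 1)
    px <- ax + tt * vx; py <- ay + tt * vy
    d <- sqrt((xy[, 1] - px)^2 + (xy[, 2] - py)^2)
    list(inside = d <= width, depth = pmin(d / width, 1))
  } else {
    # chaos map: bounded Clifford-type quadratic attractor scaled into a
    # random sub-box; membership = proximity to the attractor point cloud
    a <- -1.4; b <- 1.6; cc <- 1.0; dd <- 0.7
    m <- 1500L
    pts <- matrix(0, m, 2)
    x <- 0.1; y <- 0
    for (i in seq_len(m + 100L)) {
      xn <- sin(a * y) + cc * cos(a * x)
      yn <- sin(b * x) + dd * cos(b * y)
      x <- xn; y <- yn
      if (i > 100L) pts[i - 100L, ] <- c(x, y)
    }
    size <- runif(1, 0.3, 0.5)
    ox <- runif(1, 0, 1 - size); oy <- runif(1, 0, 1 - size)
    for (j in 1:2) {
      rng <- range(pts[, j])
      pts[, j] <- (pts[, j] - rng[1]) / diff(rng) * size +
        if (j == 1) ox else oy
    }
    eps <- 0.025
    nn <- RANN::nn2(pts, xy, k = 1)
    d <- nn$nn.dists[, 1]
    list(inside = d <= eps, depth = pmin(d / eps, 1))
  }
}

#' Simulate counts for one layout
#'
#' Draws a genes x cells integer count matrix from the regime's shared
#' gamma-Poisson cell-type models: for a cell of type t, gene g has mean
#' \code{baseline[g] * fold[g, t]} and dispersion \code{cfg$dispersion}.
#'
#' @param layout a layout data frame from \code{\link{generate_layout}}.
#' @param models shared models from \code{\link{build_type_models}}.
#' @param cfg the \code{regime_config}.
#' @param seed RNG seed for the draw.
#' @return genes x cells integer matrix with gene and barcode dimnames.
#' @export
simulate_counts <- function(layout, models, cfg, seed = 1L) {
  ng <- cfg$n_genes
  nc <- nrow(layout)
  counts <- matrix(0L, ng, nc,
                   dimnames = list(rownames(models$folds), layout$barcode))
  shape <- 1 / cfg$dispersion
  withr::with_seed(seed, {
    for (ty in unique(layout$cell_labels)) {
      idx <- which(layout$cell_labels == ty)
      if (!ty %in% colnames(models$folds)) {
        stop("no count model for cell type ", ty)
      }
      mu <- models$baseline * models$folds[, ty]
      lam <- matrix(rgamma(ng * length(idx), shape = shape,
                           scale = mu * cfg$dispersion),
                    nrow = ng)
      counts[, idx] <- rpois(ng * length(idx), lam)
    }
  })
  storage.mode(counts) <- "integer"
  counts
}

#' Add k-nearest-neighbor interaction labels
#'
#' Concatenates the cell-type labels of each cell's k nearest neighbors into
#' an "interaction" label, with labels sorted lexicographically and joined by
#' \code{@} so the label is invariant to neighbor discovery order.
#'
#' @param d a \code{spatial_dataset} with \code{cell_labels}.
#' @param k neighbors to use (default 6).
#' @return \code{d} with \code{interaction_labels} set.
#' @export
add_interactions <- function(d, k = 6) {
  if (is.null(d$cell_labels)) stop("cell_labels are required")
  xy <- as.matrix(d$coords[, c("x", "y")])
  idx <- knn_indices(xy, k)
  d$interaction_labels <- vapply(seq_len(nrow(idx)), function(i) {
    paste(sort(d$cell_labels[idx[i, ]]), collapse = "@")
  }, character(1))
  d
}

#' Generate all samples of a synthetic regime
#'
#' Builds the shared cell-type models, then generates each sample's layout,
#' counts, and interaction labels. Fully deterministic given
#' \code{cfg$seed}.
#'
#' @param cfg a \code{regime_config}.
#' @param add_interaction_labels add k-NN interaction labels (default TRUE).
#' @return List of \code{spatial_dataset}s of length \code{cfg$n_samples}.
#' @export
simulate_regime <- function(cfg, add_interaction_labels = TRUE) {
  models <- build_type_models(cfg)
  lapply(seq_len(cfg$n_samples), function(s) {
    layout <- generate_layout(cfg, s)
    counts <- simulate_counts(layout, models, cfg,
                              seed = layout_seed(cfg$seed, s, salt = 1L))
    d <- spatial_dataset(counts, layout[, c("barcode", "x", "y")],
                         sample_id = paste0(cfg$regime, "_", s),
                         cell_labels = layout$cell_labels,
                         territory_labels = layout$territory)
    if (add_interaction_labels) d <- add_interactions(d, k = cfg$interaction_k)
    d
  })
}
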