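#' Construct a spatial dataset
#'
#' A \code{spatial_dataset} bundles a genes-by-cells count matrix with per-cell
#' 2-D coordinates and optional label tracks for one sample. Coordinates are
#' treated as continuous points; no grid is assumed, so spot-, bin- and
#' cell-resolved assays are all handled the same way.
#'
#' @param counts genes x cells non-negative matrix (dense or \code{dgCMatrix})
#'   with gene identifiers as rownames and cell barcodes as colnames.
#' @param coords data frame with columns \code{barcode}, \code{x}, \code{y},
#'   one row per cell.
#' @param sample_id character scalar identifying the sample.
#' @param cell_labels,territory_labels,interaction_labels optional per-cell
#'   character vectors, named by barcode or in barcode order.
#' @param normalized optional genes x cells normalized matrix.
#' @return An object of class \code{spatial_dataset}.
#' @export
spatial_dataset <- function(counts, coords, sample_id = "sample",
                            cell_labels = NULL, territory_labels = NULL,
                            interaction_labels = NULL, normalized = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene rownames and barcode colnames")
  }
  coords <- as.data.frame(coords)
  if (!all(c("barcode", "x", "y") %in% names(coords))) {
    stop("coords must have columns barcode, x, y")
  }
  coords$barcode <- as.character(coords$barcode)
  dup <- coords$barcode[duplicated(coords$barcode)]
  if (length(dup)) {
    stop("duplicate barcodes in cell table: ", paste(head(dup, 5), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate barcodes in counts: ",
         paste(head(colnames(counts)[duplicated(colnames(counts))], 5), collapse = ", "))
  }
  missing_in_counts <- setdiff(coords$barcode, colnames(counts))
  if (length(missing_in_counts)) {
    stop("barcodes in cell table but not in counts: ",
         paste(head(missing_in_counts, 5), collapse = ", "))
  }
  missing_in_cells <- setdiff(colnames(counts), coords$barcode)
  if (length(missing_in_cells)) {
    stop("barcodes in counts but not in cell table: ",
         paste(head(missing_in_cells, 5), collapse = ", "))
  }
  if (!is.numeric(coords$x) || !is.numeric(coords$y) ||
      anyNA(coords$x) || anyNA(coords$y)) {
    stop("coordinates must be numeric with no missing values")
  }
  # reconcile order by identifier, never by position
  counts <- counts[, coords$barcode, drop = FALSE]
  if (min(counts) < 0) stop("counts must be non-negative")
  n <- nrow(coords)
  align_track <- function(track, what) {
    if (is.null(track)) return(NULL)
    if (!is.null(names(track))) {
      miss <- setdiff(coords$barcode, names(track))
      if (length(miss)) stop(what, " missing for barcodes: ",
                             paste(head(miss, 5), collapse = ", "))
      track <- track[coords$barcode]
    } else if (length(track) != n) {
      stop(what, " must have one entry per cell")
    }
    as.character(unname(track))
  }
  obj <- list(
    sample_id = as.character(sample_id),
    barcodes = coords$barcode,
    coords = coords[, c("barcode", "x", "y")],
    counts = counts,
    normalized = normalized,
    cell_labels = align_track(cell_labels, "cell_labels"),
    territory_labels = align_track(territory_labels, "territory_labels"),
    interaction_labels = align_track(interaction_labels, "interaction_labels")
  )
  class(obj) <- "spatial_dataset"
  obj
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset '", x$sample_id, "': ", nrow(x$counts), " genes x ",
      length(x$barcodes), " cells\n", sep = "")
  tracks <- c(normalized = !is.null(x$normalized),
              cell_labels = !is.null(x$cell_labels),
              territory_labels = !is.null(x$territory_labels),
              interaction_labels = !is.null(x$interaction_labels))
  cat("  tracks:", if (any(tracks)) paste(names(tracks)[tracks], collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Number of cells in a spatial dataset
#' @param d a \code{spatial_dataset}.
#' @return integer cell count.
#' @export
n_cells <- function(d) length(d$barcodes)

#' Load a spatial dataset from disk
#'
#' Reads a genes x cells count matrix either from MatrixMarket coordinate
#' format (with one-identifier-per-line gene and barcode sidecar files) or
#' from dense delimited text (header row of barcodes, first column of gene
#' identifiers), together with a cell table holding \code{barcode}, \code{x},
#' \code{y} and optional \code{cell_labels}, \code{territory},
#' \code{interactions} and \code{sample} columns. Rows are reconciled by
#' barcode, not by position.
#'
#' @param counts_path path to the count matrix (\code{.mtx} or delimited text).
#' @param cells_path path to the cell table (comma/tab/whitespace delimited,
#'   with header).
#' @param genes_path,barcodes_path sidecar files for MTX input; default to
#'   \code{genes.tsv} / \code{barcodes.tsv} next to the matrix.
#' @param sample_id sample identifier; defaults to the cell table's
#'   \code{sample} column (if unique) or the counts file stem.
#' @param rescale_coords if \code{TRUE}, translate coordinates so the minimum
#'   x and y both equal 1. Off by default; mapping is translation invariant,
#'   only radius-based niches are affected.
#' @return A validated \code{spatial_dataset}.
#' @export
load_spatial_dataset <- function(counts_path, cells_path,
                                 genes_path = NULL, barcodes_path = NULL,
                                 sample_id = NULL, rescale_coords = FALSE) {
  if (grepl("\\.mtx$", counts_path, ignore.case = TRUE)) {
    counts <- Matrix::readMM(counts_path)
    counts <- methods::as(counts, "CsparseMatrix")
    dir <- dirname(counts_path)
    genes_path <- genes_path %||% file.path(dir, "genes.tsv")
    barcodes_path <- barcodes_path %||% file.path(dir, "barcodes.tsv")
    rownames(counts) <- readLines(genes_path)
    colnames(counts) <- readLines(barcodes_path)
  } else {
    sep <- if (grepl("\\.csv$", counts_path, ignore.case = TRUE)) "," else "\t"
    tab <- read.table(counts_path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE)
    counts <- as.matrix(tab)
    if (!is.numeric(counts)) stop("non-numeric entries in count matrix")
  }
  cells <- read.table(cells_path, header = TRUE,
                      sep = detect_sep(cells_path), check.names = FALSE,
                      stringsAsFactors = FALSE)
  if (!all(c("barcode", "x", "y") %in% names(cells))) {
    stop("cell table must have columns barcode, x, y")
  }
  if (!is.numeric(cells$x) || !is.numeric(cells$y)) {
    stop("non-numeric coordinates in cell table")
  }
  if (is.null(sample_id)) {
    if ("sample" %in% names(cells) && length(unique(cells$sample)) == 1L) {
      sample_id <- as.character(cells$sample[1])
    } else {
      sample_id <- sub("\\.[^.]+$", "", basename(counts_path))
    }
  }
  if (rescale_coords) {
    cells$x <- cells$x - min(cells$x) + 1
    cells$y <- cells$y - min(cells$y) + 1
  }
  grab <- function(col) if (col %in% names(cells)) as.character(cells[[col]]) else NULL
  spatial_dataset(
    counts = counts, coords = cells, sample_id = sample_id,
    cell_labels = grab("cell_labels"),
    territory_labels = grab("territory"),
    interaction_labels = grab("interactions")
  )
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
}

#' Write a spatial dataset to disk
#'
#' Writes the counts as MatrixMarket coordinate format with \code{genes.tsv}
#' and \code{barcodes.tsv} sidecars (or as dense delimited text) plus a
#' \code{cells.tsv} table containing barcode, x, y, sample and any label
#' tracks, matching the 6-column export schema of the synthetic generator.
#'
#' @param d a \code{spatial_dataset}.
#' @param dir output directory (created if needed).
#' @param format \code{"mtx"} (default) or \code{"csv"} for dense text.
#' @return Invisibly, the paths written.
#' @export
write_spatial_dataset <- function(d, dir, format = c("mtx", "csv")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (format == "mtx") {
    counts_path <- file.path(dir, "counts.mtx")
    Matrix::writeMM(methods::as(methods::as(d$counts, "dMatrix"), "CsparseMatrix"),
                    counts_path)
    writeLines(rownames(d$counts), file.path(dir, "genes.tsv"))
    writeLines(colnames(d$counts), file.path(dir, "barcodes.tsv"))
  } else {
    counts_path <- file.path(dir, "counts.csv")
    tab <- as.data.frame(as.matrix(d$counts), check.names = FALSE)
    write.table(cbind(gene = rownames(d$counts), tab), counts_path,
                sep = ",", quote = FALSE, row.names = FALSE)
  }
  cells <- d$coords
  cells$sample <- d$sample_id
  if (!is.null(d$cell_labels)) cells$cell_labels <- d$cell_labels
  if (!is.null(d$territory_labels)) cells$territory <- d$territory_labels
  if (!is.null(d$interaction_labels)) cells$interactions <- d$interaction_labels
  cells_path <- file.path(dir, "cells.tsv")
  write.table(cells, cells_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts = counts_path, cells = cells_path))
}

#' Write a mapping result as a delimited table
#'
#' One row per retained cell pair with columns \code{query_barcode},
#' \code{ref_barcode}, \code{total_cost}, \code{epoch} and one score column
#' per similarity metric in the cost stack. The file round-trips through
#' \code{\link{read_mapping}} losslessly.
#'
#' @param result a \code{mapping_result}.
#' @param path output path (TSV).
#' @export
write_mapping <- function(result, path) {
  if (!inherits(result, "mapping_result")) stop("result must be a mapping_result")
  if (nrow(result) == 0L) stop("cannot write an empty mapping result")
  write.table(as.data.frame(result), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a mapping result written by \code{write_mapping}
#' @param path path to the TSV file.
#' @return A \code{mapping_result} data frame.
#' @export
read_mapping <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(tab) <- c("mapping_result", "data.frame")
  tab
}
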