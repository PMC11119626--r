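#' Construct an expression matrix
#'
#' The central data container: a numeric genes x spots matrix with gene
#' identifiers as row names, spot barcodes as column names, and a processing
#' `stage` attribute tracking where the object sits in the preprocessing
#' chain (`raw_counts` -> `normalized` -> `log` -> `centralized`).
#'
#' @param values numeric matrix, genes in rows, spots in columns; must carry
#'   unique, non-empty row and column names.
#' @param stage processing stage, one of `"raw_counts"`, `"normalized"`,
#'   `"log"`, `"centralized"`.
#' @return a matrix of class `expr_matrix` with a `stage` attribute.
#' @export
expression_matrix <- function(values, stage = c("raw_counts", "normalized",
                                                "log", "centralized")) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop2("`values` must be a numeric matrix")
  gene_ids <- rownames(values)
  barcodes <- colnames(values)
  if (is.null(gene_ids) || is.null(barcodes))
    stop2("`values` must have gene row names and spot barcode column names")
  if (anyDuplicated(gene_ids))
    stop2("duplicate gene ids: %s",
          paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (anyDuplicated(barcodes))
    stop2("duplicate spot barcodes: %s",
          paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  if (stage == "raw_counts") {
    if (any(values < 0) || any(values != round(values)))
      stop2("stage 'raw_counts' requires non-negative integer values")
  }
  structure(values, stage = stage, class = c("expr_matrix", class(values)))
}

#' Processing stage of an expression matrix
#' @param x an `expr_matrix`.
#' @return the stage string.
#' @export
expr_stage <- function(x) {
  s <- attr(x, "stage")
  if (is.null(s)) stop2("not an expression matrix: no stage attribute")
  s
}

# Rebuild the class/stage decoration after a plain-matrix operation.
restage <- function(values, stage) expression_matrix(values, stage)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d spots, stage=%s\n",
              nrow(x), ncol(x), expr_stage(x)))
  invisible(x)
}

#' Construct a spatial layout
#'
#' Per-spot positions on the Visium hexagonal array. `array_row`/`array_col`
#' follow the Space Ranger convention where column indices share the parity
#' of their row (a "doubled-width" hex coordinate system); `pixel_x`/
#' `pixel_y` are full-resolution image coordinates.
#'
#' @param barcode character vector of unique spot barcodes.
#' @param in_tissue logical, whether the spot overlaps tissue.
#' @param array_row,array_col non-negative integer array coordinates.
#' @param pixel_x,pixel_y numeric image coordinates.
#' @return a `spatial_layout` data frame.
#' @export
spatial_layout <- function(barcode, in_tissue, array_row, array_col,
                           pixel_x, pixel_y) {
  if (anyDuplicated(barcode))
    stop2("duplicate barcodes in layout")
  if (any(array_row < 0) || any(array_col < 0))
    stop2("array coordinates must be non-negative")
  df <- data.frame(barcode = as.character(barcode),
                   in_tissue = as.logical(in_tissue),
                   array_row = as.integer(array_row),
                   array_col = as.integer(array_col),
                   pixel_x = as.numeric(pixel_x),
                   pixel_y = as.numeric(pixel_y),
                   stringsAsFactors = FALSE)
  key <- paste(df$array_row, df$array_col)[df$in_tissue]
  if (anyDuplicated(key))
    stop2("duplicate (array_row, array_col) among in-tissue spots")
  class(df) <- c("spatial_layout", "data.frame")
  df
}

#' Construct spot labels
#'
#' User-supplied per-spot cluster or cell-type assignments (e.g. Louvain
#' clusters exported from a Seurat preprocessing run). Labels are an input
#' to this package, never computed by it.
#'
#' @param barcode character vector of spot barcodes (unique).
#' @param label character vector of labels, same length.
#' @param kind `"cluster"` or `"cell_type"`.
#' @return a `spot_labels` data frame.
#' @export
spot_labels <- function(barcode, label, kind = c("cluster", "cell_type")) {
  kind <- match.arg(kind)
  if (length(barcode) != length(label))
    stop2("barcode and label lengths differ")
  if (anyDuplicated(barcode))
    stop2("a barcode appears more than once in the labels")
  df <- data.frame(barcode = as.character(barcode),
                   label = as.character(label), stringsAsFactors = FALSE)
  attr(df, "kind") <- kind
  class(df) <- c("spot_labels", "data.frame")
  df
}

#' Construct a gene set collection
#'
#' @param sets named list; each element a character vector of gene ids
#'   (non-empty). Names are the set names and must be unique.
#' @param category optional character vector (recycled) tagging each set.
#' @return a `gene_set_collection`: named list of character vectors with a
#'   `category` attribute.
#' @export
gene_set_collection <- function(sets, category = "uncategorized") {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop2("every gene set must be named")
  if (anyDuplicated(names(sets)))
    stop2("duplicate gene set name: %s",
          paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0))
    stop2("empty gene set: %s",
          paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  sets <- lapply(sets, as.character)
  attr(sets, "category") <- rep_len(as.character(category), length(sets))
  class(sets) <- "gene_set_collection"
  sets
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}
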