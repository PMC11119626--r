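# Module extraction from the SOM landscape.
#
# A module is a connected region of grid units (8-neighbourhood) together
# with the genes assigned to those units. The six selection modes mirror
# the map-browser options: single-spot overexpression, group
# overexpression, underexpression, k-means, correlation clustering and
# distance-map (U-matrix) segmentation.

# Connected components of a logical grid mask under 8-neighbourhood.
# Returns an integer matrix of component ids (0 = outside mask).
grid_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  next_id <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || comp[r0, c0] != 0L) next
    next_id <- next_id + 1L
    queue <- matrix(c(r0, c0), ncol = 2)
    comp[r0, c0] <- next_id
    while (nrow(queue) > 0) {
      r <- queue[1, 1]; cc <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; ccc <- cc + dc
        if (rr < 1 || rr > nr || ccc < 1 || ccc > nc) next
        if (mask[rr, ccc] && comp[rr, ccc] == 0L) {
          comp[rr, ccc] <- next_id
          queue <- rbind(queue, c(rr, ccc))
        }
      }
    }
  }
  comp
}

# Deterministic module labels: A, B, ... then A1, A2, ... past 26.
module_labels <- function(n) {
  if (n <= 26) LETTERS[seq_len(n)]
  else c(LETTERS, paste0(rep(LETTERS, each = 26), rep(1:26, times = 26)))[seq_len(n)]
}

# Assemble a module_set from an id grid. Components are ordered by
# decreasing unit count, then by top-left-most unit (row-major scan).
modules_from_components <- function(comp, model, method, min_units = 1L) {
  ids <- setdiff(sort(unique(as.vector(comp))), 0L)
  units_by_id <- lapply(ids, function(i) {
    w <- which(comp == i, arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    colnames(w) <- c("row", "col")
    w
  })
  keep <- vapply(units_by_id, nrow, integer(1)) >= min_units
  units_by_id <- units_by_id[keep]
  first_seen <- vapply(units_by_id, function(u)
    unit_index(u[1, "row"], u[1, "col"], ncol(comp)), numeric(1))
  ord <- order(-vapply(units_by_id, nrow, integer(1)), first_seen)
  units_by_id <- units_by_id[ord]
  labels <- module_labels(length(units_by_id))
  modules <- lapply(seq_along(units_by_id), function(i) {
    units <- units_by_id[[i]]
    key <- unit_index(units[, "row"], units[, "col"], model$grid_cols)
    gene_key <- unit_index(model$assignment[, "row"],
                           model$assignment[, "col"], model$grid_cols)
    list(label = labels[[i]], units = units,
         gene_ids = model$gene_ids[gene_key %in% key])
  })
  names(modules) <- labels
  structure(list(modules = modules, method = method,
                 grid_rows = model$grid_rows, grid_cols = model$grid_cols),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> method=%s, %d module(s)\n",
              x$method, length(x$modules)))
  for (m in x$modules)
    cat(sprintf("  %s: %d units, %d genes\n",
                m$label, nrow(m$units), length(m$gene_ids)))
  invisible(x)
}

#' Overexpression (or underexpression) modules from portraits
#'
#' For each portrait, units above that portrait's `threshold_quantile`
#' quantile are marked ("red spots"); the marks are unioned across
#' portraits and 8-connected components of at least `min_units` units
#' become modules, labelled A, B, ... in decreasing size. Gene lists come
#' from the model's gene-to-unit assignment. With `sign = -1` the selection
#' flips to the low tail, giving underexpression modules.
#'
#' @param model a `som_model`.
#' @param portraits list of `som_portrait`s on the model's grid (typically
#'   group-mean portraits, one per spot cluster; single-spot portraits give
#'   the single-spot-overexpression mode).
#' @param threshold_quantile per-portrait quantile defining "high"
#'   (default 0.9).
#' @param min_units minimum component size (default 4).
#' @param sign +1 for overexpression (default), -1 for underexpression.
#' @param method method tag stored on the result.
#' @return a `module_set`; empty if no unit passes the threshold.
#' @export
overexpression_modules <- function(model, portraits, threshold_quantile = 0.9,
                                   min_units = 4L, sign = 1,
                                   method = "group_overexpression") {
  if (threshold_quantile <= 0 || threshold_quantile >= 1)
    stop2("threshold_quantile must lie strictly between 0 and 1")
  if (inherits(portraits, "som_portrait")) portraits <- list(portraits)
  mask <- matrix(FALSE, model$grid_rows, model$grid_cols)
  for (p in portraits) {
    v <- sign * p$values
    if (!all(dim(v) == dim(mask)))
      stop2("portrait grid %dx%d does not match model grid %dx%d",
            nrow(v), ncol(v), nrow(mask), ncol(mask))
    mask <- mask | (v > quantile(v, threshold_quantile))
  }
  modules_from_components(grid_components(mask), model, method, min_units)
}

#' Single-spot overexpression modules
#'
#' [overexpression_modules()] applied to every spot's own portrait.
#'
#' @param model a `som_model`.
#' @inheritParams overexpression_modules
#' @return a `module_set`.
#' @export
single_spot_overexpression_modules <- function(model, threshold_quantile = 0.9,
                                               min_units = 4L) {
  portraits <- lapply(model$spot_barcodes, function(b) spot_portrait(model, b))
  overexpression_modules(model, portraits, threshold_quantile, min_units,
                         sign = 1, method = "single_spot_overexpression")
}

#' Underexpression modules
#'
#' @param model a `som_model`.
#' @inheritParams overexpression_modules
#' @return a `module_set`.
#' @export
underexpression_modules <- function(model, portraits, threshold_quantile = 0.9,
                                    min_units = 4L) {
  overexpression_modules(model, portraits, threshold_quantile, min_units,
                         sign = -1, method = "underexpression")
}

#' K-means segmentation of the metagene codebook
#'
#' Clusters the unit weight vectors with k-means; the resulting unit sets
#' partition the grid (components need not be spatially connected).
#'
#' @param model a `som_model`.
#' @param k number of clusters (2 <= k <= number of units).
#' @param seed RNG seed for the k-means starts.
#' @return a `module_set` whose unit sets partition the grid.
#' @export
kmeans_segmentation <- function(model, k, seed = 1L) {
  n_units <- nrow(model$weights)
  if (k > n_units) stop2("k = %d exceeds the %d grid units", k, n_units)
  if (k < 2) stop2("k must be at least 2")
  cluster <- if (k == n_units) seq_len(n_units)  # singletons, trivially optimal
  else {
    set.seed(seed)
    suppressWarnings(kmeans(model$weights, centers = k, nstart = 10,
                            iter.max = 100))$cluster
  }
  comp <- matrix(cluster, model$grid_rows, model$grid_cols, byrow = TRUE)
  modules_from_components(comp, model, "kmeans")
}

#' Correlation-clustering segmentation
#'
#' Grid-adjacent units (8-neighbourhood) are linked when the Pearson
#' correlation of their weight vectors reaches `threshold`; connected
#' components of the resulting graph are the modules. Units with constant
#' weight vectors (undefined correlation) are never linked.
#'
#' @param model a `som_model`.
#' @param threshold correlation threshold in (-1, 1).
#' @return a `module_set` partitioning the grid.
#' @export
correlation_cluster_segmentation <- function(model, threshold = 0.8) {
  if (threshold <= -1 || threshold >= 1)
    stop2("threshold must lie strictly between -1 and 1")
  nr <- model$grid_rows; nc <- model$grid_cols
  n_units <- nr * nc
  rc <- unit_rc(seq_len(n_units), nc)
  edges <- integer(0)
  for (u in seq_len(n_units)) {
    r <- rc[u, "row"]; cc <- rc[u, "col"]
    # right, down-left, down, down-right: each undirected pair once
    for (d in list(c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
      rr <- r + d[[1]]; ccc <- cc + d[[2]]
      if (rr < 1 || rr > nr || ccc < 1 || ccc > nc) next
      v <- unit_index(rr, ccc, nc)
      w1 <- model$weights[u, ]; w2 <- model$weights[v, ]
      if (sd(w1) == 0 || sd(w2) == 0) next
      if (cor(w1, w2) >= threshold) edges <- c(edges, u, v)
    }
  }
  g <- igraph::make_empty_graph(n = n_units, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  comp <- matrix(memb, nr, nc, byrow = TRUE)
  modules_from_components(comp, model, "correlation_cluster")
}

#' Distance map (U-matrix) of a SOM
#'
#' Per unit: the mean Euclidean distance between its weight vector and
#' those of its 8-neighbourhood grid neighbours. High-distance ridges
#' separate dissimilar map regions.
#'
#' @param model a `som_model`.
#' @return grid-shaped numeric matrix.
#' @export
distance_map <- function(model) {
  nr <- model$grid_rows; nc <- model$grid_cols
  dm <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    w <- model$weights[unit_index(r, cc, nc), ]
    d <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; ccc <- cc + dc
      if (rr < 1 || rr > nr || ccc < 1 || ccc > nc) next
      d <- c(d, sqrt(sum((w - model$weights[unit_index(rr, ccc, nc), ])^2)))
    }
    dm[r, cc] <- mean(d)
  }
  dm
}

#' Distance-map segmentation
#'
#' Units whose distance-map value exceeds the `boundary_quantile` quantile
#' are treated as boundaries; 8-connected components of the remaining units
#' are the modules.
#'
#' @param model a `som_model`.
#' @param boundary_quantile quantile in (0, 1) defining boundary units.
#' @return a `module_set` (empty if every unit is a boundary).
#' @export
dmap_segmentation <- function(model, boundary_quantile = 0.9) {
  if (boundary_quantile <= 0 || boundary_quantile >= 1)
    stop2("boundary_quantile must lie strictly between 0 and 1")
  dm <- distance_map(model)
  mask <- dm <= quantile(dm, boundary_quantile)
  modules_from_components(grid_components(mask), model, "dmap")
}

#' Per-spot spatial score of a module
#'
#' The mean, over the module's units, of each spot's portrait value there —
#' equivalently the mean of the module metagenes' components at that spot.
#' Used to colour the tissue image by module activity.
#'
#' @param model a `som_model`.
#' @param modules a `module_set`.
#' @param label module label (e.g. `"A"`).
#' @return named numeric vector over the model's spots.
#' @export
module_spatial_score <- function(model, modules, label) {
  m <- modules$modules[[label]]
  if (is.null(m)) stop2("unknown module label: %s", label)
  key <- unit_index(m$units[, "row"], m$units[, "col"], model$grid_cols)
  setNames(colMeans(model$weights[key, , drop = FALSE]), model$spot_barcodes)
}
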