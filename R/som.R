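#' SOM training configuration
#'
#' Classical online Kohonen training on a rectangular grid: Gaussian
#' neighbourhood, learning rate and radius both decaying exponentially over
#' the training steps. The default 50 x 50 grid yields 2,500 metagenes.
#'
#' @param grid_rows,grid_cols grid dimensions (default 50 x 50).
#' @param epochs passes over the gene profiles (default 20).
#' @param initial_learning_rate,final_learning_rate exponential decay
#'   endpoints, in (0, 1]; defaults 0.5 -> 0.01.
#' @param initial_radius starting Gaussian neighbourhood radius in grid
#'   units; default `max(grid_rows, grid_cols) / 2`.
#' @param final_radius end radius, default 1.
#' @param init `"pca_plane"` (units spread on the plane of the top two
#'   principal axes of the gene profiles; reproducible without randomness)
#'   or `"random"`.
#' @param seed integer seed governing the sample order shuffle (and random
#'   init when selected).
#' @return a `som_config` list.
#' @export
som_config <- function(grid_rows = 50L, grid_cols = 50L, epochs = 20L,
                       initial_learning_rate = 0.5,
                       final_learning_rate = 0.01,
                       initial_radius = NULL, final_radius = 1,
                       init = c("pca_plane", "random"), seed = 42L) {
  init <- match.arg(init)
  grid_rows <- as.integer(grid_rows); grid_cols <- as.integer(grid_cols)
  if (grid_rows * grid_cols < 4) stop2("grid must have at least 4 units")
  if (is.null(initial_radius)) initial_radius <- max(grid_rows, grid_cols) / 2
  if (initial_learning_rate < final_learning_rate)
    stop2("initial_learning_rate must be >= final_learning_rate")
  if (initial_radius < final_radius)
    stop2("initial_radius must be >= final_radius")
  if (any(c(initial_learning_rate, final_learning_rate) <= 0) ||
      any(c(initial_learning_rate, final_learning_rate) > 1))
    stop2("learning rates must lie in (0, 1]")
  if (final_radius <= 0) stop2("radii must be positive")
  if (epochs < 1) stop2("epochs must be >= 1")
  structure(list(grid_rows = grid_rows, grid_cols = grid_cols,
                 epochs = as.integer(epochs),
                 initial_learning_rate = initial_learning_rate,
                 final_learning_rate = final_learning_rate,
                 initial_radius = initial_radius,
                 final_radius = final_radius,
                 init = init, seed = as.integer(seed)),
            class = "som_config")
}

# Row-major unit indexing: unit u (1-based) <-> grid position (row, col).
unit_index <- function(row, col, grid_cols) (row - 1L) * grid_cols + col
unit_rc <- function(u, grid_cols) {
  cbind(row = (u - 1L) %/% grid_cols + 1L, col = (u - 1L) %% grid_cols + 1L)
}

som_init_weights <- function(X, config) {
  n_units <- config$grid_rows * config$grid_cols
  if (config$init == "pca_plane") {
    ctr <- colMeans(X)
    pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = 2)
    d1 <- pc$rotation[, 1]
    d2 <- if (ncol(pc$rotation) >= 2) pc$rotation[, 2] else rep(0, ncol(X))
    s1 <- pc$sdev[[1]]
    s2 <- if (length(pc$sdev) >= 2) pc$sdev[[2]] else 0
    a <- if (config$grid_rows > 1)
      seq(-2, 2, length.out = config$grid_rows) else 0
    b <- if (config$grid_cols > 1)
      seq(-2, 2, length.out = config$grid_cols) else 0
    W <- matrix(0, n_units, ncol(X))
    for (r in seq_len(config$grid_rows)) {
      for (cc in seq_len(config$grid_cols)) {
        W[unit_index(r, cc, config$grid_cols), ] <-
          ctr + a[[r]] * s1 * d1 + b[[cc]] * s2 * d2
      }
    }
    W
  } else {
    matrix(rnorm(n_units * ncol(X), mean = mean(X), sd = sd(X)),
           n_units, ncol(X))
  }
}

#' Train a self-organizing map on gene expression profiles
#'
#' Each gene's expression across spots is one training sample; the fitted
#' codebook holds one prototype profile ("metagene") per grid unit and
#' every gene is assigned to its best-matching unit under Euclidean
#' distance. Training is fully deterministic for a fixed seed.
#'
#' @param em an [expression_matrix()] at stage `centralized`.
#' @param config a [som_config()].
#' @return a `som_model`: list with the codebook `weights` (units x spots,
#'   row-major unit order), `gene_ids`, `spot_barcodes`, the gene
#'   `assignment` matrix (columns `row`, `col`), the config and the
#'   quantization error before (`qe_initial`) and after (`qe_final`)
#'   training.
#' @export
train_som <- function(em, config = som_config()) {
  if (expr_stage(em) != "centralized")
    stop2("train_som expects centralized data, got stage '%s'", expr_stage(em))
  X <- unclass_matrix(em)
  if (nrow(X) == 0 || ncol(X) == 0) stop2("empty expression matrix")
  set.seed(config$seed)
  W0 <- som_init_weights(X, config)
  n_genes <- nrow(X)
  steps <- config$epochs * n_genes
  order0 <- unlist(lapply(seq_len(config$epochs),
                          function(e) sample.int(n_genes))) - 1L
  tt <- if (steps > 1) (seq_len(steps) - 1) / (steps - 1) else 0
  alpha <- config$initial_learning_rate *
    (config$final_learning_rate / config$initial_learning_rate)^tt
  # Two-phase Kohonen schedule: the radius decays exponentially from its
  # initial to its final value over the ordering phase (first 35% of the
  # steps), then holds at the final value for the convergence phase. The
  # Gaussian neighbourhood sigma is radius/2, so the radius bounds the
  # effectively updated neighbourhood.
  radius <- config$initial_radius *
    (config$final_radius / config$initial_radius)^pmin(1, tt / 0.35)
  qe0 <- mean(sqrt(bmu_all_cpp(X, W0)$dist2))
  W <- som_train_cpp(X, W0, order0, alpha, radius / 2,
                     config$grid_rows, config$grid_cols)
  fit <- bmu_all_cpp(X, W)
  assignment <- unit_rc(fit$unit + 1L, config$grid_cols)
  rownames(assignment) <- rownames(X)
  structure(list(config = config,
                 grid_rows = config$grid_rows, grid_cols = config$grid_cols,
                 weights = W,
                 gene_ids = rownames(X),
                 spot_barcodes = colnames(X),
                 assignment = assignment,
                 qe_initial = qe0,
                 qe_final = mean(sqrt(fit$dist2))),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("<som_model> %dx%d grid (%d metagenes), %d genes, %d spots\n",
              x$grid_rows, x$grid_cols, x$grid_rows * x$grid_cols,
              length(x$gene_ids), length(x$spot_barcodes)))
  cat(sprintf("  quantization error %.4g -> %.4g\n", x$qe_initial, x$qe_final))
  invisible(x)
}

#' Best-matching unit of a profile
#'
#' Returns the grid unit whose metagene weight vector minimizes the
#' Euclidean distance to the given profile; exact ties resolve to the
#' lowest row, then the lowest column.
#'
#' @param model a `som_model`.
#' @param profile numeric vector of length `n_spots`.
#' @return integer vector `c(row, col)` (1-based).
#' @export
best_matching_unit <- function(model, profile) {
  if (length(profile) != ncol(model$weights))
    stop2("profile has length %d; model expects %d spots",
          length(profile), ncol(model$weights))
  u <- bmu_all_cpp(matrix(as.numeric(profile), nrow = 1),
                   model$weights)$unit + 1L
  rc <- unit_rc(u, model$grid_cols)
  c(row = as.integer(rc[[1, "row"]]), col = as.integer(rc[[1, "col"]]))
}

#' Quantization error of a model on data
#'
#' Mean Euclidean distance from each gene profile to its best-matching
#' metagene; the standard goodness-of-fit diagnostic for a SOM.
#'
#' @param model a `som_model`.
#' @param em an `expr_matrix` whose columns match the model's spots.
#' @return non-negative scalar.
#' @export
quantization_error <- function(model, em) {
  X <- unclass_matrix(em)
  if (ncol(X) != ncol(model$weights))
    stop2("matrix has %d spots; model expects %d", ncol(X), ncol(model$weights))
  mean(sqrt(bmu_all_cpp(X, model$weights)$dist2))
}

make_portrait <- function(values, subject, kind) {
  structure(list(values = values, subject = subject, kind = kind),
            class = "som_portrait")
}

#' @export
print.som_portrait <- function(x, ...) {
  cat(sprintf("<som_portrait> %s '%s', %dx%d grid, range [%.3g, %.3g]\n",
              x$kind, x$subject, nrow(x$values), ncol(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Expression portrait of a single spot
#'
#' The grid-shaped image of metagene values at one spot: cell (r, c) holds
#' the component of unit (r, c)'s weight vector at that spot's index. The
#' gene layout is shared by construction, so portraits of different spots
#' are directly comparable.
#'
#' @param model a `som_model`.
#' @param barcode spot barcode.
#' @return a `som_portrait` (list with `values` matrix, `subject`, `kind`).
#' @export
spot_portrait <- function(model, barcode) {
  idx <- match(barcode, model$spot_barcodes)
  if (is.na(idx)) stop2("unknown spot barcode: %s", barcode)
  v <- matrix(model$weights[, idx], nrow = model$grid_rows,
              ncol = model$grid_cols, byrow = TRUE)
  make_portrait(v, barcode, "single_spot")
}

#' Mean expression portrait of a group of spots
#'
#' Element-wise mean of the member spots' portraits, e.g. one portrait per
#' spot cluster or cell type.
#'
#' @param model a `som_model`.
#' @param barcodes non-empty character vector of member barcodes.
#' @param label subject label for the portrait.
#' @return a `som_portrait` with `kind = "group_mean"`.
#' @export
group_portrait <- function(model, barcodes, label = "group") {
  if (length(barcodes) == 0) stop2("empty spot group")
  idx <- match(barcodes, model$spot_barcodes)
  if (anyNA(idx))
    stop2("unknown spot barcode(s): %s",
          paste(barcodes[is.na(idx)], collapse = ", "))
  v <- matrix(rowMeans(model$weights[, idx, drop = FALSE]),
              nrow = model$grid_rows, ncol = model$grid_cols, byrow = TRUE)
  make_portrait(v, label, "group_mean")
}

#' Group portraits for every level of a label set
#'
#' @param model a `som_model`.
#' @param labels a [spot_labels()] object; barcodes absent from the model
#'   are ignored.
#' @return named list of `som_portrait`s, one per label.
#' @export
group_portraits_by_label <- function(model, labels) {
  labels <- labels[labels$barcode %in% model$spot_barcodes, , drop = FALSE]
  if (nrow(labels) == 0) stop2("no labelled barcode is present in the model")
  split_bc <- split(labels$barcode, labels$label)
  lapply(stats::setNames(names(split_bc), names(split_bc)),
         function(l) group_portrait(model, split_bc[[l]], label = l))
}
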