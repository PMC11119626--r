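# Shared fixture builders. Everything is generated in code; no data files.

# Small raw-count matrix with named genes/spots.
make_counts <- function(n_genes = 10, n_spots = 6, seed = 1, max_count = 20) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_spots, lambda = max_count / 2),
              n_genes, n_spots,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("BC%03d-1", seq_len(n_spots))))
  expression_matrix(m, "raw_counts")
}

# Centralized matrix straight from values (bypassing the count chain).
make_centralized <- function(values) {
  v <- values - rowMeans(values)
  out <- expression_matrix(v, "centralized")
  attr(out, "log_base") <- 2
  out
}

# Build a som_model directly from a codebook matrix (units x spots,
# row-major unit order), optionally assigning the genes of X.
manual_model <- function(W, grid_rows, grid_cols, barcodes = NULL, X = NULL) {
  if (is.null(barcodes)) barcodes <- sprintf("BC%03d-1", seq_len(ncol(W)))
  gene_ids <- character(0)
  assignment <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  if (!is.null(X)) {
    fit <- spotsom:::bmu_all_cpp(X, W)
    assignment <- spotsom:::unit_rc(fit$unit + 1L, grid_cols)
    rownames(assignment) <- rownames(X)
    gene_ids <- rownames(X)
  }
  structure(list(config = som_config(grid_rows = grid_rows,
                                     grid_cols = grid_cols),
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 weights = W, gene_ids = gene_ids, spot_barcodes = barcodes,
                 assignment = assignment, qe_initial = NA_real_,
                 qe_final = NA_real_),
            class = "som_model")
}

# Hex lattice layout in Visium doubled-width coordinates.
make_hex_layout <- function(n_rows = 5, n_cols = 5, in_tissue = TRUE) {
  grid <- expand.grid(c0 = seq_len(n_cols) - 1L, r0 = seq_len(n_rows) - 1L)
  spatial_layout(barcode = sprintf("HX%03d-1", seq_len(nrow(grid))),
                 in_tissue = in_tissue,
                 array_row = grid$r0,
                 array_col = 2L * grid$c0 + grid$r0 %% 2L,
                 pixel_x = (2L * grid$c0 + grid$r0 %% 2L) * 50,
                 pixel_y = grid$r0 * 87)
}

# Jaccard index between two gene sets.
jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# Rank-based AUC of score for the positive class.
rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Independent R-side best-matching-unit scan (oracle for the C++ path):
# exhaustive distances, ties broken by lowest row then lowest column.
bmu_oracle <- function(W, x, grid_rows, grid_cols) {
  best <- Inf; best_rc <- c(NA, NA)
  for (r in seq_len(grid_rows)) for (cc in seq_len(grid_cols)) {
    u <- (r - 1) * grid_cols + cc
    d <- sum((W[u, ] - x)^2)
    if (d < best) { best <- d; best_rc <- c(r, cc) }
  }
  best_rc
}
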