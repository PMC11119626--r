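# A 4x4 model whose codebook carries a high plateau in the top-left 2x2
# block at spot 1, used by several cases below.
plateau_model <- function() {
  W <- matrix(0, 16, 4)
  high <- c(1, 2, 5, 6)  # row-major units of the 2x2 top-left block
  W[high, 1] <- 10
  genes <- matrix(0, 6, 4, dimnames = list(sprintf("g%d", 1:6),
                                           sprintf("s%d", 1:4)))
  genes[1:4, 1] <- 10                     # genes of the plateau
  genes[5:6, ] <- rnorm(8, sd = 0.01)     # background genes elsewhere
  manual_model(W, 4, 4, barcodes = colnames(genes), X = genes)
}

test_that("overexpression modules find planted plateaus and respect limits", {
  set.seed(1)
  model <- plateau_model()
  p <- spot_portrait(model, "s1")
  mods <- overexpression_modules(model, p, threshold_quantile = 0.7,
                                 min_units = 4)
  expect_length(mods$modules, 1)
  expect_equal(nrow(mods$modules$A$units), 4)
  expect_setequal(apply(mods$modules$A$units, 1, paste, collapse = ","),
                  c("1,1", "1,2", "2,1", "2,2"))
  # genes attached are exactly those assigned to the plateau units
  expect_setequal(mods$modules$A$gene_ids, sprintf("g%d", 1:4))

  # quantile -> 1 limit gives an empty module set (not an error)
  empty <- overexpression_modules(model, p, threshold_quantile = 0.999,
                                  min_units = 4)
  expect_length(empty$modules, 0)

  # two disjoint plateaus give two modules equal to the plateaus
  W <- matrix(0, 25, 2)
  blockA <- c(1, 2, 6, 7)        # top-left 2x2 on a 5x5 grid
  blockB <- c(14, 15, 19, 20)    # rows 3-4, cols 4-5
  W[blockA, 1] <- 5
  W[blockB, 1] <- 7
  m2 <- manual_model(W, 5, 5, barcodes = c("x", "y"))
  mods2 <- overexpression_modules(m2, spot_portrait(m2, "x"),
                                  threshold_quantile = 0.6, min_units = 3)
  expect_length(mods2$modules, 2)
  units_found <- lapply(mods2$modules, function(m)
    sort(spotsom:::unit_index(m$units[, "row"], m$units[, "col"], 5)))
  expect_setequal(unlist(lapply(units_found, paste, collapse = ",")),
                  c(paste(sort(blockA), collapse = ","),
                    paste(sort(blockB), collapse = ",")))
})

test_that("raising the threshold quantile never enlarges a module", {
  set.seed(33)
  W <- matrix(rnorm(36 * 3), 36, 3)
  model <- manual_model(W, 6, 6)
  p <- spot_portrait(model, model$spot_barcodes[[1]])
  total_units <- function(tq) {
    mods <- overexpression_modules(model, p, tq, min_units = 1)
    sum(vapply(mods$modules, function(m) nrow(m$units), integer(1)))
  }
  sizes <- vapply(c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95), total_units, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("underexpression is overexpression with the sign flipped", {
  set.seed(2)
  W <- matrix(rnorm(16 * 3), 16, 3)
  model <- manual_model(W, 4, 4)
  p <- spot_portrait(model, model$spot_barcodes[[2]])
  neg <- p; neg$values <- -p$values
  under <- underexpression_modules(model, p, 0.75, min_units = 1)
  over_of_neg <- overexpression_modules(model, neg, 0.75, min_units = 1)
  expect_equal(lapply(under$modules, `[[`, "units"),
               lapply(over_of_neg$modules, `[[`, "units"))
})

test_that("k-means segmentation partitions the grid and separates masses", {
  # two exact point masses
  W <- rbind(matrix(5, 8, 3), matrix(-5, 8, 3))
  model <- manual_model(W, 4, 4)
  mods <- kmeans_segmentation(model, 2, seed = 1)
  expect_length(mods$modules, 2)
  sizes <- vapply(mods$modules, function(m) nrow(m$units), integer(1))
  expect_equal(unname(sizes), c(8, 8))
  all_units <- do.call(rbind, lapply(mods$modules, `[[`, "units"))
  expect_equal(nrow(unique(all_units)), 16)  # partition, no overlap

  # k = number of units -> singletons
  set.seed(5)
  Wr <- matrix(rnorm(9 * 4), 9, 4)
  mr <- manual_model(Wr, 3, 3)
  singletons <- kmeans_segmentation(mr, 9, seed = 1)
  expect_length(singletons$modules, 9)
  expect_error(kmeans_segmentation(mr, 10), "exceeds")

  # within-cluster SS no worse than random partitions
  mods3 <- kmeans_segmentation(mr, 3, seed = 2)
  wss_of <- function(assign_vec) {
    sum(vapply(unique(assign_vec), function(k) {
      rows <- Wr[assign_vec == k, , drop = FALSE]
      sum(sweep(rows, 2, colMeans(rows))^2)
    }, numeric(1)))
  }
  memb <- integer(9)
  for (m in mods3$modules) {
    u <- spotsom:::unit_index(m$units[, "row"], m$units[, "col"], 3)
    memb[u] <- match(m$label, names(mods3$modules))
  }
  wss_fit <- wss_of(memb)
  set.seed(7)
  random_wss <- replicate(50, wss_of(sample(1:3, 9, replace = TRUE)))
  expect_true(all(wss_fit <= random_wss))
})

test_that("correlation clustering links by correlation and adjacency", {
  ns <- 6
  set.seed(9)
  base <- rnorm(ns)
  # all units share one profile shape -> one module at high threshold
  W <- matrix(rep(base, each = 16), 16, ns) * runif(16, 0.5, 2)
  model <- manual_model(W, 4, 4)
  mods <- correlation_cluster_segmentation(model, 0.9)
  expect_length(mods$modules, 1)
  expect_equal(nrow(mods$modules$A$units), 16)

  # threshold above max pairwise correlation -> all singletons
  set.seed(10)
  Wr <- matrix(rnorm(9 * 12), 9, 12)
  mr <- manual_model(Wr, 3, 3)
  pairmax <- max(cor(t(Wr))[upper.tri(diag(9))])
  singl <- correlation_cluster_segmentation(mr, min(0.999, pairmax + 1e-6))
  expect_length(singl$modules, 9)

  # two anticorrelated half-grids separate into two modules
  half <- rbind(matrix(rep(base, each = 8), 8, ns),
                matrix(rep(-base, each = 8), 8, ns))
  mh <- manual_model(half, 4, 4)
  mods2 <- correlation_cluster_segmentation(mh, 0.5)
  expect_length(mods2$modules, 2)
  rows_by_mod <- lapply(mods2$modules, function(m) sort(unique(m$units[, "row"])))
  expect_setequal(vapply(rows_by_mod, paste, collapse = ",", FUN.VALUE = ""),
                  c("1,2", "3,4"))
})

test_that("distance map matches brute force and drives segmentation", {
  set.seed(12)
  W <- matrix(rnorm(9 * 5), 9, 5)
  model <- manual_model(W, 3, 3)
  dm <- distance_map(model)
  # brute-force neighbour distances
  for (r in 1:3) for (cc in 1:3) {
    ds <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr < 1 || rr > 3 || c2 < 1 || c2 > 3) next
      u <- (r - 1) * 3 + cc; v <- (rr - 1) * 3 + c2
      ds <- c(ds, sqrt(sum((W[u, ] - W[v, ])^2)))
    }
    expect_equal(dm[r, cc], mean(ds))
  }

  # uniform codebook: no boundaries, one module covering the grid
  mu <- manual_model(matrix(2, 16, 3), 4, 4)
  mods <- dmap_segmentation(mu, 0.9)
  expect_length(mods$modules, 1)
  expect_equal(nrow(mods$modules$A$units), 16)

  # sharp jump between two homogeneous half-grids isolates two modules
  Wj <- rbind(matrix(0, 8, 4), matrix(50, 8, 4))
  mj <- manual_model(Wj, 4, 4)
  mods2 <- dmap_segmentation(mj, 0.5)  # rows 2-3 form the boundary ridge
  expect_length(mods2$modules, 2)
  expect_setequal(unlist(lapply(mods2$modules, function(m)
    paste(sort(unique(m$units[, "row"])), collapse = ","))), c("1", "4"))
})

test_that("module spatial scores average metagenes and find the home domain", {
  # single-unit module: score equals that metagene profile
  set.seed(3)
  W <- matrix(rnorm(16 * 5), 16, 5)
  model <- manual_model(W, 4, 4)
  p <- spot_portrait(model, model$spot_barcodes[[1]])
  mods <- overexpression_modules(model, p, 0.9, min_units = 1)
  one_unit <- Filter(function(m) nrow(m$units) == 1, mods$modules)
  if (length(one_unit) > 0) {
    m1 <- one_unit[[1]]
    u <- spotsom:::unit_index(m1$units[1, "row"], m1$units[1, "col"], 4)
    expect_equal(unname(module_spatial_score(model, mods, m1$label)),
                 unname(W[u, ]))
  }
  expect_error(module_spatial_score(model, mods, "ZZ"), "label")

  # planted-domain ground truth: score is higher inside the home domain
  fx <- generate_synthetic(synthetic_config(seed = 5))
  pp <- preprocess(fx$matrix)
  m <- train_som(pp$centralized, som_config(grid_rows = 10, grid_cols = 10,
                                            epochs = 10, seed = 5))
  labels <- spot_labels(names(fx$truth$domains),
                        paste0("d", fx$truth$domains))
  mods <- overexpression_modules(m, group_portraits_by_label(m, labels))
  for (pm in names(fx$truth$modules)) {
    jac_all <- vapply(mods$modules, function(mm)
      jaccard(fx$truth$modules[[pm]], mm$gene_ids), numeric(1))
    best <- names(which.max(jac_all))
    sc <- module_spatial_score(m, mods, best)
    inside <- fx$truth$domains[names(sc)] == fx$truth$module_domain[[pm]]
    expect_gt(median(sc[inside]), median(sc[!inside]))
  }
})

test_that("partition-type segmentations conserve every gene exactly once", {
  fx <- generate_synthetic(synthetic_config(n_rows = 6, n_cols = 6,
                                            genes_per_module = 6,
                                            n_background_genes = 40, seed = 4))
  pp <- preprocess(fx$matrix, preprocess_config(min_spots_expressed = 1))
  m <- train_som(pp$centralized, som_config(grid_rows = 5, grid_cols = 5,
                                            epochs = 5, seed = 4))
  for (mods in list(kmeans_segmentation(m, 4, seed = 1),
                    correlation_cluster_segmentation(m, 0.3))) {
    genes <- unname(unlist(lapply(mods$modules, `[[`, "gene_ids")))
    expect_equal(sort(genes), sort(m$gene_ids))
    expect_equal(anyDuplicated(genes), 0)
  }
})
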