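test_that("best-matching unit agrees with the exhaustive scan, ties row-major", {
  set.seed(21)
  for (dims in list(c(3, 3, 4), c(10, 10, 7))) {
    gr <- dims[[1]]; gc <- dims[[2]]; ns <- dims[[3]]
    W <- matrix(rnorm(gr * gc * ns), gr * gc, ns)
    model <- manual_model(W, gr, gc)
    for (i in 1:50) {
      x <- rnorm(ns)
      expect_equal(unname(best_matching_unit(model, x)),
                   bmu_oracle(W, x, gr, gc))
    }
  }

  # exact profile match lands on that unit (unit 3 = row 2, col 1)
  model <- manual_model(matrix(1:12, 4, 3), 2, 2)
  expect_equal(unname(best_matching_unit(model, c(3, 7, 11))), c(2, 1))

  # tie between units (1,2) and (2,1) resolves to (1,2)
  W <- rbind(c(5, 5), c(0, 0), c(0, 0), c(5, 5))  # units (1,1),(1,2),(2,1),(2,2)
  model <- manual_model(W, 2, 2)
  expect_equal(unname(best_matching_unit(model, c(0, 0))), c(1, 2))

  expect_error(best_matching_unit(model, c(1, 2, 3)), "length")
})

test_that("portraits index the codebook correctly and average linearly", {
  # hand-built 2x2 model over 3 spots
  W <- rbind(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9), c(10, 11, 12))
  model <- manual_model(W, 2, 2, barcodes = c("a", "b", "c"))
  p2 <- spot_portrait(model, "b")
  expect_equal(p2$values, matrix(c(2, 5, 8, 11), 2, 2, byrow = TRUE))
  expect_error(spot_portrait(model, "nope"), "barcode")

  # stacking all spot portraits reconstructs the codebook
  stacked <- vapply(c("a", "b", "c"),
                    function(b) as.vector(t(spot_portrait(model, b)$values)),
                    numeric(4))
  expect_equal(unname(stacked), unname(W))

  # group portrait is the element-wise mean; a singleton group collapses
  g <- group_portrait(model, c("a", "c"))
  expect_equal(g$values, (spot_portrait(model, "a")$values +
                            spot_portrait(model, "c")$values) / 2)
  expect_equal(group_portrait(model, "b")$values, p2$values)
  expect_error(group_portrait(model, character(0)), "empty")

  # mean oracle on a random model
  set.seed(4)
  Wr <- matrix(rnorm(9 * 8), 9, 8)
  mr <- manual_model(Wr, 3, 3)
  members <- mr$spot_barcodes[c(1, 3, 4, 7, 8)]
  expect_equal(as.vector(t(group_portrait(mr, members)$values)),
               unname(rowMeans(Wr[, c(1, 3, 4, 7, 8)])))

  # opposite portraits cancel in a group mean
  W2 <- cbind(c(1, -2, 3, -4), -c(1, -2, 3, -4))
  m2 <- manual_model(W2, 2, 2, barcodes = c("p", "q"))
  expect_equal(group_portrait(m2, c("p", "q"))$values, matrix(0, 2, 2))

  # flat codebook gives flat portraits
  mf <- manual_model(matrix(3, 4, 2), 2, 2, barcodes = c("p", "q"))
  expect_equal(spot_portrait(mf, "p")$values, matrix(3, 2, 2))
})

test_that("quantization error matches brute force and is order-invariant", {
  set.seed(11)
  W <- matrix(rnorm(9 * 5), 9, 5)
  X <- matrix(rnorm(20 * 5), 20, 5,
              dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:5)))
  model <- manual_model(W, 3, 3, barcodes = colnames(X))
  em <- expression_matrix(X, "centralized")
  qe <- quantization_error(model, em)
  brute <- mean(apply(X, 1, function(x)
    sqrt(min(rowSums(sweep(W, 2, x)^2)))))
  expect_equal(qe, brute, tolerance = 1e-12)

  em_perm <- expression_matrix(X[sample(20), ], "centralized")
  expect_equal(quantization_error(model, em_perm), qe)

  # genes sitting exactly on units have zero error
  W0 <- W[1:4, , drop = FALSE]
  dimnames(W0) <- list(paste0("g", 1:4), colnames(X))
  expect_equal(quantization_error(model, expression_matrix(W0, "centralized")),
               0)
})

test_that("training is seed-deterministic and reduces quantization error", {
  fx <- generate_synthetic(synthetic_config(n_rows = 6, n_cols = 6,
                                            genes_per_module = 8,
                                            n_background_genes = 60, seed = 3))
  pp <- preprocess(fx$matrix, preprocess_config(min_spots_expressed = 1))
  cfg <- som_config(grid_rows = 6, grid_cols = 6, epochs = 5, seed = 17)
  m1 <- train_som(pp$centralized, cfg)
  m2 <- train_som(pp$centralized, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_true(m1$qe_final <= m1$qe_initial)
  # assignment is consistent with the final weights
  fit <- spotsom:::bmu_all_cpp(unclass(pp$centralized), m1$weights)
  rc <- spotsom:::unit_rc(fit$unit + 1L, m1$grid_cols)
  expect_equal(unname(m1$assignment), unname(rc))
})

test_that("well-separated point masses are captured by distinct units", {
  set.seed(8)
  k <- 3; per <- 12; ns <- 10
  centers <- matrix(rnorm(k * ns, sd = 8), k, ns)
  X <- centers[rep(1:k, each = per), ] + matrix(rnorm(k * per * ns, sd = 0.05),
                                                k * per, ns)
  dimnames(X) <- list(sprintf("g%02d", seq_len(k * per)),
                      sprintf("s%02d", seq_len(ns)))
  em <- make_centralized(X)
  m <- train_som(em, som_config(grid_rows = 4, grid_cols = 4, epochs = 10,
                                seed = 2))
  unit_of <- apply(m$assignment, 1, paste, collapse = ",")
  masses <- split(unit_of, rep(1:k, each = per))
  # the masses occupy pairwise disjoint unit sets, with distinct majority units
  for (i in 1:(k - 1)) for (j in (i + 1):k)
    expect_length(intersect(masses[[i]], masses[[j]]), 0)
  reps <- vapply(masses, function(u) names(sort(table(u),
                                                decreasing = TRUE))[[1]],
                 character(1))
  expect_equal(length(unique(reps)), k)
})

test_that("anticorrelated gene modules land in disjoint connected regions", {
  ok <- logical(8)
  for (s in seq_along(ok)) {
    set.seed(100 + s)
    ns <- 20
    pattern <- rnorm(ns, sd = 2)
    up <- matrix(rep(pattern, each = 25), 25, ns) + rnorm(25 * ns, sd = 0.3)
    dn <- matrix(rep(-pattern, each = 25), 25, ns) + rnorm(25 * ns, sd = 0.3)
    X <- rbind(up, dn)
    dimnames(X) <- list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:ns))
    m <- train_som(make_centralized(X),
                   som_config(grid_rows = 6, grid_cols = 6, epochs = 10,
                              seed = s))
    mask_for <- function(rows) {
      mm <- matrix(FALSE, 6, 6)
      mm[m$assignment[rows, , drop = FALSE]] <- TRUE
      mm
    }
    comp_up <- spotsom:::grid_components(mask_for(1:25))
    comp_dn <- spotsom:::grid_components(mask_for(26:50))
    disjoint <- !any(mask_for(1:25) & mask_for(26:50))
    ok[s] <- disjoint && max(comp_up) == 1 && max(comp_dn) == 1
  }
  expect_gte(mean(ok), 0.9)
})
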