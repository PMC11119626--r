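rli_em <- function(r_vals, l_vals, extra = NULL) {
  v <- rbind(R1 = r_vals, L1 = l_vals)
  if (!is.null(extra)) v <- rbind(v, extra)
  colnames(v) <- sprintf("s%d", seq_len(ncol(v)))
  expression_matrix(v, "log")
}

test_that("state calls follow the 9-case threshold truth table", {
  t <- 2
  lv <- c(below = 1, equal = 2, above = 3)
  expected <- function(r, l) {
    r_on <- r > t; l_on <- l > t
    if (r_on && l_on) "coexpressed"
    else if (r_on) "receptor_only"
    else if (l_on) "ligand_only"
    else "none"
  }
  cases <- expand.grid(r = lv, l = lv)
  em <- rli_em(cases$r, cases$l)
  calls <- classify_rli(em, "R1", "L1", expr_threshold = t)
  for (i in seq_len(nrow(cases)))
    expect_equal(calls$state[[i]], expected(cases$r[[i]], cases$l[[i]]))
  # values exactly at the threshold count as not expressed
  expect_equal(calls$state[cases$r == 2 & cases$l == 2][[1]], "none")
})

test_that("joint score and saturation follow the definitions", {
  em <- rli_em(c(2, 0, 4), c(3, 5, 0))
  calls <- classify_rli(em, "R1", "L1", expr_threshold = 0)
  expect_equal(calls$state, c("coexpressed", "ligand_only", "receptor_only"))
  expect_equal(calls$joint_score, c(2.5, 0, 0))
  q95 <- quantile(c(2, 0, 4, 3, 5, 0), 0.95, names = FALSE)
  expect_equal(calls$saturation, pmin(1, c(2.5, 5, 4) / q95))
  expect_error(classify_rli(em, "R1", "GHOST"), "GHOST")
  # centralized input is rejected: detection needs a pre-centralized scale
  cem <- make_centralized(matrix(rnorm(6), 2, 3,
                                 dimnames = list(c("R1", "L1"),
                                                 paste0("s", 1:3))))
  expect_error(classify_rli(cem, "R1", "L1"), "centraliz")
})

test_that("swapping receptor and ligand swaps only the one-sided states", {
  set.seed(13)
  em <- rli_em(rnorm(20), rnorm(20))
  a <- classify_rli(em, "R1", "L1")
  b <- classify_rli(em, "L1", "R1")
  swap <- c(coexpressed = "coexpressed", none = "none",
            receptor_only = "ligand_only", ligand_only = "receptor_only")
  expect_equal(b$state, unname(swap[a$state]))
  expect_equal(b$joint_score, a$joint_score)
})

test_that("raising the threshold only degrades states monotonically", {
  set.seed(14)
  em <- rli_em(runif(30, 0, 5), runif(30, 0, 5))
  rank_of <- function(s) match(s, c("none", "receptor_only",
                                    "ligand_only", "coexpressed"))
  prev <- classify_rli(em, "R1", "L1", 0)
  for (t in c(1, 2, 3, 4)) {
    cur <- classify_rli(em, "R1", "L1", t)
    # a spot never moves towards coexpressed as the threshold rises
    expect_true(all(!(prev$state == "none" & cur$state == "coexpressed")))
    expect_true(all(rank_of(cur$state) <= rank_of(prev$state) |
                      (prev$state %in% c("receptor_only", "ligand_only") &
                         cur$state %in% c("receptor_only", "ligand_only"))))
    prev <- cur
  }
})

test_that("pathway-wide maps equal the precedence fold over per-pair calls", {
  set.seed(15)
  genes <- matrix(runif(8 * 10, 0, 4), 8, 10,
                  dimnames = list(c(paste0("R", 1:4), paste0("L", 1:4)),
                                  sprintf("s%d", 1:10)))
  em <- expression_matrix(genes, "log")
  pairs <- rli_pairs(paste0("R", 1:4), paste0("L", 1:4))
  agg <- pathway_rli_map(em, pairs, expr_threshold = 2)

  # independent fold: precedence scan over individual calls
  calls <- lapply(1:4, function(i)
    classify_rli(em, paste0("R", i), paste0("L", i), 2))
  precedence <- c("coexpressed", "receptor_only", "ligand_only", "none")
  for (s in seq_len(ncol(genes))) {
    states <- vapply(calls, function(cl) cl$state[[s]], character(1))
    want <- precedence[min(match(states, precedence))]
    expect_equal(agg$state[[s]], want)
    if (want == "coexpressed") {
      expect_equal(agg$joint_score[[s]],
                   max(vapply(calls, function(cl) cl$joint_score[[s]],
                              numeric(1))))
    }
  }

  # single-pair list reduces to classify_rli
  single <- pathway_rli_map(em, pairs[1, , drop = FALSE], 2)
  expect_equal(single$state, calls[[1]]$state)
  expect_equal(single$joint_score, calls[[1]]$joint_score)

  # one coexpressed + one receptor_only pair -> coexpressed wins
  em2 <- expression_matrix(
    matrix(c(3, 3, 3, 0), 4, 1,
           dimnames = list(c("Ra", "La", "Rb", "Lb"), "s1")), "log")
  two <- pathway_rli_map(em2, rli_pairs(c("Ra", "Rb"), c("La", "Lb")), 0)
  expect_equal(two$state, "coexpressed")

  # absent genes first warn (skip), then abort when nothing is left
  expect_warning(expect_error(pathway_rli_map(em, rli_pairs("nope", "nada")),
                              "no receptor"), "skipping")
})

test_that("per-spot pair ranking matches a sort oracle", {
  set.seed(16)
  genes <- matrix(runif(12 * 3, 0, 6), 12, 3,
                  dimnames = list(c(paste0("R", 1:6), paste0("L", 1:6)),
                                  c("s1", "s2", "s3")))
  em <- expression_matrix(genes, "log")
  pairs <- rli_pairs(paste0("R", 1:6), paste0("L", 1:6))
  rk <- rank_rli_pairs(em, "s2", pairs)
  oracle_scores <- (genes[paste0("R", 1:6), "s2"] +
                      genes[paste0("L", 1:6), "s2"]) / 2
  expect_equal(rk$joint_mean_expression, unname(sort(oracle_scores,
                                                     decreasing = TRUE)))
  expect_true(!is.unsorted(rev(rk$joint_mean_expression)))

  # two pairs with known scores order correctly, zero pair ranks last
  em3 <- expression_matrix(
    matrix(c(4, 4, 1, 1, 0, 0), 6, 1,
           dimnames = list(c("Ra", "La", "Rb", "Lb", "Rc", "Lc"), "s1")),
    "log")
  rk3 <- rank_rli_pairs(em3, "s1", rli_pairs(c("Ra", "Rb", "Rc"),
                                             c("La", "Lb", "Lc")))
  expect_equal(rk3$receptor, c("Ra", "Rb", "Rc"))
  expect_equal(rk3$joint_mean_expression, c(4, 1, 0))
})

test_that("hex neighbourhoods respect the Visium lattice", {
  lay <- make_hex_layout(5, 5)
  # centre spot of the 5x5 lattice
  centre <- lay$barcode[lay$array_row == 2 & lay$array_col == 4]
  expect_equal(rli_neighborhood(lay, centre, ring = 0), centre)
  n1 <- rli_neighborhood(lay, centre, ring = 1)
  expect_length(n1, 7)  # six neighbours + the spot itself
  # all six neighbours are at hex distance exactly 1
  others <- setdiff(n1, centre)
  i0 <- match(centre, lay$barcode); io <- match(others, lay$barcode)
  expect_true(all(spotsom:::hex_distance(lay$array_row[i0], lay$array_col[i0],
                                         lay$array_row[io],
                                         lay$array_col[io]) == 1))

  # corner spot has fewer neighbours, all in tissue
  corner <- lay$barcode[lay$array_row == 0 & lay$array_col == 0]
  nc <- rli_neighborhood(lay, corner, ring = 1)
  expect_lt(length(nc), 7)
  expect_true(all(lay$in_tissue[match(nc, lay$barcode)]))

  # out-of-tissue spots are never returned
  lay2 <- lay
  lay2$in_tissue[match(others[1], lay2$barcode)] <- FALSE
  expect_false(others[1] %in% rli_neighborhood(lay2, centre, ring = 1))

  expect_error(rli_neighborhood(lay, "GHOST-1", 1), "GHOST")
})
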