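# Receptor-ligand co-expression calls.
#
# Calls are made on the log-normalized scale *before* gene centralization:
# centralized values are signed relative levels ("above this gene's
# average"), whereas the receptor/ligand states are about detection, so
# "expressed" means strictly above the threshold on the log scale
# (default 0). Values exactly at the threshold count as not expressed.

rli_states <- c("coexpressed", "receptor_only", "ligand_only", "none")

check_rli_stage <- function(em) {
  if (!expr_stage(em) %in% c("normalized", "log"))
    stop2("receptor-ligand calls need stage 'normalized' or 'log' values (pre-centralization), got '%s'",
          expr_stage(em))
}

#' Classify receptor-ligand co-expression per spot
#'
#' Each spot is assigned one of four states: `coexpressed` (both receptor
#' and ligand above threshold), `receptor_only`, `ligand_only`, or `none`.
#' The joint score is the mean of the two expression values when
#' coexpressed and 0 otherwise. Saturation (used for colour intensity when
#' rendering) is the relevant expression level divided by the matrix-wide
#' 95th percentile of the two genes' pooled values, clipped to `[0, 1]`.
#'
#' @param em an `expr_matrix` at stage `normalized` or `log`.
#' @param receptor,ligand gene ids; both must be present in the matrix.
#' @param expr_threshold detection threshold (strict inequality),
#'   default 0.
#' @return data frame (class `rli_calls`) with columns `barcode`,
#'   `receptor`, `ligand`, `state`, `joint_score`, `saturation`.
#' @export
classify_rli <- function(em, receptor, ligand, expr_threshold = 0) {
  check_rli_stage(em)
  for (g in c(receptor, ligand)) {
    if (!g %in% rownames(em))
      stop2("gene '%s' is absent from the expression matrix", g)
  }
  v <- unclass_matrix(em)
  r <- v[receptor, ]
  l <- v[ligand, ]
  r_on <- r > expr_threshold
  l_on <- l > expr_threshold
  state <- ifelse(r_on & l_on, "coexpressed",
                  ifelse(r_on, "receptor_only",
                         ifelse(l_on, "ligand_only", "none")))
  joint <- ifelse(r_on & l_on, (r + l) / 2, 0)
  relevant <- ifelse(r_on & l_on, (r + l) / 2,
                     ifelse(r_on, r, ifelse(l_on, l, 0)))
  q95 <- quantile(c(r, l), 0.95, names = FALSE)
  sat <- if (q95 > 0) pmin(1, pmax(0, relevant / q95)) else as.numeric(relevant > 0)
  out <- data.frame(barcode = colnames(v), receptor = receptor,
                    ligand = ligand, state = state, joint_score = joint,
                    saturation = sat, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("rli_calls", "data.frame")
  out
}

#' Pathway-wide receptor-ligand map
#'
#' Aggregates per-pair calls over a list of pairs with the precedence
#' coexpressed > receptor_only > ligand_only > none: a spot is
#' `coexpressed` if any pair is, otherwise `receptor_only` if any pair is,
#' and so on. The joint score is the maximum over coexpressed pairs, and
#' the saturation is carried from the best pair in the winning state.
#'
#' @param em an `expr_matrix` at stage `normalized` or `log`.
#' @param pairs an `rli_pairs` table; pairs whose genes are absent are
#'   skipped with a warning.
#' @param expr_threshold detection threshold.
#' @return an `rli_calls` data frame with `receptor`/`ligand` set to the
#'   winning pair per spot.
#' @export
pathway_rli_map <- function(em, pairs, expr_threshold = 0) {
  check_rli_stage(em)
  present <- pairs$receptor %in% rownames(em) & pairs$ligand %in% rownames(em)
  if (any(!present))
    warn2("skipping %d pair(s) with genes absent from the matrix",
          sum(!present))
  pairs <- pairs[present, , drop = FALSE]
  if (nrow(pairs) == 0)
    stop2("no receptor-ligand pair has both genes in the matrix")
  calls <- lapply(seq_len(nrow(pairs)), function(i)
    classify_rli(em, pairs$receptor[[i]], pairs$ligand[[i]], expr_threshold))
  out <- calls[[1]]
  if (length(calls) > 1) {
    rank_of <- function(s) match(s, rli_states)  # lower rank wins
    for (k in 2:length(calls)) {
      nxt <- calls[[k]]
      better <- rank_of(nxt$state) < rank_of(out$state) |
        (nxt$state == out$state & nxt$state == "coexpressed" &
           nxt$joint_score > out$joint_score) |
        (nxt$state == out$state & nxt$state != "coexpressed" &
           nxt$saturation > out$saturation)
      out[better, ] <- nxt[better, ]
    }
  }
  out
}

#' Rank receptor-ligand pairs within one spot
#'
#' Pairs are ordered by descending joint (mean) expression of receptor and
#' ligand in the spot; ties break lexicographically on the pair name.
#'
#' @param em an `expr_matrix` at stage `normalized` or `log`.
#' @param barcode spot barcode.
#' @param pairs an `rli_pairs` table; pairs with absent genes are skipped
#'   with a warning.
#' @return data frame with columns `receptor`, `ligand`, `pair`,
#'   `joint_mean_expression`, ordered best first.
#' @export
rank_rli_pairs <- function(em, barcode, pairs) {
  check_rli_stage(em)
  if (!barcode %in% colnames(em)) stop2("unknown spot barcode: %s", barcode)
  present <- pairs$receptor %in% rownames(em) & pairs$ligand %in% rownames(em)
  if (any(!present))
    warn2("skipping %d pair(s) with genes absent from the matrix",
          sum(!present))
  pairs <- pairs[present, , drop = FALSE]
  v <- unclass_matrix(em)[, barcode]
  score <- (v[pairs$receptor] + v[pairs$ligand]) / 2
  pair_name <- paste(pairs$receptor, pairs$ligand, sep = "_")
  ord <- order(-score, pair_name, method = "radix")
  data.frame(receptor = pairs$receptor[ord], ligand = pairs$ligand[ord],
             pair = pair_name[ord],
             joint_mean_expression = unname(score[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Hex distance on Visium array coordinates. Space Ranger uses
# "doubled-width" coordinates (array_col shares the parity of array_row,
# stepping by 2 within a row), for which the lattice distance is
#   dy + max(0, (dx - dy) / 2),  dx = |col1-col2|, dy = |row1-row2|.
hex_distance <- function(row1, col1, row2, col2) {
  dx <- abs(col1 - col2)
  dy <- abs(row1 - row2)
  dy + pmax(0, (dx - dy) / 2)
}

#' Spots within a hex-lattice ring of a spot
#'
#' Neighbourhood on the Visium array: all in-tissue spots whose hex-lattice
#' distance from the centre spot is at most `ring`. `ring = 0` returns just
#' the spot itself; an interior spot with `ring = 1` has six neighbours.
#'
#' @param layout a [spatial_layout()].
#' @param barcode centre spot barcode (must be in the layout).
#' @param ring non-negative integer ring radius.
#' @return character vector of barcodes (centre included), in layout order.
#' @export
rli_neighborhood <- function(layout, barcode, ring = 1L) {
  i <- match(barcode, layout$barcode)
  if (is.na(i)) stop2("unknown spot barcode: %s", barcode)
  d <- hex_distance(layout$array_row[[i]], layout$array_col[[i]],
                    layout$array_row, layout$array_col)
  layout$barcode[layout$in_tissue & d <= ring]
}
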