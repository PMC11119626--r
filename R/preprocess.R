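#' Preprocessing configuration
#'
#' Bundles the knobs that turn raw spot counts into the normalized,
#' log-scaled, gene-centred matrix the SOM is trained on.
#'
#' @param min_spots_expressed keep genes detected (count > 0) in at least
#'   this many spots. Default 3: removes all-zero and near-empty profiles
#'   that destabilize map training without biasing module content.
#' @param normalization_target `"median_library_size"` (default; keeps
#'   values on a count-like scale) or `"counts_per_10k"`.
#' @param log_base 2 (default) or `exp(1)`.
#' @param pseudocount added before the log; must be positive.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(min_spots_expressed = 3L,
                              normalization_target = c("median_library_size",
                                                       "counts_per_10k"),
                              log_base = 2, pseudocount = 1) {
  normalization_target <- match.arg(normalization_target)
  if (pseudocount <= 0) stop2("pseudocount must be positive")
  if (min_spots_expressed < 0) stop2("min_spots_expressed must be >= 0")
  if (!log_base %in% c(2, exp(1))) stop2("log_base must be 2 or e")
  structure(list(min_spots_expressed = as.integer(min_spots_expressed),
                 normalization_target = normalization_target,
                 log_base = log_base, pseudocount = pseudocount),
            class = "preprocess_config")
}

#' Filter uninformative genes
#'
#' Keeps genes detected (count > 0) in at least `min_spots_expressed` spots
#' and with nonzero variance across spots; gene order is preserved.
#'
#' @param em an [expression_matrix()] at stage `raw_counts`.
#' @param config a [preprocess_config()].
#' @return the filtered `expr_matrix` (still `raw_counts`).
#' @export
filter_genes <- function(em, config = preprocess_config()) {
  if (expr_stage(em) != "raw_counts")
    stop2("filter_genes expects raw counts, got stage '%s'", expr_stage(em))
  v <- unclass_matrix(em)
  detected <- rowSums(v > 0) >= config$min_spots_expressed
  nonconst <- apply(v, 1, function(r) any(r != r[[1]]))
  keep <- detected & nonconst
  if (!any(keep))
    stop2("no gene passes the filter (min_spots_expressed = %d)",
          config$min_spots_expressed)
  restage(v[keep, , drop = FALSE], "raw_counts")
}

#' Normalize spot library sizes
#'
#' Scales each spot (column) so its total equals the target: the median
#' library size across spots by default, or 10,000.
#'
#' @inheritParams filter_genes
#' @return an `expr_matrix` at stage `normalized`.
#' @export
normalize_spots <- function(em, config = preprocess_config()) {
  if (expr_stage(em) != "raw_counts")
    stop2("normalize_spots expects raw counts, got stage '%s'", expr_stage(em))
  v <- unclass_matrix(em)
  totals <- colSums(v)
  if (any(totals == 0))
    stop2("spot(s) with zero total counts: %s",
          paste(colnames(v)[totals == 0], collapse = ", "))
  target <- switch(config$normalization_target,
                   median_library_size = median(totals),
                   counts_per_10k = 1e4)
  restage(sweep(v, 2, target / totals, `*`), "normalized")
}

#' Log-transform normalized expression
#'
#' @inheritParams filter_genes
#' @return an `expr_matrix` at stage `log`, carrying a `log_base` attribute
#'   used downstream (e.g. when pathway node values are folded back to a
#'   linear scale).
#' @export
log_transform <- function(em, config = preprocess_config()) {
  if (expr_stage(em) != "normalized")
    stop2("log_transform expects normalized values, got stage '%s'",
          expr_stage(em))
  v <- log(unclass_matrix(em) + config$pseudocount, base = config$log_base)
  if (any(!is.finite(v))) stop2("log transform produced non-finite values")
  out <- restage(v, "log")
  attr(out, "log_base") <- config$log_base
  out
}

#' Centre each gene on its mean across spots
#'
#' Subtracting the per-gene mean log expression is what makes SOM portraits
#' signed: positive metagene values read as overexpression relative to the
#' gene's average over the section, negative as underexpression.
#'
#' @param em an `expr_matrix` at stage `log`.
#' @return an `expr_matrix` at stage `centralized`; every row mean is zero
#'   to floating-point tolerance.
#' @export
centralize <- function(em) {
  if (expr_stage(em) != "log")
    stop2("centralize expects log-scale values, got stage '%s'", expr_stage(em))
  base <- attr(em, "log_base")
  v <- unclass_matrix(em)
  v <- v - rowMeans(v)
  if (any(!is.finite(v))) stop2("centralization produced non-finite values")
  out <- restage(v, "centralized")
  attr(out, "log_base") <- base
  out
}

#' Log-transform and centralize in one step
#'
#' @inheritParams filter_genes
#' @return an `expr_matrix` at stage `centralized`.
#' @export
log_and_centralize <- function(em, config = preprocess_config()) {
  centralize(log_transform(em, config))
}

#' Full preprocessing chain
#'
#' `filter_genes()`, `normalize_spots()`, `log_transform()`, `centralize()`
#' in sequence. The intermediate `log`-stage matrix is also returned since
#' receptor-ligand thresholding works on that scale (centralized values are
#' signed relative levels, not detection).
#'
#' @inheritParams filter_genes
#' @return list with elements `centralized` and `log`.
#' @export
preprocess <- function(em, config = preprocess_config()) {
  lg <- log_transform(normalize_spots(filter_genes(em, config), config), config)
  list(centralized = centralize(lg), log = lg)
}
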