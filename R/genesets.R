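#' Map a gene set into the SOM
#'
#' Counts, per grid unit, how many members of the set are assigned there.
#' Comparing such gene set maps with the red modules of expression
#' portraits links map regions to known functional signatures.
#'
#' @param model a `som_model`.
#' @param genes character vector of member gene ids.
#' @param set_name name stored on the result.
#' @return a `geneset_map`: list with grid-shaped integer `counts` and
#'   `set_name`. Members absent from the model are ignored (empty
#'   intersection gives an all-zero map with a warning).
#' @export
geneset_map <- function(model, genes, set_name = "gene set") {
  counts <- matrix(0L, model$grid_rows, model$grid_cols)
  present <- intersect(unique(genes), model$gene_ids)
  if (length(present) == 0)
    warn2("no member of '%s' is present in the model", set_name)
  for (g in present) {
    rc <- model$assignment[g, ]
    counts[rc[["row"]], rc[["col"]]] <- counts[rc[["row"]], rc[["col"]]] + 1L
  }
  structure(list(counts = counts, set_name = set_name),
            class = "geneset_map")
}

#' Per-spot gene set score
#'
#' Mean centralized expression of the set's member genes in each spot;
#' positive where the signature is overexpressed relative to its average
#' over the section.
#'
#' @param em an `expr_matrix` at stage `centralized`.
#' @param genes character vector of member gene ids.
#' @param set_name used in error messages.
#' @return named numeric vector over spots.
#' @export
geneset_spot_score <- function(em, genes, set_name = "gene set") {
  if (expr_stage(em) != "centralized")
    stop2("geneset_spot_score expects centralized data, got stage '%s'",
          expr_stage(em))
  present <- intersect(unique(genes), rownames(em))
  if (length(present) == 0)
    stop2("no member of gene set '%s' is present in the matrix", set_name)
  colMeans(unclass_matrix(em)[present, , drop = FALSE])
}

#' One-sided hypergeometric enrichment p-value
#'
#' Probability of observing at least `overlap` shared genes when
#' `module_size` genes are drawn without replacement from a universe of
#' `universe_size` genes of which `set_size` belong to the set.
#'
#' @param overlap,module_size,set_size,universe_size integers.
#' @return p-value in `[0, 1]`.
#' @export
hypergeom_enrichment_p <- function(overlap, module_size, set_size,
                                   universe_size) {
  phyper(overlap - 1, set_size, universe_size - set_size, module_size,
         lower.tail = FALSE)
}

#' Module / gene set enrichment
#'
#' Tests every (module gene list, gene set) pair for overrepresentation
#' with a one-sided hypergeometric test, then applies Benjamini-Hochberg
#' FDR control across all pairs. Gene sets are intersected with the
#' universe first; the universe defaults to (and must cover) the analysed
#' genes.
#'
#' @param modules a `module_set`.
#' @param collection a [gene_set_collection()].
#' @param universe character vector of background gene ids; must contain
#'   every module gene.
#' @return data frame with columns `module_label`, `set_name`, `overlap`,
#'   `module_size`, `set_size_in_universe`, `universe_size`, `p_value`,
#'   `fdr`, ordered by increasing p-value.
#' @export
enrich_modules <- function(modules, collection, universe) {
  universe <- unique(universe)
  for (m in modules$modules) {
    out <- setdiff(m$gene_ids, universe)
    if (length(out) > 0)
      stop2("module %s contains gene(s) outside the universe: %s",
            m$label, paste(utils::head(out, 5), collapse = ", "))
  }
  rows <- list()
  for (m in modules$modules) {
    mod_genes <- unique(m$gene_ids)
    for (s in names(collection)) {
      set_in_universe <- intersect(collection[[s]], universe)
      ov <- length(intersect(mod_genes, set_in_universe))
      rows[[length(rows) + 1L]] <- data.frame(
        module_label = m$label, set_name = s, overlap = ov,
        module_size = length(mod_genes),
        set_size_in_universe = length(set_in_universe),
        universe_size = length(universe),
        p_value = hypergeom_enrichment_p(ov, length(mod_genes),
                                         length(set_in_universe),
                                         length(universe)),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, res$module_label, res$set_name), ]
}
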