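# Pathway signal flow: propagate expression-derived node activities
# through a signed directed pathway graph from sources towards sinks.
#
# The propagation rule used here is multiplicative with reciprocal
# inhibition and geometric-mean fan-in; it is this package's declared
# choice (exposed and swappable), satisfying the qualitative contract that
# activity flows along the topology from sources to sinks.

#' Node activity values for one spot cluster
#'
#' For each pathway node, a fold-change-like positive value: the log base
#' raised to the mean centralized log expression of the node's genes over
#' the cluster's spots. Genes at their section-wide average give 1;
#' overexpression in the cluster gives > 1. Nodes with no matched gene
#' (e.g. small-molecule or process nodes) get the neutral value 1.
#'
#' @param em an `expr_matrix` at stage `centralized`.
#' @param labels a [spot_labels()] object.
#' @param cluster label of the cluster to profile.
#' @param graph a [pathway_graph()].
#' @param node_genes optional named list mapping node id -> gene ids; by
#'   default a node id is matched directly against the matrix's gene ids.
#' @return named numeric vector of positive node values.
#' @export
node_values_from_cluster <- function(em, labels, cluster, graph,
                                     node_genes = NULL) {
  if (expr_stage(em) != "centralized")
    stop2("node values need centralized data, got stage '%s'", expr_stage(em))
  spots <- intersect(labels$barcode[labels$label == cluster], colnames(em))
  if (length(spots) == 0) stop2("cluster '%s' is empty", cluster)
  base <- attr(em, "log_base")
  if (is.null(base)) base <- 2
  v <- unclass_matrix(em)[, spots, drop = FALSE]
  vals <- vapply(graph$nodes, function(node) {
    genes <- if (is.null(node_genes)) node else node_genes[[node]]
    genes <- intersect(genes, rownames(v))
    if (length(genes) == 0) return(1)
    base^mean(v[genes, , drop = FALSE])
  }, numeric(1))
  setNames(vals, graph$nodes)
}

#' Propagate node values through a pathway graph
#'
#' Evaluates nodes in topological order. Source nodes keep their own
#' value. Every other node's signal is its own value times the combined
#' input of its parents: an activating edge contributes the parent's
#' signal, an inhibiting edge the reciprocal of the parent's signal, and
#' multiple inputs combine by their geometric mean.
#'
#' Cycles are handled (when `condense_cycles = TRUE`) by collapsing each
#' strongly connected component to a single node whose value is the
#' geometric mean of its members' values — an explicit approximation; with
#' condensation disabled a cyclic graph is an error listing the cycle.
#'
#' @param graph a [pathway_graph()].
#' @param values named numeric vector of positive node values (see
#'   [node_values_from_cluster()]).
#' @param condense_cycles collapse strongly connected components first?
#' @return a `psf_result` data frame with columns `node`, `value`,
#'   `signal`, `is_source`, `is_sink`. For condensed cycles every member
#'   node reports its component's signal.
#' @export
propagate_psf <- function(graph, values, condense_cycles = TRUE) {
  if (!all(graph$nodes %in% names(values)))
    stop2("missing value for node(s): %s",
          paste(setdiff(graph$nodes, names(values)), collapse = ", "))
  values <- values[graph$nodes]
  if (any(!is.finite(values)) || any(values <= 0))
    stop2("node values must be positive and finite")

  g <- igraph::graph_from_data_frame(
    graph$edges[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = graph$nodes))
  scc <- igraph::components(g, mode = "strong")
  has_cycle <- any(scc$csize > 1) ||
    any(graph$edges$source == graph$edges$target)
  if (has_cycle && !condense_cycles) {
    cyc <- if (any(scc$csize > 1))
      graph$nodes[scc$membership == which(scc$csize > 1)[[1]]]
    else graph$edges$source[graph$edges$source == graph$edges$target][[1]]
    stop2("pathway graph contains a cycle (%s); enable condense_cycles to collapse it",
          paste(cyc, collapse = " -> "))
  }

  memb <- scc$membership[graph$nodes]
  n_comp <- scc$no
  comp_value <- vapply(seq_len(n_comp), function(k)
    exp(mean(log(values[memb == k]))), numeric(1))

  # condensed edge list (drop intra-component edges, dedupe)
  es <- unique(data.frame(source = memb[graph$edges$source],
                          target = memb[graph$edges$target],
                          sign = graph$edges$sign))
  es <- es[es$source != es$target, , drop = FALSE]

  cg <- igraph::graph_from_data_frame(
    data.frame(from = as.character(es$source), to = as.character(es$target)),
    directed = TRUE, vertices = data.frame(name = as.character(seq_len(n_comp))))
  topo <- as.integer(igraph::topo_sort(cg, mode = "out")$name)

  signal <- comp_value
  for (k in topo) {
    inc <- es[es$target == k, , drop = FALSE]
    if (nrow(inc) == 0) next  # source component: signal = own value
    contrib <- ifelse(inc$sign > 0, signal[inc$source], 1 / signal[inc$source])
    signal[k] <- comp_value[k] * exp(mean(log(contrib)))
  }

  out <- data.frame(node = graph$nodes, value = unname(values),
                    signal = unname(signal[memb]),
                    is_source = graph$nodes %in% graph$sources,
                    is_sink = graph$nodes %in% graph$sinks,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("psf_result", "data.frame")
  out
}

#' Cluster-wise pathway signal flow
#'
#' Runs [node_values_from_cluster()] and [propagate_psf()] for every
#' cluster label and returns the per-sink signals.
#'
#' @param em an `expr_matrix` at stage `centralized`.
#' @param labels a [spot_labels()] object.
#' @param graph a [pathway_graph()].
#' @param node_genes optional node -> genes map (see
#'   [node_values_from_cluster()]).
#' @return data frame with columns `cluster`, `node`, `signal` for every
#'   sink node.
#' @export
psf_by_cluster <- function(em, labels, graph, node_genes = NULL) {
  clusters <- sort(unique(labels$label))
  rows <- lapply(clusters, function(cl) {
    vals <- node_values_from_cluster(em, labels, cl, graph, node_genes)
    res <- propagate_psf(graph, vals)
    sinks <- res[res$is_sink, , drop = FALSE]
    data.frame(cluster = cl, node = sinks$node, signal = sinks$signal,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
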