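#' Thresholded co-occurrence network
#'
#' Builds the display network of a community: pairwise Spearman rank
#' correlations between taxa across samples, keeping an edge only when
#' `|r| > r_threshold` and the two-sided p-value is below `p_threshold`
#' (the conventional r > 0.6, P < 0.05 rule). Taxa with zero variance
#' are excluded.
#'
#' @param x a [count_table()] or samples x taxa abundance matrix.
#' @param r_threshold absolute correlation threshold (default 0.6).
#' @param p_threshold significance threshold (default 0.05).
#' @param method correlation method (default `"spearman"`).
#' @return list with `edges` (data.frame `from`, `to`, `r`, `p`, `sign`)
#'   and `nodes` (taxa entering the correlation screen).
#' @export
cooccurrence_network <- function(x, r_threshold = 0.6, p_threshold = 0.05,
                                 method = "spearman") {
  m <- if (inherits(x, "count_table")) rel_abundance(x) else as.matrix(x)
  if (nrow(m) < 4) stop("need at least 4 samples")
  keep <- apply(m, 2, stats::sd) > 0
  m <- m[, keep, drop = FALSE]
  taxa <- colnames(m)
  edges <- list()
  if (length(taxa) >= 2) {
    for (i in seq_len(length(taxa) - 1L)) {
      for (j in seq.int(i + 1L, length(taxa))) {
        ct <- suppressWarnings(
          stats::cor.test(m[, i], m[, j], method = method, exact = FALSE))
        r <- unname(ct$estimate)
        if (!is.na(r) && abs(r) > r_threshold && ct$p.value < p_threshold) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = taxa[i], to = taxa[j], r = r, p = ct$p.value,
            sign = ifelse(r > 0, "+", "-"), stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(), to = character(), r = numeric(),
               p = numeric(), sign = character(), stringsAsFactors = FALSE)
  list(edges = edges, nodes = taxa)
}

#' Topology of a co-occurrence network
#'
#' Degree, closeness centrality and betweenness centrality on the
#' unweighted graph. Disconnected networks are handled per connected
#' component: closeness is computed within each component (the standard
#' convention for disconnected graphs); isolated nodes get closeness 0.
#'
#' @param net result of [cooccurrence_network()].
#' @return data.frame `taxon`, `degree`, `closeness`, `betweenness`,
#'   `component`.
#' @export
network_topology <- function(net) {
  nodes <- net$nodes
  if (!length(nodes)) {
    return(data.frame(taxon = character(), degree = numeric(),
                      closeness = numeric(), betweenness = numeric(),
                      component = integer(), stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE)
  clo <- rep(0, length(nodes)); names(clo) <- nodes
  for (k in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == k]
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    clo[members] <- igraph::closeness(sub)
  }
  data.frame(taxon = nodes, degree = unname(deg[nodes]),
             closeness = unname(clo[nodes]),
             betweenness = unname(btw[nodes]),
             component = unname(comp$membership[nodes]),
             stringsAsFactors = FALSE)
}
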