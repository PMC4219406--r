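# Markov clustering of one connected component, given its dense symmetric
# weight matrix. Self-loops are set to each node's maximum incident weight,
# columns are normalized, and expansion (matrix square) alternates with
# inflation (elementwise power + renormalization) and pruning until the
# column-stochastic matrix stabilizes. Clusters are the connected components
# of the attractor structure (nonzero pattern of the limit matrix).
.mcl_component <- function(W, inflation, max_iter, tol, prune) {
  n <- nrow(W)
  if (n == 1L) return(list(seq_len(1L)))
  loops <- apply(W, 1L, max)
  loops[loops <= 0] <- 1
  diag(W) <- loops
  M <- sweep(W, 2L, colSums(W), "/")
  for (iter in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2 ^ inflation
    M2 <- sweep(M2, 2L, colSums(M2), "/")
    if (prune > 0) {
      M2[M2 < prune] <- 0
      M2 <- sweep(M2, 2L, colSums(M2), "/")
    }
    change <- max(abs(M2 - M))
    M <- M2
    if (change < tol) break
  }
  A <- (M > max(prune, 1e-8)) | t(M > max(prune, 1e-8))
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(A, mode = "undirected"))
  split(seq_len(n), comp$membership)
}

#' Markov clustering of the ortholog graph into COGs
#'
#' Runs MCL independently on each connected component of the graph (distinct
#' components are never merged). Proteins without any surviving edge become
#' singleton COGs. Cluster ids are assigned deterministically by descending
#' size, ties broken by the lexicographically smallest member protein id.
#'
#' @param graph An [build_ortholog_graph()] result.
#' @param params A [cluster_params()] object.
#' @return A data.frame of COG membership with columns `cog_id`, `genome_id`,
#'   `protein_id`, one row per protein (the COGs partition the input).
#' @export
mcl_cluster <- function(graph, params = cluster_params()) {
  stopifnot(inherits(graph, "ortholog_graph"))
  edges <- graph$edges
  if (nrow(edges) && any(!is.finite(edges$weight)))
    stop("non-finite edge weight in ortholog graph")
  if (nrow(edges) && any(edges$weight < 0))
    stop("negative edge weight in ortholog graph")
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(graph$proteins),
                            name = graph$proteins)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$p1, edges$p2),
                           weight = edges$weight)
  comp <- igraph::components(g)
  clusters <- list()
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    vnames <- igraph::V(g)$name[vids]
    if (length(vids) == 1L) {
      clusters[[length(clusters) + 1L]] <- vnames
      next
    }
    sub <- igraph::induced_subgraph(g, vids)
    W <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    parts <- .mcl_component(W, params$inflation, params$mcl_max_iter,
                            params$mcl_tol, params$mcl_prune)
    for (p in parts)
      clusters[[length(clusters) + 1L]] <- igraph::V(sub)$name[p]
  }
  sizes <- lengths(clusters)
  first_member <- vapply(clusters, function(m) min(m), character(1))
  ord <- order(-sizes, first_member)
  clusters <- clusters[ord]
  width <- max(4L, nchar(length(clusters)))
  ids <- sprintf(paste0("COG%0", width, "d"), seq_along(clusters))
  out <- data.frame(
    cog_id = rep(ids, lengths(clusters)),
    protein_id = unlist(clusters, use.names = FALSE),
    stringsAsFactors = FALSE)
  out$genome_id <- unname(graph$genome_map[out$protein_id])
  out <- out[, c("cog_id", "genome_id", "protein_id")]
  rownames(out) <- NULL
  out
}
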