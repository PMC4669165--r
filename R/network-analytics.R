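#' Degree and betweenness centralities
#'
#' Degree is the total number of incident edges (in + out, parallel signed
#' edges counted separately). Betweenness is computed on the directed,
#' unweighted simple projection (parallel edges collapsed): the number of
#' shortest paths passing through a node as an interior point, with
#' fractional credit when several shortest paths tie.
#'
#' @param graph A non-empty [signed_digraph()].
#' @return A tibble with columns `node`, `degree`, `betweenness`, sorted by
#'   decreasing degree.
#' @export
centralities <- function(graph) {
  stopifnot_sdg(graph)
  if (n_nodes(graph) == 0) stop("graph is empty", call. = FALSE)
  ig_multi <- as_igraph(graph, directed = TRUE, collapse = FALSE)
  deg <- igraph::degree(ig_multi, mode = "all", loops = TRUE)
  ig_simple <- as_igraph(graph, directed = TRUE, collapse = TRUE)
  btw <- igraph::betweenness(ig_simple, directed = TRUE, weights = NA)
  tibble::tibble(node = names(deg),
                 degree = as.integer(unname(deg)),
                 betweenness = unname(btw[names(deg)])) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
}

#' Network key nodes
#'
#' A key node ranks among the top-`k` nodes by degree centrality *and* among
#' the top-`k` by betweenness centrality. Ties at rank `k` are all included,
#' so each candidate list may exceed `k` entries. Graphs with fewer than `k`
#' nodes use every node for both lists (with a message).
#'
#' @param graph A non-empty [signed_digraph()].
#' @param k Rank cut-off, default 15.
#' @return Character vector of key node ids, ordered by decreasing degree.
#' @export
key_nodes <- function(graph, k = 15L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  ct <- centralities(graph)
  if (nrow(ct) < k) {
    message("graph has fewer than k = ", k, " nodes; using all nodes")
    return(ct$node)
  }
  top_with_ties <- function(values) {
    cutoff <- sort(values, decreasing = TRUE)[k]
    ct$node[values >= cutoff]
  }
  top_deg <- top_with_ties(ct$degree)
  top_btw <- top_with_ties(ct$betweenness)
  ct$node[ct$node %in% intersect(top_deg, top_btw)]
}

#' Community detection by fast greedy modularity optimization
#'
#' Runs Clauset-Newman-Moore greedy agglomerative modularity maximization
#' (igraph's `cluster_fast_greedy`, the implementation the approach was
#' built around) on the undirected, unweighted, loop-free simple projection
#' of the graph, and returns the partition at maximal modularity along the
#' merge path. The algorithm is deterministic for a given node ordering; its
#' tie-break among equal-gain merges is the implementation's fixed scan
#' order.
#'
#' @param graph A non-empty [signed_digraph()]. Disconnected graphs are
#'   allowed; singleton components form their own communities.
#' @return An object of class `community_partition`: a list with
#'   `$membership` (tibble `node`, `community`, indices contiguous from 0)
#'   and `$modularity`.
#' @export
detect_communities <- function(graph) {
  stopifnot_sdg(graph)
  if (n_nodes(graph) == 0) stop("graph is empty", call. = FALSE)
  ig <- as_igraph(graph, directed = FALSE, collapse = TRUE)
  cl <- igraph::cluster_fast_greedy(ig)
  # cut the dendrogram explicitly at the maximal-modularity step (first
  # maximum when tied, i.e. the finer partition)
  n_comm <- igraph::vcount(ig) - (which.max(cl$modularity) - 1L)
  memb <- igraph::cut_at(cl, no = n_comm)
  names(memb) <- igraph::V(ig)$name
  # relabel community indices contiguously from 0 in order of first appearance
  idx <- as.integer(factor(memb, levels = unique(memb))) - 1L
  structure(
    list(
      membership = tibble::tibble(node = names(memb), community = idx),
      modularity = igraph::modularity(ig, memb)
    ),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("<community_partition> %d nodes in %d communities (modularity %.4f)\n",
              nrow(x$membership), length(unique(x$membership$community)),
              x$modularity))
  invisible(x)
}

#' @rdname detect_communities
#' @param x A `community_partition`.
#' @param ... Unused.
#' @export
tidy.community_partition <- function(x, ...) x$membership

#' @rdname detect_communities
#' @export
glance.community_partition <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$membership),
                 n_communities = length(unique(x$membership$community)),
                 modularity = x$modularity)
}

#' Modularity of an explicit partition
#'
#' Direct recomputation of Newman-Girvan modularity on the undirected simple
#' projection, used to check reported partition scores.
#'
#' @param graph A [signed_digraph()].
#' @param membership Named vector or tibble (`node`, `community`).
#' @return Modularity value.
#' @export
partition_modularity <- function(graph, membership) {
  if (is.data.frame(membership)) {
    membership <- stats::setNames(membership$community, membership$node)
  }
  ig <- as_igraph(graph, directed = FALSE, collapse = TRUE)
  igraph::modularity(ig, membership[igraph::V(ig)$name] + 1L)
}

#' Extract the subnetwork induced by a gene list across several networks
#'
#' Unions, over all supplied networks, the edges whose *both* endpoints are
#' in the gene list; duplicate triples collapse. Used to survey how a
#' curated list of pathway genes is interconnected across the merged
#' networks.
#'
#' @param networks Named list of [signed_digraph()]s (gene-labelled nodes).
#' @param genes Non-empty character vector of gene symbols.
#' @return A [signed_digraph()] with attribute `n_connected`, the number of
#'   listed genes with degree >= 1 in the subnetwork (also retrievable via
#'   [n_connected_genes()]).
#' @export
extract_gene_subnetwork <- function(networks, genes) {
  if (length(genes) == 0) stop("gene list is empty", call. = FALSE)
  genes <- unique(as.character(genes))
  edges <- dplyr::distinct(purrr::map_dfr(networks, function(net) {
    e <- net$edges
    e[e$source %in% genes & e$target %in% genes, , drop = FALSE]
  }))
  sub <- signed_digraph(edges)
  attr(sub, "n_connected") <- sum(genes %in% node_ids(sub))
  sub
}

#' @rdname extract_gene_subnetwork
#' @param subnetwork Result of `extract_gene_subnetwork()`.
#' @export
n_connected_genes <- function(subnetwork) {
  attr(subnetwork, "n_connected")
}
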