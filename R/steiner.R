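#' Map differential genes onto network terminals
#'
#' Terminal nodes are the network nodes matched by an up- or down-regulated
#' differential gene. Because the tree heuristic needs a connected host
#' graph, terminals are restricted to the largest connected component of
#' the network's undirected projection; gene symbols absent from the
#' network, or falling outside that component, are reported as dropped
#' rather than silently lost.
#'
#' @param network A gene-labelled [signed_digraph()].
#' @param up,down Disjoint character vectors of up-/down-regulated gene
#'   symbols.
#' @return A list with `terminals` (node ids) and `dropped` (symbols).
#' @export
map_terminals <- function(network, up, down) {
  stopifnot_sdg(network, "network")
  if (length(intersect(up, down)) > 0) {
    stop("up and down gene sets must be disjoint", call. = FALSE)
  }
  degs <- unique(c(up, down))
  ig <- as_igraph(network, directed = FALSE, collapse = TRUE)
  comp <- igraph::components(ig)
  main <- names(comp$membership)[comp$membership == which.max(comp$csize)]
  terminals <- intersect(degs, main)
  if (length(terminals) == 0) {
    stop("no DEGs map to network", call. = FALSE)
  }
  list(terminals = terminals, dropped = setdiff(degs, terminals))
}

# undirected simple adjacency list with lexicographically sorted neighbours
und_adjacency <- function(edges, nodes) {
  pairs <- unique(rbind(
    data.frame(a = edges$source, b = edges$target),
    data.frame(a = edges$target, b = edges$source)
  ))
  pairs <- pairs[pairs$a != pairs$b, , drop = FALSE]
  adj <- split(pairs$b, factor(pairs$a, levels = nodes))
  lapply(adj, function(v) sort(unique(v)))
}

bfs_distances <- function(adj, start) {
  dist <- stats::setNames(rep(NA_integer_, length(adj)), names(adj))
  dist[start] <- 0L
  frontier <- start
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    if (length(nxt) == 0) break
    dist[nxt] <- dist[frontier[1]] + 1L
    frontier <- nxt
  }
  dist
}

# shortest path from `from` to `to` given distances from `from`;
# deterministic: lexicographically smallest predecessor at every step
reconstruct_path <- function(adj, dist_from, to) {
  path <- to
  v <- to
  while (dist_from[v] > 0L) {
    preds <- adj[[v]]
    preds <- preds[!is.na(dist_from[preds]) & dist_from[preds] == dist_from[v] - 1L]
    v <- sort(preds)[1]
    path <- c(v, path)
  }
  path
}

#' Steiner tree approximation over terminal nodes
#'
#' Kou-Markowsky-Berman 2-approximation on the undirected, unweighted (hop
#' metric) simple projection of the network: build the metric closure over
#' the terminals, take its minimum spanning tree, expand every closure edge
#' into a shortest path in the host graph, take a spanning tree of that
#' expansion, and prune non-terminal leaves. Non-terminal nodes introduced
#' to keep the tree connected are the Steiner nodes. All tie-breaks
#' (shortest-path predecessor choice, closure-MST edge order, spanning-tree
#' traversal) are lexicographic, so the result is deterministic.
#'
#' @param network A [signed_digraph()].
#' @param terminals Node ids, all within one connected component of the
#'   undirected projection (see [map_terminals()]).
#' @return A list with `nodes` (character), `edges` (tibble `from`, `to` of
#'   undirected tree edges) and `terminals`.
#' @export
steiner_tree <- function(network, terminals) {
  stopifnot_sdg(network, "network")
  terminals <- sort(unique(as.character(terminals)))
  missing_t <- setdiff(terminals, node_ids(network))
  if (length(missing_t) > 0) {
    stop("terminal(s) not in network: ", paste(missing_t, collapse = ", "),
         call. = FALSE)
  }
  adj <- und_adjacency(network$edges, node_ids(network))
  dists <- lapply(stats::setNames(terminals, terminals),
                  function(t) bfs_distances(adj, t))
  reach <- dists[[1]][terminals]
  if (any(is.na(reach))) {
    stop("terminals lie in different connected components: restrict to one ",
         "component first (see map_terminals)", call. = FALSE)
  }
  if (length(terminals) == 1) {
    return(list(nodes = terminals,
                edges = tibble::tibble(from = character(), to = character()),
                terminals = terminals))
  }

  # metric closure MST (Kruskal, edges ordered by weight then endpoints)
  closure <- purrr::map_dfr(seq_along(terminals), function(i) {
    if (i == length(terminals)) return(NULL)
    tibble::tibble(from = terminals[i],
                   to = terminals[(i + 1):length(terminals)],
                   w = unname(dists[[terminals[i]]][terminals[(i + 1):length(terminals)]]))
  })
  closure <- closure[order(closure$w, closure$from, closure$to), , drop = FALSE]
  parent <- stats::setNames(terminals, terminals)
  find_root <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  mst_rows <- integer(0)
  for (i in seq_len(nrow(closure))) {
    ra <- find_root(closure$from[i]); rb <- find_root(closure$to[i])
    if (ra != rb) {
      parent[[ra]] <- rb
      mst_rows <- c(mst_rows, i)
    }
  }
  mst <- closure[mst_rows, , drop = FALSE]

  # expand closure edges into host-graph shortest paths
  sub_edges <- list()
  sub_nodes <- character(0)
  for (i in seq_len(nrow(mst))) {
    p <- reconstruct_path(adj, dists[[mst$from[i]]], mst$to[i])
    sub_nodes <- union(sub_nodes, p)
    if (length(p) > 1) {
      sub_edges[[length(sub_edges) + 1]] <-
        tibble::tibble(a = p[-length(p)], b = p[-1])
    }
  }
  sub_edges <- dplyr::bind_rows(sub_edges)
  und <- dplyr::distinct(tibble::tibble(a = pmin(sub_edges$a, sub_edges$b),
                                        b = pmax(sub_edges$a, sub_edges$b)))

  # spanning tree of the expansion: BFS from the smallest terminal
  sub_adj <- und_adjacency(tibble::tibble(source = und$a, target = und$b),
                           sort(sub_nodes))
  root <- terminals[1]
  visited <- stats::setNames(rep(FALSE, length(sub_adj)), names(sub_adj))
  visited[root] <- TRUE
  queue <- root
  tree <- tibble::tibble(from = character(), to = character())
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in sub_adj[[v]]) {
      if (!visited[u]) {
        visited[u] <- TRUE
        queue <- c(queue, u)
        tree <- dplyr::bind_rows(tree, tibble::tibble(from = v, to = u))
      }
    }
  }

  # prune non-terminal leaves until fixpoint
  repeat {
    deg <- table(c(tree$from, tree$to))
    leaves <- names(deg)[deg == 1]
    drop <- setdiff(leaves, terminals)
    if (length(drop) == 0) break
    tree <- tree[!(tree$from %in% drop) & !(tree$to %in% drop), , drop = FALSE]
  }
  nodes <- sort(unique(c(terminals, tree$from, tree$to)))
  list(nodes = nodes, edges = tree, terminals = terminals)
}

#' Induce a differentially regulated module from tree nodes
#'
#' The module contains *all* directed signed edges of the source network
#' whose both endpoints are tree nodes — not only the tree edges. Node
#' roles (`terminal` for DEG-induced nodes, `steiner` for
#' connectivity-introduced ones) are recorded and terminal nodes are
#' annotated with their log fold-changes from the differential table.
#'
#' @param network The source [signed_digraph()].
#' @param tree_nodes Character vector of module nodes (subset of the
#'   network's nodes).
#' @param terminals Character vector marking which `tree_nodes` are
#'   DEG-induced terminals; the rest are Steiner nodes.
#' @param de_table Gene-level data frame with columns `gene`, `log_fc`.
#' @param provenance Optional free-form list (e.g. network group, DE table
#'   id) stored with the module.
#' @return An object of class `steiner_module`.
#' @export
induce_module <- function(network, tree_nodes, terminals, de_table = NULL,
                          provenance = list()) {
  stopifnot_sdg(network, "network")
  tree_nodes <- unique(as.character(tree_nodes))
  extra <- setdiff(tree_nodes, node_ids(network))
  if (length(extra) > 0) {
    stop("tree node(s) not in network: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  e <- network$edges
  edges <- e[e$source %in% tree_nodes & e$target %in% tree_nodes, ,
             drop = FALSE]
  nodes <- network$nodes[network$nodes$node_id %in% tree_nodes, , drop = FALSE]
  graph <- structure(list(nodes = nodes, edges = edges),
                     class = "signed_digraph")
  roles <- stats::setNames(
    ifelse(tree_nodes %in% terminals, "terminal", "steiner"), tree_nodes
  )
  log_fc <- stats::setNames(rep(NA_real_, length(tree_nodes)), tree_nodes)
  if (!is.null(de_table)) {
    idx <- match(tree_nodes[roles == "terminal"], de_table$gene)
    log_fc[roles == "terminal"] <- de_table$log_fc[idx]
  }
  structure(list(graph = graph, roles = roles, log_fc = log_fc,
                 provenance = provenance),
            class = "steiner_module")
}

#' @export
print.steiner_module <- function(x, ...) {
  cat(sprintf("<steiner_module> %d nodes (%d terminal, %d steiner), %d edges\n",
              n_nodes(x$graph), sum(x$roles == "terminal"),
              sum(x$roles == "steiner"), n_edges(x$graph)))
  invisible(x)
}

#' Tidy a Steiner module into its node table
#'
#' @param x A `steiner_module`.
#' @param ... Unused.
#' @return A tibble with columns `node`, `role`, `log_fc`.
#' @export
tidy.steiner_module <- function(x, ...) {
  tibble::tibble(node = names(x$roles), role = unname(x$roles),
                 log_fc = unname(x$log_fc[names(x$roles)]))
}

#' @rdname tidy.steiner_module
#' @export
glance.steiner_module <- function(x, ...) {
  tibble::tibble(
    n_nodes = n_nodes(x$graph),
    n_terminals = sum(x$roles == "terminal"),
    n_steiner = sum(x$roles == "steiner"),
    n_edges = n_edges(x$graph)
  )
}

#' Extract a differentially regulated module from a network
#'
#' Convenience pipeline: map DEGs to terminals ([map_terminals()]),
#' approximate the Steiner tree ([steiner_tree()]), and induce the module
#' with all network edges among the tree nodes ([induce_module()]).
#'
#' @param network A gene-labelled [signed_digraph()].
#' @param up,down Up-/down-regulated gene symbol vectors.
#' @param de_table Gene-level differential table for fold-change annotation.
#' @param provenance Optional provenance list.
#' @return A `steiner_module`; dropped DEG symbols are available as
#'   attribute `"dropped"`.
#' @export
extract_module <- function(network, up, down, de_table = NULL,
                           provenance = list()) {
  tm <- map_terminals(network, up, down)
  tree <- steiner_tree(network, tm$terminals)
  mod <- induce_module(network, tree$nodes, tm$terminals, de_table,
                       provenance)
  attr(mod, "dropped") <- tm$dropped
  mod
}

#' Node attribute table for module export
#'
#' Fold-changes are clamped to `[-cap, +cap]` for display (color-coding of
#' extreme values saturates at the cap) while the raw value is preserved in
#' its own column. Steiner nodes carry no fold-change: their display value
#' is empty.
#'
#' @param module A `steiner_module`.
#' @param cap Positive clamp for the display value (conventionally 3 for
#'   microarray-derived and 4 for RNA-Seq-derived modules).
#' @return A tibble with columns `node`, `role`, `log_fc_raw`,
#'   `log_fc_display`.
#' @export
annotate_for_export <- function(module, cap = 3) {
  if (length(cap) != 1 || is.na(cap) || cap <= 0) {
    stop("cap must be a positive number", call. = FALSE)
  }
  tab <- tidy(module)
  tibble::tibble(
    node = tab$node,
    role = tab$role,
    log_fc_raw = tab$log_fc,
    log_fc_display = ifelse(tab$role == "steiner", NA_real_,
                            pmin(pmax(tab$log_fc, -cap), cap))
  )
}

#' Write / read a module export
#'
#' A module is exported as two TSV files: `<prefix>.edges.tsv` (`source`,
#' `target`, `weight`) and `<prefix>.nodes.tsv` (the
#' [annotate_for_export()] table).
#'
#' @param module A `steiner_module`.
#' @param prefix Output path prefix.
#' @param cap Display clamp, see [annotate_for_export()].
#' @return `write_module()` returns the two paths invisibly; `read_module()`
#'   returns a `steiner_module` (raw fold-changes restored, display column
#'   ignored).
#' @export
write_module <- function(module, prefix, cap = 3) {
  edge_file <- paste0(prefix, ".edges.tsv")
  node_file <- paste0(prefix, ".nodes.tsv")
  write_sif(module$graph, edge_file)
  readr::write_tsv(annotate_for_export(module, cap), node_file,
                   progress = FALSE)
  invisible(c(edge_file, node_file))
}

#' @rdname write_module
#' @export
read_module <- function(prefix) {
  edge_file <- paste0(prefix, ".edges.tsv")
  node_file <- paste0(prefix, ".nodes.tsv")
  nodes <- read_tsv_strict(node_file, c("node", "role", "log_fc_raw"))
  edges <- read_sif(edge_file)
  # module nodes may include isolated tree nodes absent from the edge list
  graph <- signed_digraph(edges$edges, default_node_table(
    sort(union(nodes$node, node_ids(edges)))
  ))
  roles <- stats::setNames(nodes$role, nodes$node)
  roles[setdiff(node_ids(graph), names(roles))] <- "steiner"
  log_fc <- stats::setNames(suppressWarnings(as.numeric(nodes$log_fc_raw)),
                            nodes$node)
  structure(list(graph = graph, roles = roles[node_ids(graph)],
                 log_fc = log_fc[node_ids(graph)], provenance = list()),
            class = "steiner_module")
}

#' Plot a Steiner module
#'
#' Force-directed drawing with terminals coloured by fold-change (blue =
#' down, red = up, saturating at `cap`) and Steiner nodes drawn smaller and
#' grey; activating edges grey, inhibiting edges orange.
#'
#' @param object A `steiner_module`.
#' @param cap Fold-change saturation for the colour scale.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.steiner_module <- function(object, cap = 3, seed = 1L, ...) {
  ig <- as_igraph(object$graph, directed = TRUE, collapse = FALSE)
  xy <- withr_seed(seed, igraph::layout_with_fr(ig))
  layout <- tibble::tibble(node = igraph::V(ig)$name,
                           x = xy[, 1], y = xy[, 2])
  layout <- dplyr::left_join(layout, annotate_for_export(object, cap),
                             by = "node")
  edges <- object$graph$edges
  edges <- dplyr::left_join(edges, dplyr::select(layout, "node", "x", "y"),
                            by = c(source = "node"))
  edges <- dplyr::left_join(
    edges,
    dplyr::select(layout, "node", xend = "x", yend = "y"),
    by = c(target = "node")
  )
  edges$interaction <- ifelse(edges$sign == 1L, "activation", "inhibition")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$interaction),
      linewidth = 0.3, alpha = 0.6,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))
    ) +
    ggplot2::scale_colour_manual(
      values = c(activation = "grey50", inhibition = "darkorange")
    ) +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$log_fc_display,
                   size = .data$role),
      shape = 21
    ) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-cap, cap), na.value = "grey80") +
    ggplot2::scale_size_manual(values = c(terminal = 4, steiner = 2)) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
      vjust = -1, size = 2.7
    ) +
    ggplot2::theme_void()
}
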