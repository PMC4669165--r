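#' Signed directed graphs of annotated entities
#'
#' `signed_digraph()` is the universal carrier for pathways, merged networks
#' and extracted modules. Nodes are annotated entities (proteins, complexes,
#' small molecules, ...) and every directed edge carries a sign: `+1` for
#' activation, `-1` for inhibition. Edge identity is the full
#' `(source, target, sign)` triple, so a pair of nodes may be connected by two
#' parallel edges of opposite sign. Duplicate triples are collapsed on
#' construction and self-loops are dropped unless `allow_self_loops = TRUE`.
#'
#' @param edges A data frame with columns `source`, `target` (character) and
#'   `sign` (integer, `+1` or `-1`).
#' @param nodes Optional data frame of node annotations with columns
#'   `node_id`, `entity_class`, `reference_ids` (semicolon-joined
#'   `namespace:id` pairs), `gene_symbols` (list column of character vectors,
#'   or a semicolon-joined character column) and `display_name`. When `NULL`,
#'   a minimal annotation table is derived from the edge endpoints: each
#'   endpoint becomes a protein node whose single gene symbol and display
#'   name equal its id.
#' @param allow_self_loops Keep edges with `source == target`? Defaults to
#'   `FALSE` (they are silently dropped), matching the loop-free convention
#'   of the downstream Steiner and modularity algorithms.
#'
#' @return An object of class `signed_digraph`: a list with tibbles `$nodes`
#'   and `$edges`.
#' @export
#' @examples
#' g <- signed_digraph(data.frame(source = "A", target = "B", sign = -1L))
#' g
signed_digraph <- function(edges, nodes = NULL, allow_self_loops = FALSE) {
  edges <- tibble::as_tibble(edges)
  required <- c("source", "target", "sign")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols) > 0) {
    stop("edge table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (!all(edges$sign %in% c(1, -1))) {
    bad <- which(!(edges$sign %in% c(1, -1)))
    stop("edge sign must be 1 or -1; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  edges$sign <- as.integer(edges$sign)
  if (!allow_self_loops) {
    edges <- edges[edges$source != edges$target, , drop = FALSE]
  }
  edges <- dplyr::distinct(edges[, required], .keep_all = FALSE)

  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$source, edges$target)))
    nodes <- default_node_table(ids)
  } else {
    nodes <- as_node_table(nodes)
  }
  if (anyDuplicated(nodes$node_id)) {
    stop("duplicated node_id in node table: ",
         paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(c(edges$source, edges$target)), nodes$node_id)
  if (length(unknown) > 0) {
    stop("edge endpoint(s) not present in node table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "signed_digraph")
}

entity_classes <- function() {
  c("protein", "complex", "small_molecule", "dna", "rna",
    "nested_pathway", "other")
}

default_node_table <- function(ids) {
  tibble::tibble(
    node_id = ids,
    entity_class = rep("protein", length(ids)),
    reference_ids = rep("", length(ids)),
    gene_symbols = as.list(ids),
    display_name = ids
  )
}

as_node_table <- function(nodes) {
  nodes <- tibble::as_tibble(nodes)
  required <- c("node_id", "entity_class", "reference_ids", "gene_symbols",
                "display_name")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0) {
    stop("node table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  nodes$node_id <- as.character(nodes$node_id)
  if (any(!nzchar(nodes$node_id))) {
    stop("node_id must be non-empty", call. = FALSE)
  }
  bad_class <- setdiff(unique(nodes$entity_class), entity_classes())
  if (length(bad_class) > 0) {
    stop("unknown entity_class value(s): ",
         paste(bad_class, collapse = ", "), call. = FALSE)
  }
  if (!is.list(nodes$gene_symbols)) {
    nodes$gene_symbols <- split_multi(nodes$gene_symbols)
  }
  nodes$gene_symbols <- lapply(nodes$gene_symbols, normalize_symbols)
  nodes$reference_ids <- as.character(nodes$reference_ids)
  nodes$reference_ids[is.na(nodes$reference_ids)] <- ""
  nodes$display_name <- as.character(nodes$display_name)
  nodes$display_name[is.na(nodes$display_name)] <- ""
  nodes[, required]
}

# ";"-joined character vector -> list of character vectors
split_multi <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE), function(v) v[nzchar(trimws(v))])
}

normalize_symbols <- function(sym) {
  sym <- toupper(gsub("\\s+", "", as.character(sym)))
  unique(sym[nzchar(sym)])
}

#' @export
print.signed_digraph <- function(x, ...) {
  cat(sprintf("<signed_digraph> %d nodes, %d edges (%d activating, %d inhibiting)\n",
              n_nodes(x), n_edges(x),
              sum(x$edges$sign == 1L), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' Number of nodes / edges of a signed digraph
#' @param graph A `signed_digraph`.
#' @return An integer count.
#' @export
n_nodes <- function(graph) nrow(graph$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' @rdname n_nodes
#' @export
node_ids <- function(graph) graph$nodes$node_id

is_signed_digraph <- function(x) inherits(x, "signed_digraph")

stopifnot_sdg <- function(x, arg = "graph") {
  if (!is_signed_digraph(x)) {
    stop("`", arg, "` must be a signed_digraph", call. = FALSE)
  }
  invisible(x)
}

#' Display label of each node
#'
#' The canonical label is the single gene symbol when the node carries
#' exactly one; otherwise the display name (the instance-name fallback of the
#' source pathway model); otherwise the raw node id.
#'
#' @param graph A `signed_digraph`.
#' @return A named character vector (names are node ids).
#' @export
node_labels <- function(graph) {
  stopifnot_sdg(graph)
  lab <- vapply(seq_len(n_nodes(graph)), function(i) {
    sym <- graph$nodes$gene_symbols[[i]]
    if (length(sym) == 1) return(sym)
    dn <- graph$nodes$display_name[i]
    if (nzchar(dn)) return(dn)
    graph$nodes$node_id[i]
  }, character(1))
  stats::setNames(lab, graph$nodes$node_id)
}

#' Convert a signed digraph to an igraph object
#'
#' @param graph A `signed_digraph`.
#' @param directed Keep edge directions? `FALSE` yields the undirected
#'   projection.
#' @param collapse Collapse parallel edges (and drop any loops), i.e. return
#'   the simple projection used by shortest-path, community and Steiner
#'   algorithms? Signs are not carried over when collapsing.
#' @return An `igraph` object whose vertex names are the node ids. Edge
#'   attribute `sign` is present when `collapse = FALSE`.
#' @export
as_igraph <- function(graph, directed = TRUE, collapse = FALSE) {
  stopifnot_sdg(graph)
  ig <- igraph::graph_from_data_frame(
    d = data.frame(from = graph$edges$source, to = graph$edges$target,
                   sign = graph$edges$sign),
    directed = directed,
    vertices = data.frame(name = graph$nodes$node_id)
  )
  if (collapse) {
    ig <- igraph::simplify(ig, remove.multiple = TRUE, remove.loops = TRUE,
                           edge.attr.comb = "ignore")
  }
  ig
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signed digraph into its edge table
#'
#' @param x A `signed_digraph`.
#' @param ... Unused.
#' @return A tibble with columns `source`, `target`, `sign`.
#' @export
tidy.signed_digraph <- function(x, ...) x$edges

#' One-row summary of a signed digraph
#'
#' @param x A `signed_digraph`.
#' @param ... Unused.
#' @return A tibble with node/edge counts and sign composition.
#' @export
glance.signed_digraph <- function(x, ...) {
  tibble::tibble(
    n_nodes = n_nodes(x),
    n_edges = n_edges(x),
    n_activating = sum(x$edges$sign == 1L),
    n_inhibiting = sum(x$edges$sign == -1L)
  )
}

#' Plot a signed digraph
#'
#' A static force-directed (Fruchterman-Reingold) drawing: activating edges
#' grey, inhibiting edges orange.
#'
#' @param object A `signed_digraph`.
#' @param label_nodes Draw node labels? Default `TRUE` for graphs of at most
#'   50 nodes.
#' @param seed Integer seed for the layout.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.signed_digraph <- function(object, label_nodes = n_nodes(object) <= 50,
                                    seed = 1L, ...) {
  stopifnot_sdg(object)
  ig <- as_igraph(object, directed = TRUE, collapse = FALSE)
  xy <- withr_seed(seed, igraph::layout_with_fr(ig))
  layout <- tibble::tibble(
    node_id = igraph::V(ig)$name, x = xy[, 1], y = xy[, 2]
  )
  edges <- dplyr::left_join(object$edges,
                            dplyr::rename(layout, xend = "x", yend = "y"),
                            by = c(target = "node_id"))
  edges <- dplyr::left_join(edges, layout, by = c(source = "node_id"))
  edges$interaction <- ifelse(edges$sign == 1L, "activation", "inhibition")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$interaction),
      linewidth = 0.3, alpha = 0.7,
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))
    ) +
    ggplot2::scale_colour_manual(
      values = c(activation = "grey40", inhibition = "darkorange")
    ) +
    ggplot2::geom_point(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::theme_void()
  if (label_nodes) {
    p <- p + ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$node_id),
      vjust = -0.8, size = 3
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# run expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @importFrom rlang .data
NULL
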