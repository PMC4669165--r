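#' Select pathways by keyword
#'
#' Keeps records where any keyword occurs case-insensitively as a substring
#' of the pathway name, of any member node's gene symbols, or of any member
#' node's display name. This mirrors how pathways of interest are picked
#' from database exports using terms such as "wnt", "catenin" or "pcp".
#'
#' @param records List of [pathway_record()]s.
#' @param keywords Non-empty character vector of non-empty keywords.
#' @return The matching records, original order preserved.
#' @export
select_pathways_by_keywords <- function(records, keywords) {
  if (length(keywords) == 0 || any(!nzchar(trimws(keywords)))) {
    stop("keywords must be non-empty strings", call. = FALSE)
  }
  kw <- tolower(keywords)
  hit <- vapply(records, function(r) {
    hay <- tolower(c(r$name,
                     unlist(r$graph$nodes$gene_symbols, use.names = FALSE),
                     r$graph$nodes$display_name))
    any(vapply(kw, function(k) any(grepl(k, hay, fixed = TRUE)), logical(1)))
  }, logical(1))
  records[hit]
}

#' Map node reference identifiers to HGNC gene symbols
#'
#' Each node's `gene_symbols` is replaced by the mapped symbols of its
#' `reference_ids` (deduplicated, order of the references preserved).
#' Unmapped references are silently dropped; a node whose references map to
#' nothing keeps an empty symbol list and is later labelled by its display
#' name (the instance-name fallback).
#'
#' @param graph A [signed_digraph()].
#' @param id_map A data frame with columns `namespace`, `id`, `symbol`
#'   mapping `(namespace, id)` pairs (e.g. `("uniprot", "P35222")`) to HGNC
#'   symbols.
#' @return A [signed_digraph()] with updated `gene_symbols`.
#' @export
map_identifiers <- function(graph, id_map) {
  stopifnot_sdg(graph)
  id_map <- tibble::as_tibble(id_map)
  req <- c("namespace", "id", "symbol")
  if (!all(req %in% names(id_map))) {
    stop("id_map needs columns namespace, id, symbol", call. = FALSE)
  }
  lut <- stats::setNames(normalize_symbols_keep_order(id_map$symbol),
                         paste(id_map$namespace, id_map$id, sep = ":"))
  nodes <- graph$nodes
  nodes$gene_symbols <- lapply(nodes$reference_ids, function(refs) {
    keys <- strsplit(refs, ";", fixed = TRUE)[[1]]
    keys <- trimws(keys[nzchar(trimws(keys))])
    syms <- unname(lut[keys])
    unique(syms[!is.na(syms)])
  })
  signed_digraph(graph$edges, nodes)
}

normalize_symbols_keep_order <- function(sym) {
  toupper(gsub("\\s+", "", as.character(sym)))
}

#' Remove non-mappable entities while preserving connectivity
#'
#' Entities that cannot carry gene expression — small molecules, DNA, RNA and
#' nested pathways by default, plus any node with neither a gene symbol nor a
#' display name — are removed from the graph. Connectivity is preserved: for
#' every directed path `u -> r1 -> ... -> rk -> w` whose interior nodes are
#' all removable, a direct edge `u -> w` is added with sign equal to the
#' product of the path's edge signs (so inhibition of an inhibitor
#' activates). Removal is computed by signed reachability through the
#' removable subgraph, so the result does not depend on any removal order.
#' Self-loops arising from rewiring are dropped and duplicate
#' `(source, target, sign)` triples collapse.
#'
#' @param graph A [signed_digraph()].
#' @param removable_classes Entity classes to remove.
#' @return A [signed_digraph()] over the retained nodes.
#' @export
filter_nonmappable_nodes <- function(graph,
                                     removable_classes = c("small_molecule",
                                                           "dna", "rna",
                                                           "nested_pathway")) {
  stopifnot_sdg(graph)
  nodes <- graph$nodes
  removable <- nodes$entity_class %in% removable_classes |
    (lengths(nodes$gene_symbols) == 0 & !nzchar(nodes$display_name))
  rem <- nodes$node_id[removable]
  if (length(rem) == 0) return(graph)
  keep <- nodes$node_id[!removable]
  edges <- graph$edges

  # signed reachability: reach[[r]] = kept targets (and path signs) reachable
  # from removable node r through removable interiors; fixpoint handles
  # chains and cycles of removable nodes
  direct <- function(id) {
    e <- edges[edges$source == id, , drop = FALSE]
    list(kept = e[e$target %in% keep, c("target", "sign")],
         rem  = e[e$target %in% rem,  c("target", "sign")])
  }
  adj <- lapply(stats::setNames(rem, rem), direct)
  reach <- lapply(adj, function(a) dplyr::distinct(a$kept))
  repeat {
    changed <- FALSE
    for (r in rem) {
      acc <- reach[[r]]
      via <- adj[[r]]$rem
      if (nrow(via) > 0) {
        for (i in seq_len(nrow(via))) {
          nxt <- reach[[via$target[i]]]
          if (nrow(nxt) > 0) {
            acc <- rbind(acc, tibble::tibble(target = nxt$target,
                                             sign = via$sign[i] * nxt$sign))
          }
        }
      }
      acc <- dplyr::distinct(acc)
      if (nrow(acc) != nrow(reach[[r]])) {
        reach[[r]] <- acc
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  kept_edges <- edges[edges$source %in% keep & edges$target %in% keep, ,
                      drop = FALSE]
  into_rem <- edges[edges$source %in% keep & edges$target %in% rem, ,
                    drop = FALSE]
  new_edges <- purrr::map_dfr(seq_len(nrow(into_rem)), function(i) {
    hits <- reach[[into_rem$target[i]]]
    if (nrow(hits) == 0) return(NULL)
    tibble::tibble(source = into_rem$source[i], target = hits$target,
                   sign = as.integer(into_rem$sign[i] * hits$sign))
  })
  all_edges <- dplyr::bind_rows(kept_edges, new_edges)
  out <- signed_digraph(all_edges, nodes[!removable, , drop = FALSE])
  if (n_nodes(out) == 0) {
    warning("filtering removed every node; returning an empty graph",
            call. = FALSE)
  }
  out
}

#' Split nodes annotated with several gene symbols
#'
#' A node carrying k > 1 gene symbols is replaced by k single-symbol nodes,
#' each inheriting every incident edge of the original (same directions and
#' signs). Edges between two multi-symbol nodes are expanded to the full
#' cross product.
#'
#' @param graph A [signed_digraph()] after identifier mapping.
#' @return A [signed_digraph()] in which every node has at most one symbol.
#' @export
split_multi_symbol_nodes <- function(graph) {
  stopifnot_sdg(graph)
  nodes <- graph$nodes
  edges <- graph$edges
  multi <- nodes$node_id[lengths(nodes$gene_symbols) > 1]
  for (id in multi) {
    i <- match(id, nodes$node_id)
    syms <- nodes$gene_symbols[[i]]
    new_ids <- paste(id, syms, sep = "|")
    repl <- nodes[rep(i, length(syms)), , drop = FALSE]
    repl$node_id <- new_ids
    repl$gene_symbols <- as.list(syms)
    nodes <- dplyr::bind_rows(nodes[-i, , drop = FALSE], repl)
    expand <- function(e, col) {
      hit <- e[[col]] == id
      if (!any(hit)) return(e)
      dup <- e[rep(which(hit), each = length(new_ids)), , drop = FALSE]
      dup[[col]] <- rep(new_ids, times = sum(hit))
      dplyr::bind_rows(e[!hit, , drop = FALSE], dup)
    }
    edges <- expand(expand(edges, "source"), "target")
  }
  signed_digraph(dplyr::distinct(edges), nodes)
}

#' Merge nodes carrying the same gene symbol
#'
#' After splitting, every gene node carries exactly one symbol; nodes sharing
#' a symbol are merged into one node labelled by that symbol, whose edge set
#' is the union of the constituents' edges with endpoints relabelled.
#' Symbol-less nodes are kept under their display name. Self-loops created by
#' merging are dropped; duplicate triples collapse. In the result, node ids
#' equal the labels (gene symbols or display names).
#'
#' @param graph A [signed_digraph()] whose gene nodes each carry one symbol.
#' @return A [signed_digraph()] with one node per label.
#' @export
merge_same_symbol_nodes <- function(graph) {
  stopifnot_sdg(graph)
  if (any(lengths(graph$nodes$gene_symbols) > 1)) {
    stop("run split_multi_symbol_nodes() first: some nodes carry several symbols",
         call. = FALSE)
  }
  lab <- node_labels(graph)
  edges <- graph$edges
  edges$source <- unname(lab[edges$source])
  edges$target <- unname(lab[edges$target])

  nodes <- graph$nodes
  nodes$.label <- unname(lab[nodes$node_id])
  merged <- nodes |>
    dplyr::group_by(.data$.label) |>
    dplyr::summarise(
      entity_class = if (any(.data$entity_class == "protein")) "protein" else .data$entity_class[1],
      reference_ids = paste(unique(unlist(strsplit(.data$reference_ids, ";", fixed = TRUE))),
                            collapse = ";"),
      gene_symbols = list(unique(unlist(.data$gene_symbols))),
      display_name = {
        dn <- .data$display_name[nzchar(.data$display_name)]
        if (length(dn) > 0) dn[1] else .data$.label[1]
      },
      .groups = "drop"
    ) |>
    dplyr::rename(node_id = ".label")
  signed_digraph(edges, merged)
}

#' Transform an annotated pathway graph into a gene-level graph
#'
#' Convenience pipeline: optional identifier mapping, then
#' connectivity-preserving removal of non-mappable entities, then splitting
#' of multi-symbol nodes and merging of same-symbol nodes. The result is a
#' gene graph whose node ids are HGNC symbols (or display-name labels for
#' unmapped entities).
#'
#' @param graph A [signed_digraph()].
#' @param id_map Optional identifier map for [map_identifiers()].
#' @inheritParams filter_nonmappable_nodes
#' @return A gene-level [signed_digraph()].
#' @export
to_gene_graph <- function(graph, id_map = NULL,
                          removable_classes = c("small_molecule", "dna",
                                                "rna", "nested_pathway")) {
  if (!is.null(id_map)) graph <- map_identifiers(graph, id_map)
  graph |>
    filter_nonmappable_nodes(removable_classes) |>
    split_multi_symbol_nodes() |>
    merge_same_symbol_nodes()
}
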