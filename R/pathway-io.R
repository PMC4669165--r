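#' Pathway records
#'
#' A `pathway_record` bundles one pathway graph with its name, source
#' database and curation group label. Records start out `unassigned` and are
#' sorted into the conceptual groups (`canonical`, `noncanonical`,
#' `inhibition`, `regulation`, or `discarded`) before merging; discarded
#' records never enter a merge.
#'
#' @param pathway_id Unique identifier of the pathway.
#' @param graph A [signed_digraph()].
#' @param name Free-text pathway name (defaults to the id).
#' @param source_db Source database label.
#' @param group Curation group, one of [pathway_groups()].
#' @return A `pathway_record` object.
#' @export
pathway_record <- function(pathway_id, graph, name = pathway_id,
                           source_db = "unknown", group = "unassigned") {
  stopifnot_sdg(graph)
  group <- match.arg(group, pathway_groups())
  structure(
    list(pathway_id = as.character(pathway_id), name = as.character(name),
         source_db = as.character(source_db), group = group, graph = graph),
    class = "pathway_record"
  )
}

#' Valid curation group labels
#' @return Character vector of group labels.
#' @export
pathway_groups <- function() {
  c("canonical", "noncanonical", "inhibition", "regulation",
    "unassigned", "discarded")
}

#' @export
print.pathway_record <- function(x, ...) {
  cat(sprintf("<pathway_record> %s (%s, group=%s): %d nodes, %d edges\n",
              x$pathway_id, x$source_db, x$group,
              n_nodes(x$graph), n_edges(x$graph)))
  invisible(x)
}

#' Read a pathway collection from the tabular pathway exchange format
#'
#' The pathway exchange format is a pair of UTF-8 TSV files emulating parsed
#' BioPAX Level 3 pathway graphs at the level of controlling interactions.
#' The edge file has columns `pathway_id`, `source`, `target`, `sign`
#' (1 = activation, -1 = inhibition); the node file has `pathway_id`,
#' `node_id`, `entity_class`, `reference_ids` (semicolon-joined
#' `namespace:id`), `gene_symbols` (semicolon-joined) and `display_name`.
#' Optional node-file columns `pathway_name` and `source_db` annotate the
#' record itself.
#'
#' @param edge_file,node_file Paths to the two TSV files.
#' @return A list of [pathway_record()]s, one per distinct `pathway_id`, in
#'   order of first appearance, each with `group = "unassigned"`.
#' @export
read_pathway_exchange <- function(edge_file, node_file) {
  edges <- read_tsv_strict(edge_file, c("pathway_id", "source", "target", "sign"))
  nodes <- read_tsv_strict(node_file, c("pathway_id", "node_id", "entity_class",
                                        "reference_ids", "gene_symbols",
                                        "display_name"))
  bad_sign <- !(edges$sign %in% c("1", "-1", 1, -1))
  if (any(bad_sign)) {
    stop("edge file `", edge_file, "`: sign must be 1 or -1 (rows ",
         paste(utils::head(which(bad_sign), 5), collapse = ", "), ")",
         call. = FALSE)
  }
  edges$sign <- as.integer(edges$sign)

  ids <- unique(c(edges$pathway_id, nodes$pathway_id))
  lapply(ids, function(pid) {
    e <- edges[edges$pathway_id == pid, c("source", "target", "sign")]
    n <- nodes[nodes$pathway_id == pid, , drop = FALSE]
    endpoints <- unique(c(e$source, e$target))
    unannotated <- setdiff(endpoints, n$node_id)
    if (length(unannotated) > 0) {
      stop("pathway `", pid, "`: edge endpoint(s) missing from node file: ",
           paste(unannotated, collapse = ", "), call. = FALSE)
    }
    g <- signed_digraph(e, n[, c("node_id", "entity_class", "reference_ids",
                                 "gene_symbols", "display_name")])
    pathway_record(
      pid, g,
      name = if ("pathway_name" %in% names(n) && nrow(n) > 0) n$pathway_name[1] else pid,
      source_db = if ("source_db" %in% names(n) && nrow(n) > 0) n$source_db[1] else "unknown"
    )
  })
}

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                       progress = FALSE, na = character())
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("`", path, "` is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x
}

#' Write a pathway collection in the pathway exchange format
#'
#' Inverse of [read_pathway_exchange()].
#'
#' @param records List of [pathway_record()]s.
#' @param edge_file,node_file Output TSV paths.
#' @return Invisibly, `c(edge_file, node_file)`.
#' @export
write_pathway_exchange <- function(records, edge_file, node_file) {
  edges <- purrr::map_dfr(records, function(r) {
    tibble::tibble(pathway_id = r$pathway_id, r$graph$edges)
  })
  nodes <- purrr::map_dfr(records, function(r) {
    n <- r$graph$nodes
    tibble::tibble(
      pathway_id = r$pathway_id,
      node_id = n$node_id,
      entity_class = n$entity_class,
      reference_ids = n$reference_ids,
      gene_symbols = vapply(n$gene_symbols, paste, character(1), collapse = ";"),
      display_name = n$display_name,
      pathway_name = r$name,
      source_db = r$source_db
    )
  })
  readr::write_tsv(edges, edge_file, progress = FALSE)
  readr::write_tsv(nodes, node_file, progress = FALSE)
  invisible(c(edge_file, node_file))
}

#' Read / write signed networks in simple interaction format (SIF)
#'
#' The SIF dialect used throughout is a headered TSV with columns `source`,
#' `target`, `weight`, one directed edge per row, weight `1` for activation
#' and `-1` for inhibition. Isolated nodes are not representable, so
#' `read_sif(write_sif(g))` is the identity on graphs without isolated
#' nodes.
#'
#' @param path Path to a SIF file.
#' @return `read_sif()` returns a [signed_digraph()]; `write_sif()` returns
#'   `path` invisibly.
#' @export
read_sif <- function(path) {
  x <- read_tsv_strict(path, c("source", "target", "weight"))
  w <- suppressWarnings(as.numeric(x$weight))
  bad <- is.na(w) | !(w %in% c(1, -1))
  if (any(bad)) {
    # +1 for the header row so the message points at the physical file line
    stop("`", path, "`: weight must be 1 or -1 (line ",
         paste(which(bad)[1] + 1L, collapse = ", "), ")", call. = FALSE)
  }
  signed_digraph(tibble::tibble(source = x$source, target = x$target,
                                sign = as.integer(w)))
}

#' @rdname read_sif
#' @param graph A [signed_digraph()].
#' @export
write_sif <- function(graph, path) {
  stopifnot_sdg(graph)
  readr::write_tsv(
    tibble::tibble(source = graph$edges$source, target = graph$edges$target,
                   weight = graph$edges$sign),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read / write gene sets
#'
#' Gene sets travel either as GMT (one set per line: name, description, then
#' tab-separated symbols) or as plain one-symbol-per-line lists.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors;
#'   `read_gene_list()` a character vector.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 2) stop("malformed GMT line: ", f[1], call. = FALSE)
    stats::setNames(list(unique(f[-(1:2)])), f[1])
  })
  do.call(c, sets)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_gmt
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x)])
}
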