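#' Assign curation groups to pathway records
#'
#' Group assignment is an explicit input (mirroring a curated table of
#' pathway name, source database and group) rather than something the
#' package derives: the original stratification into canonical,
#' non-canonical, inhibition and regulation groups was expert judgment.
#' Records not mentioned in the assignment are marked `discarded`, matching
#' the treatment of pathways considered too general to classify.
#'
#' @param records List of [pathway_record()]s.
#' @param assignment Either a named character vector (`pathway_id -> group`)
#'   or a data frame with columns `pathway_id`, `group`.
#' @return The records with groups set.
#' @export
assign_groups <- function(records, assignment) {
  if (is.data.frame(assignment)) {
    if (!all(c("pathway_id", "group") %in% names(assignment))) {
      stop("assignment table needs columns pathway_id, group", call. = FALSE)
    }
    assignment <- stats::setNames(as.character(assignment$group),
                                  assignment$pathway_id)
  }
  ids <- vapply(records, function(r) r$pathway_id, character(1))
  unknown <- setdiff(names(assignment), ids)
  if (length(unknown) > 0) {
    stop("assignment names unknown pathway_id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(assignment), pathway_groups())
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lapply(records, function(r) {
    r$group <- if (r$pathway_id %in% names(assignment)) {
      unname(assignment[r$pathway_id])
    } else {
      "discarded"
    }
    r
  })
}

#' Split a pathway record by weakly connected components
#'
#' Some database pathways bundle several signaling branches in one graph
#' (e.g. a generic "Wnt signaling pathway" export holding both the
#' beta-catenin-dependent and -independent branches as separate components).
#' Each weakly connected component containing a representative node becomes
#' its own record with the mapped group; components without a representative
#' are not emitted.
#'
#' @param record A [pathway_record()].
#' @param component_groups Named character vector `representative node id ->
#'   group`; each representative must lie in a distinct component.
#' @return A list of [pathway_record()]s, one per represented component,
#'   with ids `<pathway_id>.1`, `<pathway_id>.2`, ...
#' @export
split_record_by_components <- function(record, component_groups) {
  ig <- as_igraph(record$graph, directed = TRUE)
  comp <- igraph::components(ig, mode = "weak")
  membership <- comp$membership
  reps <- names(component_groups)
  missing_rep <- setdiff(reps, names(membership))
  if (length(missing_rep) > 0) {
    stop("representative node(s) not in pathway graph: ",
         paste(missing_rep, collapse = ", "), call. = FALSE)
  }
  rep_comp <- membership[reps]
  if (anyDuplicated(rep_comp)) {
    dups <- reps[rep_comp %in% rep_comp[duplicated(rep_comp)]]
    stop("representatives share a connected component: ",
         paste(dups, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_along(reps), function(k) {
    ids <- names(membership)[membership == rep_comp[k]]
    nodes <- record$graph$nodes[record$graph$nodes$node_id %in% ids, ,
                                drop = FALSE]
    edges <- record$graph$edges[record$graph$edges$source %in% ids &
                                  record$graph$edges$target %in% ids, ,
                                drop = FALSE]
    pathway_record(paste0(record$pathway_id, ".", k),
                   signed_digraph(edges, nodes),
                   name = paste0(record$name, " [component ", k, "]"),
                   source_db = record$source_db,
                   group = unname(component_groups[[k]]))
  })
  out
}

#' Merge all pathway graphs of one group into a single network
#'
#' The per-pathway interaction tables are concatenated and duplicated
#' interactions (identical `(source, target, sign)` triples) removed; the
#' merged network keeps only nodes with at least one interaction. The result
#' is independent of record order (set-union semantics). Node ids are
#' expected to be gene-level labels at this point, so node annotations are
#' rebuilt from the surviving endpoints.
#'
#' @param records List of [pathway_record()]s.
#' @param group Group label to merge.
#' @return A [signed_digraph()].
#' @export
merge_group <- function(records, group) {
  sel <- Filter(function(r) identical(r$group, group), records)
  if (length(sel) == 0) {
    stop("no records carry group `", group, "`", call. = FALSE)
  }
  edges <- dplyr::distinct(purrr::map_dfr(sel, function(r) r$graph$edges))
  signed_digraph(edges)
}

#' Build one merged network per curation group
#'
#' Applies [merge_group()] to every non-discarded, non-unassigned group
#' present among the records and logs each network's size.
#'
#' @param records List of grouped [pathway_record()]s.
#' @param quiet Suppress the size log?
#' @return A named list of [signed_digraph()]s, one per group.
#' @export
build_networks <- function(records, quiet = FALSE) {
  groups <- unique(vapply(records, function(r) r$group, character(1)))
  groups <- setdiff(groups, c("discarded", "unassigned"))
  nets <- lapply(stats::setNames(groups, groups),
                 function(g) merge_group(records, g))
  if (!quiet) {
    for (g in names(nets)) {
      message(sprintf("network `%s`: %d nodes, %d edges",
                      g, n_nodes(nets[[g]]), n_edges(nets[[g]])))
    }
  }
  nets
}

#' Summarise a set of networks as a tibble
#'
#' @param networks Named list of [signed_digraph()]s.
#' @return A tibble with one row per network: group, node and edge counts.
#' @export
network_sizes <- function(networks) {
  purrr::map_dfr(names(networks), function(g) {
    tibble::tibble(group = g, n_nodes = n_nodes(networks[[g]]),
                   n_edges = n_edges(networks[[g]]))
  })
}
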