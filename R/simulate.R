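#' Simulate a pathway collection with non-gene entities and multi-symbol nodes
#'
#' Generates a collection of connected signed pathway graphs over a shared
#' gene universe, emulating the controlling-interaction graphs parsed from
#' pathway databases: a stated fraction of entities are non-gene nodes
#' (small molecules, DNA, RNA, nested pathways) and a stated fraction of
#' gene nodes carry two gene symbols (unresolved families/complex members).
#' Pathways draw their members from the common universe, so they overlap.
#' Each pathway is built on a random recursive tree backbone (hence weakly
#' connected) plus extra random edges; roughly a quarter of the edges are
#' inhibiting. Fully deterministic given `seed`.
#'
#' @param n_pathways Number of pathways.
#' @param genes Size of the shared gene universe (symbols `G001`, `G002`,
#'   ...; entrez-style reference ids `1, 2, ...`).
#' @param p_nongene Probability that a node is a non-gene entity.
#' @param p_multisymbol Probability that a gene node carries two symbols.
#' @param seed Integer seed.
#' @param nodes_per_pathway Two-element range of pathway sizes.
#' @return A list of [pathway_record()]s (group `unassigned`).
#' @export
simulate_pathway_collection <- function(n_pathways, genes,
                                        p_nongene = 0.2,
                                        p_multisymbol = 0.1,
                                        seed = 1L,
                                        nodes_per_pathway = c(8L, 18L)) {
  if (any(c(p_nongene, p_multisymbol) < 0 | c(p_nongene, p_multisymbol) > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (n_pathways < 1 || genes < max(nodes_per_pathway)) {
    stop("need at least one pathway and a gene universe no smaller than the ",
         "largest pathway", call. = FALSE)
  }
  symbols <- sprintf("G%03d", seq_len(genes))
  withr_seed(seed, {
    lapply(seq_len(n_pathways), function(p) {
      pid <- sprintf("path%02d", p)
      m <- sample(nodes_per_pathway[1]:nodes_per_pathway[2], 1)
      is_nongene <- stats::runif(m) < p_nongene
      gene_idx <- sample(genes, sum(!is_nongene))

      node_id <- sprintf("%s_n%02d", pid, seq_len(m))
      entity_class <- character(m)
      reference_ids <- character(m)
      gene_symbols <- vector("list", m)
      display_name <- character(m)

      gi <- 0
      for (i in seq_len(m)) {
        if (is_nongene[i]) {
          entity_class[i] <- sample(c("small_molecule", "dna", "rna",
                                      "nested_pathway"), 1)
          reference_ids[i] <- ""
          gene_symbols[[i]] <- character(0)
          display_name[i] <- sprintf("entity %d of %s", i, pid)
        } else {
          gi <- gi + 1
          idx <- gene_idx[gi]
          entity_class[i] <- "protein"
          if (stats::runif(1) < p_multisymbol) {
            idx2 <- sample(setdiff(seq_len(genes), idx), 1)
            reference_ids[i] <- sprintf("entrez:%d;entrez:%d", idx, idx2)
            gene_symbols[[i]] <- symbols[c(idx, idx2)]
          } else {
            reference_ids[i] <- sprintf("entrez:%d", idx)
            gene_symbols[[i]] <- symbols[idx]
          }
          display_name[i] <- sprintf("%s protein", gene_symbols[[i]][1])
        }
      }
      nodes <- tibble::tibble(node_id = node_id, entity_class = entity_class,
                              reference_ids = reference_ids,
                              gene_symbols = gene_symbols,
                              display_name = display_name)

      # random recursive tree backbone + extra edges, ~25% inhibiting
      src <- integer(0); tgt <- integer(0)
      for (i in 2:m) {
        parent <- sample(i - 1, 1)
        if (stats::runif(1) < 0.5) {
          src <- c(src, parent); tgt <- c(tgt, i)
        } else {
          src <- c(src, i); tgt <- c(tgt, parent)
        }
      }
      n_extra <- round(0.6 * m)
      if (n_extra > 0) {
        es <- sample(m, n_extra, replace = TRUE)
        et <- sample(m, n_extra, replace = TRUE)
        keep <- es != et
        src <- c(src, es[keep]); tgt <- c(tgt, et[keep])
      }
      edges <- tibble::tibble(
        source = node_id[src], target = node_id[tgt],
        sign = ifelse(stats::runif(length(src)) < 0.25, -1L, 1L)
      )
      graph <- signed_digraph(edges, nodes)
      if (n_nodes(graph) == 0) {
        stop("simulation parameters produced an empty pathway graph",
             call. = FALSE)
      }
      pathway_record(pid, graph,
                     name = sprintf("synthetic signaling pathway %d", p),
                     source_db = "synthetic")
    })
  })
}

#' Identifier map for the simulated gene universe
#'
#' @param genes Universe size used in [simulate_pathway_collection()].
#' @return A tibble (`namespace`, `id`, `symbol`) mapping entrez-style ids
#'   to the simulated symbols, suitable for [map_identifiers()].
#' @export
simulate_id_map <- function(genes) {
  tibble::tibble(namespace = "entrez", id = as.character(seq_len(genes)),
                 symbol = sprintf("G%03d", seq_len(genes)))
}

#' Simulate two-group expression data with planted differential genes
#'
#' Log-scale intensities with independent Gaussian noise: every measured
#' gene has a gene-specific baseline, and planted genes are shifted by
#' `effect` in the second group. The returned differential table is computed
#' by per-gene two-sample Welch t-tests with Bonferroni adjustment — a
#' deliberately plain stand-in for platform-specific differential models,
#' since the pipeline consumes differential tables agnostically. The
#' measured universe is the network's gene nodes plus `n_background_genes`
#' off-network genes. Deterministic given `seed`.
#'
#' @param network A gene-labelled [signed_digraph()].
#' @param planted Character vector of planted differential genes (subset of
#'   the network's nodes).
#' @param effect Log-scale group-mean shift for planted genes: a scalar, or
#'   a vector recycled along `planted`. Positive values up-regulate and
#'   negative values down-regulate the gene in the second group, so a signed
#'   vector plants heterogeneous fold-changes.
#' @param sigma Noise standard deviation.
#' @param n_per_group Samples per group (>= 2).
#' @param n_background_genes Number of measured genes outside the network.
#' @param seed Integer seed.
#' @return A list with `expression` (matrix, genes x samples; group labels
#'   in `colnames`) and `de_table` (tibble `gene`, `log_fc`, `p_value`,
#'   `adj_p`).
#' @export
simulate_expression <- function(network, planted, effect = 2, sigma = 0.5,
                                n_per_group = 5L, n_background_genes = 200L,
                                seed = 1L) {
  stopifnot_sdg(network, "network")
  planted <- unique(as.character(planted))
  if (!all(planted %in% node_ids(network))) {
    stop("planted genes must be network nodes", call. = FALSE)
  }
  if (any(is.na(effect))) stop("effect must not contain NA", call. = FALSE)
  if (n_per_group < 2) stop("n_per_group must be >= 2", call. = FALSE)
  effect <- rep_len(effect, length(planted))
  genes <- c(node_ids(network),
             if (n_background_genes > 0) sprintf("B%04d", seq_len(n_background_genes)))
  withr_seed(seed, {
    baseline <- stats::runif(length(genes), 6, 10)
    n_samples <- 2L * n_per_group
    mat <- matrix(stats::rnorm(length(genes) * n_samples, sd = sigma),
                  nrow = length(genes)) + baseline
    grp2 <- (n_per_group + 1):n_samples
    shift <- rep(0, length(genes))
    shift[match(planted, genes)] <- effect
    mat[, grp2] <- mat[, grp2] + shift
    dimnames(mat) <- list(genes,
                          c(paste0("ctrl_", seq_len(n_per_group)),
                            paste0("case_", seq_len(n_per_group))))
    # pooled-variance t-test: the noise model is homoskedastic by construction
    p <- apply(mat, 1, function(x) {
      stats::t.test(x[grp2], x[-grp2], var.equal = TRUE)$p.value
    })
    de <- tibble::tibble(
      gene = genes,
      log_fc = rowMeans(mat[, grp2, drop = FALSE]) -
        rowMeans(mat[, -grp2, drop = FALSE]),
      p_value = unname(p),
      adj_p = bonferroni(unname(p))
    )
    list(expression = mat, de_table = de)
  })
}

#' Sample mutually connected terminals from a network
#'
#' Draws `n_terminals` nodes from a breadth-first neighbourhood of a random
#' start node in the network's largest connected component, so the sampled
#' genes are mutually reachable in the undirected projection — a planted
#' "active region" for Steiner-module recovery experiments. Deterministic
#' given `seed`.
#'
#' @param network A [signed_digraph()].
#' @param n_terminals Number of terminals (at most the largest component's
#'   size).
#' @param seed Integer seed.
#' @return Character vector of node ids.
#' @export
plant_connected_terminals <- function(network, n_terminals, seed = 1L) {
  stopifnot_sdg(network, "network")
  if (n_nodes(network) == 0) stop("network is empty", call. = FALSE)
  ig <- as_igraph(network, directed = FALSE, collapse = TRUE)
  comp <- igraph::components(ig)
  main <- sort(names(comp$membership)[comp$membership == which.max(comp$csize)])
  if (n_terminals > length(main)) {
    stop("n_terminals exceeds the largest component size (",
         length(main), ")", call. = FALSE)
  }
  adj <- und_adjacency(network$edges, node_ids(network))
  withr_seed(seed, {
    start <- sample(main, 1)
    dist <- bfs_distances(adj, start)
    order_bfs <- names(sort(dist[main]))
    order_bfs[seq_len(n_terminals)]
  })
}
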