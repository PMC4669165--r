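# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid igraph and the package's own graph code: they work on plain edge
# data frames and adjacency matrices.

edges_df <- function(...) {
  v <- c(...)
  if (length(v) == 0) {
    return(tibble::tibble(source = character(), target = character(),
                          sign = integer()))
  }
  m <- matrix(v, ncol = 3, byrow = TRUE)
  tibble::tibble(source = m[, 1], target = m[, 2], sign = as.integer(m[, 3]))
}

quick_graph <- function(...) signed_digraph(edges_df(...))

random_edges <- function(n_nodes, p_edge = 0.25, p_inhibit = 0.3) {
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pairs <- pairs[stats::runif(nrow(pairs)) < p_edge, ]
  tibble::tibble(source = pairs$source, target = pairs$target,
                 sign = ifelse(stats::runif(nrow(pairs)) < p_inhibit, -1L, 1L))
}

# ---- shortest-path / betweenness oracle (directed, unweighted) ----------

# all shortest paths s -> t by breadth-first layer expansion on an edge list
oracle_all_shortest_paths <- function(edges, nodes, s, t) {
  if (s == t) return(list())
  paths <- list(s)
  found <- list()
  repeat {
    nxt <- list()
    for (p in paths) {
      tail <- p[length(p)]
      outs <- edges$target[edges$source == tail]
      for (o in setdiff(outs, p)) nxt[[length(nxt) + 1]] <- c(p, o)
    }
    if (length(nxt) == 0) return(list())
    found <- Filter(function(p) p[length(p)] == t, nxt)
    if (length(found) > 0) return(found)
    paths <- nxt
    if (length(paths[[1]]) > length(nodes)) return(list())
  }
}

oracle_betweenness <- function(edges, nodes) {
  btw <- stats::setNames(rep(0, length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    sp <- oracle_all_shortest_paths(edges, nodes, s, t)
    if (length(sp) == 0) next
    for (p in sp) {
      interior <- setdiff(p, c(s, t))
      btw[interior] <- btw[interior] + 1 / length(sp)
    }
  }
  btw
}

# ---- reachability through removable interiors (transitive closure) ------

oracle_removable_reachability <- function(edges, kept, removable) {
  nodes <- c(kept, removable)
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) adj[edges$source[i], edges$target[i]] <- TRUE
  # closure over paths whose interiors are removable: repeatedly splice
  # removable midpoints
  reach <- adj
  repeat {
    new_reach <- reach
    for (mid in removable) {
      new_reach <- new_reach | outer(reach[, mid], reach[mid, ], `&`)
    }
    if (identical(new_reach, reach)) break
    reach <- new_reach
  }
  diag(reach) <- FALSE
  reach[kept, kept, drop = FALSE]
}

# ---- exhaustive Steiner minimum (unweighted, undirected) ----------------

und_pairs <- function(edges) {
  u <- unique(tibble::tibble(a = pmin(edges$source, edges$target),
                             b = pmax(edges$source, edges$target)))
  u[u$a != u$b, ]
}

is_connected_on <- function(pairs, nodes) {
  if (length(nodes) <= 1) return(TRUE)
  sub <- pairs[pairs$a %in% nodes & pairs$b %in% nodes, ]
  seen <- nodes[1]
  repeat {
    nbr <- unique(c(sub$b[sub$a %in% seen], sub$a[sub$b %in% seen]))
    grow <- setdiff(nbr, seen)
    if (length(grow) == 0) break
    seen <- c(seen, grow)
  }
  all(nodes %in% seen)
}

oracle_steiner_optimum <- function(edges, terminals) {
  pairs <- und_pairs(edges)
  nodes <- unique(c(pairs$a, pairs$b))
  others <- setdiff(nodes, terminals)
  best <- Inf
  for (k in 0:length(others)) {
    if (k + length(terminals) - 1 >= best) break
    subsets <- if (k == 0) list(character(0)) else
      utils::combn(others, k, simplify = FALSE)
    for (s in subsets) {
      ns <- c(terminals, s)
      if (is_connected_on(pairs, ns)) best <- min(best, length(ns) - 1)
    }
    if (is.finite(best)) break  # smallest k wins: fewer nodes = fewer edges
  }
  best
}

# ---- hypergeometric tail / rank-sum enumeration -------------------------

oracle_fisher_tail <- function(q, m, n, k) {
  i <- q:min(m, k)
  sum(choose(m, i) * choose(n, k - i)) / choose(m + n, k)
}

oracle_wilcoxon_less <- function(ranks_in, n_total) {
  k <- length(ranks_in)
  obs <- sum(ranks_in)
  sums <- apply(utils::combn(n_total, k), 2, sum)
  mean(sums <= obs)
}

# ---- modularity ---------------------------------------------------------

oracle_modularity <- function(pairs, membership) {
  m <- nrow(pairs)
  deg <- table(factor(c(pairs$a, pairs$b), levels = names(membership)))
  q <- 0
  for (comm in unique(membership)) {
    nodes <- names(membership)[membership == comm]
    e_in <- sum(pairs$a %in% nodes & pairs$b %in% nodes)
    d_c <- sum(deg[nodes])
    q <- q + e_in / m - (d_c / (2 * m))^2
  }
  q
}

# all set partitions of a character vector (recursive)
all_partitions <- function(items) {
  if (length(items) == 1) return(list(list(items)))
  rest <- all_partitions(items[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(items[1], q[[i]])
      out[[length(out) + 1]] <- q
    }
    out[[length(out) + 1]] <- c(list(items[1]), p)
  }
  out
}

oracle_best_modularity <- function(pairs, nodes) {
  best <- -Inf
  best_p <- NULL
  for (p in all_partitions(nodes)) {
    memb <- stats::setNames(rep(seq_along(p), lengths(p)), unlist(p))
    q <- oracle_modularity(pairs, memb[nodes])
    if (q > best) {
      best <- q
      best_p <- p
    }
  }
  list(modularity = best, partition = best_p)
}

# small synthetic study used by several files: pathway collection -> gene
# networks -> one merged network
build_test_network <- function(seed = 7, n_pathways = 12, genes = 120) {
  recs <- simulate_pathway_collection(n_pathways, genes, p_nongene = 0.2,
                                      p_multisymbol = 0.1, seed = seed)
  recs <- lapply(recs, function(r) {
    r$graph <- to_gene_graph(r$graph)
    r
  })
  ids <- vapply(recs, function(r) r$pathway_id, character(1))
  grp <- rep(c("canonical", "noncanonical", "inhibition", "regulation"),
             length.out = length(recs))
  recs <- assign_groups(recs, stats::setNames(grp, ids))
  build_networks(recs, quiet = TRUE)
}
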