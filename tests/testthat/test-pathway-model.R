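test_that("pathway exchange files round into one record per pathway", {
  edge_file <- withr::local_tempfile(fileext = ".tsv")
  node_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tsource\ttarget\tsign",
               "p1\tA\tB\t1",
               "p2\tC\tD\t-1",
               "p1\tB\tC1\t1"), edge_file)
  writeLines(c(paste("pathway_id", "node_id", "entity_class", "reference_ids",
                     "gene_symbols", "display_name", sep = "\t"),
               "p1\tA\tprotein\tentrez:1\tA\tA protein",
               "p2\tC\tprotein\tentrez:3\tC\tC protein",
               "p1\tB\tprotein\tentrez:2\tB\tB protein",
               "p1\tC1\tprotein\tentrez:3\tC\tC protein",
               "p2\tD\tsmall_molecule\t\t\tsome compound"), node_file)
  recs <- read_pathway_exchange(edge_file, node_file)
  expect_length(recs, 2)
  expect_equal(vapply(recs, function(r) r$pathway_id, character(1)),
               c("p1", "p2"))
  # interleaved rows resolve by pathway_id: group-by over the raw rows
  expect_equal(n_nodes(recs[[1]]$graph), 3)
  expect_equal(n_edges(recs[[1]]$graph), 2)
  expect_equal(n_edges(recs[[2]]$graph), 1)
  expect_length(intersect(node_ids(recs[[1]]$graph),
                          c("D")), 0)
  expect_true(all(vapply(recs, function(r) r$group == "unassigned",
                         logical(1))))
})

test_that("pathway exchange reader reports format and integrity violations", {
  edge_file <- withr::local_tempfile(fileext = ".tsv")
  node_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tsource\ttarget\tsign", "p1\tA\tX\t1"), edge_file)
  writeLines(c(paste("pathway_id", "node_id", "entity_class", "reference_ids",
                     "gene_symbols", "display_name", sep = "\t"),
               "p1\tA\tprotein\t\tA\tA"), node_file)
  expect_error(read_pathway_exchange(edge_file, node_file), "X")

  bad_edges <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tsource\ttarget", "p1\tA\tB"), bad_edges)
  expect_error(read_pathway_exchange(bad_edges, node_file), "sign")

  bad_sign <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tsource\ttarget\tsign", "p1\tA\tA2\t2"), bad_sign)
  expect_error(read_pathway_exchange(bad_sign, node_file), "sign must be 1 or -1")
})

test_that("keyword selection scans names and member annotations case-insensitively", {
  g_wnt <- quick_graph("A", "B", 1)
  g_mapk <- quick_graph("C", "D", 1)
  recs <- list(pathway_record("p1", g_wnt, name = "Wnt signaling"),
               pathway_record("p2", g_mapk, name = "MAPK"))
  sel <- select_pathways_by_keywords(recs, "wnt")
  expect_equal(vapply(sel, function(r) r$name, character(1)), "Wnt signaling")

  # symbol-only CTNNB1 node carries no substring "catenin"
  nodes <- tibble::tibble(node_id = c("n1", "n2"), entity_class = "protein",
                          reference_ids = "", gene_symbols = list("CTNNB1", "HK1"),
                          display_name = c("CTNNB1", "HK1"))
  glyco <- pathway_record("p3", signed_digraph(edges_df("n1", "n2", 1), nodes),
                          name = "Glycolysis")
  expect_length(select_pathways_by_keywords(list(glyco), "catenin"), 0)
  # but a display-name annotation does match
  nodes$display_name[1] <- "beta-catenin"
  glyco2 <- pathway_record("p3", signed_digraph(edges_df("n1", "n2", 1), nodes),
                           name = "Glycolysis")
  expect_length(select_pathways_by_keywords(list(glyco2), "catenin"), 1)

  pcp <- pathway_record("p4", g_wnt, name = "planar cell polarity (pcp) pathway")
  expect_length(select_pathways_by_keywords(list(pcp), "PCP"), 1)
  expect_error(select_pathways_by_keywords(recs, character(0)), "keyword")
  expect_error(select_pathways_by_keywords(recs, c("wnt", " ")), "keyword")
})

test_that("identifier mapping rewrites symbols and keeps the instance-name fallback", {
  nodes <- tibble::tibble(
    node_id = c("n1", "n2", "n3"),
    entity_class = "protein",
    reference_ids = c("uniprot:P35222", "uniprot:P49841;entrez:2932", ""),
    gene_symbols = list(character(0), character(0), character(0)),
    display_name = c("", "", "beta-catenin destruction complex")
  )
  g <- signed_digraph(edges_df("n1", "n2", 1, "n2", "n3", -1), nodes)
  id_map <- tibble::tibble(namespace = c("uniprot", "uniprot", "entrez"),
                           id = c("P35222", "P49841", "2932"),
                           symbol = c("CTNNB1", "GSK3B", "GSK3B"))
  mapped <- map_identifiers(g, id_map)
  expect_equal(mapped$nodes$gene_symbols[[1]], "CTNNB1")
  # two references to the same symbol collapse to one
  expect_equal(mapped$nodes$gene_symbols[[2]], "GSK3B")
  expect_length(mapped$nodes$gene_symbols[[3]], 0)
  expect_equal(unname(node_labels(mapped)["n3"]),
               "beta-catenin destruction complex")
})

test_that("rewiring removes entities and composes signs as products", {
  mk <- function(s1, s2) {
    nodes <- tibble::tibble(node_id = c("A", "x", "B"),
                            entity_class = c("protein", "small_molecule", "protein"),
                            reference_ids = "", gene_symbols = list("A", character(0), "B"),
                            display_name = c("A", "metabolite", "B"))
    signed_digraph(edges_df("A", "x", s1, "x", "B", s2), nodes)
  }
  for (s1 in c(1L, -1L)) for (s2 in c(1L, -1L)) {
    out <- filter_nonmappable_nodes(mk(s1, s2))
    expect_equal(node_ids(out), c("A", "B"))
    expect_equal(out$edges$sign, s1 * s2)
  }
  # graph with no removable nodes is returned unchanged
  g <- quick_graph("A", "B", 1, "B", "C", -1)
  expect_identical(filter_nonmappable_nodes(g), g)
})

test_that("rewiring reachability matches a transitive-closure oracle on random graphs", {
  set.seed(42)
  for (rep in 1:12) {
    n <- sample(6:12, 1)
    edges <- random_edges(n, p_edge = 0.2)
    if (nrow(edges) == 0) next
    ids <- sprintf("n%02d", seq_len(n))
    removable <- sample(ids, sample(1:4, 1))
    kept <- setdiff(ids, removable)
    nodes <- tibble::tibble(
      node_id = ids,
      entity_class = ifelse(ids %in% removable, "small_molecule", "protein"),
      reference_ids = "",
      gene_symbols = lapply(ids, function(i) if (i %in% removable) character(0) else i),
      display_name = ifelse(ids %in% removable, "metabolite", ids)
    )
    g <- signed_digraph(edges, nodes)
    out <- suppressWarnings(filter_nonmappable_nodes(g))
    reach <- oracle_removable_reachability(g$edges, kept, removable)
    for (u in kept) for (w in kept) {
      if (u == w) next
      has_edge <- any(out$edges$source == u & out$edges$target == w)
      expect_equal(has_edge, unname(reach[u, w]),
                   info = sprintf("rep %d: %s -> %s", rep, u, w))
    }
  }
})

test_that("chains of removable nodes rewire with multiplied signs, loops dropped", {
  nodes <- tibble::tibble(
    node_id = c("A", "x", "y", "B"),
    entity_class = c("protein", "small_molecule", "rna", "protein"),
    reference_ids = "",
    gene_symbols = list("A", character(0), character(0), "B"),
    display_name = c("A", "m1", "m2", "B")
  )
  g <- signed_digraph(edges_df("A", "x", -1, "x", "y", -1, "y", "B", 1), nodes)
  out <- filter_nonmappable_nodes(g)
  expect_equal(out$edges,
               tibble::tibble(source = "A", target = "B", sign = 1L))

  # opposite-sign parallel paths both survive as distinct triples
  g2 <- signed_digraph(
    edges_df("A", "x", 1, "A", "y", -1, "x", "B", 1, "y", "B", 1), nodes)
  out2 <- filter_nonmappable_nodes(g2)
  expect_setequal(out2$edges$sign, c(1L, -1L))
  expect_equal(nrow(out2$edges), 2)
})

test_that("multi-symbol nodes split into single-symbol copies inheriting all edges", {
  nodes <- tibble::tibble(
    node_id = c("A", "m"),
    entity_class = "protein", reference_ids = "",
    gene_symbols = list("A", c("G1", "G2")),
    display_name = c("A", "G1/G2")
  )
  g <- signed_digraph(edges_df("A", "m", 1), nodes)
  out <- split_multi_symbol_nodes(g)
  expect_equal(n_nodes(out), 3)
  expect_equal(n_edges(out), 2)
  expect_setequal(out$edges$target, c("m|G1", "m|G2"))

  # k = 3 symbols, 2 in-edges + 1 out-edge -> 9 incident edges afterwards
  nodes3 <- tibble::tibble(
    node_id = c("A", "B", "C", "m"),
    entity_class = "protein", reference_ids = "",
    gene_symbols = list("A", "B", "C", c("G1", "G2", "G3")),
    display_name = c("A", "B", "C", "m")
  )
  g3 <- signed_digraph(edges_df("A", "m", 1, "B", "m", -1, "m", "C", 1), nodes3)
  out3 <- split_multi_symbol_nodes(g3)
  expect_equal(n_edges(out3), 9)  # 3 copies x (2 in + 1 out)
  expect_equal(n_nodes(out3), 6)

  # single-symbol graphs pass through unchanged
  g1 <- quick_graph("A", "B", 1)
  expect_equal(split_multi_symbol_nodes(g1)$edges, g1$edges)
})

test_that("same-symbol nodes merge with relabelled unions, loops and duplicates dropped", {
  nodes <- tibble::tibble(
    node_id = c("A", "n1", "n2", "B"),
    entity_class = "protein", reference_ids = "",
    gene_symbols = list("A", "CTNNB1", "CTNNB1", "B"),
    display_name = c("A", "", "", "B")
  )
  g <- signed_digraph(edges_df("A", "n1", 1, "n2", "B", 1), nodes)
  out <- merge_same_symbol_nodes(g)
  expect_setequal(node_ids(out), c("A", "B", "CTNNB1"))
  expect_setequal(paste(out$edges$source, out$edges$target),
                  c("A CTNNB1", "CTNNB1 B"))

  # edge between two nodes mapping to the same symbol becomes a dropped loop
  nodes2 <- tibble::tibble(
    node_id = c("n1", "n2", "A"), entity_class = "protein", reference_ids = "",
    gene_symbols = list("GSK3B", "GSK3B", "A"), display_name = ""
  )
  g2 <- signed_digraph(edges_df("n1", "n2", 1, "A", "n1", 1, "A", "n2", 1),
                       nodes2)
  out2 <- merge_same_symbol_nodes(g2)
  expect_setequal(node_ids(out2), c("A", "GSK3B"))
  # the two parallel A->GSK3B triples deduplicate
  expect_equal(nrow(out2$edges), 1)
  expect_false(any(out2$edges$source == out2$edges$target))

  expect_error(merge_same_symbol_nodes(split_multi_symbol_nodes(g2)), NA)
})

test_that("split-then-merge preserves edges when multi-symbol nodes have distinct symbols", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:7, 1)
    edges <- random_edges(n, p_edge = 0.35)
    if (nrow(edges) == 0) next
    ids <- sprintf("n%02d", seq_len(n))
    # give each node its own distinct symbol set (one node gets two)
    syms <- lapply(seq_len(n), function(i) sprintf("S%02d", i))
    syms[[1]] <- c("S01", sprintf("S%02d", n + 1))
    nodes <- tibble::tibble(node_id = ids, entity_class = "protein",
                            reference_ids = "", gene_symbols = syms,
                            display_name = ids)
    g <- signed_digraph(edges, nodes)
    out <- merge_same_symbol_nodes(split_multi_symbol_nodes(g))
    # brute-force expectation: relabel every edge by symbol, expand the
    # multi-symbol endpoint, drop loops, dedupe
    lut <- stats::setNames(syms, ids)
    expanded <- purrr::map_dfr(seq_len(nrow(g$edges)), function(i) {
      expand.grid(source = lut[[g$edges$source[i]]],
                  target = lut[[g$edges$target[i]]],
                  stringsAsFactors = FALSE) |>
        dplyr::mutate(sign = g$edges$sign[i])
    })
    expanded <- dplyr::distinct(expanded[expanded$source != expanded$target, ])
    expect_equal(nrow(out$edges), nrow(expanded))
    expect_setequal(paste(out$edges$source, out$edges$target, out$edges$sign),
                    paste(expanded$source, expanded$target, expanded$sign))
  }
})

test_that("SIF round trips are lossless and malformed weights are rejected with a line", {
  g <- quick_graph("A", "B", 1, "B", "C", -1)
  path <- withr::local_tempfile(fileext = ".sif")
  write_sif(g, path)
  lines <- readLines(path)
  expect_equal(lines[1], "source\ttarget\tweight")
  expect_length(lines, 3)
  back <- read_sif(path)
  expect_equal(back$edges, g$edges)

  # random graphs without isolated nodes round trip exactly
  set.seed(3)
  for (rep in 1:5) {
    e <- random_edges(sample(4:9, 1), p_edge = 0.3)
    if (nrow(e) == 0) next
    g2 <- signed_digraph(e)
    write_sif(g2, path)
    back2 <- read_sif(path)
    expect_equal(dplyr::arrange(back2$edges, source, target, sign),
                 dplyr::arrange(g2$edges, source, target, sign))
    expect_setequal(node_ids(back2), node_ids(g2))
  }

  writeLines(c("source\ttarget\tweight", "A\tB\t1", "B\tC\t2"), path)
  expect_error(read_sif(path), "line 3")

  # empty edge set -> header-only file -> empty graph
  empty <- signed_digraph(edges_df())
  write_sif(empty, path)
  expect_length(readLines(path), 1)
  expect_equal(n_nodes(read_sif(path)), 0)
})
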