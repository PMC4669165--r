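test_that("probe summarization keeps the best probe per gene with documented tie-breaks", {
  tab <- tibble::tibble(
    probe_id = c("pr1", "pr2", "pr3", "pr4", "pr5"),
    gene = c("g1", "g1", "g2", "g3", "g3"),
    log_fc = c(1.5, -0.2, 0.7, 1.0, 2.0),
    p_value = c(0.01, 0.5, 0.2, 0.01, 0.01),
    adj_p = c(0.1, 1, 1, 0.1, 0.1)
  )
  out <- summarize_probes(tab)
  expect_equal(nrow(out), 3)
  expect_equal(out$probe_id[out$gene == "g1"], "pr1")
  # single-probe genes unchanged
  expect_equal(out$probe_id[out$gene == "g2"], "pr3")
  # p tie broken by larger |log_fc|
  expect_equal(out$probe_id[out$gene == "g3"], "pr5")
  # equal p and |log_fc|: lexicographic probe id
  tie <- tibble::tibble(probe_id = c("b", "a"), gene = "g",
                        log_fc = c(1, -1), p_value = 0.01, adj_p = 0.1)
  expect_equal(summarize_probes(tie)$probe_id, "a")
})

test_that("Bonferroni adjustment is min(1, p * m)", {
  expect_equal(bonferroni(c(1e-4, rep(0.5, 9))),
               pmin(1, c(1e-4, rep(0.5, 9)) * 10))
  expect_equal(bonferroni(rep(0.05, 100))[1], 1)
  expect_equal(bonferroni(0.3), 0.3)
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG selection splits by direction at the adjusted-p threshold", {
  tab <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        log_fc = c(2, -1, 0),
                        adj_p = c(0.01, 0.2, 0.001))
  expect_warning(degs <- select_degs(tab, alpha = 0.05), "log_fc = 0")
  expect_equal(degs$up, "g1")
  expect_length(degs$down, 0)
  none <- select_degs(tibble::tibble(gene = "g", log_fc = 1, adj_p = 1), 0.05)
  expect_length(none$up, 0)
  expect_length(none$down, 0)
  expect_error(select_degs(tab, alpha = 0), "alpha")
  expect_error(select_degs(tab, alpha = 1.5), "alpha")
})

test_that("the six network gene sets follow set algebra", {
  can <- quick_graph("A", "B", 1, "B", "C", 1)
  noncan <- quick_graph("B", "C", 1, "C", "D", 1)
  sets <- build_gene_sets(can, noncan)
  expect_equal(sets$can_minus_noncan, "A")
  expect_setequal(sets$intersection, c("B", "C"))
  expect_setequal(sets$union, c("A", "B", "C", "D"))
  same <- build_gene_sets(can, can)
  expect_length(same$can_minus_noncan, 0)
  expect_length(same$noncan_minus_can, 0)
  disjoint <- build_gene_sets(can, quick_graph("X", "Y", 1))
  expect_length(disjoint$intersection, 0)
  expect_setequal(disjoint$union, c("A", "B", "C", "X", "Y"))
  expect_error(build_gene_sets(can, signed_digraph(edges_df())), "non-empty")
})

test_that("Fisher over-representation equals the hypergeometric tail", {
  universe <- sprintf("u%03d", 1:100)
  gene_set <- universe[1:10]
  degs <- c(universe[1:8], universe[11:22])  # overlap 8 of 20 DEGs
  p <- fisher_overrepresentation(degs, gene_set, universe)
  expect_equal(p, oracle_fisher_tail(8, 10, 90, 20), tolerance = 1e-12)

  # gene_set covering the whole universe is always "enriched" with p = 1
  expect_equal(fisher_overrepresentation(degs, universe, universe), 1)
  # observed overlap at the minimum of the support -> tail = 1
  expect_equal(fisher_overrepresentation(universe[11:13], universe[1:2],
                                         universe), 1)
  expect_error(fisher_overrepresentation(c("zzz"), gene_set, universe),
               "subset")
  expect_error(fisher_overrepresentation(degs, "zzz", universe),
               "no member")
})

test_that("Fisher p matches brute-force point-mass sums on random tables", {
  set.seed(23)
  for (rep in 1:25) {
    N <- sample(20:200, 1)
    m <- sample(2:(N - 2), 1)
    k <- sample(1:(N - 1), 1)
    universe <- sprintf("u%03d", 1:N)
    gene_set <- sample(universe, m)
    degs <- sample(universe, k)
    q <- length(intersect(degs, gene_set))
    expect_equal(fisher_overrepresentation(degs, gene_set, universe),
                 oracle_fisher_tail(q, m, N - m, k), tolerance = 1e-9)
  }
})

test_that("planting DEGs uniformly keeps the one-sided Fisher p super-uniform", {
  set.seed(101)
  n_sims <- 500
  universe <- sprintf("u%03d", 1:200)
  gene_set <- universe[1:30]
  hits <- vapply(seq_len(n_sims), function(i) {
    degs <- sample(universe, 25)
    fisher_overrepresentation(degs, gene_set, universe) < 0.05
  }, logical(1))
  # type-I control: rejection rate at alpha = 0.05 must not exceed alpha
  # (beyond binomial noise, ~2 sd)
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("Wilcoxon enrichment reproduces exact rank-sum probabilities", {
  tab <- tibble::tibble(gene = sprintf("g%02d", 1:10),
                        p_value = (1:10) / 100,
                        log_fc = 0)
  # in-set genes occupy the top ranks 1, 2, 3
  expect_equal(wilcoxon_set_enrichment(tab, c("g01", "g02", "g03")),
               1 / choose(10, 3), tolerance = 1e-12)
  # perfectly interleaved set of 5: mid-distribution, p > 0.4
  p_alt <- wilcoxon_set_enrichment(tab, c("g02", "g04", "g06", "g08", "g10"))
  expect_gt(p_alt, 0.4)
  expect_equal(p_alt, oracle_wilcoxon_less(c(2, 4, 6, 8, 10), 10),
               tolerance = 1e-12)
  expect_error(wilcoxon_set_enrichment(tab, tab$gene), "some but not all")
  expect_error(wilcoxon_set_enrichment(tab, "zzz"), "some but not all")
  expect_error(
    wilcoxon_set_enrichment(dplyr::bind_rows(tab, tab[1, ]), c("g01", "g02")),
    "gene level")
})

test_that("exact Wilcoxon path matches full enumeration for small universes", {
  set.seed(29)
  for (rep in 1:15) {
    n <- sample(6:12, 1)
    k <- sample(2:(n - 2), 1)
    tab <- tibble::tibble(gene = sprintf("g%02d", 1:n),
                          p_value = sample(seq(0.01, 0.99, length.out = n)),
                          log_fc = 0)
    in_set <- sample(tab$gene, k)
    p <- wilcoxon_set_enrichment(tab, in_set)
    ranks_in <- rank(tab$p_value)[tab$gene %in% in_set]
    expect_equal(p, oracle_wilcoxon_less(ranks_in, n), tolerance = 1e-10)
  }
})

test_that("concentrated planting gives both tests power >= 0.95", {
  set.seed(31)
  n_sims <- 40
  universe <- sprintf("u%04d", 1:1000)
  gene_set <- universe[1:30]
  both_reject <- vapply(seq_len(n_sims), function(i) {
    # planted alternative: in-set genes get strongly depressed p-values
    p_val <- stats::runif(1000)
    p_val[1:30] <- stats::rbeta(30, 0.1, 1) * 1e-3
    tab <- tibble::tibble(gene = universe, p_value = p_val, log_fc = 0)
    degs <- universe[order(p_val)][1:100]  # 100 DEGs, set members among them
    fisher_overrepresentation(degs, gene_set, universe) < 0.05 &&
      wilcoxon_set_enrichment(tab, gene_set) < 0.05
  }, logical(1))
  expect_gte(mean(both_reject), 0.95)
})

test_that("enrichment_table reports both tests per gene set", {
  nets <- build_test_network(seed = 7)
  sets <- build_gene_sets(nets$canonical, nets$noncanonical)
  planted <- plant_connected_terminals(nets$noncanonical, 12, seed = 2)
  sim <- simulate_expression(nets$noncanonical, planted, effect = 3,
                             sigma = 0.5, n_per_group = 5,
                             n_background_genes = 150, seed = 5)
  degs <- select_degs(sim$de_table)
  out <- enrichment_table(sim$de_table, c(degs$up, degs$down), sets)
  expect_equal(out$gene_set,
               c("canonical", "noncanonical", "can_minus_noncan",
                 "noncan_minus_can", "intersection", "union"))
  expect_true(all(out$fisher_p >= 0 & out$fisher_p <= 1, na.rm = TRUE))
  # planted signal sits in the non-canonical network
  expect_lt(out$fisher_p[out$gene_set == "noncanonical"], 0.05)
  expect_lt(out$wilcoxon_p[out$gene_set == "noncanonical"], 0.05)
})
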