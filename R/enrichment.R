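#' Summarize probe-level differential-expression rows to gene level
#'
#' For every gene, the probe with the smallest p-value is kept as its
#' representative row. Ties on p-value are broken by larger absolute log
#' fold-change, then by lexicographic probe id.
#'
#' @param table A data frame with columns `gene`, `log_fc`, `p_value`,
#'   `adj_p` and `probe_id`; rows without gene annotation must already be
#'   removed.
#' @return A tibble with one row per gene.
#' @export
summarize_probes <- function(table) {
  table <- tibble::as_tibble(table)
  req <- c("gene", "log_fc", "p_value", "probe_id")
  if (!all(req %in% names(table))) {
    stop("table needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  table |>
    dplyr::arrange(.data$p_value, dplyr::desc(abs(.data$log_fc)),
                   .data$probe_id) |>
    dplyr::distinct(.data$gene, .keep_all = TRUE)
}

#' Bonferroni adjustment
#'
#' Family-wise error-rate control: each p-value is multiplied by the number
#' of tests and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length.
#' @export
bonferroni <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Select significantly differentially expressed genes
#'
#' Splits a gene-level differential-expression table at an adjusted-p
#' threshold into up-regulated (`log_fc > 0`) and down-regulated
#' (`log_fc < 0`) gene sets. Significant genes with `log_fc == 0` belong to
#' neither direction and are excluded with a warning.
#'
#' @param table Gene-level data frame with columns `gene`, `log_fc`,
#'   `adj_p`.
#' @param alpha Significance threshold on `adj_p`, in `(0, 1]`. Default
#'   0.05.
#' @return A list with character vectors `up` and `down`.
#' @export
select_degs <- function(table, alpha = 0.05) {
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  table <- tibble::as_tibble(table)
  sig <- table[table$adj_p < alpha, , drop = FALSE]
  zero <- sig$gene[sig$log_fc == 0]
  if (length(zero) > 0) {
    warning("significant gene(s) with log_fc = 0 excluded from both lists: ",
            paste(zero, collapse = ", "), call. = FALSE)
  }
  list(up = unique(sig$gene[sig$log_fc > 0]),
       down = unique(sig$gene[sig$log_fc < 0]))
}

#' Gene sets derived from the canonical and non-canonical networks
#'
#' Builds the six gene sets used for over-representation analysis from two
#' gene-labelled networks: each network's full node set, the two relative
#' complements, the intersection and the union.
#'
#' @param canonical,noncanonical Non-empty gene-labelled
#'   [signed_digraph()]s.
#' @return A named list of character vectors with names `canonical`,
#'   `noncanonical`, `can_minus_noncan`, `noncan_minus_can`, `intersection`,
#'   `union`.
#' @export
build_gene_sets <- function(canonical, noncanonical) {
  stopifnot_sdg(canonical, "canonical")
  stopifnot_sdg(noncanonical, "noncanonical")
  if (n_nodes(canonical) == 0 || n_nodes(noncanonical) == 0) {
    stop("both networks must be non-empty", call. = FALSE)
  }
  can <- node_ids(canonical)
  noncan <- node_ids(noncanonical)
  list(
    canonical = can,
    noncanonical = noncan,
    can_minus_noncan = setdiff(can, noncan),
    noncan_minus_can = setdiff(noncan, can),
    intersection = intersect(can, noncan),
    union = union(can, noncan)
  )
}

#' Fisher's exact test for gene-set over-representation
#'
#' One-sided enrichment test: the hypergeometric upper-tail probability of
#' observing at least the realized overlap between the differential genes
#' and the gene set, over the measured gene universe. The gene set is
#' intersected with the universe before testing.
#'
#' @param degs Character vector of differential genes (must be a subset of
#'   `universe`).
#' @param gene_set Character vector, the tested set.
#' @param universe Character vector of all measured genes.
#' @return The one-sided p-value.
#' @export
fisher_overrepresentation <- function(degs, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("universe is empty", call. = FALSE)
  degs <- unique(degs)
  if (!all(degs %in% universe)) {
    stop("degs must be a subset of the universe", call. = FALSE)
  }
  set_in_universe <- intersect(unique(gene_set), universe)
  if (length(set_in_universe) == 0) {
    stop("gene_set has no member in the universe", call. = FALSE)
  }
  q <- length(intersect(degs, set_in_universe))
  m <- length(set_in_universe)
  n <- length(universe) - m
  k <- length(degs)
  stats::phyper(q - 1, m, n, k, lower.tail = FALSE)
}

#' Wilcoxon rank-sum gene-set enrichment on a ranked gene list
#'
#' Ranking-based enrichment: genes are ranked by the chosen statistic
#' (default: p-value, ascending) over the full tested universe, and the
#' ranks of in-set genes are compared to the ranks of all remaining genes
#' with a two-sample Wilcoxon rank-sum test. The default alternative is
#' one-sided, "in-set genes rank higher in the list (smaller p-values /
#' stronger signal)". Exact p-values are used for universes of at most 50
#' genes without ties; otherwise the normal approximation with tie
#' correction.
#'
#' @param table Gene-level data frame covering the full tested universe
#'   (not only significant genes), with columns `gene` and the ranking
#'   column.
#' @param gene_set Character vector; its intersection with the table must be
#'   non-empty and a proper subset.
#' @param rank_by Column to rank by: `"p_value"` (ascending, default) or
#'   `"log_fc"` (descending, so up-regulated genes rank first).
#' @param alternative Sidedness passed to the rank-sum test; default
#'   `"less"` means in-set genes have smaller ranks.
#' @return The p-value.
#' @export
wilcoxon_set_enrichment <- function(table, gene_set,
                                    rank_by = c("p_value", "log_fc"),
                                    alternative = "less") {
  rank_by <- match.arg(rank_by)
  table <- tibble::as_tibble(table)
  if (anyDuplicated(table$gene)) {
    stop("table must be summarized to gene level (duplicate genes present)",
         call. = FALSE)
  }
  score <- if (rank_by == "p_value") table$p_value else -table$log_fc
  r <- rank(score)
  in_set <- table$gene %in% gene_set
  if (!any(in_set) || all(in_set)) {
    stop("gene_set must cover some but not all genes of the table",
         call. = FALSE)
  }
  exact <- nrow(table) <= 50 && !any(duplicated(score))
  suppressWarnings(
    stats::wilcox.test(r[in_set], r[!in_set], alternative = alternative,
                       exact = exact, correct = !exact)$p.value
  )
}

#' Run both enrichment tests for every gene set
#'
#' Convenience wrapper applying [fisher_overrepresentation()] (on a DEG
#' list) and [wilcoxon_set_enrichment()] (on the ranked table) to each set
#' in a collection.
#'
#' @param table Gene-level differential-expression table (the universe).
#' @param degs Character vector of selected differential genes.
#' @param gene_sets Named list of character vectors.
#' @inheritParams wilcoxon_set_enrichment
#' @return A tibble: `gene_set`, `set_size`, `n_overlap`, `fisher_p`,
#'   `wilcoxon_p`.
#' @export
enrichment_table <- function(table, degs, gene_sets,
                             rank_by = "p_value") {
  universe <- unique(table$gene)
  purrr::map_dfr(names(gene_sets), function(nm) {
    set <- gene_sets[[nm]]
    set_in <- intersect(set, universe)
    fp <- if (length(set_in) > 0) {
      fisher_overrepresentation(intersect(degs, universe), set, universe)
    } else NA_real_
    wp <- if (length(set_in) > 0 && length(set_in) < length(universe)) {
      wilcoxon_set_enrichment(table, set, rank_by = rank_by)
    } else NA_real_
    tibble::tibble(gene_set = nm, set_size = length(set_in),
                   n_overlap = length(intersect(degs, set_in)),
                   fisher_p = fp, wilcoxon_p = wp)
  })
}
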