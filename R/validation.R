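#' Node and edge overlap of a module pair
#'
#' Fractions of the reference graph's nodes and edges found in the other
#' graph. Edge identity is the ordered `(source, target)` pair; interaction
#' signs are ignored by default (set `use_sign = TRUE` to require matching
#' signs too).
#'
#' @param reference A non-empty [signed_digraph()] (the reference module).
#' @param other A [signed_digraph()] compared against it.
#' @param use_sign Compare signs as part of edge identity?
#' @return A list with `node_overlap`, `edge_overlap` (both in `[0, 1]`),
#'   `n_ref_nodes`, `n_ref_edges`.
#' @export
graph_overlap <- function(reference, other, use_sign = FALSE) {
  stopifnot_sdg(reference, "reference")
  stopifnot_sdg(other, "other")
  if (n_nodes(reference) == 0) stop("reference graph is empty", call. = FALSE)
  node_overlap <- mean(node_ids(reference) %in% node_ids(other))
  key <- function(e) {
    if (use_sign) paste(e$source, e$target, e$sign, sep = "\r")
    else unique(paste(e$source, e$target, sep = "\r"))
  }
  ref_keys <- key(reference$edges)
  edge_overlap <- if (length(ref_keys) == 0) NA_real_ else {
    mean(ref_keys %in% key(other$edges))
  }
  list(node_overlap = node_overlap, edge_overlap = edge_overlap,
       n_ref_nodes = n_nodes(reference), n_ref_edges = length(ref_keys))
}

#' Fold-change correlation between two modules
#'
#' Pearson correlation of log fold-changes over the genes present in both
#' modules' node sets and carrying a fold-change in both differential
#' tables, with the two-sided t-test p-value and the Fisher-z 95% confidence
#' interval.
#'
#' @param ref_module,val_module `steiner_module`s.
#' @param ref_de,val_de Gene-level data frames with columns `gene`,
#'   `log_fc`.
#' @return A list with `r`, `p`, `conf_low`, `conf_high`, `n_genes`.
#' @export
foldchange_correlation <- function(ref_module, val_module, ref_de, val_de) {
  genes <- intersect(names(ref_module$roles), names(val_module$roles))
  genes <- intersect(genes, intersect(ref_de$gene, val_de$gene))
  x <- ref_de$log_fc[match(genes, ref_de$gene)]
  y <- val_de$log_fc[match(genes, val_de$gene)]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) {
    stop("need at least 3 overlap genes with fold-changes in both tables",
         call. = FALSE)
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson",
                        conf.level = 0.95)
  list(r = unname(ct$estimate), p = ct$p.value,
       conf_low = ct$conf.int[1], conf_high = ct$conf.int[2],
       n_genes = sum(ok))
}

#' Steiner-node status concordance between modules
#'
#' For every Steiner node of the reference module: `confirmed_as_steiner` if
#' it appears in the validation module with role steiner,
#' `confirmed_as_deg` if it appears there as a DEG-induced terminal, and
#' `unconfirmed` otherwise. The three counts partition the reference Steiner
#' set.
#'
#' @param ref_module,val_module `steiner_module`s from the same network
#'   group.
#' @return A list of counts plus the per-node status table (`$status`).
#' @export
steiner_concordance <- function(ref_module, val_module) {
  ref_steiner <- names(ref_module$roles)[ref_module$roles == "steiner"]
  val_roles <- val_module$roles
  status <- vapply(ref_steiner, function(s) {
    if (!s %in% names(val_roles)) return("unconfirmed")
    if (val_roles[[s]] == "steiner") "confirmed_as_steiner" else "confirmed_as_deg"
  }, character(1))
  list(
    confirmed_as_steiner = sum(status == "confirmed_as_steiner"),
    confirmed_as_deg = sum(status == "confirmed_as_deg"),
    unconfirmed = sum(status == "unconfirmed"),
    status = tibble::tibble(node = ref_steiner, status = unname(status))
  )
}

#' Overlap of significant genes between two differential tables
#'
#' Counts the genes significant (adjusted p below `alpha`) in both tables
#' and reports the Pearson correlation of their log fold-changes over that
#' overlap. With fewer than 3 overlap genes the correlation is omitted with
#' a warning.
#'
#' @param de_a,de_b Gene-level data frames with columns `gene`, `log_fc`,
#'   `adj_p`.
#' @param alpha Significance threshold (default 0.05).
#' @return A list with `n_overlap`, `r` (possibly `NA`), `p`, `conf_low`,
#'   `conf_high`.
#' @export
deg_overlap <- function(de_a, de_b, alpha = 0.05) {
  sig_a <- de_a[de_a$adj_p < alpha, , drop = FALSE]
  sig_b <- de_b[de_b$adj_p < alpha, , drop = FALSE]
  genes <- intersect(sig_a$gene, sig_b$gene)
  out <- list(n_overlap = length(genes), r = NA_real_, p = NA_real_,
              conf_low = NA_real_, conf_high = NA_real_)
  if (length(genes) < 3) {
    warning("fewer than 3 overlap genes; correlation omitted", call. = FALSE)
    return(out)
  }
  ct <- stats::cor.test(sig_a$log_fc[match(genes, sig_a$gene)],
                        sig_b$log_fc[match(genes, sig_b$gene)],
                        method = "pearson")
  out$r <- unname(ct$estimate)
  out$p <- ct$p.value
  out$conf_low <- ct$conf.int[1]
  out$conf_high <- ct$conf.int[2]
  out
}

#' Full concordance report for a module pair
#'
#' Combines [graph_overlap()], [foldchange_correlation()] and
#' [steiner_concordance()] into one report, with the microarray-derived
#' (reference) module as the yardstick.
#'
#' @inheritParams foldchange_correlation
#' @param use_sign Sign-aware edge overlap? See [graph_overlap()].
#' @return An object of class `overlap_report` (a list of all fields);
#'   `tidy()` returns it as a one-row tibble.
#' @export
overlap_report <- function(ref_module, val_module, ref_de = NULL,
                           val_de = NULL, use_sign = FALSE) {
  go <- graph_overlap(ref_module$graph, val_module$graph, use_sign = use_sign)
  fc <- if (!is.null(ref_de) && !is.null(val_de)) {
    foldchange_correlation(ref_module, val_module, ref_de, val_de)
  } else {
    list(r = NA_real_, p = NA_real_, conf_low = NA_real_,
         conf_high = NA_real_, n_genes = NA_integer_)
  }
  sc <- steiner_concordance(ref_module, val_module)
  structure(c(go, fc_correlation = list(fc), steiner = list(sc)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap_report> node overlap %.1f%%, edge overlap %.1f%% (of %d nodes / %d edges)\n",
              100 * x$node_overlap, 100 * x$edge_overlap,
              x$n_ref_nodes, x$n_ref_edges))
  if (!is.na(x$fc_correlation$r)) {
    cat(sprintf("  fold-change correlation r = %.2f (p = %.3g, 95%% CI [%.2f, %.2f], n = %d)\n",
                x$fc_correlation$r, x$fc_correlation$p,
                x$fc_correlation$conf_low, x$fc_correlation$conf_high,
                x$fc_correlation$n_genes))
  }
  cat(sprintf("  Steiner concordance: %d as steiner, %d as DEG, %d unconfirmed\n",
              x$steiner$confirmed_as_steiner, x$steiner$confirmed_as_deg,
              x$steiner$unconfirmed))
  invisible(x)
}

#' @rdname overlap_report
#' @param x An `overlap_report`.
#' @param ... Unused.
#' @export
tidy.overlap_report <- function(x, ...) {
  tibble::tibble(
    node_overlap = x$node_overlap,
    edge_overlap = x$edge_overlap,
    n_ref_nodes = x$n_ref_nodes,
    n_ref_edges = x$n_ref_edges,
    fc_r = x$fc_correlation$r,
    fc_p = x$fc_correlation$p,
    fc_conf_low = x$fc_correlation$conf_low,
    fc_conf_high = x$fc_correlation$conf_high,
    confirmed_as_steiner = x$steiner$confirmed_as_steiner,
    confirmed_as_deg = x$steiner$confirmed_as_deg,
    unconfirmed = x$steiner$unconfirmed
  )
}
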