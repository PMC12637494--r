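#' Aggregate enriched terms by semantic similarity components
#'
#' Generic graph-based term aggregation: keep terms with at least
#' `min_genes` member genes, retain the `top_n` most significant by adjusted
#' p-value, connect terms whose supplied similarity is at least
#' `sim_threshold`, take connected components, and pick each component's
#' most significant term as its representative (ties broken by term id).
#'
#' @param terms Data frame with `term_id`, `p_adjusted`, `gene_count` (and
#'   optionally `description`).
#' @param similarity Symmetric term-by-term similarity matrix in `[0, 1]`
#'   with unit diagonal, dimnames covering all retained terms.
#' @param top_n Number of most significant terms kept after the gene-count
#'   filter.
#' @param min_genes Minimum member genes for a term to enter.
#' @param sim_threshold Similarity at or above which two terms are linked.
#' @return Tibble `term_id`, `p_adjusted`, `gene_count`, `component`,
#'   `representative` (term id of the component representative),
#'   `is_representative`. Empty after filtering gives an empty tibble.
#' @export
aggregate_terms <- function(terms, similarity, top_n = 50, min_genes = 10,
                            sim_threshold = 0.3) {
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("term_id", "p_adjusted", "gene_count") %in% names(terms)))
  keep <- terms[terms$gene_count >= min_genes, , drop = FALSE]
  keep <- keep[order(keep$p_adjusted, keep$term_id), , drop = FALSE]
  keep <- utils::head(keep, top_n)
  if (nrow(keep) == 0L) {
    return(tibble::add_column(keep, component = integer(),
                              representative = character(),
                              is_representative = logical()))
  }
  ids <- keep$term_id
  if (!all(ids %in% rownames(similarity)))
    stop("similarity matrix must cover all retained terms")
  s <- similarity[ids, ids, drop = FALSE]
  adj <- (s >= sim_threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  keep$component <- as.integer(comp)
  rep_of <- vapply(split(seq_len(nrow(keep)), keep$component), function(i) {
    i <- i[order(keep$p_adjusted[i], keep$term_id[i])]
    keep$term_id[i[1]]
  }, character(1))
  keep$representative <- unname(rep_of[as.character(keep$component)])
  keep$is_representative <- keep$term_id == keep$representative
  keep
}

#' Over-representation of gene sets in TECs
#'
#' Exact hypergeometric upper-tail test of the overlap between each TEC's
#' genes and each supplied gene set within a common universe, with
#' Benjamini-Hochberg adjustment across all TEC-set cells.
#'
#' @param tec_genes Named list of character vectors (genes per TEC), or a
#'   `tec_assignment` (split by `tec`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of all considered genes; TEC genes and
#'   sets must be subsets of it.
#' @return Tibble `tec`, `set`, `overlap`, `tec_size`, `set_size`,
#'   `fraction` (overlap / TEC size), `p`, `padj`.
#' @export
enrich_sets <- function(tec_genes, gene_sets, universe) {
  if (inherits(tec_genes, "tec_assignment"))
    tec_genes <- split(tec_genes$gene_id, tec_genes$tec)
  if (length(universe) == 0L) stop("universe must be non-empty")
  universe <- unique(universe)
  N <- length(universe)
  tec_genes <- lapply(tec_genes, intersect, universe)
  gene_sets <- lapply(gene_sets, intersect, universe)

  out <- tidyr::expand_grid(tec = names(tec_genes), set = names(gene_sets))
  out <- dplyr::rowwise(out)
  out <- dplyr::mutate(out, {
    tg <- tec_genes[[.data$tec]]; gs <- gene_sets[[.data$set]]
    k <- length(intersect(tg, gs))
    tibble::tibble(
      overlap = k, tec_size = length(tg), set_size = length(gs),
      fraction = if (length(tg)) k / length(tg) else NA_real_,
      p = phyper(k - 1, length(gs), N - length(gs), length(tg),
                 lower.tail = FALSE))
  })
  out <- dplyr::ungroup(out)
  out$padj <- p.adjust(out$p, method = "BH")
  out
}
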