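# Running-sum enrichment score of a gene set against a ranked gene list,
# and the weighted bidirectional combination used to score a pair.

# Scan a ranked gene order against a query set. With N ranked genes of which
# n belong to the query, the running sum rises by (N - n)/n at each query
# gene and falls by n/(N - n) otherwise; the score is the maximum over all
# prefixes. Note the increments are not the zero-sum GSEA normalization:
# the final prefix equals N - 2n, as the printed formulation prescribes.
es_scan <- function(order_genes, query) {
  n_total <- length(order_genes)
  hit <- order_genes %in% query
  n <- sum(hit)
  if (n == 0L) {
    stop("query set has no gene in the ranking", call. = FALSE)
  }
  if (n == n_total) {
    stop("query set covers the whole ranking; miss decrement undefined",
      call. = FALSE
    )
  }
  steps <- ifelse(hit, (n_total - n) / n, -(n / (n_total - n)))
  rs <- cumsum(steps)
  es <- max(rs)
  if (es < 0) {
    warning("running sum never positive; returning its (negative) maximum",
      call. = FALSE
    )
  }
  list(es = es, argmax_rank = which.max(rs), n_set = n)
}

#' Running-sum enrichment score of a gene set in a ranking
#'
#' Measures whether the query genes concentrate at the top of a ranked gene
#' list. Query genes absent from the ranking are dropped before scanning.
#'
#' @param ranking A `rwr_ranking` (or any tibble with genes in rank order in
#'   a `gene` column).
#' @param query Character vector of query genes, or a single-set
#'   `geneset_collection`.
#' @return A one-row tibble with columns `es` (the maximal running sum),
#'   `argmax_rank` (where the peak occurs), and `n_set` (in-ranking query
#'   size).
#' @export
running_sum_es <- function(ranking, query) {
  if (inherits(query, "geneset_collection")) {
    query <- unique(query$gene)
  }
  res <- es_scan(ranking$gene, as.character(query))
  tibble::tibble(
    es = res$es,
    argmax_rank = res$argmax_rank,
    n_set = res$n_set
  )
}

#' Combine the two directional enrichment scores
#'
#' The pair score is `beta * es1 + (1 - beta) * es2`, weighting the
#' enrichment of miRNA targets in the disease-seeded ranking (`es1`) against
#' the enrichment of disease genes in the target-seeded ranking (`es2`).
#'
#' @param es1,es2 Directional enrichment scores.
#' @param beta Weight in (0, 1); the default 0.5 treats both directions
#'   equally.
#' @return The combined score (vectorized over `es1`/`es2`).
#' @export
combine_es <- function(es1, es2, beta = 0.5) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 1) {
    stop("`beta` must be a single number strictly between 0 and 1",
      call. = FALSE
    )
  }
  beta * es1 + (1 - beta) * es2
}

#' Bidirectional enrichment score of one miRNA-disease pair
#'
#' Propagates the disease genes and scores the miRNA targets against that
#' ranking (`es1`), propagates the targets and scores the disease genes
#' (`es2`), and combines the two with weight `beta`.
#'
#' @param net A `ppi_network`.
#' @param disease_genes,targets Character vectors (or single-set
#'   collections) of disease genes and miRNA targets; both must intersect
#'   the network.
#' @param alpha Restart probability of the random walk.
#' @param beta Combination weight, see [combine_es()].
#' @param ... Further arguments passed to [rwr_rank()].
#' @return A one-row tibble with columns `es1`, `es2`, `es`, `beta`.
#' @export
score_pair_es <- function(net, disease_genes, targets,
                          alpha = 0.7, beta = 0.5, ...) {
  net <- as_ppi_network(net, quiet = TRUE)
  if (inherits(disease_genes, "geneset_collection")) {
    disease_genes <- unique(disease_genes$gene)
  }
  if (inherits(targets, "geneset_collection")) {
    targets <- unique(targets$gene)
  }
  rank_d <- rwr_rank(net, disease_genes, alpha = alpha, ...)
  rank_t <- rwr_rank(net, targets, alpha = alpha, ...)
  es1 <- es_scan(rank_d$gene, targets)$es
  es2 <- es_scan(rank_t$gene, disease_genes)$es
  tibble::tibble(es1 = es1, es2 = es2, es = combine_es(es1, es2, beta), beta = beta)
}
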