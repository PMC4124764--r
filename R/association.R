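# All-pairs association scoring with permutation significance from
# degree-preserving random networks, and the thresholded bipartite network.

#' Permutation p-value of an observed enrichment score
#'
#' `k` counts null scores greater than or equal to the observed score (ties
#' count), and `p = k / n_null`. A p-value of exactly 0 is possible and is
#' reported as such; set `pseudocount = TRUE` for the `(k + 1) / (n + 1)`
#' variant.
#'
#' @param observed_es Observed combined enrichment score.
#' @param null_ess Numeric vector of scores from randomized networks.
#' @param pseudocount Use the add-one estimator instead of the exact
#'   fraction.
#' @return A one-row tibble with columns `k`, `n_null`, `p_value`.
#' @export
permutation_pvalue <- function(observed_es, null_ess, pseudocount = FALSE) {
  if (length(null_ess) == 0L) {
    stop("empty null distribution", call. = FALSE)
  }
  k <- sum(null_ess >= observed_es)
  n <- length(null_ess)
  p <- if (pseudocount) (k + 1) / (n + 1) else k / n
  tibble::tibble(k = k, n_null = n, p_value = p)
}

# Combined ES for every (disease, miRNA) pair on one network. One RWR
# propagation per seed set (not per pair): the ranking seeded by a disease
# is reused against every miRNA and vice versa.
score_network_pairs <- function(net, dis_list, mir_list,
                                alpha, beta, tol, max_iter) {
  op <- rwr_operator(net)
  rank_order <- function(seeds) {
    fit <- rwr_solve(op, resolve_seeds(op, seeds), alpha, tol, max_iter)
    op$nodes[order(-fit$p, op$nodes)]
  }
  ord_d <- lapply(dis_list, rank_order)
  ord_m <- lapply(mir_list, rank_order)
  nd <- length(dis_list)
  nm <- length(mir_list)
  es1 <- matrix(NA_real_, nd, nm)
  es2 <- matrix(NA_real_, nd, nm)
  for (d in seq_len(nd)) {
    for (m in seq_len(nm)) {
      es1[d, m] <- es_scan(ord_d[[d]], mir_list[[m]])$es
      es2[d, m] <- es_scan(ord_m[[m]], dis_list[[d]])$es
    }
  }
  list(es1 = es1, es2 = es2, es = beta * es1 + (1 - beta) * es2)
}

#' Score every disease-miRNA pair with permutation significance
#'
#' For each pair the combined bidirectional enrichment score is computed on
#' the observed network, then recomputed on `n_null` degree-preserving
#' randomizations of the network (same seed sets); the p-value is the
#' fraction of null scores at least as large as the observed one. Random
#' network `i` is generated with seed `seed + i`, so results are fully
#' reproducible. Per-network rankings are shared across pairs, giving
#' `n_null * (n_diseases + n_mirnas)` propagations in total.
#'
#' @param net A `ppi_network` (typically its largest component).
#' @param diseases,mirnas `geneset_collection`s annotated to the network.
#' @param n_null Ensemble size (1000 at production scale).
#' @param alpha Restart probability of the random walk.
#' @param beta Combination weight for the two directional scores.
#' @param swaps_per_edge Edge-switch attempts per edge for each random
#'   network.
#' @param seed Integer seed governing all randomization.
#' @param tol,max_iter Convergence control for [rwr_rank()]; the default
#'   tolerance is looser than `rwr_rank`'s because only rank order matters
#'   here.
#' @return An `mdn_assoc` tibble with one row per pair: `mirna_id`,
#'   `disease_id`, `es1`, `es2`, `es`, `k`, `n_null`, `p_value`.
#' @export
score_associations <- function(net, diseases, mirnas,
                               n_null = 1000L, alpha = 0.7, beta = 0.5,
                               swaps_per_edge = 10L, seed,
                               tol = 1e-8, max_iter = 1000L) {
  stopifnot(n_null >= 1L, alpha > 0, alpha < 1)
  if (beta <= 0 || beta >= 1) {
    stop("`beta` must lie strictly between 0 and 1", call. = FALSE)
  }
  net <- as_ppi_network(net, quiet = TRUE)
  seed <- as.integer(seed)
  dis_list <- geneset_list(diseases)
  mir_list <- geneset_list(mirnas)
  if (length(dis_list) == 0L || length(mir_list) == 0L) {
    stop("empty gene-set collection", call. = FALSE)
  }

  obs <- score_network_pairs(net, dis_list, mir_list, alpha, beta, tol, max_iter)
  k <- matrix(0L, nrow(obs$es), ncol(obs$es))
  attempts <- swaps_per_edge * nrow(net)
  for (b in seq_len(n_null)) {
    net_b <- edge_switch_randomize(net, attempts, rng_seed = seed + b)
    null_b <- score_network_pairs(
      net_b, dis_list, mir_list, alpha, beta, tol, max_iter
    )$es
    k <- k + (null_b >= obs$es)
  }

  records <- tidyr::expand_grid(
    disease_id = names(dis_list),
    mirna_id = names(mir_list)
  ) |>
    dplyr::mutate(
      es1 = as.vector(t(obs$es1)),
      es2 = as.vector(t(obs$es2)),
      es = as.vector(t(obs$es)),
      k = as.vector(t(k)),
      n_null = as.integer(n_null),
      p_value = .data$k / n_null
    ) |>
    dplyr::relocate("mirna_id", "disease_id")
  structure(
    records,
    alpha = alpha, beta = beta, seed = seed,
    swaps_per_edge = swaps_per_edge,
    disease_classes = set_classes(diseases),
    class = c("mdn_assoc", class(tibble::tibble()))
  )
}

#' Build the bipartite miRNA-disease network
#'
#' Connects a miRNA and a disease when their association p-value is strictly
#' below the threshold `delta`; pairs tied at the threshold are excluded.
#' miRNAs and diseases left without any edge do not appear as nodes.
#'
#' @param records An `mdn_assoc` tibble (or any data frame with `mirna_id`,
#'   `disease_id`, `p_value`).
#' @param delta Significance threshold in (0, 1]; 0.05 in the reference
#'   analysis. The threshold changes how many associations survive but not
#'   the p-value ranking of miRNAs within a disease.
#' @param classes Optional tibble (`set_id`, `class`) of disease-class
#'   labels; defaults to the labels carried by `records`.
#' @return An `mdn_bipartite` tibble of edges (`mirna_id`, `disease_id`,
#'   `p_value`, `class`) with the threshold stored as an attribute.
#' @export
build_bipartite <- function(records, delta = 0.05, classes = NULL) {
  stopifnot(delta > 0, delta <= 1)
  if (is.null(classes)) {
    classes <- attr(records, "disease_classes")
  }
  edges <- tibble::as_tibble(records) |>
    dplyr::filter(.data$p_value < delta) |>
    dplyr::select("mirna_id", "disease_id", "p_value")
  if (!is.null(classes)) {
    edges <- dplyr::left_join(
      edges,
      dplyr::rename(classes, disease_id = "set_id"),
      by = "disease_id"
    )
  } else {
    edges$class <- NA_character_
  }
  edges$class[is.na(edges$class)] <- "Unknown"
  structure(
    edges,
    threshold = delta,
    class = c("mdn_bipartite", class(tibble::tibble()))
  )
}

#' @exportS3Method base::print
print.mdn_bipartite <- function(x, ...) {
  cat(
    "# miRNA-disease network (p < ", attr(x, "threshold"), "): ",
    dplyr::n_distinct(x$mirna_id), " miRNAs, ",
    dplyr::n_distinct(x$disease_id), " diseases, ",
    nrow(x), " edges\n",
    sep = ""
  )
  NextMethod()
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' One-row summary of a bipartite miRNA-disease network
#'
#' @param x An `mdn_bipartite`.
#' @param ... Unused.
#' @return A tibble with `n_mirnas`, `n_diseases`, `n_edges`, `threshold`.
#' @method glance mdn_bipartite
#' @export
glance.mdn_bipartite <- function(x, ...) {
  tibble::tibble(
    n_mirnas = dplyr::n_distinct(x$mirna_id),
    n_diseases = dplyr::n_distinct(x$disease_id),
    n_edges = nrow(x),
    threshold = attr(x, "threshold")
  )
}
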