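# Random walk with restart over an interaction network.
#
# The walker starts on the seed genes and at every step either restarts at a
# seed (probability alpha) or moves to a uniformly chosen neighbour. The
# stationary distribution p solves p = (1 - alpha) W p + alpha p0 with W the
# column-normalized adjacency and p0 uniform over seeds; it measures global
# network proximity of every gene to the seed set.

# Column-normalized sparse adjacency plus the node order it is expressed in.
# Nodes come from an edge list so every column has positive degree.
rwr_operator <- function(net) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  i <- match(c(net$from, net$to), nodes)
  j <- match(c(net$to, net$from), nodes)
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  w <- a %*% Matrix::Diagonal(x = 1 / Matrix::colSums(a))
  list(w = w, nodes = nodes)
}

# Power iteration to the stationary distribution; L1 stopping rule.
rwr_solve <- function(op, seed_idx, alpha, tol = 1e-10, max_iter = 1000L) {
  n <- length(op$nodes)
  p0 <- numeric(n)
  p0[seed_idx] <- 1 / length(seed_idx)
  p <- p0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p_new <- as.numeric((1 - alpha) * (op$w %*% p)) + alpha * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol || iter >= max_iter) break
  }
  if (delta >= tol) {
    warning("RWR did not converge in ", max_iter,
      " iterations (L1 change ", format(delta), ")",
      call. = FALSE
    )
  }
  list(p = p, iterations = iter, converged = delta < tol)
}

resolve_seeds <- function(op, seeds) {
  if (inherits(seeds, "geneset_collection")) {
    seeds <- unique(seeds$gene)
  }
  seeds <- as.character(seeds)
  idx <- match(unique(seeds), op$nodes)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) {
    stop(
      "no seed gene is present in the network (seeds: ",
      paste(utils::head(seeds, 5L), collapse = ", "),
      if (length(seeds) > 5L) ", ..." else "", ")",
      call. = FALSE
    )
  }
  idx
}

#' Rank all network genes by proximity to a seed set
#'
#' Runs a random walk with restart from the seed genes and returns every
#' gene of the network ranked by its stationary visiting probability.
#' Genes in components that contain no seed receive probability 0. Ties
#' (e.g. structurally equivalent genes) are broken by ascending gene
#' identifier so that downstream enrichment scores are reproducible.
#'
#' @param net A `ppi_network` (or edge data frame).
#' @param seeds Character vector of seed genes, or a single-set
#'   `geneset_collection`. Seeds absent from the network are ignored; it is
#'   an error if none remain.
#' @param alpha Restart probability in (0, 1). The default 0.7 sits in the
#'   0.5-0.9 range over which ranking performance is stable.
#' @param tol L1 convergence tolerance of the power iteration.
#' @param max_iter Iteration cap; non-convergence raises a warning.
#' @return A `rwr_ranking` tibble with columns `gene`, `probability`, `rank`
#'   (1 = most proximal), sorted by rank.
#' @examples
#' net <- as_ppi_network(data.frame(from = c("a", "b"), to = c("b", "c")))
#' rwr_rank(net, seeds = "a", alpha = 0.5)
#' @export
rwr_rank <- function(net, seeds, alpha = 0.7, tol = 1e-10, max_iter = 1000L) {
  stopifnot(alpha > 0, alpha < 1, tol > 0, max_iter >= 1L)
  net <- as_ppi_network(net, quiet = TRUE)
  op <- rwr_operator(net)
  fit <- rwr_solve(op, resolve_seeds(op, seeds), alpha, tol, max_iter)
  ord <- order(-fit$p, op$nodes)
  out <- tibble::tibble(
    gene = op$nodes[ord],
    probability = fit$p[ord],
    rank = seq_along(ord)
  )
  structure(
    out,
    iterations = fit$iterations,
    converged = fit$converged,
    alpha = alpha,
    class = c("rwr_ranking", class(tibble::tibble()))
  )
}

#' Rank of a gene in a ranking
#'
#' @param ranking A `rwr_ranking` (any tibble with `gene` and `rank`).
#' @param gene Gene identifier.
#' @return The 1-based rank.
#' @export
rank_of <- function(ranking, gene) {
  i <- match(gene, ranking$gene)
  if (anyNA(i)) {
    stop(
      "gene(s) not in ranking: ",
      paste(gene[is.na(i)], collapse = ", "),
      call. = FALSE
    )
  }
  ranking$rank[i]
}
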