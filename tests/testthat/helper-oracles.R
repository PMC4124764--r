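# Independent oracles and tiny fixtures shared across tests. Each oracle
# recomputes a quantity by a route unrelated to the implementation it checks.

# Running-sum enrichment evaluated independently at every prefix, straight
# from the definition: at prefix i, sum (N-n)/n over query genes among the
# first i and subtract n/(N-n) for each non-query gene.
es_oracle <- function(order_genes, query) {
  n_total <- length(order_genes)
  hit <- order_genes %in% query
  n <- sum(hit)
  prefix <- vapply(seq_len(n_total), function(i) {
    h <- sum(hit[seq_len(i)])
    h * (n_total - n) / n - (i - h) * n / (n_total - n)
  }, numeric(1L))
  max(prefix)
}

# Stationary RWR distribution by dense linear solve:
# p = alpha * (I - (1 - alpha) W)^{-1} p0.
rwr_direct_oracle <- function(net, seeds, alpha) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  a <- matrix(0, n, n, dimnames = list(nodes, nodes))
  a[cbind(net$from, net$to)] <- 1
  a[cbind(net$to, net$from)] <- 1
  w <- sweep(a, 2L, colSums(a), "/")
  p0 <- as.numeric(nodes %in% seeds)
  p0 <- p0 / sum(p0)
  as.numeric(solve(diag(n) - (1 - alpha) * w, alpha * p0))
}

# AUC as the Mann-Whitney concordant-pair fraction; lower score = stronger
# prediction, so a (positive, negative) pair is concordant when the positive
# scores lower. Ties count one half.
auc_concordance_oracle <- function(score_pos, score_neg) {
  grid <- expand.grid(p = score_pos, n = score_neg)
  mean((grid$p < grid$n) + 0.5 * (grid$p == grid$n))
}

# Upper-tail hypergeometric by exhaustive enumeration of all target draws.
hyper_enum_oracle <- function(n_universe, n_disease, n_targets, overlap) {
  draws <- utils::combn(n_universe, n_targets)
  hits <- colSums(draws <= n_disease) # disease genes are items 1..n_disease
  mean(hits >= overlap)
}

# Small deterministic fixtures ------------------------------------------------

path_network <- function(genes = c("a", "b", "c")) {
  as_ppi_network(
    data.frame(from = genes[-length(genes)], to = genes[-1]),
    quiet = TRUE
  )
}

star_network <- function(center = "s", leaves = paste0("l", 1:4)) {
  as_ppi_network(
    data.frame(from = center, to = leaves),
    quiet = TRUE
  )
}

# Erdos-Renyi-style random connected-ish test graph over n nodes.
random_network <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(sprintf("g%03d", seq_len(n)), 2L))
    keep <- stats::runif(nrow(pairs)) < p_edge
    # guarantee no isolated node by adding a backbone path
    backbone <- cbind(sprintf("g%03d", 1:(n - 1)), sprintf("g%03d", 2:n))
    as_ppi_network(
      as.data.frame(rbind(pairs[keep, , drop = FALSE], backbone)),
      quiet = TRUE
    )
  })
}

# A ranking tibble from an explicit gene order (rank 1 first).
ranking_of <- function(order_genes) {
  tibble::tibble(
    gene = order_genes,
    probability = rev(seq_along(order_genes)) / sum(seq_along(order_genes)),
    rank = seq_along(order_genes)
  )
}
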