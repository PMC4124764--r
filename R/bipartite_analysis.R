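# Global analysis of the bipartite miRNA-disease network: degrees,
# disease-class modularity (BD/BH), and two-way hierarchical clustering.

#' Node degrees of the bipartite network
#'
#' @param net An `mdn_bipartite`.
#' @return A tibble with columns `node`, `side` (`"mirna"` or `"disease"`),
#'   and `degree`, sorted by decreasing degree within side. Both sides sum
#'   to the edge count.
#' @export
bipartite_degrees <- function(net) {
  stopifnot(nrow(net) > 0L)
  dplyr::bind_rows(
    tibble::as_tibble(net) |>
      dplyr::count(node = .data$mirna_id, name = "degree") |>
      dplyr::mutate(side = "mirna"),
    tibble::as_tibble(net) |>
      dplyr::count(node = .data$disease_id, name = "degree") |>
      dplyr::mutate(side = "disease")
  ) |>
    dplyr::arrange(.data$side, dplyr::desc(.data$degree), .data$node) |>
    dplyr::select("node", "side", "degree")
}

#' Average disease degree per disease class
#'
#' @param net An `mdn_bipartite` with class labels (unlabeled diseases are
#'   grouped under `"Unknown"`).
#' @return A tibble with columns `class`, `n_diseases`, `avg_degree`.
#' @export
class_average_degree <- function(net) {
  tibble::as_tibble(net) |>
    dplyr::count(.data$disease_id, .data$class, name = "degree") |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n_diseases = dplyr::n(),
      avg_degree = mean(.data$degree)
    ) |>
    dplyr::arrange(dplyr::desc(.data$avg_degree))
}

# Binary incidence matrix, diseases in rows, miRNAs in columns.
incidence_matrix <- function(net) {
  d <- sort(unique(net$disease_id))
  m <- sort(unique(net$mirna_id))
  mat <- matrix(0L, length(d), length(m), dimnames = list(d, m))
  mat[cbind(match(net$disease_id, d), match(net$mirna_id, m))] <- 1L
  mat
}

# Mean number of shared miRNA regulators over a set of disease pairs.
# shared[i, j] counts miRNAs linked to both disease i and disease j.
shared_regulators <- function(net) {
  mat <- incidence_matrix(net)
  tcrossprod(mat)
}

#' Disease-class modularity of the bipartite network (BD and BH)
#'
#' Quantifies whether the diseases of a class cluster through shared miRNA
#' regulators. With `s(d_i, d_j)` the number of miRNAs linked to both
#' diseases, `BD` is the mean of `s` over within-class disease pairs and
#' `BH` the mean over (in-class, out-of-class) pairs, each divided by the
#' mean of `s` over all disease pairs in the network. `BD > 1` with
#' `BH < 1` indicates that the class's diseases share regulators clearly
#' more among themselves than with the rest of the network; `BD > BH`
#' indicates a clustering tendency. The exact published definition is not
#' available, so this shared-neighbour-ratio form is a reconstruction chosen
#' to satisfy those interpretive properties.
#'
#' @param net An `mdn_bipartite` with class labels.
#' @param class_name Class (or classes) to score; defaults to every class
#'   with at least two member diseases.
#' @return A tibble with columns `class`, `n_diseases`, `bd`, `bh`.
#' @export
bd_bh <- function(net, class_name = NULL) {
  shared <- shared_regulators(net)
  diseases <- rownames(shared)
  nd <- length(diseases)
  if (nd < 2L) {
    stop("need at least two diseases in the network", call. = FALSE)
  }
  labels <- tibble::as_tibble(net) |>
    dplyr::distinct(.data$disease_id, .data$class)
  cls <- labels$class[match(diseases, labels$disease_id)]
  all_mean <- (sum(shared) - sum(diag(shared))) / (nd * (nd - 1))
  if (all_mean == 0) {
    stop("no disease pair shares a regulator; BD/BH undefined", call. = FALSE)
  }
  if (is.null(class_name)) {
    class_name <- sort(unique(cls[duplicated(cls)]))
  }
  purrr::map_dfr(class_name, function(cn) {
    inside <- which(cls == cn)
    nc <- length(inside)
    if (nc < 2L) {
      stop("class '", cn, "' has fewer than two diseases in the network",
        call. = FALSE
      )
    }
    if (nc == nd) {
      stop("class '", cn, "' covers every disease; BH undefined",
        call. = FALSE
      )
    }
    within_sum <- sum(shared[inside, inside]) - sum(diag(shared)[inside])
    bd <- (within_sum / (nc * (nc - 1))) / all_mean
    between_mean <- sum(shared[inside, -inside]) / (nc * (nd - nc))
    tibble::tibble(
      class = cn, n_diseases = nc,
      bd = bd, bh = between_mean / all_mean
    )
  })
}

#' Two-way hierarchical clustering into co-regulated modules
#'
#' Clusters the binary incidence matrix of the bipartite network on both
#' axes with city-block (L1) distance and complete linkage, cuts each
#' dendrogram, and reports every (disease-cluster, miRNA-cluster) block
#' whose edge density reaches `min_density` as a co-regulated module.
#'
#' @param net An `mdn_bipartite` with at least two nodes on each side.
#' @param k_diseases,k_mirnas Number of clusters to cut each dendrogram
#'   into.
#' @param min_density Minimum fraction of present edges inside a block for
#'   it to be reported as a module.
#' @return An `mdn_modules` tibble with one row per module: `module`,
#'   list-columns `diseases` and `mirnas`, `n_edges`, `density`, plus the
#'   two `hclust` trees and cluster assignments as attributes.
#' @export
cluster_bipartite <- function(net, k_diseases = 2L, k_mirnas = k_diseases,
                              min_density = 0.8) {
  mat <- incidence_matrix(net)
  if (nrow(mat) < 2L || ncol(mat) < 2L) {
    stop("need at least two diseases and two miRNAs to cluster", call. = FALSE)
  }
  if (all(mat == 0L)) {
    stop("incidence matrix has no edges", call. = FALSE)
  }
  hc_d <- stats::hclust(stats::dist(mat, method = "manhattan"), method = "complete")
  hc_m <- stats::hclust(stats::dist(t(mat), method = "manhattan"), method = "complete")
  cut_d <- stats::cutree(hc_d, k = k_diseases)
  cut_m <- stats::cutree(hc_m, k = k_mirnas)
  blocks <- tidyr::expand_grid(dc = seq_len(k_diseases), mc = seq_len(k_mirnas))
  modules <- purrr::pmap_dfr(blocks, function(dc, mc) {
    rows <- names(cut_d)[cut_d == dc]
    cols <- names(cut_m)[cut_m == mc]
    block <- mat[rows, cols, drop = FALSE]
    tibble::tibble(
      diseases = list(rows), mirnas = list(cols),
      n_edges = sum(block), density = mean(block)
    )
  }) |>
    dplyr::filter(.data$density >= min_density) |>
    dplyr::arrange(dplyr::desc(.data$density)) |>
    dplyr::mutate(module = dplyr::row_number(), .before = 1L)
  structure(
    modules,
    hclust_diseases = hc_d, hclust_mirnas = hc_m,
    cut_diseases = cut_d, cut_mirnas = cut_m,
    min_density = min_density,
    class = c("mdn_modules", class(tibble::tibble()))
  )
}

#' Export the clustering dendrograms in Newick format
#'
#' @param modules An `mdn_modules` result.
#' @return Named list with `diseases` and `mirnas` Newick strings.
#' @export
dendrogram_newick <- function(modules) {
  list(
    diseases = ape::write.tree(ape::as.phylo(attr(modules, "hclust_diseases"))),
    mirnas = ape::write.tree(ape::as.phylo(attr(modules, "hclust_mirnas")))
  )
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items; 1 for
#' identical partitions, approximately 0 for independent ones. Used to
#' verify recovery of planted module structure.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    return(1)
  }
  (sum_ij - expected) / (max_index - expected)
}

#' Correlation of miRNA degree with target-set statistics
#'
#' Tests whether a miRNA's degree in the bipartite network tracks the size
#' of its target set (`targets`) and the fraction of its targets that are
#' disease genes (`ratio`), with Pearson correlation and a two-sided test.
#'
#' @param net An `mdn_bipartite`.
#' @param mirna_stats Tibble with columns `mirna_id`, `n_targets`, and
#'   `n_disease_genes_targeted`.
#' @return A tibble with columns `metric` (`"targets"`, `"ratio"`),
#'   `estimate`, `p_value`, `n`.
#' @export
degree_correlations <- function(net, mirna_stats) {
  stopifnot(all(c("mirna_id", "n_targets", "n_disease_genes_targeted") %in%
    names(mirna_stats)))
  df <- bipartite_degrees(net) |>
    dplyr::filter(.data$side == "mirna") |>
    dplyr::inner_join(mirna_stats, by = c(node = "mirna_id")) |>
    dplyr::mutate(ratio = .data$n_disease_genes_targeted / .data$n_targets)
  if (nrow(df) < 3L) {
    stop("need at least 3 matched miRNAs for a correlation", call. = FALSE)
  }
  one <- function(metric, x) {
    if (stats::sd(x) == 0 || stats::sd(df$degree) == 0) {
      stop("correlation undefined: '", metric, "' or degree is constant",
        call. = FALSE
      )
    }
    ct <- stats::cor.test(df$degree, x)
    tibble::tibble(
      metric = metric, estimate = unname(ct$estimate),
      p_value = ct$p.value, n = nrow(df)
    )
  }
  dplyr::bind_rows(
    one("targets", df$n_targets),
    one("ratio", df$ratio)
  )
}
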