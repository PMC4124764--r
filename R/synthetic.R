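# Seeded synthetic worlds: a scale-free interaction network, locally
# connected disease modules, miRNA target sets with tunable proximity signal,
# disease classes with shared regulators, and labeled evaluation pairs.
#
# The generator emulates the structure of the real inputs (a hub-dominated
# PPI network, modular disease genes, target sets of a few dozen genes) at
# desk scale so that every pipeline stage can be exercised and calibrated
# without external curated data.

safe_sample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# Grow a connected-ish gene module: with probability `cohesion` the next
# gene is a network neighbour of the current module, otherwise uniform.
grow_module <- function(adj, all_genes, anchor, size, cohesion) {
  mod <- anchor
  while (length(mod) < size) {
    nb <- setdiff(unique(unlist(adj[mod], use.names = FALSE)), mod)
    pick_local <- length(nb) > 0L && stats::runif(1) < cohesion
    pool <- if (pick_local) nb else setdiff(all_genes, mod)
    mod <- c(mod, safe_sample(pool, 1L))
  }
  mod
}

#' Simulate a full miRNA-disease association world
#'
#' Generates (i) a connected scale-free gene network by preferential
#' attachment, (ii) disease gene modules grown as seeded network
#' neighbourhoods, (iii) miRNA target sets in which a tunable fraction of
#' targets lies in the immediate neighbourhood of a paired disease module
#' (adjacent to, but never inside, the module — the signal is proximity,
#' not overlap), and (iv) disease classes whose positive miRNAs draw part of
#' their signal from a class-wide neighbourhood pool, planting within-class
#' regulator sharing. Half of the miRNAs are signal-free negatives with
#' uniformly sampled targets; each miRNA is paired with one disease to form
#' the labeled evaluation pairs.
#'
#' @param n_genes Number of genes in the network before component
#'   extraction.
#' @param attachment Edges added per gene during preferential attachment
#'   (mean degree is about twice this).
#' @param n_diseases Number of diseases.
#' @param disease_module_size Genes per disease module.
#' @param module_cohesion Probability that each added module gene is a
#'   network neighbour of the module grown so far.
#' @param n_mirnas Total miRNAs; must be even (half positive, half
#'   negative).
#' @param targets_per_mirna Target-set size.
#' @param signal_fraction Fraction of a positive miRNA's targets drawn from
#'   the neighbourhood of its disease module (0 = pure null world).
#' @param n_classes Number of disease classes.
#' @param class_overlap Probability that a signal target is drawn from the
#'   class-wide pool rather than the paired disease's own neighbourhood.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list with elements `network` (`ppi_network`), `diseases` and
#'   `mirnas` (`geneset_collection`s, diseases carrying class labels),
#'   `labels` (tibble `mirna_id`, `disease_id`, `label`), and `classes`
#'   (tibble `set_id`, `class`).
#' @export
simulate_mirna_disease <- function(n_genes = 800L,
                                   attachment = 4L,
                                   n_diseases = 20L,
                                   disease_module_size = 10L,
                                   module_cohesion = 0.8,
                                   n_mirnas = 40L,
                                   targets_per_mirna = 25L,
                                   signal_fraction = 0.5,
                                   n_classes = 4L,
                                   class_overlap = 0.5,
                                   seed) {
  stopifnot(
    n_genes > 2L, attachment >= 1L, n_diseases >= 1L,
    disease_module_size >= 1L, n_mirnas >= 2L, n_mirnas %% 2L == 0L,
    targets_per_mirna >= 1L, n_classes >= 1L,
    module_cohesion >= 0, module_cohesion <= 1,
    signal_fraction >= 0, signal_fraction <= 1,
    class_overlap >= 0, class_overlap <= 1
  )
  if (disease_module_size > n_genes || targets_per_mirna > n_genes) {
    stop("module or target-set size exceeds the number of genes", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    g <- igraph::sample_pa(n_genes, m = attachment, directed = FALSE)
    igraph::V(g)$name <- sprintf("g%04d", seq_len(n_genes))
    net <- largest_component(as_ppi_network(
      tibble::as_tibble(
        as.data.frame(igraph::as_edgelist(g), stringsAsFactors = FALSE)
      ),
      quiet = TRUE
    ))
    gl <- as_igraph(net)
    adj <- lapply(igraph::as_adj_list(gl), names)
    all_genes <- network_nodes(net)

    disease_ids <- sprintf("disease%02d", seq_len(n_diseases))
    class_of <- sprintf("Class%d", rep_len(seq_len(n_classes), n_diseases))
    anchors <- safe_sample(all_genes, n_diseases)
    modules <- lapply(seq_len(n_diseases), function(i) {
      grow_module(adj, all_genes, anchors[i], disease_module_size, module_cohesion)
    })
    names(modules) <- disease_ids

    # proximity pool per disease: neighbours of the module, module excluded
    pools <- lapply(modules, function(mod) {
      setdiff(unique(unlist(adj[mod], use.names = FALSE)), mod)
    })
    class_pools <- lapply(seq_len(n_classes), function(c) {
      members <- which(class_of == sprintf("Class%d", c))
      unique(unlist(pools[members], use.names = FALSE))
    })

    n_pos <- n_mirnas %/% 2L
    paired_disease <- rep_len(seq_len(n_diseases), n_pos)
    pos_targets <- lapply(seq_len(n_pos), function(i) {
      d <- paired_disease[i]
      pool_own <- pools[[d]]
      pool_class <- class_pools[[match(class_of[d], sprintf("Class%d", seq_len(n_classes)))]]
      n_signal <- round(signal_fraction * targets_per_mirna)
      signal <- character(0L)
      while (length(signal) < n_signal) {
        use_class <- stats::runif(1) < class_overlap
        pool <- setdiff(if (use_class) pool_class else pool_own, signal)
        if (length(pool) == 0L) pool <- setdiff(all_genes, signal)
        signal <- c(signal, safe_sample(pool, 1L))
      }
      filler <- safe_sample(
        setdiff(all_genes, signal),
        targets_per_mirna - length(signal)
      )
      c(signal, filler)
    })
    neg_targets <- lapply(seq_len(n_mirnas - n_pos), function(i) {
      safe_sample(all_genes, targets_per_mirna)
    })
    mirna_ids <- c(
      sprintf("mirP%03d", seq_len(n_pos)),
      sprintf("mirN%03d", seq_len(n_mirnas - n_pos))
    )
    targets <- c(pos_targets, neg_targets)
    names(targets) <- mirna_ids

    classes <- tibble::tibble(set_id = disease_ids, class = class_of)
    diseases <- geneset_collection(
      tibble::tibble(
        set_id = rep(disease_ids, lengths(modules)),
        gene = unlist(modules, use.names = FALSE)
      ),
      kind = "disease", classes = classes
    )
    mirnas <- geneset_collection(
      tibble::tibble(
        set_id = rep(mirna_ids, lengths(targets)),
        gene = unlist(targets, use.names = FALSE)
      ),
      kind = "mirna"
    )
    labels <- tibble::tibble(
      mirna_id = mirna_ids,
      disease_id = disease_ids[rep_len(paired_disease, n_mirnas)],
      label = rep(c(1L, 0L), c(n_pos, n_mirnas - n_pos))
    )
    list(
      network = net, diseases = diseases, mirnas = mirnas,
      labels = labels, classes = classes
    )
  })
}

#' Simulate a bipartite network with planted class structure
#'
#' Builds a miRNA-disease network directly (no scoring): each disease class
#' owns a private pool of miRNAs, each of the class's diseases links to each
#' pool miRNA with probability `within_class_rate`, and every
#' (disease, miRNA) pair additionally links with a small `background_rate`.
#' Useful for exercising the modularity and clustering analyses in
#' isolation.
#'
#' @param n_diseases,n_mirnas Node counts; both split evenly over classes.
#' @param n_classes Number of planted classes.
#' @param within_class_rate Link probability between a disease and its own
#'   class's miRNAs.
#' @param background_rate Link probability for any pair.
#' @param seed Integer seed.
#' @return A list with `network` (`mdn_bipartite`), `disease_classes`,
#'   and `mirna_classes` (tibbles mapping node to planted class).
#' @export
simulate_class_bipartite <- function(n_diseases = 30L, n_mirnas = 60L,
                                     n_classes = 3L,
                                     within_class_rate = 0.6,
                                     background_rate = 0.03,
                                     seed) {
  stopifnot(n_classes >= 1L, n_diseases >= n_classes, n_mirnas >= n_classes)
  withr::with_seed(as.integer(seed), {
    disease_ids <- sprintf("disease%02d", seq_len(n_diseases))
    mirna_ids <- sprintf("mir%03d", seq_len(n_mirnas))
    d_class <- rep_len(seq_len(n_classes), n_diseases)
    m_class <- rep_len(seq_len(n_classes), n_mirnas)
    prob <- matrix(background_rate, n_diseases, n_mirnas)
    prob[outer(d_class, m_class, `==`)] <- within_class_rate
    hit <- matrix(stats::runif(length(prob)) < prob, n_diseases, n_mirnas)
    idx <- which(hit, arr.ind = TRUE)
    edges <- tibble::tibble(
      mirna_id = mirna_ids[idx[, 2L]],
      disease_id = disease_ids[idx[, 1L]],
      p_value = 0.01,
      class = sprintf("Class%d", d_class[idx[, 1L]])
    )
    net <- structure(
      edges,
      threshold = 0.05,
      class = c("mdn_bipartite", class(tibble::tibble()))
    )
    list(
      network = net,
      disease_classes = tibble::tibble(
        set_id = disease_ids, class = sprintf("Class%d", d_class)
      ),
      mirna_classes = tibble::tibble(
        set_id = mirna_ids, class = sprintf("Class%d", m_class)
      )
    )
  })
}

#' Simulate a noisy block-structured incidence matrix
#'
#' Plants `k` disjoint (disease, miRNA) blocks: within-block cells are 1 and
#' all others 0, then every cell is flipped independently with probability
#' `noise`. Used to verify that two-way hierarchical clustering recovers
#' planted co-regulated modules.
#'
#' @param n_diseases,n_mirnas Matrix dimensions.
#' @param k Number of planted blocks.
#' @param noise Per-cell flip probability.
#' @param seed Integer seed.
#' @return A list with `network` (`mdn_bipartite` of the 1-cells),
#'   `disease_blocks` and `mirna_blocks` (named integer vectors of planted
#'   block labels).
#' @export
simulate_block_incidence <- function(n_diseases = 30L, n_mirnas = 30L,
                                     k = 3L, noise = 0.05, seed) {
  stopifnot(k >= 1L, n_diseases >= k, n_mirnas >= k, noise >= 0, noise < 0.5)
  withr::with_seed(as.integer(seed), {
    disease_ids <- sprintf("disease%02d", seq_len(n_diseases))
    mirna_ids <- sprintf("mir%03d", seq_len(n_mirnas))
    d_block <- sort(rep_len(seq_len(k), n_diseases))
    m_block <- sort(rep_len(seq_len(k), n_mirnas))
    mat <- outer(d_block, m_block, `==`) * 1L
    flip <- matrix(stats::runif(length(mat)) < noise, nrow(mat))
    mat[flip] <- 1L - mat[flip]
    idx <- which(mat == 1L, arr.ind = TRUE)
    edges <- tibble::tibble(
      mirna_id = mirna_ids[idx[, 2L]],
      disease_id = disease_ids[idx[, 1L]],
      p_value = 0.01,
      class = sprintf("Class%d", d_block[idx[, 1L]])
    )
    net <- structure(
      edges,
      threshold = 0.05,
      class = c("mdn_bipartite", class(tibble::tibble()))
    )
    list(
      network = net,
      disease_blocks = stats::setNames(d_block, disease_ids),
      mirna_blocks = stats::setNames(m_block, mirna_ids)
    )
  })
}
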