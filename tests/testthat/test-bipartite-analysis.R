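toy_bipartite <- function(edges, classes = NULL) {
  edges$p_value <- 0.01
  if (is.null(classes)) {
    edges$class <- "Unknown"
  } else {
    edges$class <- classes[edges$disease_id]
  }
  structure(
    tibble::as_tibble(edges),
    threshold = 0.05,
    class = c("mdn_bipartite", class(tibble::tibble()))
  )
}

test_that("degree tables obey the bipartite handshake", {
  net <- toy_bipartite(data.frame(
    mirna_id = c("m1", "m1", "m1", "m2"),
    disease_id = c("d1", "d2", "d3", "d1")
  ))
  deg <- bipartite_degrees(net)
  expect_equal(deg$degree[deg$node == "m1"], 3L)
  expect_equal(deg$degree[deg$node == "d1"], 2L)
  expect_equal(
    sum(deg$degree[deg$side == "mirna"]),
    sum(deg$degree[deg$side == "disease"])
  )
  expect_equal(sum(deg$degree[deg$side == "mirna"]), nrow(net))
})

test_that("per-class average degree averages disease degrees", {
  net <- toy_bipartite(
    data.frame(
      mirna_id = c("m1", "m2", "m1", "m2", "m3", "m4", "m1"),
      disease_id = c("d1", "d1", "d2", "d2", "d2", "d2", "d3")
    ),
    classes = c(d1 = "A", d2 = "A", d3 = "B")
  )
  tab <- class_average_degree(net)
  expect_equal(tab$avg_degree[tab$class == "A"], 3) # degrees 2 and 4
  expect_equal(tab$avg_degree[tab$class == "B"], 1)
  # weighted overall mean equals |edges| / #diseases
  expect_equal(
    sum(tab$avg_degree * tab$n_diseases) / sum(tab$n_diseases),
    nrow(net) / dplyr::n_distinct(net$disease_id)
  )
})

test_that("a class with a private shared regulator has BD > 1 and BH = 0", {
  # class A diseases share miRNA mShared and nothing with class B diseases
  net <- toy_bipartite(
    data.frame(
      mirna_id = c("mShared", "mShared", "m1", "m2", "m3", "m3"),
      disease_id = c("d1", "d2", "d1", "d2", "d3", "d4")
    ),
    classes = c(d1 = "A", d2 = "A", d3 = "B", d4 = "B")
  )
  mod <- bd_bh(net, "A")
  expect_gt(mod$bd, 1)
  expect_equal(mod$bh, 0)
})

test_that("BD/BH is invariant to miRNA relabeling and guards its domain", {
  s <- simulate_class_bipartite(
    n_diseases = 12, n_mirnas = 24, n_classes = 2,
    within_class_rate = 0.7, seed = 31
  )
  base <- bd_bh(s$network)
  relabeled <- s$network
  relabeled$mirna_id <- paste0("x_", relabeled$mirna_id)
  expect_equal(bd_bh(relabeled), base)

  singleton <- s$network
  singleton$class[singleton$disease_id == "disease01"] <- "Lonely"
  expect_error(bd_bh(singleton, "Lonely"), "fewer than two")
  whole <- s$network
  whole$class <- "All"
  expect_error(bd_bh(whole, "All"), "BH undefined")
})

test_that("random class labels give BD near 1 on average", {
  s <- simulate_class_bipartite(
    n_diseases = 24, n_mirnas = 40, n_classes = 3,
    within_class_rate = 0.5, seed = 32
  )
  withr::with_seed(33, {
    mean_bd <- mean(replicate(100, {
      net <- s$network
      perm <- sample(s$disease_classes$class)
      net$class <- perm[match(net$disease_id, s$disease_classes$set_id)]
      mean(bd_bh(net)$bd)
    }))
  })
  expect_gt(mean_bd, 0.9)
  expect_lt(mean_bd, 1.1)
})

test_that("two perfect blocks are recovered exactly at the 2-cluster cut", {
  edges <- expand.grid(
    mirna_id = paste0("mA", 1:3), disease_id = paste0("dA", 1:3),
    stringsAsFactors = FALSE
  )
  edges <- rbind(edges, expand.grid(
    mirna_id = paste0("mB", 1:4), disease_id = paste0("dB", 1:2),
    stringsAsFactors = FALSE
  ))
  net <- toy_bipartite(edges)
  mods <- cluster_bipartite(net, k_diseases = 2, k_mirnas = 2)
  expect_equal(nrow(mods), 2L)
  expect_equal(mods$density, c(1, 1))
  disease_sides <- lapply(mods$diseases, sort)
  mirna_sides <- lapply(mods$mirnas, sort)
  expect_true(any(vapply(
    disease_sides, identical, logical(1), y = paste0("dA", 1:3)
  )))
  expect_true(any(vapply(
    mirna_sides, identical, logical(1), y = paste0("mB", 1:4)
  )))
})

test_that("identical incidence rows sit in the same cluster at any cut", {
  edges <- data.frame(
    mirna_id = c("m1", "m2", "m1", "m2", "m3"),
    disease_id = c("d1", "d1", "d2", "d2", "d3")
  )
  net <- toy_bipartite(edges) # d1 and d2 have identical rows (L1 distance 0)
  mods <- cluster_bipartite(net, k_diseases = 2, k_mirnas = 2, min_density = 0)
  cut <- attr(mods, "cut_diseases")
  expect_equal(cut[["d1"]], cut[["d2"]])
  expect_false(cut[["d3"]] == cut[["d1"]])
})

test_that("noisy planted blocks are recovered with high adjusted Rand", {
  b <- simulate_block_incidence(
    n_diseases = 30, n_mirnas = 30, k = 3, noise = 0.05, seed = 34
  )
  mods <- cluster_bipartite(b$network, k_diseases = 3, k_mirnas = 3)
  cut_d <- attr(mods, "cut_diseases")
  cut_m <- attr(mods, "cut_mirnas")
  expect_gte(adjusted_rand_index(cut_d, b$disease_blocks[names(cut_d)]), 0.8)
  expect_gte(adjusted_rand_index(cut_m, b$mirna_blocks[names(cut_m)]), 0.8)
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  withr::with_seed(35, {
    near_zero <- mean(replicate(200, {
      adjusted_rand_index(sample(rep(1:3, 10)), sample(rep(1:3, 10)))
    }))
  })
  expect_lt(abs(near_zero), 0.05)
})

test_that("dendrograms export as Newick for both axes", {
  b <- simulate_block_incidence(n_diseases = 8, n_mirnas = 8, k = 2, noise = 0, seed = 36)
  mods <- cluster_bipartite(b$network, k_diseases = 2, k_mirnas = 2)
  nwk <- dendrogram_newick(mods)
  expect_match(nwk$diseases, "^\\(.*\\);$")
  expect_no_match(nwk$mirnas, "disease", fixed = TRUE)
  tree <- ape::read.tree(text = nwk$diseases)
  expect_setequal(tree$tip.label, unique(b$network$disease_id))
})

test_that("degree correlations match a closed-form Pearson computation", {
  net <- toy_bipartite(data.frame(
    mirna_id = rep(paste0("m", 1:5), times = c(1, 2, 3, 4, 5)),
    disease_id = paste0("d", c(1, 1:2, 1:3, 1:4, 1:5))
  ))
  stats_tbl <- tibble::tibble(
    mirna_id = paste0("m", 1:5),
    n_targets = c(50, 40, 30, 20, 10),
    n_disease_genes_targeted = c(5, 8, 9, 8, 5)
  )
  res <- degree_correlations(net, stats_tbl)
  deg <- c(1, 2, 3, 4, 5)
  pearson <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  expect_equal(
    res$estimate[res$metric == "targets"],
    pearson(deg, stats_tbl$n_targets)
  )
  expect_equal(
    res$estimate[res$metric == "ratio"],
    pearson(deg, stats_tbl$n_disease_genes_targeted / stats_tbl$n_targets)
  )
  expect_equal(res$estimate[res$metric == "targets"], -1)

  constant <- dplyr::mutate(stats_tbl, n_targets = 10)
  expect_error(degree_correlations(net, constant), "constant")
  expect_error(
    degree_correlations(net, stats_tbl[1:2, ]),
    "at least 3"
  )
})
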