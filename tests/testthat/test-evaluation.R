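labeled_records <- function(p_pos, p_neg) {
  n_pos <- length(p_pos)
  n_neg <- length(p_neg)
  records <- tibble::tibble(
    mirna_id = paste0("m", seq_len(n_pos + n_neg)),
    disease_id = "d1",
    p_value = c(p_pos, p_neg)
  )
  labels <- tibble::tibble(
    mirna_id = records$mirna_id,
    disease_id = "d1",
    label = rep(c(1L, 0L), c(n_pos, n_neg))
  )
  list(records = records, labels = labels)
}

test_that("perfect separation gives AUC 1 and a full confusion sweep", {
  x <- labeled_records(p_pos = rep(0, 4), p_neg = rep(1, 4))
  roc <- roc_auc(x$records, x$labels)
  expect_equal(roc$auc, 1)
  curve <- tidy(roc)
  expect_equal(curve$sensitivity, curve$tp / (curve$tp + curve$fn))
  expect_equal(curve$specificity, curve$tn / (curve$tn + curve$fp))
  expect_equal(glance(roc)$auc, 1)
})

test_that("AUC equals the Mann-Whitney concordance oracle", {
  withr::with_seed(41, {
    for (i in 1:50) {
      # discrete scores force ties across and within groups
      p_pos <- sample(seq(0, 1, by = 0.1), 6, replace = TRUE)
      p_neg <- sample(seq(0, 1, by = 0.1), 8, replace = TRUE)
      x <- labeled_records(p_pos, p_neg)
      expect_equal(
        roc_auc(x$records, x$labels)$auc,
        auc_concordance_oracle(p_pos, p_neg)
      )
    }
  })
})

test_that("randomly labeled scores hover around AUC 0.5", {
  withr::with_seed(42, {
    aucs <- replicate(100, {
      scores <- runif(30)
      x <- labeled_records(scores[1:15], scores[16:30])
      x$labels$label <- sample(x$labels$label)
      roc_auc(x$records, x$labels)$auc
    })
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("the ROC sweep is monotone in the threshold", {
  withr::with_seed(43, {
    x <- labeled_records(runif(10, 0, 0.6), runif(10, 0.2, 1))
  })
  curve <- tidy(roc_auc(x$records, x$labels))
  expect_true(all(diff(curve$sensitivity) >= 0))
  expect_true(all(diff(curve$specificity) <= 0))
})

test_that("labels without scores are reported as an error", {
  x <- labeled_records(c(0.1, 0.2), c(0.8, 0.9))
  orphan <- dplyr::bind_rows(
    x$labels,
    tibble::tibble(mirna_id = "ghost", disease_id = "d1", label = 1L)
  )
  expect_error(roc_auc(x$records, orphan), "ghost")
  expect_error(
    roc_auc(x$records, dplyr::mutate(x$labels, label = 2L)),
    "0 or 1"
  )
})

test_that("hypergeometric baseline reproduces exact combinatorial values", {
  # universe of 10 genes: disease genes g01..g05, targets exactly the same 5
  net <- path_network(sprintf("g%02d", 1:10))
  dg <- sprintf("g%02d", 1:5)
  expect_equal(hypergeometric_baseline(dg, dg, net), 1 / choose(10, 5))

  # zero observed overlap is never significant
  tg_disjoint <- sprintf("g%02d", 6:10)
  expect_equal(hypergeometric_baseline(dg, tg_disjoint, net), 1)

  expect_error(
    hypergeometric_baseline("absent", dg, net),
    "empty gene set"
  )
})

test_that("hypergeometric baseline equals brute-force enumeration (N <= 12)", {
  for (n_universe in c(8, 12)) {
    net <- path_network(sprintf("g%02d", seq_len(n_universe)))
    for (n_disease in c(3, 5)) {
      for (n_targets in c(2, 4)) {
        dg <- sprintf("g%02d", seq_len(n_disease))
        for (overlap in 0:min(n_disease, n_targets)) {
          if (n_disease + n_targets - overlap > n_universe) next
          tg <- c(
            sprintf("g%02d", seq_len(overlap)),
            sprintf("g%02d", n_disease + seq_len(n_targets - overlap))
          )
          expect_equal(
            hypergeometric_baseline(dg, tg, net),
            hyper_enum_oracle(n_universe, n_disease, n_targets, overlap)
          )
        }
      }
    }
  }
})

test_that("hypergeometric p falls as the observed overlap grows", {
  net <- path_network(sprintf("g%02d", 1:12))
  dg <- sprintf("g%02d", 1:5)
  p <- vapply(0:4, function(k) {
    tg <- c(sprintf("g%02d", seq_len(k)), sprintf("g%02d", 5 + seq_len(4 - k)))
    hypergeometric_baseline(dg, tg, net)
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})
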