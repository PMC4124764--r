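# Evaluation: ROC/AUC against labeled miRNA-disease pairs, and the
# hypergeometric target/disease-gene overlap baseline.

#' ROC curve and AUC of association p-values against known pairs
#'
#' Lower p-values are stronger predictions: a pair is called positive when
#' `p <= delta`, and the threshold `delta` is swept over every distinct
#' p-value (plus a call-nothing sentinel). Sensitivity is TP / (TP + FN)
#' and specificity TN / (TN + FP); the AUC is the trapezoidal area under
#' sensitivity versus 1 - specificity, which equals the Mann-Whitney
#' concordance probability (ties between a positive and a negative count
#' one half).
#'
#' @param records An `mdn_assoc` tibble (needs `mirna_id`, `disease_id`,
#'   `p_value`).
#' @param labels A data frame with columns `mirna_id`, `disease_id`, and
#'   `label` (1 = known association, 0 = negative control). Every labeled
#'   pair must have a scored record.
#' @return An `mdn_roc` object: list with `curve` (tibble of `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`), `auc`, `n_pos`,
#'   `n_neg`. Use [tidy()] / [glance()] / [ggplot2::autoplot()] on it.
#' @export
roc_auc <- function(records, labels) {
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("mirna_id", "disease_id", "label") %in% names(labels)))
  if (!all(labels$label %in% c(0, 1))) {
    stop("`label` must be 0 or 1", call. = FALSE)
  }
  scored <- dplyr::left_join(
    labels,
    tibble::as_tibble(records)[c("mirna_id", "disease_id", "p_value")],
    by = c("mirna_id", "disease_id")
  )
  if (anyNA(scored$p_value)) {
    miss <- scored[is.na(scored$p_value), ]
    stop(
      "no score for labeled pair(s): ",
      paste(utils::head(paste(miss$mirna_id, miss$disease_id, sep = "/"), 5L),
        collapse = ", "
      ),
      call. = FALSE
    )
  }
  n_pos <- sum(scored$label == 1)
  n_neg <- sum(scored$label == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative pair", call. = FALSE)
  }
  thresholds <- c(-Inf, sort(unique(scored$p_value)))
  curve <- purrr::map_dfr(thresholds, function(delta) {
    called <- scored$p_value <= delta
    tp <- sum(called & scored$label == 1)
    fp <- sum(called & scored$label == 0)
    tibble::tibble(
      threshold = delta, tp = tp, fp = fp,
      tn = n_neg - fp, fn = n_pos - tp,
      sensitivity = tp / n_pos,
      specificity = (n_neg - fp) / n_neg
    )
  })
  fpr <- 1 - curve$specificity
  auc <- sum(diff(fpr) * (utils::head(curve$sensitivity, -1L) +
    utils::tail(curve$sensitivity, -1L)) / 2)
  structure(
    list(curve = curve, auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "mdn_roc"
  )
}

#' @exportS3Method base::print
print.mdn_roc <- function(x, ...) {
  cat(
    "# ROC over", x$n_pos, "positive and", x$n_neg, "negative pairs; AUC =",
    format(round(x$auc, 4)), "\n"
  )
  invisible(x)
}

#' @rdname roc_auc
#' @param x An `mdn_roc` object.
#' @param ... Unused.
#' @method tidy mdn_roc
#' @export
tidy.mdn_roc <- function(x, ...) {
  x$curve
}

#' @rdname roc_auc
#' @method glance mdn_roc
#' @export
glance.mdn_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Hypergeometric overlap baseline for one pair
#'
#' The comparison method: scores a miRNA-disease pair only by the overlap
#' between the miRNA's targets and the disease genes, ignoring network
#' proximity. Returns the upper-tail probability of observing at least the
#' actual overlap when drawing the target set uniformly from the network's
#' genes.
#'
#' @param disease_genes,targets Character vectors (or single-set
#'   collections); both are intersected with the network first.
#' @param net A `ppi_network` providing the gene universe.
#' @return Upper-tail hypergeometric p-value for the observed overlap.
#' @export
hypergeometric_baseline <- function(disease_genes, targets, net) {
  if (inherits(disease_genes, "geneset_collection")) {
    disease_genes <- unique(disease_genes$gene)
  }
  if (inherits(targets, "geneset_collection")) {
    targets <- unique(targets$gene)
  }
  nodes <- network_nodes(net)
  dg <- intersect(unique(as.character(disease_genes)), nodes)
  tg <- intersect(unique(as.character(targets)), nodes)
  if (length(dg) == 0L || length(tg) == 0L) {
    stop("empty gene set after restricting to the network", call. = FALSE)
  }
  overlap <- length(intersect(dg, tg))
  stats::phyper(
    overlap - 1L,
    m = length(dg), n = length(nodes) - length(dg), k = length(tg),
    lower.tail = FALSE
  )
}
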