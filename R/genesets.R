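# Gene-set collections: disease genes and miRNA targets, GMT-like I/O,
# evidence voting, and annotation onto a network.

#' Build a gene-set collection
#'
#' A collection is a long tibble with one row per (set, gene) membership and
#' a `kind` marking whether the sets are diseases or miRNAs. Disease
#' collections may carry a class label per set (e.g. the 18 broad disease
#' classes used for modularity analysis).
#'
#' @param x A data frame with columns `set_id` and `gene` (extra columns are
#'   dropped); memberships are deduplicated.
#' @param kind `"disease"` or `"mirna"`.
#' @param classes Optional data frame with columns `set_id` and `class`.
#' @return A `geneset_collection` tibble.
#' @export
geneset_collection <- function(x, kind = c("disease", "mirna"), classes = NULL) {
  kind <- match.arg(kind)
  x <- tibble::as_tibble(x)
  stopifnot(all(c("set_id", "gene") %in% names(x)))
  sets <- x |>
    dplyr::transmute(
      set_id = as.character(.data$set_id),
      gene = as.character(.data$gene)
    ) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$set_id, .data$gene)
  if (!is.null(classes)) {
    classes <- tibble::as_tibble(classes) |>
      dplyr::transmute(
        set_id = as.character(.data$set_id),
        class = as.character(.data$class)
      ) |>
      dplyr::distinct(.data$set_id, .keep_all = TRUE)
  }
  structure(
    sets,
    kind = kind,
    classes = classes,
    class = c("geneset_collection", class(tibble::tibble()))
  )
}

#' @exportS3Method base::print
print.geneset_collection <- function(x, ...) {
  cat(
    "# ", attr(x, "kind"), " gene sets: ",
    dplyr::n_distinct(x$set_id), " sets, ",
    dplyr::n_distinct(x$gene), " distinct genes\n",
    sep = ""
  )
  NextMethod()
}

set_kind <- function(coll) attr(coll, "kind")

#' Class labels of a disease collection
#'
#' @param coll A `geneset_collection`.
#' @return A tibble (`set_id`, `class`) or `NULL` when no labels were given.
#' @export
set_classes <- function(coll) attr(coll, "classes")

#' Set sizes within a collection
#'
#' @param coll A `geneset_collection`.
#' @return A tibble with columns `set_id` and `size`.
#' @export
geneset_sizes <- function(coll) {
  dplyr::count(tibble::as_tibble(coll), .data$set_id, name = "size")
}

# Named list of member vectors; the hot path for scoring.
geneset_list <- function(coll) {
  split(coll$gene, coll$set_id)
}

#' Read gene sets from a GMT-like file
#'
#' Tab-separated, one set per line: `set_id`, a description column, then the
#' member genes. For disease collections the description column is read as
#' the disease class unless it is empty, `"."`, or `"-"`.
#'
#' @param source Path to the file.
#' @param kind `"disease"` or `"mirna"`.
#' @return A `geneset_collection`. Duplicate set identifiers are an error;
#'   lines with no genes are skipped with a warning.
#' @export
read_gmt <- function(source, kind = c("disease", "mirna")) {
  kind <- match.arg(kind)
  lines <- readLines(source)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) {
    stop("no gene sets found in ", source, call. = FALSE)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop(
      "duplicate set id(s): ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "),
      call. = FALSE
    )
  }
  empty <- lengths(fields) < 3L
  if (any(empty)) {
    warning(
      sum(empty), " set(s) with no genes skipped: ",
      paste(ids[empty], collapse = ", "),
      call. = FALSE
    )
    fields <- fields[!empty]
    ids <- ids[!empty]
  }
  members <- tibble::tibble(
    set_id = rep(ids, lengths(fields) - 2L),
    gene = unlist(lapply(fields, function(f) f[-(1:2)]), use.names = FALSE)
  )
  classes <- NULL
  if (kind == "disease") {
    desc <- vapply(fields, `[[`, character(1L), 2L)
    has_class <- !(desc %in% c("", ".", "-"))
    if (any(has_class)) {
      classes <- tibble::tibble(set_id = ids[has_class], class = desc[has_class])
    }
  }
  geneset_collection(members, kind = kind, classes = classes)
}

#' Write a collection in GMT format
#'
#' @param coll A `geneset_collection`.
#' @param path Output file.
#' @param header Optional comment lines written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path, header = NULL) {
  classes <- set_classes(coll)
  members <- geneset_list(coll)
  desc <- rep(".", length(members))
  if (!is.null(classes)) {
    m <- match(names(members), classes$set_id)
    desc[!is.na(m)] <- classes$class[m[!is.na(m)]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  writeLines(
    vapply(
      seq_along(members),
      function(i) {
        paste(c(names(members)[i], desc[i], members[[i]]), collapse = "\t")
      },
      character(1L)
    ),
    con
  )
  invisible(path)
}

#' Keep miRNA-target pairs supported by several databases
#'
#' Target predictions are noisy, so a pair is retained only when it is
#' reported by at least `min_databases` distinct databases (three in the
#' original curation of seven prediction databases). Repeated listings by
#' the same database count once.
#'
#' @param evidence A data frame with columns `mirna`, `gene`, `database`.
#' @param min_databases Minimum number of distinct supporting databases.
#' @return A `geneset_collection` of kind `"mirna"` holding the surviving
#'   target sets.
#' @export
vote_filter_targets <- function(evidence, min_databases = 3L) {
  stopifnot(min_databases >= 1L)
  evidence <- tibble::as_tibble(evidence)
  stopifnot(all(c("mirna", "gene", "database") %in% names(evidence)))
  kept <- evidence |>
    dplyr::distinct(.data$mirna, .data$gene, .data$database) |>
    dplyr::count(.data$mirna, .data$gene, name = "n_db") |>
    dplyr::filter(.data$n_db >= min_databases) |>
    dplyr::transmute(set_id = .data$mirna, gene = .data$gene)
  geneset_collection(kept, kind = "mirna")
}

#' Restrict gene sets to a network and drop small sets
#'
#' Members absent from the network cannot take part in propagation or
#' scoring, so they are removed; sets left with `min_genes` or fewer members
#' are dropped entirely (the curation kept miRNAs with more than five
#' in-network targets). The operation is idempotent.
#'
#' @param coll A `geneset_collection`.
#' @param net A `ppi_network`.
#' @param min_genes Strict lower bound on surviving set size. Defaults to 5
#'   for miRNA collections and 0 for disease collections, whose filter rule
#'   was not stated.
#' @return The filtered `geneset_collection`; class labels are kept for the
#'   surviving sets.
#' @export
annotate_to_network <- function(coll, net,
                                min_genes = if (set_kind(coll) == "mirna") 5L else 0L) {
  nodes <- network_nodes(net)
  kept <- tibble::as_tibble(coll) |>
    dplyr::filter(.data$gene %in% nodes) |>
    dplyr::group_by(.data$set_id) |>
    dplyr::filter(dplyr::n() > min_genes) |>
    dplyr::ungroup()
  classes <- set_classes(coll)
  if (!is.null(classes)) {
    classes <- dplyr::filter(classes, .data$set_id %in% kept$set_id)
    if (nrow(classes) == 0L) classes <- NULL
  }
  geneset_collection(kept, kind = set_kind(coll), classes = classes)
}
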