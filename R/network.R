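# Interaction networks: loading, validation, largest component, and
# degree-preserving randomization.

new_ppi_network <- function(edges) {
  structure(edges, class = c("ppi_network", class(tibble::tibble())))
}

#' Coerce an edge table to a validated interaction network
#'
#' An interaction network is an undirected simple graph over opaque gene
#' identifiers, stored as a canonical two-column tibble (`from`, `to`) with
#' `from < to` lexicographically, no self-loops, and no duplicate edges.
#'
#' @param x A data frame whose first two columns are gene identifiers, one
#'   interaction per row.
#' @param quiet If `FALSE` (default), report how many self-loop rows were
#'   dropped.
#' @return A `ppi_network` tibble with columns `from` and `to`.
#' @examples
#' as_ppi_network(data.frame(a = c("g1", "g2"), b = c("g2", "g3")))
#' @export
as_ppi_network <- function(x, quiet = FALSE) {
  if (inherits(x, "ppi_network")) {
    return(x)
  }
  x <- as.data.frame(x)
  if (nrow(x) == 0L || ncol(x) < 2L) {
    stop("edge table must have at least one row and two columns", call. = FALSE)
  }
  from <- as.character(x[[1L]])
  to <- as.character(x[[2L]])
  if (anyNA(from) || anyNA(to) || any(from == "") || any(to == "")) {
    stop("edge table contains missing or empty gene identifiers", call. = FALSE)
  }
  loops <- from == to
  if (any(loops) && !quiet) {
    message("dropped ", sum(loops), " self-loop(s)")
  }
  from2 <- pmin(from[!loops], to[!loops])
  to2 <- pmax(from[!loops], to[!loops])
  edges <- tibble::tibble(from = from2, to = to2) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$from, .data$to)
  if (nrow(edges) == 0L) {
    stop("no edges remain after removing self-loops", call. = FALSE)
  }
  new_ppi_network(edges)
}

#' Read an interaction network from an edge-list file
#'
#' Accepts whitespace- or tab-delimited text with two or more identifier
#' columns per line (extra columns are ignored); lines starting with `#` and
#' blank lines are skipped. Duplicate edges and self-loops are removed, the
#' latter with a reported count.
#'
#' @param source Path to an edge-list file, or a data frame already holding
#'   the edges (passed to [as_ppi_network()]).
#' @param delimiter Field separator regex; defaults to any whitespace run.
#' @param quiet Passed on to [as_ppi_network()].
#' @return A `ppi_network` tibble.
#' @export
load_network <- function(source, delimiter = "[ \t]+", quiet = FALSE) {
  if (is.data.frame(source)) {
    return(as_ppi_network(source, quiet = quiet))
  }
  lines <- readLines(source)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) {
    stop("no edges found in ", source, call. = FALSE)
  }
  fields <- strsplit(trimws(lines[keep]), delimiter)
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop(
      "line ", which(keep)[bad[1L]], " of ", source,
      " has fewer than two columns",
      call. = FALSE
    )
  }
  edges <- tibble::tibble(
    from = vapply(fields, `[[`, character(1L), 1L),
    to = vapply(fields, `[[`, character(1L), 2L)
  )
  as_ppi_network(edges, quiet = quiet)
}

#' @exportS3Method base::print
print.ppi_network <- function(x, ...) {
  nodes <- network_nodes(x)
  cat(
    "# Interaction network: ", length(nodes), " genes, ",
    nrow(x), " edges\n",
    sep = ""
  )
  NextMethod()
}

#' Genes present in a network
#'
#' @param net A `ppi_network`.
#' @return Sorted character vector of gene identifiers.
#' @export
network_nodes <- function(net) {
  sort(unique(c(net$from, net$to)))
}

#' Per-gene degree table
#'
#' @param net A `ppi_network`.
#' @return A tibble with columns `gene` and `degree`, sorted by gene.
#' @export
network_degree <- function(net) {
  tibble::tibble(gene = c(net$from, net$to)) |>
    dplyr::count(.data$gene, name = "degree") |>
    dplyr::arrange(.data$gene)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net, directed = FALSE)
}

#' Extract the largest connected component
#'
#' Analyses run on the largest component of the interaction network so that
#' every gene is reachable from every seed. Ties in component size are broken
#' towards the component containing the lexicographically smallest gene.
#'
#' @param net A `ppi_network`.
#' @return A `ppi_network` restricted to the winning component.
#' @export
largest_component <- function(net) {
  net <- as_ppi_network(net, quiet = TRUE)
  g <- as_igraph(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    mins <- vapply(
      best,
      function(k) min(igraph::V(g)$name[comp$membership == k]),
      character(1L)
    )
    best <- best[order(mins)[1L]]
  }
  keep <- igraph::V(g)$name[comp$membership == best]
  new_ppi_network(dplyr::filter(net, .data$from %in% keep))
}

#' Degree-preserving network randomization
#'
#' Produces a random simple graph with exactly the degree sequence of the
#' input by repeated double-edge swaps (Maslov-Sneppen edge switching):
#' two edges (a,b) and (c,d) are replaced by (a,d) and (c,b) unless that
#' would create a self-loop or a duplicate edge, in which case the attempt
#' is rejected. Randomized networks supply the null distribution for the
#' enrichment-score permutation test.
#'
#' @param net A `ppi_network`.
#' @param n_swap_attempts Number of swap attempts; defaults to 10 times the
#'   edge count, a standard mixing length.
#' @param rng_seed Integer seed; the result is deterministic given the seed.
#' @return A `ppi_network` with the same degree for every gene.
#' @export
edge_switch_randomize <- function(net,
                                  n_swap_attempts = 10L * nrow(net),
                                  rng_seed) {
  net <- as_ppi_network(net, quiet = TRUE)
  stopifnot(n_swap_attempts >= 1L)
  g <- as_igraph(net)
  r <- withr::with_seed(
    rng_seed,
    igraph::rewire(
      g,
      igraph::keeping_degseq(loops = FALSE, niter = n_swap_attempts)
    )
  )
  as_ppi_network(
    tibble::as_tibble(
      as.data.frame(igraph::as_edgelist(r), stringsAsFactors = FALSE)
    ),
    quiet = TRUE
  )
}

#' Build an ensemble of degree-preserving random networks
#'
#' Member `i` is generated with seed `rng_seed + i`, so any member can be
#' regenerated independently from the ensemble metadata.
#'
#' @param net A `ppi_network`.
#' @param n_networks Ensemble size (1000 at production scale; tests use far
#'   fewer).
#' @param swaps_per_edge Swap attempts per edge for each member.
#' @param rng_seed Integer base seed.
#' @return A `rw_ensemble` list with elements `networks` (list of
#'   `ppi_network`), `source_degrees`, `n_networks`, `swaps_per_edge`, and
#'   `rng_seed`.
#' @export
build_ensemble <- function(net, n_networks, swaps_per_edge = 10L, rng_seed) {
  net <- as_ppi_network(net, quiet = TRUE)
  stopifnot(n_networks >= 1L)
  attempts <- swaps_per_edge * nrow(net)
  networks <- lapply(
    seq_len(n_networks),
    function(i) edge_switch_randomize(net, attempts, rng_seed + i)
  )
  structure(
    list(
      networks = networks,
      source_degrees = network_degree(net),
      n_networks = as.integer(n_networks),
      swaps_per_edge = swaps_per_edge,
      rng_seed = as.integer(rng_seed)
    ),
    class = "rw_ensemble"
  )
}

#' @exportS3Method base::print
print.rw_ensemble <- function(x, ...) {
  cat(
    "# Ensemble of", x$n_networks, "degree-preserving random networks",
    "(seed", paste0(x$rng_seed, ","), "swaps/edge", paste0(x$swaps_per_edge, ")\n")
  )
  invisible(x)
}

#' Write a network as a tab-separated edge list
#'
#' @param net A `ppi_network`.
#' @param path Output file.
#' @param header Optional comment lines (without the leading `#`) recording
#'   provenance such as seeds and parameters.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("# ", header), con)
  }
  writeLines(paste(net$from, net$to, sep = "\t"), con)
  invisible(path)
}
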