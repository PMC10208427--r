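#' Cell-contact graphs
#'
#' A contact graph is a simple undirected graph with one node per cell and
#' one edge per touching cell pair.  Nodes carry a validity mask: nodes close
#' to the image border or to gaps are kept as *context* (they participate in
#' graphlet counting as neighbors) but are excluded from graphlet degree
#' distributions, realizing the edge-distance exclusion border used when
#' quantifying graphlet frequencies near montage edges.
#'
#' @name contact-graph
NULL

new_contact_graph <- function(n, edges, valid = rep(TRUE, n),
                              labels = seq_len(n)) {
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    edges <- t(apply(edges, 1, sort))
    if (any(edges[, 1] == edges[, 2])) .stop_invalid("self-loop in contact graph")
    edges <- unique(edges)
  }
  adj <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, sort)
  structure(list(n = n, edges = edges, adj = adj, valid = valid,
                 labels = labels), class = "epi_contact_graph")
}

#' Build a contact graph from a tessellation or cell collection
#'
#' @param x an `epi_tessellation` (all nodes valid) or `epi_cells` from
#'   [extract_cells()].
#' @param ... passed to methods.
#' @return an `epi_contact_graph`.
#' @export
contact_graph <- function(x, ...) UseMethod("contact_graph")

#' @export
contact_graph.epi_tessellation <- function(x, ...) {
  n <- length(x$adjacency)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- x$adjacency[[i]]
    nb <- nb[nb > i]
    if (length(nb)) cbind(i, nb) else NULL
  }))
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  new_contact_graph(n, edges)
}

#' @rdname build_contact_graph
#' @export
contact_graph.epi_cells <- function(x, exclusion_depth = 4, ...) {
  build_contact_graph(x, exclusion_depth = exclusion_depth)
}

#' Contact graph of a segmented cell collection with an exclusion border
#'
#' Cells touching the image border or a gap have unknowable context, and so
#' do their near neighbors: every node within graph distance
#' `exclusion_depth` of a border- or gap-touching cell is marked
#' context-only.  Context nodes still contribute to their neighbors' orbit
#' counts; only their own rows are dropped from graphlet degree
#' distributions.
#'
#' @param cells an `epi_cells` collection from [extract_cells()].
#' @param exclusion_depth graph distance (edges) of the exclusion border.
#' @return an `epi_contact_graph` whose `valid` mask encodes the border.
#' @export
build_contact_graph <- function(cells, exclusion_depth = 4) {
  df <- cells$cells
  n <- nrow(df)
  if (n < 5) .stop_invalid("need at least 5 cells for a contact graph")
  lab2idx <- setNames(seq_len(n), df$label)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nb <- lab2idx[as.character(cells$neighbors[[i]])]
    nb <- nb[!is.na(nb) & nb > i]
    if (length(nb)) cbind(i, as.integer(nb)) else NULL
  }))
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  g <- new_contact_graph(n, edges, labels = df$label)
  bad <- df$touches_border | df$touches_gap
  if (any(bad)) {
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, n - igraph::vcount(ig)))
    d <- suppressWarnings(igraph::distances(ig, v = which(bad)))
    mind <- if (nrow(d)) apply(d, 2, min) else rep(Inf, n)
    g$valid <- mind > exclusion_depth
  }
  if (igraph::components(igraph::graph_from_edgelist(g$edges,
        directed = FALSE))$no > 1 && nrow(g$edges) > 0)
    warning("contact graph is disconnected; components analyzed jointly")
  g
}

#' Contact graph from an explicit edge list
#'
#' @param n number of nodes.
#' @param edges two-column matrix of 1-based node pairs.
#' @param valid optional validity mask.
#' @return an `epi_contact_graph`.
#' @export
contact_graph_from_edges <- function(n, edges, valid = rep(TRUE, n)) {
  new_contact_graph(n, edges, valid = valid)
}

#' Seeded Erdos-Renyi random graph
#'
#' Small random graphs used as test material for the orbit counters.
#'
#' @param n nodes; `p` edge probability; `rng_seed` integer seed.
#' @param p edge probability.
#' @param rng_seed integer seed.
#' @return an `epi_contact_graph`.
#' @export
random_graph <- function(n, p, rng_seed) {
  pairs <- t(combn(n, 2))
  keep <- with_seed(rng_seed, runif(nrow(pairs)) < p)
  new_contact_graph(n, pairs[keep, , drop = FALSE])
}

#' Read/write plain edge lists
#'
#' Two whitespace-separated integer columns, one edge per line.
#' @param path file path.
#' @param n number of nodes (defaults to the largest id in the file).
#' @export
read_edgelist <- function(path, n = NULL) {
  e <- as.matrix(read.table(path, col.names = c("a", "b")))
  if (is.null(n)) n <- max(e)
  new_contact_graph(n, e)
}

#' @rdname read_edgelist
#' @param g an `epi_contact_graph`.
#' @export
write_edgelist <- function(g, path) {
  write.table(g$edges, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.epi_contact_graph <- function(x, ...) {
  cat(sprintf("<epi_contact_graph> %d nodes (%d valid), %d edges\n",
              x$n, sum(x$valid), nrow(x$edges)))
  invisible(x)
}
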