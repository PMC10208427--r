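#' Count graphlet orbits for every node of a contact graph
#'
#' Exact induced-subgraph orbit counts for all 73 orbits of the 30 connected
#' graphlets on 2-5 nodes, obtained by single-pass ESU enumeration of every
#' connected induced subgraph (each visited exactly once) and bit-code
#' classification against the catalog.  Column 1 (orbit 0) equals the node
#' degree.
#'
#' @param g an `epi_contact_graph`.
#' @return an orbit count matrix (nodes x 73) of class `epi_orbits`, with the
#'   graph's validity mask attached as attribute `valid`.
#' @seealso [brute_force_orbits()] for the independent enumeration oracle.
#' @export
count_orbits <- function(g) {
  stopifnot(inherits(g, "epi_contact_graph"))
  cat_obj <- graphlet_catalog()
  adj0 <- lapply(g$adj, function(a) as.integer(a - 1L))
  counts <- cpp_count_orbits(g$n, adj0,
                             as.integer(t(cat_obj$tables[[3]])),
                             as.integer(t(cat_obj$tables[[4]])),
                             as.integer(t(cat_obj$tables[[5]])))
  colnames(counts) <- paste0("O", 0:72)
  rownames(counts) <- as.character(g$labels)
  structure(counts, valid = g$valid, class = c("epi_orbits", class(counts)))
}

#' Brute-force graphlet orbit counts (testing oracle)
#'
#' Independently recomputes the orbit count matrix by exhaustively visiting
#' every node subset of size 2-5 (not just connected ones), testing
#' connectivity, and classifying each connected induced subgraph from scratch
#' by explicit minimization over all node relabelings.  Shares only the final
#' orbit numbering with [count_orbits()]; the enumeration and classification
#' paths are disjoint.  Combinatorial cost limits it to `n <= 60`.
#'
#' @param g an `epi_contact_graph` with at most 60 nodes.
#' @return an `epi_orbits` matrix as in [count_orbits()].
#' @export
brute_force_orbits <- function(g) {
  stopifnot(inherits(g, "epi_contact_graph"))
  n <- g$n
  if (n > 60) .stop_invalid("brute_force_orbits is limited to n <= 60")
  cat_obj <- graphlet_catalog()
  A <- matrix(0L, n, n)
  if (nrow(g$edges)) {
    A[g$edges] <- 1L
    A[g$edges[, 2:1, drop = FALSE]] <- 1L
  }
  counts <- matrix(0, n, 73)
  for (k in 2:5) {
    if (n < k) break
    pb <- perm_bit_index(k)
    w <- 2^(seq_len(pb$np) - 1)
    wperm <- matrix(0, nrow(pb$perms), pb$np)
    for (p in seq_len(nrow(pb$perms)))
      for (t in seq_len(pb$np))
        wperm[p, pb$pidx[p, t]] <- wperm[p, pb$pidx[p, t]] + w[t]
    invpos <- apply(pb$perms, 1, order)          # k x nperm: invpos[v,p]
    # own connectivity table via boolean matrix closure
    connk <- vapply(0:(2^pb$np - 1), function(code) {
      M <- code_adjacency(code, k)
      R <- diag(k) + M
      for (i in seq_len(k)) R <- 0 + ((R %*% R) > 0)
      all(R[1, ] > 0)
    }, logical(1))

    subs <- combn(n, k)                          # k x nsub
    bits <- matrix(0L, pb$np, ncol(subs))
    for (t in seq_len(pb$np))
      bits[t, ] <- A[cbind(subs[pb$pairs[t, 1], ], subs[pb$pairs[t, 2], ])]
    codes <- as.integer(w %*% bits)
    keep <- connk[codes + 1L]
    if (!any(keep)) next
    subs <- subs[, keep, drop = FALSE]
    bits <- bits[, keep, drop = FALSE]
    permcodes <- wperm %*% bits                  # nperm x nsub
    cano <- as.vector(do.call(pmin, asplit(permcodes, 1)))
    iscano <- sweep(permcodes, 2, cano, "==")
    for (v in seq_len(k)) {
      key <- do.call(pmin, lapply(seq_len(nrow(iscano)), function(p)
        ifelse(iscano[p, ], invpos[v, p], Inf)))
      orb <- vapply(seq_along(key), function(s)
        cat_obj$orbit_of_rep[[k]][[as.character(cano[s])]][key[s]],
        0L)
      flat <- orb * n + subs[v, ]                # (orbit)*n + node, 1-based node
      tab <- tabulate(flat, nbins = 73L * n)
      counts <- counts + matrix(tab, n, 73)
    }
  }
  colnames(counts) <- paste0("O", 0:72)
  rownames(counts) <- as.character(g$labels)
  structure(counts, valid = g$valid, class = c("epi_orbits", "matrix", "array"))
}

#' @export
print.epi_orbits <- function(x, ...) {
  cat(sprintf("<epi_orbits> %d nodes x 73 orbits (%d valid nodes)\n",
              nrow(x), sum(attr(x, "valid"))))
  invisible(x)
}

orbit_rows_valid <- function(orbits) {
  v <- attr(orbits, "valid")
  if (is.null(v)) v <- rep(TRUE, nrow(orbits))
  unclass(orbits)[v, , drop = FALSE]
}

#' Graphlet degree distribution agreement distance (GDD)
#'
#' Compares two graphs through their per-orbit graphlet degree
#' distributions.  For orbit \eqn{j}, \eqn{d_j(k)} counts the (valid) nodes
#' that touch orbit \eqn{j} exactly \eqn{k \ge 1} times; it is scaled as
#' \eqn{S_j(k) = d_j(k)/k}, normalized to \eqn{N_j(k) = S_j(k)/\sum_k
#' S_j(k)}, and the per-orbit distance is \eqn{D_j = 2^{-1/2}
#' \sqrt{\sum_k (N_j^a(k)-N_j^b(k))^2} \in [0,1]}.  The distance is the mean
#' of \eqn{D_j} over `orbit_subset` (arithmetic by default).  Orbits absent
#' from both graphs are skipped; an orbit present in only one graph
#' contributes the maximal distance 1.
#'
#' @param a,b orbit matrices from [count_orbits()] (or contact graphs, which
#'   are counted on the fly).
#' @param orbit_subset integer orbit ids (0-72) to aggregate over.
#' @param aggregate `"arithmetic"` (default) or `"geometric"` mean.
#' @return the distance, a number in `[0, 1]`, with attributes
#'   `orbits_used` and `orbits_skipped`.
#' @export
#' @examples
#' g <- random_graph(20, 0.2, 1)
#' gdd_distance(g, g)   # identical graphs: 0
gdd_distance <- function(a, b, orbit_subset = 0:72,
                         aggregate = c("arithmetic", "geometric")) {
  aggregate <- match.arg(aggregate)
  if (inherits(a, "epi_contact_graph")) a <- count_orbits(a)
  if (inherits(b, "epi_contact_graph")) b <- count_orbits(b)
  if (!all(orbit_subset %in% 0:72))
    .stop_invalid("orbit_subset must be orbit ids in 0..72")
  ma <- orbit_rows_valid(a); mb <- orbit_rows_valid(b)
  dj <- rep(NA_real_, length(orbit_subset))
  for (i in seq_along(orbit_subset)) {
    j <- orbit_subset[i] + 1L
    ca <- ma[, j]; cb <- mb[, j]
    ha <- ca[ca >= 1]; hb <- cb[cb >= 1]
    if (!length(ha) && !length(hb)) next       # skipped
    if (!length(ha) || !length(hb)) { dj[i] <- 1; next }
    kmax <- max(ha, hb)
    na_ <- tabulate(ha, nbins = kmax) / seq_len(kmax)
    nb_ <- tabulate(hb, nbins = kmax) / seq_len(kmax)
    na_ <- na_ / sum(na_); nb_ <- nb_ / sum(nb_)
    dj[i] <- sqrt(sum((na_ - nb_)^2) / 2)
  }
  used <- which(!is.na(dj))
  if (!length(used)) .stop_invalid("no informative orbits in either graph")
  d <- if (aggregate == "arithmetic") mean(dj[used])
       else exp(mean(log(pmax(dj[used], .Machine$double.eps))))
  structure(d, orbits_used = orbit_subset[used],
            orbits_skipped = orbit_subset[-used])
}

#' Write an orbit matrix as CSV
#' @param orbits an `epi_orbits` matrix.
#' @param path output file.
#' @export
write_orbits_csv <- function(orbits, path) {
  df <- data.frame(node = rownames(orbits),
                   valid = attr(orbits, "valid"),
                   unclass(orbits), check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
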