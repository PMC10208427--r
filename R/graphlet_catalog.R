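# Graphlet/orbit catalog ------------------------------------------------------
#
# All 30 connected graphlets on 2-5 nodes and their 73 automorphism orbits,
# generated from first principles: every labeled graph on k nodes is encoded
# as a bit code over the C(k,2) node pairs (pair order (1,2),(1,3),...,
# (k-1,k)); canonical form = the minimum code over all k! relabelings;
# orbits = equivalence classes of nodes under the automorphism group.
# Graphlets are numbered by (node count, edge count, max degree, degree
# sequence, canonical code) ascending and orbits within a graphlet by
# (degree, sorted neighbor-degree signature, canonical node id) ascending,
# which reproduces the classic 2-4-node orbit numbering 0-14 (orbit 0 =
# degree, orbit 3 = triangle, ...).

pair_table <- function(k) {
  p <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  p[order(p[, "row"], p[, "col"]), , drop = FALSE]
}

all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# bit index permutation: permuted code bit t = original bit P_idx[perm, t]
perm_bit_index <- function(k) {
  pt <- pair_table(k)
  np <- nrow(pt)
  perms <- all_perms(k)
  pidx <- matrix(0L, nrow(perms), np)
  lookup <- matrix(0L, k, k)
  for (t in seq_len(np)) {
    lookup[pt[t, 1], pt[t, 2]] <- t
    lookup[pt[t, 2], pt[t, 1]] <- t
  }
  for (p in seq_len(nrow(perms)))
    for (t in seq_len(np))
      pidx[p, t] <- lookup[perms[p, pt[t, 1]], perms[p, pt[t, 2]]]
  list(perms = perms, pidx = pidx, pairs = pt, np = np)
}

code_bits <- function(codes, np) {
  vapply(seq_len(np), function(t) bitwAnd(codes %/% (2L^(t - 1L)), 1L),
         integer(length(codes)))
}

code_adjacency <- function(code, k) {
  pt <- pair_table(k)
  A <- matrix(0L, k, k)
  for (t in seq_len(nrow(pt)))
    if (bitwAnd(code %/% (2L^(t - 1L)), 1L) == 1L)
      A[pt[t, 1], pt[t, 2]] <- A[pt[t, 2], pt[t, 1]] <- 1L
  A
}

code_connected <- function(code, k) {
  A <- code_adjacency(code, k)
  reach <- diag(k) + A
  for (i in seq_len(k)) reach <- (reach %*% (diag(k) + A)) > 0
  all(reach[1, ] > 0)
}

#' Graphlet and orbit catalog (2-5 node graphlets, 73 orbits)
#'
#' Returns the package's catalog of the 30 connected graphlets on 2-5 nodes
#' and their 73 node orbits, with per-size lookup tables mapping a labeled
#' adjacency bit code and node position to a global orbit id.  Computed once
#' and cached for the session.
#'
#' @return a list with `graphlets` (data frame: id, k, n_edges, canonical
#'   code), `orbits` (data frame: orbit id 0-72, graphlet id, node degree),
#'   and internal lookup tables used by [count_orbits()].
#' @export
graphlet_catalog <- function() {
  if (!is.null(.epitess_cache$catalog)) return(.epitess_cache$catalog)
  graphlets <- list()
  orbit_rows <- list()
  tables <- list()        # per k: matrix [2^np, k] of 0-based global orbit id
  orbit_of_rep <- list()  # per k: list cano -> named int: rep node -> orbit id
  conn <- list()
  next_orbit <- 0L
  next_graphlet <- 0L
  for (k in 2:5) {
    pb <- perm_bit_index(k)
    ncode <- 2L^pb$np
    codes <- 0:(ncode - 1L)
    bits <- code_bits(codes, pb$np)                  # ncode x np
    w <- 2^(seq_len(pb$np) - 1)
    permcodes <- vapply(seq_len(nrow(pb$perms)), function(p)
      as.integer(bits[, pb$pidx[p, ], drop = FALSE] %*% w),
      integer(ncode))                                # ncode x nperm
    cano <- as.integer(do.call(pmin, asplit(permcodes, 2)))
    is_conn <- vapply(codes, code_connected, logical(1), k = k)
    conn[[k]] <- is_conn

    reps <- sort(unique(cano[is_conn]))
    info <- lapply(reps, function(cc) {
      A <- code_adjacency(cc, k)
      deg <- colSums(A)
      list(code = cc, nedges = sum(A) / 2L, maxdeg = max(deg),
           degseq = paste(sort(deg), collapse = ""))
    })
    ord <- order(sapply(info, function(x) x$nedges),
                 sapply(info, function(x) x$maxdeg),
                 sapply(info, function(x) x$degseq),
                 sapply(info, function(x) x$code))
    orbit_of_rep[[k]] <- list()
    for (gi in ord) {
      cc <- info[[gi]]$code
      A <- code_adjacency(cc, k)
      deg <- colSums(A)
      # automorphisms: permutations fixing the canonical code
      auto <- which(permcodes[cc + 1L, ] == cc)
      orb_class <- vapply(seq_len(k), function(v)
        min(vapply(auto, function(p) which(pb$perms[p, ] == v), 0L)),
        0L)
      classes <- unique(orb_class)
      sig <- vapply(classes, function(u)
        paste(sort(deg[which(A[u, ] == 1)]), collapse = ""), "")
      cord <- order(deg[classes], sig, classes)
      classes <- classes[cord]
      omap <- integer(k)
      for (ci in seq_along(classes)) {
        omap[orb_class == classes[ci]] <- next_orbit + ci - 1L
        orbit_rows[[length(orbit_rows) + 1L]] <- data.frame(
          orbit = next_orbit + ci - 1L, graphlet = next_graphlet,
          degree = deg[classes[ci]], k = k)
      }
      orbit_of_rep[[k]][[as.character(cc)]] <- omap
      graphlets[[length(graphlets) + 1L]] <- data.frame(
        id = next_graphlet, k = k, n_edges = info[[gi]]$nedges, code = cc)
      next_orbit <- next_orbit + length(classes)
      next_graphlet <- next_graphlet + 1L
    }
    # per labeled code: orbit id of each node position
    tab <- matrix(-1L, ncode, k)
    first_min <- apply(permcodes == cano, 1, which.max)
    for (code in codes[is_conn]) {
      p <- first_min[code + 1L]
      perm <- pb$perms[p, ]
      omap <- orbit_of_rep[[k]][[as.character(cano[code + 1L])]]
      # representative node u corresponds to original node perm[u]
      tab[code + 1L, perm] <- omap
    }
    tables[[k]] <- tab
  }
  cat_obj <- list(graphlets = do.call(rbind, graphlets),
                  orbits = do.call(rbind, orbit_rows),
                  tables = tables, orbit_of_rep = orbit_of_rep,
                  connected = conn, n_orbits = next_orbit)
  stopifnot(nrow(cat_obj$graphlets) == 30L, cat_obj$n_orbits == 73L)
  .epitess_cache$catalog <- cat_obj
  cat_obj
}
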