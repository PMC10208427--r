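#' Extract cells, neighbors, vertices and border polylines from a label image
#'
#' Cells are the labeled pixel regions; two cells are neighbors when they
#' share at least `min_shared_border_px` boundary pixel pairs under
#' 4-connectivity (which rejects corner-point contacts); vertices are lattice
#' corners whose 2x2 pixel block contains three or more distinct regions
#' (gap and image exterior included); border polylines are traced
#' vertex-to-vertex along the crack boundary between the two pixel regions.
#' Areas are pixel counts times `pixel_size^2`.  The polygon class of a cell
#' is its neighbor count, which equals its side and vertex count at
#' trivalent junctions.
#'
#' @param img an [epi_label_image()].
#' @param min_shared_border_px minimum shared boundary pixel pairs for two
#'   labels to count as neighbors.
#' @return an object of class `epi_cells`: `cells` (data frame with label,
#'   area_um2, n_sides, touches_border, touches_gap, excluded,
#'   exclude_reason), `neighbors` (list per cell), `vertices` (list per cell
#'   of junction coordinates, um), `borders` (named list `"a|b"` of polyline
#'   matrices in um), `gap_fraction`, and the source `image`.
#' @export
extract_cells <- function(img, min_shared_border_px = 3) {
  stopifnot(inherits(img, "epi_label_image"))
  L <- img$pixels
  px <- img$pixel_size
  nr <- nrow(L); nc <- ncol(L)
  labels <- sort(setdiff(unique(as.vector(L)), 0L))
  if (length(labels) < 2) .stop_invalid("need at least 2 labels")

  P <- matrix(-1L, nr + 2, nc + 2)
  P[2:(nr + 1), 2:(nc + 1)] <- L

  # vertical crack segments: boundary between horizontally adjacent pixels
  lf <- P[2:(nr + 1), 1:(nc + 1)]
  rt <- P[2:(nr + 1), 2:(nc + 2)]
  vidx <- which(lf != rt, arr.ind = TRUE)          # row = L row, col = x
  vseg <- data.frame(a = lf[vidx], b = rt[vidx],
                     x1 = vidx[, 2] - 1, y1 = vidx[, 1] - 1,
                     x2 = vidx[, 2] - 1, y2 = vidx[, 1])
  # horizontal crack segments: boundary between vertically adjacent pixels
  tp <- P[1:(nr + 1), 2:(nc + 1)]
  bt <- P[2:(nr + 2), 2:(nc + 1)]
  hidx <- which(tp != bt, arr.ind = TRUE)          # row = y, col = L col
  hseg <- data.frame(a = tp[hidx], b = bt[hidx],
                     x1 = hidx[, 2] - 1, y1 = hidx[, 1] - 1,
                     x2 = hidx[, 2], y2 = hidx[, 1] - 1)
  seg <- rbind(vseg, hseg)

  touches_gap <- labels %in% c(seg$a[seg$b == 0L], seg$b[seg$a == 0L])
  touches_border <- labels %in% c(seg$a[seg$b == -1L], seg$b[seg$a == -1L])

  # cell-cell segments and neighbor counts
  cc <- seg[seg$a >= 1L & seg$b >= 1L, ]
  lo <- pmin(cc$a, cc$b); hi <- pmax(cc$a, cc$b)
  key <- paste0(lo, "|", hi)
  cnt <- table(key)
  good_keys <- names(cnt)[cnt >= min_shared_border_px]
  pair_mat <- do.call(rbind, strsplit(good_keys, "|", fixed = TRUE))
  neighbors <- setNames(rep(list(integer(0)), length(labels)),
                        as.character(labels))
  if (length(good_keys)) {
    pa <- as.integer(pair_mat[, 1]); pb <- as.integer(pair_mat[, 2])
    for (i in seq_along(pa)) {
      neighbors[[as.character(pa[i])]] <-
        c(neighbors[[as.character(pa[i])]], pb[i])
      neighbors[[as.character(pb[i])]] <-
        c(neighbors[[as.character(pb[i])]], pa[i])
    }
    neighbors <- lapply(neighbors, sort)
  } else .stop_invalid("degenerate topology: no shared borders found")

  # junction corners: >= 3 distinct cell labels in the 2x2 block (gap and
  # image exterior do not make a vertex; borders ending there are traced to
  # their free end instead)
  b1 <- P[1:(nr + 1), 1:(nc + 1)]; b2 <- P[1:(nr + 1), 2:(nc + 2)]
  b3 <- P[2:(nr + 2), 1:(nc + 1)]; b4 <- P[2:(nr + 2), 2:(nc + 2)]
  ndist <- (b1 > 0L) + (b2 > 0L & b2 != b1) +
    (b3 > 0L & b3 != b1 & b3 != b2) +
    (b4 > 0L & b4 != b1 & b4 != b2 & b4 != b3)
  jc <- which(ndist >= 3L, arr.ind = TRUE)         # row = cy+1, col = cx+1
  if (!nrow(jc))
    warning("degenerate topology: no junction vertices found")
  jx <- jc[, 2] - 1L; jy <- jc[, 1] - 1L
  jid <- jy * (nc + 1L) + jx + 1L
  # vertices per cell
  vert_lab <- rbind(
    data.frame(lab = b1[jc], x = jx, y = jy), data.frame(lab = b2[jc], x = jx, y = jy),
    data.frame(lab = b3[jc], x = jx, y = jy), data.frame(lab = b4[jc], x = jx, y = jy))
  vert_lab <- unique(vert_lab[vert_lab$lab >= 1L, ])
  vertices <- lapply(as.character(labels), function(l) {
    vv <- vert_lab[vert_lab$lab == as.integer(l), c("x", "y"), drop = FALSE]
    as.matrix(vv) * px
  })
  names(vertices) <- as.character(labels)

  # trace border polylines per neighbor pair
  cid <- function(x, y) y * (nc + 1L) + x + 1L
  cc$u <- cid(cc$x1, cc$y1); cc$v <- cid(cc$x2, cc$y2)
  cc$key <- paste0(pmin(cc$a, cc$b), "|", pmax(cc$a, cc$b))
  segsplit <- split(cc[, c("u", "v")], cc$key)
  borders <- list()
  for (kkey in good_keys) {
    s <- segsplit[[kkey]]
    borders[[kkey]] <- trace_polyline(s$u, s$v, nc, px)
  }

  areas <- tabulate(L, nbins = max(labels))[labels] * px^2
  cells <- data.frame(label = labels, area_um2 = areas,
                      n_sides = lengths(neighbors)[as.character(labels)],
                      touches_border = touches_border,
                      touches_gap = touches_gap,
                      excluded = FALSE, exclude_reason = "",
                      row.names = NULL)
  structure(list(cells = cells, neighbors = neighbors, vertices = vertices,
                 borders = borders, gap_fraction = mean(L == 0L),
                 image = img),
            class = "epi_cells")
}

# order crack segments (corner-id pairs) into a polyline; endpoints are
# degree-1 corners (junctions); closed loops start anywhere.  If the
# interface has several components the longest is returned.
trace_polyline <- function(u, v, nc, px) {
  corners <- unique(c(u, v))
  lu <- match(u, corners); lv <- match(v, corners)
  m <- length(u)
  inc <- vector("list", length(corners))
  for (s in seq_len(m)) {
    inc[[lu[s]]] <- c(inc[[lu[s]]], s)
    inc[[lv[s]]] <- c(inc[[lv[s]]], s)
  }
  used <- logical(m)
  paths <- list()
  repeat {
    deg1 <- which(lengths(lapply(inc, function(ss) ss[!used[ss]])) == 1L)
    anyleft <- which(!used)
    if (!length(anyleft)) break
    start <- if (length(deg1)) deg1[1] else lu[anyleft[1]]
    path <- start
    cur <- start
    repeat {
      nxt <- inc[[cur]][!used[inc[[cur]]]]
      if (!length(nxt)) break
      s <- nxt[1]
      used[s] <- TRUE
      cur <- if (lu[s] == cur) lv[s] else lu[s]
      path <- c(path, cur)
    }
    paths[[length(paths) + 1L]] <- path
  }
  best <- paths[[which.max(lengths(paths))]]
  ids <- corners[best]
  xy <- cbind((ids - 1L) %% (nc + 1L), (ids - 1L) %/% (nc + 1L)) * px
  # deterministic orientation: start at the smaller corner id
  if (ids[1] > ids[length(ids)]) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  attr(xy, "n_components") <- length(paths)
  xy
}
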