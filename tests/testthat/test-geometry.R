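test_that("label images round trip through TIFF and PNG", {
  img <- block_label_image(4, 5, pixel_size = 0.5)
  tf <- tempfile(fileext = ".tif")
  write_label_image(img, tf)
  back <- read_label_image(tf, 0.5)
  expect_identical(back$pixels, img$pixels)

  pf <- tempfile(fileext = ".png")
  write_label_image(img, pf)
  expect_identical(read_label_image(pf, 0.5)$pixels, img$pixels)

  expect_error(read_label_image(tempfile(fileext = ".png")), "cannot read")
  rgb <- tempfile(fileext = ".png")
  png::writePNG(array(runif(12), c(2, 2, 3)), rgb)
  expect_error(read_label_image(rgb, 1), "single-channel")
  expect_warning(read_label_image(tf), "pixel_size")
})

test_that("square-cell fixture: 4-neighborhood, corner contacts rejected", {
  img <- block_label_image(3, 3)
  cl <- extract_cells(img)
  expect_setequal(cl$neighbors[["5"]], c(2L, 4L, 6L, 8L))  # no diagonals
  expect_equal(cl$cells$area_um2, rep(9, 9))
  expect_true(all(cl$cells$touches_border ==
                    (cl$cells$label != 5L)))
})

test_that("hexagonal raster round trip recovers 6 neighbors and 6 vertices", {
  hx <- fixture("hex88", function() hexagonal_lattice(8, 8))
  ri <- fixture("hex88_raster", function() rasterize(hx, 512, 512, 1))
  ce <- extract_cells(ri)
  interior <- ce$cells[!ce$cells$touches_border, ]
  expect_gt(nrow(interior), 20)
  expect_true(all(interior$n_sides == 6L))
  for (l in interior$label) {
    expect_identical(ce$neighbors[[as.character(l)]], sort(hx$adjacency[[l]]))
    expect_equal(nrow(ce$vertices[[as.character(l)]]), 6)
  }
  # areas within 2% of the polygon truth (cells >= 200 px)
  truth_um2 <- hx$areas[interior$label] * 512^2
  expect_true(all(abs(interior$area_um2 - truth_um2) / truth_um2 < 0.02))
})

test_that("two-label image is flagged as degenerate topology", {
  L <- cbind(matrix(1L, 8, 4), matrix(2L, 8, 4))
  expect_warning(cl <- extract_cells(epi_label_image(L, 1)), "degenerate")
  expect_length(cl$borders, 1)
  expect_equal(nrow(cl$vertices[["1"]]), 0)
})

test_that("neighbor symmetry holds on segmented rasters", {
  tess <- relaxed_tess(60, 6, seed = 3)
  ce <- extract_cells(rasterize(tess, 384, 384, 0.5))
  for (l in names(ce$neighbors))
    for (nb in ce$neighbors[[l]])
      expect_true(as.integer(l) %in% ce$neighbors[[as.character(nb)]])
})

test_that("montage QC rejects above the gap threshold and is idempotent", {
  base <- fixture("hex88_raster", function() rasterize(hexagonal_lattice(8, 8), 512, 512, 1))

  bad <- punch_gap(base, fraction = 0.10)
  qc_bad <- qc_filter(extract_cells(bad))
  expect_false(qc_bad$report$montage_pass)
  expect_true(all(qc_bad$cells$cells$excluded))

  ok <- punch_gap(base, center_px = c(256, 256), radius_px = 64)  # ~1.9% gap
  ce <- extract_cells(ok)
  qc <- qc_filter(ce)
  expect_true(qc$report$montage_pass)
  # exactly the hole-adjacent cells are excluded: audit pixel adjacency
  L <- ok$pixels
  gap_adj <- integer(0)
  gp <- which(L == 0L, arr.ind = TRUE)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    r2 <- gp[, 1] + d[1]; c2 <- gp[, 2] + d[2]
    keep <- r2 >= 1 & r2 <= nrow(L) & c2 >= 1 & c2 <= ncol(L)
    gap_adj <- union(gap_adj, L[cbind(r2[keep], c2[keep])])
  }
  gap_adj <- setdiff(gap_adj, 0L)
  expect_setequal(qc$cells$cells$label[qc$cells$cells$excluded], gap_adj)

  # no gaps: nothing excluded
  qc0 <- qc_filter(extract_cells(base))
  expect_true(qc0$report$montage_pass)
  expect_false(any(qc0$cells$cells$excluded))

  # idempotence
  qc2 <- qc_filter(qc$cells)
  expect_identical(qc2$cells$cells, qc$cells$cells)
  expect_identical(qc2$report$excluded_cells, qc$report$excluded_cells)
})

test_that("polygon distribution frequencies and balance deviation", {
  pd <- polygon_distribution(c(5L, 6L, 7L, 6L, 6L))
  expect_equal(unname(pd$freq[c("5", "6", "7")]), c(0.2, 0.6, 0.2))
  expect_equal(pd$balance_deviation, 0)
  expect_equal(sum(pd$freq), 1, tolerance = 1e-9)

  pd2 <- polygon_distribution(c(4L, 5L, 6L))
  expect_equal(pd2$balance_deviation, 2 / 3, tolerance = 1e-12)

  hx <- fixture("hex88", function() hexagonal_lattice(8, 8))
  pdh <- polygon_distribution(hx)
  expect_identical(names(pdh$freq), "6")
  expect_equal(unname(pdh$freq), 1)

  expect_error(polygon_distribution(integer(0)), "no valid cells")
})

test_that("area statistics", {
  as1 <- area_stats(c(100, 300))
  expect_equal(as1$mean, 200)
  expect_equal(as1$median, 200)
  as2 <- area_stats(42)
  expect_equal(as2$mean, 42)
  expect_equal(as2$median, 42)
  expect_equal(as2$iqr, 0)
  expect_true(as1$min <= as1$median && as1$median <= as1$max)
})
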