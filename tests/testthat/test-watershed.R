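test_that("watershed recovers synthetic boundary-stain segmentations", {
  tess <- relaxed_tess(50, 5, seed = 21)
  truth <- rasterize(tess, 384, 384, 0.5)

  g0 <- render_boundary_stain(truth, ridge = 1, background = 0.1)
  seg0 <- watershed_segment(g0, pixel_size = 0.5)
  expect_equal(length(setdiff(unique(as.vector(seg0$pixels)), 0L)), 50)
  expect_gt(label_iou(truth, seg0), 0.9)

  # noise at 10% of the ridge contrast
  gn <- render_boundary_stain(truth, 1, 0.1, noise_sd = 0.09, rng_seed = 3)
  segn <- watershed_segment(gn, pixel_size = 0.5)
  expect_gt(label_iou(truth, segn), 0.9)

  expect_identical(watershed_segment(gn, pixel_size = 0.5)$pixels, segn$pixels)
})

test_that("constant image degenerates to a single region with a warning", {
  expect_warning(seg <- watershed_segment(matrix(0.5, 64, 64)), "constant")
  expect_true(all(seg$pixels == 1L))
})
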