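test_that("rendered arc length matches analytic geometry", {
  # straight 2-point spec: arc length equals the endpoint distance
  bs <- straight_spec(100)
  expect_equal(bs$arc_length_px, 100, tolerance = 0.5 / 100)

  # semicircular control polygon of radius 50: length pi * r within 1%
  th <- seq(0, pi, length.out = 9)
  cp <- cbind(row = 100 + 50 * sin(th), col = 100 + 50 * cos(th))
  bs2 <- bivalent_spec(cp)
  expect_lt(abs(bs2$arc_length_px - pi * 50) / (pi * 50), 0.01)

  # degenerate (coincident) control points are rejected
  expect_error(bivalent_spec(cbind(c(10, 10), c(10, 10))), "degenerate")
})

test_that("render_bivalent writes channels as specified", {
  canvas <- blank_canvas()
  bs <- straight_spec(100, centromere_arc_pos = 25, foci_arc_pos = c(30, 90))
  r <- render_bivalent(bs, canvas)
  expect_gt(max(r$canvas[, , 1]), 0.5)
  expect_gt(max(r$canvas[, , 2]), 0.5)
  expect_gt(max(r$canvas[, , 3]), 0.5)
  expect_equal(r$truth$n_foci, 2)

  # zero foci: green channel untouched
  r0 <- render_bivalent(straight_spec(100), blank_canvas())
  expect_identical(max(r0$canvas[, , 2]), 0)
  expect_identical(max(r0$canvas[, , 3]), 0)

  # control points too close to the border are rejected
  expect_error(render_bivalent(straight_spec(100, row = 2), blank_canvas()),
               "margin")

  # positions outside the arc are rejected at spec time
  expect_error(straight_spec(100, foci_arc_pos = c(120)), "arc")
  expect_error(straight_spec(100, foci_arc_pos = c(50, 40)), "increasing")
})

test_that("generate_cell conserves ground truth and is seed-stable", {
  sp <- cell_spec(n_bivalents = 5, include_xy = FALSE,
                  canvas_size = c(400, 400), seed = 11)
  a <- generate_cell(sp, "c")
  b <- generate_cell(sp, "c")
  expect_identical(a$image, b$image)     # bit-identical from the seed
  expect_identical(a$manifest, b$manifest)
  expect_equal(nrow(a$manifest), 5)
  foci <- parse_foci_string(a$manifest$foci_pos_px)
  expect_equal(vapply(foci, length, 0L), a$manifest$n_foci)
  for (i in seq_len(5)) {
    expect_true(all(foci[[i]] >= 0 & foci[[i]] <= a$manifest$arc_length_px[i]))
    cen <- a$manifest$centromere_pos_px[i]
    expect_true(cen >= 0 && cen <= a$manifest$arc_length_px[i])
  }

  # different seed changes the image
  c2 <- generate_cell(cell_spec(n_bivalents = 5, include_xy = FALSE,
                                canvas_size = c(400, 400), seed = 12), "c")
  expect_false(identical(a$image, c2$image))

  # zero bivalents: pure-noise image, empty manifest
  z <- generate_cell(cell_spec(n_bivalents = 0, include_xy = FALSE,
                               canvas_size = c(128, 128), seed = 1), "c")
  expect_equal(nrow(z$manifest), 0)
  expect_lt(max(z$image), 0.25)
})

test_that("XY body is flagged and overlap budget is respected", {
  sp <- cell_spec(n_bivalents = 6, include_xy = TRUE,
                  canvas_size = c(500, 500), seed = 4)
  cell <- generate_cell(sp, "c")
  expect_equal(nrow(cell$manifest), 7)
  expect_equal(sum(cell$manifest$is_xy), 1)
  # overlap_fraction = 0 means no bivalent intersects another
  expect_true(all(!cell$manifest$overlaps))
})

test_that("generate_dataset writes TIFFs, manifest and config sidecar", {
  d <- withr::local_tempdir()
  res <- generate_dataset(d, n_cells = 3, base_seed = 7, n_bivalents = 4,
                          include_xy = FALSE, canvas_size = c(300, 300))
  expect_length(res$tiff_paths, 3)
  expect_true(all(file.exists(res$tiff_paths)))
  expect_true(file.exists(res$manifest_path))
  expect_true(file.exists(res$config_path))
  man <- read_manifest(res$manifest_path)
  expect_equal(length(unique(man$cell_id)), 3)

  # refusing to clobber a non-empty directory
  expect_error(generate_dataset(d, n_cells = 1), "overwrite")

  # same config + seed: byte-identical manifest
  d2 <- withr::local_tempdir()
  generate_dataset(d2, n_cells = 3, base_seed = 7, n_bivalents = 4,
                   include_xy = FALSE, canvas_size = c(300, 300))
  expect_identical(unname(tools::md5sum(file.path(d, "manifest.csv"))),
                   unname(tools::md5sum(file.path(d2, "manifest.csv"))))

  # disjoint per-cell seed ranges produce pixelwise different images
  d3 <- withr::local_tempdir()
  generate_dataset(d3, n_cells = 3, base_seed = 100, n_bivalents = 4,
                   include_xy = FALSE, canvas_size = c(300, 300))
  img_a <- read_image_tiff(res$tiff_paths[1])
  img_b <- read_image_tiff(file.path(d3, "cell_001.tif"))
  expect_false(identical(img_a, img_b))

  # TIFF round trip preserves the 16-bit quantized image
  cell <- generate_cell(cell_spec(n_bivalents = 2, include_xy = FALSE,
                                  canvas_size = c(200, 200), seed = 5), "c")
  tf <- withr::local_tempfile(fileext = ".tif")
  write_image_tiff(cell$image, tf)
  back <- read_image_tiff(tf)
  expect_equal(max(abs(back - cell$image)), 0, tolerance = 1e-9)
})
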