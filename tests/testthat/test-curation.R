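base_row <- function(cell = "c1", idx = 1, len_px = 130, n_foci = 1,
                     branch = 0, skel = 120, offset = 0.5) {
  data.frame(cell_id = cell, object_index = idx,
             sc_length_px = len_px, sc_length_um = len_px / 9.8152,
             centromere_pos_px = 30, centromere_pos_norm = 30 / len_px,
             foci_pos_px = "60.000", foci_pos_norm = "0.46154",
             n_foci = n_foci, foci_max_offset_px = offset,
             branch_points = branch, skeleton_length_px = skel,
             centroid_row = 50, centroid_col = 50, flags = "",
             stringsAsFactors = FALSE)
}

test_that("diagnose flags merged bivalents and extra foci deterministically", {
  clean <- base_row()
  d <- diagnose(clean)
  expect_false(d$merged_bivalent)
  expect_false(d$extra_foci)
  expect_true(d$curated_ok)

  # branched skeleton: merged
  d2 <- diagnose(base_row(branch = 2))
  expect_true(d2$merged_bivalent)
  expect_false(d2$curated_ok)

  # more foci than the per-bivalent maximum (4): extra_foci
  d3 <- diagnose(base_row(n_foci = 6))
  expect_true(d3$extra_foci)

  # off-center focus fails the centrality re-check
  d4 <- diagnose(base_row(offset = 4.5))
  expect_true(d4$extra_foci)

  # over-long skeleton relative to cell-mates: merged
  cellm <- do.call(rbind, c(lapply(1:6, function(i)
    base_row(idx = i, skel = 120 + i)), list(base_row(idx = 7, skel = 320))))
  d5 <- diagnose(cellm)
  expect_true(d5$merged_bivalent[7])
  expect_false(any(d5$merged_bivalent[1:6]))

  # deterministic
  expect_identical(diagnose(cellm), diagnose(cellm))
})

test_that("diagnose honors a manual reject list", {
  m <- rbind(base_row(idx = 1), base_row(idx = 2))
  rj <- data.frame(cell_id = "c1", object_index = 2)
  d <- diagnose(m, reject_list = rj)
  expect_equal(d$manual_reject, c(FALSE, TRUE))
  expect_equal(d$curated_ok, c(TRUE, FALSE))
})

test_that("a rendered two-bivalent merge is flagged when measured", {
  canvas <- blank_canvas(220, 220)
  a <- bivalent_spec(cbind(row = c(40, 180), col = c(40, 180)))
  b <- bivalent_spec(cbind(row = c(180, 40), col = c(40, 180)))
  canvas <- render_bivalent(a, canvas)$canvas
  canvas <- render_bivalent(b, canvas)$canvas
  # permissive classification lets the merged object through to measurement
  perm <- segmentation_params(max_branch_points = 10,
                              min_eccentricity = 0, min_solidity = 0.05)
  res <- suppressMessages(measure_image(canvas, "c", seg_params = perm))
  expect_equal(nrow(res$measurements), 1)
  d <- diagnose(res$measurements)
  expect_true(d$merged_bivalent[1])
})

test_that("filter_chromosome1 selects the longest in-window bivalent per cell", {
  m <- rbind(base_row(idx = 1, len_px = 130),   # 13.2 um, longest
             base_row(idx = 2, len_px = 110),
             base_row("c2", idx = 1, len_px = 125),
             base_row("c2", idx = 2, len_px = 100))
  d <- diagnose(m)
  f <- filter_chromosome1(d)
  expect_equal(nrow(f), 2)
  expect_equal(f$object_index, c(1, 1))
  expect_true(all(f$is_chr1))

  # subset + idempotence
  f2 <- filter_chromosome1(f)
  expect_equal(f2[names(f)], f[names(f)])

  # the longest bivalent flagged merged: the cell yields no candidate
  m3 <- rbind(base_row(idx = 1, len_px = 130, branch = 3),
              base_row(idx = 2, len_px = 110))
  expect_equal(nrow(filter_chromosome1(diagnose(m3))), 0)

  # out-of-window lengths are excluded
  m4 <- base_row(idx = 1, len_px = 60)  # 6.1 um, below the window
  expect_equal(nrow(filter_chromosome1(diagnose(m4))), 0)

  expect_error(filter_chromosome1(m), "diagnosed")
})

test_that("compare_to_reference recovers identity and affine bias", {
  auto <- data.frame(cell_id = rep("c", 5), bivalent_id = 1:5,
                     sc_length_px = c(100, 110, 120, 130, 140),
                     centromere_pos_px = c(20, 25, 30, 35, 40),
                     foci_pos_px = c("50", "55", "60", "65", "70"))
  ref <- data.frame(cell_id = rep("c", 5), bivalent_id = 1:5,
                    arc_length_px = c(100, 110, 120, 130, 140),
                    centromere_pos_px = c(20, 25, 30, 35, 40),
                    foci_pos_px = c("50", "55", "60", "65", "70"))
  r <- compare_to_reference(auto, ref)
  expect_true(all(abs(r$pearson_r - 1) < 1e-12))
  expect_true(all(abs(r$bias_percent) < 1e-9))

  auto2 <- auto
  auto2$sc_length_px <- auto$sc_length_px * 1.04
  r2 <- compare_to_reference(auto2, ref)
  sc <- r2[r2$metric == "sc_length", ]
  expect_equal(sc$bias_percent, 4, tolerance = 1e-9)
  expect_equal(sc$pearson_r, 1, tolerance = 1e-12)

  expect_error(compare_to_reference(auto[0, ], ref), "joinable")
})

test_that("pipeline accuracy against the manifest is high on clean data", {
  cell <- clean_cell(seed = 31, n = 6, canvas = 512)
  res <- suppressMessages(measure_image(cell$image, cell$manifest$cell_id[1]))
  m <- match_to_manifest(res$measurements, cell$manifest)
  acc <- compare_to_reference(m, cell$manifest)
  expect_gte(acc$pearson_r[acc$metric == "sc_length"], 0.96)
})
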