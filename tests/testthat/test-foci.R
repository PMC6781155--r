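# One controlled scene shared by the focus/centromere tests: a straight
# bivalent with known focus and centromere arc positions.
scene <- local({
  canvas <- blank_canvas(120, 220)
  bs <- straight_spec(170, row = 60, col0 = 25,
                      centromere_arc_pos = 25, foci_arc_pos = c(30, 90))
  r <- render_bivalent(bs, canvas)
  pre <- preprocess(r$canvas)
  objs <- detect_objects(pre[, , 1])
  ml <- extract_midline(objs$labels == 1)
  list(pre = pre, ml = ml, truth = r$truth)
})

test_that("foci are recovered at their true arc positions", {
  f <- detect_foci(scene$pre[, , 2], scene$ml, half_width = 5,
                   background = list(mean = 0.0, sd = 0.005))
  expect_equal(nrow(f), 2)
  # cap offset: the measured arc origin may differ from the spec origin by
  # the end-extension residual (~1 px)
  expect_lt(abs(f$arc_pos_px[1] - 30), 2.5)
  expect_lt(abs(f$arc_pos_px[2] - 90), 2.5)
  expect_lt(abs(diff(f$arc_pos_px) - 60), 2)

  # blank green channel: no foci
  f0 <- detect_foci(matrix(0, 120, 220), scene$ml, half_width = 5,
                    background = list(mean = 0, sd = 0.005))
  expect_equal(nrow(f0), 0)
})

test_that("bright off-ribbon spots are rejected", {
  green <- scene$pre[, , 2]
  # a bright spot 3 half-widths off the midline
  spot <- stats::dnorm(seq(-4, 4), 0, 1.5)
  blob <- outer(spot, spot); blob <- blob / max(blob)
  green2 <- green
  green2[75:83, 90:98] <- pmax(green2[75:83, 90:98], blob)  # 15 px off axis
  f <- detect_foci(green2, scene$ml, half_width = 5,
                   background = list(mean = 0, sd = 0.005))
  expect_equal(nrow(f), 2)  # still only the two on-axis foci
})

test_that("nearby maxima are merged by the arc separation rule", {
  canvas <- blank_canvas(120, 220)
  bs <- straight_spec(170, row = 60, col0 = 25, foci_arc_pos = c(60, 63))
  r <- render_bivalent(bs, canvas)
  pre <- preprocess(r$canvas)
  objs <- detect_objects(pre[, , 1])
  ml <- extract_midline(objs$labels == 1)
  f <- detect_foci(pre[, , 2], ml, half_width = 5,
                   background = list(mean = 0, sd = 0.005))
  expect_equal(nrow(f), 1)   # 3 px apart: one physical focus
})

test_that("centromere localization handles absence and ties", {
  cen <- locate_centromere(scene$pre[, , 3], scene$ml, half_width = 5,
                           background = list(mean = 0, sd = 0.005))
  expect_lt(abs(cen$arc_pos_px - 25), 2.5)
  expect_length(cen$flags, 0)

  # blank blue channel: missing + flag
  c0 <- locate_centromere(matrix(0, 120, 220), scene$ml, half_width = 5,
                          background = list(mean = 0, sd = 0.005))
  expect_true(is.na(c0$arc_pos_px))
  expect_equal(c0$flags, "no_centromere")

  # two equal maxima: nearer-to-end one chosen, flagged ambiguous
  canvas <- blank_canvas(120, 220)
  bs <- straight_spec(170, row = 60, col0 = 25, centromere_arc_pos = 40)
  r <- render_bivalent(bs, canvas)
  blue <- r$canvas[, , 3]
  blue2 <- blue
  # duplicate the centromere blob at arc ~130 (mirror along the bar)
  src <- blue[, 55:75]
  blue2[, 145:165] <- pmax(blue2[, 145:165], src)
  img <- r$canvas; img[, , 3] <- blue2
  pre <- preprocess(img)
  objs <- detect_objects(pre[, , 1])
  ml <- extract_midline(objs$labels == 1)
  ct <- locate_centromere(pre[, , 3], ml, half_width = 5,
                          background = list(mean = 0, sd = 0.005))
  expect_equal(ct$flags, "ambiguous_centromere")
  L <- ml$total_length_px
  expect_lt(min(ct$arc_pos_px, L - ct$arc_pos_px), L / 2 - 5)
})

test_that("orientation reflects distal centromeres and is an involution", {
  m <- list(sc_length_px = 100, centromere_pos_px = 75,
            foci_pos_px = 90, flags = character(0))
  o <- orient_and_normalize(m)
  expect_equal(o$centromere_pos_norm, 0.25)
  expect_equal(o$foci_pos_norm, 0.10)

  m2 <- list(sc_length_px = 100, centromere_pos_px = 25,
             foci_pos_px = c(40, 80), flags = character(0))
  o2 <- orient_and_normalize(m2)
  expect_equal(o2$centromere_pos_px, 25)
  expect_equal(o2$foci_pos_norm, c(0.4, 0.8))

  # involution: orienting twice equals orienting once
  oo <- orient_and_normalize(o)
  expect_equal(oo$centromere_pos_px, o$centromere_pos_px)
  expect_equal(oo$foci_pos_px, o$foci_pos_px)

  # missing centromere: orientation skipped
  m3 <- list(sc_length_px = 100, centromere_pos_px = NA_real_,
             foci_pos_px = 90, flags = "no_centromere")
  o3 <- orient_and_normalize(m3)
  expect_false(o3$oriented)
  expect_equal(o3$foci_pos_px, 90)

  expect_error(orient_and_normalize(list(sc_length_px = 0,
                                         centromere_pos_px = 1,
                                         foci_pos_px = numeric(0))),
               "sc_length_px")

  # normalized positions stay in [0, 1] and flank gaps sum to 1
  set.seed(2)
  for (i in 1:25) {
    L <- runif(1, 50, 200)
    k <- sample(0:3, 1)
    foci <- sort(runif(k, 0, L))
    om <- orient_and_normalize(list(sc_length_px = L,
                                    centromere_pos_px = runif(1, 0, L),
                                    foci_pos_px = foci,
                                    flags = character(0)))
    expect_true(all(om$foci_pos_norm >= 0 & om$foci_pos_norm <= 1))
    expect_lte(om$centromere_pos_norm, 0.5)
    gaps <- diff(c(0, om$foci_pos_norm, 1))
    expect_equal(sum(gaps), 1, tolerance = 1e-9)
  }
})

test_that("cell records tally counts and validate quality", {
  m <- data.frame(cell_id = "c1", n_foci = rep(1L, 23))
  rec <- assemble_cell_record(m, quality = 2)
  expect_equal(rec$mlh1_total, 23)
  expect_equal(rec$n_zero_foci_bivalents, 0)

  m2 <- data.frame(cell_id = "c1", n_foci = c(rep(1L, 22), 0L))
  rec2 <- assemble_cell_record(m2)
  expect_equal(rec2$mlh1_total, 22)
  expect_equal(rec2$n_zero_foci_bivalents, 1)

  expect_error(assemble_cell_record(m, quality = 6), "quality")
  expect_error(assemble_cell_record(rbind(m, data.frame(cell_id = "c2",
                                                        n_foci = 1L))),
               "single cell_id")
})

test_that("clean synthetic cells reproduce manifest focus counts", {
  cell <- clean_cell(seed = 23, n = 6, canvas = 512)
  res <- suppressMessages(measure_image(cell$image, cell$manifest$cell_id[1]))
  m <- match_to_manifest(res$measurements, cell$manifest)
  j <- merge(m, cell$manifest, by = "bivalent_id")
  expect_gte(nrow(j), 5)
  agree <- j$n_foci.x == j$n_foci.y
  expect_gte(mean(agree), 0.95)
  expect_equal(sum(j$n_foci.x), sum(j$n_foci.y))

  # arc positions: RMSE <= 2 px against oriented truth
  errs <- c()
  for (i in seq_len(nrow(j))) {
    if (!agree[i] || j$n_foci.x[i] == 0) next
    tr <- orient_truth(parse_foci_string(j$foci_pos_px.y[i])[[1]],
                       j$centromere_pos_px.y[i], j$arc_length_px[i])
    au <- parse_foci_string(j$foci_pos_px.x[i])[[1]]
    errs <- c(errs, au - tr)
  }
  expect_lt(sqrt(mean(errs^2)), 2)
})
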