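# Synthetic spermatocyte-spread generator.
#
# Renders curved, ribbon-like bivalents of known arc length into a
# three-channel canvas (red = SYCP3 axis, green = MLH1 foci, blue = CREST
# centromere) and records exact ground truth for every rendered object, so
# that the measurement pipeline can be validated against a known answer.
# Images are H x W x 3 numeric arrays in [0, 1]; pixel (1, 1) is the top-left
# corner, coordinates are (row, col).

#' Specification of a single synthetic bivalent
#'
#' Describes one ribbon-like bivalent: a smooth midline through a set of
#' control points, a ribbon width, and the arc-length positions of the
#' centromere and MLH1 foci along that midline. Arc length is measured in
#' pixels from the first control point.
#'
#' @param control_points numeric matrix with columns `row`, `col`: ordered
#'   control points of the midline, in pixel coordinates.
#' @param ribbon_width full ribbon width in pixels (>= 2).
#' @param sc_intensity peak red-channel intensity as a fraction of the
#'   dynamic range.
#' @param centromere_arc_pos arc-length position of the centromere (px), or
#'   `NA` for no centromere signal (used for the XY body).
#' @param foci_arc_pos numeric vector of strictly increasing arc-length
#'   positions of MLH1 foci (px); may be empty.
#' @param foci_sigma Gaussian sigma of rendered foci (px).
#' @param foci_intensity peak green-channel intensity of foci.
#' @param centromere_intensity peak blue-channel intensity.
#' @param is_xy logical; marks the XY body, rendered with attenuated
#'   green/blue signal and flagged in the manifest.
#'
#' @return An object of class `bivalent_spec` with the fields above plus
#'   `arc_length_px`, the numerically integrated length of the midline
#'   spline.
#' @export
bivalent_spec <- function(control_points,
                          ribbon_width = 5,
                          sc_intensity = 0.8,
                          centromere_arc_pos = NA_real_,
                          foci_arc_pos = numeric(0),
                          foci_sigma = 2,
                          foci_intensity = 0.9,
                          centromere_intensity = 0.9,
                          is_xy = FALSE) {
  control_points <- as.matrix(control_points)
  if (ncol(control_points) != 2L || nrow(control_points) < 2L)
    stop("control_points must be an n x 2 matrix (row, col) with n >= 2")
  if (ribbon_width < 2) stop("ribbon_width must be >= 2 px")
  path <- midline_spline(control_points, step = 0.25)
  L <- path$total_length
  if (L <= 0) stop("degenerate control polygon: zero arc length")
  foci_arc_pos <- as.numeric(foci_arc_pos)
  if (length(foci_arc_pos) && any(diff(foci_arc_pos) <= 0))
    stop("foci_arc_pos must be strictly increasing")
  pos <- c(centromere_arc_pos, foci_arc_pos)
  pos <- pos[!is.na(pos)]
  if (length(pos) && (any(pos < 0) | any(pos > L)))
    stop("arc positions must lie in [0, arc_length_px]")
  structure(list(
    control_points = control_points,
    ribbon_width = ribbon_width,
    sc_intensity = sc_intensity,
    arc_length_px = L,
    centromere_arc_pos = centromere_arc_pos,
    foci_arc_pos = foci_arc_pos,
    foci_sigma = foci_sigma,
    foci_intensity = foci_intensity,
    centromere_intensity = centromere_intensity,
    is_xy = is_xy
  ), class = "bivalent_spec")
}

#' @export
print.bivalent_spec <- function(x, ...) {
  cat(sprintf("bivalent_spec: arc length %.1f px, %d foci, width %g px%s\n",
              x$arc_length_px, length(x$foci_arc_pos), x$ribbon_width,
              if (isTRUE(x$is_xy)) " (XY)" else ""))
  invisible(x)
}

# Natural cubic spline through control points, chord-length parameterized,
# resampled at `step` px of parameter; returns the dense polyline and its
# cumulative arc length. Sub-pixel accuracy of the integrated length relies
# on the 0.25 px resampling step.
midline_spline <- function(control_points, step = 0.25) {
  d <- sqrt(rowSums(diff(control_points)^2))
  t <- c(0, cumsum(d))
  if (t[length(t)] <= 0) stop("degenerate control polygon: zero arc length")
  keep <- c(TRUE, d > 0)  # drop repeated points
  control_points <- control_points[keep, , drop = FALSE]
  t <- unique(t)
  if (nrow(control_points) == 2L) {
    fr <- stats::approxfun(t, control_points[, 1])
    fc <- stats::approxfun(t, control_points[, 2])
  } else {
    fr <- stats::splinefun(t, control_points[, 1], method = "natural")
    fc <- stats::splinefun(t, control_points[, 2], method = "natural")
  }
  tt <- seq(0, max(t), by = step)
  if (tt[length(tt)] < max(t)) tt <- c(tt, max(t))
  pts <- cbind(row = fr(tt), col = fc(tt))
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  list(points = pts, s = s, total_length = s[length(s)])
}

# Interpolate the (row, col) point at arc position `a` on a dense polyline.
point_at_arc <- function(path, a) {
  r <- stats::approx(path$s, path$points[, 1], xout = a, rule = 2)$y
  c_ <- stats::approx(path$s, path$points[, 2], xout = a, rule = 2)$y
  cbind(row = r, col = c_)
}

# Stamp value = f(distance to center) into `img` (matrix) by max-composite
# over a square window of radius `rad` around (r0, c0).
stamp_max <- function(img, r0, c0, rad, f) {
  H <- nrow(img); W <- ncol(img)
  rr <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
  cc <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
  if (!length(rr) || !length(cc)) return(img)
  d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
  v <- f(d)
  img[rr, cc] <- pmax(img[rr, cc], v)
  img
}

#' Render one bivalent into a canvas
#'
#' Draws a smooth tube of the spec's width along the midline spline into the
#' red channel, Gaussian spots at the focus arc positions into the green
#' channel, and a Gaussian spot at the centromere arc position into the blue
#' channel. All signal is composited by maximum, so overlapping bivalents do
#' not add intensities.
#'
#' @param spec a [bivalent_spec()].
#' @param canvas H x W x 3 numeric array in `[0, 1]`.
#' @param require_margin if `TRUE` (default), reject control points closer
#'   than `ribbon_width` to the canvas border.
#' @return A list with elements `canvas` (the updated array) and `truth`, a
#'   one-row data frame of realized ground truth (`arc_length_px`,
#'   `centromere_pos_px`, semicolon-delimited `foci_pos_px`, midline
#'   centroid, XY flag).
#' @export
render_bivalent <- function(spec, canvas, require_margin = TRUE) {
  stopifnot(inherits(spec, "bivalent_spec"),
            is.array(canvas), length(dim(canvas)) == 3L, dim(canvas)[3] == 3L)
  H <- dim(canvas)[1]; W <- dim(canvas)[2]
  cp <- spec$control_points
  m <- spec$ribbon_width
  if (require_margin &&
      (any(cp[, 1] < 1 + m) || any(cp[, 1] > H - m) ||
       any(cp[, 2] < 1 + m) || any(cp[, 2] > W - m)))
    stop("control points must lie inside the canvas with margin >= ribbon_width")

  path <- midline_spline(cp, step = 0.25)
  hw <- spec$ribbon_width / 2
  # soft-edged tube profile: flat core, logistic falloff at the boundary
  tube <- function(d) spec$sc_intensity / (1 + exp((d - hw) / 0.35))
  rad <- hw + 2.5
  idx <- seq(1, nrow(path$points), by = 2L)  # 0.5 px stamping stride
  red <- canvas[, , 1]
  for (i in idx) {
    red <- stamp_max(red, path$points[i, 1], path$points[i, 2], rad, tube)
  }
  canvas[, , 1] <- red

  gsig <- spec$foci_sigma
  if (length(spec$foci_arc_pos)) {
    green <- canvas[, , 2]
    amp <- spec$foci_intensity * if (isTRUE(spec$is_xy)) 0.4 else 1
    pts <- point_at_arc(path, spec$foci_arc_pos)
    for (i in seq_len(nrow(pts))) {
      green <- stamp_max(green, pts[i, 1], pts[i, 2], 3 * gsig,
                         function(d) ifelse(d <= 3 * gsig,
                                            amp * exp(-d^2 / (2 * gsig^2)), 0))
    }
    canvas[, , 2] <- green
  }
  if (!is.na(spec$centromere_arc_pos)) {
    amp <- spec$centromere_intensity * if (isTRUE(spec$is_xy)) 0.4 else 1
    p <- point_at_arc(path, spec$centromere_arc_pos)
    csig <- 2.5
    canvas[, , 3] <- stamp_max(canvas[, , 3], p[1, 1], p[1, 2], 3 * csig,
                               function(d) ifelse(d <= 3 * csig,
                                                  amp * exp(-d^2 / (2 * csig^2)), 0))
  }

  truth <- data.frame(
    arc_length_px = path$total_length,
    centromere_pos_px = spec$centromere_arc_pos,
    foci_pos_px = paste(formatC(spec$foci_arc_pos, format = "f", digits = 3),
                        collapse = ";"),
    n_foci = length(spec$foci_arc_pos),
    centroid_row = mean(path$points[, 1]),
    centroid_col = mean(path$points[, 2]),
    is_xy = isTRUE(spec$is_xy),
    stringsAsFactors = FALSE
  )
  list(canvas = canvas, truth = truth)
}

#' Specification of a synthetic spermatocyte cell
#'
#' Parameters of one rendered spread. Defaults emulate a full mouse-like
#' pachytene karyotype: 23 autosomal bivalents plus an XY body, most
#' bivalents carrying one or two MLH1 foci, a sub-metacentric centromere,
#' 10% corner-to-corner illumination gradient and mild Gaussian noise.
#'
#' @param n_bivalents number of autosomal bivalents to render.
#' @param include_xy render an additional XY body with attenuated green/blue
#'   signal.
#' @param overlap_fraction fraction of bivalents allowed to intersect another
#'   (0 = strictly non-overlapping placement).
#' @param noise_sd additive Gaussian noise SD (fraction of dynamic range).
#' @param illumination_gradient multiplicative corner-to-corner gradient
#'   amplitude (0.1 = +/-5% about the mean).
#' @param canvas_size integer vector `c(H, W)` in pixels.
#' @param seed integer seed; the same spec renders a bit-identical image.
#' @param len_range arc-length range (px) bivalent midlines are drawn from.
#' @param ribbon_width ribbon width (px).
#' @param foci_prob probabilities of 0/1/2/3 foci per bivalent.
#' @param foci_sigma rendered focus sigma (px).
#' @param n_background_foci number of spurious green spots scattered over
#'   the canvas (off-bivalent clutter for curation experiments).
#' @param salt_fraction fraction of pixels set to bright salt speckle.
#' @param curviness SD of the per-segment heading increment (radians) used
#'   when drawing random midlines; larger values give more serpentine SCs.
#'
#' @return An object of class `cell_spec`.
#' @export
cell_spec <- function(n_bivalents = 23,
                      include_xy = TRUE,
                      overlap_fraction = 0,
                      noise_sd = 0.02,
                      illumination_gradient = 0.10,
                      canvas_size = c(900, 900),
                      seed = 1L,
                      len_range = c(95, 185),
                      ribbon_width = 5,
                      foci_prob = c(`0` = 0.03, `1` = 0.70, `2` = 0.25, `3` = 0.02),
                      foci_sigma = 2,
                      n_background_foci = 0,
                      salt_fraction = 0,
                      curviness = 0.30) {
  stopifnot(n_bivalents >= 0, overlap_fraction >= 0, overlap_fraction <= 1,
            length(canvas_size) == 2L, all(canvas_size >= 64))
  stopifnot(abs(sum(foci_prob) - 1) < 1e-8)
  structure(list(
    n_bivalents = as.integer(n_bivalents),
    include_xy = isTRUE(include_xy),
    overlap_fraction = overlap_fraction,
    noise_sd = noise_sd,
    illumination_gradient = illumination_gradient,
    canvas_size = as.integer(canvas_size),
    seed = as.integer(seed),
    len_range = len_range,
    ribbon_width = ribbon_width,
    foci_prob = foci_prob,
    foci_sigma = foci_sigma,
    n_background_foci = as.integer(n_background_foci),
    salt_fraction = salt_fraction,
    curviness = curviness
  ), class = "cell_spec")
}

# Draw one random smooth midline of roughly `len` px as a heading random
# walk with 6 control points, entirely inside the margin box.
random_control_points <- function(len, H, W, margin, curviness) {
  nseg <- 5L
  step <- len / nseg
  for (try in 1:300) {
    r0 <- stats::runif(1, margin + 1, H - margin)
    c0 <- stats::runif(1, margin + 1, W - margin)
    th <- stats::runif(1, 0, 2 * pi)
    pts <- matrix(NA_real_, nseg + 1L, 2L)
    pts[1, ] <- c(r0, c0)
    ok <- TRUE
    for (k in seq_len(nseg)) {
      th <- th + stats::rnorm(1, 0, curviness)
      pts[k + 1L, ] <- pts[k, ] + step * c(sin(th), cos(th))
      if (pts[k + 1L, 1] < margin + 1 || pts[k + 1L, 1] > H - margin ||
          pts[k + 1L, 2] < margin + 1 || pts[k + 1L, 2] > W - margin) {
        ok <- FALSE; break
      }
    }
    if (ok) return(pts)
  }
  NULL
}

# Footprint of a spec's tube on a logical canvas (for overlap bookkeeping).
tube_footprint <- function(spec, H, W, dilate = 2) {
  path <- midline_spline(spec$control_points, step = 0.5)
  rad <- spec$ribbon_width / 2 + dilate
  occ <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(path$points))) {
    r0 <- path$points[i, 1]; c0 <- path$points[i, 2]
    rr <- max(1L, floor(r0 - rad)):min(H, ceiling(r0 + rad))
    cc <- max(1L, floor(c0 - rad)):min(W, ceiling(c0 + rad))
    d <- sqrt(outer((rr - r0)^2, (cc - c0)^2, `+`))
    occ[rr, cc] <- occ[rr, cc] | (d <= rad)
  }
  occ
}

# Sample focus arc positions for a bivalent of length L: single foci are
# drawn centrally (Beta(2.5, 2.5)), double foci are displaced toward the two
# ends, emulating interference-like spacing.
sample_foci_positions <- function(n_foci, L) {
  if (n_foci == 0L) return(numeric(0))
  pos <- switch(as.character(n_foci),
    "1" = stats::rbeta(1, 2.5, 2.5),
    "2" = c(stats::runif(1, 0.10, 0.40), stats::runif(1, 0.60, 0.90)),
    "3" = c(stats::runif(1, 0.08, 0.28), stats::runif(1, 0.42, 0.58),
            stats::runif(1, 0.72, 0.92)),
    stats::runif(n_foci, 0.08, 0.92))
  sort(pos) * L
}

#' Generate one synthetic spermatocyte spread
#'
#' Places `n_bivalents` random curved bivalents (plus an optional XY body)
#' on the canvas, renders them, applies an illumination gradient, Gaussian
#' noise and optional salt speckle, quantizes to 16-bit depth, and returns
#' the image together with its ground-truth manifest.
#'
#' @param spec a [cell_spec()].
#' @param cell_id character id recorded in the manifest.
#' @return A list with `image` (H x W x 3 array in `[0, 1]`, 16-bit
#'   quantized) and `manifest`, a data frame with one row per rendered
#'   bivalent (`cell_id`, `bivalent_id`, `arc_length_px`,
#'   `centromere_pos_px`, `foci_pos_px`, `overlaps`, `is_xy`, centroid).
#' @export
generate_cell <- function(spec, cell_id = "cell_001") {
  stopifnot(inherits(spec, "cell_spec"))
  set.seed(spec$seed)
  H <- spec$canvas_size[1]; W <- spec$canvas_size[2]
  canvas <- array(0, dim = c(H, W, 3))
  occupied <- matrix(FALSE, H, W)
  margin <- spec$ribbon_width + 2
  n_total <- spec$n_bivalents + as.integer(spec$include_xy)
  allow_overlap <- ceiling(spec$overlap_fraction * n_total)
  n_overlapping <- 0L
  truth <- vector("list", n_total)

  fc <- as.numeric(spec$foci_prob)
  for (b in seq_len(n_total)) {
    is_xy <- spec$include_xy && b == n_total
    placed <- FALSE
    for (try in 1:60) {
      len <- stats::runif(1, spec$len_range[1], spec$len_range[2])
      if (is_xy) len <- len * 0.6
      cp <- random_control_points(len, H, W, margin, spec$curviness)
      if (is.null(cp)) next
      bs_try <- bivalent_spec(cp, ribbon_width = spec$ribbon_width,
                              foci_sigma = spec$foci_sigma)
      fp <- tube_footprint(bs_try, H, W)
      intersects <- any(fp & occupied)
      if (intersects && n_overlapping >= allow_overlap) next
      L <- bs_try$arc_length_px
      n_foci <- if (is_xy) 1L else
        sample(0:3, 1, prob = fc)
      foci <- sample_foci_positions(n_foci, L)
      # keep foci off the very ends and >= 8 px apart
      foci <- pmin(pmax(foci, 8), L - 8)
      if (length(foci) > 1 && any(diff(foci) < 8)) next
      cen <- if (is_xy) NA_real_ else {
        u <- stats::runif(1, 0.15, 0.35)
        if (stats::runif(1) < 0.5) u <- 1 - u
        u * L
      }
      bs <- bivalent_spec(cp, ribbon_width = spec$ribbon_width,
                          centromere_arc_pos = cen, foci_arc_pos = foci,
                          foci_sigma = spec$foci_sigma, is_xy = is_xy)
      res <- render_bivalent(bs, canvas)
      canvas <- res$canvas
      row <- res$truth
      row$cell_id <- cell_id
      row$bivalent_id <- b
      row$overlaps <- intersects
      truth[[b]] <- row
      if (intersects) n_overlapping <- n_overlapping + 1L
      occupied <- occupied | fp
      placed <- TRUE
      break
    }
    if (!placed)
      stop(sprintf("could not place bivalent %d after bounded retries", b))
  }

  # spurious green clutter for curation experiments
  if (spec$n_background_foci > 0) {
    green <- canvas[, , 2]
    for (k in seq_len(spec$n_background_foci)) {
      r0 <- stats::runif(1, 5, H - 5); c0 <- stats::runif(1, 5, W - 5)
      sg <- spec$foci_sigma
      green <- stamp_max(green, r0, c0, 3 * sg,
                         function(d) ifelse(d <= 3 * sg,
                                            0.8 * exp(-d^2 / (2 * sg^2)), 0))
    }
    canvas[, , 2] <- green
  }

  # illumination gradient: multiplicative plane, corner-to-corner
  if (spec$illumination_gradient > 0) {
    g <- spec$illumination_gradient
    plane <- outer(seq(0, 1, length.out = H), seq(0, 1, length.out = W),
                   function(a, b) (a + b) / 2)
    mult <- 1 - g / 2 + g * plane
    for (ch in 1:3) canvas[, , ch] <- canvas[, , ch] * mult
  }
  if (spec$noise_sd > 0) {
    canvas <- canvas + stats::rnorm(length(canvas), 0, spec$noise_sd)
  }
  if (spec$salt_fraction > 0) {
    n_salt <- round(spec$salt_fraction * H * W)
    if (n_salt > 0) {
      ij <- cbind(sample.int(H, n_salt, TRUE), sample.int(W, n_salt, TRUE),
                  sample.int(3, n_salt, TRUE))
      canvas[ij] <- 1
    }
  }
  canvas[canvas < 0] <- 0
  canvas[canvas > 1] <- 1
  canvas <- round(canvas * 65535) / 65535  # 16-bit camera depth

  manifest <- if (n_total > 0) do.call(rbind, truth) else
    data.frame(arc_length_px = numeric(0), centromere_pos_px = numeric(0),
               foci_pos_px = character(0), n_foci = integer(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               is_xy = logical(0), cell_id = character(0),
               bivalent_id = integer(0), overlaps = logical(0))
  front <- c("cell_id", "bivalent_id", "arc_length_px", "centromere_pos_px",
             "foci_pos_px", "n_foci", "overlaps", "is_xy",
             "centroid_row", "centroid_col")
  manifest <- manifest[, front]
  list(image = canvas, manifest = manifest)
}

#' Generate a synthetic dataset on disk
#'
#' Renders `n_cells` spreads as 16-bit RGB TIFF files plus a single
#' ground-truth manifest CSV and a YAML sidecar echoing the configuration.
#' Per-cell seeds are `base_seed + cell index`, so datasets with disjoint
#' seed ranges are pixelwise distinct and the same configuration is
#' byte-reproducible.
#'
#' @param out_dir output directory (created if absent).
#' @param n_cells number of cells.
#' @param base_seed integer; cell `i` uses seed `base_seed + i`.
#' @param overwrite allow writing into an existing non-empty directory.
#' @param ... further arguments passed to [cell_spec()].
#' @return Invisibly, a list with `tiff_paths`, `manifest_path`,
#'   `config_path` and the combined `manifest` data frame.
#' @export
generate_dataset <- function(out_dir, n_cells = 10, base_seed = 1L,
                             overwrite = FALSE, ...) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("output directory exists and is not empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  extra <- list(...)
  paths <- character(n_cells)
  mans <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cid <- sprintf("cell_%03d", i)
    sp <- do.call(cell_spec, c(list(seed = base_seed + i), extra))
    cell <- generate_cell(sp, cell_id = cid)
    paths[i] <- file.path(out_dir, paste0(cid, ".tif"))
    write_image_tiff(cell$image, paths[i])
    mans[[i]] <- cell$manifest
  }
  manifest <- do.call(rbind, mans)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(format_manifest(manifest), manifest_path,
                   row.names = FALSE, quote = FALSE)
  config <- c(list(n_cells = n_cells, base_seed = base_seed), extra)
  config_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  invisible(list(tiff_paths = paths, manifest_path = manifest_path,
                 config_path = config_path, manifest = manifest))
}

# Fixed-precision manifest formatting keeps on-disk output byte-stable.
format_manifest <- function(m) {
  num <- c("arc_length_px", "centromere_pos_px", "centroid_row", "centroid_col")
  for (nm in num) m[[nm]] <- formatC(m[[nm]], format = "f", digits = 3)
  m
}

#' Read a ground-truth manifest CSV
#' @param path manifest file written by [generate_dataset()].
#' @return Data frame with numeric positions; `foci_pos_px` stays a
#'   semicolon-delimited string (see [parse_foci_string()]).
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(foci_pos_px = "character"))
  m$centromere_pos_px <- suppressWarnings(as.numeric(m$centromere_pos_px))
  m
}

#' Parse a semicolon-delimited focus-position string
#' @param s character vector like `"30.000;90.000"`.
#' @return List of numeric vectors.
#' @export
parse_foci_string <- function(s) {
  lapply(strsplit(as.character(s), ";", fixed = TRUE), function(x) {
    x <- x[nzchar(x)]
    as.numeric(x)
  })
}

#' Write a 3-channel image as 16-bit TIFF
#' @param img H x W x 3 array in `[0, 1]`.
#' @param path output file.
#' @export
write_image_tiff <- function(img, path) {
  tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a 3-channel TIFF image
#' @param path TIFF file; must have 3 channels (RGB order:
#'   SYCP3/MLH1/CREST).
#' @return H x W x 3 numeric array in `[0, 1]`.
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) != 3L || dim(img)[3] < 3L)
    stop("expected a 3-channel image: ", path)
  img[, , 1:3, drop = FALSE]
}
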