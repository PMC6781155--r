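# Segmentation of candidate chromosome objects from the SYCP3 (red) channel.
#
# Candidate objects are connected components of the thresholded, cleaned red
# mask. Each object is measured (area, skeleton length, eccentricity,
# solidity, branch points) and classified against range heuristics that
# capture the elongated shape of a single pachytene bivalent; merged
# bivalents show up as branched skeletons and fail.

#' Segmentation parameters
#'
#' @param threshold_offset additive offset applied to the Otsu threshold of
#'   the red channel.
#' @param min_area,max_area object area bounds (px^2).
#' @param min_skeleton,max_skeleton pruned-skeleton longest-path bounds (px).
#' @param min_eccentricity minimum moment eccentricity (elongation).
#' @param min_solidity minimum area / convex-hull-area ratio.
#' @param max_branch_points maximum branch points in the pruned skeleton
#'   (0 = strictly unbranched; merged bivalents are branched).
#' @param border_margin objects whose bounding box comes within this margin
#'   of the image border fail.
#' @param spur_px skeleton spurs shorter than this are pruned before
#'   branch-point counting.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_offset = 0,
                                min_area = 150, max_area = 6000,
                                min_skeleton = 30, max_skeleton = 400,
                                min_eccentricity = 0.85,
                                min_solidity = 0.25,
                                max_branch_points = 0,
                                border_margin = 3,
                                spur_px = 5) {
  stopifnot(min_area < max_area, min_skeleton < max_skeleton)
  structure(list(threshold_offset = threshold_offset,
                 min_area = min_area, max_area = max_area,
                 min_skeleton = min_skeleton, max_skeleton = max_skeleton,
                 min_eccentricity = min_eccentricity,
                 min_solidity = min_solidity,
                 max_branch_points = max_branch_points,
                 border_margin = border_margin,
                 spur_px = spur_px),
            class = "segmentation_params")
}

#' Preprocess a three-channel image
#'
#' Per channel: estimate the smooth background as a plane fitted to
#' block-minimum samples, subtract it, clamp at zero, and rescale so the
#' maximum is 1. Removes constant offsets and linear illumination gradients;
#' idempotent on its own output.
#'
#' @param img H x W x 3 numeric array.
#' @param block block size (px) for background sampling.
#' @return Array of the same shape, each channel in `[0, 1]`.
#' @export
preprocess <- function(img, block = 16L) {
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected a 3-channel image")
  for (ch in 1:3) img[, , ch] <- remove_background_plane(img[, , ch], block)
  img
}

remove_background_plane <- function(x, block = 16L) {
  H <- nrow(x); W <- ncol(x)
  ri <- split(seq_len(H), ceiling(seq_len(H) / block))
  ci <- split(seq_len(W), ceiling(seq_len(W) / block))
  samp <- expand.grid(bi = seq_along(ri), bj = seq_along(ci))
  samp$r <- vapply(ri, mean, 0)[samp$bi]
  samp$c <- vapply(ci, mean, 0)[samp$bj]
  samp$z <- mapply(function(i, j) min(x[ri[[i]], ci[[j]]]), samp$bi, samp$bj)
  fit <- stats::lm(z ~ r + c, data = samp)
  co <- stats::coef(fit)
  plane <- co[1] + co[2] * matrix(seq_len(H), H, W) +
    co[3] * matrix(seq_len(W), H, W, byrow = TRUE)
  y <- x - plane
  y[y < 0] <- 0
  mx <- max(y)
  if (mx > 0) y <- y / mx
  y
}

#' Detect candidate chromosome objects in the red channel
#'
#' Thresholds the preprocessed SYCP3 channel (Otsu plus an offset), bridges
#' 1-px staining gaps by morphological closing, fills holes, labels
#' connected components, and measures shape features per object. Objects are
#' enumerated row-major by bounding-box origin so indices are reproducible.
#'
#' @param sc_channel preprocessed red-channel matrix in `[0, 1]`.
#' @param params a [segmentation_params()].
#' @return An object of class `sc_objects`: list with `labels` (integer
#'   matrix, 0 = background, values = object_index) and `objects`, a data
#'   frame of per-object features (`object_index`, bbox, `area_px`,
#'   `skeleton_length_px`, `eccentricity`, `solidity`, `branch_points`,
#'   `touches_border`, centroid).
#' @export
detect_objects <- function(sc_channel, params = segmentation_params()) {
  stopifnot(is.matrix(sc_channel))
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(sc_channel), ncol(sc_channel)),
                   objects = data.frame(object_index = integer(0)),
                   skeletons = list()),
              class = "sc_objects")
  }
  if (max(sc_channel) <= 0) return(empty())
  thr <- EBImage::otsu(EBImage::Image(sc_channel), range = c(0, 1)) +
    params$threshold_offset
  mask <- EBImage::Image(sc_channel > thr)
  mask <- EBImage::closing(mask, EBImage::makeBrush(3, shape = "disc"))
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  labm <- as.integer(EBImage::imageData(lab))
  dim(labm) <- dim(sc_channel)
  n <- max(labm)
  if (n == 0) return(empty())

  H <- nrow(labm); W <- ncol(labm)
  feats <- vector("list", n)
  skels <- vector("list", n)
  for (k in seq_len(n)) {
    idx <- which(labm == k)
    rr <- ((idx - 1L) %% H) + 1L
    cc <- ((idx - 1L) %/% H) + 1L
    area <- length(idx)
    bbox <- c(rmin = min(rr), rmax = max(rr), cmin = min(cc), cmax = max(cc))
    touches <- bbox["rmin"] <= params$border_margin ||
      bbox["cmin"] <= params$border_margin ||
      bbox["rmax"] > H - params$border_margin ||
      bbox["cmax"] > W - params$border_margin
    ecc <- moment_eccentricity(rr, cc)
    sol <- mask_solidity(rr, cc)
    skl <- NA_real_; nbp <- NA_integer_
    skel_px <- NULL
    if (area >= params$min_area * 0.3 && area <= params$max_area * 2) {
      crop <- matrix(FALSE, bbox["rmax"] - bbox["rmin"] + 3L,
                     bbox["cmax"] - bbox["cmin"] + 3L)
      crop[cbind(rr - bbox["rmin"] + 2L, cc - bbox["cmin"] + 2L)] <- TRUE
      sk <- skeleton_graph(crop, spur_px = params$spur_px)
      if (!is.null(sk)) {
        skl <- sk$longest_path_length
        nbp <- sk$n_branch_points
        skel_px <- list(offset = c(bbox["rmin"] - 2L, bbox["cmin"] - 2L),
                        graph = sk)
      }
    }
    feats[[k]] <- data.frame(label = k,
                             rmin = bbox[["rmin"]], rmax = bbox[["rmax"]],
                             cmin = bbox[["cmin"]], cmax = bbox[["cmax"]],
                             area_px = area,
                             skeleton_length_px = skl,
                             eccentricity = ecc, solidity = sol,
                             branch_points = nbp,
                             touches_border = touches,
                             centroid_row = mean(rr), centroid_col = mean(cc))
    skels[[k]] <- skel_px
  }
  objects <- do.call(rbind, feats)
  ord <- order(objects$rmin, objects$cmin, objects$label)
  objects <- objects[ord, , drop = FALSE]
  objects$object_index <- seq_len(nrow(objects))
  # relabel the label matrix to the reproducible row-major indices
  relab <- integer(n)
  relab[objects$label] <- objects$object_index
  labm[labm > 0] <- relab[labm[labm > 0]]
  skels <- skels[ord]
  rownames(objects) <- NULL
  objects <- objects[, c("object_index", setdiff(names(objects), c("object_index", "label")))]
  structure(list(labels = labm, objects = objects, skeletons = skels),
            class = "sc_objects")
}

# Moment (ellipse) eccentricity from pixel coordinates.
moment_eccentricity <- function(rr, cc) {
  if (length(rr) < 3) return(0)
  mrr <- stats::var(rr) * (length(rr) - 1) / length(rr)
  mcc <- stats::var(cc) * (length(cc) - 1) / length(cc)
  mrc <- mean((rr - mean(rr)) * (cc - mean(cc)))
  tr <- mrr + mcc
  det <- mrr * mcc - mrc^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

# Area / convex-hull-area ratio.
mask_solidity <- function(rr, cc) {
  if (length(rr) < 3) return(1)
  pts <- unique(cbind(rr, cc))
  if (nrow(pts) < 3) return(1)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  a <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                 hp[, 2] * c(hp[-1, 1], hp[1, 1]))) / 2
  if (a <= 0) return(1)
  min(1, length(rr) / a)
}

#' Classify a candidate object against the bivalent heuristics
#'
#' Checks are applied in a fixed, documented order and the first violated
#' criterion is reported: `area_min`, `area_max`, `skeleton_min`,
#' `skeleton_max`, `branch_points`, `eccentricity`, `solidity`, `border`.
#' Branching is checked before the shape criteria so that merged bivalents
#' (whose skeletons branch) are reported as such rather than as oddly
#' shaped. The verdict is a pure function of the feature row.
#'
#' @param obj one-row data frame of features as produced by
#'   [detect_objects()].
#' @param params a [segmentation_params()].
#' @return List with `pass` (logical) and `reason` (`NA` if passing, else
#'   the first failing criterion name).
#' @export
classify_bivalent <- function(obj, params = segmentation_params()) {
  checks <- list(
    area_min = obj$area_px >= params$min_area,
    area_max = obj$area_px <= params$max_area,
    skeleton_min = !is.na(obj$skeleton_length_px) &&
      obj$skeleton_length_px >= params$min_skeleton,
    skeleton_max = !is.na(obj$skeleton_length_px) &&
      obj$skeleton_length_px <= params$max_skeleton,
    branch_points = !is.na(obj$branch_points) &&
      obj$branch_points <= params$max_branch_points,
    eccentricity = obj$eccentricity >= params$min_eccentricity,
    solidity = obj$solidity >= params$min_solidity,
    border = !obj$touches_border
  )
  bad <- which(!vapply(checks, isTRUE, TRUE))
  if (length(bad) == 0) list(pass = TRUE, reason = NA_character_)
  else list(pass = FALSE, reason = names(checks)[bad[1]])
}

#' Classify all objects of a cell
#' @param objs an `sc_objects` result.
#' @param params a [segmentation_params()].
#' @return The feature data frame with `pass` and `fail_reason` columns.
#' @export
classify_objects <- function(objs, params = segmentation_params()) {
  df <- objs$objects
  if (nrow(df) == 0) {
    df$pass <- logical(0); df$fail_reason <- character(0)
    return(df)
  }
  res <- lapply(seq_len(nrow(df)), function(i)
    classify_bivalent(df[i, , drop = FALSE], params))
  df$pass <- vapply(res, `[[`, TRUE, "pass")
  df$fail_reason <- vapply(res, `[[`, "", "reason")
  df
}

# 3 x 5 bitmap digits for overlay index labels.
.digit_font <- local({
  rows <- list(
    "0" = c("111", "101", "101", "101", "111"),
    "1" = c("010", "110", "010", "010", "111"),
    "2" = c("111", "001", "111", "100", "111"),
    "3" = c("111", "001", "111", "001", "111"),
    "4" = c("101", "101", "111", "001", "001"),
    "5" = c("111", "100", "111", "001", "111"),
    "6" = c("111", "100", "111", "101", "111"),
    "7" = c("111", "001", "010", "010", "010"),
    "8" = c("111", "101", "111", "101", "111"),
    "9" = c("111", "101", "111", "001", "111"))
  lapply(rows, function(r)
    do.call(rbind, lapply(r, function(s) as.integer(strsplit(s, "")[[1]]) == 1)))
})

draw_digits <- function(channel, text, r0, c0, scale = 2) {
  H <- nrow(channel); W <- ncol(channel)
  cpos <- c0
  for (ch in strsplit(text, "")[[1]]) {
    glyph <- .digit_font[[ch]]
    if (is.null(glyph)) next
    g <- glyph[rep(seq_len(5), each = scale), rep(seq_len(3), each = scale)]
    rr <- r0:(r0 + nrow(g) - 1); cc <- cpos:(cpos + ncol(g) - 1)
    ok_r <- rr >= 1 & rr <= H; ok_c <- cc >= 1 & cc <= W
    sub <- channel[rr[ok_r], cc[ok_c], drop = FALSE]
    sub[g[ok_r, ok_c, drop = FALSE]] <- 1
    channel[rr[ok_r], cc[ok_c]] <- sub
    cpos <- cpos + ncol(g) + scale
  }
  channel
}

#' Annotate an image with detection boxes and indices
#'
#' Draws a box around every detected object and an index label at objects
#' that pass the bivalent heuristics, mirroring the whole-cell overlay
#' output of the measurement tool.
#'
#' @param img H x W x 3 array (the original image).
#' @param classified data frame from [classify_objects()].
#' @return Overlay array of the same dimensions, with attributes `n_boxes`
#'   and `labels_drawn` (the object indices that received labels).
#' @export
annotate_overlay <- function(img, classified) {
  out <- img
  if (nrow(classified) == 0) {
    attr(out, "n_boxes") <- 0L
    attr(out, "labels_drawn") <- integer(0)
    return(out)
  }
  H <- dim(img)[1]; W <- dim(img)[2]
  red <- out[, , 1]; green <- out[, , 2]; blue <- out[, , 3]
  for (i in seq_len(nrow(classified))) {
    o <- classified[i, ]
    rmin <- max(1, o$rmin - 2); rmax <- min(H, o$rmax + 2)
    cmin <- max(1, o$cmin - 2); cmax <- min(W, o$cmax + 2)
    red[c(rmin, rmax), cmin:cmax] <- 1
    red[rmin:rmax, c(cmin, cmax)] <- 1
    green[c(rmin, rmax), cmin:cmax] <- 0.3
    blue[c(rmin, rmax), cmin:cmax] <- 0.3
  }
  drawn <- integer(0)
  for (i in seq_len(nrow(classified))) {
    o <- classified[i, ]
    if (!isTRUE(o$pass)) next
    r0 <- max(1, o$rmin - 14); c0 <- max(1, o$cmin)
    lab <- as.character(o$object_index)
    red <- draw_digits(red, lab, r0, c0)
    green <- draw_digits(green, lab, r0, c0)
    blue <- draw_digits(blue, lab, r0, c0)
    drawn <- c(drawn, o$object_index)
  }
  out[, , 1] <- red; out[, , 2] <- green; out[, , 3] <- blue
  attr(out, "n_boxes") <- nrow(classified)
  attr(out, "labels_drawn") <- drawn
  out
}
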