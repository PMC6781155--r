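# Whole-image measurement: segmentation -> midline -> foci/centromere.

#' Measure all passing bivalents in a three-channel image
#'
#' Runs the full single-image pipeline: preprocessing, red-channel object
#' detection, bivalent classification, midline extraction, SC length, MLH1
#' focus and centromere localization, and orientation/normalization.
#' Background statistics for focus detection are computed outside a dilated
#' union of all detected objects.
#'
#' @param img H x W x 3 array (red = SYCP3, green = MLH1, blue = CREST).
#' @param cell_id id recorded in the output rows.
#' @param seg_params a [segmentation_params()].
#' @param mid_params a [midline_params()].
#' @param foc_params a [foci_params()].
#' @param half_width ribbon half-width (px) for focus/centromere search and
#'   for straightened renderings.
#' @param keep_straightened if `TRUE`, straightened ribbons of passing
#'   bivalents are returned in the `straightened` list.
#' @return List of class `cell_measurement`:
#'   `measurements` (data frame, one row per passing bivalent:
#'   `cell_id`, `object_index`, `sc_length_px`, `sc_length_um`,
#'   `centromere_pos_px`, `centromere_pos_norm`, `foci_pos_px`
#'   (semicolon string), `foci_pos_norm` (semicolon string), `n_foci`,
#'   `foci_max_offset_px`, `branch_points`, `skeleton_length_px`,
#'   `centroid_row`, `centroid_col`, `flags`),
#'   `objects` (classified feature table), `labels`, `background`, and
#'   optionally `straightened`.
#' @export
measure_image <- function(img, cell_id = "cell",
                          seg_params = segmentation_params(),
                          mid_params = midline_params(),
                          foc_params = foci_params(),
                          half_width = 5,
                          keep_straightened = FALSE) {
  pre <- preprocess(img)
  objs <- detect_objects(pre[, , 1], seg_params)
  cls <- classify_objects(objs, seg_params)

  # background statistics outside a dilated union of all objects
  obj_mask <- objs$labels > 0
  if (any(obj_mask)) {
    dil <- EBImage::dilate(EBImage::Image(obj_mask * 1),
                           EBImage::makeBrush(7, shape = "disc"))
    bgpix <- as.array(dil) == 0
  } else {
    bgpix <- !obj_mask
  }
  bg_green <- list(mean = mean(pre[, , 2][bgpix]), sd = stats::sd(pre[, , 2][bgpix]))
  bg_blue <- list(mean = mean(pre[, , 3][bgpix]), sd = stats::sd(pre[, , 3][bgpix]))

  passing <- cls[cls$pass, , drop = FALSE]
  rows <- list()
  straightened <- list()
  for (i in seq_len(nrow(passing))) {
    o <- passing[i, ]
    mask <- objs$labels == o$object_index
    # reuse the skeleton graph computed during feature extraction
    sk <- objs$skeletons[[o$object_index]]
    graph <- if (!is.null(sk)) translate_skeleton(sk$graph, sk$offset)
    ml <- tryCatch(extract_midline(mask, mid_params, graph = graph),
                   error = function(e) NULL)
    if (is.null(ml)) {
      rows[[length(rows) + 1L]] <- measurement_row(
        cell_id, o, sc_px = NA_real_, sc_um = NA_real_,
        cen = list(arc_pos_px = NA_real_, flags = "degenerate_skeleton"),
        foci = empty_foci(), norm = NULL, px_per_um = mid_params$px_per_um)
      next
    }
    foci <- detect_foci(pre[, , 2], ml, half_width, bg_green, foc_params)
    cen <- locate_centromere(pre[, , 3], ml, half_width, bg_blue, foc_params)
    raw <- list(sc_length_px = ml$total_length_px,
                centromere_pos_px = cen$arc_pos_px,
                foci_pos_px = foci$arc_pos_px,
                flags = cen$flags)
    norm <- orient_and_normalize(raw)
    rows[[length(rows) + 1L]] <- measurement_row(
      cell_id, o, sc_px = ml$total_length_px,
      sc_um = ml$total_length_um, cen = cen, foci = foci, norm = norm,
      px_per_um = mid_params$px_per_um)
    if (keep_straightened)
      straightened[[as.character(o$object_index)]] <-
        straighten(pre, ml, half_width = half_width + 3)
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else
    empty_measurements()
  structure(list(measurements = measurements, objects = cls,
                 labels = objs$labels,
                 background = list(green = bg_green, blue = bg_blue),
                 straightened = if (keep_straightened) straightened),
            class = "cell_measurement")
}

measurement_row <- function(cell_id, o, sc_px, sc_um, cen, foci, norm,
                            px_per_um) {
  flags <- cen$flags
  if (is.null(norm)) {
    data.frame(cell_id = cell_id, object_index = o$object_index,
               sc_length_px = sc_px, sc_length_um = sc_um,
               centromere_pos_px = NA_real_, centromere_pos_norm = NA_real_,
               foci_pos_px = "", foci_pos_norm = "", n_foci = 0L,
               foci_max_offset_px = NA_real_,
               branch_points = o$branch_points,
               skeleton_length_px = o$skeleton_length_px,
               centroid_row = o$centroid_row, centroid_col = o$centroid_col,
               flags = paste(flags, collapse = "|"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(cell_id = cell_id, object_index = o$object_index,
               sc_length_px = sc_px, sc_length_um = sc_um,
               centromere_pos_px = norm$centromere_pos_px,
               centromere_pos_norm = norm$centromere_pos_norm,
               foci_pos_px = paste(formatC(norm$foci_pos_px, format = "f",
                                           digits = 3), collapse = ";"),
               foci_pos_norm = paste(formatC(norm$foci_pos_norm, format = "f",
                                             digits = 5), collapse = ";"),
               n_foci = norm$n_foci,
               foci_max_offset_px = if (nrow(foci)) max(abs(foci$offset_px)) else NA_real_,
               branch_points = o$branch_points,
               skeleton_length_px = o$skeleton_length_px,
               centroid_row = o$centroid_row, centroid_col = o$centroid_col,
               flags = paste(flags, collapse = "|"),
               stringsAsFactors = FALSE)
  }
}

# shift crop-frame skeleton coordinates into the full-image frame
translate_skeleton <- function(g, offset) {
  if (is.null(g)) return(NULL)
  shift <- function(m) {
    if (is.null(m)) return(NULL)
    m[, 1] <- m[, 1] + offset[1]
    m[, 2] <- m[, 2] + offset[2]
    m
  }
  g$coords <- shift(g$coords)
  g$path_coords <- shift(g$path_coords)
  g
}

empty_measurements <- function() {
  data.frame(cell_id = character(0), object_index = integer(0),
             sc_length_px = numeric(0), sc_length_um = numeric(0),
             centromere_pos_px = numeric(0), centromere_pos_norm = numeric(0),
             foci_pos_px = character(0), foci_pos_norm = character(0),
             n_foci = integer(0), foci_max_offset_px = numeric(0),
             branch_points = integer(0), skeleton_length_px = numeric(0),
             centroid_row = numeric(0), centroid_col = numeric(0),
             flags = character(0), stringsAsFactors = FALSE)
}

#' Match automated measurements to a ground-truth manifest
#'
#' Assigns each measured object the `bivalent_id` of the nearest manifest
#' bivalent of the same cell (by midline centroid), greedily and uniquely,
#' within a distance cap.
#'
#' @param measurements measurement data frame with `centroid_row/col`.
#' @param manifest data frame from [read_manifest()] or
#'   [generate_dataset()].
#' @param max_dist maximum centroid distance (px) for a valid match.
#' @return `measurements` with a `bivalent_id` column (`NA` = unmatched).
#' @export
match_to_manifest <- function(measurements, manifest, max_dist = 30) {
  measurements$bivalent_id <- NA_integer_
  for (cid in unique(measurements$cell_id)) {
    mi <- which(measurements$cell_id == cid)
    ti <- which(manifest$cell_id == cid)
    if (!length(ti)) next
    d <- outer(seq_along(mi), seq_along(ti), function(a, b) {
      sqrt((measurements$centroid_row[mi[a]] - manifest$centroid_row[ti[b]])^2 +
             (measurements$centroid_col[mi[a]] - manifest$centroid_col[ti[b]])^2)
    })
    while (TRUE) {
      j <- which(d == min(d), arr.ind = TRUE)[1, , drop = TRUE]
      if (!is.finite(d[j[1], j[2]]) || d[j[1], j[2]] > max_dist) break
      measurements$bivalent_id[mi[j[1]]] <- manifest$bivalent_id[ti[j[2]]]
      d[j[1], ] <- Inf
      d[, j[2]] <- Inf
      if (all(!is.finite(d))) break
    }
  }
  measurements
}
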