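# MLH1 focus and centromere localization along the midline.
#
# Foci are local maxima of the green (MLH1) channel that rise above the
# background by a configurable number of SDs and sit centered within the
# ribbon around the midline; each is projected to its arc-length coordinate.
# The centromere is the brightest in-ribbon blue (CREST) maximum. After
# measurement, each bivalent is oriented so that the centromere-proximal
# end is at arc coordinate 0 (normalized centromere position <= 0.5).

#' Focus/centromere detection parameters
#'
#' @param k_sd detection threshold is `background mean + k_sd * background
#'   SD`. Background statistics are computed outside all object masks; the
#'   default is set for a profile that takes the maximum across the ribbon
#'   width, which inflates the background tail relative to single pixels.
#' @param min_separation local maxima closer than this along the arc (px)
#'   are merged to their intensity-weighted centroid.
#' @param centrality_frac a peak only counts as an in-SC focus if its
#'   perpendicular offset is at most `centrality_frac * half_width`.
#' @param tie_tol intensity difference below which two centromere maxima
#'   are considered tied.
#' @return List of class `foci_params`.
#' @export
foci_params <- function(k_sd = 6, min_separation = 5,
                        centrality_frac = 0.75, tie_tol = 1e-3) {
  structure(list(k_sd = k_sd, min_separation = min_separation,
                 centrality_frac = centrality_frac, tie_tol = tie_tol),
            class = "foci_params")
}

# Column-wise peak profile of a straightened ribbon: per arc sample, the
# maximum intensity across the ribbon width and its perpendicular offset.
ribbon_profile <- function(channel, midline, half_width) {
  rib <- straighten(channel, midline, half_width = half_width)
  peak <- apply(rib, 2, max)
  off <- apply(rib, 2, which.max) - (half_width + 1)
  list(peak = peak, offset = off)
}

#' Detect MLH1 foci along a midline
#'
#' @param green_channel preprocessed green-channel matrix.
#' @param midline a [extract_midline()] result.
#' @param half_width ribbon half-width (px) within which a focus must sit.
#' @param background list with `mean` and `sd` of the green background
#'   (computed outside all object masks).
#' @param params a [foci_params()].
#' @return Data frame with one row per accepted focus: `arc_pos_px`
#'   (sub-pixel, parabolic refinement), `offset_px`, `intensity`.
#' @export
detect_foci <- function(green_channel, midline, half_width = 5,
                        background = list(mean = 0, sd = 0),
                        params = foci_params()) {
  prof <- ribbon_profile(green_channel, midline, half_width)
  y <- prof$peak
  m <- length(y)
  thr <- background$mean + params$k_sd * background$sd
  if (m < 3) return(empty_foci())
  is_max <- c(FALSE, y[2:(m - 1)] >= y[1:(m - 2)] & y[2:(m - 1)] > y[3:m],
              FALSE) & y > thr
  central <- abs(prof$offset) <= params$centrality_frac * half_width
  cand <- which(is_max & central)
  if (length(cand) == 0) return(empty_foci())

  step <- midline$step
  pos <- (cand - 1) * step
  # sub-pixel parabolic refinement of each peak
  for (i in seq_along(cand)) {
    j <- cand[i]
    if (j > 1 && j < m) {
      den <- y[j - 1] - 2 * y[j] + y[j + 1]
      if (den < 0) {
        delta <- 0.5 * (y[j - 1] - y[j + 1]) / den
        pos[i] <- pos[i] + max(-1, min(1, delta)) * step
      }
    }
  }
  inten <- y[cand]
  off <- prof$offset[cand]
  # merge peaks closer than min_separation along the arc
  ord <- order(pos)
  pos <- pos[ord]; inten <- inten[ord]; off <- off[ord]
  groups <- cumsum(c(1, diff(pos) >= params$min_separation))
  agg <- lapply(split(seq_along(pos), groups), function(ix) {
    w <- inten[ix] / sum(inten[ix])
    data.frame(arc_pos_px = sum(pos[ix] * w),
               offset_px = off[ix][which.max(inten[ix])],
               intensity = max(inten[ix]))
  })
  out <- do.call(rbind, agg)
  out$arc_pos_px <- pmin(pmax(out$arc_pos_px, 0), midline$total_length_px)
  rownames(out) <- NULL
  out
}

empty_foci <- function() {
  data.frame(arc_pos_px = numeric(0), offset_px = numeric(0),
             intensity = numeric(0))
}

#' Locate the centromere along a midline
#'
#' Arc position of the brightest in-ribbon blue maximum. If no blue signal
#' rises above background the position is missing and flagged; if two
#' maxima tie within `tie_tol`, the one nearer to an end of the SC is
#' chosen and the measurement is flagged ambiguous.
#'
#' @inheritParams detect_foci
#' @param blue_channel preprocessed blue-channel matrix.
#' @return List with `arc_pos_px` (may be `NA`) and `flags` (character
#'   vector, possibly empty; `no_centromere` or `ambiguous_centromere`).
#' @export
locate_centromere <- function(blue_channel, midline, half_width = 5,
                              background = list(mean = 0, sd = 0),
                              params = foci_params()) {
  prof <- ribbon_profile(blue_channel, midline, half_width)
  y <- prof$peak
  central <- abs(prof$offset) <= params$centrality_frac * half_width
  y[!central] <- -Inf
  thr <- background$mean + params$k_sd * background$sd
  top <- max(y)
  if (!is.finite(top) || top <= thr)
    return(list(arc_pos_px = NA_real_, flags = "no_centromere"))
  step <- midline$step
  L <- midline$total_length_px
  tied <- which(y >= top - params$tie_tol)
  pos <- (tied - 1) * step
  flags <- character(0)
  if (diff(range(pos)) > params$min_separation) {
    # distinct tied maxima: documented tie-break, nearer-to-end wins
    end_dist <- pmin(pos, L - pos)
    pos <- pos[which.min(end_dist)]
    flags <- "ambiguous_centromere"
  } else {
    pos <- pos[which.max(y[tied])]
  }
  list(arc_pos_px = pos, flags = flags)
}

#' Orient a bivalent measurement and normalize positions
#'
#' Reflects all arc positions (`x -> L - x`) when the centromere lies in
#' the distal half, so that after orientation the centromere-proximal end
#' is at coordinate 0 and the normalized centromere position is <= 0.5.
#' Foci are sorted ascending, i.e. by proximity to the centromere end.
#' Reflection is an involution: orienting twice equals orienting once. A
#' measurement without a centromere is returned unoriented with its flag
#' retained.
#'
#' @param m list with at least `sc_length_px`, `centromere_pos_px`,
#'   `foci_pos_px` (numeric vector), and optionally `flags`.
#' @return The measurement with `centromere_pos_norm`, `foci_pos_norm`,
#'   `n_foci` and `oriented` fields added.
#' @export
orient_and_normalize <- function(m) {
  L <- m$sc_length_px
  if (!is.numeric(L) || is.na(L) || L <= 0) stop("sc_length_px must be > 0")
  m$foci_pos_px <- sort(as.numeric(m$foci_pos_px))
  if (is.na(m$centromere_pos_px)) {
    m$oriented <- FALSE
    m$centromere_pos_norm <- NA_real_
  } else {
    if (m$centromere_pos_px > L / 2) {
      m$centromere_pos_px <- L - m$centromere_pos_px
      m$foci_pos_px <- sort(L - m$foci_pos_px)
    }
    m$oriented <- TRUE
    m$centromere_pos_norm <- m$centromere_pos_px / L
  }
  m$foci_pos_norm <- m$foci_pos_px / L
  m$n_foci <- length(m$foci_pos_px)
  m
}

#' Assemble a per-cell record
#'
#' Tallies per-spermatocyte quality-control fields the way cells are scored
#' at the microscope: total MLH1 count over scored bivalents, number of
#' focus-free bivalents, asynapsis count, a 1-5 quality score (1 = high),
#' and XY pairing / pseudo-autosomal focus flags.
#'
#' @param measurements data frame of bivalent measurements sharing one
#'   `cell_id`, with an `n_foci` column (XY rows, if present, are excluded
#'   from the MLH1 tally).
#' @param quality integer quality score in 1..5.
#' @param n_asynapsis_bivalents count of bivalents with signs of asynapsis.
#' @param xy_paired,par_focus logical QC flags.
#' @param mouse_id optional mouse label.
#' @return One-row data frame (`CellRecord`).
#' @export
assemble_cell_record <- function(measurements, quality = 1L,
                                 n_asynapsis_bivalents = 0L,
                                 xy_paired = TRUE, par_focus = FALSE,
                                 mouse_id = NA_character_) {
  if (!is.numeric(quality) || length(quality) != 1 ||
      !(quality %in% 1:5))
    stop("quality must be an integer in 1..5")
  cid <- unique(measurements$cell_id)
  if (length(cid) != 1) stop("measurements must share a single cell_id")
  scored <- measurements
  if ("is_xy" %in% names(scored)) scored <- scored[!scored$is_xy, , drop = FALSE]
  data.frame(mouse_id = mouse_id, cell_id = cid,
             mlh1_total = sum(scored$n_foci),
             n_zero_foci_bivalents = sum(scored$n_foci == 0),
             n_asynapsis_bivalents = as.integer(n_asynapsis_bivalents),
             quality = as.integer(quality),
             xy_paired = isTRUE(xy_paired),
             par_focus = isTRUE(par_focus),
             stringsAsFactors = FALSE)
}
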