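# Rule-based curation: diagnose measurement errors, isolate chromosome 1,
# and quantify automated-vs-reference accuracy.
#
# The dominant failure modes of automated single-bivalent measurement are
# incorrectly merged bivalents (two SCs crossing or touching measured as
# one, visible as branched or over-long skeletons) and extra foci (clutter
# detected as MLH1 signal). Both are diagnosable from the output tables
# alone, which makes curation reproducible and non-interactive.

#' Curation parameters
#'
#' @param max_foci bivalents with more detected foci than this are flagged
#'   `extra_foci` (flagging, never silent truncation).
#' @param offset_frac foci whose perpendicular offset exceeds
#'   `offset_frac * half_width` fail the centrality re-check and flag the
#'   bivalent `extra_foci`.
#' @param half_width ribbon half-width used at measurement time (px).
#' @param length_mad_k a bivalent whose skeleton length exceeds the cell
#'   median by more than `length_mad_k` MADs is flagged `merged_bivalent`
#'   (requires >= `min_cell_n` measured bivalents in the cell).
#' @param min_cell_n minimum bivalents per cell for the robust length bound.
#' @param min_skeleton_px bivalents with shorter skeletons are flagged
#'   `short_skeleton`.
#' @return List of class `curation_params`.
#' @export
curation_params <- function(max_foci = 4, offset_frac = 0.6, half_width = 5,
                            length_mad_k = 3.5, min_cell_n = 5,
                            min_skeleton_px = 30) {
  structure(list(max_foci = max_foci, offset_frac = offset_frac,
                 half_width = half_width, length_mad_k = length_mad_k,
                 min_cell_n = min_cell_n, min_skeleton_px = min_skeleton_px),
            class = "curation_params")
}

#' Diagnose measurement errors
#'
#' Deterministic per-bivalent error flags, evaluated against the other
#' measurements of the same cell:
#' `merged_bivalent` (branched skeleton, or skeleton length beyond the
#' cell's robust upper bound), `extra_foci` (focus count above `max_foci`,
#' or a focus failing the centrality re-check), `short_skeleton`,
#' `ambiguous_centromere` / `no_centromere` (carried from measurement), and
#' `manual_reject` (from an optional reject list).
#'
#' @param measurements measurement data frame (one or more cells).
#' @param params a [curation_params()].
#' @param reject_list optional data frame with `cell_id` and either
#'   `object_index` or `bivalent_id` columns; listed rows are flagged
#'   `manual_reject`.
#' @return The input with logical flag columns `merged_bivalent`,
#'   `extra_foci`, `short_skeleton`, `ambiguous_centromere`,
#'   `no_centromere`, `manual_reject` and a summary `curated_ok` column
#'   (`TRUE` = no flag set).
#' @export
diagnose <- function(measurements, params = curation_params(),
                     reject_list = NULL) {
  m <- measurements
  n <- nrow(m)
  m$merged_bivalent <- !is.na(m$branch_points) & m$branch_points > 0
  for (cid in unique(m$cell_id)) {
    ix <- which(m$cell_id == cid)
    len <- m$skeleton_length_px[ix]
    if (sum(!is.na(len)) >= params$min_cell_n) {
      med <- stats::median(len, na.rm = TRUE)
      mad <- stats::mad(len, na.rm = TRUE)
      bound <- med + params$length_mad_k * max(mad, 1)
      m$merged_bivalent[ix] <- m$merged_bivalent[ix] |
        (!is.na(len) & len > bound)
    }
  }
  off_bound <- params$offset_frac * params$half_width
  m$extra_foci <- (!is.na(m$n_foci) & m$n_foci > params$max_foci) |
    (!is.na(m$foci_max_offset_px) & m$foci_max_offset_px > off_bound)
  m$short_skeleton <- !is.na(m$skeleton_length_px) &
    m$skeleton_length_px < params$min_skeleton_px
  flags_chr <- as.character(m$flags)
  flags_chr[is.na(flags_chr)] <- ""
  fl <- strsplit(flags_chr, "|", fixed = TRUE)
  m$ambiguous_centromere <- vapply(fl, function(x) "ambiguous_centromere" %in% x, TRUE)
  m$no_centromere <- vapply(fl, function(x) "no_centromere" %in% x, TRUE)
  m$manual_reject <- rep(FALSE, n)
  if (!is.null(reject_list) && nrow(reject_list)) {
    key <- if ("object_index" %in% names(reject_list)) "object_index" else "bivalent_id"
    if (!key %in% names(m)) stop("reject list uses ", key,
                                 " but measurements lack that column")
    bad <- paste(m$cell_id, m[[key]]) %in%
      paste(reject_list$cell_id, reject_list[[key]])
    m$manual_reject <- bad
  }
  m$curated_ok <- !(m$merged_bivalent | m$extra_foci | m$short_skeleton |
                      m$no_centromere | m$manual_reject)
  m
}

#' Chromosome 1 filter
#'
#' Chromosome 1 is the metacentric chromosome with the longest SC, so its
#' observations are isolated by an SC-length window, a normalized
#' centromere-position window, and (by default) the requirement of being
#' the longest measured bivalent in its cell. The defaults bracket typical
#' per-mouse chromosome 1 means (11.4-14.1 um) and the ~0.25 normalized
#' centromere position.
#'
#' @param sc_length_um_window length window in micrometers.
#' @param centromere_norm_window normalized centromere position window.
#' @param require_longest_in_cell only accept the longest unflagged
#'   bivalent of each cell.
#' @return List of class `chr1_filter`.
#' @export
chr1_filter <- function(sc_length_um_window = c(10, 17),
                        centromere_norm_window = c(0.15, 0.40),
                        require_longest_in_cell = TRUE) {
  stopifnot(sc_length_um_window[1] < sc_length_um_window[2],
            centromere_norm_window[1] < centromere_norm_window[2])
  structure(list(sc_length_um_window = sc_length_um_window,
                 centromere_norm_window = centromere_norm_window,
                 require_longest_in_cell = require_longest_in_cell),
            class = "chr1_filter")
}

#' Isolate chromosome 1 observations
#'
#' @param measurements diagnosed measurement data frame (see [diagnose()]).
#' @param filter a [chr1_filter()].
#' @return The subset of unflagged measurements passing the filter, at most
#'   one per cell, with an `is_chr1` column set. Idempotent: filtering the
#'   output returns it unchanged.
#' @export
filter_chromosome1 <- function(measurements, filter = chr1_filter()) {
  m <- measurements
  if (!"curated_ok" %in% names(m))
    stop("measurements must be diagnosed first (missing curated_ok)")
  keep <- rep(FALSE, nrow(m))
  for (cid in unique(m$cell_id)) {
    ix <- which(m$cell_id == cid)
    ok <- ix[m$curated_ok[ix] & !is.na(m$sc_length_um[ix])]
    if (!length(ok)) next
    cand <- ok
    if (filter$require_longest_in_cell) {
      longest_all <- ix[which.max(m$sc_length_um[ix])]
      longest_ok <- ok[which.max(m$sc_length_um[ok])]
      # if the longest bivalent in the cell is itself flagged, chromosome 1
      # cannot be identified with confidence in that cell
      if (!identical(longest_all, longest_ok)) next
      cand <- longest_ok
    }
    inside <- m$sc_length_um[cand] >= filter$sc_length_um_window[1] &
      m$sc_length_um[cand] <= filter$sc_length_um_window[2] &
      !is.na(m$centromere_pos_norm[cand]) &
      m$centromere_pos_norm[cand] >= filter$centromere_norm_window[1] &
      m$centromere_pos_norm[cand] <= filter$centromere_norm_window[2]
    cand <- cand[inside]
    if (length(cand) > 1) cand <- cand[which.max(m$sc_length_um[cand])]
    keep[cand] <- TRUE
  }
  out <- m[keep, , drop = FALSE]
  out$is_chr1 <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Compare automated measurements to a reference table
#'
#' Joins the automated and reference tables on (`cell_id`, `bivalent_id`)
#' and reports, per metric, the Pearson correlation and the mean signed
#' percent difference (automated relative to reference). Focus positions
#' are compared pairwise for joined bivalents whose focus counts agree.
#'
#' @param auto measurement data frame carrying `bivalent_id` (see
#'   [match_to_manifest()]).
#' @param reference data frame with `cell_id`, `bivalent_id` and reference
#'   values: `arc_length_px` (or `sc_length_px`), optionally
#'   `centromere_pos_px` and `foci_pos_px`.
#' @param px_per_um conversion used for reporting lengths.
#' @return Data frame with one row per metric: `metric`, `n`, `pearson_r`,
#'   `bias_percent`, `n_dropped` (pairs lost to missing values).
#' @export
compare_to_reference <- function(auto, reference, px_per_um = 9.8152) {
  refcol <- if ("arc_length_px" %in% names(reference)) "arc_length_px" else "sc_length_px"
  j <- merge(auto, reference, by = c("cell_id", "bivalent_id"),
             suffixes = c("", ".ref"))
  if (nrow(j) == 0) stop("no joinable (cell_id, bivalent_id) pairs")
  out <- list()

  metric_row <- function(name, a, r) {
    ok <- is.finite(a) & is.finite(r)
    n <- sum(ok)
    if (n < 3) return(data.frame(metric = name, n = n, pearson_r = NA_real_,
                                 bias_percent = NA_real_,
                                 n_dropped = length(a) - n))
    data.frame(metric = name, n = n,
               pearson_r = stats::cor(a[ok], r[ok]),
               bias_percent = 100 * mean((a[ok] - r[ok]) / r[ok]),
               n_dropped = length(a) - n)
  }
  out$sc <- metric_row("sc_length", j$sc_length_px, j[[refcol]])

  cenref <- intersect(c("centromere_pos_px.ref", "centromere_pos_px"), names(j))
  if ("centromere_pos_px" %in% names(reference)) {
    rc <- j[[if ("centromere_pos_px.ref" %in% names(j)) "centromere_pos_px.ref" else "centromere_pos_px"]]
    # compare under a common orientation: reference positions are reflected
    # when that brings them closer to the automated value
    ac <- j$centromere_pos_px
    L <- j[[refcol]]
    rc2 <- ifelse(!is.na(ac) & !is.na(rc) &
                    abs(ac - (L - rc)) < abs(ac - rc), L - rc, rc)
    out$cen <- metric_row("centromere_pos", ac, rc2)
  }

  if ("foci_pos_px" %in% names(reference)) {
    rf_col <- if ("foci_pos_px.ref" %in% names(j)) "foci_pos_px.ref" else "foci_pos_px"
    af <- parse_foci_string(j$foci_pos_px)
    rf <- parse_foci_string(j[[rf_col]])
    a <- numeric(0); r <- numeric(0); dropped <- 0L
    for (i in seq_len(nrow(j))) {
      ra <- af[[i]]; rr <- rf[[i]]
      if (length(ra) != length(rr) || length(ra) == 0) {
        dropped <- dropped + 1L
        next
      }
      L <- j[[refcol]][i]
      rr_flip <- sort(L - rr)
      if (sum(abs(sort(ra) - rr_flip)) < sum(abs(sort(ra) - sort(rr))))
        rr <- rr_flip
      a <- c(a, sort(ra)); r <- c(r, sort(rr))
    }
    fr <- metric_row("foci_pos", a, r)
    fr$n_dropped <- dropped
    out$foci <- fr
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
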