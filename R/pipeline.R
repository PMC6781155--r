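# Pipeline runners tying the modules together: simulate -> measure ->
# curate -> stats, with bit-stable CSV output. Every output CSV starts with
# a header comment carrying the tool version and the configuration hash.
# CSV dialect: UTF-8, comma separator, "." decimal point, full precision in
# machine files, 3 decimals in report files.

pkg_version <- function() as.character(utils::packageVersion("meioscope"))

write_csv_commented <- function(df, path, config) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# meioscope %s config=%s", pkg_version(),
                     config_hash(config)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a pipeline CSV (skipping header comments)
#' @param path CSV written by the pipeline runners.
#' @return Data frame.
#' @export
read_pipeline_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

round_df <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Simulate a synthetic dataset (pipeline entry point)
#'
#' @param config validated `run_config` (or list of overrides).
#' @param out_dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return Invisibly, the [generate_dataset()] result.
#' @export
run_simulate <- function(config = default_config(), out_dir,
                         overwrite = FALSE) {
  config <- validate_config(unclass(config))
  s <- config$simulate
  generate_dataset(out_dir, n_cells = s$n_cells, base_seed = s$base_seed,
                   overwrite = overwrite,
                   n_bivalents = s$n_bivalents, include_xy = s$include_xy,
                   overlap_fraction = s$overlap_fraction,
                   noise_sd = s$noise_sd,
                   illumination_gradient = s$illumination_gradient,
                   canvas_size = c(s$canvas_height, s$canvas_width),
                   len_range = c(s$len_min, s$len_max),
                   ribbon_width = s$ribbon_width, foci_sigma = s$foci_sigma,
                   n_background_foci = s$n_background_foci,
                   salt_fraction = s$salt_fraction, curviness = s$curviness)
}

#' Measure a set of images (pipeline entry point)
#'
#' For every readable TIFF: writes `<stem>_measurements.csv`, a
#' `<stem>_whole.tif` overlay (boxes around all objects, indices at passing
#' ones), and optionally `<stem>_objNN_straight2.tif` straightened ribbons
#' per passing bivalent. Unreadable images are skipped with a warning; the
#' call fails only if every image fails. A combined
#' `measurements_all.csv` covering all images is also written.
#'
#' @param inputs directory containing `.tif` files, or a character vector
#'   of TIFF paths.
#' @param config validated `run_config` or override list.
#' @param out_dir output directory (defaults to the input directory).
#' @param write_overlays,write_straightened toggles for image output.
#' @return Invisibly, the combined measurement data frame.
#' @export
run_measure <- function(inputs, config = default_config(), out_dir = NULL,
                        write_overlays = TRUE, write_straightened = FALSE) {
  config <- validate_config(unclass(config))
  p <- params_from_config(config)
  paths <- if (length(inputs) == 1 && dir.exists(inputs))
    sort(list.files(inputs, pattern = "\\.tiff?$", full.names = TRUE))
  else inputs
  paths <- paths[!grepl("_whole\\.tiff?$|_straight2\\.tiff?$", paths)]
  if (!length(paths)) stop("no input TIFF files found")
  if (is.null(out_dir)) out_dir <- dirname(paths[1])
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all <- list()
  n_fail <- 0L
  for (pt in paths) {
    stem <- sub("\\.tiff?$", "", basename(pt))
    res <- tryCatch({
      img <- read_image_tiff(pt)
      measure_image(img, cell_id = stem, seg_params = p$seg,
                    mid_params = p$mid, foc_params = p$foc,
                    half_width = p$half_width,
                    keep_straightened = write_straightened)
    }, error = function(e) {
      warning("skipping ", pt, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) { n_fail <- n_fail + 1L; next }
    message(sprintf("%s: %d objects, %d passing", stem,
                    nrow(res$objects), sum(res$objects$pass)))
    write_csv_commented(res$measurements,
                        file.path(out_dir, paste0(stem, "_measurements.csv")),
                        config)
    if (write_overlays) {
      ov <- annotate_overlay(read_image_tiff(pt), res$objects)
      write_image_tiff(ov, file.path(out_dir, paste0(stem, "_whole.tif")))
    }
    if (write_straightened && length(res$straightened)) {
      for (nm in names(res$straightened)) {
        rib <- res$straightened[[nm]]
        rib[rib < 0] <- 0; rib[rib > 1] <- 1
        write_image_tiff(rib, file.path(out_dir,
          sprintf("%s_obj%02d_straight2.tif", stem, as.integer(nm))))
      }
    }
    all[[stem]] <- res$measurements
  }
  if (n_fail == length(paths)) stop("all images failed")
  combined <- do.call(rbind, all)
  rownames(combined) <- NULL
  write_csv_commented(combined, file.path(out_dir, "measurements_all.csv"),
                      config)
  invisible(combined)
}

#' Curate measurements (pipeline entry point)
#'
#' Diagnoses error flags, marks chromosome 1 candidates, writes
#' `curated.csv`; when a ground-truth or manual reference is supplied,
#' matches measurements to it and writes `accuracy.csv` with one row per
#' metric (pre- and post-curation).
#'
#' @param measurements data frame or path to a measurement CSV.
#' @param config validated `run_config` or override list.
#' @param out_dir output directory (optional; no files written if `NULL`).
#' @param reference optional manifest/reference data frame or CSV path.
#' @param reject_list optional data frame or CSV with `cell_id` +
#'   `object_index` (or `bivalent_id`) rows to force-reject.
#' @return Invisibly, a list with `curated` (flagged measurements with
#'   `is_chr1`), `chr1`, and `accuracy` (or `NULL`).
#' @export
run_curate <- function(measurements, config = default_config(),
                       out_dir = NULL, reference = NULL,
                       reject_list = NULL) {
  config <- validate_config(unclass(config))
  p <- params_from_config(config)
  if (is.character(measurements)) measurements <- read_pipeline_csv(measurements)
  if (is.character(reference)) reference <- read_manifest(reference)
  if (is.character(reject_list)) reject_list <- utils::read.csv(reject_list)
  cur <- diagnose(measurements, p$cur, reject_list = reject_list)
  chr1 <- filter_chromosome1(cur, p$chr1)
  cur$is_chr1 <- paste(cur$cell_id, cur$object_index) %in%
    paste(chr1$cell_id, chr1$object_index)
  acc <- NULL
  if (!is.null(reference)) {
    matched <- match_to_manifest(cur, reference)
    pre <- compare_to_reference(matched, reference, config$px_per_um)
    post <- compare_to_reference(matched[matched$curated_ok, , drop = FALSE],
                                 reference, config$px_per_um)
    pre$stage <- "pre_curation"; post$stage <- "post_curation"
    acc <- rbind(pre, post)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_csv_commented(cur, file.path(out_dir, "curated.csv"), config)
    if (!is.null(acc))
      write_csv_commented(round_df(acc, 6),
                          file.path(out_dir, "accuracy.csv"), config)
  }
  invisible(list(curated = cur, chr1 = chr1, accuracy = acc))
}

#' Crossover-patterning statistics reports (pipeline entry point)
#'
#' From a curated per-bivalent table and a per-cell table, writes report
#' CSVs: per-mouse/group count summaries (`counts_summary.csv`),
#' chromosome 1 focus-class table (`focus_classes.csv`), normalized
#' position histograms (`positions_1focus.csv`, `positions_2foci.csv`),
#' interference fits (`interference.csv`), intra-chromosomal r-bar
#' (`rbar.csv`), and mouse-level permutation tests (`permutation.csv`)
#' when two statuses are present. Sections without sufficient data are
#' marked `insufficient data` rather than failing.
#'
#' @param curated curated measurement data frame (or CSV path) with
#'   `is_chr1`, `n_foci`, `foci_pos_norm`, `sc_length_um`.
#' @param cells per-cell data frame (or CSV path) with `cell_id`,
#'   `mlh1_total`, and optionally `mouse_id`, `species`, `status`.
#' @param config validated `run_config` or override list.
#' @param out_dir output directory.
#' @return Invisibly, a list of the report data frames.
#' @export
run_stats <- function(curated, cells, config = default_config(), out_dir) {
  config <- validate_config(unclass(config))
  if (is.character(curated)) curated <- read_pipeline_csv(curated)
  if (is.character(cells)) cells <- read_pipeline_csv(cells)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("mouse_id", "species", "status")) {
    if (!nm %in% names(cells)) cells[[nm]] <- "synthetic"
    cells[[nm]][is.na(cells[[nm]])] <- "synthetic"
  }
  st <- config$stats

  # per-mouse count summary plus pooled group rows
  per_mouse <- summarize_counts(cells$mlh1_total,
                                paste(cells$species, cells$status,
                                      cells$mouse_id, sep = "|"))
  lab <- do.call(rbind, strsplit(per_mouse$group, "|", fixed = TRUE))
  counts <- data.frame(species = lab[, 1], status = lab[, 2],
                       mouse_id = lab[, 3],
                       per_mouse[, c("n", "mean", "sd", "se", "cv")],
                       stringsAsFactors = FALSE)
  groups <- unique(counts[, c("species", "status")])
  for (i in seq_len(nrow(groups))) {
    sel <- counts$species == groups$species[i] & counts$status == groups$status[i] &
      counts$mouse_id != "Group"
    raw <- split(cells$mlh1_total[cells$species == groups$species[i] &
                                    cells$status == groups$status[i]],
                 cells$mouse_id[cells$species == groups$species[i] &
                                  cells$status == groups$status[i]])
    g <- pool_group(values = raw)
    counts <- rbind(counts, data.frame(species = groups$species[i],
                                       status = groups$status[i],
                                       mouse_id = "Group", n = g$n,
                                       mean = g$mean_weighted, sd = g$sd,
                                       se = g$se, cv = g$cv))
  }
  write_csv_commented(round_df(counts, 3),
                      file.path(out_dir, "counts_summary.csv"), config)

  chr1 <- curated[isTRUE_vec(curated$is_chr1), , drop = FALSE]
  chr1 <- merge(chr1, cells[, c("cell_id", "mouse_id", "species", "status")],
                by = "cell_id", all.x = TRUE)
  reports <- list(counts = counts)

  if (nrow(chr1)) {
    fc <- focus_class_table(chr1$n_foci, paste(chr1$species, chr1$status))
    write_csv_commented(round_df(fc, 3),
                        file.path(out_dir, "focus_classes.csv"), config)
    reports$focus_classes <- fc

    pos <- parse_foci_string(chr1$foci_pos_norm)
    one <- pos[chr1$n_foci == 1]
    two <- pos[chr1$n_foci == 2]
    if (length(one)) {
      h1 <- position_histogram(one, "1-focus", st$bin_width)
      write_csv_commented(h1, file.path(out_dir, "positions_1focus.csv"), config)
      reports$positions_1focus <- h1
    }
    if (length(two)) {
      h2 <- position_histogram(two, "2-foci", st$bin_width)
      write_csv_commented(h2, file.path(out_dir, "positions_2foci.csv"), config)
      reports$positions_2foci <- h2
    }

    rb <- rbar_group(pos, paste(chr1$species, chr1$status))
    write_csv_commented(round_df(rb$group_means, 4),
                        file.path(out_dir, "rbar.csv"), config)
    reports$rbar <- rb$group_means

    irows <- list()
    for (md in c("absolute_um", "normalized")) {
      omin <- if (md == "absolute_um") st$outlier_min_distance_um else 0
      fit <- tryCatch(fit_interference(chr1, mode = md,
                                       outlier_min_distance = omin,
                                       px_per_um = config$px_per_um),
                      error = function(e) NULL)
      irows[[md]] <- if (is.null(fit))
        data.frame(mode = md, nu = NA_real_, scale = NA_real_,
                   n_distances = 0L, n_excluded = NA_integer_,
                   note = "insufficient data")
      else data.frame(mode = md, nu = fit$nu, scale = fit$scale,
                      n_distances = fit$n_distances,
                      n_excluded = length(fit$excluded), note = "")
    }
    interference <- do.call(rbind, irows)
    rownames(interference) <- NULL
    write_csv_commented(round_df(interference, 4),
                        file.path(out_dir, "interference.csv"), config)
    reports$interference <- interference
  } else {
    write_csv_commented(data.frame(note = "insufficient data"),
                        file.path(out_dir, "interference.csv"), config)
  }

  # mouse-level permutation tests (need two statuses with >= 2 mice each)
  statuses <- unique(cells$status)
  prow <- NULL
  if (length(statuses) == 2) {
    by_mouse <- split(cells$mlh1_total, cells$mouse_id)
    mstat <- vapply(split(cells$status, cells$mouse_id), `[`, "", 1)
    if (all(table(mstat) >= 2) && all(vapply(by_mouse, length, 0L) >= 2)) {
      res <- lapply(c("within_mouse_variance", "among_mouse_variance"),
                    function(lv) {
        r <- permutation_test_variance(by_mouse, mstat, lv,
                                       n_perm = st$n_perm, seed = st$seed)
        data.frame(level = lv, observed = r$observed, p_value = r$p_value,
                   n_permutations = r$n_permutations, seed = r$seed)
      })
      prow <- do.call(rbind, res)
    }
  }
  if (is.null(prow))
    prow <- data.frame(level = "none", observed = NA_real_,
                       p_value = NA_real_, n_permutations = 0L,
                       seed = st$seed, note = "insufficient data")
  write_csv_commented(prow, file.path(out_dir, "permutation.csv"), config)
  reports$permutation <- prow
  invisible(reports)
}

isTRUE_vec <- function(x) !is.na(x) & x == TRUE

#' Build a per-cell table from measurement output
#'
#' Convenience for synthetic pipelines: tallies [assemble_cell_record()]
#' fields per cell from the measurement table.
#'
#' @param measurements measurement data frame.
#' @param mouse_of optional named vector mapping `cell_id` to `mouse_id`.
#' @return Data frame of cell records.
#' @export
cells_from_measurements <- function(measurements, mouse_of = NULL) {
  rows <- lapply(split(measurements, measurements$cell_id), function(m) {
    mid <- if (!is.null(mouse_of)) unname(mouse_of[m$cell_id[1]]) else NA_character_
    assemble_cell_record(m, mouse_id = mid)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
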