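# Published per-mouse summary tables for Peromyscus spermatocytes, entered
# as code so that desk arithmetic (SE/CV identities, pooled group rows,
# focus-class percentages, map length) can be recomputed from them.

#' Per-mouse MLH1 count summaries
#'
#' Published per-mouse MLH1 focus-count statistics for wild-caught
#' *P. leucopus* (Madison, WI), laboratory-raised *P. leucopus*, and
#' laboratory-raised *P. m. bairdii*: number of scored spermatocytes, mean
#' count, sample SD, SE and CV as printed (3 decimals).
#'
#' @return Data frame with columns `species`, `status`, `mouse_id`, `n`,
#'   `mean`, `sd`, `se`, `cv`.
#' @export
mlh1_count_table <- function() {
  w <- function(id, n, m, s, se, cv)
    data.frame(species = "P. leucopus", status = "wild", mouse_id = id,
               n = n, mean = m, sd = s, se = se, cv = cv,
               stringsAsFactors = FALSE)
  l <- function(id, n, m, s, se, cv)
    data.frame(species = "P. leucopus", status = "lab", mouse_id = id,
               n = n, mean = m, sd = s, se = se, cv = cv,
               stringsAsFactors = FALSE)
  b <- function(id, n, m, s, se, cv)
    data.frame(species = "P. m. bairdii", status = "lab", mouse_id = id,
               n = n, mean = m, sd = s, se = se, cv = cv,
               stringsAsFactors = FALSE)
  rbind(
    w("MAD_m1", 26, 23.269, 0.667, 0.131, 2.865),
    w("MAD_m3", 28, 23.393, 0.832, 0.157, 3.555),
    w("MAD_m6", 12, 22.917, 1.084, 0.313, 4.728),
    w("MAD_m7", 19, 23.474, 1.219, 0.280, 5.192),
    w("MAD_m18", 37, 23.000, 1.179, 0.194, 5.124),
    w("MAD_m11", 30, 24.533, 1.279, 0.234, 5.215),
    w("MAD_m12", 28, 23.607, 0.956, 0.181, 4.050),
    w("MAD_m23", 15, 23.533, 1.302, 0.336, 5.533),
    w("MAD_m24", 26, 23.808, 1.877, 0.368, 7.882),
    l("LL_m1", 33, 22.909, 1.487, 0.259, 6.489),
    l("LL_m3", 29, 22.552, 1.594, 0.296, 7.070),
    l("LL_m4", 23, 22.217, 1.930, 0.402, 8.685),
    l("LL_m5", 22, 23.000, 1.690, 0.360, 7.349),
    l("LL_m6", 22, 23.318, 0.839, 0.179, 3.597),
    l("LL_m7", 29, 21.862, 1.382, 0.257, 6.320),
    l("LL_m8", 28, 22.107, 1.685, 0.318, 7.623),
    l("LL_m9", 28, 23.107, 1.397, 0.264, 6.045),
    l("LL_m10", 29, 22.552, 1.682, 0.312, 7.456),
    b("BW_m1", 22, 23.000, 1.543, 0.329, 6.709),
    b("BW_m2", 31, 22.774, 1.146, 0.206, 5.033)
  )
}

#' Per-mouse chromosome 1 SC summaries
#'
#' Published per-mouse chromosome 1 statistics: number of scored bivalents,
#' mean SC length (um), SD, SE, counts of 1-focus and 2-foci bivalents
#' (plus the rare 0-focus and 3-foci observations), and the mean
#' intra-chromosomal r-bar.
#'
#' @return Data frame with columns `species`, `status`, `mouse_id`,
#'   `n_bivalents`, `mean_um`, `sd`, `se`, `n_0focus`, `n_1focus`,
#'   `n_2foci`, `n_3foci`, `rbar_mean`.
#' @export
chr1_summary_table <- function() {
  row <- function(species, status, id, n, m, s, se, n0, n1, n2, n3, rb)
    data.frame(species = species, status = status, mouse_id = id,
               n_bivalents = n, mean_um = m, sd = s, se = se,
               n_0focus = n0, n_1focus = n1, n_2foci = n2, n_3foci = n3,
               rbar_mean = rb, stringsAsFactors = FALSE)
  pl <- "P. leucopus"; bw <- "P. m. bairdii"
  rbind(
    row(pl, "wild", "MAD_m1", 21, 13.264, 1.218, 0.266, 0, 13, 8, 0, 0.239),
    row(pl, "wild", "MAD_m3", 21, 14.137, 1.608, 0.351, 0, 15, 6, 0, 0.228),
    row(pl, "wild", "MAD_m7", 8, 13.174, 1.017, 0.360, 0, 2, 6, 0, 0.248),
    row(pl, "wild", "MAD_m9", 8, 12.939, 0.929, 0.328, 1, 2, 5, 0, 0.243),
    row(pl, "wild", "MAD_m11", 19, 12.194, 0.919, 0.211, 0, 4, 15, 0, 0.268),
    row(pl, "wild", "MAD_m12", 9, 12.486, 0.554, 0.185, 0, 5, 4, 0, 0.259),
    row(pl, "wild", "MAD_m18", 14, 12.291, 1.379, 0.369, 0, 11, 3, 0, 0.232),
    row(pl, "wild", "MAD_m23", 10, 13.520, 1.093, 0.346, 0, 7, 2, 1, 0.249),
    row(pl, "wild", "MAD_m24", 11, 13.921, 1.142, 0.344, 0, 3, 8, 0, 0.272),
    row(pl, "lab", "LL_m1", 10, 12.022, 1.329, 0.420, 1, 5, 3, 1, 0.221),
    row(pl, "lab", "LL_m2", 5, 12.256, 1.030, 0.461, 0, 4, 1, 0, 0.233),
    row(pl, "lab", "LL_m3", 12, 12.300, 0.735, 0.212, 0, 6, 5, 1, 0.256),
    row(pl, "lab", "LL_m4", 11, 12.682, 0.896, 0.270, 0, 5, 6, 0, 0.244),
    row(pl, "lab", "LL_m5", 9, 13.060, 0.650, 0.194, 0, 6, 3, 0, 0.241),
    row(pl, "lab", "LL_m6", 10, 12.628, 0.756, 0.239, 0, 7, 3, 0, 0.242),
    row(pl, "lab", "LL_m7", 13, 12.583, 0.830, 0.230, 0, 9, 4, 0, 0.214),
    row(pl, "lab", "LL_m8", 14, 13.009, 1.162, 0.311, 0, 9, 4, 1, 0.220),
    row(pl, "lab", "LL_m9", 9, 11.819, 0.966, 0.322, 1, 6, 2, 0, 0.223),
    row(pl, "lab", "LL_m10", 11, 12.546, 0.861, 0.260, 0, 10, 1, 0, 0.207),
    row(bw, "lab", "BW_m1", 12, 13.446, 1.571, 0.454, 0, 12, 0, 0, 0.205),
    row(bw, "lab", "BW_m2", 10, 12.308, 0.652, 0.206, 0, 9, 1, 0, 0.210),
    row(bw, "lab", "BW_m3", 8, 11.375, 0.428, 0.139, 0, 7, 1, 0, 0.233)
  )
}
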