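# Crossover-patterning statistics: count summaries, focus-class tables,
# position distributions, gamma interference shape (nu), intra-chromosomal
# r-bar, permutation tests of variance, and the focus-number logistic model.

#' Per-group summary of MLH1 counts
#'
#' Mean, sample SD (n - 1), SE = SD / sqrt(n), and CV = 100 * SD / mean per
#' group. Values are kept at full precision; rounding is a reporting
#' concern (report tables use 3 decimals).
#'
#' @param values numeric vector of per-cell counts (or any per-observation
#'   statistic).
#' @param groups vector of group labels, same length as `values`; a single
#'   label may be given for an ungrouped summary.
#' @return Data frame with columns `group`, `n`, `mean`, `sd`, `se`, `cv`.
#'   Groups with n < 2 get `NA` for sd/se/cv.
#' @export
summarize_counts <- function(values, groups = "all") {
  if (length(groups) == 1) groups <- rep(groups, length(values))
  stopifnot(length(groups) == length(values))
  sp <- split(as.numeric(values), factor(groups, levels = unique(groups)))
  rows <- lapply(names(sp), function(g) {
    v <- sp[[g]]
    n <- length(v)
    m <- mean(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    data.frame(group = g, n = n, mean = m, sd = s,
               se = s / sqrt(n), cv = 100 * s / m,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summary-row arithmetic from printed mean/SD/n
#'
#' Recomputes SE and CV from a reported per-group mean, sample SD and n,
#' the arithmetic used in published count-summary tables.
#'
#' @param mean,sd,n reported summary values (vectorized).
#' @return Data frame with `n`, `mean`, `sd`, `se`, `cv`.
#' @export
summary_row_from_moments <- function(mean, sd, n) {
  data.frame(n = n, mean = mean, sd = sd,
             se = sd / sqrt(n), cv = 100 * sd / mean)
}

#' Pool per-mouse summaries into a group row
#'
#' Given per-mouse summary rows (or raw per-cell values), produces the
#' group-level row: pooled n, the n-weighted mean (equals the mean of raw
#' values when those are supplied), and the unweighted across-mice mean.
#' When raw values are available the group SD/SE/CV come from them
#' directly; otherwise SD is reconstructed from the within- plus
#' between-mouse moments.
#'
#' @param summaries data frame with columns `n`, `mean`, and optionally
#'   `sd` (one row per mouse). Ignored when `values` is given.
#' @param values optional list of raw per-cell count vectors, one per
#'   mouse.
#' @return One-row data frame: `n`, `mean_weighted`, `mean_unweighted`,
#'   `sd`, `se`, `cv` (sd/se/cv refer to the pooled observations).
#' @export
pool_group <- function(summaries = NULL, values = NULL) {
  if (!is.null(values)) {
    if (!length(values)) stop("no mice to pool")
    per <- vapply(values, mean, 0)
    all_v <- unlist(values)
    n <- length(all_v)
    s <- stats::sd(all_v)
    return(data.frame(n = n, mean_weighted = mean(all_v),
                      mean_unweighted = mean(per),
                      sd = s, se = s / sqrt(n),
                      cv = 100 * s / mean(all_v)))
  }
  if (is.null(summaries) || nrow(summaries) == 0) stop("no mice to pool")
  n <- sum(summaries$n)
  mw <- sum(summaries$n * summaries$mean) / n
  mu <- mean(summaries$mean)
  s <- NA_real_
  if (!is.null(summaries$sd) && all(!is.na(summaries$sd))) {
    # pooled second moment: within-mouse variance plus dispersion of means
    ss <- sum((summaries$n - 1) * summaries$sd^2) +
      sum(summaries$n * (summaries$mean - mw)^2)
    s <- sqrt(ss / (n - 1))
  }
  data.frame(n = n, mean_weighted = mw, mean_unweighted = mu,
             sd = s, se = s / sqrt(n), cv = 100 * s / mw)
}

#' Cytological genetic map length
#'
#' Converts a mean MLH1 focus count per cell to an autosomal genetic map
#' length assuming each MLH1 focus corresponds to 50 cM.
#'
#' @param mean_foci_per_cell mean MLH1 count (>= 0).
#' @param cM_per_focus centimorgans per focus.
#' @return Map length in cM.
#' @export
map_length_cM <- function(mean_foci_per_cell, cM_per_focus = 50) {
  stopifnot(all(mean_foci_per_cell >= 0))
  cM_per_focus * mean_foci_per_cell
}

#' Focus-class table
#'
#' Counts and percentages of bivalents carrying 0/1/2/3 foci per group,
#' with an overall row pooled across groups.
#'
#' @param n_foci integer vector of per-bivalent focus counts.
#' @param groups group labels (same length), or a single label.
#' @return Data frame: `group`, `total`, `n_0 .. n_3plus`, `pct_0 ..
#'   pct_3plus` (percentages of the group total, full precision).
#' @export
focus_class_table <- function(n_foci, groups = "all") {
  if (length(groups) == 1) groups <- rep(groups, length(n_foci))
  stopifnot(length(groups) == length(n_foci))
  lv <- unique(groups)
  if (length(lv) == 0) lv <- "all"   # empty input: a single zero row
  one <- function(v, g) {
    cl <- pmin(v, 3L)
    cnt <- vapply(0:3, function(k) sum(cl == k), 0L)
    tot <- length(v)
    data.frame(group = g, total = tot,
               n_0 = cnt[1], n_1 = cnt[2], n_2 = cnt[3], n_3plus = cnt[4],
               pct_0 = 100 * cnt[1] / max(tot, 1),
               pct_1 = 100 * cnt[2] / max(tot, 1),
               pct_2 = 100 * cnt[3] / max(tot, 1),
               pct_3plus = 100 * cnt[4] / max(tot, 1),
               stringsAsFactors = FALSE)
  }
  rows <- lapply(lv, function(g) one(n_foci[groups == g], g))
  if (length(lv) > 1) rows <- c(rows, list(one(n_foci, "overall")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binned distribution of normalized focus positions
#'
#' Places normalized positions in 5% bins over [0, 1]. For the two-focus
#' class the centromere-proximal (first) and distal (second) focus form
#' separate series. Binning is for display; distribution tests use the raw
#' positions.
#'
#' @param positions list of numeric vectors of normalized positions, one
#'   per bivalent (each sorted ascending), or a plain numeric vector for
#'   the single-focus class.
#' @param class `"1-focus"` or `"2-foci"`.
#' @param bin_width bin width on the normalized axis.
#' @return Data frame: `bin_lo`, `bin_hi`, and counts (`count` for
#'   1-focus; `count_first`, `count_second` for 2-foci).
#' @export
position_histogram <- function(positions, class = c("1-focus", "2-foci"),
                               bin_width = 0.05) {
  class <- match.arg(class)
  if (is.numeric(positions)) positions <- as.list(positions)
  flat <- unlist(positions)
  if (length(flat) && (any(flat < 0) || any(flat > 1)))
    stop("normalized positions must lie in [0, 1]")
  breaks <- seq(0, 1, by = bin_width)
  bin_of <- function(x) pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                             length(breaks) - 1)
  count_in <- function(x) {
    tab <- tabulate(bin_of(x), nbins = length(breaks) - 1)
    tab
  }
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1])
  if (class == "1-focus") {
    x <- vapply(positions, function(p) p[1], 0)
    out$count <- count_in(x)
  } else {
    if (any(vapply(positions, length, 0L) != 2))
      stop("2-foci class requires exactly two positions per bivalent")
    out$count_first <- count_in(vapply(positions, `[`, 0, 1))
    out$count_second <- count_in(vapply(positions, `[`, 0, 2))
  }
  out
}

#' Two-sample Kolmogorov-Smirnov comparison of position distributions
#'
#' Applied to raw (unbinned) normalized positions; asymptotic p-value.
#'
#' @param positions_a,positions_b numeric vectors (n >= 2 each).
#' @return List with `D` and `p_value`.
#' @export
ks_compare <- function(positions_a, positions_b) {
  if (length(positions_a) < 2 || length(positions_b) < 2)
    stop("each sample needs at least 2 positions")
  kt <- suppressWarnings(stats::ks.test(positions_a, positions_b,
                                        exact = FALSE))
  list(D = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Gamma maximum-likelihood fit of inter-focus distances
#'
#' Estimates the gamma shape (the interference parameter nu) and scale by
#' maximum likelihood. The shape solves `log(k) - digamma(k) = log(mean) -
#' mean(log)`; the equation is solved by safeguarded Newton iteration
#' (bisection fallback) to tolerance 1e-8.
#'
#' @param x positive distances.
#' @return List with `shape`, `scale`, `n`.
#' @export
fit_gamma_mle <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x <= 0)) stop("distances must be positive")
  if (stats::var(x) < 1e-12) stop("degenerate sample (shape unbounded)")
  s <- log(mean(x)) - mean(log(x))
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)  # Minka initialization
  lo <- 1e-8; hi <- k * 64
  f <- function(k) log(k) - digamma(k) - s
  while (f(hi) > 0) hi <- hi * 4
  for (it in 1:200) {
    fk <- f(k)
    if (abs(fk) < 1e-8) break
    if (fk > 0) lo <- k else hi <- k
    dk <- fk / (1 / k - trigamma(k))
    k_new <- k - dk
    if (!is.finite(k_new) || k_new <= lo || k_new >= hi) k_new <- (lo + hi) / 2
    k <- k_new
  }
  list(shape = k, scale = mean(x) / k, n = length(x))
}

#' Fit crossover interference strength
#'
#' Computes inter-focus distances on two-focus bivalents, either in
#' micrometers (`absolute_um`) or as a fraction of SC length
#' (`normalized`), removes distances below an outlier floor (artifactually
#' close focus pairs, e.g. one physical focus split in two), and fits a
#' gamma distribution by maximum likelihood. The shape parameter nu
#' measures interference strength (nu = 1 is no interference).
#'
#' @param measurements data frame of two-focus bivalents with
#'   `foci_pos_px` (semicolon string or list of numeric vectors),
#'   `sc_length_px`, `sc_length_um`.
#' @param mode `"absolute_um"` or `"normalized"`.
#' @param outlier_min_distance distances (um for absolute mode, fraction
#'   for normalized) strictly below this are excluded and reported.
#' @param px_per_um conversion factor.
#' @param min_n minimum number of usable distances.
#' @return Object of class `interference_fit`: `nu`, `scale`,
#'   `n_distances`, `mode`, `excluded` (the removed distances).
#' @export
fit_interference <- function(measurements,
                             mode = c("absolute_um", "normalized"),
                             outlier_min_distance = if (mode[1] == "absolute_um") 1 else 0,
                             px_per_um = 9.8152, min_n = 10) {
  mode <- match.arg(mode)
  foci <- if (is.list(measurements$foci_pos_px) &&
              !is.character(measurements$foci_pos_px))
    measurements$foci_pos_px else parse_foci_string(measurements$foci_pos_px)
  two <- vapply(foci, length, 0L) == 2L
  foci <- foci[two]
  L <- measurements$sc_length_px[two]
  d_px <- vapply(foci, function(p) abs(p[2] - p[1]), 0)
  d <- switch(mode,
              absolute_um = to_micrometers(d_px, px_per_um),
              normalized = d_px / L)
  excluded <- d[d < outlier_min_distance]
  d <- d[d >= outlier_min_distance]
  if (length(d) < min_n)
    stop(sprintf("need >= %d inter-focus distances, have %d", min_n, length(d)))
  fit <- fit_gamma_mle(d)
  structure(list(nu = fit$shape, scale = fit$scale,
                 n_distances = fit$n, mode = mode, excluded = excluded),
            class = "interference_fit")
}

#' @export
print.interference_fit <- function(x, ...) {
  cat(sprintf("gamma interference fit (%s): nu = %.3f, scale = %.4f, n = %d (%d excluded)\n",
              x$mode, x$nu, x$scale, x$n_distances, length(x$excluded)))
  invisible(x)
}

#' Intra-chromosomal r-bar
#'
#' The per-chromosome component of the genetic-shuffling measure: for
#' crossover positions partitioning the normalized SC into segment
#' proportions `a_0 .. a_m`, it equals `0.5 * (1 - sum(a_i^2))` -- the
#' probability that a uniformly drawn locus pair is separated by an odd
#' number of crossovers on a random gamete, with no chromatid interference.
#' Bounded by 0 (no crossover) and 0.5.
#'
#' @param positions sorted normalized crossover positions in [0, 1]; empty
#'   for a focus-free bivalent.
#' @return A single value in [0, 0.5].
#' @export
rbar_intra <- function(positions) {
  positions <- as.numeric(positions)
  if (length(positions) == 0) return(0)
  if (any(positions < 0) || any(positions > 1)) stop("positions must be in [0, 1]")
  if (is.unsorted(positions, strictly = FALSE)) stop("positions must be sorted")
  a <- diff(c(0, positions, 1))
  0.5 * (1 - sum(a^2))
}

#' Group means of intra-chromosomal r-bar
#'
#' @param positions list of sorted normalized position vectors, one per
#'   bivalent.
#' @param groups group labels (same length), or single label.
#' @return List with `per_bivalent` (numeric vector) and `group_means`
#'   (data frame `group`, `n`, `mean_rbar`).
#' @export
rbar_group <- function(positions, groups = "all") {
  vals <- vapply(positions, rbar_intra, 0)
  if (length(groups) == 1) groups <- rep(groups, length(vals))
  sp <- split(vals, factor(groups, levels = unique(groups)))
  gm <- data.frame(group = names(sp),
                   n = vapply(sp, length, 0L),
                   mean_rbar = vapply(sp, mean, 0),
                   stringsAsFactors = FALSE)
  rownames(gm) <- NULL
  list(per_bivalent = vals, group_means = gm)
}

#' Permutation test of variance differences between statuses
#'
#' Compares levels of variation between two status groups (e.g. wild vs
#' laboratory-raised) by randomizing status labels at the mouse level.
#' `within_mouse_variance`: the statistic is the difference in mean
#' per-mouse variance; `among_mouse_variance`: the difference in variance
#' of the per-mouse means. Two-sided p with add-one correction:
#' `p = (1 + #{|T*| >= |T|}) / (n_perm + 1)`.
#'
#' @param values_by_mouse list of numeric vectors, one per mouse.
#' @param status character/factor of group labels, one per mouse (exactly
#'   two levels, >= 2 mice each).
#' @param level `"within_mouse_variance"` or `"among_mouse_variance"`.
#' @param n_perm number of label permutations.
#' @param seed integer seed.
#' @return Object of class `permutation_result`: `observed`, `p_value`,
#'   `n_permutations`, `level`, `seed`.
#' @export
permutation_test_variance <- function(values_by_mouse, status,
                                      level = c("within_mouse_variance",
                                                "among_mouse_variance"),
                                      n_perm = 10000, seed = 1L) {
  level <- match.arg(level)
  status <- as.character(status)
  stopifnot(length(values_by_mouse) == length(status))
  lv <- unique(status)
  if (length(lv) != 2) stop("status must have exactly two levels")
  if (any(table(status) < 2)) stop("each status needs >= 2 mice")
  per_mouse <- switch(level,
    within_mouse_variance = vapply(values_by_mouse, stats::var, 0),
    among_mouse_variance = vapply(values_by_mouse, mean, 0))
  stat <- function(lab) {
    a <- per_mouse[lab == lv[1]]; b <- per_mouse[lab == lv[2]]
    if (level == "within_mouse_variance") mean(a) - mean(b)
    else stats::var(a) - stats::var(b)
  }
  obs <- stat(status)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) stat(sample(status)), 0)
  p <- (1 + sum(abs(perm) >= abs(obs))) / (n_perm + 1)
  structure(list(observed = obs, p_value = p, n_permutations = n_perm,
                 level = level, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s): T = %.4g, p = %.4g (%d permutations, seed %d)\n",
              x$level, x$observed, x$p_value, x$n_permutations, x$seed))
  invisible(x)
}

#' Logistic model of focus number on SC length
#'
#' Fits P(two foci) against chromosome 1 SC length by maximum-likelihood
#' logistic regression (optionally with a sampling-month integer
#' covariate) and reports Wald tests per coefficient.
#'
#' @param sc_length_um SC lengths (um).
#' @param n_foci per-bivalent focus counts; only values 1 and 2 enter the
#'   model, others are dropped.
#' @param month optional integer covariate.
#' @return List with `coefficients` (data frame: term, estimate, se, z,
#'   p_value), `n`, and `separation` flag.
#' @export
logistic_focus_model <- function(sc_length_um, n_foci, month = NULL) {
  keep <- n_foci %in% c(1L, 2L) & is.finite(sc_length_um)
  y <- as.integer(n_foci[keep] == 2L)
  x <- sc_length_um[keep]
  if (length(unique(y)) < 2)
    stop("both focus classes (1 and 2) must be present")
  df <- data.frame(y = y, sc_length = x)
  form <- y ~ sc_length
  if (!is.null(month)) {
    df$month <- as.integer(month[keep])
    form <- y ~ sc_length + month
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = df))
  sep <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8) ||
    !fit$converged
  co <- summary(fit)$coefficients
  res <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    z = co[, 3], p_value = co[, 4], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  list(coefficients = res, n = length(y), separation = sep)
}
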