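# Shared fixtures: all synthetic inputs are generated in code at test time.

# straight horizontal bivalent spec of given length
straight_spec <- function(len = 100, row = 50, col0 = 20, ...) {
  bivalent_spec(cbind(row = c(row, row), col = c(col0, col0 + len)), ...)
}

blank_canvas <- function(H = 120, W = 200) array(0, dim = c(H, W, 3))

# small clean cell used across tests (no XY, no overlaps)
clean_cell <- function(seed = 3, n = 6, canvas = 512) {
  generate_cell(cell_spec(n_bivalents = n, include_xy = FALSE,
                          canvas_size = c(canvas, canvas), seed = seed),
                cell_id = sprintf("cell_s%d", seed))
}

# Monte-Carlo chromatid oracle for the intra-chromosomal shuffling measure:
# draw locus pairs uniformly on [0,1]; each crossover strictly between the
# pair involves the sampled gamete's chromatid independently with
# probability 1/2 (no chromatid interference); the pair is shuffled when an
# odd number of its intervening crossovers hit that chromatid.
mc_rbar_oracle <- function(positions, n_pairs = 1e6, seed = 99) {
  set.seed(seed)
  u1 <- stats::runif(n_pairs); u2 <- stats::runif(n_pairs)
  lo <- pmin(u1, u2); hi <- pmax(u1, u2)
  k <- rep(0L, n_pairs)
  for (p in positions) k <- k + (lo < p & p < hi)
  hits <- stats::rbinom(n_pairs, k, 0.5)
  mean(hits %% 2L == 1L)
}

# orient ground-truth arc positions the same way measurements are oriented
orient_truth <- function(pos, centromere, L) {
  if (!is.na(centromere) && centromere > L / 2) pos <- L - pos
  sort(pos)
}
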