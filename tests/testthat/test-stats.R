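test_that("count summaries reproduce the moment identities", {
  s <- summarize_counts(c(22, 23, 24))
  expect_equal(s$mean, 23)
  expect_equal(s$sd, 1)
  expect_equal(s$se, 1 / sqrt(3))
  expect_equal(s$cv, 100 / 23)

  s0 <- summarize_counts(c(23, 23, 23))
  expect_equal(s0$sd, 0)
  expect_equal(s0$cv, 0)

  # n < 2: sd/se/cv missing
  s1 <- summarize_counts(5, "g")
  expect_true(is.na(s1$sd) && is.na(s1$se) && is.na(s1$cv))

  # identities hold on random grouped inputs
  set.seed(7)
  v <- rpois(60, 23)
  g <- sample(letters[1:3], 60, TRUE)
  ss <- summarize_counts(v, g)
  expect_equal(ss$se * sqrt(ss$n), ss$sd, tolerance = 1e-9)
  expect_equal(ss$cv * ss$mean, 100 * ss$sd, tolerance = 1e-9)
})

test_that("per-mouse SE and CV arithmetic matches the published rows", {
  tab <- mlh1_count_table()
  m1 <- tab[tab$mouse_id == "MAD_m1", ]
  r <- summary_row_from_moments(m1$mean, m1$sd, m1$n)
  expect_equal(round(r$se, 3), 0.131)
  expect_lt(abs(r$cv - m1$cv), 0.005)
  # all published rows at once: SE to printed precision, CV within the
  # rounding of the printed inputs
  all_r <- summary_row_from_moments(tab$mean, tab$sd, tab$n)
  expect_true(all(abs(round(all_r$se, 3) - tab$se) <= 0.001))
  expect_true(all(abs(all_r$cv - tab$cv) < 0.005))
})

test_that("group pooling reproduces weighted and unweighted means", {
  tab <- mlh1_count_table()
  wild <- tab[tab$status == "wild", ]
  g <- pool_group(wild)
  expect_equal(g$n, 221)
  expect_equal(round(g$mean_unweighted, 2), 23.50)
  expect_equal(round(g$mean_weighted, 2), 23.53)

  # single mouse: group row equals the mouse row
  one <- pool_group(tab[1, ])
  expect_equal(one$mean_weighted, tab$mean[1])
  expect_equal(one$mean_unweighted, tab$mean[1])
  expect_equal(one$n, tab$n[1])

  # raw-value pooling agrees with direct computation
  vals <- list(c(22, 23, 24), c(23, 25))
  gr <- pool_group(values = vals)
  expect_equal(gr$mean_weighted, mean(unlist(vals)))
  expect_equal(gr$mean_unweighted, mean(c(23, 24)))
  expect_error(pool_group(values = list()), "pool")
})

test_that("map length conversion is exact", {
  expect_equal(map_length_cM(0), 0)
  expect_equal(map_length_cM(23), 1150)
  wild <- mlh1_count_table()
  wild <- wild[wild$status == "wild", ]
  expect_equal(round(map_length_cM(mean(wild$mean)), 1), 1175.2)
})

test_that("focus-class tables reproduce published percentages", {
  t4 <- chr1_summary_table()
  m1 <- t4[t4$mouse_id == "MAD_m1", ]
  n_foci <- rep(0:3, c(m1$n_0focus, m1$n_1focus, m1$n_2foci, m1$n_3foci))
  fc <- focus_class_table(n_foci)
  expect_equal(fc$total, 21)
  expect_equal(round(fc$pct_1), 62)
  expect_equal(round(fc$pct_2), 38)

  # 4 three-foci bivalents among all 255 surveyed: 1.6%
  all_foci <- rep(rep(0:3, nrow(t4)),
                  as.vector(t(t4[, c("n_0focus", "n_1focus", "n_2foci", "n_3foci")])))
  fc_all <- focus_class_table(all_foci)
  expect_equal(fc_all$total, 255)
  expect_equal(fc_all$n_3plus, 4)
  expect_equal(round(fc_all$pct_3plus, 1), 1.6)

  # empty input: zero table
  fc0 <- focus_class_table(integer(0))
  expect_equal(fc0$total, 0)
  expect_equal(fc0$n_1, 0)

  # counts always sum to the total
  expect_equal(fc_all$n_0 + fc_all$n_1 + fc_all$n_2 + fc_all$n_3plus,
               fc_all$total)
})

test_that("position histograms bin and conserve counts", {
  h <- position_histogram(0.50, "1-focus")
  expect_equal(nrow(h), 20)
  expect_equal(h$count[h$bin_lo == 0.50], 1)
  expect_equal(sum(h$count), 1)

  two <- replicate(7, sort(runif(2)), simplify = FALSE)
  h2 <- position_histogram(two, "2-foci")
  expect_equal(sum(h2$count_first), 7)
  expect_equal(sum(h2$count_second), 7)

  expect_error(position_histogram(1.2, "1-focus"), "\\[0, 1\\]")

  # uniform positions look uniform: chi-square vs uniform non-significant
  # at alpha = 0.01 in at least 95% of seeded replicates
  set.seed(41)
  rej <- replicate(100, {
    hh <- position_histogram(runif(200), "1-focus")
    suppressWarnings(chisq.test(hh$count)$p.value) < 0.01
  })
  expect_lte(mean(rej), 0.05)
})

test_that("KS comparison behaves on degenerate and calibrated inputs", {
  x <- c(0.1, 0.4, 0.5, 0.9)
  same <- ks_compare(x, x)
  expect_equal(same$D, 0)

  # disjoint supports: D = 1
  sep <- ks_compare(runif(20, 0, 0.4), runif(20, 0.6, 1))
  expect_equal(sep$D, 1)

  expect_error(ks_compare(numeric(0), x), "at least 2")

  # equal distributions reject at about the nominal rate
  set.seed(43)
  rej <- replicate(200, ks_compare(runif(40), runif(40))$p_value < 0.05)
  expect_gte(mean(rej), 0.005)
  expect_lte(mean(rej), 0.10)
})

test_that("gamma MLE recovers known shapes", {
  set.seed(5)
  x <- rgamma(10000, shape = 11, scale = 0.5)
  f <- fit_gamma_mle(x)
  expect_gte(f$shape, 10); expect_lte(f$shape, 12)

  # exponential data: shape near 1
  set.seed(6)
  e <- rexp(10000, rate = 2)
  fe <- fit_gamma_mle(e)
  expect_gte(fe$shape, 0.9); expect_lte(fe$shape, 1.1)

  # agrees with an independent ML fitter
  skip_if_not_installed("fitdistrplus")
  fd <- suppressWarnings(fitdistrplus::fitdist(x, "gamma"))
  expect_equal(f$shape, unname(fd$estimate["shape"]), tolerance = 1e-2)

  # zero-variance sample: shape unbounded
  expect_error(fit_gamma_mle(rep(2, 50)), "degenerate")
  expect_error(fit_gamma_mle(c(-1, 2, 3)), "positive")
})

test_that("fit_interference computes distances, modes and the outlier rule", {
  set.seed(8)
  L <- runif(40, 110, 140)
  d_px <- rgamma(40, shape = 10, scale = 6)
  first <- runif(40, 5, 30)
  m <- data.frame(sc_length_px = L, sc_length_um = L / 9.8152,
                  foci_pos_px = paste(round(first, 3),
                                      round(pmin(first + d_px, L - 2), 3),
                                      sep = ";"))
  fit <- fit_interference(m, mode = "absolute_um", outlier_min_distance = 0)
  expect_gt(fit$nu, 1)
  expect_equal(fit$n_distances, 40)

  fitn <- fit_interference(m, mode = "normalized")
  expect_equal(fitn$mode, "normalized")

  # distances below the floor are excluded and reported
  m2 <- m
  m2$foci_pos_px[1] <- "50.000;53.000"   # 0.31 um apart
  fit2 <- fit_interference(m2, mode = "absolute_um", outlier_min_distance = 1)
  expect_equal(fit2$n_distances, 39)
  expect_length(fit2$excluded, 1)

  expect_error(fit_interference(m[1:4, ], mode = "absolute_um",
                                outlier_min_distance = 0), ">= 10")
})

test_that("rbar closed form matches the chromatid-simulation oracle", {
  expect_equal(rbar_intra(numeric(0)), 0)
  # frozen oracle values (mc_rbar_oracle at 1e6 gametes agrees to 2e-3):
  # one central crossover -> 0.25; crossovers at 0.2/0.8 -> 0.28
  expect_equal(rbar_intra(0.5), 0.25)
  expect_equal(rbar_intra(c(0.2, 0.8)), 0.28)
  expect_lt(abs(rbar_intra(0.5) - mc_rbar_oracle(0.5, 2e5, seed = 1)), 0.004)
  expect_lt(abs(rbar_intra(c(0.2, 0.8)) -
                  mc_rbar_oracle(c(0.2, 0.8), 2e5, seed = 2)), 0.004)

  expect_error(rbar_intra(c(0.8, 0.2)), "sorted")
  expect_error(rbar_intra(1.4), "\\[0, 1\\]")

  # bounded by [0, 0.5] on random configurations
  set.seed(9)
  for (i in 1:50) {
    v <- rbar_intra(sort(runif(sample(0:5, 1))))
    expect_gte(v, 0); expect_lte(v, 0.5)
  }

  rg <- rbar_group(list(0.5, c(0.2, 0.8), numeric(0)), c("a", "a", "b"))
  expect_equal(rg$group_means$mean_rbar, c(mean(c(0.25, 0.28)), 0))
})

test_that("permutation test matches exhaustive enumeration and is calibrated", {
  # small 4 + 4 mouse layout: enumerate all label assignments exactly
  set.seed(10)
  vals <- lapply(1:8, function(i) rnorm(6, sd = 1))
  status <- rep(c("w", "l"), each = 4)
  pm <- permutation_test_variance(vals, status, "within_mouse_variance",
                                  n_perm = 4000, seed = 3)
  v <- vapply(vals, var, 0)
  combs <- combn(8, 4)
  stats_all <- apply(combs, 2, function(ix)
    mean(v[ix]) - mean(v[-ix]))
  obs <- mean(v[1:4]) - mean(v[5:8])
  p_exact <- mean(abs(stats_all) >= abs(obs) - 1e-12)
  expect_lt(abs(pm$p_value - p_exact), 0.02)

  # among-mouse level runs and is reproducible from the seed
  pa <- permutation_test_variance(vals, status, "among_mouse_variance",
                                  n_perm = 500, seed = 4)
  pb <- permutation_test_variance(vals, status, "among_mouse_variance",
                                  n_perm = 500, seed = 4)
  expect_identical(pa$p_value, pb$p_value)

  expect_error(permutation_test_variance(vals[1:3], c("w", "w", "l"),
                                         "within_mouse_variance"), ">= 2")
  expect_error(permutation_test_variance(vals, rep("w", 8),
                                         "within_mouse_variance"),
               "two levels")

  # power: groups with a 10-fold variance ratio are usually detected
  set.seed(11)
  hits <- vapply(1:40, function(i) {
    a <- lapply(1:8, function(j) rnorm(8, sd = 1))
    b <- lapply(1:8, function(j) rnorm(8, sd = sqrt(10)))
    permutation_test_variance(c(a, b), rep(c("w", "l"), each = 8),
                              "within_mouse_variance", n_perm = 300,
                              seed = i)$p_value < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("logistic model recovers effects and refuses degenerate input", {
  set.seed(12)
  n <- 500
  len <- runif(n, 10, 16)
  beta1 <- 1.5
  p <- plogis(-18 + beta1 * len)
  cls <- ifelse(runif(n) < p, 2L, 1L)
  fit <- logistic_focus_model(len, cls)
  b1 <- fit$coefficients$estimate[fit$coefficients$term == "sc_length"]
  expect_gte(b1, 1.1); expect_lte(b1, 1.9)

  # null effect: coefficient near zero, p usually > 0.05
  set.seed(13)
  null_p <- replicate(20, {
    cls0 <- sample(1:2, n, TRUE)
    f0 <- logistic_focus_model(len, cls0)
    f0$coefficients$p_value[f0$coefficients$term == "sc_length"]
  })
  expect_gte(mean(null_p > 0.05), 0.9)

  # month covariate is accepted
  fm <- logistic_focus_model(len, cls, month = sample(1:10, n, TRUE))
  expect_true("month" %in% fm$coefficients$term)

  expect_error(logistic_focus_model(len, rep(1L, n)), "both focus classes")
})
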