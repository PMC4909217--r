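test_that("ULF conversion matches the traced-length formula", {
  expect_equal(length_to_ulfs(60), 1)
  expect_equal(round(length_to_ulfs(353), 1), 7.9)
  expect_equal(length_to_ulfs(353), (353 - 60) / 42.7 + 1)
  expect_equal(round(length_to_ulfs(2100)), 49)
  expect_error(length_to_ulfs(50), "below one ULF")
})

test_that("ulfs_to_length is the exact inverse", {
  expect_equal(ulfs_to_length(1), 60)
  expect_equal(ulfs_to_length(2), 102.7)
  expect_error(ulfs_to_length(0.5), "at least 1")
  set.seed(1)
  i <- runif(100, 1, 80)
  expect_equal(length_to_ulfs(ulfs_to_length(i)), i, tolerance = 1e-12)
  expect_true(all(diff(ulfs_to_length(sort(i))) > 0))
})

test_that("summarize_lengths reports count, means and SD", {
  d <- length_distribution(c(60, 102.7))
  s <- summarize_lengths(d)
  expect_equal(s$n, 2)
  expect_equal(s$mean_ulf, 1.5)
  s1 <- summarize_lengths(length_distribution(rep(500, 5)))
  expect_equal(s1$sd_ulf, 0)
  # oracle: independent recomputation from first principles
  set.seed(3)
  lens <- runif(200, 60, 4000)
  s2 <- summarize_lengths(length_distribution(lens))
  u <- (lens - 60) / 42.7 + 1
  expect_equal(s2$mean_length_um, mean(lens) / 1000)
  expect_equal(s2$mean_ulf, mean(u))
  expect_equal(s2$sd_ulf, sd(u))
  expect_error(length_distribution(numeric(0)), "no lengths")
  expect_error(length_distribution(30), "at least one ULF")
})

test_that("number histogram bins are left-closed with unit origin", {
  d <- length_distribution(c(1, 1, 2, 2), unit = "ulf")
  h <- number_histogram(d, 1)
  expect_equal(h$fraction, c(0.5, 0.5))
  expect_equal(h$bin_lo_ulf, c(1, 2))

  one <- number_histogram(length_distribution(rep(150, 7)), 5)
  expect_equal(one$fraction, 1)

  set.seed(4)
  lens <- ulfs_to_length(sample(1:40, 500, replace = TRUE))
  h <- number_histogram(length_distribution(lens), 5)
  expect_equal(sum(h$fraction), 1, tolerance = 1e-12)
  # brute-force recount
  u <- length_to_ulfs(lens)
  for (r in seq_len(nrow(h)))
    expect_equal(h$count[r], sum(u >= h$bin_lo_ulf[r] & u < h$bin_hi_ulf[r]))
})

test_that("mass-weighted histogram weights bins by total length", {
  d <- length_distribution(c(1, 3), unit = "ulf")
  num <- number_histogram(d, 1)
  mass <- mass_weighted_histogram(d, 1)
  expect_equal(num$fraction, c(0.5, 0, 0.5))
  l1 <- ulfs_to_length(1)
  l3 <- ulfs_to_length(3)
  expect_equal(mass$fraction, c(l1, 0, l3) / (l1 + l3))

  # equal lengths: mass fractions equal number fractions
  d2 <- length_distribution(rep(5, 9), unit = "ulf")
  expect_equal(mass_weighted_histogram(d2, 2)$fraction,
               number_histogram(d2, 2)$fraction)

  # heterogeneous lengths always shift mass toward longer bins
  set.seed(5)
  lens <- ulfs_to_length(1 + rexp(800, 1 / 10))
  d3 <- length_distribution(lens)
  num <- number_histogram(d3, 5)$fraction
  mass <- mass_weighted_histogram(d3, 5)$fraction
  expect_equal(sum(mass), 1, tolerance = 1e-12)
  expect_lt(mass[1], num[1])          # short bin loses weight
  n <- length(num)
  expect_gt(sum(mass[(n %/% 2):n]), sum(num[(n %/% 2):n]))  # long bins gain
  # oracle
  u <- length_to_ulfs(lens)
  h <- mass_weighted_histogram(d3, 5)
  for (r in seq_len(nrow(h)))
    expect_equal(h$total_length_nm[r],
                 sum(lens[u >= h$bin_lo_ulf[r] & u < h$bin_hi_ulf[r]]))
})

test_that("lp-normalized fractions are length-weighted lp-multiples", {
  lp <- 1000
  d <- length_distribution(c(0.5, 1.5, 3.5) * lp)
  f <- lp_normalized_fractions(d, lp)
  expect_equal(f$fraction[1], 0.5 / 5.5)
  expect_equal(sum(f$fraction), 1, tolerance = 1e-12)
  expect_equal(f$k, 0:3)

  all_short <- length_distribution(runif(50, 60, 900))
  expect_equal(lp_normalized_fractions(all_short, lp)$fraction, 1)

  set.seed(6)
  lens <- runif(300, 60, 8000)
  f <- lp_normalized_fractions(length_distribution(lens), lp)
  for (r in seq_len(nrow(f)))
    expect_equal(f$fraction[r],
                 sum(lens[lens >= f$bin_lo_nm[r] & lens < f$bin_hi_nm[r]]) /
                   sum(lens))
})

test_that("elongation constants reproduce the reference kinetics values", {
  expect_equal(elongation_constant(1, 0.5, 100), 0)
  # vimentin 2 h and keratin 1 min rows
  expect_equal(round(elongation_constant(35, 0.1, 7200), 2), 0.05)
  expect_equal(round(elongation_constant(3.7, 0.0025, 60)), 18)
  # vimentin 10 min and 4 h rows
  expect_equal(round(elongation_constant(7.9, 0.1, 600), 2), 0.12)
  expect_equal(round(elongation_constant(49, 0.1, 14400), 2), 0.03)
  # scaling invariance c -> k c, t -> t / k
  expect_equal(elongation_constant(12, 0.3, 500),
               elongation_constant(12, 3, 50))
})

test_that("mass concentration links the reference (c, V, n0) run triples", {
  p <- vim_params()
  runs <- data.frame(c = c(0.10, 2.19, 7.46, 17.8, 17.5),
                     V = c(28.0, 7.63, 2.24, 0.94, 7.63),
                     n0 = c(1000, 5832, 5832, 5832, 46656))
  for (r in seq_len(nrow(runs)))
    expect_equal(mass_concentration(runs$n0[r], runs$V[r], p), runs$c[r],
                 tolerance = 0.03)
  # inverse round-trips through the same constant
  for (r in seq_len(nrow(runs)))
    expect_equal(ulfs_for_concentration(runs$c[r], runs$V[r], p),
                 runs$n0[r], tolerance = 0.03 * runs$n0[r])
  expect_equal(mass_concentration(0, 1, p), 0)
})

test_that("normalized sweeps and fold reduction are plain arithmetic", {
  expect_equal(normalized_sweeps(17.8, 4.30e6), 76.5e6, tolerance = 0.01)
  expect_equal(normalized_sweeps(0.10, 750e6), 75e6)
  expect_equal(normalized_sweeps(1, 123), 123)
  expect_equal(fold_reduction(300000, 9000), 33.3, tolerance = 0.01)
  expect_equal(fold_reduction(64, 64), 1)
  # tracing aggregate: N-weighted mean ULF over the three time points
  N <- c(2324, 3674, 2944)
  ln <- c(7.9, 35, 49)
  expect_equal(fold_reduction(sum(N * ln), sum(N)), 33, tolerance = 0.02)
})

test_that("system_length_distribution converts ULF counts to lengths", {
  sys <- make_reactive_pair(11, 0)
  run <- run_assembly(sys, max_sweeps = 1, record_every = 1, seed = 1)
  d <- system_length_distribution(run$system)
  expect_equal(d$lengths_nm, 102.7)  # one 2-ULF filament
})
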