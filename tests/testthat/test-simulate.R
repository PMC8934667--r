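test_that("wild-type expected map is a unit-mean Toeplitz decay", {
  p <- toy_sim_params()
  wt <- expected_map(p, "wt")
  expect_equal(mean(wt$values), 1)
  expect_identical(wt$values, t(wt$values))
  # diagonal-constant: every cell depends only on the bin separation
  n <- wt$n_bins
  expect_equal(wt$values[cbind(1:(n - 5), 6:n)],
               rep(wt$values[1, 6], n - 5))
  expect_gt(wt$values[1, 2], wt$values[1, 10])
})

test_that("mutant expected map carries each planted signature", {
  p <- toy_sim_params()
  wt <- expected_map(p, "wt")
  mut <- expected_map(p, "mutant")
  n <- wt$n_bins
  sep <- separation_matrix(n, bin_size = p$bin_size)
  ter_bins <- 57:80  # bins overlapping 280-400 kb
  out <- !(seq_len(n) %in% ter_bins)
  rat <- log2(mut$values / wt$values)
  band <- sep >= p$precat_range[1] & sep <= p$precat_range[2]
  oo <- outer(out, out, "&")
  # multiplicative band outside the terminus (up to the global rescale)
  band_lr <- mean(rat[oo & band]) - mean(rat[oo & sep > p$precat_range[2]])
  expect_equal(band_lr, log2(1 + p$beta), tolerance = 0.02)
  # terminus mid-range depletion
  tt <- outer(!out, !out, "&")
  expect_lt(mean(rat[tt & sep >= p$short_range]), log2(p$iota) / 2)
  # short-range terminus gain relative to outside
  d0 <- diag(rat)
  expect_gt(mean(d0[ter_bins]), mean(d0[out]))
  # wings: excess is distance-independent and spares the dif bin
  difb <- 69L
  cells <- butterfly_cells(p$genome, p$bin_size, exclude = difb,
                           guard = p$wing_guard, width = p$wing_width)
  excess <- mut$values / mean(mut$values) - wt$values / mean(wt$values)
  dl <- distance_law_test(excess, cells, bin_size = p$bin_size)
  expect_lt(abs(dl$slope), 0.1)
  expect_gt(min(excess[cells]), 0)
  arm_bin <- setdiff(which(out), seq_len(n)[abs(seq_len(n) - difb) * p$bin_size <= p$wing_guard])
  expect_lt(mean(excess[difb, arm_bin]), 0.5 * mean(excess[difb + 1, arm_bin]))
})

test_that("wing amplitude is calibrated to the normalized pooled fold", {
  p <- toy_sim_params(alpha = 1.5)
  wtn <- scn_normalize(expected_map(p, "wt"))
  mutn <- scn_normalize(expected_map(p, "mutant"))
  r <- ratio_map(mutn, wtn)
  we <- wing_enrichment(r, exclude = 69L, guard = p$wing_guard,
                        width = p$wing_width)
  expect_equal(we$fold, 1.5, tolerance = 0.02)
})

test_that("sample_counts is reproducible, respects masks and Poisson tails", {
  p <- toy_sim_params()
  wt <- expected_map(p, "wt")
  a <- sample_counts(wt, 2e5, seed = 3)
  b <- sample_counts(wt, 2e5, seed = 3)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, sample_counts(wt, 2e5, seed = 4)$values))
  expect_equal(sum(a$values[upper.tri(a$values, diag = TRUE)]), 2e5,
               tolerance = 0.02)
  # masked (all-zero) expected rows stay empty
  v <- wt$values; g <- wt$genome
  wtm <- contact_map(g, p$bin_size, v,
                     mask = seq_len(nrow(v)) <= 5, state = "expected")
  cm <- sample_counts(wtm, 1e5, seed = 5)
  expect_true(all(cm$values[1:5, ] == 0))
  # uniform expected: counts within 5 sd of the mean for ~99.9% of cells
  u <- contact_map(genome("u", length = 5e4), 1000,
                   matrix(1, 50, 50), state = "expected")
  cu <- sample_counts(u, 127500, seed = 6)  # mean 100 per upper cell
  ut <- upper.tri(cu$values, diag = TRUE)
  frac <- mean(abs(cu$values[ut] - 100) <= 5 * 10)
  expect_gte(frac, 0.998)
})

test_that("sample_pairs round-trips exactly through ingest and is seed-stable", {
  p <- toy_sim_params()
  mut <- expected_map(p, "mutant")
  f1 <- tempfile(fileext = ".pairs"); f2 <- tempfile(fileext = ".pairs")
  s1 <- sample_pairs(mut, total_pairs = 5e4, seed = 9, mapq_noise = 0.2,
                     path = f1)
  s2 <- sample_pairs(mut, total_pairs = 5e4, seed = 9, mapq_noise = 0.2,
                     path = f2)
  expect_identical(readLines(f1), readLines(f2))
  pr <- read_pairs(f1)
  m <- build_matrix(pr, p$genome, p$bin_size)
  expect_equal(m$values, s1$counts$values, ignore_attr = TRUE)
  fl <- filter_pairs(pr, mapq_min = 31, chroms = p$genome)
  expect_equal(fl$stats$retained_fraction, 0.8, tolerance = 0.02)
  unlink(c(f1, f2))
})

test_that("wt/wt ratio maps from independent seeds show no spurious structure", {
  p <- toy_sim_params(bin_size = 5e4)
  wt <- expected_map(p, "wt")
  norm <- function(seed) scn_normalize(mask_sparse_bins(
    sample_counts(wt, 2e5, seed = seed)))
  r <- ratio_map(norm(31), norm(32))
  expect_lt(abs(mean(r$values, na.rm = TRUE)), 0.02)
  # recovery error shrinks with depth
  deep <- function(seed) scn_normalize(mask_sparse_bins(
    sample_counts(wt, 2e6, seed = seed)))
  r2 <- ratio_map(deep(33), deep(34))
  expect_lt(mean(abs(r2$values), na.rm = TRUE),
            mean(abs(r$values), na.rm = TRUE))
})

test_that("simulate_foci is reproducible and plants recoverable fractions", {
  fp <- foci_sim_params(n_cells = 400)
  a <- simulate_foci(fp, "mutant", seed = 2)
  b <- simulate_foci(fp, "mutant", seed = 2)
  expect_identical(a, b)
  expect_true(all(table(a$cell, a$tag) <= 2))
  # colocalization excess 0: wt and mutant agree within sampling error
  fp0 <- foci_sim_params(n_cells = 500, coloc_p = c(wt = 0.1, mutant = 0.1),
                         var_scale = c(wt = 1, mutant = 1))
  dw <- interfocal_distances(simulate_foci(fp0, "wt", seed = 5),
                             "ter", "left")
  dm <- interfocal_distances(simulate_foci(fp0, "mutant", seed = 6),
                             "ter", "left")
  cw <- coloc_fraction(dw$closest); cm <- coloc_fraction(dm$closest)
  expect_true(cw$fraction >= cm$ci[1] && cw$fraction <= cm$ci[2])
})
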