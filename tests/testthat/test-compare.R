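test_that("ratio_map identities: self-ratio zero, doubling gives 1, pseudocount arithmetic", {
  A <- as_norm_map(decay_matrix(20))
  r0 <- ratio_map(A, A)
  expect_true(all(r0$values == 0))
  B <- as_norm_map(decay_matrix(20) * 2)
  r1 <- ratio_map(B, A, pseudocount = 0)
  expect_true(all(r1$values == 1))
  # mutant 0, control 0.01, p = 0.01 -> log2(0.01/0.02) = -1
  vm <- matrix(0.01, 4, 4); vc <- matrix(0.01, 4, 4)
  vm[2, 3] <- vm[3, 2] <- 0
  r2 <- ratio_map(as_norm_map(vm), as_norm_map(vc), pseudocount = 0.01)
  expect_equal(r2$values[2, 3], -1)
})

test_that("ratio_map is antisymmetric under operand swap and propagates masks", {
  set.seed(5)
  A <- random_map(15, seed = 21, state = "normalized")
  B <- random_map(15, seed = 22, state = "normalized", mask = 6)
  r1 <- ratio_map(A, B)
  r2 <- ratio_map(B, A)
  expect_equal(r1$values, -r2$values)
  expect_true(all(is.na(r1$values[6, ])))
  expect_error(ratio_map(A, random_map(10, seed = 1, state = "normalized")),
               "binning")
})

test_that("scalogram of a map with itself is identically zero", {
  A <- as_norm_map(decay_matrix(100), bin_size = 1000)
  sc <- distance_ratio_plot(A, A, d_min = 1000, d_max = 20000, step = 1000)
  expect_true(all(sc$values == 0))
  expect_equal(dim(sc$values), c(100, 20))
})

test_that("a multiplicative band shows up only in its scalogram distance columns", {
  n <- 200; bs <- 1000
  base <- decay_matrix(n, bin_size = bs)
  sep <- separation_matrix(n, bin_size = bs)
  mut <- base
  band <- sep >= 50000 & sep <= 100000
  mut[band] <- mut[band] * 2
  sc <- distance_ratio_plot(as_norm_map(mut, bs), as_norm_map(base, bs),
                            d_min = 1000, d_max = 90000, step = 1000,
                            pseudocount = 0)
  in_band <- sc$distances >= 50000 & sc$distances <= 90000
  expect_true(all(sc$values[, in_band] == 1))
  expect_true(all(sc$values[, !in_band] == 0))
})

test_that("an anchored enrichment stays confined to bins near the anchor", {
  n <- 100; bs <- 1000
  base <- decay_matrix(n, bin_size = bs)
  mut <- base
  mut[40, ] <- mut[40, ] * 3; mut[, 40] <- mut[40, ]
  sc <- distance_ratio_plot(as_norm_map(mut, bs), as_norm_map(base, bs),
                            d_min = 1000, d_max = 10000, step = 1000,
                            pseudocount = 0)
  touched <- apply(sc$values != 0, 1, any)
  expect_true(all(which(touched) %in% 30:50))
  expect_true(touched[40])
})

test_that("scalogram rejects distances past half the circular genome", {
  A <- as_norm_map(decay_matrix(50))
  expect_error(distance_ratio_plot(A, A, d_max = 25000), "half the genome")
})

test_that("scalogram column means match an independent P(s)-curve log ratio", {
  # distance-modulated multiplicative change: every cell at separation d is
  # scaled by f(d), so column means must equal log2 of the mean-P(s) ratio
  n <- 150; bs <- 1000
  base <- decay_matrix(n, bin_size = bs)
  sep <- separation_matrix(n, bin_size = bs)
  f <- 1 + 0.5 * sin(sep / 20000)
  mut <- base * f
  sc <- distance_ratio_plot(as_norm_map(mut, bs), as_norm_map(base, bs),
                            d_min = 1000, d_max = 60000, step = 1000,
                            pseudocount = 0)
  ps <- function(M, d) {  # independent P(s) routine: direct cell averaging
    idx <- which(sep == d, arr.ind = TRUE)
    mean(M[idx])
  }
  expected <- vapply(sc$distances,
                     function(d) log2(ps(mut, d) / ps(base, d)), numeric(1))
  expect_equal(colMeans(sc$values), expected, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("virtual_4c extracts rows, averages spans and respects symmetry", {
  m <- random_map(30, bin_size = 1000, seed = 31, state = "normalized")
  p5 <- virtual_4c(m, 5 * 1000 - 500)   # a position inside bin 5
  expect_equal(p5$values, m$values[5, ])
  expect_equal(virtual_4c(m, 4500)$values[10], virtual_4c(m, 9500)$values[5])
  sp <- virtual_4c(m, c(4000, 7000))    # bins 5,6,7
  expect_equal(sp$values, colMeans(m$values[5:7, ]))
  u <- matrix(1, 20, 20); diag(u) <- 0
  flat <- virtual_4c(as_norm_map(u), 1500)
  expect_equal(length(unique(flat$values[-2])), 1)
  n <- scn_normalize(random_map(30, seed = 32))
  expect_equal(sum(virtual_4c(n, 0)$values, na.rm = TRUE), 1,
               tolerance = 1e-5)
  mm <- random_map(30, bin_size = 1000, seed = 33, mask = 3,
                   state = "normalized")
  expect_error(virtual_4c(mm, 2500), "fully masked")
})

test_that("zscore_window standardizes query-window contact sums over the target", {
  # build a map whose query-column sums over the target are (1,1,1,1,6)
  v <- matrix(0, 10, 10)
  q <- 1:2; tg <- 5:9
  v[q, tg] <- 0.5
  v[q, 9] <- 3
  v <- (v + t(v))
  m <- as_norm_map(v, bin_size = 100)
  z <- zscore_window(m, query_window = c(0, 200), target_region = c(400, 900))
  expect_equal(unname(z$values), c(-0.5, -0.5, -0.5, -0.5, 2))
  expect_equal(mean(z$values), 0)
  expect_equal(sqrt(mean(z$values^2)), 1)
  flat <- as_norm_map(matrix(1, 10, 10) - diag(0, 10), bin_size = 100)
  expect_error(zscore_window(flat, c(0, 200), c(400, 900)), "degenerate")
  expect_error(zscore_window(m, c(0, 500), c(400, 900)), "disjoint")
})
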