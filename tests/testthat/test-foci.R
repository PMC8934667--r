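foci_row <- function(cell, tag, x, y, len = 3) {
  data.frame(cell = cell, cell_length = len, tag = tag, x = x, y = y,
             axis_pos = pmin(pmax(x / len, 0), 1), stringsAsFactors = FALSE)
}

test_that("interfocal distances: 3-4-5 triangle and multi-focus enumeration", {
  tab <- rbind(foci_row(1, "A", 0, 0), foci_row(1, "B", 3, 4))
  d <- interfocal_distances(tab, "A", "B")
  expect_equal(d$closest, 5)
  expect_equal(d$furthest, 5)
  tab2 <- rbind(foci_row(1, "A", 0, 0), foci_row(1, "A", 2, 0),
                foci_row(1, "B", 1, 0))
  d2 <- interfocal_distances(tab2, "A", "B")
  expect_equal(d2$closest, 1)
  expect_equal(d2$furthest, 1)
  expect_true(all(d2$closest <= d2$furthest))
})

test_that("cells missing a tag are skipped and counted; extra foci are excluded", {
  tab <- rbind(foci_row(1, "A", 0, 0), foci_row(1, "B", 1, 0),
               foci_row(2, "A", 0, 0))
  d <- interfocal_distances(tab, "A", "B")
  expect_equal(nrow(d), 1)
  expect_equal(attr(d, "stats")$skipped, 1)
  tab3 <- rbind(tab, foci_row(3, "A", c(0, 1, 2), 0), foci_row(3, "B", 5, 0))
  expect_warning(d3 <- interfocal_distances(tab3, "A", "B"), "> 2 foci")
  expect_equal(attr(d3, "stats")$excluded, 1)
  expect_false(3 %in% d3$cell)
  expect_error(interfocal_distances(tab[tab$tag == "A", ], "A", "B"),
               "both tags")
})

test_that("interfocal distances are invariant to tag order", {
  set.seed(9)
  tab <- simulate_foci(foci_sim_params(n_cells = 50), "wt", seed = 9)
  d1 <- interfocal_distances(tab, "ter", "left")
  d2 <- interfocal_distances(tab, "left", "ter")
  expect_equal(d1$closest, d2$closest)
  expect_equal(d1$furthest, d2$furthest)
})

test_that("coloc_fraction counts below-threshold cells with a binomial CI", {
  cf <- coloc_fraction(c(0.1, 0.3, 0.2, 0.5), 0.25)
  expect_equal(cf$fraction, 0.5)
  expect_equal(coloc_fraction(c(0.3, 0.4), 0.25)$fraction, 0)
  expect_equal(coloc_fraction(c(0.1, 0.2), 0.25)$fraction, 1)
  expect_error(coloc_fraction(numeric(0)), "empty")
  # monotone non-decreasing in the threshold
  set.seed(4)
  d <- runif(200)
  th <- seq(0.05, 0.95, by = 0.05)
  fr <- vapply(th, function(t) coloc_fraction(d, t)$fraction, numeric(1))
  expect_true(all(diff(fr) >= 0))
})

test_that("variance F test follows the larger-over-smaller convention", {
  a <- c(1, 3, 5, 7, 9); b <- c(2, 3, 4, 5, 6)  # variances 10 and 2.5
  ft <- variance_f_test(a, b)
  expect_equal(ft$F, 4)
  expect_equal(ft$variance_ratio, 4)
  ft_swap <- variance_f_test(b, a)
  expect_equal(ft_swap$F, 4)
  expect_equal(ft_swap$p_value, ft$p_value)
  expect_equal(ft_swap$variance_ratio, 1 / 4)
  same <- variance_f_test(a, a)
  expect_equal(same$F, 1)
  expect_equal(same$p_value, 1)
  expect_error(variance_f_test(c(1, 1, 1), a), "zero variance")
})

test_that("variance F test agrees with stats::var.test", {
  set.seed(11)
  for (k in 1:5) {
    a <- rnorm(30, sd = runif(1, 0.5, 2))
    b <- rnorm(40, sd = runif(1, 0.5, 2))
    ft <- variance_f_test(a, b)
    vt <- stats::var.test(a, b)
    expect_equal(ft$p_value, vt$p.value, tolerance = 1e-12)
  }
})

test_that("relative positions fold and orient cell-axis coordinates", {
  tab <- foci_row(1:10, "A", 1.5, 0)  # all at mid-cell of 3-um cells
  rp <- relative_positions(tab, "A")
  expect_equal(sum(rp$counts), 10)
  expect_true(all(rp$coords == 0.5))
  # symmetric quarter/three-quarter mixture folds to one mode at 1/4
  tab2 <- rbind(foci_row(1:50, "A", 0.75, 0), foci_row(51:100, "A", 2.25, 0))
  rp2 <- relative_positions(tab2, "A", fold = TRUE)
  expect_true(all(abs(rp2$coords - 0.25) < 1e-12))
  # orientation reflects two-focus cells so the first focus is left
  tab3 <- rbind(foci_row(1, "A", 2.4, 0), foci_row(1, "A", 2.7, 0))
  rp3 <- relative_positions(tab3, "A", orient = TRUE)
  expect_equal(sort(rp3$coords), c(0.1, 0.2))
  expect_error(relative_positions(tab, "missing"), "not present")
})

test_that("planted colocalization and variance ratios are recovered at n = 600", {
  fp <- foci_sim_params(n_cells = 600)
  # colocalization: planted 0.09 (wt) and 0.18 (mutant)
  dw <- interfocal_distances(simulate_foci(fp, "wt", seed = 19),
                             "ter", "left")
  dm <- interfocal_distances(simulate_foci(fp, "mutant", seed = 119),
                             "ter", "left")
  cw <- coloc_fraction(dw$closest)
  cm <- coloc_fraction(dm$closest)
  expect_true(cw$ci[1] <= 0.09 && 0.09 <= cw$ci[2])
  expect_true(cm$ci[1] <= 0.18 && 0.18 <= cm$ci[2])
  # variance ratio: planted scale 0.5, colocalization off for a pure test
  fpv <- foci_sim_params(n_cells = 600, coloc_p = c(wt = 0, mutant = 0),
                         p_two_foci = 0)
  vw <- interfocal_distances(simulate_foci(fpv, "wt", seed = 23),
                             "ter", "left")
  vm <- interfocal_distances(simulate_foci(fpv, "mutant", seed = 24),
                             "ter", "left")
  ft <- variance_f_test(vw$closest, vm$closest)
  planted <- 1 / 0.5
  ci <- planted * c(1 / stats::qf(0.975, ft$df[1], ft$df[2]),
                    stats::qf(0.975, ft$df[1], ft$df[2]))
  expect_true(ft$variance_ratio >= ci[1] && ft$variance_ratio <= ci[2])
  expect_lt(ft$p_value, 0.05)
})
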