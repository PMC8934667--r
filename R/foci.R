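#' Parameters for the synthetic foci-table generator
#'
#' Describes a two-color tagged-locus imaging experiment: per cell, one or
#' two foci per tag with 2-D coordinates (µm) in the cell, an inter-tag
#' distance drawn from a bounded baseline distribution, and two mutant
#' modifiers — an excess colocalization probability (the pair is placed
#' closer than the colocalization threshold) and a variance scale applied
#' to the baseline distance spread. The baseline distance is bounded away
#' from the colocalization threshold (support starts at \code{d_floor} >
#' threshold), so the planted colocalization probability and variance
#' ratio are exactly recoverable by [coloc_fraction()] and
#' [variance_f_test()].
#'
#' @param n_cells cells per condition (default 600, a typical per-strain
#'   count in this kind of experiment).
#' @param tags names of the two tags.
#' @param cell_length_mean,cell_length_sd cell length distribution, µm
#'   (truncated below at 1.5 µm).
#' @param p_two_foci probability that a tag shows two foci (requires cell
#'   length >= 2 µm; the sister pair sits in the other cell half).
#' @param d_floor,d_spread baseline inter-tag distance is \code{d_floor +
#'   d_spread * Beta(a, b)} µm.
#' @param beta_a,beta_b Beta shape parameters of the baseline distance.
#' @param coloc_p named vector: colocalization probability per condition
#'   (distance drawn uniform below \code{coloc_max}).
#' @param var_scale named vector: baseline distance variance scale per
#'   condition (spread rescaled by \code{sqrt(var_scale)} about its mean).
#' @param coloc_max upper bound of colocalized distances, µm.
#' @return A list of class \code{"foci_sim_params"}.
#' @export
foci_sim_params <- function(n_cells = 600, tags = c("ter", "left"),
                            cell_length_mean = 2.5, cell_length_sd = 0.4,
                            p_two_foci = 0.4,
                            d_floor = 0.3, d_spread = 0.6,
                            beta_a = 2, beta_b = 2,
                            coloc_p = c(wt = 0.09, mutant = 0.18),
                            var_scale = c(wt = 1, mutant = 0.5),
                            coloc_max = 0.22) {
  stopifnot(n_cells > 0, length(tags) == 2,
            all(coloc_p >= 0), all(coloc_p <= 1), all(var_scale > 0),
            coloc_max < d_floor)
  structure(list(n_cells = n_cells, tags = tags,
                 cell_length_mean = cell_length_mean,
                 cell_length_sd = cell_length_sd,
                 p_two_foci = p_two_foci, d_floor = d_floor,
                 d_spread = d_spread, beta_a = beta_a, beta_b = beta_b,
                 coloc_p = coloc_p, var_scale = var_scale,
                 coloc_max = coloc_max),
            class = "foci_sim_params")
}

#' Simulate a per-cell foci coordinate table
#'
#' Generates the coordinate table a spot-detection pipeline would produce
#' for a two-color tagged-locus experiment, under the model of
#' [foci_sim_params()]. Reproducible under a fixed seed.
#'
#' @param params a [foci_sim_params()].
#' @param condition \code{"wt"} or \code{"mutant"}.
#' @param seed RNG seed.
#' @return A \code{data.frame} of class \code{"foci_table"} with columns
#'   \code{cell, cell_length, tag, x, y, axis_pos} (µm; \code{axis_pos} in
#'   [0, 1]).
#' @export
simulate_foci <- function(params, condition = c("wt", "mutant"), seed = 1L) {
  condition <- match.arg(condition)
  p <- params
  set.seed(seed)
  nc <- p$n_cells
  len <- pmax(1.5, stats::rnorm(nc, p$cell_length_mean, p$cell_length_sd))
  coloc <- stats::runif(nc) < p$coloc_p[[condition]]
  v <- p$var_scale[[condition]]
  bmean <- p$beta_a / (p$beta_a + p$beta_b)
  bdraw <- stats::rbeta(nc, p$beta_a, p$beta_b)
  d <- p$d_floor + p$d_spread * (bmean + (bdraw - bmean) * sqrt(v))
  d[coloc] <- stats::runif(sum(coloc)) * p$coloc_max
  # first focus of tag A near the quarter position; B at distance d,
  # displaced mostly along the cell axis so both stay inside the cell
  ax <- len * stats::runif(nc, 0.22, 0.28)
  ay <- stats::runif(nc, -0.05, 0.05)
  theta <- stats::runif(nc, -pi / 12, pi / 12)
  bx <- ax + d * cos(theta)
  by <- ay + d * sin(theta)
  # sisters only in cells long enough that cross-pair distances stay above
  # the colocalization threshold (no spurious colocalization)
  two <- stats::runif(nc) < p$p_two_foci & len >= 2.6
  rows <- list(
    data.frame(cell = seq_len(nc), cell_length = len, tag = p$tags[1],
               x = ax, y = ay, stringsAsFactors = FALSE),
    data.frame(cell = seq_len(nc), cell_length = len, tag = p$tags[2],
               x = bx, y = by, stringsAsFactors = FALSE))
  if (any(two)) {
    # sister pair in the other cell half, far enough that every cross-pair
    # distance stays above the baseline floor; the sister A-B distance
    # follows the baseline law (never the colocalization draw, which is
    # decided once per cell)
    idx <- which(two)
    sax <- len[idx] * stats::runif(length(idx), 0.75, 0.80)
    say <- stats::runif(length(idx), -0.05, 0.05)
    d2 <- p$d_floor + p$d_spread *
      (bmean + (stats::rbeta(length(idx), p$beta_a, p$beta_b) - bmean) * sqrt(v))
    th2 <- stats::runif(length(idx), -pi / 12, pi / 12)
    rows[[length(rows) + 1]] <-
      data.frame(cell = idx, cell_length = len[idx], tag = p$tags[1],
                 x = sax, y = say, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <-
      data.frame(cell = idx, cell_length = len[idx], tag = p$tags[2],
                 x = sax - d2 * cos(th2), y = say + d2 * sin(th2),
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$cell, out$tag, out$x), ]
  out$axis_pos <- pmin(pmax(out$x / out$cell_length, 0), 1)
  rownames(out) <- NULL
  class(out) <- c("foci_table", "data.frame")
  attr(out, "condition") <- condition
  out
}

#' Per-cell closest and furthest interfocal distances
#'
#' For every cell containing both tags, computes the Euclidean distances
#' between all tagA-by-tagB focus pairs and reports the minimum and
#' maximum (equal when each tag has a single focus). Cells missing a tag
#' are skipped and counted; cells with more than two foci of a tag are
#' excluded with a warning (spot-detection artifacts).
#'
#' @param table a foci table (\code{cell, tag, x, y} columns).
#' @param tagA,tagB tag names.
#' @return A \code{data.frame} with \code{cell, closest, furthest} and a
#'   \code{stats} attribute (cells skipped / excluded).
#' @export
interfocal_distances <- function(table, tagA, tagB) {
  ta <- table[table$tag == tagA, ]
  tb <- table[table$tag == tagB, ]
  if (!nrow(ta) || !nrow(tb)) stop("both tags must be present in >= 1 cell")
  over_a <- names(which(table(ta$cell) > 2))
  over_b <- names(which(table(tb$cell) > 2))
  excluded <- union(over_a, over_b)
  if (length(excluded))
    warning(length(excluded), " cell(s) with > 2 foci per tag excluded")
  cells <- setdiff(intersect(unique(ta$cell), unique(tb$cell)), excluded)
  skipped <- length(setdiff(union(unique(ta$cell), unique(tb$cell)),
                            union(cells, excluded)))
  if (!length(cells)) stop("no cell carries both tags")
  res <- lapply(cells, function(cl) {
    a <- ta[ta$cell == cl, c("x", "y")]
    b <- tb[tb$cell == cl, c("x", "y")]
    dd <- sqrt(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2)
    c(min(dd), max(dd))
  })
  res <- do.call(rbind, res)
  out <- data.frame(cell = cells, closest = res[, 1], furthest = res[, 2])
  attr(out, "stats") <- list(cells = length(cells), skipped = skipped,
                             excluded = length(excluded))
  out
}

#' Colocalization fraction
#'
#' Fraction of cells whose closest interfocal distance falls below a
#' threshold (250 nm by default), with an exact binomial 95\% confidence
#' interval.
#'
#' @param distances numeric vector of per-cell closest distances (µm).
#' @param threshold colocalization threshold, µm.
#' @return A list with \code{fraction}, \code{n}, \code{k}, \code{ci}.
#' @export
coloc_fraction <- function(distances, threshold = 0.25) {
  distances <- distances[!is.na(distances)]
  if (!length(distances)) stop("empty input")
  k <- sum(distances < threshold)
  n <- length(distances)
  ci <- as.numeric(stats::binom.test(k, n)$conf.int)
  list(fraction = k / n, n = n, k = k, ci = ci)
}

#' Two-sided F test for equality of variances
#'
#' Ratio of the larger unbiased sample variance to the smaller, with the
#' two-sided p-value \code{min(1, 2 * P(F > observed))} from the F
#' distribution on the corresponding degrees of freedom.
#'
#' @param sampleA,sampleB numeric vectors (each n >= 2, nonzero variance).
#' @return A list with \code{F} (>= 1), \code{df}, \code{p_value}, and
#'   \code{variance_ratio} = var(A)/var(B) (orientation preserved).
#' @export
variance_f_test <- function(sampleA, sampleB) {
  va <- stats::var(sampleA); vb <- stats::var(sampleB)
  if (is.na(va) || is.na(vb)) stop("each sample needs n >= 2")
  if (va == 0 || vb == 0) stop("zero variance")
  if (va >= vb) {
    f <- va / vb; df <- c(length(sampleA) - 1, length(sampleB) - 1)
  } else {
    f <- vb / va; df <- c(length(sampleB) - 1, length(sampleA) - 1)
  }
  p <- min(1, 2 * stats::pf(f, df[1], df[2], lower.tail = FALSE))
  list(F = f, df = df, p_value = p, variance_ratio = va / vb)
}

#' Relative positions of a tag along the cell axis
#'
#' Bins the cell-axis coordinates (in [0, 1]) of a tag's foci. With
#' \code{orient = TRUE}, cells with two foci are oriented so the first
#' focus lies in the first half of the cell (both coordinates reflected
#' when it does not). With \code{fold = TRUE} coordinates are folded about
#' mid-cell (\code{x -> min(x, 1 - x)}), mapping a symmetric 1/4-3/4
#' pattern onto a single mode at 1/4.
#'
#' @param table a foci table.
#' @param tag tag name.
#' @param orient orient two-focus cells by their first focus.
#' @param fold fold coordinates about mid-cell.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return A list with \code{coords} (the processed coordinates),
#'   \code{mids}, \code{density}, \code{counts}.
#' @export
relative_positions <- function(table, tag, orient = FALSE, fold = FALSE,
                               breaks = seq(0, 1, by = 0.05)) {
  tt <- table[table$tag == tag, ]
  if (!nrow(tt)) stop("tag '", tag, "' not present")
  coords <- numeric(0)
  for (cl in unique(tt$cell)) {
    x <- sort(tt$axis_pos[tt$cell == cl])
    if (orient && length(x) >= 2 && x[1] > 0.5) x <- sort(1 - x)
    coords <- c(coords, x)
  }
  if (fold) coords <- pmin(coords, 1 - coords)
  h <- graphics::hist(coords, breaks = breaks, plot = FALSE)
  list(coords = coords, mids = h$mids, density = h$density,
       counts = h$counts)
}
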