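#' Cell set connecting an anchor span with an arm span
#'
#' Enumerates the matrix cells (i, j) with bin i in the anchor span and bin
#' j in the arm span whose circular separation exceeds a near-diagonal
#' guard, skipping excluded bins (by default the bin containing \emph{dif},
#' which the butterfly wings leave out). Used by [wing_enrichment()] and
#' [distance_law_test()].
#'
#' @param genome a [genome()].
#' @param bin_size bin size in bp.
#' @param anchor,arm half-open bp spans (may wrap on a circular genome).
#' @param exclude integer vector of 1-based bin indices to skip entirely,
#'   or \code{NULL}.
#' @param guard minimum separation in bp (default 300 kb, below which the
#'   diagonal-decay regime dominates).
#' @return Two-column integer matrix of (i, j) cell indices with an
#'   attribute \code{separation} (bp).
#' @export
wing_cells <- function(genome, bin_size, anchor, arm, exclude = NULL,
                       guard = 3e5) {
  n <- n_bins_for(genome, bin_size)
  ab <- bins_of_span(anchor, bin_size, n, genome$circular)
  rb <- bins_of_span(arm, bin_size, n, genome$circular)
  if (!is.null(exclude)) {
    ab <- setdiff(ab, exclude)
    rb <- setdiff(rb, exclude)
  }
  cells <- cbind(i = rep(ab, each = length(rb)),
                 j = rep(rb, times = length(ab)))
  sep <- bin_separation(cells[, 1], cells[, 2], bin_size, n, genome$circular)
  keep <- sep > guard
  cells <- cells[keep, , drop = FALSE]
  attr(cells, "separation") <- sep[keep]
  cells
}

# default anchor spans: the dif-flanking zone, split per wing
dif_wing_anchors <- function(genome, width = 2e5) {
  dif <- genome$anchors[["dif"]]
  if (is.null(dif)) stop("genome has no 'dif' anchor")
  list(left = c(dif - width / 2, dif) %% genome$length,
       right = c(dif, dif + width / 2) %% genome$length)
}

#' Default butterfly cell set
#'
#' The butterfly wings connect the \emph{dif}-proximal zone (200 kb
#' surrounding \emph{dif} by default, bins on both flanks but never the
#' \emph{dif} bin itself) with the rest of the chromosome outside the
#' terminus span: distant regions on either arm contact bins symmetrically
#' localized around \emph{dif}. Requires \code{dif} anchor and a
#' \code{terminus} span on the genome.
#'
#' @inheritParams wing_cells
#' @param width total width in bp of the dif-flanking zone (default
#'   200 kb, i.e. 100 kb per flank).
#' @return Two-column (i, j) cell index matrix with a \code{separation}
#'   attribute.
#' @export
butterfly_cells <- function(genome, bin_size, exclude = NULL, guard = 3e5,
                            width = 2e5) {
  ter <- genome$spans$terminus
  if (is.null(ter)) stop("genome needs a 'terminus' span")
  anch <- dif_wing_anchors(genome, width)
  zone <- c(anch$left[1], anch$right[2])      # dif +/- width/2
  arm <- c(ter[2], ter[1])                    # wrapping complement of Ter
  wing_cells(genome, bin_size, zone, arm, exclude, guard)
}

#' Quantify a butterfly-wing stripe
#'
#' Aggregates a [ratio_map()] over anchor-by-arm cells at separations
#' beyond a near-diagonal guard: returns the mean log2 ratio (the stripe
#' statistic), a per-arm-bin log2 profile (mean over anchor bins, which
#' dips at the excluded \emph{dif} bin when the wings spare it), and a
#' pooled fold enrichment computed from the ratio map's source maps as
#' sum(mutant) / sum(control) over the same cells. The pooled fold is
#' robust at shallow sequencing depth, where per-cell log2 ratios are
#' shrunk toward 0 by the pseudocount.
#'
#' @param ratio a [ratio_map()].
#' @param anchor half-open bp span of the stripe anchor; when both
#'   \code{anchor} and \code{arm} are \code{NULL} the default
#'   [butterfly_cells()] geometry is used (the dif-surrounding zone against
#'   every non-terminus bin).
#' @param arm half-open bp span of the interacting arm.
#' @param exclude 1-based bin indices skipped in both spans; default the
#'   \emph{dif} bin.
#' @param guard minimum separation in bp (default 300 kb).
#' @param width dif-zone width in bp for the default geometry (passed to
#'   [butterfly_cells()]).
#' @return A list with \code{mean_log2}, \code{fold} (pooled),
#'   \code{profile} (data.frame: arm bin, mean log2, pooled fold),
#'   \code{n_cells}, \code{cells}.
#' @export
wing_enrichment <- function(ratio, anchor = NULL, arm = NULL,
                            exclude = dif_bin(ratio), guard = 3e5,
                            width = 2e5) {
  g <- ratio$genome
  if (is.null(anchor) && is.null(arm)) {
    cells <- butterfly_cells(g, ratio$bin_size, exclude, guard, width)
  } else {
    if (is.null(anchor) || is.null(arm))
      stop("supply both 'anchor' and 'arm', or neither")
    cells <- wing_cells(g, ratio$bin_size, anchor, arm, exclude, guard)
  }
  vals <- ratio$values[cells]
  ok <- !is.na(vals)
  if (!any(ok)) stop("no wing cells left after exclusions and masking")
  mut <- ratio$sources$mutant$values[cells]
  ctl <- ratio$sources$control$values[cells]
  arm_bin <- cells[ok, 2]
  prof <- data.frame(
    bin = sort(unique(arm_bin)),
    mean_log2 = as.numeric(tapply(vals[ok], arm_bin, mean)),
    fold = as.numeric(tapply(mut[ok], arm_bin, sum) /
                        tapply(ctl[ok], arm_bin, sum)))
  list(mean_log2 = mean(vals[ok]),
       fold = sum(mut[ok]) / sum(ctl[ok]),
       profile = prof,
       n_cells = sum(ok),
       cells = cells)
}

# 1-based bin index containing the dif anchor
dif_bin <- function(x) {
  dif <- x$genome$anchors[["dif"]]
  if (is.null(dif)) return(NULL)
  bin_of(dif, x$bin_size)
}

#' Distance-law test on a cell set
#'
#' Ordinary least-squares slope of log(contact) versus log(separation)
#' over a set of matrix cells. A genuine 3-D hub such as a butterfly wing
#' yields a slope near 0 on its differential (mutant minus control)
#' contact signal, while the decaying background gives a clearly negative
#' slope. Cells are averaged within each unique separation before fitting
#' (\code{aggregate = TRUE}), which suppresses shot noise on sampled maps;
#' nonpositive aggregated values cannot be log-transformed and are dropped
#' (their number is reported).
#'
#' @param x a [contact_map()], or a plain matrix of contact values (for
#'   example the difference of two normalized maps), with \code{bin_size},
#'   \code{n_bins} and \code{circular} supplied.
#' @param cells two-column (i, j) index matrix, e.g. from [wing_cells()].
#' @param bin_size,circular required when \code{x} is a plain matrix.
#' @param aggregate average cells per unique separation before the fit.
#' @return A list with \code{slope}, \code{ci} (95\% confidence interval),
#'   \code{intercept}, \code{n_points}, \code{n_dropped}.
#' @export
distance_law_test <- function(x, cells, bin_size = NULL, circular = TRUE,
                              aggregate = TRUE) {
  if (inherits(x, "contact_map")) {
    M <- x$values; bin_size <- x$bin_size
    n <- x$n_bins; circular <- x$genome$circular
  } else {
    M <- x
    if (is.null(bin_size)) stop("'bin_size' required for a plain matrix")
    n <- nrow(M)
  }
  sep <- attr(cells, "separation")
  if (is.null(sep))
    sep <- bin_separation(cells[, 1], cells[, 2], bin_size, n, circular)
  v <- M[cells[, 1:2, drop = FALSE]]
  keep <- !is.na(v)
  v <- v[keep]; sep <- sep[keep]
  if (length(v) < 10) stop("need at least 10 cells")
  if (max(sep) / min(sep) < 4)
    stop("insufficient dynamic range: separations must span >= 4-fold")
  if (aggregate) {
    s <- sort(unique(sep))
    v <- as.numeric(tapply(v, sep, mean))
    sep <- s
  }
  pos <- v > 0
  n_dropped <- sum(!pos)
  v <- v[pos]; sep <- sep[pos]
  if (length(v) < 10) stop("fewer than 10 positive points for the log fit")
  fit <- stats::lm(log(v) ~ log(sep))
  # confint warns on numerically perfect fits (e.g. exactly flat cells)
  ci <- tryCatch(suppressWarnings(stats::confint(fit)["log(sep)", ]),
                 error = function(e) c(NA_real_, NA_real_))
  list(slope = unname(stats::coef(fit)[2]), ci = unname(ci),
       intercept = unname(stats::coef(fit)[1]),
       n_points = length(v), n_dropped = n_dropped)
}
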