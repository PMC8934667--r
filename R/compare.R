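#' Log2 ratio matrix of two contact maps
#'
#' Cellwise \code{log2((mutant + p) / (control + p))} on unmasked cells,
#' the standard differential view of two normalized Hi-C maps: gains in the
#' mutant are positive (red in the usual blue-white-red rendering), losses
#' negative. Cells masked in either input are \code{NA} in the output. The
#' default pseudocount is the smallest positive value across both maps,
#' i.e. roughly the weight of a single read pair after normalization.
#'
#' @param mutant,control [contact_map()]s with identical genome, bin size
#'   and state (normally \code{"normalized"}).
#' @param pseudocount nonnegative pseudocount \code{p}; \code{NULL} for the
#'   default policy.
#' @return An object of class \code{"ratio_map"}: list with \code{values}
#'   (symmetric matrix of log2 ratios, \code{NA} where masked), \code{mask},
#'   \code{bin_size}, \code{genome}, \code{pseudocount}, \code{sources}
#'   (the two input maps, kept so downstream quantifiers can pool raw
#'   contact sums).
#' @export
ratio_map <- function(mutant, control, pseudocount = NULL) {
  check_compatible(mutant, control)
  p <- if (is.null(pseudocount)) min_positive(mutant, control) else pseudocount
  stopifnot(p >= 0)
  values <- log2((mutant$values + p) / (control$values + p))
  mask <- mutant$mask | control$mask
  values[mask, ] <- values[, mask] <- NA_real_
  structure(list(values = values, mask = mask, bin_size = mutant$bin_size,
                 genome = mutant$genome, pseudocount = p,
                 sources = list(mutant = mutant, control = control)),
            class = "ratio_map")
}

check_compatible <- function(a, b) {
  if (a$n_bins != b$n_bins || a$bin_size != b$bin_size)
    stop("maps have different binning")
  if (a$genome$length != b$genome$length)
    stop("maps are on different genomes")
  if (a$state != b$state)
    stop("maps have different normalization states (", a$state, " vs ",
         b$state, ")")
  invisible(TRUE)
}

#' @export
print.ratio_map <- function(x, ...) {
  cat("<ratio_map> ", x$genome$name, ": ", nrow(x$values), " bins of ",
      format(x$bin_size, big.mark = ","), " bp, pseudocount ",
      format(x$pseudocount, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Distance-stratified ratio plot (scalogram)
#'
#' For each bin \code{b} and each genomic separation \code{d} on a grid,
#' the average contact \code{AC(b, d)} is the mean of the map values at the
#' two bins exactly \code{d} upstream and downstream of \code{b} (circular
#' wrap; orientations pooled). The scalogram cell is
#' \code{log2((AC_mutant + p) / (AC_control + p))}, displayed as a
#' bin-by-distance heatmap. Cells touching masked bins are \code{NA}.
#'
#' @param mutant,control normalized [contact_map()]s.
#' @param d_min,d_max,step distance grid in bp (defaults 5 kb to 1 Mb in
#'   5 kb increments); on a circular genome \code{d_max} must be below half
#'   the genome length.
#' @param pseudocount as in [ratio_map()].
#' @return An object of class \code{"scalogram"}: \code{values}
#'   (\code{n_bins x n_distances}), \code{distances} (bp), \code{bin_size}.
#' @export
distance_ratio_plot <- function(mutant, control, d_min = 5e3, d_max = 1e6,
                                step = 5e3, pseudocount = NULL) {
  check_compatible(mutant, control)
  g <- mutant$genome
  if (g$circular && d_max >= g$length / 2)
    stop("'d_max' must be below half the genome length on a circular genome")
  distances <- seq(d_min, d_max, by = step)
  offsets <- distances / mutant$bin_size
  if (any(offsets != round(offsets)))
    stop("distance grid must be a multiple of the bin size")
  p <- if (is.null(pseudocount)) min_positive(mutant, control) else pseudocount
  n <- mutant$n_bins
  acm <- average_contacts(mutant, as.integer(round(offsets)))
  acc <- average_contacts(control, as.integer(round(offsets)))
  values <- log2((acm + p) / (acc + p))
  dimnames(values) <- list(NULL, format(distances, scientific = FALSE))
  structure(list(values = values, distances = distances,
                 bin_size = mutant$bin_size, genome = g, pseudocount = p),
            class = "scalogram")
}

# mean of the two cells at +/- k bins from each bin (circular wrap);
# NA where the bin itself or either partner is masked
average_contacts <- function(map, offsets) {
  n <- map$n_bins
  idx <- seq_len(n)
  M <- map$values
  mask <- map$mask
  out <- matrix(NA_real_, n, length(offsets))
  for (c in seq_along(offsets)) {
    k <- offsets[c]
    if (map$genome$circular) {
      up <- ((idx - 1 - k) %% n) + 1L
      dn <- ((idx - 1 + k) %% n) + 1L
      ac <- (M[cbind(idx, up)] + M[cbind(idx, dn)]) / 2
      bad <- mask | mask[up] | mask[dn]
    } else {
      up <- idx - k; dn <- idx + k
      vu <- ifelse(up >= 1, M[cbind(idx, pmax(up, 1L))], NA_real_)
      vd <- ifelse(dn <= n, M[cbind(idx, pmin(dn, n))], NA_real_)
      ac <- rowMeans(cbind(vu, vd), na.rm = TRUE)
      ac[is.nan(ac)] <- NA_real_
      bad <- mask |
        (up >= 1 & mask[pmax(up, 1L)]) | (dn <= n & mask[pmin(dn, n)])
    }
    ac[bad] <- NA_real_
    out[, c] <- ac
  }
  out
}

#' @export
print.scalogram <- function(x, ...) {
  cat("<scalogram> ", nrow(x$values), " bins x ", length(x$distances),
      " distances (", min(x$distances), "-", max(x$distances), " bp)\n",
      sep = "")
  invisible(x)
}

#' Virtual 4C profile
#'
#' Extracts one anchor bin's row of a normalized contact map (or the mean
#' of the rows over an anchor span) as a genome-wide contact-frequency
#' track, the matrix analogue of a 4C experiment. With L1-SCN input a
#' single-bin profile sums to ~1 over unmasked bins.
#'
#' @param map a normalized [contact_map()].
#' @param anchor bp position (length 1) or half-open bp span (length 2;
#'   may wrap on a circular genome).
#' @return An object of class \code{"hic_profile"} with \code{values}
#'   (length \code{n_bins}, \code{NA} at masked bins), \code{kind =
#'   "contact-frequency"}, \code{anchor}, \code{anchor_bins},
#'   \code{bin_size}.
#' @export
virtual_4c <- function(map, anchor) {
  bins <- anchor_bins(map, anchor)
  bins <- bins[!map$mask[bins]]
  if (!length(bins)) stop("anchor fully masked")
  values <- if (length(bins) == 1) map$values[bins, ] else
    colMeans(map$values[bins, , drop = FALSE])
  values[map$mask] <- NA_real_
  structure(list(values = values, kind = "contact-frequency",
                 anchor = anchor, anchor_bins = bins,
                 bin_size = map$bin_size, genome = map$genome),
            class = "hic_profile")
}

anchor_bins <- function(map, anchor) {
  if (length(anchor) == 1) {
    if (anchor < 0 || anchor >= map$genome$length)
      stop("anchor outside genome")
    bin_of(anchor, map$bin_size)
  } else if (length(anchor) == 2) {
    bins_of_span(anchor, map$bin_size, map$n_bins, map$genome$circular)
  } else stop("'anchor' must be a position or a c(start, end) span")
}

#' @export
print.hic_profile <- function(x, ...) {
  cat("<hic_profile> kind=", x$kind, ", ", length(x$values), " bins\n",
      sep = "")
  invisible(x)
}

#' Windowed Z-transformation of contacts
#'
#' Sums the contacts made by a query window with each bin of a disjoint
#' target region, then standardizes the resulting track over the target
#' bins: \code{z_j = (c_j - mean(c)) / sd(c)} with the population standard
#' deviation. This is the representation used to show that a distant window
#' contacts most of the terminus but not the \emph{dif} bin itself.
#'
#' @param map a normalized [contact_map()].
#' @param query_window half-open bp span whose rows are summed.
#' @param target_region half-open bp span over which the track is computed;
#'   must be disjoint from the query window.
#' @return A \code{"hic_profile"} of kind \code{"zscore"} over the target
#'   bins (\code{values} named by 0-based bin index; \code{bins} holds the
#'   1-based indices).
#' @export
zscore_window <- function(map, query_window = c(3500e3, 3600e3),
                          target_region = c(1250e3, 2450e3)) {
  qb <- bins_of_span(query_window, map$bin_size, map$n_bins,
                     map$genome$circular)
  tb <- bins_of_span(target_region, map$bin_size, map$n_bins,
                     map$genome$circular)
  if (length(intersect(qb, tb)))
    stop("query window and target region must be disjoint")
  qb <- qb[!map$mask[qb]]
  if (!length(qb)) stop("query window fully masked")
  tb <- tb[!map$mask[tb]]
  if (!length(tb)) stop("target region fully masked")
  cj <- colSums(map$values[qb, tb, drop = FALSE])
  sdp <- sqrt(mean((cj - mean(cj))^2))
  if (sdp == 0) stop("degenerate target: constant contact sums")
  z <- (cj - mean(cj)) / sdp
  names(z) <- tb - 1L
  structure(list(values = z, kind = "zscore", bins = tb,
                 query_window = query_window, target_region = target_region,
                 bin_size = map$bin_size, genome = map$genome),
            class = "hic_profile")
}
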