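#' Mask under-covered bins
#'
#' Adds to the mask every bin whose marginal sum falls below a fraction of
#' the median nonzero marginal (default 10\%), plus any explicitly listed
#' bins. Masked rows and columns are zeroed; the policy and resulting mask
#' are recorded on the returned map. Normalization quality degrades sharply
#' on bins with very low visibility, so this is applied before
#' [scn_normalize()].
#'
#' @param map a raw [contact_map()].
#' @param min_coverage_fraction threshold as a fraction of the median
#'   nonzero marginal, in \code{[0, 1]}.
#' @param explicit_bins optional integer vector of additional 1-based bin
#'   indices to mask.
#' @return The masked [contact_map()].
#' @export
mask_sparse_bins <- function(map, min_coverage_fraction = 0.1,
                             explicit_bins = NULL) {
  stopifnot(min_coverage_fraction >= 0, min_coverage_fraction <= 1)
  marg <- rowSums(map$values)
  pos <- marg > 0 & !map$mask
  if (!any(pos)) stop("matrix too sparse: all bins masked")
  med <- stats::median(marg[pos])
  mask <- map$mask | marg < min_coverage_fraction * med
  if (!is.null(explicit_bins)) mask[explicit_bins] <- TRUE
  if (all(mask)) stop("matrix too sparse: all bins masked")
  contact_map(map$genome, map$bin_size, map$values, mask = mask,
              state = map$state,
              stats = c(map$stats,
                        list(mask_policy = list(
                          min_coverage_fraction = min_coverage_fraction,
                          threshold = min_coverage_fraction * med))))
}

#' Sequential component normalization (SCN)
#'
#' Iteratively divides each unmasked row by its component norm, then each
#' unmasked column, until the maximum deviation of the unmasked row norms
#' from 1 falls below \code{tol}; the result is then symmetrized by
#' averaging with its transpose. With the default L1 norm every unmasked
#' row sums to 1 (within \code{2 * tol}), so a row reads as the contact
#' frequency distribution of its bin; \code{norm = "l2"} balances Euclidean
#' norms instead.
#'
#' @param map a raw or expected [contact_map()] (already masked if needed).
#' @param tol convergence tolerance on the row-norm deviation.
#' @param max_iter maximum number of row+column sweeps.
#' @param norm \code{"l1"} (sum) or \code{"l2"} (Euclidean).
#' @return A [contact_map()] with \code{state = "normalized"}; masked bins
#'   stay zero. \code{$stats$scn} records iterations and final residual.
#' @export
scn_normalize <- function(map, tol = 1e-6, max_iter = 200,
                          norm = c("l1", "l2")) {
  norm <- match.arg(norm)
  keep <- !map$mask
  if (sum(keep) < 2) stop("need at least 2 unmasked bins")
  M <- map$values[keep, keep, drop = FALSE]
  norm_fun <- if (norm == "l1") rowSums else function(m) sqrt(rowSums(m * m))
  rn <- norm_fun(M)
  if (any(rn == 0))
    stop("unmasked bin with zero marginal; re-mask with mask_sparse_bins()")
  it <- 0L
  repeat {
    it <- it + 1L
    M <- M / norm_fun(M)              # rows (recycles down columns)
    cn <- if (norm == "l1") colSums(M) else sqrt(colSums(M * M))
    M <- sweep(M, 2L, cn, "/")        # columns
    resid <- max(abs(norm_fun(M) - 1))
    if (resid < tol) break
    if (it >= max_iter)
      stop("SCN did not converge in ", max_iter,
           " iterations; last residual ", format(resid))
  }
  M <- (M + t(M)) / 2
  values <- matrix(0, map$n_bins, map$n_bins)
  values[keep, keep] <- M
  contact_map(map$genome, map$bin_size, values, mask = map$mask,
              state = "normalized",
              stats = c(map$stats,
                        list(scn = list(norm = norm, iterations = it,
                                        residual = resid, tol = tol))))
}
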