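#' Simulation parameters for synthetic contact maps
#'
#' Assembles and validates the parameters of the synthetic contact-map
#' generator. The wild-type model is a pure power-law distance decay
#' \code{P(s) = (s0 + s)^(-gamma)} on a circular chromosome; the mutant
#' condition switches on planted, parameterized versions of the chromosome
#' reorganization signatures seen when Topo IV is inactivated:
#' \itemize{
#'   \item a multiplicative \code{(1 + beta)} boost of contacts at 50--300
#'     kb separations outside the terminus ("precatenane" band);
#'   \item depletion (\code{iota}) of mid-range (>= 50 kb) contacts inside
#'     the terminus span, a sharp border at \emph{dif} (cells straddling
#'     \emph{dif} further multiplied by \code{dif_border}), and a
#'     \code{(1 + short_boost)} gain of very short-range (< 50 kb)
#'     terminus contacts;
#'   \item additive, distance-independent "butterfly wing" stripes
#'     connecting each \emph{dif}-flanking zone with its replichore arm,
#'     sparing the \emph{dif} bin. The wing amplitude \code{alpha} is
#'     defined as the pooled fold enrichment of wing cells beyond the
#'     guard, measured between SCN-normalized maps; [expected_map()]
#'     calibrates the planted mass to meet it.
#' }
#'
#' @param genome a [genome()]; defaults to [ecoli_genome()].
#' @param bin_size bin size in bp.
#' @param total_pairs default sequencing depth used by the samplers.
#' @param gamma,s0 decay exponent (> 0) and offset (bp) of \code{P(s)}.
#' @param beta precatenane band amplitude (>= 0).
#' @param precat_range length-2 bp range of the band.
#' @param iota terminus mid-range depletion factor in (0, 1].
#' @param dif_border extra multiplier in (0, 1] for terminus cells
#'   straddling \emph{dif}.
#' @param short_boost terminus short-range gain (>= 0), applied below
#'   \code{short_range} bp.
#' @param short_range boundary between "very short" and "mid" range, bp.
#' @param alpha wing amplitude (>= 1; 1 disables the wings).
#' @param wing_width total width of the dif-flanking zone, bp.
#' @param wing_guard separation beyond which the wing amplitude is
#'   calibrated, bp.
#' @return A list of class \code{"sim_params"}.
#' @export
sim_params <- function(genome = ecoli_genome(), bin_size = 5000,
                       total_pairs = 1e6, gamma = 0.8, s0 = 1e4,
                       beta = 0.1, precat_range = c(5e4, 3e5),
                       iota = 0.5, dif_border = 0.3, short_boost = 0.3,
                       short_range = 5e4, alpha = 1.5, wing_width = 2e5,
                       wing_guard = 3e5) {
  stopifnot(gamma > 0, s0 >= 0, beta >= 0,
            precat_range[1] < precat_range[2],
            iota > 0, iota <= 1, dif_border > 0, dif_border <= 1,
            short_boost >= 0, alpha >= 1, wing_width > 0, wing_guard >= 0,
            total_pairs > 0)
  if (is.null(genome$spans$terminus) || is.null(genome$anchors[["dif"]]) ||
      is.null(genome$anchors[["oriC"]]))
    stop("genome needs 'terminus' span and 'dif'/'oriC' anchors")
  structure(list(genome = genome, bin_size = bin_size,
                 total_pairs = total_pairs, gamma = gamma, s0 = s0,
                 beta = beta, precat_range = precat_range, iota = iota,
                 dif_border = dif_border, short_boost = short_boost,
                 short_range = short_range, alpha = alpha,
                 wing_width = wing_width, wing_guard = wing_guard),
            class = "sim_params")
}

#' Expected-intensity contact map under the simulation model
#'
#' Builds the noise-free expected matrix \code{lambda(i, j) = P(s) *
#' boost * insulation + wing} described in [sim_params()], scaled to unit
#' mean and symmetric. The \code{"wt"} condition is the pure decay;
#' \code{"mutant"} switches every planted feature on. The additive wing
#' mass is calibrated internally (a few fixed-point iterations on
#' SCN-normalized expected maps) so that the pooled wing fold enrichment
#' beyond the guard equals \code{alpha}.
#'
#' @param params a [sim_params()].
#' @param condition \code{"wt"} or \code{"mutant"}.
#' @return A [contact_map()] with \code{state = "expected"}.
#' @export
expected_map <- function(params, condition = c("wt", "mutant")) {
  condition <- match.arg(condition)
  p <- params
  g <- p$genome
  n <- n_bins_for(g, p$bin_size)
  # separation (bp) between bin centers, circular
  doff <- 0:(n - 1)
  doff <- pmin(doff, n - doff) * p$bin_size
  Pvec <- (p$s0 + doff)^(-p$gamma)
  M <- stats::toeplitz(Pvec)
  if (condition == "mutant") {
    sep <- stats::toeplitz(doff)
    ter_bins <- bins_of_span(g$spans$terminus, p$bin_size, n, g$circular)
    in_ter <- seq_len(n) %in% ter_bins
    out_ter <- !in_ter
    # precatenane band outside the terminus
    if (p$beta > 0) {
      band <- sep >= p$precat_range[1] & sep <= p$precat_range[2]
      sel <- outer(out_ter, out_ter, "&") & band
      M[sel] <- M[sel] * (1 + p$beta)
    }
    # terminus: mid-range depletion, dif border, short-range gain
    tt <- outer(in_ter, in_ter, "&")
    mid <- sep >= p$short_range
    M[tt & mid] <- M[tt & mid] * p$iota
    dif <- g$anchors[["dif"]]
    side <- (seq_len(n) - 1) * p$bin_size >= dif  # bin start right of dif
    cross <- outer(side, side, "!=")
    M[tt & cross] <- M[tt & cross] * p$dif_border
    short <- sep < p$short_range
    M[tt & short] <- M[tt & short] * (1 + p$short_boost)
    # butterfly wings: additive, distance-independent, dif bin spared
    if (p$alpha > 1) {
      difb <- bin_of(dif, p$bin_size)
      cells <- butterfly_cells(g, p$bin_size, exclude = difb,
                               guard = 0, width = p$wing_width)
      quant <- butterfly_cells(g, p$bin_size, exclude = difb,
                               guard = p$wing_guard, width = p$wing_width)
      M <- calibrate_wings(M, stats::toeplitz(Pvec), cells, quant, p)
    }
  }
  M <- M / mean(M)
  contact_map(g, p$bin_size, M, state = "expected",
              stats = list(condition = condition, params = p))
}

# add the wing mass w to 'cells' (symmetrically), choosing w so the pooled
# fold over 'quant' cells between the SCN-normalized mutant map and the
# SCN-normalized wild-type (pure-decay) map is alpha
calibrate_wings <- function(M, wt_base, cells, quant, p) {
  g <- p$genome
  wt_n <- scn_normalize(contact_map(g, p$bin_size, wt_base, state = "expected"))
  ctl <- sum(wt_n$values[quant])
  add_wings <- function(M, w) {
    W <- M
    W[cells] <- W[cells] + w
    W[cells[, 2:1, drop = FALSE]] <- W[cells[, 2:1, drop = FALSE]] + w
    W
  }
  sep <- attr(quant, "separation")
  base <- M[quant]
  w <- (p$alpha - 1) * mean(base)  # first guess: match the raw-map fold
  for (k in 1:12) {
    mut <- add_wings(M, w)
    mut_n <- scn_normalize(contact_map(g, p$bin_size, mut, state = "expected"))
    fold <- sum(mut_n$values[quant]) / ctl
    if (abs(fold - p$alpha) < 1e-3) break
    w <- w * (p$alpha - 1) / (fold - 1)
  }
  add_wings(M, w)
}

#' Poisson-sample a count matrix from an expected map
#'
#' Draws independent Poisson counts for every upper-triangle cell with
#' means proportional to the expected intensities and summing to
#' \code{total_pairs} in expectation, then mirrors to a symmetric matrix.
#'
#' @param expected an [expected_map()] result (any nonnegative
#'   [contact_map()] works).
#' @param total_pairs expected total number of pairs (> 0).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @return A raw [contact_map()] of counts.
#' @export
sample_counts <- function(expected, total_pairs, seed = 1L) {
  stopifnot(total_pairs > 0)
  n <- expected$n_bins
  ut <- upper.tri(matrix(0, n, n), diag = TRUE)
  lam <- expected$values[ut]
  lam <- lam / sum(lam) * total_pairs
  set.seed(seed)
  cnt <- stats::rpois(length(lam), lam)
  U <- matrix(0, n, n)
  U[ut] <- cnt
  values <- U + t(U)
  diag(values) <- diag(U)
  contact_map(expected$genome, expected$bin_size, values,
              mask = expected$mask, state = "raw",
              stats = list(total_pairs = total_pairs, seed = seed))
}

#' Sample a `.pairs` file from an expected map
#'
#' Draws \code{total_pairs} bin pairs multinomially from the expected
#' matrix, places each end uniformly within its bin, assigns MAPQ 60 to
#' every mate except a \code{mapq_noise} fraction of records downgraded to
#' MAPQ 10 (so the strictly-greater-than-30 filter removes them), and
#' writes the pairs dialect understood by [read_pairs()]. Re-ingesting the
#' file with [build_matrix()] at the same bin size recovers the sampled
#' count matrix exactly (when the same-fragment filter is off).
#'
#' @param expected an [expected_map()] result.
#' @param genome genome to write coordinates on (defaults to the map's).
#' @param fragmap optional [digest()] result, used only to report the
#'   fraction of sampled records whose two ends fall on one fragment.
#' @param total_pairs number of records to draw.
#' @param seed RNG seed.
#' @param mapq_noise fraction of records given MAPQ 10.
#' @param path output file; defaults to a temp file.
#' @return Invisibly, a list with \code{path}, \code{counts} (the sampled
#'   [contact_map()] the file encodes) and \code{stats}.
#' @export
sample_pairs <- function(expected, genome = expected$genome, fragmap = NULL,
                         total_pairs = 1e6, seed = 1L, mapq_noise = 0,
                         path = tempfile(fileext = ".pairs")) {
  stopifnot(total_pairs > 0, mapq_noise >= 0, mapq_noise < 1)
  n <- expected$n_bins
  bs <- expected$bin_size
  L <- genome$length
  ut_idx <- which(upper.tri(matrix(0, n, n), diag = TRUE))
  lam <- expected$values[ut_idx]
  set.seed(seed)
  cnt <- as.integer(stats::rmultinom(1, total_pairs, lam))
  cell <- rep.int(ut_idx, cnt)
  i <- ((cell - 1L) %% n) + 1L   # row index
  j <- ((cell - 1L) %/% n) + 1L  # column index
  # uniform positions within each end's bin (last bin may be short)
  draw_pos <- function(b) {
    lo <- (b - 1) * bs
    hi <- pmin(b * bs, L)
    floor(lo + stats::runif(length(b)) * (hi - lo))
  }
  pos1 <- draw_pos(i)
  pos2 <- draw_pos(j)
  swap <- stats::runif(length(pos1)) < 0.5
  tmp <- pos1[swap]; pos1[swap] <- pos2[swap]; pos2[swap] <- tmp
  m <- length(pos1)
  mapq1 <- mapq2 <- rep.int(60L, m)
  noisy <- stats::runif(m) < mapq_noise
  mapq1[noisy] <- mapq2[noisy] <- 10L
  pairs <- data.frame(
    read_id = sprintf("r%08d", seq_len(m)),
    chrom1 = genome$name, pos1 = pos1,
    strand1 = sample(c("+", "-"), m, replace = TRUE),
    mapq1 = mapq1,
    chrom2 = genome$name, pos2 = pos2,
    strand2 = sample(c("+", "-"), m, replace = TRUE),
    mapq2 = mapq2,
    stringsAsFactors = FALSE)
  write_pairs(pairs, path, genome = genome)
  U <- matrix(0, n, n)
  U[ut_idx] <- cnt
  counts <- U + t(U)
  diag(counts) <- diag(U)
  stats <- list(total_pairs = m, seed = seed, mapq_noise = mapq_noise)
  if (!is.null(fragmap)) {
    same <- assign_fragment(fragmap, pos1) == assign_fragment(fragmap, pos2)
    stats$same_fragment_fraction <- mean(same)
  }
  invisible(list(
    path = path,
    counts = contact_map(genome, bs, counts, state = "raw",
                         stats = stats),
    stats = stats))
}
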