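#' Read aligned read pairs from a `.pairs`-style text file
#'
#' Parses the tab-separated dialect \code{readID chrom1 pos1 chrom2 pos2
#' strand1 strand2 [mapq1 mapq2]} with any number of leading header lines
#' starting with \code{#}. Positions are 1-based in the file and converted
#' to the package's 0-based convention. Records with unparseable or missing
#' coordinates are dropped and counted (never silently). When the MAPQ
#' columns are absent every record is treated as passing the quality filter,
#' with a warning.
#'
#' @param path file path.
#' @return A \code{data.frame} with columns \code{read_id, chrom1, pos1,
#'   strand1, mapq1, chrom2, pos2, strand2, mapq2} (positions 0-based) and
#'   an attribute \code{stats} counting input and malformed records.
#' @export
read_pairs <- function(path) {
  first <- readLines(path, n = 10000L)
  n_hdr <- match(FALSE, startsWith(first, "#")) - 1L
  if (is.na(n_hdr)) n_hdr <- length(first)
  dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = n_hdr,
                          fill = TRUE, colClasses = "character")
  if (ncol(dt) < 7) stop("expected >= 7 columns in ", path)
  has_mapq <- ncol(dt) >= 9
  out <- data.frame(
    read_id = dt[[1]],
    chrom1 = dt[[2]], pos1 = suppressWarnings(as.numeric(dt[[3]])) - 1,
    strand1 = dt[[6]],
    chrom2 = dt[[4]], pos2 = suppressWarnings(as.numeric(dt[[5]])) - 1,
    strand2 = dt[[7]],
    stringsAsFactors = FALSE)
  if (has_mapq) {
    out$mapq1 <- suppressWarnings(as.numeric(dt[[8]]))
    out$mapq2 <- suppressWarnings(as.numeric(dt[[9]]))
  } else {
    warning("no MAPQ columns in ", path, "; all records treated as passing")
    out$mapq1 <- out$mapq2 <- Inf
  }
  bad <- !is.finite(out$pos1) | !is.finite(out$pos2) |
    out$pos1 < 0 | out$pos2 < 0 |
    (has_mapq & (is.na(out$mapq1) | is.na(out$mapq2)))
  bad[is.na(bad)] <- TRUE
  res <- out[!bad, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "stats") <- list(input = nrow(out), malformed = sum(bad))
  res
}

#' Write read pairs in the `.pairs` text dialect
#'
#' @param pairs data.frame as returned by [read_pairs()] (0-based
#'   positions).
#' @param path output file.
#' @param genome optional [genome()] used to emit a \code{#chromsize} header
#'   line.
#' @return \code{path}, invisibly.
#' @export
write_pairs <- function(pairs, path, genome = NULL) {
  hdr <- c("## pairs format v1.0",
           "#columns: readID chrom1 pos1 chrom2 pos2 strand1 strand2 mapq1 mapq2")
  if (!is.null(genome))
    hdr <- c(hdr, paste0("#chromsize: ", genome$name, " ", genome$length))
  writeLines(hdr, path)
  dt <- data.table::data.table(
    pairs$read_id, pairs$chrom1, format(pairs$pos1 + 1, scientific = FALSE, trim = TRUE),
    pairs$chrom2, format(pairs$pos2 + 1, scientific = FALSE, trim = TRUE),
    pairs$strand1, pairs$strand2, pairs$mapq1, pairs$mapq2)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Filter read pairs on mapping quality and chromosome
#'
#' Implements the study's read filter: a pair is retained iff both mates
#' map to a known chromosome and both have \code{MAPQ >= mapq_min}. The
#' default \code{mapq_min = 31} encodes "mapping quality strictly > 30".
#'
#' @param pairs data.frame from [read_pairs()].
#' @param mapq_min inclusive MAPQ threshold (default 31).
#' @param chroms character vector of known chromosome names, or a
#'   [genome()] whose name is used; \code{NULL} disables the chromosome
#'   check.
#' @return A list with \code{pairs} (the retained records) and \code{stats}
#'   (input/retained/discarded counts and \code{retained_fraction}, which is
#'   \code{NaN} on empty input).
#' @export
filter_pairs <- function(pairs, mapq_min = 31, chroms = NULL) {
  if (inherits(chroms, "genome")) chroms <- chroms$name
  n_in <- nrow(pairs)
  ok_chrom <- if (is.null(chroms)) rep(TRUE, n_in) else
    (pairs$chrom1 %in% chroms & pairs$chrom2 %in% chroms)
  ok_mapq <- pairs$mapq1 >= mapq_min & pairs$mapq2 >= mapq_min
  keep <- ok_chrom & ok_mapq
  prior <- attr(pairs, "stats")
  stats <- list(
    input = n_in,
    malformed_upstream = if (is.null(prior)) 0L else prior$malformed,
    retained = sum(keep),
    discarded_chrom = sum(!ok_chrom),
    discarded_mapq = sum(ok_chrom & !ok_mapq),
    retained_fraction = if (n_in == 0) NaN else sum(keep) / n_in)
  res <- pairs[keep, , drop = FALSE]
  rownames(res) <- NULL
  list(pairs = res, stats = stats)
}

#' Bin filtered read pairs into a raw contact matrix
#'
#' Each pair increments \code{values[bin(pos1), bin(pos2)]} and its mirror
#' once; pairs whose two ends fall in the same bin increment the diagonal
#' cell by 1, counted once. \code{bin(pos) = floor(pos / bin_size)}. When a
#' fragment map is supplied, pairs with both ends on the same restriction
#' fragment (religation / self-circle proxy) are discarded and counted.
#'
#' @param pairs data.frame of retained pairs (0-based positions).
#' @param genome a [genome()].
#' @param bin_size bin size in bp.
#' @param fragmap optional [digest()] result enabling the same-fragment
#'   filter.
#' @param drop_same_fragment logical; defaults to \code{TRUE} when
#'   \code{fragmap} is supplied.
#' @return A raw [contact_map()]; \code{$stats} records \code{n_pairs} used
#'   and \code{same_fragment} dropped.
#' @export
build_matrix <- function(pairs, genome, bin_size, fragmap = NULL,
                         drop_same_fragment = !is.null(fragmap)) {
  stopifnot(bin_size > 0)
  L <- genome$length
  bad <- which(pairs$pos1 >= L | pairs$pos2 >= L | pairs$pos1 < 0 |
                 pairs$pos2 < 0)
  if (length(bad))
    stop("pair position beyond genome length at record index ", bad[1])
  same_frag <- 0L
  if (drop_same_fragment) {
    if (is.null(fragmap)) stop("'fragmap' required to drop same-fragment pairs")
    f1 <- assign_fragment(fragmap, pairs$pos1)
    f2 <- assign_fragment(fragmap, pairs$pos2)
    same <- f1 == f2
    same_frag <- sum(same)
    pairs <- pairs[!same, , drop = FALSE]
  }
  n <- n_bins_for(genome, bin_size)
  b1 <- bin_of(pairs$pos1, bin_size)
  b2 <- bin_of(pairs$pos2, bin_size)
  i <- pmin(b1, b2); j <- pmax(b1, b2)
  counts <- tabulate((i - 1) * n + j, nbins = n * n)
  U <- matrix(counts, n, n, byrow = TRUE)  # upper triangle holds the counts
  values <- U + t(U)
  diag(values) <- diag(U)
  contact_map(genome, bin_size, values, state = "raw",
              stats = list(n_pairs = nrow(pairs), same_fragment = same_frag))
}
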