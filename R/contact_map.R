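#' Binned contact map
#'
#' Symmetric matrix of contact counts or frequencies at a fixed bin size on
#' one replicon, together with a mask of excluded bins and a normalization
#' state. The genome is tiled into \code{ceiling(length / bin_size)} bins;
#' the last bin may be shorter than \code{bin_size} and is kept. Masked
#' rows/columns are all-zero.
#'
#' @param genome a [genome()].
#' @param bin_size bin size in bp.
#' @param values symmetric nonnegative numeric matrix, one row/column per
#'   bin.
#' @param mask logical vector (length \code{n_bins}) of excluded bins.
#' @param state one of \code{"raw"}, \code{"expected"}, \code{"normalized"}.
#' @param stats optional list of provenance counters (pair totals, filter
#'   counts, ...), kept as metadata.
#' @return An object of class \code{"contact_map"}.
#' @export
contact_map <- function(genome, bin_size, values,
                        mask = rep(FALSE, nrow(values)),
                        state = c("raw", "expected", "normalized"),
                        stats = list()) {
  state <- match.arg(state)
  n <- n_bins_for(genome, bin_size)
  if (!is.matrix(values) || nrow(values) != n || ncol(values) != n)
    stop("'values' must be a ", n, " x ", n, " matrix for this genome/bin size")
  if (any(values < 0)) stop("contact values must be nonnegative")
  if (max(abs(values - t(values))) > 1e-8 * max(1, max(abs(values))))
    stop("'values' must be symmetric")
  mask <- as.logical(mask)
  if (length(mask) != n) stop("'mask' must have one entry per bin")
  if (any(mask)) values[mask, ] <- values[, mask] <- 0
  structure(list(genome = genome, bin_size = as.numeric(bin_size),
                 n_bins = n, values = values, mask = mask, state = state,
                 stats = stats),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("<contact_map> ", x$genome$name, ": ", x$n_bins, " bins of ",
      format(x$bin_size, big.mark = ","), " bp, state=", x$state,
      ", ", sum(x$mask), " masked bin(s), total=",
      format(sum(x$values), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Write a contact map as sparse text
#'
#' Plain-text sparse upper-triangle dialect: header lines starting with
#' \code{#} carry the genome name/length/circularity, bin size, bin count,
#' normalization state and masked bins (0-based); body rows are
#' \code{bin_i<TAB>bin_j<TAB>value} with \code{i <= j}, 0-based, nonzero
#' cells only. Values are written with 17 significant digits so that
#' [read_contact_map()] round-trips bit-exactly.
#'
#' @param map a [contact_map()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_contact_map <- function(map, path) {
  ut <- which(upper.tri(map$values, diag = TRUE) & map$values != 0,
              arr.ind = TRUE)
  hdr <- c(
    paste0("# genome: ", map$genome$name),
    paste0("# length: ", format(map$genome$length, scientific = FALSE)),
    paste0("# circular: ", map$genome$circular),
    paste0("# bin_size: ", format(map$bin_size, scientific = FALSE)),
    paste0("# n_bins: ", map$n_bins),
    paste0("# state: ", map$state),
    paste0("# masked_bins: ", paste(which(map$mask) - 1L, collapse = ",")))
  body <- sprintf("%d\t%d\t%.17g", ut[, 1] - 1L, ut[, 2] - 1L,
                  map$values[ut])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#'
#' @param path input file.
#' @param genome optional [genome()] to attach (anchors/spans are not stored
#'   in the file); its name, length and circularity must agree with the
#'   header.
#' @return A [contact_map()].
#' @export
read_contact_map <- function(path, genome = NULL) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  get <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) stop("header key '", key, "' missing in ", path)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  gname <- get("genome"); L <- as.numeric(get("length"))
  circ <- as.logical(get("circular"))
  bin_size <- as.numeric(get("bin_size")); n <- as.integer(get("n_bins"))
  state <- get("state")
  mb <- get("masked_bins")
  mask <- rep(FALSE, n)
  if (nzchar(mb))
    mask[as.integer(strsplit(mb, ",")[[1]]) + 1L] <- TRUE
  if (is.null(genome)) {
    genome <- genome(gname, length = L, circular = circ)
  } else if (genome$length != L || genome$name != gname) {
    stop("supplied genome does not match file header")
  }
  values <- matrix(0, n, n)
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  if (length(body)) {
    dt <- data.table::fread(text = body, header = FALSE, sep = "\t",
                            colClasses = list(integer = 1:2, numeric = 3))
    i <- dt[[1]] + 1L; j <- dt[[2]] + 1L
    if (any(i > j)) stop("sparse body must have bin_i <= bin_j")
    values[cbind(i, j)] <- dt[[3]]
    values[cbind(j, i)] <- dt[[3]]
  }
  contact_map(genome, bin_size, values, mask = mask, state = state)
}

# mean over unmasked cells utility
unmasked_cells <- function(map) {
  keep <- !map$mask
  map$values[keep, keep, drop = FALSE]
}

# smallest positive value across one or more maps (pseudocount default)
min_positive <- function(...) {
  v <- unlist(lapply(list(...), function(m) {
    x <- unmasked_cells(m)
    x[x > 0]
  }))
  if (!length(v)) stop("maps contain no positive values")
  min(v)
}
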