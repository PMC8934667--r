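#' Genome description for a single (usually circular) replicon
#'
#' Lightweight container holding the replicon name, its length, circularity,
#' optionally the nucleotide sequence, and named coordinate anchors (such as
#' \code{dif} or \code{oriC}) and spans (such as the terminus region).
#' All coordinates are 0-based, half-open \code{[start, end)}; a span with
#' \code{start > end} wraps through the origin and is only allowed on a
#' circular genome.
#'
#' @param name replicon name (matched against the chromosome columns of
#'   read-pair files).
#' @param length genome length in bp; inferred from \code{sequence} when
#'   omitted.
#' @param circular logical; is the replicon circular?
#' @param sequence optional nucleotide sequence (single string). Required by
#'   [digest()] only.
#' @param anchors named numeric vector of point coordinates in bp, each in
#'   \code{[0, length)}.
#' @param spans named list of length-2 numeric vectors \code{c(start, end)}
#'   in bp (half-open; may wrap on a circular genome).
#' @return An object of class \code{"genome"}.
#' @seealso [ecoli_genome()] for the K-12 coordinate preset, [digest()],
#'   [build_matrix()].
#' @export
genome <- function(name, length = NULL, circular = TRUE, sequence = NULL,
                   anchors = numeric(), spans = list()) {
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (is.null(length)) length <- nchar(sequence)
    if (nchar(sequence) != length)
      stop("sequence length (", nchar(sequence),
           ") does not match 'length' (", length, ")")
  }
  if (is.null(length)) stop("either 'length' or 'sequence' is required")
  length <- as.numeric(length)
  if (length <= 0 || length != floor(length)) stop("'length' must be a positive integer")
  if (base::length(anchors)) {
    if (is.null(names(anchors)) || any(names(anchors) == ""))
      stop("anchors must be named")
    if (any(anchors < 0 | anchors >= length))
      stop("anchor coordinates must lie in [0, length)")
  }
  for (nm in names(spans)) {
    sp <- spans[[nm]]
    if (base::length(sp) != 2 || any(sp < 0) || any(sp > length))
      stop("span '", nm, "' must be c(start, end) within [0, length]")
    if (sp[1] > sp[2] && !circular)
      stop("span '", nm, "' wraps the origin but the genome is linear")
  }
  structure(
    list(name = as.character(name), length = length,
         circular = isTRUE(circular), sequence = sequence,
         anchors = anchors, spans = spans),
    class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("<genome> ", x$name, ": ", format(x$length, big.mark = ","), " bp, ",
      if (x$circular) "circular" else "linear",
      if (!is.null(x$sequence)) ", with sequence" else "", "\n", sep = "")
  if (length(x$anchors))
    cat("  anchors: ", paste0(names(x$anchors), "=", x$anchors, collapse = ", "), "\n")
  for (nm in names(x$spans))
    cat("  span ", nm, ": [", x$spans[[nm]][1], ", ", x$spans[[nm]][2], ")\n", sep = "")
  invisible(x)
}

#' E. coli K-12 coordinate preset
#'
#' Genome object with the coordinates used throughout the study system:
#' the NC_000913 replicon length, the \emph{dif} site, \emph{oriC}, and the
#' terminus span 1315--1830 kb. No sequence is attached (coordinates are
#' sufficient for everything except [digest()]).
#'
#' @param length replicon length in bp.
#' @param dif,oriC point anchors in bp.
#' @param terminus length-2 vector, terminus span in bp.
#' @return A [genome()] object.
#' @export
ecoli_genome <- function(length = 4641652, dif = 1588800, oriC = 3925744,
                         terminus = c(1315000, 1830000)) {
  genome("NC_000913", length = length, circular = TRUE,
         anchors = c(dif = dif, oriC = oriC),
         spans = list(terminus = terminus))
}

#' Read a genome from a FASTA file
#'
#' Reads a (multi-)FASTA file and returns a [genome()] built from one
#' record: the first record by default, or the record whose name matches
#' \code{name}.
#'
#' @param path FASTA file path.
#' @param name optional record name to select.
#' @param circular logical, passed through to [genome()].
#' @param anchors,spans passed through to [genome()].
#' @return A [genome()] object carrying the sequence.
#' @export
read_genome_fasta <- function(path, name = NULL, circular = TRUE,
                              anchors = numeric(), spans = list()) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (!length(seqs)) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  k <- 1L
  if (!is.null(name)) {
    k <- match(name, ids)
    if (is.na(k)) stop("record '", name, "' not found in ", path)
  }
  genome(ids[k], sequence = as.character(seqs[[k]]), circular = circular,
         anchors = anchors, spans = spans)
}

# ---- internal coordinate helpers (0-based bp; 1-based bin indices) ----

# number of bins tiling the genome
n_bins_for <- function(genome, bin_size) as.integer(ceiling(genome$length / bin_size))

# 1-based bin index of a 0-based bp position
bin_of <- function(pos, bin_size) as.integer(pos %/% bin_size) + 1L

# 1-based bin indices overlapping a half-open bp span (wrap-aware)
bins_of_span <- function(span, bin_size, n_bins, circular = TRUE) {
  stopifnot(length(span) == 2)
  if (span[1] <= span[2]) {
    if (span[1] == span[2]) return(integer())
    lo <- bin_of(span[1], bin_size)
    hi <- bin_of(span[2] - 1, bin_size)
    lo:hi
  } else {
    if (!circular) stop("wrapping span on a linear genome")
    c(bins_of_span(c(span[1], n_bins * bin_size), bin_size, n_bins),
      bins_of_span(c(0, span[2]), bin_size, n_bins))
  }
}

# circular (or linear) separation between 1-based bin indices, in bp
bin_separation <- function(i, j, bin_size, n_bins, circular = TRUE) {
  d <- abs(i - j)
  if (circular) d <- pmin(d, n_bins - d)
  d * bin_size
}
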