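#' In-silico restriction digest
#'
#' Finds all occurrences of a restriction site on the forward strand
#' (HpaII's \code{CCGG} by default; palindromic sites need no reverse-strand
#' scan) and returns the resulting fragment map. On a circular genome sites
#' spanning the origin are found and the last fragment wraps from the last
#' cut to the first. Matching is exact: ambiguous letters (N etc.) never
#' match and their count is reported via a message.
#'
#' Cut positions follow the convention \code{cut = match_start + cut_offset},
#' so HpaII (\code{C^CGG}) has \code{cut_offset = 1}.
#'
#' @param genome a [genome()] carrying a sequence.
#' @param site recognition sequence (A/C/G/T only).
#' @param cut_offset 0-based cut offset within the site.
#' @return An object of class \code{"fragment_map"} with elements
#'   \code{genome}, \code{site}, \code{cut_offset}, \code{cut_positions}
#'   (sorted, 0-based bp) and \code{fragments} (data.frame with
#'   \code{start}, \code{end}, \code{length}, \code{wraps}).
#' @examples
#' g <- genome("toy", sequence = "AACCGGTTCCGG", circular = TRUE)
#' digest(g)$cut_positions   # 3, 9
#' @export
digest <- function(genome, site = "CCGG", cut_offset = 1L) {
  if (is.null(genome$sequence)) stop("sequence required")
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site))
    stop("'site' must be a fixed A/C/G/T pattern")
  k <- nchar(site)
  cut_offset <- as.integer(cut_offset)
  if (cut_offset < 0 || cut_offset > k)
    stop("'cut_offset' must be in [0, nchar(site)]")
  s <- genome$sequence
  L <- genome$length
  n_amb <- if (grepl("[^ACGT]", s)) L - nchar(gsub("[^ACGT]", "", s)) else 0L
  if (n_amb > 0)
    message("digest: ", n_amb, " non-ACGT characters treated as mismatches")
  ext <- if (genome$circular && k > 1) paste0(s, substr(s, 1L, k - 1L)) else s
  # lookahead so overlapping occurrences are all found
  m <- gregexpr(paste0("(?=", site, ")"), ext, perl = TRUE)[[1]]
  starts <- if (m[1] == -1) integer() else as.integer(m) - 1L  # 0-based
  starts <- starts[starts < L]
  cuts <- starts + cut_offset
  if (genome$circular) {
    cuts <- sort(unique(cuts %% L))
  } else {
    cuts <- sort(unique(cuts[cuts > 0 & cuts < L]))
  }
  new_fragment_map(genome, cuts, site, cut_offset)
}

# build a fragment_map from sorted 0-based cut positions
new_fragment_map <- function(genome, cuts, site = NA_character_,
                             cut_offset = NA_integer_) {
  L <- genome$length
  if (!length(cuts)) {
    fr <- data.frame(start = 0, end = L, length = L, wraps = FALSE)
  } else if (genome$circular) {
    start <- cuts
    end <- c(cuts[-1], cuts[1])
    len <- (end - start) %% L
    len[len == 0] <- L  # single cut: one fragment spanning the whole circle
    fr <- data.frame(start = start, end = end, length = len,
                     wraps = end <= start)
  } else {
    start <- c(0, cuts)
    end <- c(cuts, L)
    fr <- data.frame(start = start, end = end, length = end - start,
                     wraps = FALSE)
  }
  stopifnot(sum(fr$length) == L)
  structure(list(genome = genome, site = site, cut_offset = cut_offset,
                 cut_positions = cuts, fragments = fr),
            class = "fragment_map")
}

#' @export
print.fragment_map <- function(x, ...) {
  cat("<fragment_map> ", nrow(x$fragments), " fragments (site ", x$site,
      ") on ", x$genome$name, "\n", sep = "")
  invisible(x)
}

#' Assign positions to restriction fragments
#'
#' Returns, for each 0-based bp position, the 1-based index of the fragment
#' whose half-open interval contains it, using bisection over the cut
#' positions (wrap-aware on circular genomes).
#'
#' @param fragmap a [digest()] result.
#' @param pos numeric vector of 0-based positions in \code{[0, length)}.
#' @return Integer vector of fragment indices (rows of
#'   \code{fragmap$fragments}).
#' @export
assign_fragment <- function(fragmap, pos) {
  L <- fragmap$genome$length
  if (any(pos < 0 | pos >= L)) stop("position out of range [0, ", L, ")")
  cuts <- fragmap$cut_positions
  if (!length(cuts)) return(rep.int(1L, length(pos)))
  idx <- findInterval(pos, cuts)
  if (fragmap$genome$circular) {
    # positions before the first cut belong to the wrapping last fragment
    idx[idx == 0L] <- length(cuts)
  } else {
    idx <- idx + 1L  # fragment 1 is [0, first cut)
  }
  as.integer(idx)
}
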