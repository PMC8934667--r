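#' Blue-white-red palette for log ratio heatmaps
#'
#' @param n number of colors.
#' @return Character vector of colors (losses blue, no change white,
#'   gains red).
#' @export
ratio_palette <- function(n = 63) {
  grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(n)
}

#' @export
plot.contact_map <- function(x, log = TRUE, main = NULL, ...) {
  v <- x$values
  if (log) v <- log10(v + min_positive(x))
  pal <- grDevices::colorRampPalette(c("white", "#FDDBC7", "#B2182B",
                                       "#67001F"))(64)
  graphics::image(seq_len(x$n_bins) * x$bin_size / 1e6,
                  seq_len(x$n_bins) * x$bin_size / 1e6,
                  v, col = pal, useRaster = TRUE,
                  xlab = "position (Mb)", ylab = "position (Mb)",
                  main = main %||% paste0(x$genome$name, " (", x$state, ")"),
                  ...)
  invisible(x)
}

#' @export
plot.ratio_map <- function(x, zlim = NULL, main = "log2 ratio", ...) {
  v <- x$values
  if (is.null(zlim)) zlim <- c(-1, 1) * max(abs(v), na.rm = TRUE)
  v[v < zlim[1]] <- zlim[1]; v[v > zlim[2]] <- zlim[2]
  graphics::image(seq_len(nrow(v)) * x$bin_size / 1e6,
                  seq_len(nrow(v)) * x$bin_size / 1e6,
                  v, col = ratio_palette(), zlim = zlim, useRaster = TRUE,
                  xlab = "position (Mb)", ylab = "position (Mb)",
                  main = main, ...)
  invisible(x)
}

#' @export
plot.scalogram <- function(x, zlim = NULL, main = "scalogram", ...) {
  v <- x$values
  if (is.null(zlim)) zlim <- c(-1, 1) * max(abs(v), na.rm = TRUE)
  v[v < zlim[1]] <- zlim[1]; v[v > zlim[2]] <- zlim[2]
  graphics::image(seq_len(nrow(v)) * x$bin_size / 1e6, x$distances / 1e3,
                  v, col = ratio_palette(), zlim = zlim, useRaster = TRUE,
                  xlab = "bin position (Mb)", ylab = "separation (kb)",
                  main = main, ...)
  invisible(x)
}

#' @export
plot.hic_profile <- function(x, ...) {
  if (x$kind == "zscore") {
    graphics::plot(x$bins * x$bin_size / 1e6, x$values, type = "l",
                   xlab = "position (Mb)", ylab = "z score", ...)
  } else {
    graphics::plot(seq_along(x$values) * x$bin_size / 1e6, x$values,
                   type = "l", xlab = "position (Mb)",
                   ylab = "contact frequency", ...)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
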