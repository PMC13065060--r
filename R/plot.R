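#' Render a class-label overlay on a grayscale spectral slice
#'
#' The backdrop is the mean over energy bins, min-max windowed per slice; the
#' label map is alpha-blended on top using the fixed class palette
#' (background transparent). The same windowing rule is used for every model,
#' so overlays are directly comparable. Output bytes are a pure function of
#' the inputs.
#'
#' @param spectral_slice F x H x W array
#' @param label_map H x W integer map (0..12)
#' @param path output PNG path
#' @param palette class palette, see [default_palette()]
#' @param alpha blend weight of the label color
#' @return `path`, invisibly
#' @export
render_overlay <- function(spectral_slice, label_map, path,
                           palette = default_palette(), alpha = 0.5) {
  d <- dim(spectral_slice)
  if (!identical(dim(label_map), d[2:3]))
    stopf("label map not aligned with slice")
  gray <- apply(spectral_slice, c(2, 3), mean)
  rng <- range(gray)
  gray <- if (diff(rng) > 0) (gray - rng[1]) / diff(rng) else gray * 0
  img <- array(rep(gray, 3), c(d[2], d[3], 3))
  cols <- grDevices::col2rgb(palette, alpha = TRUE) / 255
  for (cid in sort(unique(label_map[label_map > 0L]))) {
    m <- label_map == cid
    rgbc <- cols[1:3, as.character(cid)]
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[m] <- (1 - alpha) * plane[m] + alpha * rgbc[ch]
      img[, , ch] <- plane
    }
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Slice-wise Dice-error band plot
#'
#' Plots the per-slice error `e = 1 - Dice` for one class group with a solid
#' mean line and a shaded `mean +/- 1.96 * SD` band (the 95% reference
#' range).
#'
#' @param series one group entry from [slice_error_series()]
#' @param path output PNG path
#' @param title plot title
#' @return `path`, invisibly
#' @export
render_error_band_plot <- function(series, path, title = "slice-wise error") {
  df <- series$series[!is.na(series$series$e), ]
  if (nrow(df) == 0) stopf("empty error series")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$e)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = series$mean - series$half_width,
                      ymax = series$mean + series$half_width,
                      alpha = 0.2, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = series$mean, color = "steelblue") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "test slice index", y = "e = 1 - Dice",
                  title = title) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 3.2, dpi = 150)
  invisible(path)
}

#' @importFrom ggplot2 .data
NULL
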