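#' Plot a processed spectrum
#'
#' Real part against chemical shift, ppm decreasing left to right (the
#' field's convention).
#'
#' @param object A [processed_spectrum()].
#' @param xlim_ppm Optional ppm range to display, e.g. `c(1.8, 4.2)`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.processed_spectrum <- function(object, xlim_ppm = NULL, ...) {
  d <- as_tibble(object)
  if (!is.null(xlim_ppm))
    d <- dplyr::filter(d, .data$ppm >= min(xlim_ppm),
                       .data$ppm <= max(xlim_ppm))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$real)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)")
}

#' Plot the five processed spectra of one scan
#'
#' Overlays the block spectra (real part), which makes the water
#' suppression and the editing differences directly visible.
#'
#' @param object A `famous_spectra` list from [preprocess_set()].
#' @param xlim_ppm Optional ppm range to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.famous_spectra <- function(object, xlim_ppm = c(1.5, 5.5), ...) {
  d <- purrr::imap_dfr(object, function(s, lab)
    dplyr::mutate(as_tibble(s), block = lab))
  if (!is.null(xlim_ppm))
    d <- dplyr::filter(d, .data$ppm >= min(xlim_ppm),
                       .data$ppm <= max(xlim_ppm))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ppm, y = .data$real,
                                  color = .data$block)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = "intensity (a.u.)")
}

#' Plot a test-retest table
#'
#' Paired scan concentrations per subject.
#'
#' @param object A [retest_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.retest_table <- function(object, ...) {
  long <- tidyr_longer(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scan, y = .data$value,
                                     group = .data$subject)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "Glu (mM)")
}

# minimal wide-to-long for the retest table (avoids a tidyr dependency)
tidyr_longer <- function(table) {
  scans <- setdiff(names(table), "subject")
  purrr::map_dfr(scans, function(s)
    tibble(subject = table$subject, scan = s, value = table[[s]]))
}
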