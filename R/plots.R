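#' Score plot of a PCA model
#'
#' PC1 x PC2 scores coloured by group, with the explained variance of
#' each axis in its label.
#'
#' @param object A `pca_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.pca_model <- function(object, ...) {
  r <- object$explained_variance_ratio
  df <- tibble::tibble(
    PC1 = object$scores[, 1],
    PC2 = if (ncol(object$scores) > 1) object$scores[, 2] else 0,
    group = object$row_labels$group
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC-1 (%.0f%%)", 100 * r[1]),
      y = if (length(r) > 1) sprintf("PC-2 (%.0f%%)", 100 * r[2]) else "PC-2",
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Spectra overlay plot
#'
#' Group-mean spectra (solid) over individual scans (faint), for a quick
#' look at the water region and planted band structure.
#'
#' @param s A spectra tibble.
#' @return A ggplot object.
#' @export
plot_spectra <- function(s) {
  s <- validate_spectra(s)
  means <- group_mean_spectra(s)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$wavelength_nm, y = .data$value,
                                  colour = .data$group)) +
    ggplot2::geom_line(ggplot2::aes(
      group = interaction(.data$sample_id, .data$replicate)),
      alpha = 0.1, linewidth = 0.2) +
    ggplot2::geom_line(data = means,
                       ggplot2::aes(group = .data$group), linewidth = 0.9) +
    ggplot2::labs(x = "Wavelength (nm)", y = s$mode[1], colour = NULL) +
    ggplot2::theme_minimal()
}

#' Radar-chart aquagram (water spectral pattern)
#'
#' The twelve WAMACS coordinates on a polar axis, one polygon per group;
#' the water reference sits at zero by construction.
#'
#' @param object An `aquagram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.aquagram <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$band <- factor(df$band, levels = paste0("C", 1:12))
  closed <- dplyr::bind_rows(df, dplyr::filter(df, .data$band == "C1"))
  ggplot2::ggplot(closed,
                  ggplot2::aes(x = .data$band, y = .data$value,
                               group = .data$group,
                               colour = .data$group)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.8) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = NULL, y = "Normalized absorbance", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.aquagram
#' @export
plot_aquagram <- function(object, ...) autoplot.aquagram(object, ...)

#' WAMACS barcode plot
#'
#' One vertical tick per group at each band's WABS wavelength, the
#' band limits shaded behind them; chemical shifts between groups read as
#' horizontal displacement within a band.
#'
#' @param object A `wamacs_barcode`.
#' @param bands WAMACS registry used for the band limit shading.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.wamacs_barcode <- function(object, bands = wamacs_bands(), ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("band", grep("^wabs_", names(object),
                                             value = TRUE))],
    dplyr::starts_with("wabs_"), names_to = "group",
    values_to = "wavelength_nm", names_prefix = "wabs_")
  ggplot2::ggplot(long) +
    ggplot2::geom_rect(data = bands,
                       ggplot2::aes(xmin = .data$lo_nm, xmax = .data$hi_nm),
                       ymin = -Inf, ymax = Inf, fill = "grey92") +
    ggplot2::geom_vline(data = long,
                        ggplot2::aes(xintercept = .data$wavelength_nm,
                                     colour = .data$group),
                        linewidth = 0.8) +
    ggplot2::facet_wrap(~group, ncol = 1) +
    ggplot2::labs(x = "Wavelength (nm)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @rdname autoplot.wamacs_barcode
#' @export
plot_barcode <- function(object, bands = wamacs_bands(), ...) {
  autoplot.wamacs_barcode(object, bands = bands, ...)
}

#' Volcano-style plot of differential-protein results
#'
#' Effect (log10 emPAI ratio, Passed/Failed) against -log10 p-value for
#' the proteins called at the result's alpha.
#'
#' @param object A `dep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.dep_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect,
                                   y = -log10(.data$p_value),
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$gene_id),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "log10 emPAI ratio (Passed / Failed)",
                  y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}
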