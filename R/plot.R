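#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

plot_raster <- function(df, fill, title, legend) {
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = {{ fill }})) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = "Longitude", y = "Latitude",
                  fill = legend) +
    ggplot2::theme_minimal()
}

#' @describeIn env_stack Plot one layer of a stack.
#' @param object An `env_stack`.
#' @param layer Layer to plot.
#' @method autoplot env_stack
#' @export
autoplot.env_stack <- function(object, layer = 1, ...) {
  nm <- if (is.numeric(layer)) object$layer_names[layer] else layer
  df <- as_tibble(object)
  df$value <- df[[nm]]
  df$value[df$nodata] <- NA
  plot_raster(df, .data$value, nm, nm) +
    ggplot2::scale_fill_viridis_c(na.value = "grey90")
}

#' @describeIn niche_grid Plot the corrected occupancy density and the
#'   occupancy outline in niche space.
#' @param object A `niche_grid`.
#' @method autoplot niche_grid
#' @export
autoplot.niche_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$pc1, .data$pc2)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z_cor)) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "PC1", y = "PC2", fill = "occupancy") +
    ggplot2::theme_minimal()
}

#' @describeIn niche_overlap Overlap map in niche space: reference-only,
#'   introduced-only, and shared occupancy cells.
#' @param object A `niche_overlap` object.
#' @method autoplot niche_overlap
#' @export
autoplot.niche_overlap <- function(object, ...) {
  dn <- as_tibble(object$native); di <- as_tibble(object$invaded)
  df <- dn |>
    dplyr::mutate(status = dplyr::case_when(
      .data$occupied & di$occupied ~ "overlap",
      .data$occupied ~ "reference only",
      di$occupied ~ "introduced only",
      TRUE ~ NA_character_))
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$status)),
                  ggplot2::aes(.data$pc1, .data$pc2, fill = .data$status)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      "overlap" = "#4477aa", "reference only" = "#d8c29d",
      "introduced only" = "#6f4e37")) +
    ggplot2::labs(x = "PC1", y = "PC2", fill = NULL,
                  title = sprintf("Niche overlap (D = %.3f)", object$D)) +
    ggplot2::theme_minimal()
}

#' @describeIn mess_map Plot a MESS surface on the symmetric -100..100
#'   convention (values below -100 shown at -100).
#' @param object A `mess_result`.
#' @method autoplot mess_result
#' @export
autoplot.mess_result <- function(object, ...) {
  df <- as_tibble(object)
  df$similarity <- pmax(df$similarity, -100)
  plot_raster(df, .data$similarity, "Environmental similarity (MESS)",
              "similarity") +
    ggplot2::scale_fill_gradient2(low = "#6f4e37", mid = "white",
                                  high = "#2166ac", limits = c(-100, 100),
                                  na.value = "grey90")
}

#' @describeIn risk_map Plot the invasion-risk surface.
#' @param object A `risk_map` (needs a grid).
#' @method autoplot risk_map
#' @export
autoplot.risk_map <- function(object, ...) {
  if (is.null(object$grid)) stop("risk map has no geographic grid to plot")
  plot_raster(as_tibble(object), .data$risk, "Invasion risk", "risk") +
    ggplot2::scale_fill_viridis_c(option = "inferno", na.value = "grey90")
}

#' @describeIn similarity_test Histogram of the null D distribution with
#'   the observed D marked.
#' @param object A `similarity_test`.
#' @param ... Unused.
#' @method autoplot similarity_test
#' @export
autoplot.similarity_test <- function(object, ...) {
  ggplot2::ggplot(tibble::tibble(d = object$d_null), ggplot2::aes(.data$d)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$d_obs, colour = "#b2182b") +
    ggplot2::labs(x = "null Schoener's D", y = "count",
                  title = sprintf("Similarity test (%s null): p = %.3g",
                                  object$method, object$p)) +
    ggplot2::theme_minimal()
}
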