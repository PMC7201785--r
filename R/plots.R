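# ggplot2 views of the package's image and result objects.

thermo_raster_df <- function(m, value_name = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value_name]] <- as.vector(m)
  tibble::as_tibble(df)
}

#' Plot a temperature field
#'
#' @param object A [temperature_field()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thermo_field <- function(object, ...) {
  df <- thermo_raster_df(as_field_matrix(object), "temperature")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$temperature)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(
      colours = c("#0A0AFC", "#00FCFC", "#0AFC0A", "#FCFC00", "#FC0A0A"),
      name = "deg C"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot a rendered color thermogram
#'
#' @param object A `color_thermogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.color_thermogram <- function(object, ...) {
  hexes <- grDevices::rgb(object[, , 1], object[, , 2], object[, , 3],
                          maxColorValue = 255)
  df <- thermo_raster_df(object[, , 1], "dummy")
  df$fill <- hexes
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot an ROC curve
#'
#' @param object A `thermo_roc` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thermo_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}

#' Plot a correlation matrix as a tile heatmap
#'
#' @param object A `thermo_corrmat` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thermo_corrmat <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$r), "", sprintf("%.2f%s", .data$r, .data$stars))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", high = "#B2182B",
                                  limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL)
}
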