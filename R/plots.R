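#' Plot a group time course (mean with between-subject SEM ribbon)
#'
#' @param object A `group_timecourse`.
#' @param clusters Optional `cluster_result`; significant clusters are drawn
#'   as horizontal bars below the curve.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.group_timecourse <- function(object, clusters = NULL, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(object), .data$time_ms),
    mean = mean(.data$value),
    sem = stats::sd(.data$value) / sqrt(dplyr::n()), .groups = "drop")
  chance <- attr(object, "chance") %||% 0
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = chance, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted",
                        color = "grey70") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = attr(object, "statistic") %||% "value") +
    ggplot2::theme_minimal()
  if (!is.null(clusters)) {
    sig <- clusters$clusters[clusters$clusters$significant, ]
    if (nrow(sig)) {
      y0 <- min(df$mean - df$sem)
      p <- p + ggplot2::annotate("segment", x = sig$start_ms, xend = sig$end_ms,
                                 y = y0, yend = y0, linewidth = 2,
                                 color = "firebrick")
    }
  }
  p
}

#' Plot one time slice of an RDM series (group average)
#'
#' @param rdms An `rdm_series`.
#' @param time_ms Time point (nearest sample is used).
#' @return A ggplot heat map of the condition x condition decoding matrix.
#' @export
plot_rdm <- function(rdms, time_ms) {
  ti <- which.min(abs(rdms$times - time_ms))
  m <- apply(rdms$acc[, ti, , , drop = FALSE], c(3, 4), mean)
  df <- tidyr::expand_grid(i = seq_along(rdms$conditions),
                           j = seq_along(rdms$conditions))
  df$acc <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$acc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "% correct", na.value = "white") +
    ggplot2::labs(x = "condition", y = "condition",
                  title = sprintf("decoding RDM at %g ms", rdms$times[ti])) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a model RDM
#'
#' @param rdm A `model_rdm`.
#' @return A ggplot heat map.
#' @export
plot_model_rdm <- function(rdm) {
  m <- unclass(rdm)
  df <- tidyr::expand_grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  df$d <- m[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = .data$d)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "dissimilarity") +
    ggplot2::labs(x = "condition", y = "condition",
                  title = attr(rdm, "source") %||% "model RDM") +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
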