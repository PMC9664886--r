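#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a GAN fit
#'
#' One row per epoch and loss component (`d_loss`, `g_adv`, `g_l1`,
#' `g_total`, `val_l1`).
#'
#' @param x A `ganpop_fit`.
#' @param ... Unused.
#' @return A long tibble with columns `epoch`, `metric`, `value`, `lr`.
#' @export
tidy.ganpop_fit <- function(x, ...) {
  x$loss_history |>
    tidyr::pivot_longer(cols = c("d_loss", "g_adv", "g_l1", "g_total",
                                 "val_l1"),
                        names_to = "metric", values_to = "value") |>
    dplyr::select("epoch", "metric", "value", "lr")
}

#' One-row summary of a GAN fit
#'
#' @param x A `ganpop_fit`.
#' @param ... Unused.
#' @return A tibble with the training scale, lambda, final losses and the
#'   divergence flag.
#' @export
glance.ganpop_fit <- function(x, ...) {
  h <- x$loss_history
  last <- h[nrow(h), ]
  v <- h$val_l1[!is.na(h$val_l1)]
  tibble::tibble(
    epochs = nrow(h), n_train = x$n_train, n_val = x$n_val,
    lambda_l1 = x$config$lambda_l1, size = x$generator$size,
    final_d_loss = last$d_loss, final_g_total = last$g_total,
    final_val_l1 = if (length(v)) v[length(v)] else NA_real_,
    diverged = x$diverged
  )
}

#' Tidy an NMAE report
#'
#' @param x An `nmae_report`.
#' @param ... Unused.
#' @return Long tibble: `sample_id`, `channel` (absorption/scattering),
#'   `nmae`, and `condition` when present.
#' @export
tidy.nmae_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::pivot_longer(cols = c("nmae_abs", "nmae_sct"),
                        names_to = "channel", values_to = "nmae") |>
    dplyr::mutate(channel = dplyr::recode(.data$channel,
                                          nmae_abs = "absorption",
                                          nmae_sct = "scattering"))
}

#' One-row summary of an NMAE report (means and envelopes, %)
#'
#' @param x An `nmae_report`.
#' @param ... Unused.
#' @return See [nmae_summary()].
#' @export
glance.nmae_report <- function(x, ...) nmae_summary(x)

#' Validation NMAE scatter plot
#'
#' Scattering vs absorption NMAE (%) per validation image, one point per
#' image, coloured by condition when several are present.
#'
#' @param object An `nmae_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nmae_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = 100 * .data$nmae_abs,
                                        y = 100 * .data$nmae_sct)) +
    ggplot2::labs(x = "absorption NMAE (%)", y = "scattering NMAE (%)")
  if ("condition" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$condition))
  } else {
    p + ggplot2::geom_point()
  }
}

#' Training-loss convergence plot
#'
#' Loss components against epoch (cf. the convergence study over seeded
#' runs).
#'
#' @param object A `ganpop_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ganpop_fit <- function(object, ...) {
  tidy(object) |>
    dplyr::filter(!is.na(.data$value)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$epoch, y = .data$value,
                                 colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss")
}

image_to_df <- function(px) {
  d <- dim(px)
  tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    r = as.vector(px[, , 1]), g = as.vector(px[, , 2]),
    b = as.vector(px[, , 3])
  )
}

#' Display an SFDI render
#'
#' @param object An `sfdi_image`.
#' @param ... Unused.
#' @return A ggplot raster of the image.
#' @export
autoplot.sfdi_image <- function(object, ...) {
  df <- image_to_df(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = grDevices::rgb(.data$r, .data$g,
                                                            .data$b))) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Display a paired training sample (input | ground truth)
#'
#' @param object A `paired_sample`.
#' @param ... Unused.
#' @return A ggplot raster of the concatenated pair.
#' @export
autoplot.paired_sample <- function(object, ...) {
  df <- image_to_df(object$pixels / 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = grDevices::rgb(.data$r, .data$g,
                                                            .data$b))) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' Display a per-pixel percentage difference map
#'
#' Masked (zero-reference) pixels are blank.
#'
#' @param object A `difference_map`.
#' @param ... Unused.
#' @return A ggplot raster with a continuous percent scale.
#' @export
autoplot.difference_map <- function(object, ...) {
  d <- dim(object$map)
  df <- tibble::tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    pct = as.vector(object$map)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$pct)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "% diff")
}
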