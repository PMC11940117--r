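# ggplot2 views of the pipeline outputs.

#' Plot group-mean age trends with confidence ribbons
#'
#' @param summary_tbl A [run_pipeline()] `group_summary` tibble (or any
#'   tibble with `group`, `mean`, `ci_lo`, `ci_hi`, and optional `montage` /
#'   `outcome` columns).
#' @param outcome Which outcome to show when the tibble carries several.
#' @return A ggplot object.
#' @export
plot_age_trend <- function(summary_tbl, outcome = "peak99") {
  d <- summary_tbl
  if ("outcome" %in% names(d)) {
    d <- dplyr::filter(d, .data$outcome == .env$outcome)
  }
  ylab <- if (outcome == "focality75") {
    expression("focality"[75] ~ (cm^3))
  } else {
    "E-field amplitude (V/m)"
  }
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = .data$group, y = .data$mean, group = 1
  )) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "age group (years)", y = ylab) +
    ggplot2::theme_minimal()
  if ("montage" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(~montage, scales = "free_y")
  }
  p
}

#' Plot standardized stepwise coefficients
#'
#' Bar chart of the standardized regression coefficients of one stepwise
#' fit; retained predictors are filled, eliminated ones appear at zero.
#'
#' @param object A [stepwise_backward()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tes_stepwise <- function(object, ...) {
  d <- tidy(object) |>
    dplyr::mutate(estimate = ifelse(is.na(.data$estimate), 0, .data$estimate))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$term, abs(.data$estimate)),
    y = .data$estimate, fill = .data$status
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = "standardized coefficient", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot the radial field-magnitude profile of a solution
#'
#' Median element |E| in radial bins, per tissue: a quick visual check of
#' the layered field structure (high in CSF, attenuated through skull).
#'
#' @param field A [compute_efield()] result.
#' @param mesh The mesh it was solved on.
#' @param bins Number of radial bins.
#' @return A ggplot object.
#' @export
plot_radial_profile <- function(field, mesh, bins = 60L) {
  r <- sqrt(rowSums(tet_centroids(mesh)^2))
  d <- tibble::tibble(
    r_mm = r * 1e3, mag = field$magnitude, tissue = mesh$tissue
  ) |>
    dplyr::mutate(bin = cut(.data$r_mm, bins)) |>
    dplyr::group_by(.data$tissue, .data$bin) |>
    dplyr::summarise(
      r_mm = mean(.data$r_mm), mag = stats::median(.data$mag),
      .groups = "drop"
    )
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$r_mm, y = .data$mag, colour = .data$tissue
  )) +
    ggplot2::geom_line(ggplot2::aes(group = .data$tissue)) +
    ggplot2::labs(x = "radius (mm)", y = "|E| (V/m)", colour = NULL) +
    ggplot2::theme_minimal()
}
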