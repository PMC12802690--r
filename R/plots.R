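#' Plot one site's methylation trajectory
#'
#' Scatter of a site's beta values against developmental age with a
#' smooth trend.
#'
#' @param beta Beta matrix.
#' @param sheet Sample sheet with `age_value`.
#' @param site_id Site to plot.
#' @param smooth Add a loess trend line.
#' @return A ggplot object.
#' @export
plot_trajectory <- function(beta, sheet, site_id, smooth = TRUE) {
  if (!site_id %in% rownames(beta)) mt_abort("site '%s' not in beta", site_id)
  df <- tibble(age = sheet$age_value[match(colnames(beta), sheet$sample_id)],
               meth = beta[site_id, ] * 100)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age, y = .data$meth)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Age (pcw)", y = "DNA methylation (%)", title = site_id) +
    ggplot2::theme_minimal()
  if (smooth) p <- p + ggplot2::geom_smooth(method = "loess", formula = y ~ x,
                                            se = FALSE, colour = "firebrick")
  p
}

#' Plot module eigengenes against age
#'
#' @param eigengenes Tibble from [module_eigengenes()].
#' @param sheet Sample sheet with `age_value`.
#' @return A ggplot object, one facet per module.
#' @export
plot_eigengenes <- function(eigengenes, sheet) {
  df <- dplyr::left_join(eigengenes,
                         sheet |> select("sample_id", "age_value"),
                         by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_value, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
    ggplot2::facet_wrap(~module, scales = "free_y") +
    ggplot2::labs(x = "Age (pcw)", y = "Eigengene score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.meth_enrichment <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(sig = .data$p_corrected < 0.05)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$category,
                                   colour = .data$sig)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$effect - 1.96 * .data$se,
                                         xmax = .data$effect + 1.96 * .data$se),
                            height = 0.2, na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey50"),
                                 name = "corrected p < 0.05") +
    ggplot2::labs(x = "Effect (log odds)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.meth_gp_classification <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::count(.data$class, .data$high_confidence)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n,
                                   fill = .data$high_confidence)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Trajectory class", y = "Sites",
                  fill = "High confidence") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.meth_deconv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$proportion,
                                   fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Estimated proportion", fill = "Cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}
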