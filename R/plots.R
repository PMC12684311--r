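#' @export
autoplot.joint_sfs <- function(object, trans = "log1p", ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$count2, y = .data$count1,
                               fill = .data$n_sites)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "sites") +
    ggplot2::labs(x = "allele count, population 2",
                  y = "allele count, population 1",
                  title = sprintf("Joint SFS (%s)",
                                  if (object$folded) "folded" else "unfolded")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.folded_sfs <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$minor_count, y = .data$n_sites)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "minor-allele count", y = "sites",
                  title = "Folded site frequency spectrum") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gene_flow_scan <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$m_recent)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), alpha = 0.7) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 4)) +
    ggplot2::labs(x = "epoch breakpoint X (generations ago)",
                  y = expression(t[2] ~ "(integrated gene flow)"),
                  shape = "excluded") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.deconvolution <- function(object, clamped = TRUE, ...) {
  d <- as_tibble(object)
  y <- if (clamped) d$act_clamped else d$act_raw
  ggplot2::ggplot(d, ggplot2::aes(x = .data$interval_end, y = y)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generations before present",
                  y = "gene flow per 100-generation interval") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.geneflow_band <- function(object, clamped = TRUE, ...) {
  d <- as_tibble(object)
  d$rate <- if (clamped) d$act_clamped else d$act_raw
  ggplot2::ggplot(d, ggplot2::aes(x = .data$interval_end)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "firebrick", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rate), colour = "firebrick") +
    ggplot2::labs(x = "generations before present",
                  y = "gene flow per interval (95% bootstrap band)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ne_aggregate <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "purple", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_z), colour = "purple") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "years before present",
                  y = "mean z-transformed Ne") +
    ggplot2::theme_minimal()
}
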