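# ggplot2 methods for interactive inspection of result objects.
# (File writers export tables only; see write_topogram / write_predictions.)

#' @describeIn auc_topogram heatmap of the AUC(m, k) lattice with the
#'   accountable cells at confidence `p` outlined.
#' @param object a `flowps_topogram`.
#' @param p optional confidence level to outline the accountable set.
#' @export
autoplot.flowps_topogram <- function(object, p = NULL, ...) {
  df <- tidy(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$m,
                                         fill = .data$auc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80", limits = c(0, 1)) +
    ggplot2::labs(x = "k (nearest neighbors kept)",
                  y = "m (flanking points required)", fill = "inner AUC")
  if (!is.null(p)) {
    cells <- accountable_set(object, p)
    gg <- gg + ggplot2::geom_tile(data = cells, fill = NA,
                                  colour = "yellow", linewidth = 0.4)
  }
  gg
}

#' @describeIn flowps_loo violin/jitter plot of the P_F predictions split
#'   by true response, with the discrimination threshold tau.
#' @param object a `flowps_loo` result.
#' @export
autoplot.flowps_loo <- function(object, ...) {
  df <- mutate(object$predictions,
               response = ifelse(.data$true_label == 100,
                                 "responder", "non-responder"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$response, y = .data$p_f,
                                   fill = .data$response)) +
    ggplot2::geom_violin(alpha = 0.4, scale = "width") +
    ggplot2::geom_jitter(width = 0.08, height = 0,
                         ggplot2::aes(colour = .data$response)) +
    ggplot2::geom_hline(yintercept = object$metrics$tau, linetype = 2) +
    ggplot2::guides(fill = "none", colour = "none") +
    ggplot2::labs(y = expression(P[F]), x = NULL)
}
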