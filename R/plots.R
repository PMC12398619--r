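#' Group comparison plot of per-ROI SCS values
#'
#' Box-and-jitter plot of subject-level SCS per ROI and group, for one
#' component window.
#'
#' @param scs_tbl SCS tibble from [run_pipeline()].
#' @param component component window to show (default `"N100"`).
#' @return a ggplot object.
#' @export
plot_scs_groups <- function(scs_tbl, component = "N100") {
  sub <- scs_tbl[scs_tbl$component == component, ]
  ggplot2::ggplot(sub, ggplot2::aes(.data$group, .data$scs,
                                    fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6) +
    ggplot2::geom_jitter(width = 0.15, size = 0.7, alpha = 0.6) +
    ggplot2::facet_wrap(~roi, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "SCS (strength · mm)",
                  title = paste("Significant current scattering,",
                                component, "window")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
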