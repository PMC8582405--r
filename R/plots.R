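# Result figures beyond the autoplot() methods.

#' Scatter of the two top discriminative dispersion features
#'
#' Case-level scatter of the variance-in-perimeter feature against the
#' variance-in-irregularity feature, coloured by diagnosis -- the classic
#' monomorphic-versus-pleomorphic view in which MEITL cases cluster at low
#' dispersion and ITCL-NOS cases spread to high dispersion, with borderline
#' cases in between.
#'
#' @param cases Case profiles from [aggregate_cases()].
#' @return A ggplot object.
#' @export
plot_variance_scatter <- function(cases) {
  ggplot2::ggplot(cases,
                  ggplot2::aes(x = .data$perimeter_variance,
                               y = .data$irregularity_variance,
                               colour = .data$diagnosis,
                               shape = .data$diagnosis)) +
    ggplot2::geom_point(size = 2.5, alpha = 0.85) +
    ggplot2::labs(x = "Variance of perimeter (µm²)",
                  y = "Variance of irregularity (µm⁴)",
                  colour = "Diagnosis", shape = "Diagnosis") +
    ggplot2::theme_minimal()
}

#' Gain importance bar chart
#'
#' Features of the final classifier ranked by total gain.
#'
#' @param model A `subtype_model` (or fitted booster).
#' @param top_n Show at most this many features.
#' @return A ggplot object.
#' @export
plot_gain_importance <- function(model, top_n = 15L) {
  imp <- feature_importance_gain(model) |> head(top_n)
  ggplot2::ggplot(imp,
                  ggplot2::aes(x = .data$gain,
                               y = stats::reorder(.data$feature,
                                                  .data$gain))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Gain", y = NULL) +
    ggplot2::theme_minimal()
}
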