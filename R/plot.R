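#' Plot a model's training trace
#'
#' Reconstruction MSE per epoch for the feature autoencoder, mean ELBO per
#' epoch for the CVAE.
#'
#' @param model A `fae_model` or `cvae_model`.
#' @return A ggplot object.
#' @export
plot_training <- function(model) {
  df <- loss_trace(model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch",
                  y = if (df$metric[1] == "mse") "reconstruction MSE" else "mean ELBO") +
    ggplot2::theme_minimal()
}

#' Plot imputed versus complete values on the injected mask
#'
#' Scatter of imputed against true (complete) logged values at the
#' corrupted coordinates, with the identity line; points on the x-axis are
#' injected zeros the imputation failed to restore.
#'
#' @param experiment A `corruption_experiment`.
#' @param result The matching `mbsparse_result`.
#' @return A ggplot object.
#' @export
plot_recovery <- function(experiment, result) {
  tm <- result$transform
  complete <- transform_counts(experiment$complete,
                               target = tm$target_library_size,
                               method = tm$method)$logged
  idx <- mask_linear_index(experiment$injected_mask)
  df <- tibble::tibble(true = complete[idx],
                       imputed = result$imputed_logged[idx])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$true, y = .data$imputed)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "complete (logged)", y = "imputed (logged)") +
    ggplot2::theme_minimal()
}
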