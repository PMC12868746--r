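#' Plot a persistence image
#'
#' @param pi a `persistence_image` matrix.
#' @return a ggplot raster of the image in (birth, persistence) axes.
#' @export
plot_pi <- function(pi) {
  stopifnot(is.matrix(pi))
  df <- expand.grid(birth = seq_len(nrow(pi)), persistence = seq_len(ncol(pi)))
  df$intensity <- as.vector(pi)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$birth, y = .data$persistence,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "birth (grid index)", y = "persistence (grid index)",
                  fill = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot generator / discriminator loss curves
#'
#' @param gen_losses,disc_losses per-epoch mean losses (as returned by
#'   [adversarial_train()]); `disc_losses` may be `NULL` for pretraining
#'   curves.
#' @return a ggplot line chart.
#' @export
plot_training_losses <- function(gen_losses, disc_losses = NULL) {
  df <- data.frame(epoch = seq_along(gen_losses), loss = gen_losses,
                   model = "generator")
  if (!is.null(disc_losses)) {
    df <- rbind(df, data.frame(epoch = seq_along(disc_losses),
                               loss = disc_losses, model = "discriminator"))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                   colour = .data$model)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}
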