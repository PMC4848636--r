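# ggplot2 autoplot methods for the main result types.

# palette matching the conventional residue-class colouring of Kunitz toxin
# alignments: negative red, positive blue, polar uncharged magenta,
# hydrophobic green
CLASS_PALETTE <- c(negative = "#d62728", positive = "#1f77b4",
                   polar_uncharged = "#e377c2", hydrophobic = "#2ca02c",
                   unclassifiable = "grey60")

#' @method autoplot morrison_fit
#' @export
autoplot.morrison_fit <- function(object, n = 200, ...) {
  grid <- tibble(conc = seq(0, max(object$data$conc), length.out = n))
  grid$activity <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc * 1e9, y = .data$activity)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "[inhibitor] (nM)", y = expression(v[i] / v[0]),
                  title = sprintf("Morrison fit: Ki_app = %.3g nM", object$ki_app * 1e9)) +
    ggplot2::theme_minimal()
}

#' @method autoplot hill_fit
#' @export
autoplot.hill_fit <- function(object, n = 200, ...) {
  rng <- range(object$data$conc)
  grid <- tibble(conc = 10^seq(log10(rng[1]), log10(rng[2]), length.out = n))
  grid$block <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$block)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "[toxin] (M)", y = "current block (%)",
                  title = sprintf("Hill fit: IC50 = %.3g nM, h = %.2f",
                                  object$ic50 * 1e9, object$h)) +
    ggplot2::theme_minimal()
}

#' @method autoplot boltzmann_fit
#' @export
autoplot.boltzmann_fit <- function(object, n = 200, ...) {
  grid <- tibble(v = seq(min(object$data$v), max(object$data$v), length.out = n))
  grid$g <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$v, y = .data$g)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "test potential (mV)", y = "G / Gmax",
                  title = sprintf("Boltzmann fit: V1/2 = %.1f mV, k = %.1f mV",
                                  object$v_half, object$slope_k)) +
    ggplot2::theme_minimal()
}

#' @method autoplot class_profile
#' @export
autoplot.class_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$slot, y = .data$id, fill = .data$class)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$residue), size = 3) +
    ggplot2::scale_fill_manual(values = CLASS_PALETTE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_minimal()
}
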