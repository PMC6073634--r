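# ggplot2 autoplot methods for the main result types

#' @export
autoplot.gard_trace <- function(object, ...) {
  h <- carpet(object)
  df <- tibble::tibble(
    t1 = rep(seq_len(nrow(h)), times = ncol(h)),
    t2 = rep(seq_len(ncol(h)), each = nrow(h)),
    H = as.vector(h))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t1, y = .data$t2,
                                   fill = .data$H)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "generation", y = "generation",
                  title = "Compositional time-correlation carpet",
                  fill = "H")
}

#' @export
autoplot.gard_timeseries <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$fraction,
                                   group = .data$compound,
                                   colour = factor(.data$compound))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "simulated time", y = "molar fraction n_i / N",
                  title = "Finite-supply relaxation to equilibrium")
}

#' @export
autoplot.reactor_history <- function(object, ...) {
  df <- object$frequencies
  df$label <- ifelse(df$compotype == 0, "drift",
                     paste0("C", df$compotype))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$split, y = .data$frequency,
                                   colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "split events", y = "population frequency",
                  colour = "compotype",
                  title = "Compotype dynamics in a constant-population reactor")
}

#' @export
autoplot.depletion_screen <- function(object, ...) {
  df <- dplyr::filter(object, .data$ratio > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::geom_vline(xintercept = c(0.79, 1.25), linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "growth-rate ratio (after / before depletion)",
                  y = "depletion instances",
                  title = "Single-compound depletion screen")
}

#' @export
autoplot.pgard_trace <- function(object, ...) {
  df <- tibble::tibble(generation = seq_along(object$dimer_fraction),
                       dimer_fraction = object$dimer_fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation,
                                   y = .data$dimer_fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation",
                  y = "fraction of monomer equivalents in dimers",
                  title = "Dimer content along a polymer-GARD trace")
}

#' @export
autoplot.shift_experiment <- function(object, ...) {
  df <- tidy(object)
  df$label <- ifelse(df$compotype == 0, "drift", paste0("C", df$compotype))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$split, y = .data$frequency,
                                   colour = .data$label,
                                   linetype = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$switch_at, linetype = 3) +
    ggplot2::labs(x = "split events", y = "population frequency",
                  colour = "compotype", linetype = "phase",
                  title = sprintf(
                    "Environment shift towards compotype C%d (weight %g)",
                    object$target, object$weight))
}
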