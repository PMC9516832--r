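# ggplot2 plotting methods ----------------------------------------------------

#' Plot a generator's training loss curve
#'
#' @param object An `smi_generator`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smi_generator <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean cross-entropy per character",
                  title = "General model training loss")
}

#' Plot a biasing run's trace
#'
#' For CRLV: desirable fraction and loss scale per epoch; for REINFORCE:
#' mean episode reward. The best-epoch probe counts are shown for both.
#'
#' @param object An `smi_biased`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smi_biased <- function(object, ...) {
  tr <- object$trace
  long <- tidyr::pivot_longer(
    tr, cols = -dplyr::any_of(c("epoch")),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(title = paste0("Biasing trace (", object$method, ", ",
                                 object$objective, ")"),
                  x = "epoch", y = NULL)
}

#' Plot a temperature sweep
#'
#' @param object An `smi_sweep` from [temperature_sweep()].
#' @param ... Unused.
#' @return A ggplot of each funnel metric against temperature.
#' @export
autoplot.smi_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::all_of(c("validity", "novelty", "uniqueness", "int_div")),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$temperature, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "sampling temperature", y = NULL,
                  title = "Funnel metrics across sampling temperature")
}

#' Compare a descriptor's distribution across molecule sets
#'
#' Density plot of one descriptor over several generated sets — the
#' property-shift picture for an objective, e.g. unbiased versus biased
#' models.
#'
#' @param sets Named list of SMILES character vectors.
#' @param descriptor Descriptor name (see [property_distribution()]).
#' @param threshold Optional vertical reference line (e.g. an objective
#'   bound).
#' @return A ggplot.
#' @export
plot_property_shift <- function(sets, descriptor, threshold = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  df <- purrr::imap_dfr(sets, function(mols, nm) {
    tibble::tibble(set = nm,
                   value = property_distribution(mols, descriptor))
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                        colour = .data$set,
                                        fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.2) +
    ggplot2::labs(x = descriptor, y = "density",
                  title = paste("Distribution of", descriptor))
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = 2)
  }
  p
}
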