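# broom-style tidiers for fitted objects --------------------------------------

#' Tidy a trained generator's loss trace
#'
#' @param x An `smi_generator`.
#' @param ... Unused.
#' @return Tibble with `epoch` and `loss`.
#' @export
tidy.smi_generator <- function(x, ...) x$loss_trace

#' One-row summary of a trained generator
#'
#' @param x An `smi_generator`.
#' @param ... Unused.
#' @return Tibble with architecture and final-loss columns.
#' @export
glance.smi_generator <- function(x, ...) {
  tibble::tibble(
    recurrent_layers = x$config$recurrent_layers,
    hidden_units = x$config$hidden_units,
    embedding_dim = x$config$embedding_dim,
    vocab_size = x$vocab$size_k,
    epochs_trained = nrow(x$loss_trace),
    final_loss = if (nrow(x$loss_trace)) utils::tail(x$loss_trace$loss, 1)
                 else NA_real_
  )
}

#' Tidy a biasing run's per-epoch trace
#'
#' @param x An `smi_biased`.
#' @param ... Unused.
#' @return The per-epoch trace tibble.
#' @export
tidy.smi_biased <- function(x, ...) x$trace

#' One-row summary of a biasing run
#'
#' @param x An `smi_biased`.
#' @param ... Unused.
#' @return Tibble with method, objective, epoch counts and best epoch.
#' @export
glance.smi_biased <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    objective = x$objective,
    epochs = nrow(x$trace),
    best_epoch = x$best_epoch,
    final_probe_desirable = if (nrow(x$trace))
      utils::tail(x$trace$probe_desirable, 1) else NA_integer_
  )
}
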