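# The general model G: configs, training, sampling ---------------------------

#' Generator configuration
#'
#' Defaults follow the reference architecture: three GRU layers of 512 units,
#' Adam with learning rate 0.0005. The embedding width is an implementation
#' choice (default 128). Desk-scale experiments typically shrink layers and
#' units rather than the learning rate.
#'
#' @param embedding_dim Embedding width.
#' @param recurrent_layers Number of stacked GRU layers.
#' @param hidden_units Units per GRU layer.
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Sequences per batch.
#' @param seed Integer seed controlling initialization and batch order.
#' @param checkpoint_every Write a checkpoint every this many epochs
#'   (`NULL` = never).
#' @param checkpoint_dir Directory for checkpoints.
#' @return A `gen_config` list.
#' @export
gen_config <- function(embedding_dim = 128L, recurrent_layers = 3L,
                       hidden_units = 512L, learning_rate = 5e-4,
                       epochs = 10L, batch_size = 64L, seed = 1L,
                       checkpoint_every = NULL, checkpoint_dir = NULL) {
  stopifnot(embedding_dim >= 1, recurrent_layers >= 1, hidden_units >= 1,
            learning_rate > 0, epochs >= 0, batch_size >= 1)
  structure(list(
    embedding_dim = as.integer(embedding_dim),
    recurrent_layers = as.integer(recurrent_layers),
    hidden_units = as.integer(hidden_units),
    learning_rate = learning_rate,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    seed = as.integer(seed),
    checkpoint_every = checkpoint_every,
    checkpoint_dir = checkpoint_dir
  ), class = "gen_config")
}

#' Sampling configuration
#'
#' @param temperature Softmax temperature; values below 1 sharpen the
#'   distribution (default 0.50, the benchmark operating point).
#' @param max_length Maximum generated SMILES length in characters.
#' @param n_samples Number of molecules to draw.
#' @param seed Integer seed.
#' @return A `sampling_config` list.
#' @export
sampling_config <- function(temperature = 0.5, max_length = 100L,
                            n_samples = 1000L, seed = 1L) {
  stopifnot(temperature > 0, max_length >= 1, n_samples >= 0)
  structure(list(
    temperature = temperature,
    max_length = as.integer(max_length),
    n_samples = as.integer(n_samples),
    seed = as.integer(seed)
  ), class = "sampling_config")
}

#' Temperature-scaled softmax
#'
#' Computes `exp(y/T) / sum(exp(y/T))` with max-subtraction for numerical
#' stability. `T = 1` is the plain softmax; `T < 1` sharpens towards the
#' argmax, `T > 1` flattens towards uniform.
#'
#' @param logits Numeric vector (or matrix, rows treated independently).
#' @param temperature Positive scalar temperature.
#' @return Probabilities of the same shape; each (row) sums to 1.
#' @examples
#' temperature_softmax(c(2, 0), temperature = 1)
#' @export
temperature_softmax <- function(logits, temperature = 1) {
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      is.na(temperature) || temperature <= 0) {
    stop("temperature must be a positive scalar", call. = FALSE)
  }
  if (!all(is.finite(logits))) stop("logits must be finite", call. = FALSE)
  if (is.matrix(logits)) return(softmax_rows(logits / temperature))
  x <- logits / temperature
  e <- exp(x - max(x))
  e / sum(e)
}

#' Cross-entropy between a predicted distribution and a one-hot target
#'
#' By default uses the `1/k` prefactor of the printed definition,
#' `-(1/k) * sum(yr * log(yp))`; `prefactor = "none"` gives the conventional
#' `-log(yp[true class])`. The two differ only by the constant `1/k`, which in
#' training merely rescales the learning rate; the training loop uses the
#' conventional per-position mean.
#'
#' @param yp Numeric probability vector.
#' @param yr One-hot numeric vector of the same length, or a single integer
#'   class index.
#' @param prefactor `"inverse_k"` (printed form) or `"none"`.
#' @param eps Floor inside the log, so a zero predicted probability yields a
#'   large finite value rather than `Inf`.
#' @return Nonnegative scalar.
#' @export
cross_entropy <- function(yp, yr, prefactor = c("inverse_k", "none"),
                          eps = 1e-12) {
  prefactor <- match.arg(prefactor)
  k <- length(yp)
  stopifnot(k >= 1, all(yp >= 0), abs(sum(yp) - 1) < 1e-6)
  if (length(yr) == 1L && yr == round(yr) && yr >= 1 && yr <= k) {
    idx <- as.integer(yr)
  } else {
    stopifnot(length(yr) == k, sum(yr == 1) == 1L, all(yr %in% c(0, 1)))
    idx <- which(yr == 1)
  }
  ce <- -log(max(yp[idx], eps))
  if (prefactor == "inverse_k") ce / k else ce
}

#' Train the general SMILES language model
#'
#' Teacher-forced next-character training: each record is encoded as
#' `start, chars, end`, padded per batch, and the mean cross-entropy over
#' non-padding positions is minimized with Adam. Fully deterministic for a
#' fixed `config$seed`.
#'
#' @param corpus An `smi_corpus`.
#' @param config A [gen_config()].
#' @return An `smi_generator` with elements `params`, `config`, `vocab` and
#'   `loss_trace` (tibble of per-epoch mean loss).
#' @export
train_general_model <- function(corpus, config) {
  stopifnot(inherits(corpus, "smi_corpus"), inherits(config, "gen_config"))
  vocab <- corpus$vocab
  seqs <- lapply(corpus$records$raw, tokenize, vocab = vocab)
  len_max <- max(lengths(seqs))
  n <- length(seqs)
  full <- matrix(vocab$pad_id, n, len_max)
  for (i in seq_len(n)) full[i, seq_along(seqs[[i]])] <- seqs[[i]]
  inputs_all <- full[, -len_max, drop = FALSE]
  targets_all <- full[, -1L, drop = FALSE]

  withr::with_seed(config$seed, {
    params <- gru_init_params(vocab$size_k, config$embedding_dim,
                              config$hidden_units, config$recurrent_layers)
    state <- adam_init(params)
    trace <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      order_ <- sample.int(n)
      epoch_loss <- 0
      epoch_chars <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- order_[start:min(start + config$batch_size - 1L, n)]
        inputs <- inputs_all[idx, , drop = FALSE]
        targets <- targets_all[idx, , drop = FALSE]
        mask <- (targets != vocab$pad_id) * 1
        n_char <- sum(mask)
        bp <- gru_backprop(params, config$recurrent_layers,
                           inputs, targets, mask / n_char)
        if (!is.finite(bp$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch,
               call. = FALSE)
        }
        upd <- adam_step(params, bp$grads, state, config$learning_rate)
        params <- upd$params
        state <- upd$state
        epoch_loss <- epoch_loss + bp$loss * n_char
        epoch_chars <- epoch_chars + n_char
      }
      trace[epoch] <- epoch_loss / epoch_chars
      if (!is.null(config$checkpoint_every) && !is.null(config$checkpoint_dir) &&
          epoch %% config$checkpoint_every == 0L) {
        done <- seq_len(epoch)
        save_generator(
          new_generator(params, config, vocab,
                        tibble::tibble(epoch = done, loss = trace[done])),
          file.path(config$checkpoint_dir, sprintf("epoch-%04d.rds", epoch))
        )
      }
    }
    new_generator(params, config, vocab,
                  tibble::tibble(epoch = seq_len(config$epochs), loss = trace))
  })
}

new_generator <- function(params, config, vocab, loss_trace) {
  structure(
    list(params = params, config = config, vocab = vocab,
         loss_trace = loss_trace),
    class = "smi_generator"
  )
}

#' Initialize an untrained generator (random weights)
#'
#' @inheritParams train_general_model
#' @param vocab An `smi_vocab`.
#' @return An `smi_generator` with random parameters.
#' @export
init_generator <- function(vocab, config) {
  stopifnot(inherits(vocab, "smi_vocab"), inherits(config, "gen_config"))
  params <- withr::with_seed(config$seed, {
    gru_init_params(vocab$size_k, config$embedding_dim,
                    config$hidden_units, config$recurrent_layers)
  })
  new_generator(params, config, vocab,
                tibble::tibble(epoch = integer(), loss = numeric()))
}

#' @export
print.smi_generator <- function(x, ...) {
  cat("<smi_generator> ", x$config$recurrent_layers, " GRU layer(s) x ",
      x$config$hidden_units, " units, vocab ", x$vocab$size_k, "\n", sep = "")
  if (nrow(x$loss_trace) > 0L) {
    cat("  trained ", nrow(x$loss_trace), " epochs; final mean loss ",
        signif(utils::tail(x$loss_trace$loss, 1), 4), "\n", sep = "")
  } else {
    cat("  untrained (random weights)\n")
  }
  invisible(x)
}

# sample raw token trajectories; returns actions matrix (pad-filled after the
# end token), lengths (actions emitted, end token included) and strings
sample_trajectories <- function(model, n_samples, temperature, max_length,
                                chunk = 256L) {
  vocab <- model$vocab
  cfg <- model$config
  out_ids <- matrix(vocab$pad_id, n_samples, max_length)
  lengths <- integer(n_samples)
  for (start in seq(1L, n_samples, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n_samples)
    bsz <- length(rows)
    hs <- rep(list(matrix(0, bsz, cfg$hidden_units)), cfg$recurrent_layers)
    cur <- rep(vocab$start_id, bsz)
    done <- logical(bsz)
    for (t in seq_len(max_length)) {
      step <- gru_step(model$params, cfg$recurrent_layers, cur, hs)
      hs <- step$hs
      probs <- temperature_softmax(step$logits, temperature)
      cum <- t(apply(probs, 1L, cumsum))
      u <- stats::runif(bsz)
      ids <- 1L + rowSums(cum < u)
      ids[ids > vocab$size_k] <- vocab$size_k  # guard fp round-off
      ids[done] <- vocab$pad_id
      live <- !done
      out_ids[rows[live], t] <- ids[live]
      lengths[rows[live]] <- t
      done <- done | (ids == vocab$end_id)
      cur <- ids
      cur[done] <- vocab$pad_id
      if (all(done)) break
    }
  }
  out_ids <- out_ids[, seq_len(max(1L, max(lengths))), drop = FALSE]
  smiles <- vapply(seq_len(n_samples), function(i) {
    detokenize(out_ids[i, seq_len(lengths[i])], vocab)
  }, character(1))
  list(actions = out_ids, lengths = lengths, smiles = smiles)
}

#' Sample SMILES strings from a generator
#'
#' Autoregressive sampling from the temperature-scaled softmax, starting at
#' the start token and stopping at the end token or `max_length` characters.
#' Returns exactly `n_samples` strings; they are raw model output and may be
#' chemically invalid.
#'
#' @param model An `smi_generator`.
#' @param sampling A [sampling_config()].
#' @return Character vector of length `sampling$n_samples`.
#' @export
sample_smiles <- function(model, sampling) {
  stopifnot(inherits(model, "smi_generator"),
            inherits(sampling, "sampling_config"))
  if (sampling$n_samples == 0L) return(character())
  withr::with_seed(sampling$seed, {
    sample_trajectories(model, sampling$n_samples, sampling$temperature,
                        sampling$max_length)$smiles
  })
}

#' Log-probability of a SMILES string under a generator
#'
#' Teacher-forced sum of log-probabilities of each character (end token
#' included), at temperature 1.
#'
#' @param model An `smi_generator`.
#' @param smiles Character vector.
#' @return Numeric vector of log-probabilities.
#' @export
sequence_logprob <- function(model, smiles) {
  stopifnot(inherits(model, "smi_generator"))
  vapply(smiles, function(s) {
    ids <- tokenize(s, model$vocab)
    inputs <- matrix(ids[-length(ids)], 1L)
    targets <- ids[-1L]
    hs <- rep(list(matrix(0, 1L, model$config$hidden_units)),
              model$config$recurrent_layers)
    lp <- 0
    for (t in seq_len(ncol(inputs))) {
      step <- gru_step(model$params, model$config$recurrent_layers,
                       inputs[, t], hs)
      hs <- step$hs
      p <- temperature_softmax(step$logits[1L, ], 1)
      lp <- lp + log(max(p[targets[t]], 1e-12))
    }
    lp
  }, numeric(1), USE.NAMES = FALSE)
}

#' Save / load a generator checkpoint
#'
#' Single-file serialized checkpoint holding parameters, configuration, the
#' vocabulary manifest and the loss trace, with a format version tag.
#'
#' @param model An `smi_generator`.
#' @param path Checkpoint file path.
#' @return `save_generator` returns `path` invisibly; `load_generator`
#'   returns the model.
#' @export
save_generator <- function(model, path) {
  stopifnot(inherits(model, "smi_generator"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(format = "smigen-checkpoint-v1", model = model), path)
  invisible(path)
}

#' @rdname save_generator
#' @export
load_generator <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "smigen-checkpoint-v1")) {
    stop("not a smigen checkpoint: ", path, call. = FALSE)
  }
  obj$model
}
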