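# CRLV: conditional reduction of the cross-entropy loss value ----------------

#' CRLV configuration
#'
#' @param epochs Biasing epochs.
#' @param n_probe Molecules sampled per epoch to estimate the desirable
#'   fraction (default 20).
#' @param scale_fn Loss-reduction rule: `"linear"` (scale = 1 - d) or
#'   `"step@tau"` (scale 1 while d < tau, then a small epsilon).
#' @param checkpoint_probe_k Molecules per best-epoch probe (default 20).
#' @param learning_rate Adam learning rate for the biasing loop.
#' @param batch_size,batches_per_epoch Random training batches drawn from the
#'   corpus per epoch.
#' @param seed Master seed; every per-epoch probe, batch draw and checkpoint
#'   probe derives its own stream from it.
#' @param sampling A [sampling_config()]; its temperature is used for probes
#'   so the optimized quantity matches the benchmarked one (the seed and
#'   sample count are overridden per probe).
#' @return A `crlv_config`.
#' @export
crlv_config <- function(epochs = 50L, n_probe = 20L, scale_fn = "linear",
                        checkpoint_probe_k = 20L, learning_rate = 5e-4,
                        batch_size = 32L, batches_per_epoch = 8L, seed = 1L,
                        sampling = sampling_config()) {
  stopifnot(epochs >= 0L, n_probe >= 1L, checkpoint_probe_k >= 1L,
            learning_rate > 0, batch_size >= 1L, batches_per_epoch >= 1L)
  crlv_loss_scale(0, scale_fn)  # validate the rule identifier early
  structure(list(
    epochs = as.integer(epochs), n_probe = as.integer(n_probe),
    scale_fn = scale_fn,
    checkpoint_probe_k = as.integer(checkpoint_probe_k),
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    batches_per_epoch = as.integer(batches_per_epoch),
    seed = as.integer(seed), sampling = sampling
  ), class = "crlv_config")
}

#' Fraction of sampled molecules that are valid and desirable
#'
#' Samples `n` molecules from the model and returns the fraction that are
#' chemically valid *and* satisfy the objective (for objectives that do not
#' require validity, the predicate alone decides).
#'
#' @param model An `smi_generator`.
#' @param obj An `smi_objective`.
#' @param n Sample size.
#' @param sampling A [sampling_config()] (its `n_samples` is ignored in
#'   favour of `n`).
#' @return Scalar in \[0, 1\].
#' @export
desirable_fraction <- function(model, obj, n, sampling = sampling_config()) {
  stopifnot(n >= 1L)
  smp <- sample_smiles(model, sampling_config(
    temperature = sampling$temperature, max_length = sampling$max_length,
    n_samples = n, seed = sampling$seed
  ))
  mean(satisfies_objective(smp, obj))
}

# count variant used by the best-epoch checkpoint probe
desirable_count <- function(model, obj, k, sampling, seed) {
  smp <- sample_smiles(model, sampling_config(
    temperature = sampling$temperature, max_length = sampling$max_length,
    n_samples = k, seed = seed
  ))
  sum(satisfies_objective(smp, obj))
}

#' The CRLV loss-scale rule
#'
#' Maps the current desirable fraction `d` to a multiplier on the
#' cross-entropy loss. The `"linear"` rule is `1 - d`: at `d = 0` the full
#' general-training loss is backpropagated, at `d = 1` the update vanishes.
#' `"step@tau"` keeps the full loss while `d < tau` and drops to a small
#' epsilon (0.001) once the target fraction is reached.
#'
#' @param d Desirable fraction in \[0, 1\].
#' @param rule Rule identifier.
#' @return Scale in \[0, 1\], non-increasing in `d`.
#' @export
crlv_loss_scale <- function(d, rule = "linear") {
  if (any(!is.finite(d)) || any(d < 0) || any(d > 1)) {
    stop("desirable fraction d must lie in [0, 1]", call. = FALSE)
  }
  if (identical(rule, "linear")) return(1 - d)
  if (grepl("^step@", rule)) {
    tau <- suppressWarnings(as.numeric(sub("^step@", "", rule)))
    if (is.na(tau) || tau < 0 || tau > 1) {
      stop("step rule threshold must be in [0, 1], e.g. 'step@0.5'",
           call. = FALSE)
    }
    return(ifelse(d < tau, 1, 1e-3))
  }
  stop("unknown CRLV scale rule: ", rule, call. = FALSE)
}

# tokenize + pad a corpus once for the biasing loops
encode_corpus <- function(corpus, vocab) {
  seqs <- lapply(corpus$records$raw, tokenize, vocab = vocab)
  len_max <- max(lengths(seqs))
  n <- length(seqs)
  full <- matrix(vocab$pad_id, n, len_max)
  for (i in seq_len(n)) full[i, seq_along(seqs[[i]])] <- seqs[[i]]
  list(inputs = full[, -len_max, drop = FALSE],
       targets = full[, -1L, drop = FALSE], n = n)
}

# one scaled training pass over randomly drawn batches; scale multiplies the
# gradients (equivalently, the loss). Returns the updated parameters, the
# optimizer state and the unscaled mean CE per character.
scaled_epoch <- function(params, opt_state, enc, vocab, n_layers,
                         batch_size, batches_per_epoch, learning_rate,
                         scale, batch_seed) {
  withr::with_seed(batch_seed, {
    total_loss <- 0
    total_chars <- 0
    for (b in seq_len(batches_per_epoch)) {
      idx <- sample.int(enc$n, min(batch_size, enc$n))
      inputs <- enc$inputs[idx, , drop = FALSE]
      targets <- enc$targets[idx, , drop = FALSE]
      mask <- (targets != vocab$pad_id) * 1
      n_char <- sum(mask)
      bp <- gru_backprop(params, n_layers, inputs, targets, mask / n_char)
      if (!is.finite(bp$loss)) {
        stop("biasing diverged (non-finite loss)", call. = FALSE)
      }
      grads <- if (scale == 1) bp$grads else lapply(bp$grads, function(g) g * scale)
      upd <- adam_step(params, grads, opt_state, learning_rate)
      params <- upd$params
      opt_state <- upd$state
      total_loss <- total_loss + bp$loss * n_char
      total_chars <- total_chars + n_char
    }
    list(params = params, opt_state = opt_state,
         mean_loss = total_loss / total_chars)
  })
}

#' One CRLV epoch
#'
#' Estimates the desirable fraction `d` from `n_probe` sampled molecules,
#' computes the loss scale, then runs one pass of scaled teacher-forced
#' training over randomly drawn corpus batches (one optimizer step per
#' batch).
#'
#' @param model An `smi_generator` (typically a trained general model).
#' @param corpus Training `smi_corpus`.
#' @param obj An `smi_objective`.
#' @param config A [crlv_config()].
#' @param opt_state Adam state from the previous epoch (`NULL` = fresh).
#' @param epoch_seed Seed for this epoch's probe and batch draws.
#' @return List with `model`, `opt_state` and `record` (one-row tibble:
#'   `desirable_fraction`, `loss_scale`, `mean_loss`).
#' @export
crlv_epoch <- function(model, corpus, obj, config, opt_state = NULL,
                       epoch_seed = config$seed) {
  stopifnot(inherits(model, "smi_generator"), inherits(config, "crlv_config"))
  seeds <- derive_seeds(epoch_seed, 2L)
  probe_sampling <- sampling_config(
    temperature = config$sampling$temperature,
    max_length = config$sampling$max_length,
    n_samples = config$n_probe, seed = seeds[1]
  )
  d <- desirable_fraction(model, obj, config$n_probe, probe_sampling)
  scale <- crlv_loss_scale(d, config$scale_fn)
  if (is.null(opt_state)) opt_state <- adam_init(model$params)
  enc <- encode_corpus(corpus, model$vocab)
  res <- scaled_epoch(model$params, opt_state, enc, model$vocab,
                      model$config$recurrent_layers, config$batch_size,
                      config$batches_per_epoch, config$learning_rate,
                      scale, seeds[2])
  model$params <- res$params
  list(
    model = model,
    opt_state = res$opt_state,
    record = tibble::tibble(desirable_fraction = d, loss_scale = scale,
                            mean_loss = res$mean_loss)
  )
}

#' One unscaled training epoch over random batches
#'
#' The plain counterpart of [crlv_epoch()]: the identical batch stream with
#' the loss scale pinned to 1 (no probe). Exposed so scaled and unscaled
#' updates can be compared under the same seed.
#'
#' @inheritParams crlv_epoch
#' @return List with `model`, `opt_state` and `record`.
#' @export
training_epoch <- function(model, corpus, config, opt_state = NULL,
                           epoch_seed = config$seed) {
  stopifnot(inherits(model, "smi_generator"), inherits(config, "crlv_config"))
  seeds <- derive_seeds(epoch_seed, 2L)
  if (is.null(opt_state)) opt_state <- adam_init(model$params)
  enc <- encode_corpus(corpus, model$vocab)
  res <- scaled_epoch(model$params, opt_state, enc, model$vocab,
                      model$config$recurrent_layers, config$batch_size,
                      config$batches_per_epoch, config$learning_rate,
                      1, seeds[2])
  model$params <- res$params
  list(model = model, opt_state = res$opt_state,
       record = tibble::tibble(desirable_fraction = NA_real_, loss_scale = 1,
                               mean_loss = res$mean_loss))
}

new_biased_result <- function(final_model, best_model, best_epoch, trace,
                              method, obj) {
  structure(
    list(final_model = final_model, best_model = best_model,
         best_epoch = best_epoch, trace = trace, method = method,
         objective = obj$name),
    class = "smi_biased"
  )
}

#' @export
print.smi_biased <- function(x, ...) {
  cat("<smi_biased> method ", x$method, ", objective ", x$objective, ", ",
      nrow(x$trace), " epoch(s); best epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Bias a generator with CRLV
#'
#' Runs [crlv_epoch()] for `config$epochs` epochs. After every epoch the
#' current model generates `checkpoint_probe_k` molecules; the checkpoint is
#' kept only when its desirable count strictly surpasses the best so far
#' (ties keep the earlier model). The input model is the epoch-0 reference.
#'
#' @inheritParams crlv_epoch
#' @param g_model The trained general model to bias.
#' @return An `smi_biased`: `final_model`, `best_model`, `best_epoch` and a
#'   per-epoch `trace` tibble (`epoch`, `desirable_fraction`, `loss_scale`,
#'   `mean_loss`, `probe_desirable`).
#' @export
run_crlv <- function(g_model, corpus, obj, config) {
  stopifnot(inherits(g_model, "smi_generator"), inherits(obj, "smi_objective"),
            inherits(config, "crlv_config"))
  seeds <- derive_seeds(config$seed, 2L * config$epochs + 1L)
  model <- g_model
  best_model <- g_model
  best_epoch <- 0L
  best_count <- desirable_count(g_model, obj, config$checkpoint_probe_k,
                                config$sampling, seeds[1])
  opt_state <- NULL
  trace <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    step <- crlv_epoch(model, corpus, obj, config, opt_state,
                       epoch_seed = seeds[2L * epoch])
    model <- step$model
    opt_state <- step$opt_state
    probe <- desirable_count(model, obj, config$checkpoint_probe_k,
                             config$sampling, seeds[2L * epoch + 1L])
    if (probe > best_count) {
      best_count <- probe
      best_model <- model
      best_epoch <- epoch
    }
    trace[[epoch]] <- dplyr::mutate(step$record, epoch = epoch,
                                    probe_desirable = probe, .before = 1L)
  }
  new_biased_result(model, best_model, best_epoch,
                    dplyr::bind_rows(trace), "crlv", obj)
}
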