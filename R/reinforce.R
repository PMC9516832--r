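# REINFORCE policy-gradient biasing ------------------------------------------

#' REINFORCE configuration
#'
#' Terminal rewards only, broadcast to every step of the episode, no
#' discounting and no baseline — plain REINFORCE. The reward table is not
#' canonical (hand-engineered rewards are a known reproducibility sore point
#' for policy-gradient molecule generators), so all three values are
#' configurable; validation enforces
#' `reward_desirable > reward_valid_undesirable >= reward_invalid`.
#'
#' @param epochs Biasing epochs.
#' @param batch_episodes Episodes sampled per epoch.
#' @param reward_desirable Reward for a valid molecule satisfying the
#'   objective (default 1).
#' @param reward_valid_undesirable Reward for a valid but undesirable
#'   molecule (default 0).
#' @param reward_invalid Reward for an unparsable string (default -0.1).
#' @param learning_rate Adam learning rate.
#' @param checkpoint_probe_k Molecules per best-epoch probe (default 20).
#' @param baseline Subtract a running mean-reward baseline? Off by default
#'   (plain REINFORCE); available to reduce gradient variance.
#' @param seed Master seed.
#' @param sampling A [sampling_config()] providing the rollout temperature
#'   and length cap.
#' @return An `rl_config`.
#' @export
rl_config <- function(epochs = 50L, batch_episodes = 32L,
                      reward_desirable = 1.0, reward_valid_undesirable = 0.0,
                      reward_invalid = -0.1, learning_rate = 5e-4,
                      checkpoint_probe_k = 20L, baseline = FALSE, seed = 1L,
                      sampling = sampling_config()) {
  stopifnot(epochs >= 0L, batch_episodes >= 1L, learning_rate > 0,
            checkpoint_probe_k >= 1L)
  if (!(reward_desirable > reward_valid_undesirable &&
        reward_valid_undesirable >= reward_invalid)) {
    stop("rewards must satisfy desirable > valid_undesirable >= invalid",
         call. = FALSE)
  }
  structure(list(
    epochs = as.integer(epochs), batch_episodes = as.integer(batch_episodes),
    reward_desirable = reward_desirable,
    reward_valid_undesirable = reward_valid_undesirable,
    reward_invalid = reward_invalid, learning_rate = learning_rate,
    checkpoint_probe_k = as.integer(checkpoint_probe_k),
    baseline = isTRUE(baseline), seed = as.integer(seed), sampling = sampling
  ), class = "rl_config")
}

#' Terminal reward of a generated SMILES
#'
#' @param smiles Character vector of episode outputs.
#' @param obj An `smi_objective`.
#' @param config An [rl_config()] supplying the reward table.
#' @return Numeric vector of rewards.
#' @export
episode_reward <- function(smiles, obj, config) {
  stopifnot(inherits(config, "rl_config"))
  if (length(smiles) == 0L) return(numeric())
  valid <- is_valid_smiles(smiles)
  desirable <- satisfies_objective(smiles, obj)
  ifelse(desirable & valid, config$reward_desirable,
         ifelse(valid, config$reward_valid_undesirable,
                config$reward_invalid))
}

#' Sample a batch of episodes from a generator
#'
#' Rollouts follow the sampling rules exactly (start token, temperature
#' softmax, stop at the end token or the length cap); the emitted token ids
#' are the episode's actions.
#'
#' @param model An `smi_generator`.
#' @param n Number of episodes.
#' @param sampling A [sampling_config()].
#' @return List with `actions` (n x T id matrix, padded after the end token),
#'   `lengths` (actions per episode, end token included) and `smiles`.
#' @export
sample_episodes <- function(model, n, sampling = sampling_config()) {
  stopifnot(inherits(model, "smi_generator"), n >= 1L)
  withr::with_seed(sampling$seed, {
    sample_trajectories(model, n, sampling$temperature, sampling$max_length)
  })
}

#' One REINFORCE update
#'
#' Gradient ascent on the expected return: each episode contributes its
#' terminal reward times the gradient of the log-probability of its action
#' sequence, averaged over the batch. A zero-reward batch leaves the
#' parameters untouched.
#'
#' @param model An `smi_generator`.
#' @param episodes As returned by [sample_episodes()].
#' @param rewards Numeric vector, one terminal reward per episode.
#' @param learning_rate Step size.
#' @param opt_state Adam state carried between updates; `NULL` performs a
#'   plain gradient-ascent (SGD) step instead, in which the update is exactly
#'   linear in the rewards.
#' @return List with `model`, `opt_state` (unchanged `NULL` for SGD) and
#'   `mean_reward`.
#' @export
reinforce_update <- function(model, episodes, rewards, learning_rate,
                             opt_state = NULL) {
  stopifnot(inherits(model, "smi_generator"),
            length(rewards) == nrow(episodes$actions))
  bsz <- nrow(episodes$actions)
  len <- ncol(episodes$actions)
  vocab <- model$vocab
  inputs <- cbind(rep(vocab$start_id, bsz),
                  episodes$actions[, -len, drop = FALSE])
  mask <- outer(episodes$lengths, seq_len(len), ">=") * 1
  weights <- mask * (rewards / bsz)
  if (all(weights == 0)) {
    return(list(model = model, opt_state = opt_state,
                mean_reward = mean(rewards)))
  }
  bp <- gru_backprop(model$params, model$config$recurrent_layers,
                     inputs, episodes$actions, weights)
  if (any(!vapply(bp$grads, function(g) all(is.finite(g)), logical(1)))) {
    stop("REINFORCE update produced non-finite gradients", call. = FALSE)
  }
  if (is.null(opt_state)) {
    model$params <- purrr::map2(model$params, bp$grads,
                                ~.x - learning_rate * .y)
  } else {
    upd <- adam_step(model$params, bp$grads, opt_state, learning_rate)
    model$params <- upd$params
    opt_state <- upd$state
  }
  list(model = model, opt_state = opt_state, mean_reward = mean(rewards))
}

#' Bias a generator with REINFORCE
#'
#' Per epoch: sample `batch_episodes` rollouts, score them with the reward
#' table, take one policy-gradient (Adam) step, then run the same
#' `checkpoint_probe_k` best-epoch probe as the CRLV loop (strict
#' improvement keeps the earlier model on ties).
#'
#' @param g_model The trained general model to bias.
#' @param obj An `smi_objective`.
#' @param config An [rl_config()].
#' @return An `smi_biased` with a per-epoch trace (`epoch`, `mean_reward`,
#'   `probe_desirable`).
#' @export
run_reinforce <- function(g_model, obj, config) {
  stopifnot(inherits(g_model, "smi_generator"), inherits(obj, "smi_objective"),
            inherits(config, "rl_config"))
  seeds <- derive_seeds(config$seed, 2L * config$epochs + 1L)
  model <- g_model
  best_model <- g_model
  best_epoch <- 0L
  best_count <- desirable_count(g_model, obj, config$checkpoint_probe_k,
                                config$sampling, seeds[1])
  opt_state <- adam_init(g_model$params)
  baseline_value <- 0
  trace <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    ep_sampling <- sampling_config(
      temperature = config$sampling$temperature,
      max_length = config$sampling$max_length,
      n_samples = config$batch_episodes, seed = seeds[2L * epoch]
    )
    episodes <- sample_episodes(model, config$batch_episodes, ep_sampling)
    rewards <- episode_reward(episodes$smiles, obj, config)
    adv <- rewards
    if (config$baseline) {
      adv <- rewards - baseline_value
      baseline_value <- 0.9 * baseline_value + 0.1 * mean(rewards)
    }
    upd <- reinforce_update(model, episodes, adv, config$learning_rate,
                            opt_state)
    model <- upd$model
    opt_state <- upd$opt_state %||% opt_state
    probe <- desirable_count(model, obj, config$checkpoint_probe_k,
                             config$sampling, seeds[2L * epoch + 1L])
    if (probe > best_count) {
      best_count <- probe
      best_model <- model
      best_epoch <- epoch
    }
    trace[[epoch]] <- tibble::tibble(epoch = epoch,
                                     mean_reward = mean(rewards),
                                     probe_desirable = probe)
  }
  new_biased_result(model, best_model, best_epoch,
                    dplyr::bind_rows(trace), "reinforce", obj)
}
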