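# Shared fixtures, memoized so expensive objects are built once per run.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_corpus <- function() {
  memo("corpus", generate_fixture_corpus(500, seed = 7))
}

fx_ring_rich <- function() {
  memo("ring_rich", generate_fixture_corpus(300, seed = 21,
                                            template_set = "ring-rich"))
}

# small general model used by sampling, biasing and benchmark tests
fx_model <- function() {
  memo("model", {
    cfg <- gen_config(embedding_dim = 32, recurrent_layers = 1,
                      hidden_units = 64, epochs = 30, batch_size = 50,
                      seed = 1)
    train_general_model(fx_corpus(), cfg)
  })
}

fx_untrained <- function() {
  memo("untrained", {
    cfg <- gen_config(embedding_dim = 32, recurrent_layers = 1,
                      hidden_units = 64, seed = 5)
    init_generator(fx_corpus()$vocab, cfg)
  })
}

obj_no_aromatic <- function() {
  objective("no_aromatic", function(d) d$aromatic_rings == 0L,
            "no aromatic ring")
}

obj_never <- function() {
  objective("never", function(d) rep(FALSE, nrow(d)), "rejects everything")
}

# string-level predicates that skip the validity requirement; used to pin
# down the loss-scale limit behaviour without chemistry in the loop
obj_always_stringlevel <- function() {
  objective("always", function(d) rep(TRUE, nrow(d)), "accepts everything",
            requires_validity = FALSE)
}

# desirable + unique counts of a 500-sample draw from a model
eval_counts <- function(model, obj, seed) {
  smp <- sample_smiles(model, sampling_config(n_samples = 500L, seed = seed))
  can <- canonical_smiles(smp)
  list(
    desirable = sum(satisfies_objective(smp, obj)),
    unique = length(unique(stats::na.omit(can)))
  )
}

# The comparative biasing experiment: small G biased toward "no aromatic
# ring" with both methods for 50 epochs, repeated over three seeds. Shared by
# the acceptance suite and the property tests.
fx_bias_runs <- function() {
  memo("bias_runs", {
    g <- fx_model()
    corp <- fx_corpus()
    obj <- obj_no_aromatic()
    probe_sampling <- sampling_config(temperature = 0.5, n_samples = 20L,
                                      seed = 1)
    lapply(c(101L, 202L, 303L), function(s) {
      cr <- run_crlv(g, corp, obj,
                     crlv_config(epochs = 50L, seed = s,
                                 sampling = probe_sampling))
      rl <- run_reinforce(g, obj,
                          rl_config(epochs = 50L, batch_episodes = 32L,
                                    learning_rate = 2e-3, seed = s,
                                    sampling = probe_sampling))
      eval_seed <- s + 7L
      list(
        seed = s,
        crlv = cr,
        rl = rl,
        g_eval = eval_counts(g, obj, eval_seed),
        crlv_best_eval = eval_counts(cr$best_model, obj, eval_seed),
        crlv_final_eval = eval_counts(cr$final_model, obj, eval_seed),
        rl_best_eval = eval_counts(rl$best_model, obj, eval_seed),
        rl_final_eval = eval_counts(rl$final_model, obj, eval_seed)
      )
    })
  })
}

# adversarial generated list: valid, malformed and duplicated strings mixed
fx_adversarial <- function(n = 1000L) {
  valid_pool <- c("CCO", "c1ccccc1", "CC(=O)O", "CCN", "C1CCCCC1", "CCOC",
                  "Nc1cccc2ncccc12", "CC(C)O", "C=CC", "COc1ccccc1")
  invalid_pool <- c("C(", "c1ccc", "CC)O", "C1CC", "X$Z", "((", "=O=", "9CC")
  withr::with_seed(42, {
    sample(c(
      sample(valid_pool, ceiling(n * 0.6), replace = TRUE),
      sample(invalid_pool, floor(n * 0.4), replace = TRUE)
    ))
  })
}
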