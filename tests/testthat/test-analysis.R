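# Cross-model analysis tools

test_that("intersection percentage spans identical, disjoint and canonical-equal sets", {
  same <- intersection_percentage(c("CCO", "CCN"), c("OCC", "NCC"))
  expect_equal(same$pct_overlap, 100)
  expect_equal(same$n_overlap, 2L)

  disjoint <- intersection_percentage(c("CCO"), c("CCN"))
  expect_equal(disjoint$pct_overlap, 0)

  partial <- intersection_percentage(c("CCO", "CCN"), c("OCC", "CCC"))
  expect_equal(partial$n_overlap, 1L)

  expect_error(intersection_percentage(character(), "CCO"), "empty")
  expect_error(intersection_percentage(c("C("), "CCO"), "empty")
})

test_that("intersection is symmetric under the smaller-set convention", {
  a <- c("CCO", "CCN", "CCC", "CCCC")
  b <- c("OCC", "c1ccccc1")
  ab <- intersection_percentage(a, b)
  ba <- intersection_percentage(b, a)
  expect_equal(ab$n_overlap, ba$n_overlap)
  expect_equal(ab$pct_overlap, ba$pct_overlap)
})

test_that("property distributions preserve order and reject unknown names", {
  expect_equal(property_distribution(c("CCO"), "hbd"), 1)
  expect_equal(property_distribution(character(), "logp"), numeric())
  expect_equal(property_distribution(c("CC"), "sv"), 0.01)
  d <- property_distribution(c("CCO", "CCCCCCCC", "CCO"), "mol_weight")
  expect_equal(d[1], d[3])
  expect_gt(d[2], d[1])
  expect_error(property_distribution("CCO", "qed"), "logp")
})

test_that("the fingerprint matrix is aligned with its input", {
  m <- fingerprint_matrix(c("CCO", "CCO", "c1ccccc1"))
  expect_equal(dim(m), c(3L, 1024L))
  expect_identical(m[1, ], m[2, ])
  expect_false(identical(m[1, ], m[3, ]))
  expect_true(all(m %in% c(0L, 1L)))
  expect_error(fingerprint_matrix(c("CCO", "C(")), "C\\(")
})

test_that("fingerprint CSV export keeps rows aligned with molecules", {
  path <- withr::local_tempfile(fileext = ".csv")
  m <- write_fingerprints(c("CCO", "CCN"), path, n_bits = 64)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back$smiles, c("CCO", "CCN"))
  expect_equal(unname(as.matrix(back[, -1])), unname(m))
})

test_that("difficulty profiles report frequency and the SV distribution", {
  corp <- fx_corpus()
  always <- obj_always_stringlevel()
  prof <- difficulty_profile(corp, always)
  expect_equal(prof$corpus_frequency, 1)
  expect_length(prof$sv_values, nrow(corp$records))

  expect_warning(none <- difficulty_profile(corp, obj_never()),
                 "no corpus molecule")
  expect_equal(none$corpus_frequency, 0)
  expect_length(none$sv_values, 0L)
  expect_true(is.na(glance(none)$sv_mean))
})

test_that("a planted high-SV subpopulation surfaces in its objective's profile", {
  plain <- c("CCCC", "CCCCC", "CCOCC", "CCCN", "CCCCCC")
  fancy <- c("CC(=O)Oc1ccccc1C(=O)O", "N[C@H](C)C(=O)O",
             "CC(=O)NC1=CC=C(O)C=C1", "O=S(=O)(O)c1ccccc1")
  corp <- corpus_from_smiles(c(plain, fancy))
  fancy_only <- objective("fancy", function(d) grepl("=", d$smiles),
                          requires_validity = FALSE)
  prof <- difficulty_profile(corp, fancy_only)
  expect_equal(prof$corpus_frequency, length(fancy) / (length(plain) + length(fancy)))
  expect_gt(prof$sv_mean, mean(structural_variance(corp$records$raw)))
  td <- tidy(prof)
  expect_equal(nrow(td), length(fancy))
})

test_that("biasing shifts the optimized property's distribution (sign test)", {
  runs <- fx_bias_runs()
  r <- runs[[1]]
  g_smiles <- sample_smiles(fx_model(),
                            sampling_config(n_samples = 300, seed = 55))
  b_smiles <- sample_smiles(r$crlv$best_model,
                            sampling_config(n_samples = 300, seed = 55))
  # share of all generated molecules that land in the target region of the
  # optimized descriptor (valid with zero aromatic rings)
  frac_hit <- function(s) {
    v <- s[is_valid_smiles(s)]
    sum(property_distribution(v, "aromatic_rings") == 0) / length(s)
  }
  expect_gt(frac_hit(b_smiles), frac_hit(g_smiles))
})

test_that("RL learns a low-SV target faster than an equally frequent high-SV target", {
  # two planted string populations with matched corpus frequency but very
  # different alphabet sizes; epochs-to-threshold on the probe counts is the
  # difficulty readout
  low_pop <- c("CCCC", "CCCCC", "CCCCCC", "CCCCCCC", "CCCCCCCC", "CCCCCCCCC")
  high_pop <- c("NC(=O)CO", "CC(=O)NC", "NCC(=O)O", "CNC(=O)C", "NC(=O)CC",
                "CC(=O)NCC")
  filler <- c("CCO", "CCOC", "c1ccccc1", "CC=CC", "C1CCCC1", "OCCO", "CCOCC",
              "COC", "CCCO", "CCNC", "CCCN", "NCCN")
  corp <- corpus_from_smiles(c(rep(low_pop, 4), rep(high_pop, 4),
                               rep(filler, 2)))
  expect_gt(mean(structural_variance(high_pop)),
            mean(structural_variance(low_pop)))
  cfg <- gen_config(embedding_dim = 24, recurrent_layers = 1,
                    hidden_units = 48, epochs = 40, batch_size = 24, seed = 2)
  g <- train_general_model(corp, cfg)
  only_c <- objective("only_c", function(d) grepl("^C{4,}$", d$smiles),
                      requires_validity = FALSE)
  amide <- objective("amide",
                     function(d) grepl("\\(=O\\)", d$smiles) &
                       grepl("N", d$smiles),
                     requires_validity = FALSE)
  epochs_to <- function(obj, threshold = 15L, seeds = c(5L, 6L, 7L)) {
    vapply(seeds, function(s) {
      res <- run_reinforce(g, obj, rl_config(
        epochs = 30L, batch_episodes = 24L, learning_rate = 3e-3, seed = s,
        sampling = sampling_config(n_samples = 20, seed = 1)
      ))
      hit <- which(res$trace$probe_desirable >= threshold)
      if (length(hit)) hit[1] else 31L
    }, numeric(1))
  }
  easy <- epochs_to(only_c)
  hard <- epochs_to(amide)
  expect_gte(sum(easy <= hard), 2L)  # majority of seeds
})
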