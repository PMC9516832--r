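# The evaluation funnel and benchmarks

test_that("validity filter separates parsable from malformed strings", {
  res <- validity_filter(c("CCO", "C(", "c1ccccc1"))
  expect_equal(res$fraction, 2 / 3)
  expect_equal(res$molecules, c("CCO", "c1ccccc1"))
  expect_warning(empty <- validity_filter(character()), "empty")
  expect_equal(empty$fraction, 0)
  corp <- fx_corpus()
  expect_equal(validity_filter(corp$records$raw)$fraction, 1)
})

test_that("novelty is decided on canonical forms", {
  corp <- corpus_from_smiles(c("CCO", "CCN"))
  expect_equal(novelty_filter(c("CCO", "CCN"), corp)$fraction, 0)
  expect_equal(novelty_filter(c("CCC", "CCCC"), corp)$fraction, 1)
  # OCC is ethanol written backwards: same canonical form, not novel
  res <- novelty_filter(c("OCC", "CCC"), corp)
  expect_equal(res$fraction, 0.5)
  expect_equal(res$molecules, canonical_smiles("CCC"))
})

test_that("uniqueness deduplicates by canonical form, keeping first seen", {
  res <- uniqueness_filter(c("CCO", "CCO", "CCN"))
  expect_equal(res$fraction, 2 / 3)
  expect_equal(res$molecules, c("CCO", "CCN"))
  expect_equal(uniqueness_filter(c("CCO", "CCN"))$fraction, 1)
  # the resulting SET is permutation-invariant
  a <- uniqueness_filter(c("CCO", "OCC", "CCN"))$molecules
  b <- uniqueness_filter(c("CCN", "CCO", "OCC"))$molecules
  expect_setequal(canonical_smiles(a), canonical_smiles(b))
})

test_that("internal diversity is 0 for degenerate sets and matches a double loop", {
  expect_equal(internal_diversity(rep("CCO", 5)), 0)
  expect_equal(internal_diversity("c1ccccc1"), 0)

  mols <- fx_corpus()$records$raw[1:20]
  fast <- internal_diversity(mols)
  # O(n^2) oracle: explicit pairwise Tanimoto from the raw bit sets
  bits <- smigen:::morgan_bits(mols)
  n <- length(bits)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      inter <- length(intersect(bits[[i]], bits[[j]]))
      uni <- length(union(bits[[i]], bits[[j]]))
      acc <- acc + if (uni > 0) inter / uni else 1
    }
  }
  expect_equal(fast, 1 - acc / n^2, tolerance = 1e-12)
})

test_that("pairwise Tanimoto from the bit matrix matches the toolkit's own", {
  pair <- c("CCO", "c1ccccc1O")
  m <- fingerprint_matrix(pair)
  inter <- sum(m[1, ] & m[2, ])
  uni <- sum(m[1, ] | m[2, ])
  expect_equal(inter / uni, smigen:::chem_tanimoto(pair[1], pair[2]),
               tolerance = 1e-12)
})

test_that("desirability reports both fraction and count", {
  expect_equal(desirability(c("CCO", "CCN"), obj_never()),
               list(fraction = 0, count = 0L, molecules = character()))
  # 150 unique strings, 15 passing: 10% but count 15
  first15 <- objective("first15",
                       function(d) grepl("^m0(0[1-9]|1[0-5])$", d$smiles),
                       requires_validity = FALSE)
  mols <- sprintf("m%03d", 1:150)
  res <- desirability(mols, first15)
  expect_equal(res$fraction, 0.10)
  expect_equal(res$count, 15L)
  # recount oracle on a fixture list
  hits <- satisfies_objective(mols, first15)
  expect_equal(res$count, sum(hits))
})

test_that("funnel counts are monotone and fractions match recounts", {
  generated <- fx_adversarial(400)
  corp <- fx_corpus()
  fun <- run_funnel(generated, corp, obj_no_aromatic())
  n <- vapply(list(fun$generated, fun$valid, fun$novel, fun$unique,
                   fun$desirable), length, integer(1))
  expect_true(all(diff(n) <= 0))
  expect_equal(fun$summary$validity, n[2] / n[1])
  expect_equal(fun$summary$novelty, n[3] / max(n[2], 1))
  expect_equal(fun$summary$uniqueness, n[4] / max(n[3], 1))
  expect_equal(fun$summary$desirability_pct, n[5] / max(n[4], 1))
  expect_equal(fun$summary$desirability_count, n[5])
})

test_that("percentages can rank models opposite to counts", {
  # model A: 5 unique, all desirable; model B: 150 unique, 15 desirable.
  # A wins on percentage, B wins on count — the report carries both.
  pass_all <- objective("all", function(d) rep(TRUE, nrow(d)),
                        requires_validity = FALSE)
  pass_15 <- objective("some",
                       function(d) seq_len(nrow(d)) <= 15,
                       requires_validity = FALSE)
  a <- desirability(sprintf("a%03d", 1:5), pass_all)
  b <- desirability(sprintf("b%03d", 1:150), pass_15)
  expect_gt(a$fraction, b$fraction)
  expect_lt(a$count, b$count)
})

test_that("benchmarks are reproducible and summarized across seeds", {
  m <- fx_model()
  corp <- fx_corpus()
  b1 <- run_benchmark(m, corp, obj_no_aromatic(), n = 150, seeds = c(1, 2))
  b2 <- run_benchmark(m, corp, obj_no_aromatic(), n = 150, seeds = c(1, 2))
  expect_identical(tibble::as_tibble(b1), tibble::as_tibble(b2))
  expect_equal(nrow(b1), 2L)
  g <- glance(b1)
  expect_equal(g$n_repeats, 2L)
  expect_equal(g$validity_mean, mean(b1$validity))
  expect_error(run_benchmark(m, corp, n = 0), "n >= 1")
})

test_that("benchmark reports round-trip through CSV and JSON", {
  m <- fx_model()
  b <- run_benchmark(m, fx_corpus(), obj_no_aromatic(), n = 100, seeds = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_benchmark(b, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$validity, b$validity)
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$runs$desirability_count, b$desirability_count)
})

test_that("a single-temperature sweep equals the plain benchmark", {
  m <- fx_model()
  corp <- fx_corpus()
  sweep <- temperature_sweep(m, corp, temps = 1.0, n = 100, seeds = 3)
  bench <- run_benchmark(m, corp, n = 100, temperature = 1.0, seeds = 3)
  expect_equal(sweep$validity, bench$validity)
  expect_equal(sweep$uniqueness, bench$uniqueness)
  expect_error(temperature_sweep(m, corp, temps = c(1, -1)), "temps > 0")
})
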