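# Evaluation funnel: validity -> novelty -> uniqueness -> intDiv -> desirability

#' Validity filter
#'
#' A generated string is valid iff RDKit parses and fully sanitizes it.
#'
#' @param generated Character vector of generated strings.
#' @return List with `fraction` (|valid| / |generated|; 0 with a warning for
#'   empty input), `molecules` (the valid strings as generated) and
#'   `canonical` (their canonical forms).
#' @export
validity_filter <- function(generated) {
  if (length(generated) == 0L) {
    warning("validity_filter: empty input")
    return(list(fraction = 0, molecules = character(),
                canonical = character()))
  }
  parsed <- smiles_parse(generated)
  list(
    fraction = mean(parsed$valid),
    molecules = generated[parsed$valid],
    canonical = parsed$canonical[parsed$valid]
  )
}

#' Novelty filter
#'
#' A valid molecule is novel iff its canonical form does not occur among the
#' canonical forms of the training corpus.
#'
#' @param valid Character vector of valid SMILES.
#' @param training An `smi_corpus`, or a character vector of training SMILES.
#' @return List with `fraction` (relative to `|valid|`) and `molecules`
#'   (canonical forms of the novel molecules).
#' @export
novelty_filter <- function(valid, training) {
  train_canonical <- if (inherits(training, "smi_corpus")) {
    training$records$canonical[training$records$valid]
  } else {
    canonical_smiles(training)
  }
  if (length(valid) == 0L) {
    return(list(fraction = 0, molecules = character()))
  }
  canonical <- canonical_smiles(valid)
  novel <- !(canonical %in% stats::na.omit(train_canonical))
  list(fraction = mean(novel), molecules = canonical[novel])
}

#' Uniqueness filter
#'
#' Deduplicates by canonical form, keeping first occurrences.
#'
#' @param novel Character vector of (canonical or raw) valid SMILES.
#' @return List with `fraction` (|unique| / |novel|) and `molecules`.
#' @export
uniqueness_filter <- function(novel) {
  if (length(novel) == 0L) {
    return(list(fraction = 0, molecules = character()))
  }
  canonical <- canonical_smiles(novel)
  keep <- !duplicated(canonical)
  list(fraction = mean(keep), molecules = novel[keep])
}

#' Internal diversity of a molecule set
#'
#' One minus the mean pairwise Tanimoto similarity of Morgan fingerprints
#' (radius 2, 1024 bits by default), averaged over the full |S| x |S| matrix
#' including the diagonal — which makes a singleton set (and a set of copies
#' of one molecule) score exactly 0.
#'
#' @param unique_set Character vector of valid SMILES (at least one).
#' @param radius,n_bits Fingerprint parameters.
#' @return Scalar in \[0, 1\].
#' @export
internal_diversity <- function(unique_set, radius = 2, n_bits = 1024) {
  if (length(unique_set) == 0L) {
    stop("internal_diversity is undefined for an empty set", call. = FALSE)
  }
  m <- fingerprint_matrix(unique_set, radius = radius, n_bits = n_bits)
  inter <- tcrossprod(m)
  counts <- rowSums(m)
  union_ <- outer(counts, counts, "+") - inter
  sim <- ifelse(union_ > 0, inter / union_, 1)
  1 - mean(sim)
}

#' Desirability of a unique molecule set
#'
#' Reported both as a fraction of the unique set and as the integer count —
#' the count is the quantity that matters when funnel attrition differs
#' between models, because a high percentage of a tiny unique set is fewer
#' molecules than a modest percentage of a large one.
#'
#' @param unique_set Character vector of valid, novel, unique SMILES.
#' @param obj An `smi_objective`.
#' @return List with `fraction`, `count` and `molecules`.
#' @export
desirability <- function(unique_set, obj) {
  if (length(unique_set) == 0L) {
    return(list(fraction = 0, count = 0L, molecules = character()))
  }
  hit <- satisfies_objective(unique_set, obj)
  list(fraction = mean(hit), count = sum(hit), molecules = unique_set[hit])
}

#' Run the full evaluation funnel on a generated set
#'
#' Applies validity, novelty, uniqueness, internal diversity and (optionally)
#' desirability in order. Each stage's fraction is relative to the previous
#' stage's survivors.
#'
#' @param generated Character vector of generated strings.
#' @param training Training corpus (for novelty); `NULL` skips novelty
#'   (stage passes everything through).
#' @param obj Optional `smi_objective` for the desirability stage.
#' @param radius,n_bits Fingerprint parameters for internal diversity.
#' @return An `smi_funnel`: list with per-stage sets and a `summary` tibble
#'   (`n_generated`, `validity`, `novelty`, `uniqueness`, `int_div`,
#'   `desirability_pct`, `desirability_count`). Fractions are in \[0, 1\].
#' @export
run_funnel <- function(generated, training = NULL, obj = NULL,
                       radius = 2, n_bits = 1024) {
  val <- suppressWarnings(validity_filter(generated))
  if (!is.null(training)) {
    nov <- novelty_filter(val$molecules, training)
  } else {
    nov <- list(fraction = if (length(val$molecules)) 1 else 0,
                molecules = val$canonical)
  }
  uni <- uniqueness_filter(nov$molecules)
  int_div <- if (length(uni$molecules) > 0L) {
    internal_diversity(uni$molecules, radius = radius, n_bits = n_bits)
  } else {
    NA_real_
  }
  des <- if (!is.null(obj)) {
    desirability(uni$molecules, obj)
  } else {
    list(fraction = NA_real_, count = NA_integer_, molecules = character())
  }
  structure(list(
    generated = generated,
    valid = val$molecules,
    novel = nov$molecules,
    unique = uni$molecules,
    desirable = des$molecules,
    summary = tibble::tibble(
      n_generated = length(generated),
      validity = val$fraction,
      novelty = nov$fraction,
      uniqueness = uni$fraction,
      int_div = int_div,
      desirability_pct = des$fraction,
      desirability_count = des$count
    )
  ), class = "smi_funnel")
}

#' @export
print.smi_funnel <- function(x, ...) {
  s <- x$summary
  cat("<smi_funnel> ", s$n_generated, " generated -> ", length(x$valid),
      " valid -> ", length(x$novel), " novel -> ", length(x$unique),
      " unique", sep = "")
  if (!is.na(s$desirability_count)) {
    cat(" -> ", s$desirability_count, " desirable", sep = "")
  }
  cat("\n")
  print(s)
  invisible(x)
}

#' @export
glance.smi_funnel <- function(x, ...) x$summary

#' Benchmark a generator against the funnel
#'
#' Samples `n` molecules per repeat, runs the funnel, and reports per-seed
#' rows plus mean/sd across repeats. `n = 10000` matches the full-scale
#' protocol; the desk-scale default is 1000.
#'
#' @param model An `smi_generator`.
#' @param training Training corpus for the novelty stage.
#' @param obj Optional `smi_objective`.
#' @param n Molecules sampled per repeat.
#' @param temperature Sampling temperature.
#' @param seeds Integer vector, one seed per repeat.
#' @param max_length Sampling length cap.
#' @param radius,n_bits Fingerprint parameters.
#' @return An `smi_benchmark`: tibble of per-seed funnel summaries with
#'   attribute `summary` (mean and sd per metric); access via [glance()].
#' @export
run_benchmark <- function(model, training, obj = NULL, n = 1000L,
                          temperature = 0.5, seeds = 1L, max_length = 100L,
                          radius = 2, n_bits = 1024) {
  stopifnot(n >= 1L, length(seeds) >= 1L)
  rows <- purrr::map_dfr(seeds, function(s) {
    smp <- sample_smiles(model, sampling_config(
      temperature = temperature, max_length = max_length,
      n_samples = n, seed = s
    ))
    fun <- run_funnel(smp, training, obj, radius = radius, n_bits = n_bits)
    dplyr::mutate(fun$summary, seed = s, temperature = temperature,
                  objective = if (is.null(obj)) NA_character_ else obj$name,
                  .before = 1L)
  })
  class(rows) <- c("smi_benchmark", class(rows))
  rows
}

#' @export
glance.smi_benchmark <- function(x, ...) {
  metrics <- c("validity", "novelty", "uniqueness", "int_div",
               "desirability_pct", "desirability_count")
  dplyr::summarise(
    tibble::as_tibble(x),
    objective = x$objective[1],
    temperature = x$temperature[1],
    n_repeats = dplyr::n(),
    dplyr::across(dplyr::all_of(metrics),
                  list(mean = ~mean(.x), sd = ~stats::sd(.x)))
  )
}

#' Write a benchmark report as CSV and JSON
#'
#' Emits the Tables-style schema: objective, validity, novelty, uniqueness,
#' intDiv, desirability_pct, desirability_count (per seed, plus a summary row
#' in the JSON).
#'
#' @param benchmark An `smi_benchmark`.
#' @param path_csv,path_json Output paths (`NULL` to skip either).
#' @return Invisibly, the benchmark.
#' @export
write_benchmark <- function(benchmark, path_csv = NULL, path_json = NULL) {
  stopifnot(inherits(benchmark, "smi_benchmark"))
  if (!is.null(path_csv)) {
    utils::write.csv(tibble::as_tibble(benchmark), path_csv,
                     row.names = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(runs = tibble::as_tibble(benchmark), summary = glance(benchmark)),
      path_json, auto_unbox = TRUE, dataframe = "rows", pretty = TRUE,
      na = "null"
    )
  }
  invisible(benchmark)
}

#' Sweep the sampling temperature
#'
#' One benchmark per temperature, identical seed list across rows so the
#' temperatures are comparable.
#'
#' @param model An `smi_generator`.
#' @param training Training corpus.
#' @param temps Numeric vector of temperatures (> 0).
#' @param n Molecules per run.
#' @param seeds Seed vector shared by all temperatures.
#' @param obj Optional objective.
#' @param max_length Sampling length cap.
#' @return An `smi_sweep` tibble: per-temperature, per-seed funnel rows.
#' @export
temperature_sweep <- function(model, training, temps = c(0.2, 0.5, 1.0),
                              n = 1000L, seeds = 1L, obj = NULL,
                              max_length = 100L) {
  stopifnot(all(temps > 0))
  rows <- purrr::map_dfr(temps, function(tt) {
    run_benchmark(model, training, obj = obj, n = n, temperature = tt,
                  seeds = seeds, max_length = max_length)
  })
  class(rows) <- c("smi_sweep", setdiff(class(rows), "smi_benchmark"))
  rows
}
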