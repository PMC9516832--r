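# Cross-model analysis: intersection, distributions, fingerprints, difficulty

#' Intersection between two generated molecule sets
#'
#' Canonicalizes and deduplicates each side, then counts canonical-form
#' overlap. The headline percentage divides the overlap by the smaller
#' deduplicated set; both set sizes and the raw overlap are always reported
#' so any other convention can be recovered.
#'
#' @param set_a,set_b Character vectors of valid SMILES.
#' @return A one-row tibble (class `smi_intersection`): `set_a_size`,
#'   `set_b_size`, `n_overlap`, `pct_overlap` (percent of the smaller set).
#' @export
intersection_percentage <- function(set_a, set_b) {
  a <- unique(stats::na.omit(canonical_smiles(set_a)))
  b <- unique(stats::na.omit(canonical_smiles(set_b)))
  if (length(a) == 0L || length(b) == 0L) {
    stop("intersection_percentage: a set is empty after canonical ",
         "deduplication", call. = FALSE)
  }
  n_overlap <- length(intersect(a, b))
  out <- tibble::tibble(
    set_a_size = length(a), set_b_size = length(b), n_overlap = n_overlap,
    pct_overlap = 100 * n_overlap / min(length(a), length(b))
  )
  class(out) <- c("smi_intersection", class(out))
  out
}

#' Extract a descriptor distribution from a molecule list
#'
#' One value per molecule, order preserving — the raw material for property
#' shift plots comparing an unbiased and a biased generator.
#'
#' @param molecules Character vector of valid SMILES.
#' @param descriptor A [compute_descriptors()] column name or `"sv"`.
#' @return Numeric vector along `molecules`.
#' @export
property_distribution <- function(molecules, descriptor) {
  valid_names <- c("logp", "mol_weight", "hba", "hbd", "rot_bonds",
                   "aromatic_rings", "non_aromatic_rings", "heavy_atoms",
                   "r_value", "sv")
  if (!descriptor %in% valid_names) {
    stop("unknown descriptor '", descriptor, "'; choose one of: ",
         paste(valid_names, collapse = ", "), call. = FALSE)
  }
  if (length(molecules) == 0L) return(numeric())
  if (descriptor == "sv") return(structural_variance(molecules))
  as.numeric(compute_descriptors(molecules)[[descriptor]])
}

#' Morgan fingerprint matrix
#'
#' @param molecules Character vector of valid SMILES (an invalid one is an
#'   error naming it).
#' @param radius,n_bits Fingerprint parameters (defaults: radius 2,
#'   1024 bits).
#' @return Binary integer matrix, `length(molecules)` rows by `n_bits`
#'   columns, row order matching the input.
#' @export
fingerprint_matrix <- function(molecules, radius = 2, n_bits = 1024) {
  bits <- morgan_bits(molecules, radius = radius, n_bits = n_bits)
  m <- matrix(0L, length(molecules), n_bits)
  for (i in seq_along(bits)) m[i, bits[[i]]] <- 1L
  m
}

#' Write a fingerprint matrix as CSV
#'
#' Tidy export for external projection tools (e.g. a UMAP embedding): one row
#' per molecule, `smiles` column followed by the bit columns.
#'
#' @inheritParams fingerprint_matrix
#' @param path Output CSV path.
#' @return Invisibly, the matrix.
#' @export
write_fingerprints <- function(molecules, path, radius = 2, n_bits = 1024) {
  m <- fingerprint_matrix(molecules, radius = radius, n_bits = n_bits)
  df <- data.frame(smiles = molecules, m, check.names = FALSE)
  names(df) <- c("smiles", paste0("bit", seq_len(n_bits)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(m)
}

#' Difficulty profile of an objective on a corpus
#'
#' The two difficulty ingredients for biasing a generator toward an
#' objective: how often the objective is already satisfied in the reference
#' corpus, and the structural-variance distribution of the satisfying
#' molecules (rarer and higher-SV chemical spaces are harder to bias into).
#'
#' @param corpus An `smi_corpus`.
#' @param obj An `smi_objective`.
#' @return An `smi_difficulty`: list with `objective`, `corpus_frequency`,
#'   `sv_values`, `sv_mean`, `sv_median`.
#' @export
difficulty_profile <- function(corpus, obj) {
  stopifnot(inherits(corpus, "smi_corpus"), inherits(obj, "smi_objective"))
  smiles <- corpus$records$raw
  hit <- satisfies_objective(smiles, obj)
  freq <- mean(hit)
  sv_values <- if (any(hit)) structural_variance(smiles[hit]) else numeric()
  if (!any(hit)) {
    warning("no corpus molecule satisfies objective '", obj$name,
            "'; SV distribution is empty")
  }
  structure(list(
    objective = obj$name,
    corpus_frequency = freq,
    sv_values = sv_values,
    sv_mean = if (length(sv_values)) mean(sv_values) else NA_real_,
    sv_median = if (length(sv_values)) stats::median(sv_values) else NA_real_
  ), class = "smi_difficulty")
}

#' @export
print.smi_difficulty <- function(x, ...) {
  cat("<smi_difficulty> objective ", x$objective, ": corpus frequency ",
      signif(x$corpus_frequency, 3), ", mean SV ",
      signif(x$sv_mean, 3), " over ", length(x$sv_values),
      " satisfying molecule(s)\n", sep = "")
  invisible(x)
}

#' @export
tidy.smi_difficulty <- function(x, ...) {
  tibble::tibble(objective = x$objective, sv = x$sv_values)
}

#' @export
glance.smi_difficulty <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, corpus_frequency = x$corpus_frequency,
    n_satisfying = length(x$sv_values), sv_mean = x$sv_mean,
    sv_median = x$sv_median
  )
}

#' Write a JSON provenance record for a run
#'
#' @param path Output path.
#' @param config Any list-like configuration to embed.
#' @param seeds Integer seeds used.
#' @return Invisibly, the record.
#' @export
write_provenance <- function(path, config = list(), seeds = integer()) {
  rec <- list(
    package = "smigen",
    version = as.character(utils::packageVersion("smigen")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seeds = seeds,
    config = config
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(rec)
}
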