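# Objectives: descriptors, desirability predicates, structural variance ------

#' Functional-group SMARTS patterns
#'
#' The substructure definitions behind the functional-group flags: hydroxyl
#' on carbon, ester, carboxylic acid, primary amine (amides excluded). Amend
#' via `options(smigen.fg_patterns = ...)` if your medicinal-chemistry
#' conventions differ.
#'
#' @return Named list of SMARTS strings.
#' @export
fg_patterns <- function() {
  getOption("smigen.fg_patterns", list(
    fg_oh = "[OX2H][#6]",
    fg_ester = "[#6]C(=O)O[#6]",
    fg_cooh = "C(=O)[OX2H1]",
    fg_nh2 = "[NX3;H2;!$(NC=O)]"
  ))
}

# shipped placeholder for the R-value descriptor slot: rotatable bonds per
# heavy atom. The original R-value definition is literature-specific; swap in
# your own via the r_value argument of compute_descriptors().
r_value_placeholder <- function(d) d$rot_bonds / d$heavy_atoms

#' Compute molecular descriptors for SMILES
#'
#' RDKit-standard implementations throughout: Crippen logP, molecular weight,
#' Lipinski H-bond acceptor/donor counts, topological rotatable bonds, SSSR
#' ring perception split into aromatic (all ring atoms aromatic) and
#' non-aromatic rings, and functional-group substructure flags
#' (see [fg_patterns()]). The `r_value` column is a pluggable slot; the
#' shipped default is a placeholder (rotatable bonds / heavy atoms).
#'
#' @param smiles Character vector; every element must be valid (pre-filter
#'   with [validity_filter()] otherwise).
#' @param r_value Function of the descriptor tibble returning the `r_value`
#'   column.
#' @return A tibble with one row per molecule: `smiles`, `canonical`, `logp`,
#'   `mol_weight`, `hba`, `hbd`, `rot_bonds`, `aromatic_rings`,
#'   `non_aromatic_rings`, `heavy_atoms`, the four `fg_*` logical flags,
#'   `r_value` and `sv` (structural variance).
#' @export
compute_descriptors <- function(smiles, r_value = r_value_placeholder) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) {
    return(tibble::tibble(
      smiles = character(), canonical = character(), logp = numeric(),
      mol_weight = numeric(), hba = integer(), hbd = integer(),
      rot_bonds = integer(), aromatic_rings = integer(),
      non_aromatic_rings = integer(), heavy_atoms = integer(),
      fg_oh = logical(), fg_ester = logical(), fg_cooh = logical(),
      fg_nh2 = logical(), r_value = numeric(), sv = numeric()
    ))
  }
  resp <- chem_request("descriptors",
                       list(smiles = I(smiles), patterns = fg_patterns()))
  if (!all(resp$valid)) {
    bad <- smiles[!resp$valid]
    stop("compute_descriptors: invalid SMILES (pre-filter with ",
         "validity_filter): ", paste(utils::head(bad, 5L), collapse = ", "),
         if (length(bad) > 5L) " ..." else "", call. = FALSE)
  }
  d <- tibble::tibble(
    smiles = smiles,
    canonical = as.character(resp$canonical),
    logp = as.numeric(resp$logp),
    mol_weight = as.numeric(resp$mol_weight),
    hba = as.integer(resp$hba),
    hbd = as.integer(resp$hbd),
    rot_bonds = as.integer(resp$rot_bonds),
    aromatic_rings = as.integer(resp$aromatic_rings),
    non_aromatic_rings = as.integer(resp$non_aromatic_rings),
    heavy_atoms = as.integer(resp$heavy_atoms),
    fg_oh = as.logical(resp$fg_oh),
    fg_ester = as.logical(resp$fg_ester),
    fg_cooh = as.logical(resp$fg_cooh),
    fg_nh2 = as.logical(resp$fg_nh2)
  )
  d$r_value <- r_value(d)
  d$sv <- structural_variance(smiles)
  d
}

#' The built-in desirability predicates
#'
#' Boolean predicates over a descriptor tibble (as returned by
#' [compute_descriptors()]), vectorized over rows; all boundary comparisons
#' are inclusive.
#'
#' * `objective_1`: lipophilicity filter, `logp <= 3`.
#' * `objective_2`: structural filter — exactly 2 aromatic and 1 non-aromatic
#'   ring, at least one of the four functional groups, and `r_value` within
#'   `r_bounds` (clause skipped when `use_r_value = FALSE`).
#' * `objective_3`: the full rule of three — `logp <= 3`,
#'   `mol_weight <= 480`, `hba <= 3`, `hbd <= 3`, `rot_bonds <= 3`.
#' * `objective_4`: objectives 2 and 3 simultaneously.
#' * `objective_5`: objective 2 with *all four* functional groups required.
#'
#' @param d Descriptor tibble.
#' @param r_bounds Closed interval for the `r_value` clause of objectives
#'   2, 4 and 5.
#' @param use_r_value Evaluate the `r_value` clause? Disable when the
#'   placeholder descriptor is not meaningful for your corpus.
#' @return Logical vector, one element per row of `d`.
#' @export
objective_1 <- function(d) d$logp <= 3

#' @rdname objective_1
#' @export
objective_2 <- function(d, r_bounds = c(0.05, 0.50), use_r_value = TRUE) {
  ok <- d$aromatic_rings == 2L & d$non_aromatic_rings == 1L &
    (d$fg_oh | d$fg_ester | d$fg_cooh | d$fg_nh2)
  if (use_r_value) {
    ok <- ok & d$r_value >= r_bounds[1] & d$r_value <= r_bounds[2]
  }
  ok
}

#' @rdname objective_1
#' @export
objective_3 <- function(d) {
  d$logp <= 3 & d$mol_weight <= 480 & d$hba <= 3L & d$hbd <= 3L &
    d$rot_bonds <= 3L
}

#' @rdname objective_1
#' @export
objective_4 <- function(d, r_bounds = c(0.05, 0.50), use_r_value = TRUE) {
  objective_2(d, r_bounds, use_r_value) & objective_3(d)
}

#' @rdname objective_1
#' @export
objective_5 <- function(d, r_bounds = c(0.05, 0.50), use_r_value = TRUE) {
  ok <- d$aromatic_rings == 2L & d$non_aromatic_rings == 1L &
    d$fg_oh & d$fg_ester & d$fg_cooh & d$fg_nh2
  if (use_r_value) {
    ok <- ok & d$r_value >= r_bounds[1] & d$r_value <= r_bounds[2]
  }
  ok
}

#' Define a named objective
#'
#' An objective couples a pure predicate over descriptor tibbles with a name
#' and description; the biasing and benchmarking machinery consumes these.
#'
#' @param name Identifier.
#' @param predicate Function: descriptor tibble -> logical vector.
#' @param description Free-text description.
#' @param requires_validity Should invalid molecules always count as
#'   undesirable (the default, matching the evaluation funnel)? Setting
#'   `FALSE` is only useful for algorithmic edge-case testing with
#'   string-level predicates.
#' @return An `smi_objective`.
#' @export
objective <- function(name, predicate, description = name,
                      requires_validity = TRUE) {
  stopifnot(is.character(name), is.function(predicate))
  structure(
    list(name = name, predicate = predicate, description = description,
         requires_validity = requires_validity),
    class = "smi_objective"
  )
}

#' @export
print.smi_objective <- function(x, ...) {
  cat("<smi_objective> ", x$name, ": ", x$description, "\n", sep = "")
  invisible(x)
}

#' Fetch one of the five built-in objectives
#'
#' @param name `"obj1"` ... `"obj5"`.
#' @inheritParams objective_1
#' @return An `smi_objective`.
#' @export
builtin_objective <- function(name = c("obj1", "obj2", "obj3", "obj4", "obj5"),
                              r_bounds = c(0.05, 0.50), use_r_value = TRUE) {
  name <- match.arg(name)
  fns <- list(
    obj1 = function(d) objective_1(d),
    obj2 = function(d) objective_2(d, r_bounds, use_r_value),
    obj3 = function(d) objective_3(d),
    obj4 = function(d) objective_4(d, r_bounds, use_r_value),
    obj5 = function(d) objective_5(d, r_bounds, use_r_value)
  )
  desc <- c(
    obj1 = "logP <= 3",
    obj2 = "2 aromatic + 1 non-aromatic ring, >=1 functional group, R-value in bounds",
    obj3 = "rule of three (logP, MW, HBA, HBD, rotatable bonds)",
    obj4 = "objectives 2 and 3 simultaneously",
    obj5 = "objective 2 with all four functional groups required"
  )
  objective(name, fns[[name]], unname(desc[name]))
}

#' Load an objective from a YAML clause list
#'
#' The YAML document holds `name`, optional `description`, and `clauses`: a
#' list of entries with `descriptor`, `op`
#' (`le`, `ge`, `lt`, `gt`, `eq`, `between`, `any_flag`, `all_flags`) and
#' `value` (a bound, an exact value, a length-2 interval, or for the flag ops
#' a list of flag column names).
#'
#' @param path YAML file, or a pre-parsed list.
#' @return An `smi_objective`.
#' @export
objective_from_yaml <- function(path) {
  spec_list <- if (is.character(path)) yaml::read_yaml(path) else path
  stopifnot(!is.null(spec_list$name), length(spec_list$clauses) > 0L)
  clauses <- spec_list$clauses
  predicate <- function(d) {
    ok <- rep(TRUE, nrow(d))
    for (cl in clauses) {
      op <- cl$op
      if (op %in% c("any_flag", "all_flags")) {
        flags <- as.data.frame(d[, unlist(cl$value), drop = FALSE])
        hit <- if (op == "any_flag") rowSums(flags) >= 1L
               else rowSums(flags) == length(cl$value)
        ok <- ok & hit
        next
      }
      x <- d[[cl$descriptor]]
      if (is.null(x)) stop("unknown descriptor in clause: ", cl$descriptor)
      ok <- ok & switch(op,
        le = x <= cl$value,
        ge = x >= cl$value,
        lt = x < cl$value,
        gt = x > cl$value,
        eq = x == cl$value,
        between = x >= cl$value[[1]] & x <= cl$value[[2]],
        stop("unknown clause op: ", op)
      )
    }
    ok
  }
  objective(spec_list$name, predicate,
            spec_list$description %||% spec_list$name)
}

#' Which molecules satisfy an objective?
#'
#' Computes descriptors for the valid molecules and evaluates the objective's
#' predicate; invalid SMILES are `FALSE` whenever the objective requires
#' validity (the default).
#'
#' @param smiles Character vector.
#' @param obj An `smi_objective`.
#' @return Logical vector along `smiles`.
#' @export
satisfies_objective <- function(smiles, obj) {
  stopifnot(inherits(obj, "smi_objective"))
  if (length(smiles) == 0L) return(logical())
  if (!obj$requires_validity) {
    # string-level predicate: hand the raw strings over as a minimal tibble
    return(as.logical(obj$predicate(tibble::tibble(smiles = smiles))))
  }
  valid <- is_valid_smiles(smiles)
  out <- rep(FALSE, length(smiles))
  if (any(valid)) {
    d <- compute_descriptors(smiles[valid])
    out[valid] <- as.logical(obj$predicate(d))
  }
  out
}

# Structural variance ---------------------------------------------------------

#' Structural variance of SMILES strings
#'
#' The number of distinct characters in the (whitespace-stripped) SMILES
#' divided by a global maximum length, by default 100 — a fixed reference
#' that makes values comparable across molecules. Conventionally reported to
#' two decimals; the raw value is returned.
#'
#' @param smiles Character vector; empty strings are an error.
#' @param global_max_length Denominator (default 100).
#' @return Numeric vector of raw SV values.
#' @examples
#' \dontrun{
#' structural_variance("Nc1cccc2ncccc12")  # 5 distinct characters -> 0.05
#' }
#' @export
structural_variance <- function(smiles, global_max_length = 100L) {
  stopifnot(is.character(smiles), global_max_length >= 1L)
  s <- gsub("\\s+", "", smiles)
  if (any(!nzchar(s))) {
    stop("structural_variance: empty SMILES string", call. = FALSE)
  }
  n_unique <- vapply(strsplit(s, "", fixed = TRUE),
                     function(ch) length(unique(ch)), integer(1))
  n_unique / global_max_length
}

#' Per-length structural variance (non-canonical diagnostic)
#'
#' Distinct-character count divided by the molecule's own SMILES length
#' instead of the global maximum. Provided for diagnostics only: dividing by
#' the molecule's own length removes the common reference that makes SV
#' values comparable between molecules, so this variant should not be used
#' for difficulty ranking.
#'
#' @inheritParams structural_variance
#' @return Numeric vector.
#' @export
structural_variance_per_length <- function(smiles) {
  stopifnot(is.character(smiles))
  s <- gsub("\\s+", "", smiles)
  if (any(!nzchar(s))) {
    stop("structural_variance_per_length: empty SMILES string", call. = FALSE)
  }
  n_unique <- vapply(strsplit(s, "", fixed = TRUE),
                     function(ch) length(unique(ch)), integer(1))
  n_unique / nchar(s)
}

#' Write a descriptor dump CSV
#'
#' One row per molecule with canonical form, all descriptor fields and SV.
#'
#' @param smiles Character vector of valid SMILES.
#' @param path Output CSV path.
#' @return Invisibly, the descriptor tibble.
#' @export
write_descriptor_dump <- function(smiles, path) {
  d <- compute_descriptors(smiles)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(d)
}
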