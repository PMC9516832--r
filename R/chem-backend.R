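#' @keywords internal
"_PACKAGE"

# Chemistry backend -----------------------------------------------------------
#
# All molecule handling (strict SMILES validity, canonicalization, descriptors,
# SMARTS matching, Morgan fingerprints) is delegated to RDKit through a small
# Python bridge shipped in inst/python/rdkit_bridge.py. The bridge normally
# runs as a persistent worker connected over a pair of FIFOs so that repeated
# small queries (e.g. per-epoch desirability probes during biasing) cost
# microseconds, not an interpreter start-up; if the worker cannot be started
# the backend falls back to one-shot batch calls. Results are cached per
# SMILES within the session.

.chem <- new.env(parent = emptyenv())
.chem$worker <- NULL
.chem$worker_failed <- FALSE
.chem$next_id <- 1L
.chem$available <- NULL
.chem$cache_parse <- new.env(parent = emptyenv())
.chem$cache_desc <- new.env(parent = emptyenv())
.chem$cache_fp <- new.env(parent = emptyenv())

chem_python <- function() getOption("smigen.python", "python")

chem_bridge_path <- function() {
  path <- system.file("python", "rdkit_bridge.py", package = "smigen")
  if (!nzchar(path)) stop("rdkit_bridge.py not found in the smigen installation")
  path
}

#' Is the RDKit chemistry backend available?
#'
#' Checks (once per session) that a `python` interpreter with the `rdkit`
#' package can be started. The interpreter is taken from
#' `getOption("smigen.python")`, default `"python"`.
#'
#' @return `TRUE` or `FALSE`.
#' @export
chem_available <- function() {
  if (is.null(.chem$available)) {
    status <- suppressWarnings(tryCatch(
      system2(chem_python(), c("-c", shQuote("import rdkit")),
              stdout = FALSE, stderr = FALSE),
      error = function(e) 127L
    ))
    .chem$available <- identical(status, 0L)
  }
  .chem$available
}

chem_assert_available <- function() {
  if (!chem_available()) {
    stop("the RDKit chemistry backend is unavailable: `", chem_python(),
         "` cannot import rdkit", call. = FALSE)
  }
}

chem_worker_start <- function() {
  if (!is.null(.chem$worker) || .chem$worker_failed) return(invisible(NULL))
  chem_assert_available()
  ok <- tryCatch({
    dir <- tempfile("smigen-chem-")
    dir.create(dir)
    fin <- file.path(dir, "in.fifo")
    fout <- file.path(dir, "out.fifo")
    if (system2("mkfifo", c(fin, fout), stdout = FALSE, stderr = FALSE) != 0L) {
      stop("mkfifo failed")
    }
    system(paste0(
      shQuote(chem_python()), " ", shQuote(chem_bridge_path()),
      " serve < ", shQuote(fin), " > ", shQuote(fout), " 2> /dev/null"
    ), wait = FALSE)
    wcon <- fifo(fin, "w", blocking = TRUE)
    rcon <- fifo(fout, "r", blocking = TRUE)
    .chem$worker <- list(wcon = wcon, rcon = rcon, dir = dir)
    # handshake proves the interpreter is up before any real request
    writeLines(jsonlite::toJSON(list(id = 0L, task = "ping"),
                                auto_unbox = TRUE), wcon)
    flush(wcon)
    resp <- readLines(rcon, n = 1L)
    length(resp) == 1L && isTRUE(jsonlite::fromJSON(resp)$ok)
  }, error = function(e) FALSE)
  if (!ok) {
    chem_worker_stop()
    .chem$worker_failed <- TRUE
  }
  invisible(NULL)
}

chem_worker_stop <- function() {
  w <- .chem$worker
  if (!is.null(w)) {
    tryCatch({
      writeLines('{"task": "quit"}', w$wcon)
      flush(w$wcon)
    }, error = function(e) NULL)
    tryCatch(close(w$wcon), error = function(e) NULL)
    tryCatch(close(w$rcon), error = function(e) NULL)
    unlink(w$dir, recursive = TRUE)
  }
  .chem$worker <- NULL
  invisible(NULL)
}

.onUnload <- function(libpath) {
  chem_worker_stop()
}

# Send one request to the bridge; list payload in, parsed JSON out.
chem_request <- function(task, payload = list(), simplify = TRUE) {
  chem_assert_available()
  chem_worker_start()
  payload$task <- task
  payload$id <- .chem$next_id
  .chem$next_id <- .chem$next_id + 1L
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null")
  if (!is.null(.chem$worker)) {
    w <- .chem$worker
    writeLines(json, w$wcon)
    flush(w$wcon)
    line <- readLines(w$rcon, n = 1L)
    if (length(line) != 1L) {
      chem_worker_stop()
      .chem$worker_failed <- TRUE
      stop("chemistry worker died mid-request; rerun the call", call. = FALSE)
    }
    resp <- jsonlite::fromJSON(line, simplifyVector = simplify)
  } else {
    fin <- tempfile(fileext = ".json")
    fout <- tempfile(fileext = ".json")
    on.exit(unlink(c(fin, fout)))
    writeLines(json, fin)
    status <- system2(chem_python(), c(chem_bridge_path(), "batch", fin, fout),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L || !file.exists(fout)) {
      stop("one-shot chemistry call failed (exit status ", status, ")",
           call. = FALSE)
    }
    resp <- jsonlite::fromJSON(readLines(fout, warn = FALSE),
                               simplifyVector = simplify)
  }
  if (!is.null(resp$error)) stop("chemistry backend: ", resp$error, call. = FALSE)
  resp
}

#' Clear the per-session chemistry cache
#'
#' @return Invisibly, `NULL`.
#' @export
chem_cache_clear <- function() {
  .chem$cache_parse <- new.env(parent = emptyenv())
  .chem$cache_desc <- new.env(parent = emptyenv())
  .chem$cache_fp <- new.env(parent = emptyenv())
  invisible(NULL)
}

# look up `keys` in cache env; returns list(hit = logical, values = list)
cache_get <- function(cache, keys) {
  hit <- vapply(keys, function(k) !is.null(cache[[k]]), logical(1),
                USE.NAMES = FALSE)
  list(hit = hit, values = lapply(keys, function(k) cache[[k]]))
}

#' Parse SMILES strings with RDKit
#'
#' Strict parse + sanitize. A string is valid only if RDKit builds a sane
#' molecule from it; the canonical form is RDKit's canonical SMILES.
#'
#' @param smiles Character vector of SMILES strings.
#' @return A tibble with columns `smiles`, `valid` (logical) and `canonical`
#'   (character, `NA` for invalid strings).
#' @examples
#' \dontrun{
#' smiles_parse(c("CCO", "C(", "OCC"))
#' }
#' @export
smiles_parse <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) {
    return(tibble::tibble(smiles = character(), valid = logical(),
                          canonical = character()))
  }
  keys <- paste0("s:", smiles)
  cached <- cache_get(.chem$cache_parse, keys)
  todo <- unique(smiles[!cached$hit])
  if (length(todo) > 0L) {
    resp <- chem_request("parse", list(smiles = I(todo)))
    canonical <- as.character(resp$canonical)
    canonical[!resp$valid] <- NA_character_
    for (i in seq_along(todo)) {
      .chem$cache_parse[[paste0("s:", todo[i])]] <-
        list(valid = resp$valid[i], canonical = canonical[i])
    }
  }
  rec <- lapply(keys, function(k) .chem$cache_parse[[k]])
  tibble::tibble(
    smiles = smiles,
    valid = vapply(rec, `[[`, logical(1), "valid"),
    canonical = vapply(rec, `[[`, character(1), "canonical")
  )
}

#' @rdname smiles_parse
#' @export
is_valid_smiles <- function(smiles) smiles_parse(smiles)$valid

#' @rdname smiles_parse
#' @export
canonical_smiles <- function(smiles) smiles_parse(smiles)$canonical

#' Morgan fingerprints as on-bit index lists
#'
#' @param smiles Character vector of valid SMILES.
#' @param radius Circular fingerprint radius in bonds (default 2).
#' @param n_bits Folded fingerprint length (default 1024).
#' @return A list, one integer vector of 1-based on-bit indices per molecule.
#'   Invalid SMILES raise an error naming the offender.
#' @export
morgan_bits <- function(smiles, radius = 2, n_bits = 1024) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0L) return(list())
  keys <- paste0("r", radius, "b", n_bits, "|", smiles)
  cached <- cache_get(.chem$cache_fp, keys)
  if (any(!cached$hit)) {
    todo_idx <- !duplicated(keys) & !cached$hit
    todo <- smiles[todo_idx]
    resp <- chem_request("fingerprint",
                         list(smiles = I(todo), radius = radius, n_bits = n_bits),
                         simplify = FALSE)
    bits <- resp$bits
    for (i in seq_along(todo)) {
      if (is.null(bits[[i]])) {
        stop("invalid SMILES cannot be fingerprinted: ", todo[i], call. = FALSE)
      }
      .chem$cache_fp[[keys[todo_idx][i]]] <-
        as.integer(unlist(bits[[i]])) + 1L  # 0-based bit ids -> 1-based
    }
  }
  lapply(keys, function(k) .chem$cache_fp[[k]])
}

# RDKit's own Tanimoto similarity between two molecules; used in tests as an
# oracle independent of the R-side fingerprint matrix arithmetic.
chem_tanimoto <- function(a, b, radius = 2, n_bits = 1024) {
  resp <- chem_request("tanimoto",
                       list(a = a, b = b, radius = radius, n_bits = n_bits))
  as.numeric(resp$sim)
}
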