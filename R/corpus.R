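# Corpus: SMILES I/O, filtering, character tokenization, vocabulary ----------

PAD_TOKEN <- "<pad>"
START_TOKEN <- "<s>"
END_TOKEN <- "</s>"

#' Build a character vocabulary from SMILES strings
#'
#' Tokenization is strictly per character: two-letter element symbols such as
#' Cl or Br become two tokens. Three reserved special tokens (padding,
#' sequence start, sequence end) are prepended; they are multi-character names
#' and can therefore never collide with a SMILES character.
#'
#' @param smiles Character vector the alphabet is derived from.
#' @return An object of class `smi_vocab`: a list with `tokens` (character
#'   vector indexed by id), `token_to_id` (named integer vector), `pad_id`,
#'   `start_id`, `end_id` and `size_k` (total number of classes, specials
#'   included).
#' @export
build_vocabulary <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  chars <- sort(unique(unlist(strsplit(smiles, "", fixed = TRUE))))
  tokens <- c(PAD_TOKEN, START_TOKEN, END_TOKEN, chars)
  token_to_id <- stats::setNames(seq_along(tokens), tokens)
  structure(
    list(
      tokens = tokens,
      token_to_id = token_to_id,
      pad_id = 1L, start_id = 2L, end_id = 3L,
      size_k = length(tokens)
    ),
    class = "smi_vocab"
  )
}

#' @export
print.smi_vocab <- function(x, ...) {
  cat("<smi_vocab> ", x$size_k, " tokens (3 specials + ",
      x$size_k - 3L, " characters)\n", sep = "")
  cat("  alphabet: ", paste(x$tokens[-(1:3)], collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Encode a SMILES string as token ids
#'
#' Produces `start_id`, one id per character in order, then `end_id`.
#'
#' @param smiles A single SMILES string.
#' @param vocab An `smi_vocab`.
#' @return Integer vector of length `nchar(smiles) + 2`.
#' @export
tokenize <- function(smiles, vocab) {
  stopifnot(inherits(vocab, "smi_vocab"), is.character(smiles),
            length(smiles) == 1L)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  ids <- unname(vocab$token_to_id[chars])
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1]
    stop("unknown character '", chars[bad], "' at position ", bad,
         " of SMILES '", smiles, "'", call. = FALSE)
  }
  c(vocab$start_id, ids, vocab$end_id)
}

#' Decode token ids back to a SMILES string
#'
#' The sequence is truncated at the first end-of-sequence id (the sampling
#' stop rule); padding and start ids are dropped.
#'
#' @param ids Integer vector of token ids.
#' @param vocab An `smi_vocab`.
#' @return A single character string.
#' @export
detokenize <- function(ids, vocab) {
  stopifnot(inherits(vocab, "smi_vocab"))
  ids <- as.integer(ids)
  if (length(ids) > 0L && (anyNA(ids) || any(ids < 1L | ids > vocab$size_k))) {
    stop("token id outside the vocabulary range [1, ", vocab$size_k, "]",
         call. = FALSE)
  }
  stop_at <- match(vocab$end_id, ids)
  if (!is.na(stop_at)) ids <- ids[seq_len(stop_at - 1L)]
  ids <- ids[ids != vocab$pad_id & ids != vocab$start_id]
  paste(vocab$tokens[ids], collapse = "")
}

new_corpus <- function(records, vocab, max_length, n_dropped) {
  structure(
    list(records = records, vocab = vocab, max_length = max_length,
         n_dropped = n_dropped),
    class = "smi_corpus"
  )
}

#' Build a corpus from in-memory SMILES
#'
#' Whitespace is stripped, strings longer than `max_length` characters are
#' dropped, duplicates are retained (deduplication is an evaluation concern,
#' not an ingestion one), and every surviving string is canonicalized with
#' RDKit. The vocabulary is derived from the surviving strings.
#'
#' @param smiles Character vector of SMILES.
#' @param max_length Maximum SMILES character length retained (default 100).
#' @return An `smi_corpus`: `records` (tibble with `raw`, `canonical`,
#'   `valid`, `length`), `vocab`, `max_length`, `n_dropped`.
#' @export
corpus_from_smiles <- function(smiles, max_length = 100L) {
  stopifnot(is.character(smiles), max_length >= 1L)
  raw <- gsub("\\s+", "", smiles)
  raw <- raw[nzchar(raw)]
  keep <- nchar(raw) <= max_length
  n_dropped <- sum(!keep)
  raw <- raw[keep]
  if (length(raw) == 0L) {
    stop("empty corpus: no SMILES survive the length filter", call. = FALSE)
  }
  parsed <- smiles_parse(raw)
  records <- tibble::tibble(
    raw = raw,
    canonical = parsed$canonical,
    valid = parsed$valid,
    length = nchar(raw)
  )
  new_corpus(records, build_vocabulary(raw), as.integer(max_length), n_dropped)
}

#' Load a corpus from a one-SMILES-per-line file
#'
#' Accepts plain `.smi` files; an optional tab-separated molecule id column is
#' ignored. See [corpus_from_smiles()] for the filtering rules.
#'
#' @param path Path to the text file.
#' @inheritParams corpus_from_smiles
#' @return An `smi_corpus`.
#' @export
load_corpus <- function(path, max_length = 100L) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  smiles <- vapply(strsplit(lines, "\t", fixed = TRUE),
                   function(x) if (length(x) > 0L) x[[1]] else "",
                   character(1))
  corpus <- corpus_from_smiles(smiles, max_length = max_length)
  if (corpus$n_dropped > 0L) {
    message("load_corpus: dropped ", corpus$n_dropped,
            " record(s) longer than ", max_length, " characters")
  }
  corpus
}

#' @export
print.smi_corpus <- function(x, ...) {
  cat("<smi_corpus> ", nrow(x$records), " records (", x$n_dropped,
      " dropped by length filter at ", x$max_length, ")\n", sep = "")
  cat("  vocabulary: ", x$vocab$size_k, " classes\n", sep = "")
  invisible(x)
}

#' Write a corpus manifest as JSON
#'
#' @param corpus An `smi_corpus`.
#' @param path Output file.
#' @return Invisibly, the manifest list.
#' @export
write_corpus_manifest <- function(corpus, path) {
  stopifnot(inherits(corpus, "smi_corpus"))
  manifest <- list(
    n_loaded = nrow(corpus$records),
    n_dropped = corpus$n_dropped,
    max_length = corpus$max_length,
    vocabulary = corpus$vocab$tokens
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Synthetic fixture corpus ----------------------------------------------------

# random integer in [lo, hi] using the current RNG stream
rint <- function(lo, hi) sample.int(hi - lo + 1L, 1L) + lo - 1L

# a short aliphatic chain; O/N are inserted away from each other so every
# template is valid by construction
rand_chain <- function(min_len = 1L, max_len = 6L) {
  len <- rint(min_len, max_len)
  atoms <- rep("C", len)
  if (len >= 3L && stats::runif(1) < 0.5) {
    atoms[rint(2L, len - 1L)] <- sample(c("O", "N"), 1L)
  }
  if (len >= 2L && all(atoms == "C") && stats::runif(1) < 0.3) {
    # one double bond inside an all-carbon chain
    pos <- rint(1L, len - 1L)
    return(paste0(paste(atoms[1:pos], collapse = ""), "=",
                  paste(atoms[(pos + 1L):len], collapse = "")))
  }
  paste(atoms, collapse = "")
}

rand_branched <- function() {
  stem <- rand_chain(2L, 5L)
  branch <- rand_chain(1L, 3L)
  paste0(substr(stem, 1L, 1L), "(", branch, ")",
         substr(stem, 2L, nchar(stem)))
}

rand_ring <- function() {
  core <- sample(c("c1ccccc1", "C1CCCCC1", "C1CCCC1", "c1ccncc1"), 1L,
                 prob = c(0.4, 0.25, 0.15, 0.2))
  if (stats::runif(1) < 0.6) {
    sub <- sample(c(rand_chain(1L, 4L), "O", "N", "CO", "CN"), 1L)
    if (core == "c1ccccc1") {
      core <- paste0("c1ccc(", sub, ")cc1")
    } else if (core == "C1CCCCC1") {
      core <- paste0("C1CCCCC1", sub)
    } else {
      core <- paste0(core, sub)
    }
  }
  core
}

#' Generate a synthetic SMILES fixture corpus
#'
#' Emits chemically valid SMILES assembled from parametric templates (linear
#' chains, branches, double bonds, benzene/pyridine and aliphatic rings, O/N
#' substitutions). A stand-in for a real training set at desk scale:
#' deterministic for a fixed seed, 100% valid by construction, but far
#' narrower chemically than any screening library.
#'
#' @param n Number of SMILES to generate.
#' @param seed Integer RNG seed.
#' @param template_set `"simple"` (mostly acyclic, ~25% rings) or
#'   `"ring-rich"` (~70% of strings contain a ring).
#' @param max_length Length filter forwarded to [corpus_from_smiles()].
#' @return An `smi_corpus` of `n` records.
#' @export
generate_fixture_corpus <- function(n, seed,
                                    template_set = c("simple", "ring-rich"),
                                    max_length = 100L) {
  stopifnot(n >= 1L)
  template_set <- match.arg(template_set)
  p_ring <- if (template_set == "ring-rich") 0.7 else 0.25
  smiles <- withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      u <- stats::runif(1)
      if (u < p_ring) {
        rand_ring()
      } else if (u < p_ring + 0.3) {
        rand_branched()
      } else {
        rand_chain(2L, 8L)
      }
    }, character(1))
  })
  corpus_from_smiles(smiles, max_length = max_length)
}
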