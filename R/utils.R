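# Round half away from zero. base::round() rounds half to even, which does
# not match how the percentage and score tables handled here are printed.
round_half_away <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Validate a vector of sequences against the canonical 20-letter alphabet.
# Reports the first offending character and its 1-based position.
check_protein_alphabet <- function(sequences, ids = NULL) {
  ids <- ids %||% as.character(seq_along(sequences))
  for (i in seq_along(sequences)) {
    s <- sequences[[i]]
    if (is.na(s) || !nzchar(s)) {
      abort(paste0("record '", ids[[i]], "': empty sequence"),
            class = "tp_validation")
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% AA_ALPHABET)
    if (length(bad) > 0L) {
      abort(paste0(
        "record '", ids[[i]], "': illegal residue '", chars[bad[1]],
        "' at position ", bad[1],
        " (only the 20 canonical one-letter codes are allowed)"
      ), class = "tp_validation")
    }
  }
  invisible(sequences)
}

# Run code with a locally-seeded RNG, leaving the caller's random state
# untouched. All synthetic-data generators go through this.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("seed must be a single number", class = "tp_validation")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
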