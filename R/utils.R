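# Internal helpers shared across modules.

ALPHABETS <- list(
  nucleotide = c("A", "C", "G", "T"),
  protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream-specific child seed from a master seed, kept inside the
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 7919 + stream * 104729) %% 2147483647
}

random_sequence <- function(n, alphabet = "nucleotide") {
  paste(sample(ALPHABETS[[alphabet]], n, replace = TRUE), collapse = "")
}

assert_count <- function(x, field, min = 0) {
  if (length(x) != 1 || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", field, min),
          class = "panstrep_validation_error")
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, field, max_exclusive = FALSE) {
  bad <- length(x) != 1 || is.na(x) || x < 0 ||
    (if (max_exclusive) x >= 1 else x > 1)
  if (bad) {
    abort(sprintf("`%s` must be in [0, 1%s", field,
                  if (max_exclusive) ")" else "]"),
          class = "panstrep_validation_error")
  }
  invisible(as.numeric(x))
}

assert_alphabet <- function(x) {
  if (!is.character(x) || length(x) != 1 || !x %in% names(ALPHABETS)) {
    abort("`alphabet` must be one of \"nucleotide\", \"protein\"",
          class = "panstrep_validation_error")
  }
  x
}

# Coerce sequence input (character scalar, XString, length-1 XStringSet)
# to an upper-case character scalar.
as_seq_chr <- function(x) {
  if (inherits(x, "XString") || inherits(x, "XStringSet")) {
    x <- as.character(x)
  }
  if (!is.character(x) || length(x) != 1) {
    abort("expected a single sequence (character scalar or Biostrings object)")
  }
  toupper(x)
}

seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1), k:n))
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
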