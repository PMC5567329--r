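#' Alignment scoring scheme
#'
#' Bundles the substitution scoring and affine gap penalties used by
#' [align_pair()] and the pan-genome accretion loop. Defaults follow common
#' BLAST-like conventions: match/mismatch +2/-3 for nucleotide sequences and
#' BLOSUM62 for proteins, with affine gap penalties.
#'
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param match,mismatch Match reward and mismatch penalty (nucleotide only;
#'   `mismatch` is given as a negative score).
#' @param matrix Name of a built-in protein substitution matrix
#'   (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Non-negative affine gap penalties. A gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @return An object of class `scoring_scheme`.
#' @examples
#' scoring_scheme("nucleotide")
#' scoring_scheme("protein", matrix = "BLOSUM62")
#' @export
scoring_scheme <- function(alphabet = c("nucleotide", "protein"),
                           match = 2, mismatch = -3,
                           matrix = "BLOSUM62",
                           gap_open = 5, gap_extend = 2) {
  alphabet <- match.arg(alphabet)
  if (gap_open < 0 || gap_extend < 0) {
    abort("gap penalties must be >= 0", class = "panstrep_validation_error")
  }
  submat <- if (alphabet == "nucleotide") {
    Biostrings::nucleotideSubstitutionMatrix(match = match,
                                             mismatch = mismatch,
                                             baseOnly = TRUE)
  } else {
    get(data(list = matrix, package = "Biostrings", envir = environment()))
  }
  structure(
    list(alphabet = alphabet, match = match, mismatch = mismatch,
         matrix = if (alphabet == "protein") matrix else NULL,
         submat = submat, gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat("<scoring_scheme> ", x$alphabet,
      if (x$alphabet == "nucleotide") {
        sprintf(" match=%g mismatch=%g", x$match, x$mismatch)
      } else {
        paste0(" matrix=", x$matrix)
      },
      sprintf(" gap_open=%g gap_extend=%g\n", x$gap_open, x$gap_extend),
      sep = "")
  invisible(x)
}

#' Homology decision thresholds
#'
#' Thresholds for the BLAST-coverage-ratio (BCR) homology rule applied by
#' [is_homologous()]. A candidate pair is rejected only when *both* coverage
#' ratios fall below `bcr_min` (the "setting value" of the accretion
#' algorithm) or when alignment identity falls below `identity_min`.
#' Alignments shorter than `min_len` residues are discarded before the rule
#' is applied.
#'
#' @param bcr_min Minimum BLAST coverage ratio, a fraction in \[0, 1\].
#' @param identity_min Minimum percent identity over aligned columns. The
#'   default depends on `alphabet`: 50 for protein, 70 for nucleotide.
#' @param min_len Minimum alignment length in residues.
#' @param alphabet Used only to pick the `identity_min` default.
#' @return An object of class `homology_thresholds`.
#' @examples
#' homology_thresholds(bcr_min = 0.5)
#' @export
homology_thresholds <- function(bcr_min = 0.5, identity_min = NULL,
                                min_len = 30,
                                alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (is.null(identity_min)) {
    identity_min <- if (alphabet == "protein") 50 else 70
  }
  assert_fraction(bcr_min, "bcr_min")
  if (identity_min < 0 || identity_min > 100) {
    abort("`identity_min` must be a percent in [0, 100]",
          class = "panstrep_validation_error")
  }
  assert_count(min_len, "min_len")
  structure(
    list(bcr_min = bcr_min, identity_min = identity_min,
         min_len = as.integer(min_len)),
    class = "homology_thresholds"
  )
}

#' @export
print.homology_thresholds <- function(x, ...) {
  cat(sprintf("<homology_thresholds> bcr_min=%g identity_min=%g min_len=%d\n",
              x$bcr_min, x$identity_min, x$min_len))
  invisible(x)
}
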