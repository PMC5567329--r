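#' Local pairwise alignment with coverage ratios
#'
#' Aligns two sequences with the Smith-Waterman algorithm (via
#' [Biostrings::pairwiseAlignment()]) and reports percent identity, the
#' aligned span on each sequence, and the two BLAST coverage ratios (BCR):
#' the fraction of each sequence's length covered by the alignment.
#'
#' Identity is counted over aligned columns, gap columns excluded (the BLAST
#' reporting convention). When several equally good local alignments exist,
#' the single best-scoring one defines the covered spans. A pair with no
#' positive-scoring local alignment yields a zero hit (score 0, coverage 0).
#'
#' @param a,b Sequences: character scalars or Biostrings objects.
#' @param scoring A [scoring_scheme()].
#' @param query_id,subject_id Identifiers echoed into the result.
#' @return A one-row tibble with columns `query_id`, `subject_id`,
#'   `identity_pct`, `aln_len_query`, `aln_len_subject`, `bcr_query`,
#'   `bcr_subject`, `score`.
#' @examples
#' align_pair("ACGTACGTACGT", "ACGTACCTACGT")
#' @export
align_pair <- function(a, b, scoring = scoring_scheme(),
                       query_id = "query", subject_id = "subject") {
  a <- as_seq_chr(a)
  b <- as_seq_chr(b)
  if (nchar(a) == 0 || nchar(b) == 0) {
    abort("sequences must be non-empty", class = "panstrep_validation_error")
  }
  check_alphabet_match(c(a, b), scoring$alphabet)
  hits <- align_to_pool(a, seq_set(b, scoring$alphabet, subject_id), scoring)
  hits$query_id <- query_id
  hits[, c("query_id", "subject_id", "identity_pct", "aln_len_query",
           "aln_len_subject", "bcr_query", "bcr_subject", "score")]
}

check_alphabet_match <- function(seqs, alphabet) {
  letters_seen <- unique(unlist(strsplit(seqs, "", fixed = TRUE)))
  if (alphabet == "nucleotide" &&
      any(!letters_seen %in% c(ALPHABETS$nucleotide, "N"))) {
    abort("sequence contains non-nucleotide letters but scoring is nucleotide",
          class = "panstrep_validation_error")
  }
  invisible(TRUE)
}

seq_set <- function(seqs, alphabet, ids = NULL) {
  set <- if (alphabet == "nucleotide") {
    Biostrings::DNAStringSet(seqs)
  } else {
    Biostrings::AAStringSet(seqs)
  }
  if (!is.null(ids)) names(set) <- ids
  set
}

# Align one query against a set of subjects in a single vectorized call.
# Returns one row per subject. Zero/negative-score alignments are reported
# as empty hits.
align_to_pool <- function(query, subjects, scoring) {
  stopifnot(length(subjects) >= 1)
  qlen <- nchar(query)
  slen <- Biostrings::width(subjects)
  pa <- Biostrings::pairwiseAlignment(
    pattern = subjects,
    subject = if (scoring$alphabet == "nucleotide") {
      Biostrings::DNAString(query)
    } else {
      Biostrings::AAString(query)
    },
    type = "local",
    substitutionMatrix = scoring$submat,
    gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend
  )
  sc <- Biostrings::score(pa)
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  cols <- nm + nmm
  # span covered on each original sequence by the best local alignment
  cov_s <- Biostrings::width(Biostrings::pattern(pa)) # on subject (pool gene)
  cov_q <- Biostrings::width(Biostrings::subject(pa)) # on query
  empty <- sc <= 0
  out <- tibble(
    subject_id = names(subjects) %||% as.character(seq_along(subjects)),
    identity_pct = ifelse(empty | cols == 0, 0, 100 * nm / cols),
    aln_columns = ifelse(empty, 0L, as.integer(cols)),
    aln_len_query = ifelse(empty, 0L, as.integer(cov_q)),
    aln_len_subject = ifelse(empty, 0L, as.integer(cov_s)),
    score = ifelse(empty, 0, sc)
  )
  out$bcr_query <- out$aln_len_query / qlen
  out$bcr_subject <- out$aln_len_subject / slen
  out
}

#' BLAST coverage ratios
#'
#' The two coverage ratios of an alignment: the aligned span on the query
#' divided by the query length, and likewise for the subject. These are
#' computed separately for the two sides of a hit and drive the homology
#' decision rule of the pan-genome accretion algorithm.
#'
#' @param aln_len_query,aln_len_subject Aligned span on each sequence.
#' @param query_len,subject_len Full sequence lengths (must be positive).
#' @return A named numeric vector `c(bcr_query =, bcr_subject =)`.
#' @examples
#' compute_bcr(60, 100, 60, 120)
#' @export
compute_bcr <- function(aln_len_query, query_len, aln_len_subject, subject_len) {
  if (query_len <= 0 || subject_len <= 0) {
    abort("sequence lengths must be positive", class = "panstrep_validation_error")
  }
  if (aln_len_query < 0 || aln_len_query > query_len ||
      aln_len_subject < 0 || aln_len_subject > subject_len) {
    abort("aligned spans must lie in [0, length] on each side",
          class = "panstrep_validation_error")
  }
  c(bcr_query = aln_len_query / query_len,
    bcr_subject = aln_len_subject / subject_len)
}

#' BCR homology decision rule
#'
#' Applies the coverage-ratio rule of the gene-pool accretion algorithm: a
#' hit fails only when *both* BCR values are below `bcr_min`, or when
#' identity is below `identity_min`. One side covering well is enough to
#' call homology, so a short gene fully contained in a longer one still
#' matches.
#'
#' @param hit A data frame (one or more rows) with columns `bcr_query`,
#'   `bcr_subject` and `identity_pct`, e.g. from [align_pair()].
#' @param th A [homology_thresholds()].
#' @return Logical vector, one element per row of `hit`.
#' @examples
#' th <- homology_thresholds(bcr_min = 0.4)
#' is_homologous(
#'   data.frame(bcr_query = 0.5, bcr_subject = 0.2, identity_pct = 80), th
#' )
#' @export
is_homologous <- function(hit, th = homology_thresholds()) {
  stopifnot(all(c("bcr_query", "bcr_subject", "identity_pct") %in% names(hit)))
  both_low <- hit$bcr_query < th$bcr_min & hit$bcr_subject < th$bcr_min
  !(both_low | hit$identity_pct < th$identity_min)
}

# ---- k-mer prefilter ---------------------------------------------------

kmer_size <- function(alphabet) if (alphabet == "protein") 4L else 9L

# Incremental k-mer index over pool representatives: an environment mapping
# each k-mer to the integer ids of clusters whose representative contains it.
kmer_index_new <- function() new.env(parent = emptyenv(), hash = TRUE)

kmer_index_add <- function(index, seq, id, k) {
  for (km in seq_kmers(seq, k)) {
    index[[km]] <- c(index[[km]], id)
  }
  invisible(index)
}

# Candidate cluster ids sharing enough distinct k-mers with `seq`.
#
# The count threshold scales with the chance-match rate between unrelated
# sequences (expected shared k-mer positions ~ Lq * Ls / |alphabet|^k), so
# long unrelated pairs are still filtered while genuinely homologous pairs
# (identity above the decision thresholds) share an order of magnitude more.
kmer_candidates <- function(index, seq, k, alphabet, rep_len) {
  kms <- seq_kmers(seq, k)
  if (length(kms) == 0) return(integer(0))
  ids <- unlist(lapply(kms, function(km) index[[km]]), use.names = FALSE)
  if (length(ids) == 0) return(integer(0))
  counts <- table(ids)
  cand <- as.integer(names(counts))
  asize <- length(ALPHABETS[[alphabet]])
  thr <- pmax(2, ceiling(2 * nchar(seq) * rep_len[cand] / asize^k))
  cand[as.integer(counts) >= thr]
}
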