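#' ANI computation parameters
#'
#' Fragment-based average nucleotide identity settings following the ANIb
#' conventions (as popularised by JSpecies): the query genome is chopped
#' into consecutive 1,020-bp fragments, each fragment is searched against
#' the subject genome on both strands, and fragments are retained when
#' their best hit reaches at least `min_identity_pct` identity over at
#' least `min_coverage` of the fragment. ANI is the mean identity of
#' retained fragments; with `reciprocal = TRUE` both directions are
#' computed and averaged.
#'
#' @param fragment_bp Fragment length (default 1020).
#' @param min_identity_pct Identity filter, percent (default 30).
#' @param min_coverage Fragment coverage filter, fraction (default 0.70).
#' @param reciprocal Average the two directions? (default `TRUE`).
#' @return An object of class `ani_params`.
#' @export
ani_params <- function(fragment_bp = 1020, min_identity_pct = 30,
                       min_coverage = 0.70, reciprocal = TRUE) {
  assert_count(fragment_bp, "fragment_bp", min = 1)
  if (min_identity_pct < 0 || min_identity_pct > 100) {
    abort("`min_identity_pct` must be in [0, 100]",
          class = "panstrep_validation_error")
  }
  assert_fraction(min_coverage, "min_coverage")
  structure(list(fragment_bp = as.integer(fragment_bp),
                 min_identity_pct = min_identity_pct,
                 min_coverage = min_coverage,
                 reciprocal = isTRUE(reciprocal)),
            class = "ani_params")
}

#' Fragment a genome into fixed-size windows
#'
#' Consecutive non-overlapping windows of `fragment_bp`; a final remainder
#' shorter than the fragment size is kept only if it is at least 100 bp.
#'
#' @param genome Genome sequence (character or Biostrings object).
#' @param fragment_bp Window size in bp.
#' @return A tibble with `fragment_id`, `start`, `end`, `sequence`.
#' @examples
#' nrow(fragment_genome(strrep("ACGT", 765), 1020)) # 3
#' @export
fragment_genome <- function(genome, fragment_bp = 1020) {
  genome <- as_seq_chr(genome)
  L <- nchar(genome)
  if (L == 0) {
    abort("genome must be non-empty", class = "panstrep_validation_error")
  }
  starts <- seq(1L, L, by = fragment_bp)
  ends <- pmin(starts + fragment_bp - 1L, L)
  keep <- (ends - starts + 1L) >= pmin(fragment_bp, 100L)
  starts <- starts[keep]
  ends <- ends[keep]
  if (length(starts) == 0) {
    return(tibble(fragment_id = character(0), start = integer(0),
                  end = integer(0), sequence = character(0)))
  }
  tibble(fragment_id = sprintf("frag%05d", seq_along(starts)),
         start = starts, end = ends,
         sequence = substring(genome, starts, ends))
}

blast_available <- function() nzchar(Sys.which("blastn"))

require_blast <- function() {
  if (!blast_available() || !nzchar(Sys.which("makeblastdb"))) {
    abort(paste0("ANI computation requires the NCBI BLAST+ command-line ",
                 "tools (blastn, makeblastdb) on the PATH"))
  }
}

# Best-hit identity and coverage of each fragment of `query` against
# `subject`, via blastn with ANIb-style settings. Both strands are searched
# (blastn default). Returns a tibble with one row per fragment that has a
# hit.
blast_fragments <- function(frags, subject, workdir) {
  qfa <- file.path(workdir, "query_frags.fasta")
  sfa <- file.path(workdir, "subject.fasta")
  Biostrings::writeXStringSet(
    setNames(Biostrings::DNAStringSet(frags$sequence), frags$fragment_id), qfa)
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(subject_genome = subject)), sfa)
  db <- file.path(workdir, "subject_db")
  out <- file.path(workdir, "hits.tsv")
  res <- system2(Sys.which("makeblastdb"),
                 c("-in", sfa, "-dbtype", "nucl", "-out", db),
                 stdout = FALSE, stderr = FALSE)
  if (res != 0) abort("makeblastdb failed")
  res <- system2(Sys.which("blastn"),
                 c("-query", qfa, "-db", db, "-out", out,
                   "-task", "blastn", "-reward", "1", "-penalty", "-1",
                   "-xdrop_gap_final", "150", "-dust", "no",
                   "-evalue", "1e-15",
                   "-outfmt", shQuote("6 qseqid pident length qlen bitscore")),
                 stdout = FALSE, stderr = FALSE)
  if (res != 0) abort("blastn failed")
  cols <- c("fragment_id", "pident", "length", "qlen", "bitscore")
  if (file.size(out) == 0) {
    return(tibble(fragment_id = character(0), pident = numeric(0),
                  length = integer(0), qlen = integer(0),
                  bitscore = numeric(0)))
  }
  hits <- utils::read.table(out, sep = "\t", col.names = cols)
  hits <- hits[order(-hits$bitscore), ]
  as_tibble(hits[!duplicated(hits$fragment_id), ])
}

ani_one_direction <- function(a, b, params) {
  frags <- fragment_genome(a, params$fragment_bp)
  workdir <- tempfile("panstrep_ani_")
  dir.create(workdir)
  on.exit(unlink(workdir, recursive = TRUE), add = TRUE)
  hits <- blast_fragments(frags, b, workdir)
  kept <- hits[hits$pident >= params$min_identity_pct &
                 hits$length / hits$qlen >= params$min_coverage, ]
  list(ani = if (nrow(kept) > 0) mean(kept$pident) else NA_real_,
       n_used = nrow(kept), n_fragments = nrow(frags))
}

#' Average nucleotide identity of a genome pair
#'
#' ANIb-style ANI: fragments of each genome are searched against the other
#' with blastn (both strands), fragments passing the identity and coverage
#' filters contribute their percent identity, and the two directional means
#' are averaged. Identical genomes (or a genome and its reverse complement)
#' score exactly 100. When no fragment passes the filters, the ANI values
#' are `NA` with zero used fragments.
#'
#' Requires the NCBI BLAST+ tools (`blastn`, `makeblastdb`) on the PATH.
#'
#' @param a,b Genome sequences (character or Biostrings objects).
#' @param params [ani_params()].
#' @param genome_a,genome_b Labels echoed into the result.
#' @return A one-row tibble of class `ani_result` with `genome_a`,
#'   `genome_b`, `ani_ab`, `ani_ba`, `ani_mean`, `n_fragments_used_ab`,
#'   `n_fragments_used_ba`, `n_fragments_ab`, `n_fragments_ba`; the
#'   parameters used are attached as attribute `params`.
#' @export
ani_pair <- function(a, b, params = ani_params(),
                     genome_a = "a", genome_b = "b") {
  require_blast()
  a <- as_seq_chr(a)
  b <- as_seq_chr(b)
  if (nchar(a) == 0 || nchar(b) == 0) {
    abort("genomes must be non-empty", class = "panstrep_validation_error")
  }
  ab <- ani_one_direction(a, b, params)
  if (params$reciprocal) {
    ba <- ani_one_direction(b, a, params)
    both <- c(ab$ani, ba$ani)
    ani_mean <- if (all(is.na(both))) NA_real_ else mean(both, na.rm = TRUE)
  } else {
    ba <- list(ani = NA_real_, n_used = NA_integer_, n_fragments = NA_integer_)
    ani_mean <- ab$ani
  }
  out <- tibble(genome_a = genome_a, genome_b = genome_b,
                ani_ab = ab$ani, ani_ba = ba$ani, ani_mean = ani_mean,
                n_fragments_used_ab = ab$n_used,
                n_fragments_used_ba = ba$n_used,
                n_fragments_ab = ab$n_fragments,
                n_fragments_ba = ba$n_fragments)
  attr(out, "params") <- params
  class(out) <- c("ani_result", class(out))
  out
}

#' Pairwise ANI matrix over a set of genomes
#'
#' Computes [ani_pair()] for every unordered pair and returns both the
#' per-pair table and the symmetric matrix of reciprocal mean ANI values
#' (diagonal 100).
#'
#' @param genomes Named character vector of genome sequences, or a named
#'   vector/list of FASTA file paths (multi-sequence files are concatenated).
#' @param params [ani_params()].
#' @return A list with `pairs` (tibble of `ani_result` rows) and `matrix`
#'   (symmetric numeric matrix, percent).
#' @export
ani_matrix <- function(genomes, params = ani_params()) {
  if (is.list(genomes)) genomes <- unlist(genomes)
  if (is.null(names(genomes)) || any(!nzchar(names(genomes)))) {
    abort("`genomes` must be named", class = "panstrep_validation_error")
  }
  if (all(file.exists(genomes))) {
    genomes <- vapply(genomes, function(f) {
      paste(as.character(Biostrings::readDNAStringSet(f)), collapse = "")
    }, character(1))
  }
  ids <- names(genomes)
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  pairs <- list()
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        r <- ani_pair(genomes[[i]], genomes[[j]], params,
                      genome_a = ids[i], genome_b = ids[j])
        pairs[[length(pairs) + 1]] <- r
        m[i, j] <- m[j, i] <- r$ani_mean
      }
    }
  }
  list(pairs = bind_rows(pairs), matrix = m)
}
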