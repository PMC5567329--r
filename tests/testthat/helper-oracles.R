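# Independent oracles used across the suite. These deliberately take a
# different computational route from the package implementation.

# Global (Needleman-Wunsch) alignment score with affine gaps, where a gap
# run of length L costs open + L * ext. Scores s(a, b) come from `submat`.
nw_global_score <- function(a, b, submat, open, ext) {
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)  # last column aligned a[i] to b[j]
  Ix <- matrix(NEG, n + 1, m + 1) # gap in b (a[i] vs -)
  Iy <- matrix(NEG, n + 1, m + 1) # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[a[i], b[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - (open + ext),
                              Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - (open + ext),
                              Iy[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Brute-force local alignment score: maximum over all substring pairs of
# the global alignment score of the substrings (the empty alignment scores
# 0). Equivalent to Smith-Waterman but computed by exhaustive enumeration.
brute_local_score <- function(a, b, scoring) {
  ac <- strsplit(toupper(a), "")[[1]]
  bc <- strsplit(toupper(b), "")[[1]]
  submat <- scoring$submat
  best <- 0
  for (i1 in seq_along(ac)) for (i2 in i1:length(ac)) {
    for (j1 in seq_along(bc)) for (j2 in j1:length(bc)) {
      sc <- nw_global_score(ac[i1:i2], bc[j1:j2], submat,
                            scoring$gap_open, scoring$gap_extend)
      if (sc > best) best <- sc
    }
  }
  best
}

# Single-linkage clustering over the full pairwise homology graph: an edge
# joins two genes when their alignment passes the thresholds; clusters are
# the connected components (union-find).
single_linkage_clusters <- function(genes, th, scoring) {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      hit <- align_pair(genes$sequence[i], genes$sequence[j], scoring)
      cols <- hit$aln_len_query # no gaps expected at these divergences
      if (hit$score > 0 &&
          (hit$aln_len_query >= th$min_len ||
             hit$aln_len_subject >= th$min_len) &&
          is_homologous(hit, th)) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  split(genes$gene_id, comp)
}

# Partition counts from a membership list (gene ids carry strainK| prefixes).
oracle_partition <- function(members, n_strains) {
  pres <- vapply(members, function(g) {
    length(unique(sub("\\|.*$", "", g)))
  }, integer(1))
  c(core = sum(pres == n_strains),
    dispensable = sum(pres > 1 & pres < n_strains),
    specific = sum(pres == 1),
    total = length(members))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Small zero/low-divergence simulation used by several tests.
tiny_sim <- function(divergence = 0, seed = 11, n_strains = 3) {
  simulate_pangenome(sim_params(
    n_strains = n_strains, n_core = 3,
    dispensable_spec = list(c(1, 2)),
    n_specific_per_strain = 2,
    gene_length_range = c(150, 400),
    divergence = divergence, seed = seed))
}

expect_partition <- function(pg, core, dispensable, specific) {
  pc <- partition_counts(pg)
  expect_equal(unlist(pc),
               c(core = core, dispensable = dispensable,
                 specific = specific,
                 total = core + dispensable + specific),
               ignore_attr = TRUE)
}
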