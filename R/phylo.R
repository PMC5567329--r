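#' Jaccard distance between gene-family profiles
#'
#' Distance between strains based on which gene families they carry:
#' `d(i, j) = 1 - |F_i intersect F_j| / |F_i union F_j|` over family
#' presence sets. This is a documented distance surrogate for gene-family
#' trees; it claims topology-level comparability only, not equivalence to
#' SNP- or alignment-based phylogenies.
#'
#' @param m A binary strains-by-families matrix (e.g. [presence_matrix()]),
#'   or a `pan_genome` object.
#' @param metric Distance metric; only `"jaccard"` is implemented.
#' @return A symmetric `dist` object labelled by strain id.
#' @examples
#' m <- rbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1))
#' profile_distance(m) # 1 - 2/4 = 0.5
#' @export
profile_distance <- function(m, metric = "jaccard") {
  metric <- match.arg(metric, "jaccard")
  if (inherits(m, "pan_genome")) m <- presence_matrix(m)
  stopifnot(is.matrix(m))
  if (nrow(m) < 2) {
    abort("need at least 2 strains", class = "panstrep_validation_error")
  }
  if (!all(m %in% c(0, 1))) {
    abort("presence matrix entries must be 0/1",
          class = "panstrep_validation_error")
  }
  if (any(rowSums(m) == 0)) {
    abort("every strain must carry at least one family",
          class = "panstrep_validation_error")
  }
  vegan::vegdist(m, method = "jaccard", binary = TRUE)
}

#' ANI-derived distance
#'
#' Transforms a (percent) ANI matrix into a distance matrix:
#' `d = (100 - ANI) / 100`.
#'
#' @param ani Symmetric numeric matrix of reciprocal mean ANI percentages
#'   (e.g. from [ani_matrix()]`$matrix`), or the list returned by
#'   [ani_matrix()].
#' @return A `dist` object.
#' @examples
#' m <- matrix(c(100, 97.4, 97.4, 100), 2, 2,
#'             dimnames = list(c("a", "b"), c("a", "b")))
#' ani_distance(m) # 0.026
#' @export
ani_distance <- function(ani) {
  if (is.list(ani) && !is.matrix(ani)) ani <- ani$matrix
  stopifnot(is.matrix(ani))
  if (any(is.na(ani))) {
    abort("ANI matrix has missing pairs", class = "panstrep_validation_error")
  }
  if (nrow(ani) != ncol(ani) || any(abs(ani - t(ani)) > 1e-8)) {
    abort("ANI matrix must be square and symmetric",
          class = "panstrep_validation_error")
  }
  stats::as.dist((100 - ani) / 100)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor joining (via [ape::nj()]) on a strain distance
#' matrix. On an additive input matrix the tree's path-length matrix
#' reproduces the input exactly. Negative branch lengths (an NJ artefact on
#' non-additive input) are clamped to zero; the tree then carries the
#' attribute `clamped = TRUE` and a warning is raised. Trees are unrooted.
#'
#' @param d A `dist` object or symmetric non-negative matrix with zero
#'   diagonal. Two-taxon input yields the single-edge tree with the
#'   distance split equally between the pendant branches.
#' @return An [ape] `phylo` object (unrooted), with attribute `clamped`.
#' @examples
#' d <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
#' diag(d) <- 0
#' neighbor_joining(d)
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d))
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    abort("distance matrix must be square and symmetric",
          class = "panstrep_validation_error")
  }
  if (any(d < 0) || any(abs(diag(d)) > 1e-12)) {
    abort("distances must be non-negative with a zero diagonal",
          class = "panstrep_validation_error")
  }
  n <- nrow(d)
  if (n < 2) {
    abort("need at least 2 taxa", class = "panstrep_validation_error")
  }
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  if (n == 2) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = rep(d[1, 2] / 2, 2),
                 tip.label = labels, Nnode = 1L)
    class(tree) <- "phylo"
    attr(tree, "order") <- "cladewise"
    attr(tree, "clamped") <- FALSE
    return(tree)
  }
  rownames(d) <- colnames(d) <- labels
  tree <- ape::nj(stats::as.dist(d))
  clamped <- any(tree$edge.length < 0)
  if (clamped) {
    warn("negative neighbor-joining branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "clamped") <- clamped
  tree
}

#' Strain tree straight from a pan-genome
#'
#' Convenience wrapper: presence/absence profiles -> Jaccard distances ->
#' neighbor joining.
#'
#' @param result A `pan_genome` object.
#' @param metric Passed to [profile_distance()].
#' @return An unrooted `phylo` tree.
#' @export
pan_genome_tree <- function(result, metric = "jaccard") {
  neighbor_joining(profile_distance(result, metric = metric))
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
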