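#' Build a pan-genome gene pool by iterative accretion
#'
#' Implements the gene-pool accretion algorithm used in bacterial
#' pan-genome studies. The first strain's genes initialise the pool as
#' singleton clusters. Each subsequent strain is processed in order; every
#' gene is aligned against the current pool and joins the best-scoring
#' cluster it is homologous to (per the BCR rule, [is_homologous()]), or
#' founds a new cluster — and thereby a new pool member — otherwise. The
#' final pool is the pan-genome; clusters are partitioned into core
#' (present in all strains), dispensable (in more than one but not all) and
#' strain-specific (exactly one).
#'
#' Pool representatives are the founding genes; joining a cluster never
#' changes its representative (the pool only grows). Ties on alignment
#' score are broken towards the lexicographically smallest founder gene id.
#' Intra-strain paralogs in *query* strains that match a pool gene join its
#' cluster, inflating member counts but not cluster counts. Paralogs within
#' the reference strain, however, each found their own singleton cluster,
#' because the pool is initialised with all reference genes unconditionally
#' (the algorithm never clusters within the reference).
#'
#' With a single strain every cluster is simultaneously core and specific;
#' such clusters are reported as specific, and core counts are only
#' meaningful for two or more strains.
#'
#' @param genes A tibble with columns `strain_id`, `gene_id`, `sequence`
#'   (one row per gene), or a `pan_sim` object from [simulate_pangenome()].
#'   Gene ids must be unique within a strain.
#' @param th [homology_thresholds()]. Alignments shorter than `min_len`
#'   are discarded before the BCR rule is applied.
#' @param scoring [scoring_scheme()].
#' @param strain_order Optional processing order (the first entry is the
#'   reference). Defaults to order of first appearance in `genes`.
#' @param search `"founders"` (default) aligns queries against cluster
#'   founders only; `"all"` against every pool member.
#' @param prefilter Use the shared k-mer prefilter to skip pairs that cannot
#'   reach the homology thresholds? (k = 9 nucleotide / 4 protein.)
#' @return An object of class `pan_genome`: a list with
#'   * `clusters`: tibble `cluster_id`, `strain_id`, `gene_id`;
#'   * `cluster_info`: tibble `cluster_id`, `founder_gene_id`, `n_members`,
#'     `n_strains_present`, `class`;
#'   * `n_strains`, `strain_order`, `thresholds`, `scoring_alphabet`,
#'     `search`, `prefilter`.
#' @examples
#' sim <- simulate_pangenome(sim_params(n_strains = 3, n_core = 4,
#'                                      n_specific_per_strain = 1,
#'                                      gene_length_range = c(60, 120),
#'                                      seed = 7))
#' pg <- build_pan_pool(sim)
#' partition_counts(pg)
#' @export
build_pan_pool <- function(genes, th = homology_thresholds(),
                           scoring = scoring_scheme(),
                           strain_order = NULL,
                           search = c("founders", "all"),
                           prefilter = TRUE) {
  search <- match.arg(search)
  if (inherits(genes, "pan_sim")) {
    if (genes$params$alphabet != scoring$alphabet) {
      scoring <- scoring_scheme(genes$params$alphabet)
      th <- homology_thresholds(bcr_min = th$bcr_min, min_len = th$min_len,
                                alphabet = genes$params$alphabet)
    }
    genes <- genes$genes
  }
  stopifnot(is.data.frame(genes),
            all(c("strain_id", "gene_id", "sequence") %in% names(genes)))
  if (nrow(genes) == 0) {
    abort("no genes supplied", class = "panstrep_validation_error")
  }
  if (anyDuplicated(genes[, c("strain_id", "gene_id")])) {
    abort("gene ids must be unique within a strain",
          class = "panstrep_validation_error")
  }
  strains_seen <- unique(genes$strain_id)
  if (is.null(strain_order)) strain_order <- strains_seen
  if (!setequal(strain_order, strains_seen) ||
      anyDuplicated(strain_order) > 0) {
    abort("`strain_order` must be a permutation of the strain ids in `genes`",
          class = "panstrep_validation_error")
  }

  k <- kmer_size(scoring$alphabet)
  reps <- character(0)        # pool sequences searched against
  rep_id <- character(0)      # their gene ids
  rep_cluster <- integer(0)   # cluster each pool sequence belongs to
  index <- kmer_index_new()
  exact <- new.env(parent = emptyenv(), hash = TRUE)

  n_clusters <- 0L
  assign_cluster <- integer(nrow(genes))
  names(assign_cluster) <- paste(genes$strain_id, genes$gene_id, sep = "\r")

  add_pool_member <- function(seq, gene_id, cluster) {
    reps[length(reps) + 1L] <<- seq
    rep_id[length(rep_id) + 1L] <<- gene_id
    rep_cluster[length(rep_cluster) + 1L] <<- cluster
    kmer_index_add(index, seq, length(reps), k)
    if (is.null(exact[[seq]])) exact[[seq]] <- cluster
  }

  row_of <- split(seq_len(nrow(genes)), genes$strain_id)
  first <- TRUE
  for (s in strain_order) {
    rows <- row_of[[s]]
    for (i in rows) {
      seq <- genes$sequence[i]
      gid <- genes$gene_id[i]
      target <- NA_integer_
      if (first) {
        # reference strain: every gene founds a singleton cluster
      } else {
        hit_cluster <- exact[[seq]]
        if (!is.null(hit_cluster) && nchar(seq) >= th$min_len) {
          # byte-identical to a pool sequence: maximal score, join directly
          target <- hit_cluster
        } else {
          cand <- if (prefilter) {
            kmer_candidates(index, seq, k, scoring$alphabet, nchar(reps))
          } else {
            seq_along(reps)
          }
          if (length(cand) > 0) {
            hits <- align_to_pool(seq, seq_set(reps[cand], scoring$alphabet,
                                               rep_id[cand]), scoring)
            hits$cluster <- rep_cluster[cand]
            hits <- hits[hits$aln_columns >= th$min_len, , drop = FALSE]
            hits <- hits[is_homologous(hits, th), , drop = FALSE]
            if (nrow(hits) > 0) {
              hits <- hits[order(-hits$score, hits$subject_id), , drop = FALSE]
              target <- hits$cluster[1]
            }
          }
        }
      }
      if (is.na(target)) {
        n_clusters <- n_clusters + 1L
        target <- n_clusters
        add_pool_member(seq, gid, target)
      } else if (search == "all") {
        add_pool_member(seq, gid, target)
      }
      assign_cluster[[paste(s, gid, sep = "\r")]] <- target
    }
    first <- FALSE
  }

  clusters <- tibble(
    cluster_id = sprintf("cl%05d", unname(assign_cluster)),
    strain_id = genes$strain_id,
    gene_id = genes$gene_id
  )
  clusters <- clusters[order(clusters$cluster_id,
                             match(clusters$strain_id, strain_order)), ]

  founders <- tibble(cluster_id = sprintf("cl%05d", seq_len(n_clusters)),
                     founder_gene_id = rep_id[match(seq_len(n_clusters),
                                                    rep_cluster)])
  info <- clusters |>
    group_by(.data$cluster_id) |>
    summarise(n_members = n(),
              n_strains_present = n_distinct(.data$strain_id),
              .groups = "drop") |>
    left_join(founders, by = "cluster_id")
  n_strains <- length(strain_order)
  info$class <- cluster_class(info$n_strains_present, n_strains)
  info <- info[, c("cluster_id", "founder_gene_id", "n_members",
                   "n_strains_present", "class")]

  structure(
    list(clusters = clusters, cluster_info = info,
         n_strains = n_strains, strain_order = strain_order,
         thresholds = th, scoring_alphabet = scoring$alphabet,
         search = search, prefilter = prefilter),
    class = "pan_genome"
  )
}

#' Rebuild a pan-genome object from a cluster membership table
#'
#' Reconstructs the partition structure from a `cluster_id` / `strain_id` /
#' `gene_id` table (e.g. a `clusters.tsv` written by [write_pan_genome()]),
#' so rarefaction and tree stages can run without re-aligning.
#'
#' @param clusters Data frame with columns `cluster_id`, `strain_id`,
#'   `gene_id`.
#' @param strain_order Optional strain ordering; defaults to first
#'   appearance.
#' @return A `pan_genome` object (without alignment metadata).
#' @export
pan_genome_from_clusters <- function(clusters, strain_order = NULL) {
  stopifnot(is.data.frame(clusters),
            all(c("cluster_id", "strain_id", "gene_id") %in% names(clusters)))
  clusters <- as_tibble(clusters)
  strain_order <- strain_order %||% unique(clusters$strain_id)
  n_strains <- length(strain_order)
  info <- clusters |>
    group_by(.data$cluster_id) |>
    summarise(n_members = n(),
              n_strains_present = n_distinct(.data$strain_id),
              founder_gene_id = .data$gene_id[1],
              .groups = "drop")
  info$class <- cluster_class(info$n_strains_present, n_strains)
  structure(
    list(clusters = clusters,
         cluster_info = info[, c("cluster_id", "founder_gene_id",
                                 "n_members", "n_strains_present", "class")],
         n_strains = n_strains, strain_order = strain_order,
         thresholds = NULL, scoring_alphabet = NA_character_,
         search = NA_character_, prefilter = NA),
    class = "pan_genome"
  )
}

cluster_class <- function(n_present, n_strains) {
  dplyr::case_when(
    n_present == 1 ~ "specific",
    n_present == n_strains ~ "core",
    TRUE ~ "dispensable"
  )
}

#' @export
print.pan_genome <- function(x, ...) {
  pc <- partition_counts(x)
  cat(sprintf("<pan_genome> %d strains, %d genes, %d clusters\n",
              x$n_strains, nrow(x$clusters), pc$total))
  cat(sprintf("  core %d | dispensable %d | specific %d\n",
              pc$core, pc$dispensable, pc$specific))
  invisible(x)
}

#' Core / dispensable / strain-specific partition counts
#'
#' Counts orthologue clusters by the size of their strain presence set:
#' core clusters occur in all strains, dispensable in more than one but not
#' all, and strain-specific in exactly one.
#'
#' @param result A `pan_genome` object from [build_pan_pool()].
#' @return A one-row tibble with `core`, `dispensable`, `specific`, `total`.
#' @export
partition_counts <- function(result) {
  stopifnot(inherits(result, "pan_genome"))
  cls <- result$cluster_info$class
  tibble(core = sum(cls == "core"),
         dispensable = sum(cls == "dispensable"),
         specific = sum(cls == "specific"),
         total = length(cls))
}

#' Core genome fraction
#'
#' Percentage of orthologue clusters identified in every strain, rounded to
#' one decimal as conventionally reported.
#'
#' @param core Number of core clusters.
#' @param total Total number of clusters.
#' @return Percent, rounded to 1 decimal.
#' @examples
#' core_fraction(5047, 15404) # 32.8
#' @export
core_fraction <- function(core, total) {
  if (length(total) != 1 || is.na(total) || total <= 0) {
    abort("`total` must be positive", class = "panstrep_validation_error")
  }
  round(100 * core / total, 1)
}

#' Strain-by-family presence/absence matrix
#'
#' Binary matrix of strains (rows) by orthologue clusters (columns) derived
#' from a pan-genome partition.
#'
#' @param result A `pan_genome` object.
#' @return Integer matrix with strain ids as rownames and cluster ids as
#'   colnames; entries in `{0, 1}`.
#' @export
presence_matrix <- function(result) {
  stopifnot(inherits(result, "pan_genome"))
  cl <- distinct(result$clusters, .data$cluster_id, .data$strain_id)
  m <- matrix(0L, nrow = result$n_strains,
              ncol = nrow(result$cluster_info),
              dimnames = list(result$strain_order,
                              result$cluster_info$cluster_id))
  m[cbind(cl$strain_id, cl$cluster_id)] <- 1L
  m
}

#' Flower-plot counts
#'
#' The numbers shown in a pan-genome "flower plot": the shared core cluster
#' count (the centre) and each strain's specific cluster count (the petals).
#'
#' @param result A `pan_genome` object.
#' @return A tibble with `strain_id` (`"(core)"` for the centre) and `n`.
#' @export
flower_counts <- function(result) {
  stopifnot(inherits(result, "pan_genome"))
  spec <- result$cluster_info[result$cluster_info$class == "specific", ]
  owner <- result$clusters[match(spec$cluster_id, result$clusters$cluster_id),
                           "strain_id", drop = TRUE]
  per_strain <- tibble(strain_id = result$strain_order) |>
    left_join(tibble(strain_id = owner) |> count(.data$strain_id),
              by = "strain_id") |>
    mutate(n = ifelse(is.na(.data$n), 0L, .data$n))
  bind_rows(tibble(strain_id = "(core)",
                   n = sum(result$cluster_info$class == "core")),
            per_strain)
}

#' Write pan-genome outputs
#'
#' Writes the cluster membership TSV, a partition summary JSON (including
#' the thresholds used), and the flower-plot counts TSV.
#'
#' @param result A `pan_genome` object.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_pan_genome <- function(result, dir) {
  stopifnot(inherits(result, "pan_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "clusters.tsv")
  utils::write.table(result$clusters, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- file.path(dir, "partition.json")
  jsonlite::write_json(
    list(partition = as.list(partition_counts(result)),
         n_strains = result$n_strains,
         strain_order = result$strain_order,
         thresholds = unclass(result$thresholds),
         alphabet = result$scoring_alphabet,
         search = result$search, prefilter = result$prefilter),
    p2, auto_unbox = TRUE, pretty = TRUE)
  p3 <- file.path(dir, "flower_counts.tsv")
  utils::write.table(flower_counts(result), p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(clusters = p1, partition = p2, flower = p3))
}
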