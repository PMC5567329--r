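#' Parameters for the synthetic pan-genome simulator
#'
#' Defines a multi-strain gene-family structure with known ground truth:
#' `n_core` families present in every strain, dispensable families present in
#' an intermediate number of strains, and strain-specific singletons. Family
#' members are derived from a common ancestor sequence by i.i.d. per-site
#' substitution at rate `divergence`.
#'
#' @param n_strains Number of strains (>= 1).
#' @param n_core Number of core families (present in all strains).
#' @param dispensable_spec Dispensable families, as a list of
#'   `c(family_count, strains_present)` pairs; each entry adds
#'   `family_count` families present in exactly `strains_present` strains,
#'   with `2 <= strains_present <= n_strains - 1`.
#' @param n_specific_per_strain Strain-specific families per strain.
#' @param gene_length_range Ancestor length range in bp (or residues),
#'   drawn uniformly. The default (150, 3000) brackets typical bacterial
#'   CDS lengths (genome-wide averages around 900 bp).
#' @param divergence Per-site substitution probability in `[0, 1)` applied
#'   independently to each family member relative to the ancestor.
#' @param paralog_rate Probability that a strain carries an extra, duplicated
#'   member of a family it already has (an independent divergence draw from
#'   the same ancestor; the truth table keeps the same family id).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param gc Optional GC fraction for nucleotide ancestors; `NULL` (default)
#'   draws all symbols uniformly.
#' @param seed Integer RNG seed; identical parameters and seed give
#'   byte-identical output.
#' @return An object of class `sim_params`.
#' @examples
#' sim_params(n_strains = 3, n_core = 5, n_specific_per_strain = 2)
#' @export
sim_params <- function(n_strains = 9,
                       n_core = 50,
                       dispensable_spec = list(),
                       n_specific_per_strain = 5,
                       gene_length_range = c(150, 3000),
                       divergence = 0,
                       paralog_rate = 0,
                       alphabet = c("nucleotide", "protein"),
                       gc = NULL,
                       seed = 1L) {
  alphabet <- match.arg(alphabet)
  assert_count(n_strains, "n_strains", min = 1)
  assert_count(n_core, "n_core")
  assert_count(n_specific_per_strain, "n_specific_per_strain")
  assert_fraction(divergence, "divergence", max_exclusive = TRUE)
  assert_fraction(paralog_rate, "paralog_rate")
  if (length(gene_length_range) != 2 || any(gene_length_range < 1) ||
      gene_length_range[1] > gene_length_range[2]) {
    abort("`gene_length_range` must be (min_bp, max_bp) with 1 <= min <= max",
          class = "panstrep_validation_error")
  }
  if (!is.null(gc)) assert_fraction(gc, "gc")
  if (is.data.frame(dispensable_spec)) {
    dispensable_spec <- purrr::pmap(dispensable_spec[, 1:2],
                                    function(...) c(...))
  }
  for (entry in dispensable_spec) {
    if (length(entry) != 2 || any(entry != as.integer(entry)) ||
        entry[1] < 0 || entry[2] < 2 || entry[2] > n_strains - 1) {
      abort(paste0("`dispensable_spec` entries must be (family_count, ",
                   "strains_present) with 2 <= strains_present <= n_strains - 1"),
            class = "panstrep_validation_error")
    }
  }
  assert_count(seed, "seed", min = 0)
  structure(
    list(n_strains = as.integer(n_strains), n_core = as.integer(n_core),
         dispensable_spec = dispensable_spec,
         n_specific_per_strain = as.integer(n_specific_per_strain),
         gene_length_range = as.integer(gene_length_range),
         divergence = divergence, paralog_rate = paralog_rate,
         alphabet = alphabet, gc = gc, seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' @export
print.sim_params <- function(x, ...) {
  disp <- sum(purrr::map_dbl(x$dispensable_spec, 1))
  cat(sprintf(
    "<sim_params> %d strains | %d core + %d dispensable + %d specific/strain\n",
    x$n_strains, x$n_core, disp, x$n_specific_per_strain))
  cat(sprintf("  divergence=%g paralog_rate=%g lengths=[%d,%d] %s seed=%d\n",
              x$divergence, x$paralog_rate, x$gene_length_range[1],
              x$gene_length_range[2], x$alphabet, x$seed))
  invisible(x)
}

#' Mutate a sequence by i.i.d. per-site substitution
#'
#' Each site is independently replaced, with probability `rate`, by a
#' uniformly chosen *different* symbol of the alphabet. Length is preserved;
#' `rate = 0` is the identity.
#'
#' @param seq Character scalar sequence.
#' @param rate Substitution probability in `[0, 1)`.
#' @param seed Optional seed for a self-contained deterministic call; `NULL`
#'   uses (and advances) the current RNG stream.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return The mutated sequence (character scalar).
#' @examples
#' mutate_sequence("ACGT", rate = 0)
#' mutate_sequence("ACGTACGTAC", rate = 0.5, seed = 7)
#' @export
mutate_sequence <- function(seq, rate, seed = NULL,
                            alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  seq <- as_seq_chr(seq)
  assert_fraction(rate, "rate", max_exclusive = TRUE)
  n <- nchar(seq)
  if (n == 0) return(seq)
  with_seed(seed, {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(n) < rate)
    if (length(hit) > 0) {
      ab <- ALPHABETS[[alphabet]]
      a <- length(ab)
      pos <- match(chars[hit], ab)
      # uniform over the other a-1 symbols, by offset around the ring
      offset <- sample.int(a - 1, length(hit), replace = TRUE)
      chars[hit] <- ab[((pos - 1 + offset) %% a) + 1]
    }
    paste(chars, collapse = "")
  })
}

#' Simulate a multi-strain pan-genome with ground truth
#'
#' Draws one ancestor sequence per gene family (uniform over the alphabet,
#' optionally GC-biased), decides which strains carry each family per the
#' core/dispensable/specific design in `params`, and emits each member as an
#' independently mutated copy of its ancestor. The result carries a truth
#' table mapping every emitted gene to its family, so downstream clustering
#' can be scored exactly.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `pan_sim` with elements:
#'   * `genes`: tibble with `strain_id`, `gene_id`, `family_id`, `copy`,
#'     `sequence`, `length` (gene ids follow `strainK|famJ|cC`);
#'   * `truth`: tibble `gene_id`, `family_id`, `strain_id`;
#'   * `families`: tibble `family_id`, `class` (core/dispensable/specific),
#'     `n_strains_present`, `strains` (list column);
#'   * `params`: the input parameters.
#' @examples
#' sim <- simulate_pangenome(sim_params(n_strains = 3, n_core = 5,
#'                                      n_specific_per_strain = 2, seed = 42))
#' dplyr::count(sim$genes, strain_id)
#' @export
simulate_pangenome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, {
    strains <- paste0("strain", seq_len(params$n_strains))

    fam <- list()
    add_family <- function(class, strains_present) {
      fam[[length(fam) + 1]] <<- list(class = class, strains = strains_present)
    }
    for (i in seq_len(params$n_core)) add_family("core", strains)
    for (entry in params$dispensable_spec) {
      for (i in seq_len(entry[1])) {
        add_family("dispensable", sample(strains, entry[2]))
      }
    }
    for (s in strains) {
      for (i in seq_len(params$n_specific_per_strain)) add_family("specific", s)
    }
    fam_id <- paste0("fam", seq_along(fam))

    rng <- params$gene_length_range
    lens <- rng[1] + sample.int(rng[2] - rng[1] + 1L, length(fam),
                                replace = TRUE) - 1L
    ancestors <- purrr::map_chr(lens, function(L) {
      if (!is.null(params$gc) && params$alphabet == "nucleotide") {
        probs <- c(A = (1 - params$gc) / 2, C = params$gc / 2,
                   G = params$gc / 2, T = (1 - params$gc) / 2)
        paste(sample(names(probs), L, replace = TRUE, prob = probs),
              collapse = "")
      } else {
        random_sequence(L, params$alphabet)
      }
    })

    rows <- vector("list", length(fam))
    for (j in seq_along(fam)) {
      members <- list()
      for (s in fam[[j]]$strains) {
        n_copies <- 1L + (params$paralog_rate > 0 &&
                            runif(1) < params$paralog_rate)
        for (cp in seq_len(n_copies)) {
          members[[length(members) + 1]] <- tibble(
            strain_id = s,
            gene_id = paste0(s, "|", fam_id[j], "|c", cp),
            family_id = fam_id[j],
            copy = cp,
            sequence = mutate_sequence(ancestors[j], params$divergence,
                                       alphabet = params$alphabet)
          )
        }
      }
      rows[[j]] <- bind_rows(members)
    }
    genes <- bind_rows(rows)
    genes$length <- nchar(genes$sequence)
    genes <- genes[order(match(genes$strain_id, strains)), ]

    families <- tibble(
      family_id = fam_id,
      class = purrr::map_chr(fam, "class"),
      n_strains_present = purrr::map_int(fam, ~ length(.x$strains)),
      strains = purrr::map(fam, "strains")
    )

    structure(
      list(genes = as_tibble(genes),
           truth = genes[, c("gene_id", "family_id", "strain_id")],
           families = families,
           params = params),
      class = "pan_sim"
    )
  })
}

#' @export
print.pan_sim <- function(x, ...) {
  cat(sprintf("<pan_sim> %d strains, %d families, %d genes\n",
              x$params$n_strains, nrow(x$families), nrow(x$genes)))
  print(dplyr::count(x$families, .data$class))
  invisible(x)
}

#' Assemble synthetic genomes from a simulation
#'
#' Concatenates each strain's genes, separated (and flanked) by random
#' spacer sequence, into one genome per strain, and records the 1-based
#' closed coordinates of every gene. Useful for exercising the genome-stats
#' and ANI stages on data with known structure.
#'
#' @param sim A `pan_sim` object from [simulate_pangenome()].
#' @param spacer_range Spacer length range in bp, drawn uniformly.
#' @return A list with `genomes` (named character vector, one per strain)
#'   and `coords` (tibble `strain_id`, `gene_id`, `start`, `end`).
#' @export
sim_genomes <- function(sim, spacer_range = c(100, 400)) {
  stopifnot(inherits(sim, "pan_sim"))
  if (sim$params$alphabet != "nucleotide") {
    abort("genomes can only be assembled for nucleotide simulations",
          class = "panstrep_validation_error")
  }
  with_seed(derive_seed(sim$params$seed, 97L), {
    strains <- unique(sim$genes$strain_id)
    coords <- list()
    genomes <- setNames(character(length(strains)), strains)
    for (s in strains) {
      gs <- sim$genes[sim$genes$strain_id == s, ]
      parts <- character(0)
      pos <- 0L
      for (i in seq_len(nrow(gs))) {
        spacer <- random_sequence(
          spacer_range[1] + sample.int(spacer_range[2] - spacer_range[1] + 1L,
                                       1) - 1L, "nucleotide")
        parts <- c(parts, spacer, gs$sequence[i])
        start <- pos + nchar(spacer) + 1L
        end <- start + gs$length[i] - 1L
        pos <- end
        coords[[length(coords) + 1]] <- tibble(
          strain_id = s, gene_id = gs$gene_id[i], start = start, end = end)
      }
      parts <- c(parts, random_sequence(
        spacer_range[1] + sample.int(spacer_range[2] - spacer_range[1] + 1L,
                                     1) - 1L, "nucleotide"))
      genomes[[s]] <- paste(parts, collapse = "")
    }
    list(genomes = genomes, coords = bind_rows(coords))
  })
}

#' Write a simulation to disk
#'
#' Writes one gene FASTA per strain, the truth table as TSV, and optionally
#' per-strain genome FASTA plus GFF3 gene coordinates.
#'
#' @param sim A `pan_sim` object.
#' @param dir Output directory (created if needed).
#' @param genomes Also write assembled genomes ([sim_genomes()]) and GFF3?
#' @return Invisibly, a named list of written file paths.
#' @export
write_simulation <- function(sim, dir, genomes = FALSE) {
  stopifnot(inherits(sim, "pan_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (s in unique(sim$genes$strain_id)) {
    gs <- sim$genes[sim$genes$strain_id == s, ]
    set <- seq_set(gs$sequence, sim$params$alphabet, gs$gene_id)
    f <- file.path(dir, paste0(s, ".genes.fasta"))
    Biostrings::writeXStringSet(set, f)
    paths[[paste0(s, "_genes")]] <- f
  }
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$truth <- truth_path
  if (genomes) {
    g <- sim_genomes(sim)
    for (s in names(g$genomes)) {
      f <- file.path(dir, paste0(s, ".genome.fasta"))
      Biostrings::writeXStringSet(
        setNames(Biostrings::DNAStringSet(g$genomes[[s]]), s), f)
      paths[[paste0(s, "_genome")]] <- f
      gff <- file.path(dir, paste0(s, ".genes.gff3"))
      cd <- g$coords[g$coords$strain_id == s, ]
      writeLines(c(
        "##gff-version 3",
        sprintf("%s\tpanstrep_sim\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                s, cd$start, cd$end, cd$gene_id)), gff)
      paths[[paste0(s, "_gff")]] <- gff
    }
  }
  invisible(paths)
}
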