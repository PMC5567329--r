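#' GC content of a sequence
#'
#' Fraction (G + C) / (A + C + G + T), case-insensitive. IUPAC ambiguity
#' codes (including N) are excluded from both numerator and denominator; an
#' empty or all-ambiguous sequence is an error.
#'
#' @param seq Character scalar or Biostrings object.
#' @return GC fraction in \[0, 1\].
#' @examples
#' gc_content("ATGC")     # 0.5
#' gc_content("ATATNNGC") # 2/6
#' @export
gc_content <- function(seq) {
  seq <- as_seq_chr(seq)
  if (nchar(seq) == 0) {
    abort("sequence must be non-empty", class = "panstrep_validation_error")
  }
  gc <- nchar(gsub("[^GC]", "", seq))
  at <- nchar(gsub("[^AT]", "", seq))
  if (gc + at == 0) {
    abort("sequence has no unambiguous A/C/G/T bases",
          class = "panstrep_validation_error")
  }
  gc / (gc + at)
}

merge_intervals <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(IRanges::IRanges())
  }
  if (inherits(x, "IRanges")) return(IRanges::reduce(x))
  stopifnot(is.data.frame(x), all(c("start", "end") %in% names(x)))
  IRanges::reduce(IRanges::IRanges(start = x$start, end = x$end))
}

check_bounds <- function(ir, genome_bp, what) {
  if (length(ir) > 0 &&
      (min(IRanges::start(ir)) < 1 || max(IRanges::end(ir)) > genome_bp)) {
    abort(sprintf("%s intervals fall outside [1, %d]", what, genome_bp),
          class = "panstrep_validation_error")
  }
}

region_gc <- function(seq, ir) {
  if (length(ir) == 0) return(NA_real_)
  gc_content(paste(substring(seq, IRanges::start(ir), IRanges::end(ir)),
                   collapse = ""))
}

#' Per-genome feature summary
#'
#' Computes the standard genome-assembly characteristics table: genome size
#' and GC, gene count, total/average gene length, gene and intergenic
#' fractions of the genome, regional GC, and tandem-repeat totals.
#' Overlapping gene intervals are merged (union semantics) before length
#' accounting, so gene and intergenic lengths always partition the genome
#' exactly. Coordinates are 1-based closed (the GFF3 convention).
#'
#' @param genome Genome sequence (character or Biostrings object), or `NULL`
#'   if only `genome_bp` is known (GC columns are then `NA`).
#' @param genes Gene intervals: a data frame with `start`/`end` columns or an
#'   `IRanges`. `gene_count` is the number of input intervals (pre-merge).
#' @param repeats Optional repeat intervals (same forms); totals are taken
#'   from annotation, never detected.
#' @param genome_bp Genome length; required when `genome` is `NULL`.
#' @return One-row tibble of class `feature_summary` with columns
#'   `genome_bp`, `gc_pct`, `gene_count`, `gene_total_bp`, `gene_avg_bp`,
#'   `gene_pct`, `gc_gene_pct`, `intergenic_bp`, `intergenic_pct`,
#'   `gc_intergenic_pct`, `repeat_total_bp`, `repeat_pct`.
#'   Percent columns are rounded to 2 decimals (`repeat_pct` to 4);
#'   `gene_avg_bp` is rounded to the nearest bp and is `NA` when there are
#'   no genes.
#' @examples
#' feature_summary(genome_bp = 1000,
#'                 genes = data.frame(start = c(1, 501), end = c(300, 600)))
#' @export
feature_summary <- function(genome = NULL, genes = NULL, repeats = NULL,
                            genome_bp = NULL) {
  if (!is.null(genome)) {
    genome <- as_seq_chr(genome)
    genome_bp <- nchar(genome)
  }
  if (is.null(genome_bp) || genome_bp < 1) {
    abort("provide a non-empty `genome` or a positive `genome_bp`",
          class = "panstrep_validation_error")
  }
  genome_bp <- as.integer(genome_bp)
  n_genes <- if (is.null(genes)) 0L else {
    if (inherits(genes, "IRanges")) length(genes) else nrow(genes)
  }
  gene_ir <- merge_intervals(genes)
  rep_ir <- merge_intervals(repeats)
  check_bounds(gene_ir, genome_bp, "gene")
  check_bounds(rep_ir, genome_bp, "repeat")

  gene_total <- sum(IRanges::width(gene_ir))
  rep_total <- sum(IRanges::width(rep_ir))
  intergenic_ir <- IRanges::gaps(gene_ir, start = 1L, end = genome_bp)

  summary_from_totals(
    genome_bp = genome_bp,
    gene_count = n_genes,
    gene_total_bp = gene_total,
    repeat_total_bp = rep_total,
    gc_pct = if (!is.null(genome)) round(100 * gc_content(genome), 2) else NA_real_,
    gc_gene_pct = if (!is.null(genome)) {
      round(100 * region_gc(genome, gene_ir), 2)
    } else NA_real_,
    gc_intergenic_pct = if (!is.null(genome)) {
      round(100 * region_gc(genome, intergenic_ir), 2)
    } else NA_real_
  )
}

#' Feature summary from printed totals
#'
#' The arithmetic core of [feature_summary()], applied directly to totals as
#' printed in a genome-characteristics table (useful for checking published
#' tables without the underlying annotation files).
#'
#' @param genome_bp Genome length (bp).
#' @param gene_count Number of genes.
#' @param gene_total_bp Total gene length (bp, union of gene intervals).
#' @param repeat_total_bp Total tandem-repeat length (bp).
#' @param gc_pct,gc_gene_pct,gc_intergenic_pct Optional GC percentages to
#'   carry through.
#' @return One-row `feature_summary` tibble; see [feature_summary()].
#' @examples
#' summary_from_totals(genome_bp = 9307519, gene_count = 8888,
#'                     gene_total_bp = 8035014, repeat_total_bp = 99927)
#' @export
summary_from_totals <- function(genome_bp, gene_count, gene_total_bp,
                                repeat_total_bp = 0,
                                gc_pct = NA_real_, gc_gene_pct = NA_real_,
                                gc_intergenic_pct = NA_real_) {
  if (gene_total_bp > genome_bp) {
    abort("gene_total_bp cannot exceed genome_bp",
          class = "panstrep_validation_error")
  }
  intergenic <- genome_bp - gene_total_bp
  out <- tibble(
    genome_bp = as.integer(genome_bp),
    gc_pct = gc_pct,
    gene_count = as.integer(gene_count),
    gene_total_bp = as.numeric(gene_total_bp),
    gene_avg_bp = if (gene_count > 0) round(gene_total_bp / gene_count) else NA_real_,
    gene_pct = round(100 * gene_total_bp / genome_bp, 2),
    gc_gene_pct = gc_gene_pct,
    intergenic_bp = as.numeric(intergenic),
    intergenic_pct = round(100 * intergenic / genome_bp, 2),
    gc_intergenic_pct = gc_intergenic_pct,
    repeat_total_bp = as.numeric(repeat_total_bp),
    repeat_pct = round(100 * repeat_total_bp / genome_bp, 4)
  )
  class(out) <- c("feature_summary", class(out))
  out
}

#' Feature summary from FASTA + GFF3 files
#'
#' Reads a genome FASTA and GFF3 annotation and computes [feature_summary()]
#' per assembly. Multi-sequence assemblies are summarised as one unit (gene
#' and repeat intervals are resolved against their own sequence).
#'
#' @param fasta Path to the genome FASTA.
#' @param gff Path to a GFF3 with gene features.
#' @param repeat_gff Optional GFF3 (or the same file) carrying repeat
#'   features.
#' @param gene_type,repeat_type GFF3 feature types to use.
#' @return One-row `feature_summary` tibble.
#' @export
genome_feature_summary <- function(fasta, gff, repeat_gff = NULL,
                                   gene_type = "gene",
                                   repeat_type = "repeat_region") {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading GFF3 requires the rtracklayer package")
  }
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- as.data.frame(rtracklayer::import(gff))
  genes <- ann[ann$type == gene_type, c("seqnames", "start", "end")]
  reps <- NULL
  if (!is.null(repeat_gff)) {
    rann <- as.data.frame(rtracklayer::import(repeat_gff))
    reps <- rann[rann$type == repeat_type, c("seqnames", "start", "end")]
  }
  offsets <- cumsum(c(0, head(Biostrings::width(seqs), -1)))
  names(offsets) <- names(seqs)
  shift <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    miss <- setdiff(unique(as.character(df$seqnames)), names(offsets))
    if (length(miss) > 0) {
      abort(paste0("annotation references sequences absent from the FASTA: ",
                   paste(miss, collapse = ", ")),
            class = "panstrep_validation_error")
    }
    off <- offsets[as.character(df$seqnames)]
    data.frame(start = df$start + off, end = df$end + off)
  }
  feature_summary(genome = paste(as.character(seqs), collapse = ""),
                  genes = shift(genes), repeats = shift(reps))
}
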