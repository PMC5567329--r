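# Pipeline orchestration: simulate -> stats -> pangenome -> rarefy -> ani
# -> tree, driven by a validated config.

PIPELINE_SCHEMA <- list(
  seed = NULL, output_dir = NULL, stages = NULL, log_level = NULL,
  simulate = c("n_strains", "n_core", "dispensable_spec",
               "n_specific_per_strain", "gene_length_range", "divergence",
               "paralog_rate", "alphabet", "gc", "seed"),
  homology = c("bcr_min", "identity_min", "min_len"),
  pangenome = c("search", "prefilter"),
  rarefaction = c("n_perm"),
  ani = c("fragment_bp", "min_identity_pct", "min_coverage", "reciprocal"),
  tree = c("metric")
)

PIPELINE_STAGES <- c("simulate", "stats", "pangenome", "rarefy", "ani", "tree")

LOG_LEVELS <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)

#' Validate a pipeline configuration
#'
#' Checks a configuration (a named list, or a path to a YAML file) against
#' the pipeline schema: unknown keys are an error naming the key, and each
#' module block must satisfy that module's parameter invariants.
#'
#' @param config Named list or YAML file path.
#' @return The validated config list (with defaults filled in), invisibly
#'   classed as `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), names(PIPELINE_SCHEMA))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "panstrep_config_error")
  }
  for (block in names(PIPELINE_SCHEMA)) {
    fields <- PIPELINE_SCHEMA[[block]]
    if (!is.null(fields) && !is.null(config[[block]])) {
      bad <- setdiff(names(config[[block]]), fields)
      if (length(bad) > 0) {
        abort(sprintf("unknown config key(s) in `%s`: %s", block,
                      paste(bad, collapse = ", ")),
              class = "panstrep_config_error")
      }
    }
  }
  config$seed <- config$seed %||% 1L
  config$stages <- config$stages %||% c("simulate", "pangenome", "rarefy",
                                        "tree")
  bad_stage <- setdiff(config$stages, PIPELINE_STAGES)
  if (length(bad_stage) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")),
          class = "panstrep_config_error")
  }
  config$log_level <- toupper(config$log_level %||% "INFO")
  if (!config$log_level %in% names(LOG_LEVELS)) {
    abort("log_level must be one of DEBUG, INFO, WARN, ERROR",
          class = "panstrep_config_error")
  }
  # module blocks must construct cleanly
  sim_args <- config$simulate %||% list()
  sim_args$seed <- sim_args$seed %||% config$seed
  do.call(sim_params, sim_args)
  do.call(homology_thresholds, config$homology %||% list())
  do.call(ani_params, config$ani %||% list())
  structure(config, class = c("pipeline_config", "list"))
}

make_logger <- function(level, logfile) {
  threshold <- LOG_LEVELS[[level]]
  function(lvl, msg) {
    if (LOG_LEVELS[[lvl]] >= threshold) {
      line <- sprintf("[%s] %s %s", lvl,
                      format(Sys.time(), "%H:%M:%S"), msg)
      message(line)
      cat(line, "\n", file = logfile, append = TRUE)
    }
  }
}

#' Run the comparative-genomics pipeline
#'
#' Executes the requested stages in dependency order on a synthetic strain
#' set: `simulate` (gene sets + genomes with ground truth), `stats`
#' (per-genome feature summaries), `pangenome` (gene-pool accretion and
#' partition), `rarefy` (dilution curves and model fits), `ani` (pairwise
#' ANI matrix; needs the BLAST+ tools), and `tree` (presence/absence NJ
#' tree). Outputs are written to a temporary staging area and promoted to
#' `output_dir` atomically; a manifest records the package version, config
#' hash, seed, per-stage outputs and wall time. Identical config and seed
#' give identical outputs.
#'
#' @param config A [pipeline_config()], a named list, or a YAML file path.
#' @param output_dir Output directory (overrides `config$output_dir`).
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), output_dir = NULL) {
  t0 <- Sys.time()
  config <- pipeline_config(config)
  out_dir <- output_dir %||% config$output_dir %||%
    abort("no `output_dir` given", class = "panstrep_config_error")
  stages <- config$stages
  need <- function(stage, deps) {
    miss <- setdiff(deps, stages)
    if (length(miss) > 0) {
      abort(sprintf("stage `%s` needs upstream stage(s): %s", stage,
                    paste(miss, collapse = ", ")),
            class = "panstrep_config_error")
    }
  }
  staging <- tempfile("panstrep_run_")
  dir.create(staging, recursive = TRUE)
  log <- make_logger(config$log_level, file.path(staging, "run.log"))
  outputs <- list()
  state <- new.env(parent = emptyenv())

  for (stage in intersect(PIPELINE_STAGES, stages)) {
    log("INFO", paste("stage:", stage))
    sdir <- file.path(staging, stage)
    dir.create(sdir, showWarnings = FALSE)
    if (stage == "simulate") {
      sim_args <- config$simulate %||% list()
      sim_args$seed <- sim_args$seed %||% config$seed
      state$sim <- simulate_pangenome(do.call(sim_params, sim_args))
      needs_genomes <- any(c("stats", "ani") %in% stages) &&
        state$sim$params$alphabet == "nucleotide"
      outputs$simulate <- write_simulation(state$sim, sdir,
                                           genomes = needs_genomes)
      if (needs_genomes) state$genomes <- sim_genomes(state$sim)
    } else if (stage == "stats") {
      need(stage, "simulate")
      g <- state$genomes %||% abort("stage `stats` needs simulated genomes",
                                    class = "panstrep_config_error")
      rows <- purrr::imap(g$genomes, function(seq, s) {
        cd <- g$coords[g$coords$strain_id == s, ]
        cbind(strain_id = s,
              feature_summary(seq, cd[, c("start", "end")]))
      }) |> bind_rows()
      f <- file.path(sdir, "feature_summary.tsv")
      utils::write.table(rows, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs$stats <- list(feature_summary = f)
    } else if (stage == "pangenome") {
      need(stage, "simulate")
      th <- do.call(homology_thresholds,
                    c(config$homology %||% list(),
                      list(alphabet = state$sim$params$alphabet)))
      pg_args <- config$pangenome %||% list()
      state$pg <- build_pan_pool(state$sim, th = th,
                                 scoring = scoring_scheme(state$sim$params$alphabet),
                                 search = pg_args$search %||% "founders",
                                 prefilter = pg_args$prefilter %||% TRUE)
      outputs$pangenome <- write_pan_genome(state$pg, sdir)
    } else if (stage == "rarefy") {
      need(stage, "pangenome")
      n_perm <- (config$rarefaction %||% list())$n_perm
      state$curve <- rarefy(state$pg, n_perm = n_perm,
                            seed = derive_seed(config$seed, 11L))
      f <- file.path(sdir, "curve.tsv")
      utils::write.table(as_tibble(state$curve), f, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      fits <- list(core = fit_core_decay(state$curve),
                   pan = fit_pan_growth(state$curve))
      fj <- file.path(sdir, "fits.json")
      jsonlite::write_json(purrr::map(fits, function(ft) {
        c(list(model = ft$model, parameters = ft$parameters, rss = ft$rss,
               converged = ft$converged),
          if (!is.null(ft$open)) list(open = ft$open))
      }), fj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
      outputs$rarefy <- list(curve = f, fits = fj)
    } else if (stage == "ani") {
      need(stage, "simulate")
      g <- state$genomes %||% abort("stage `ani` needs simulated genomes",
                                    class = "panstrep_config_error")
      am <- ani_matrix(g$genomes,
                       params = do.call(ani_params, config$ani %||% list()))
      f <- file.path(sdir, "ani_matrix.tsv")
      utils::write.table(am$matrix, f, sep = "\t", quote = FALSE,
                         col.names = NA)
      fp <- file.path(sdir, "ani_pairs.json")
      jsonlite::write_json(am$pairs, fp, dataframe = "rows",
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      state$ani <- am
      outputs$ani <- list(matrix = f, pairs = fp)
    } else if (stage == "tree") {
      need(stage, "pangenome")
      tree <- pan_genome_tree(state$pg,
                              metric = (config$tree %||% list())$metric %||%
                                "jaccard")
      f <- file.path(sdir, "profile_tree.nwk")
      write_tree_newick(tree, f)
      outputs$tree <- list(newick = f)
    }
  }

  manifest <- list(
    package = "panstrep",
    version = as.character(utils::packageVersion("panstrep")),
    config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                      "output_dir")]),
    seed = config$seed,
    stages = stages,
    outputs = purrr::map(outputs, function(o) {
      purrr::map(o, ~ sub(paste0("^", staging, "/?"), "", .x))
    }),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  # promote atomically: stage fully, then move into place
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  dir.create(dirname(out_dir), recursive = TRUE, showWarnings = FALSE)
  if (!file.rename(staging, out_dir)) {
    # staging may sit on another filesystem; fall back to copy + remove
    dir.create(out_dir, recursive = TRUE)
    file.copy(list.files(staging, full.names = TRUE), out_dir,
              recursive = TRUE)
    unlink(staging, recursive = TRUE)
  }
  invisible(manifest)
}
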