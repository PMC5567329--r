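test_that("zero divergence yields byte-identical core members in every strain", {
  sim <- simulate_pangenome(sim_params(
    n_strains = 3, n_core = 5, n_specific_per_strain = 2,
    divergence = 0, seed = 3))
  # every strain has exactly core + specific genes
  per_strain <- dplyr::count(sim$genes, strain_id)
  expect_equal(per_strain$n, rep(7L, 3))
  # core members identical across strains
  core_ids <- sim$families$family_id[sim$families$class == "core"]
  for (f in core_ids) {
    seqs <- sim$genes$sequence[sim$genes$family_id == f]
    expect_length(seqs, 3)
    expect_length(unique(seqs), 1)
  }
  # specific families live in exactly one strain
  spec <- sim$families[sim$families$class == "specific", ]
  expect_true(all(spec$n_strains_present == 1))
})

test_that("identical parameters and seed reproduce the simulation exactly", {
  p <- sim_params(n_strains = 4, n_core = 6, dispensable_spec = list(c(2, 2)),
                  n_specific_per_strain = 1, divergence = 0.05,
                  paralog_rate = 0.3, seed = 99)
  s1 <- simulate_pangenome(p)
  s2 <- simulate_pangenome(p)
  expect_identical(s1$genes, s2$genes)
  expect_identical(s1$truth, s2$truth)
  # and written FASTA output is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
})

test_that("core pair identity matches the i.i.d. substitution expectation", {
  r <- 0.05
  len <- 300
  sim <- simulate_pangenome(sim_params(
    n_strains = 2, n_core = 10, n_specific_per_strain = 0,
    gene_length_range = c(len, len), divergence = r, seed = 21))
  core <- sim$genes[grepl("\\|c1$", sim$genes$gene_id), ]
  wide <- split(core$sequence, core$family_id)
  match_count <- sum(vapply(wide, function(s) {
    a <- strsplit(s[1], "")[[1]]
    b <- strsplit(s[2], "")[[1]]
    sum(a == b)
  }, numeric(1)))
  n_sites <- 10 * len
  # both members mutated independently from the ancestor
  p_match <- (1 - r)^2 + r^2 / 3
  se <- sqrt(p_match * (1 - p_match) / n_sites)
  expect_lt(abs(match_count / n_sites - p_match), 3 * se)
})

test_that("truth table is consistent with the genes emitted", {
  sim <- simulate_pangenome(sim_params(
    n_strains = 5, n_core = 4, dispensable_spec = list(c(3, 2), c(2, 4)),
    n_specific_per_strain = 2, divergence = 0.02, paralog_rate = 0.4,
    seed = 8))
  # every emitted gene appears exactly once in the truth table
  expect_setequal(sim$truth$gene_id, sim$genes$gene_id)
  expect_equal(anyDuplicated(sim$truth$gene_id), 0L)
  # family presence vectors agree with the genes emitted
  by_fam <- dplyr::summarise(
    dplyr::group_by(sim$genes, family_id),
    n_strains_present = dplyr::n_distinct(strain_id), .groups = "drop")
  merged <- dplyr::left_join(sim$families, by_fam, by = "family_id",
                             suffix = c("_declared", "_emitted"))
  expect_equal(merged$n_strains_present_emitted,
               merged$n_strains_present_declared)
  # core families are present in all strains
  expect_true(all(merged$n_strains_present_emitted[merged$class == "core"] == 5))
  # paralogs keep their family id and add members, not families
  expect_gt(nrow(sim$genes), nrow(sim$truth[!duplicated(sim$truth$family_id), ]))
})

test_that("invalid simulation parameters fail naming the field", {
  expect_error(sim_params(n_strains = 0), "n_strains",
               class = "panstrep_validation_error")
  expect_error(sim_params(divergence = 1), "divergence",
               class = "panstrep_validation_error")
  expect_error(sim_params(n_strains = 3, dispensable_spec = list(c(1, 3))),
               "dispensable_spec", class = "panstrep_validation_error")
  expect_error(sim_params(gene_length_range = c(100, 50)),
               "gene_length_range", class = "panstrep_validation_error")
})

test_that("mutate_sequence follows the per-site substitution contract", {
  expect_identical(mutate_sequence("ACGT", 0), "ACGT")
  expect_identical(mutate_sequence("", 0.5), "")
  expect_error(mutate_sequence("ACGT", 1), class = "panstrep_validation_error")
  expect_error(mutate_sequence("ACGT", -0.1), class = "panstrep_validation_error")
  # length preserved, only alphabet symbols introduced
  m <- mutate_sequence(strrep("ACGT", 50), 0.5, seed = 4)
  expect_equal(nchar(m), 200)
  expect_true(all(strsplit(m, "")[[1]] %in% c("A", "C", "G", "T")))
  # Hamming distance within 3 s.d. of Binomial(n, rate)
  n <- 10000
  rate <- 0.1
  s <- strrep("A", n)
  m <- mutate_sequence(s, rate, seed = 123)
  d <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_lt(abs(d - n * rate), 3 * sqrt(n * rate * (1 - rate)))
  # determinism under an explicit seed
  expect_identical(mutate_sequence(s, rate, seed = 123), m)
})

test_that("assembled genomes embed the genes at the recorded coordinates", {
  sim <- tiny_sim(seed = 44)
  g <- sim_genomes(sim)
  for (i in seq_len(nrow(g$coords))) {
    row <- g$coords[i, ]
    embedded <- substring(g$genomes[[row$strain_id]], row$start, row$end)
    expect_identical(embedded,
                     sim$genes$sequence[sim$genes$gene_id == row$gene_id])
  }
  # deterministic given the simulation seed
  g2 <- sim_genomes(sim)
  expect_identical(g$genomes, g2$genomes)
})
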