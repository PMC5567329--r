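test_that("degenerate strain sets partition as the algorithm prescribes", {
  # one strain, unrelated genes: all clusters strain-specific
  set.seed(2)
  g1 <- tibble::tibble(strain_id = "s1",
                       gene_id = paste0("g", 1:5),
                       sequence = replicate(5, random_dna(200)))
  pg <- build_pan_pool(g1)
  expect_partition(pg, core = 0, dispensable = 0, specific = 5)

  # two byte-identical strains: everything core, nothing specific
  g2 <- dplyr::bind_rows(g1, dplyr::mutate(g1, strain_id = "s2"))
  pg2 <- build_pan_pool(g2)
  expect_partition(pg2, core = 5, dispensable = 0, specific = 0)
})

test_that("zero-divergence simulation is recovered exactly, matching the truth table and a single-linkage oracle", {
  sim <- tiny_sim(divergence = 0, seed = 31)
  th <- homology_thresholds()
  sc <- scoring_scheme("nucleotide")
  pg <- build_pan_pool(sim, th = th, scoring = sc)
  expect_partition(pg, core = 3, dispensable = 1, specific = 6)

  # against the brute-force single-linkage oracle over all gene pairs
  oracle <- single_linkage_clusters(sim$genes, th, sc)
  expect_equal(sort(unname(unlist(oracle_partition(oracle, 3)))),
               sort(unname(unlist(partition_counts(pg)))))

  # cluster membership agrees with ground truth exactly
  td <- dplyr::left_join(tidy(pg), sim$truth, by = "gene_id")
  crosses <- table(td$cluster_id, td$family_id)
  expect_true(all(rowSums(crosses > 0) == 1))
  expect_true(all(colSums(crosses > 0) == 1))
})

test_that("the partition is identical for every strain ordering at zero divergence", {
  sim <- tiny_sim(divergence = 0, seed = 52)
  strains <- unique(sim$genes$strain_id)
  orders <- list(strains, rev(strains), strains[c(2, 3, 1)],
                 strains[c(2, 1, 3)], strains[c(3, 1, 2)],
                 strains[c(1, 3, 2)])
  partitions <- lapply(orders, function(o) {
    td <- tidy(build_pan_pool(sim, strain_order = o))
    # compare as sets of gene-id groups, which are order-invariant
    unname(lapply(split(td$gene_id, td$cluster_id), sort))
  })
  canon <- function(p) p[order(vapply(p, `[`, "", 1))]
  for (p in partitions[-1]) {
    expect_equal(canon(p), canon(partitions[[1]]))
  }
})

test_that("every input gene lands in exactly one cluster", {
  sim <- tiny_sim(divergence = 0.05, seed = 13)
  pg <- build_pan_pool(sim)
  expect_equal(sum(pg$cluster_info$n_members), nrow(sim$genes))
  expect_setequal(pg$clusters$gene_id, sim$genes$gene_id)
  expect_equal(anyDuplicated(pg$clusters[, c("strain_id", "gene_id")]), 0L)
  # reference-strain genes all present
  ref <- pg$strain_order[1]
  expect_setequal(pg$clusters$gene_id[pg$clusters$strain_id == ref],
                  sim$genes$gene_id[sim$genes$strain_id == ref])
})

test_that("clustering agrees with single linkage on diverged, well-separated families", {
  sim <- tiny_sim(divergence = 0.1, seed = 46)
  th <- homology_thresholds()
  sc <- scoring_scheme("nucleotide")
  pg <- build_pan_pool(sim, th = th, scoring = sc)
  oracle <- single_linkage_clusters(sim$genes, th, sc)
  expect_equal(sort(unname(unlist(oracle_partition(oracle, 3)))),
               sort(unname(unlist(partition_counts(pg)))))
})

test_that("query-strain paralogs join clusters; reference paralogs stay singletons", {
  p <- sim_params(n_strains = 3, n_core = 5, n_specific_per_strain = 0,
                  gene_length_range = c(150, 300), divergence = 0,
                  paralog_rate = 1, seed = 71)
  sim <- simulate_pangenome(p) # every strain carries 2 copies per family
  pg <- build_pan_pool(sim)
  pc <- partition_counts(pg)
  # the reference contributes 10 pool genes: 5 gather the query strains'
  # copies (core), 5 duplicate founders stay reference-only singletons
  expect_equal(pc$core, 5)
  expect_equal(pc$specific, 5)
  expect_equal(sum(pg$cluster_info$n_members), nrow(sim$genes))
  # query-strain paralogs never found clusters: no cluster is owned by a
  # non-reference strain
  ref <- pg$strain_order[1]
  spec <- pg$cluster_info$cluster_id[pg$cluster_info$class == "specific"]
  owners <- unique(pg$clusters$strain_id[pg$clusters$cluster_id %in% spec])
  expect_equal(owners, ref)
  # clusters never mix families
  td <- dplyr::left_join(tidy(pg), sim$truth, by = "gene_id")
  expect_true(all(rowSums(table(td$cluster_id, td$family_id) > 0) == 1))
})

test_that("partition counting and the core fraction follow their definitions", {
  # synthetic result with presence sizes {3,3,2,1,1} over 3 strains
  fake <- structure(list(
    clusters = tibble::tibble(
      cluster_id = c(rep("cl1", 3), rep("cl2", 3), rep("cl3", 2), "cl4", "cl5"),
      strain_id = c("a", "b", "c", "a", "b", "c", "a", "b", "c", "a"),
      gene_id = paste0("g", 1:10)),
    cluster_info = tibble::tibble(
      cluster_id = paste0("cl", 1:5),
      founder_gene_id = paste0("g", c(1, 4, 7, 9, 10)),
      n_members = c(3L, 3L, 2L, 1L, 1L),
      n_strains_present = c(3L, 3L, 2L, 1L, 1L),
      class = c("core", "core", "dispensable", "specific", "specific")),
    n_strains = 3L, strain_order = c("a", "b", "c")),
    class = "pan_genome")
  pc <- partition_counts(fake)
  expect_equal(unlist(pc), c(core = 2, dispensable = 1, specific = 2, total = 5),
               ignore_attr = TRUE)

  # empty result
  empty <- fake
  empty$clusters <- fake$clusters[0, ]
  empty$cluster_info <- fake$cluster_info[0, ]
  expect_equal(unlist(partition_counts(empty)),
               c(core = 0, dispensable = 0, specific = 0, total = 0),
               ignore_attr = TRUE)

  expect_equal(core_fraction(5047, 15404), 32.8)
  expect_equal(core_fraction(0, 100), 0.0)
  expect_equal(core_fraction(7, 9), 77.8)
  expect_error(core_fraction(1, 0), class = "panstrep_validation_error")
})

test_that("flower counts report the core centre and per-strain petals", {
  sim <- tiny_sim(divergence = 0, seed = 31)
  fc <- flower_counts(build_pan_pool(sim))
  expect_equal(fc$n[fc$strain_id == "(core)"], 3L)
  expect_equal(sum(fc$n[fc$strain_id != "(core)"]), 6L)
})

test_that("input validation rejects malformed gene sets", {
  expect_error(build_pan_pool(tibble::tibble(strain_id = character(0),
                                             gene_id = character(0),
                                             sequence = character(0))),
               class = "panstrep_validation_error")
  dup <- tibble::tibble(strain_id = c("s1", "s1"), gene_id = c("g", "g"),
                        sequence = c("ACGTACGT", "ACGTACGT"))
  expect_error(build_pan_pool(dup), class = "panstrep_validation_error")
})
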