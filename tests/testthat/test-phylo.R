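test_that("jaccard profile distance matches set-count arithmetic", {
  m <- rbind(s1 = c(1, 1, 1, 0), s2 = c(0, 1, 1, 1))
  expect_equal(as.numeric(profile_distance(m)), 0.5) # 1 - 2/4
  ident <- rbind(a = c(1, 0, 1), b = c(1, 0, 1))
  expect_equal(as.numeric(profile_distance(ident)), 0)
  disjoint <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(as.numeric(profile_distance(disjoint)), 1)
  expect_error(profile_distance(rbind(a = c(1, 0), b = c(0, 0))),
               class = "panstrep_validation_error")
})

test_that("profile distance is a metric on small presence matrices", {
  set.seed(19)
  for (rep in 1:5) {
    m <- matrix(rbinom(6 * 12, 1, 0.6), nrow = 6,
                dimnames = list(paste0("s", 1:6), NULL))
    m[rowSums(m) == 0, 1] <- 1
    m <- m[, colSums(m) > 0, drop = FALSE]
    d <- as.matrix(profile_distance(m))
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 6))
  }
})

test_that("neighbor joining reproduces an additive 4-taxon tree exactly", {
  # known tree: ((A:1,B:2):5,(C:3,D:4)); path lengths are additive
  labs <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 1 + 2
  d["A", "C"] <- d["C", "A"] <- 1 + 5 + 3
  d["A", "D"] <- d["D", "A"] <- 1 + 5 + 4
  d["B", "C"] <- d["C", "B"] <- 2 + 5 + 3
  d["B", "D"] <- d["D", "B"] <- 2 + 5 + 4
  d["C", "D"] <- d["D", "C"] <- 3 + 4
  tree <- neighbor_joining(d)
  expect_s3_class(tree, "phylo")
  expect_setequal(tree$tip.label, labs)
  # additivity oracle: recompute path lengths from the output tree
  back <- ape::cophenetic.phylo(tree)[labs, labs]
  expect_equal(back, d, tolerance = 1e-9)
  expect_false(attr(tree, "clamped"))
})

test_that("degenerate matrices resolve to the closed-form trees", {
  # 2 taxa at distance 6: single edge, pendants of 3
  d2 <- matrix(c(0, 6, 6, 0), 2, 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- neighbor_joining(d2)
  expect_equal(sort(t2$edge.length), c(3, 3))
  expect_setequal(t2$tip.label, c("x", "y"))
  expect_identical(ape::write.tree(t2), ape::write.tree(ape::read.tree(
    text = ape::write.tree(t2))))

  # 3 equidistant taxa (d = 2): star with pendant lengths 1
  d3 <- matrix(2, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d3) <- 0
  t3 <- neighbor_joining(d3)
  expect_equal(unname(t3$edge.length), rep(1, 3))
})

test_that("malformed distance input is rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(neighbor_joining(bad), class = "panstrep_validation_error")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(neighbor_joining(neg), class = "panstrep_validation_error")
})

test_that("negative NJ branch lengths are clamped and flagged", {
  # strongly non-additive matrix known to produce a negative NJ edge
  labs <- paste0("t", 1:4)
  d <- matrix(c(0, 1, 10, 10,
                1, 0, 10, 10,
                10, 10, 0, 0.1,
                10, 10, 0.1, 0), 4, 4, dimnames = list(labs, labs))
  d[1, 4] <- d[4, 1] <- 2
  expect_warning(tree <- neighbor_joining(d), "clamped")
  expect_true(attr(tree, "clamped"))
  expect_true(all(tree$edge.length >= 0))
})

test_that("ANI distances transform percent identity to [0, 1]", {
  labs <- c("a", "b")
  m <- matrix(c(100, 97.4, 97.4, 100), 2, 2, dimnames = list(labs, labs))
  expect_equal(as.numeric(ani_distance(m)), 0.026)
  m2 <- matrix(c(100, 80, 80, 100), 2, 2, dimnames = list(labs, labs))
  expect_equal(as.numeric(ani_distance(m2)), 0.2)
  expect_equal(as.numeric(ani_distance(matrix(100, 2, 2,
    dimnames = list(labs, labs)))), 0)
  m[1, 2] <- NA
  expect_error(ani_distance(m), class = "panstrep_validation_error")
})

test_that("pan-genome trees carry all strains and round-trip through Newick", {
  sim <- simulate_pangenome(sim_params(n_strains = 5, n_core = 4,
                                       dispensable_spec = list(c(3, 2), c(2, 3)),
                                       n_specific_per_strain = 2,
                                       gene_length_range = c(150, 300),
                                       seed = 27))
  pg <- build_pan_pool(sim)
  tree <- pan_genome_tree(pg)
  expect_setequal(tree$tip.label, unique(sim$genes$strain_id))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(tree, path)
  nwk1 <- readLines(path)
  reread <- ape::read.tree(path)
  path2 <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(reread, path2)
  expect_identical(nwk1, readLines(path2)) # byte-stable round trip
})
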