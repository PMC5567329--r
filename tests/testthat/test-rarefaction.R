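pg_fixture <- function(seed = 31, divergence = 0) {
  build_pan_pool(tiny_sim(divergence = divergence, seed = seed))
}

test_that("identical strains give flat pan and core curves", {
  set.seed(1)
  g1 <- tibble::tibble(strain_id = "s1", gene_id = paste0("g", 1:5),
                       sequence = replicate(5, random_dna(200)))
  genes <- dplyr::bind_rows(g1, dplyr::mutate(g1, strain_id = "s2"),
                            dplyr::mutate(g1, strain_id = "s3"))
  pg <- build_pan_pool(genes)
  rc <- rarefy(pg, n_perm = 6, seed = 2)
  expect_true(all(rc$pan == 5))
  expect_true(all(rc$core == 5))
})

test_that("sampled permutations match exhaustive enumeration when n_perm >= N!", {
  pg <- pg_fixture()
  rc <- rarefy(pg, n_perm = 6, seed = 9)
  expect_equal(attr(rc, "permutations"), 6L)
  # curves per permutation are exactly the 6 orderings' prefix counts
  m <- presence_matrix(pg)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  expected <- lapply(perms, function(p) {
    sapply(1:3, function(n) {
      sub <- m[p[seq_len(n)], , drop = FALSE]
      c(pan = sum(colSums(sub) > 0), core = sum(colSums(sub) == n))
    })
  })
  got <- lapply(split(as.data.frame(rc)[, c("pan", "core")], rc$perm),
                function(d) t(as.matrix(d)))
  canon <- function(l) l[order(sapply(l, paste, collapse = ","))]
  expect_equal(canon(unname(expected)), canon(unname(got)),
               ignore_attr = TRUE)
})

test_that("prefix set algebra forces pan monotone up and core monotone down", {
  pg <- pg_fixture(seed = 77, divergence = 0.05)
  rc <- rarefy(pg, n_perm = 6, seed = 3)
  for (k in unique(rc$perm)) {
    sub <- rc[rc$perm == k, ]
    expect_true(all(diff(sub$pan) >= 0))
    expect_true(all(diff(sub$core) <= 0))
    expect_equal(sub$pan[1], sub$core[1]) # pan(1) == core(1)
  }
  # endpoints equal the full partition for every permutation
  pc <- partition_counts(pg)
  ends <- rc[rc$n == attr(rc, "n_strains"), ]
  expect_true(all(ends$pan == pc$total))
  expect_true(all(ends$core == pc$core))
})

test_that("permutation sampling is seed-deterministic", {
  sim <- simulate_pangenome(sim_params(n_strains = 6, n_core = 4,
                                       n_specific_per_strain = 2,
                                       gene_length_range = c(150, 300),
                                       seed = 20))
  pg <- build_pan_pool(sim)
  r1 <- rarefy(pg, n_perm = 10, seed = 42)
  r2 <- rarefy(pg, n_perm = 10, seed = 42)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_error(rarefy(pg, n_perm = 0), class = "panstrep_validation_error")
})

test_that("core decay fit recovers parameters from self-generated curves", {
  n <- 1:9
  med <- data.frame(n = n, core = 200 * exp(-n / 2) + 5000,
                    pan = 200 * exp(-n / 2) + 5000)
  fit <- fit_core_decay(med)
  expect_true(fit$converged)
  expect_lt(abs(fit$parameters$omega - 5000) / 5000, 0.01)

  # constant curve: degenerate fit
  flat <- data.frame(n = n, core = 5000, pan = 5000)
  ffit <- fit_core_decay(flat)
  expect_true(ffit$converged)
  expect_equal(ffit$parameters$omega, 5000)
  expect_equal(ffit$parameters$A, 0)

  expect_error(fit_core_decay(data.frame(n = 1:2, core = c(2, 1), pan = c(2, 3))),
               class = "panstrep_validation_error")
})

test_that("core decay omega is recovered within 5% under 1% noise", {
  n <- 1:9
  true_omega <- 5000
  base <- 1500 * exp(-n / 2) + true_omega
  set.seed(7)
  errs <- replicate(100, {
    med <- data.frame(n = n, core = base + rnorm(9, 0, 0.01 * true_omega),
                      pan = base)
    fit <- fit_core_decay(med)
    abs(fit$parameters$omega - true_omega) / true_omega
  })
  expect_lt(max(errs), 0.05)
})

test_that("pan power-law fit recovers gamma and classifies openness", {
  n <- 1:9
  med <- data.frame(n = n, pan = 3000 * n^0.5, core = 3000)
  fit <- fit_pan_growth(med)
  expect_lt(abs(fit$parameters$gamma - 0.5) / 0.5, 0.02)
  expect_true(fit$open)

  flat <- data.frame(n = n, pan = 4000, core = 4000)
  ffit <- fit_pan_growth(flat)
  expect_lt(abs(ffit$parameters$gamma), 1e-8)
  expect_false(ffit$open)

  # zero-divergence simulation with specific genes is necessarily open
  rc <- rarefy(pg_fixture(seed = 31), n_perm = 6, seed = 5)
  expect_true(fit_pan_growth(rc)$open)
})

test_that("tidiers expose medians, parameters and fit diagnostics", {
  rc <- rarefy(pg_fixture(seed = 31), n_perm = 6, seed = 5)
  td <- tidy(rc)
  expect_setequal(names(td), c("n", "genome", "size"))
  fit <- fit_core_decay(rc)
  expect_setequal(tidy(fit)$term, c("A", "tau", "omega"))
  g <- glance(fit_pan_growth(rc))
  expect_true(all(c("model", "rss", "converged", "open") %in% names(g)))
})
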