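#' Pan/core rarefaction (dilution) curves
#'
#' For sampled orderings of the strains, computes for every prefix of n
#' strains the pan-genome size (clusters present in at least one of the
#' first n strains) and core-genome size (clusters present in all of the
#' first n strains). Within every permutation the pan curve is
#' non-decreasing and the core curve non-increasing, and the two coincide
#' at n = 1.
#'
#' When `n_perm` is at least the number of distinct orderings (N!), all
#' orderings are enumerated exactly once; otherwise `n_perm` orderings are
#' sampled uniformly with a seeded generator.
#'
#' @param result A `pan_genome` object from [build_pan_pool()].
#' @param n_perm Number of permutations (default `min(N!, 200)`).
#' @param seed RNG seed for permutation sampling.
#' @return A tibble of class `rarefaction_curve` with columns `perm`, `n`,
#'   `pan`, `core`, and attributes `n_strains`, `permutations`, `seed`.
#' @examples
#' sim <- simulate_pangenome(sim_params(n_strains = 3, n_core = 4,
#'                                      n_specific_per_strain = 1,
#'                                      gene_length_range = c(60, 120),
#'                                      seed = 7))
#' rarefy(build_pan_pool(sim), n_perm = 6, seed = 1)
#' @export
rarefy <- function(result, n_perm = NULL, seed = 1L) {
  stopifnot(inherits(result, "pan_genome"))
  N <- result$n_strains
  if (N < 2) {
    abort("rarefaction needs at least 2 strains",
          class = "panstrep_validation_error")
  }
  nfact <- factorial(N)
  if (is.null(n_perm)) n_perm <- min(nfact, 200)
  if (n_perm < 1) {
    abort("`n_perm` must be >= 1", class = "panstrep_validation_error")
  }
  m <- presence_matrix(result) # strains x clusters
  perms <- if (n_perm >= nfact) {
    all_permutations(N)
  } else {
    with_seed(seed, replicate(n_perm, sample.int(N), simplify = FALSE))
  }
  out <- purrr::imap(perms, function(p, k) {
    pm <- m[p, , drop = FALSE]
    any_so_far <- apply(pm, 2, cummax)          # n x clusters
    all_so_far <- apply(pm, 2, cummin)
    tibble(perm = k, n = seq_len(N),
           pan = as.integer(rowSums(matrix(any_so_far, nrow = N))),
           core = as.integer(rowSums(matrix(all_so_far, nrow = N))))
  }) |> bind_rows()
  structure(out,
            class = c("rarefaction_curve", class(out)),
            n_strains = N, permutations = length(perms), seed = seed)
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (p in sub) {
      i <- i + 1L
      out[[i]] <- c(first, rest[p])
    }
  }
  out
}

curve_medians <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("n", "pan", "core") %in% names(curve)))
  curve |>
    group_by(.data$n) |>
    summarise(pan = median(.data$pan), core = median(.data$core),
              .groups = "drop")
}

new_decay_fit <- function(model, parameters, rss, converged, medians, extra = list()) {
  structure(c(list(model = model, parameters = parameters, rss = rss,
                   converged = converged, medians = medians), extra),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> model=%s converged=%s rss=%.4g\n",
              x$model, x$converged, x$rss))
  print(unlist(x$parameters))
  invisible(x)
}

#' Fit the core-genome exponential decay
#'
#' Fits the Tettelin-style decay model `C(n) = A * exp(-n / tau) + omega`
#' to the per-n medians of a core rarefaction curve by nonlinear least
#' squares ([minpack.lm::nlsLM()]). `omega` is the asymptotic core-genome
#' size the curve converges to. A constant curve is handled as the
#' degenerate fit `A = 0, omega = mean`. Optimiser failure is reported via
#' `converged = FALSE`, never as an error.
#'
#' @param curve A `rarefaction_curve` (or any data frame with `n`, `pan`,
#'   `core`) with at least 3 distinct n values.
#' @return A `decay_fit` object with `model = "core_exp_decay"`, parameters
#'   `A`, `tau`, `omega`, the residual sum of squares over the medians, and
#'   a `converged` flag. Supports [tidy()] and [glance()].
#' @examples
#' med <- data.frame(n = 1:9)
#' med$core <- 200 * exp(-med$n / 2) + 5000
#' med$pan <- med$core
#' fit_core_decay(med)
#' @export
fit_core_decay <- function(curve) {
  med <- curve_medians(curve)
  if (nrow(med) < 3) {
    abort("need at least 3 distinct n values",
          class = "panstrep_validation_error")
  }
  y <- med$core
  n <- med$n
  if (max(y) - min(y) < 1e-8 * max(1, max(abs(y)))) {
    omega <- mean(y)
    return(new_decay_fit("core_exp_decay",
                         list(A = 0, tau = 1, omega = omega),
                         rss = sum((y - omega)^2), converged = TRUE,
                         medians = med))
  }
  start <- list(A = max(y) - min(y),
                tau = diff(range(n)) / 3,
                omega = max(min(y), 1e-8))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ A * exp(-n / tau) + omega,
                      data = data.frame(n = n, y = y),
                      start = start,
                      lower = c(A = 0, tau = 1e-9, omega = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_decay_fit("core_exp_decay",
                         c(start, list()), rss = NA_real_,
                         converged = FALSE, medians = med))
  }
  p <- as.list(coef(fit))
  rss <- sum(stats::resid(fit)^2)
  # a perfect fit can exhaust the iteration cap while chasing zero residual;
  # call that converged when the RMSE is negligible on the data's scale
  converged <- isTRUE(fit$convInfo$isConv) ||
    sqrt(rss / length(y)) < 1e-6 * max(1, diff(range(y)))
  new_decay_fit("core_exp_decay",
                list(A = p$A, tau = p$tau, omega = p$omega),
                rss = rss, converged = converged, medians = med)
}

#' Fit pan-genome growth (Heaps-style power law)
#'
#' Fits `P(n) = K * n^gamma` to the per-n medians of a pan rarefaction
#' curve by linear least squares on the log-log scale. The pan-genome is
#' classified *open* when the fitted exponent `gamma` is positive and its
#' 95% confidence interval excludes zero, and *closed* otherwise — an open
#' pan-genome keeps growing as strains are added.
#'
#' @param curve As in [fit_core_decay()].
#' @return A `decay_fit` object with `model = "pan_power_law"`, parameters
#'   `K` and `gamma`, `gamma_se`, an `open` flag, the residual sum of
#'   squares on the original scale, and `converged`.
#' @examples
#' med <- data.frame(n = 1:9)
#' med$pan <- 3000 * med$n^0.5
#' med$core <- med$pan
#' fit_pan_growth(med)
#' @export
fit_pan_growth <- function(curve) {
  med <- curve_medians(curve)
  if (nrow(med) < 3) {
    abort("need at least 3 distinct n values",
          class = "panstrep_validation_error")
  }
  if (any(med$pan <= 0)) {
    abort("pan sizes must be positive for the power-law fit",
          class = "panstrep_validation_error")
  }
  fit <- lm(log(pan) ~ log(n), data = med)
  gamma <- unname(coef(fit)[2])
  K <- exp(unname(coef(fit)[1]))
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  df <- fit$df.residual
  # the absolute floor keeps a numerically flat curve (slope ~ 1e-16 with a
  # vanishing s.e.) from being called open
  open <- gamma > 1e-6 &&
    (is.nan(se) || se == 0 || gamma - qt(0.975, df) * se > 0)
  pred <- K * med$n^gamma
  new_decay_fit("pan_power_law",
                list(K = K, gamma = gamma),
                rss = sum((med$pan - pred)^2),
                converged = TRUE, medians = med,
                extra = list(gamma_se = se, open = open))
}
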