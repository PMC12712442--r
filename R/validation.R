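## Simulation studies that validate the estimators against known truth:
## phylogenetic-signal recovery, quantile-regression parameter recovery and
## HDI calibration, and the phylogenetic-attenuation contrast (a spurious
## cross-species slope created purely by deep shared ancestry should be
## absorbed by the phylogenetic random effect).

#' Recovery study for Pagel's lambda and Blomberg's K
#'
#' Simulates traits at each `lambda` on independent pure-birth trees and
#' re-estimates lambda by maximum likelihood; under pure Brownian motion
#' (lambda = 1) Blomberg's K is also computed, whose expectation is near 1.
#'
#' @param n_trees number of replicate trees per lambda.
#' @param n_tips tips per tree.
#' @param lambdas generating lambda values.
#' @param seed integer seed.
#' @return list: `lambda_mean` (named by generating value), `lambda_hat`
#'   (matrix), `k_values`, `k_mean`.
#' @export
validate_signal_recovery <- function(n_trees = 100, n_tips = 200,
                                     lambdas = c(0, 0.5, 1), seed = 1) {
  lam_hat <- matrix(NA_real_, n_trees, length(lambdas),
                    dimnames = list(NULL, as.character(lambdas)))
  k_vals <- numeric(n_trees)
  for (t in seq_len(n_trees)) {
    tr <- sim_tree(n_tips, 1, seed = seed * 1000L + t)
    C <- phylo_vcv(tr)
    for (j in seq_along(lambdas)) {
      x <- sim_bm_traits(tr, sigma2 = 1, lambda = lambdas[j], root = 0,
                         seed = seed * 1000L + t * 10L + j)
      lam_hat[t, j] <- pagel_lambda_ml(x, C)$estimate
      if (lambdas[j] == 1) {
        ch <- chol_safe(C); M <- chol2inv(ch)
        k_vals[t] <- k_statistic(x, M, rowSums(M), sum(diag(C)), n_tips)
      }
    }
  }
  list(lambda_mean = colMeans(lam_hat), lambda_hat = lam_hat,
       k_values = k_vals, k_mean = mean(k_vals))
}

#' Null calibration of the K permutation test
#'
#' Brownian traits are shuffled across tips (destroying all signal) and the
#' permutation p-value recomputed; under this null the p-values should be
#' uniform.
#'
#' @param n_rep replicates.
#' @param n_tips tips per tree.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @return numeric vector of p-values.
#' @export
validate_k_null <- function(n_rep = 200, n_tips = 200, n_perm = 999, seed = 1) {
  vapply(seq_len(n_rep), function(r) {
    tr <- sim_tree(n_tips, 1, seed = seed * 2000L + r)
    C <- phylo_vcv(tr)
    x <- sim_bm_traits(tr, 1, 1, 0, seed = seed * 2000L + r + 1L)
    set.seed(seed * 2000L + r + 2L)
    x <- x[sample.int(n_tips)]            # tip shuffle: the no-signal null
    blomberg_k(unname(x), C, n_perm = n_perm, seed = seed * 2000L + r + 3L)$p_vs_0
  }, numeric(1))
}

#' Recovery and calibration study for the quantile regression
#'
#' Simulates grouped datasets at each quantile level with known group lines
#' and asymmetric-Laplace noise, fits the non-phylogenetic model, and records
#' per-group posterior means, HDI coverage of the generating slope, and the
#' fraction of observations below the fitted line.
#'
#' @param taus quantile levels.
#' @param n_rep fits per quantile level.
#' @param n observations per dataset.
#' @param alpha,beta,sigma generating parameters (see [sim_qr_dataset()]).
#' @param chains,iter,warmup MCMC layout per fit.
#' @param seed integer seed.
#' @return data.frame with one row per fit x group: `tau`, `rep`, `group`,
#'   `beta_true`, `beta_mean`, `hdi_lo`, `hdi_hi`, `covered`, `below_frac`.
#' @export
validate_qr_recovery <- function(taus = c(0.1, 0.5, 0.9), n_rep = 34, n = 300,
                                 alpha = c(-30, -20, -10),
                                 beta = c(-2.5, -1.5, -0.5), sigma = 3,
                                 chains = 2, iter = 2500, warmup = 1000,
                                 seed = 1) {
  out <- list()
  for (ti in seq_along(taus)) {
    tau <- taus[ti]
    for (r in seq_len(n_rep)) {
      s <- seed * 10000L + ti * 1000L + r
      d <- sim_qr_dataset(n = n, alpha = alpha, beta = beta, tau = tau,
                          sigma = sigma, seed = s)
      fit <- pqreg(y ~ x, d$data, group = "group", tau = tau, chains = chains,
                   iter = iter, warmup = warmup, seed = s, warn = FALSE)
      m <- as.matrix(fit)
      below <- mean(residuals(fit) < 0)
      for (g in seq_along(fit$groups)) {
        b <- m[, paste0("beta.", fit$groups[g])]
        h <- hdi(b)
        out[[length(out) + 1]] <- data.frame(
          tau = tau, rep = r, group = fit$groups[g], beta_true = beta[g],
          beta_mean = mean(b), hdi_lo = h[1], hdi_hi = h[2],
          covered = h[1] <= beta[g] && beta[g] <= h[2],
          below_frac = below)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## two pure-birth crowns of unit height on long basal stems: the canonical
## deep-divergence geometry behind phylogenetically spurious correlations
two_clade_tree <- function(n_per_clade = 40, stem = 12, crown = 1, seed = 1) {
  scale_to <- function(tr, h) {
    tr$edge.length <- tr$edge.length / max(diag(ape::vcv.phylo(tr))) * h
    tr
  }
  t1 <- scale_to(sim_tree(n_per_clade, 1, seed = seed), crown)
  t2 <- scale_to(sim_tree(n_per_clade, 1, seed = seed + 1L), crown)
  t1$tip.label <- sprintf("CladeA%02d_sp", seq_len(n_per_clade))
  t2$tip.label <- sprintf("CladeB%02d_sp", seq_len(n_per_clade))
  t1$root.edge <- stem
  t2$root.edge <- stem
  ape::bind.tree(t1, t2, position = stem)
}

#' Phylogenetic attenuation of a spurious cross-species slope
#'
#' Fixed-confound-strength design: the two clades of a deep two-clade tree
#' are displaced by the same fixed offset `delta` in both traits (their
#' shared deep history), while crown-level evolution of x and y is
#' independent Brownian motion and there is no causal slope. Across species
#' the traits therefore covary strongly -- but only through shared ancestry.
#' Each replicate fits the median regression with and without the
#' phylogenetic random effect; the attenuation event of interest is the
#' phylogenetic model's slope HDI covering zero while the non-phylogenetic
#' model's excludes it. Fixing `delta` (rather than drawing the deep offsets
#' at random) fixes the effect size of the confound, as in a power study;
#' the check is about attenuation of a realized confound, not about how
#' often deep divergences produce one.
#'
#' @param n_rep replicates.
#' @param n_per_clade tips per clade.
#' @param stem basal stem length (crown height is 1).
#' @param delta between-clade displacement applied to both traits, in
#'   within-clade SD units (default 5: a deep divergence dominating crown
#'   variation).
#' @param sigma residual AL scale on y.
#' @param chains,iter,warmup MCMC layout per fit.
#' @param seed integer seed.
#' @return data.frame per replicate: slope HDIs of both models, `nonphylo_excludes_0`,
#'   `phylo_covers_0`, `attenuated`.
#' @export
validate_phylo_attenuation <- function(n_rep = 50, n_per_clade = 40, stem = 12,
                                       delta = 5, sigma = 0.3, chains = 2,
                                       iter = 2500, warmup = 1000, seed = 1) {
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    s <- seed * 5000L + r * 10L
    tr <- two_clade_tree(n_per_clade, stem = stem, seed = s)
    clade <- ifelse(grepl("^CladeA", tr$tip.label), 1, -1)
    deep <- clade * delta / 2
    x <- sim_bm_traits(tr, 1, 1, 0, seed = s + 1L)
    u <- sim_bm_traits(tr, 1, 1, 0, seed = s + 2L)
    # crown-only BM: remove each clade's own mean, then add the fixed shared
    # deep offsets to both traits
    x <- unname(x) - ave(unname(x), clade) + deep
    set.seed(s + 3L)
    y <- unname(u) - ave(unname(u), clade) + deep +
      ral(length(u), 0, sigma, 0.5)
    d <- data.frame(species = tip_species(tr), x = x, y = y,
                    stringsAsFactors = FALSE)
    f_np <- pqreg(y ~ x, d, tau = 0.5, chains = chains, iter = iter,
                  warmup = warmup, seed = s + 4L, warn = FALSE)
    f_ph <- pqreg(y ~ x, d, tau = 0.5, tree = tr, chains = chains, iter = iter,
                  warmup = warmup, seed = s + 4L, warn = FALSE)
    h_np <- hdi(as.matrix(f_np)[, "beta.all"])
    h_ph <- hdi(as.matrix(f_ph)[, "beta.all"])
    out[[r]] <- data.frame(rep = r,
                           np_lo = h_np[1], np_hi = h_np[2],
                           ph_lo = h_ph[1], ph_hi = h_ph[2],
                           nonphylo_excludes_0 = h_np[1] > 0 || h_np[2] < 0,
                           phylo_covers_0 = h_ph[1] <= 0 && 0 <= h_ph[2])
  }
  res <- do.call(rbind, out)
  res$attenuated <- res$nonphylo_excludes_0 & res$phylo_covers_0
  rownames(res) <- NULL
  res
}
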