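## Phylogenetic signal statistics: Blomberg's K with a tip-permutation test
## and Pagel's lambda by profile maximum likelihood, plus Brownian-motion
## ancestral state estimates. x must be aligned with the rows of C.

## core K statistic given precomputed C^-1 (M) and w = C^-1 1
k_statistic <- function(x, M, w, trC, n) {
  s <- sum(w)
  a <- sum(w * x) / s
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- (drop(crossprod(x, M %*% x)) - a^2 * s) / (n - 1)
  e_bm <- (trC - n / s) / (n - 1)
  (mse0 / mse) / e_bm
}

#' Blomberg's K with permutation test
#'
#' K compares the observed ratio of trait variance to
#' phylogenetically-corrected variance with its Brownian-motion expectation;
#' K = 1 is the BM benchmark, values near 0 indicate little resemblance among
#' relatives. Significance against the no-signal null is assessed by
#' permuting trait values across tips (`(1 + b) / (1 + B)` convention).
#'
#' @param x trait vector aligned with `C` (names checked when present).
#' @param C phylogenetic covariance from [phylo_vcv()].
#' @param n_perm number of tip permutations (default 1000).
#' @param seed optional RNG seed for the permutations.
#' @return object of class `signal_result` with `estimate`, `p_vs_0`, `n`.
#' @export
blomberg_k <- function(x, C, n_perm = 1000, seed = NULL) {
  n <- length(x)
  stopifnot(n >= 4, nrow(C) == n)
  if (!is.null(names(x)) && !is.null(rownames(C)))
    stopifnot(identical(canonical_species(names(x)), rownames(C)))
  if (stats::var(x) == 0) stop("trait has zero variance")
  ch <- chol_safe(C)
  M <- chol2inv(ch)
  w <- rowSums(M)
  trC <- sum(diag(C))
  k_obs <- k_statistic(x, M, w, trC, n)
  if (!is.null(seed)) set.seed(as.integer(seed))
  X <- vapply(seq_len(n_perm), function(i) x[sample.int(n)], numeric(n))
  s <- sum(w)
  a_p <- colSums(w * X) / s
  mse0_p <- (colSums(X^2) - 2 * a_p * colSums(X) + n * a_p^2) / (n - 1)
  mse_p <- (colSums(X * (M %*% X)) - a_p^2 * s) / (n - 1)
  e_bm <- (trC - n / s) / (n - 1)
  k_perm <- (mse0_p / mse_p) / e_bm
  p <- (1 + sum(k_perm >= k_obs)) / (1 + n_perm)
  structure(list(statistic = "K", estimate = k_obs, p_vs_0 = p, p_vs_1 = NA_real_,
                 n = n, n_permutations = n_perm),
            class = "signal_result")
}

## profile log-likelihood of lambda (GLS mean and variance profiled out)
lambda_loglik <- function(lambda, x, C) {
  n <- length(x)
  Cl <- lambda_transform(C, lambda)
  ch <- chol_safe(Cl)
  logdet <- 2 * sum(log(diag(ch)))
  z <- forwardsolve(t(ch), x)
  one <- forwardsolve(t(ch), rep(1, n))
  a <- sum(one * z) / sum(one^2)
  r <- z - a * one
  s2 <- sum(r^2) / n
  -0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Pagel's lambda by maximum likelihood
#'
#' Maximizes the multivariate-normal profile likelihood of the
#' lambda-transformed Brownian covariance over \[0, 1\] (bounded search,
#' tolerance 1e-6, endpoints checked). Likelihood-ratio tests against
#' lambda = 0 (no signal) and lambda = 1 (Brownian motion) use the chi-square
#' reference with one degree of freedom, as is conventional despite the
#' boundary.
#'
#' @inheritParams blomberg_k
#' @return `signal_result` with `estimate`, `p_vs_0`, `p_vs_1`, `logLik`,
#'   `logLik0`, `logLik1`, and a `flat_profile` flag.
#' @export
pagel_lambda_ml <- function(x, C) {
  n <- length(x)
  stopifnot(n >= 4, nrow(C) == n)
  if (stats::var(x) == 0) stop("trait has zero variance")
  ll <- function(l) lambda_loglik(l, x, C)
  opt <- stats::optimize(ll, c(0, 1), maximum = TRUE, tol = 1e-6)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, ll(0)), c(1, ll(1)))
  best <- cand[which.max(cand[, 2]), ]
  lam <- best[1]; llhat <- best[2]
  ll0 <- cand[2, 2]; ll1 <- cand[3, 2]
  flat <- diff(range(cand[, 2])) < 1e-8
  structure(list(statistic = "lambda", estimate = lam,
                 p_vs_0 = stats::pchisq(2 * (llhat - ll0), 1, lower.tail = FALSE),
                 p_vs_1 = stats::pchisq(2 * (llhat - ll1), 1, lower.tail = FALSE),
                 n = n, logLik = llhat, logLik0 = ll0, logLik1 = ll1,
                 flat_profile = flat),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Phylogenetic signal (%s): %.4g  [n = %d]\n",
              x$statistic, x$estimate, x$n))
  cat(sprintf("  P vs 0: %.4g", x$p_vs_0))
  if (!is.na(x$p_vs_1)) cat(sprintf("   P vs 1: %.4g", x$p_vs_1))
  cat("\n")
  if (isTRUE(x$flat_profile)) cat("  (flat likelihood profile)\n")
  invisible(x)
}

#' Signal results as a summary table
#'
#' Collects `signal_result` objects into the conventional
#' trait-by-method table (estimate, P vs 0, P vs 1, n).
#'
#' @param ... named `signal_result` objects; names become the `trait` column.
#' @return data.frame with columns `trait`, `method`, `estimate`, `p_vs_0`,
#'   `p_vs_1`, `n`.
#' @export
signal_table <- function(...) {
  rs <- list(...)
  do.call(rbind, lapply(names(rs), function(nm) {
    r <- rs[[nm]]
    data.frame(trait = nm, method = r$statistic, estimate = r$estimate,
               p_vs_0 = r$p_vs_0, p_vs_1 = r$p_vs_1, n = r$n,
               stringsAsFactors = FALSE)
  }))
}

#' Brownian-motion ancestral states
#'
#' The maximum-likelihood state of each internal node under Brownian motion,
#' computed as the GLS (phylogenetically weighted) mean of the tip values on
#' the tree re-rooted at that node. The root estimate therefore equals
#' `phylo_weighted_mean(x, phylo_vcv(tree))` exactly.
#'
#' @param x trait vector named by species (canonical binomials) or in tip
#'   order.
#' @param tree `ape::phylo`.
#' @return numeric vector of estimates named by internal node number.
#' @export
bm_ancestral_states <- function(x, tree) {
  n <- ape::Ntip(tree)
  if (!is.null(names(x))) {
    idx <- match(tip_species(tree), canonical_species(names(x)))
    stopifnot(!anyNA(idx))
    x <- x[idx]
  }
  stopifnot(length(x) == n)
  nodes <- n + seq_len(tree$Nnode)
  root <- n + 1L
  est <- vapply(nodes, function(nd) {
    tr <- if (nd == root) tree else ape::root(tree, node = nd, resolve.root = FALSE)
    ord <- match(tr$tip.label, tree$tip.label)
    phylo_weighted_mean(x[ord], ape::vcv.phylo(tr))
  }, numeric(1))
  names(est) <- nodes
  est
}
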