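## Bayesian mixed-effects quantile regression with an asymmetric Laplace
## likelihood, group-specific intercepts and slopes, and an optional
## phylogenetic random effect u ~ MVN(0, sigma_p^2 C_std), where C_std is the
## Brownian covariance scaled to unit maximum diagonal so sigma_p is in
## response units.
##
## Sampler: adaptive random-walk Metropolis-within-Gibbs for (alpha_g, beta_g)
## blocks and the log-scales, elliptical slice sampling for the phylogenetic
## effects (exact, tuning-free given the prior).

#' Prior scales for [pqreg()]
#'
#' Weakly informative, scale-aware defaults: intercepts and slopes get
#' Normal(0, 10 SD(y)) (slopes divided by SD(x)); the residual AL scale gets a
#' half-Student-t(3, 0, 2.5 SD(y)); the phylogenetic SD gets a
#' half-Normal(0, SD(y)).
#'
#' @param coef_factor multiplier on SD(y) for coefficient prior SDs.
#' @param sigma_df,sigma_factor degrees of freedom and SD(y) multiplier of the
#'   half-t prior on sigma.
#' @param sigma_p_factor SD(y) multiplier of the half-normal prior on sigma_p.
#' @return list of class `pqreg_priors`.
#' @export
pqreg_priors <- function(coef_factor = 10, sigma_df = 3, sigma_factor = 2.5,
                         sigma_p_factor = 1) {
  structure(list(coef_factor = coef_factor, sigma_df = sigma_df,
                 sigma_factor = sigma_factor, sigma_p_factor = sigma_p_factor),
            class = "pqreg_priors")
}

## resolved prior scales for a given dataset
resolve_priors <- function(priors, y, x) {
  sy <- stats::sd(y); sx <- stats::sd(x)
  list(alpha_sd = priors$coef_factor * sy,
       beta_sd = priors$coef_factor * sy / max(sx, 1e-12),
       sigma_df = priors$sigma_df, sigma_scale = priors$sigma_factor * sy,
       sigma_p_scale = priors$sigma_p_factor * sy)
}

half_t_logpdf <- function(s, df, scale) {
  stats::dt(s / scale, df, log = TRUE) - log(scale) + log(2)
}
half_normal_logpdf <- function(s, scale) {
  stats::dnorm(s, 0, scale, log = TRUE) + log(2)
}

#' Log posterior density of the quantile-regression model
#'
#' The sum of asymmetric Laplace log-likelihood terms for
#' y_i ~ AL(alpha_g(i) + beta_g(i) x_i + u_i, sigma, tau), the multivariate
#' normal log-density of u under N(0, sigma_p^2 C_std) when phylogenetic
#' effects are present, and the log-priors. Exposed mainly for verification;
#' [pqreg()] uses the same terms internally.
#'
#' @param alpha,beta numeric vectors of per-group intercepts and slopes
#'   (length = number of group levels).
#' @param sigma AL scale, > 0.
#' @param y,x response and predictor vectors.
#' @param group integer vector of group indices (1-based) per observation.
#' @param tau quantile level.
#' @param u per-species phylogenetic effects (NULL when non-phylogenetic).
#' @param sigma_p phylogenetic SD (required with `u`).
#' @param C_std phylogenetic correlation-scale matrix (unit max diagonal).
#' @param prior_scales resolved prior scales as built internally (list with
#'   `alpha_sd`, `beta_sd`, `sigma_df`, `sigma_scale`, `sigma_p_scale`).
#' @return scalar log posterior (possibly -Inf).
#' @export
pqreg_log_posterior <- function(alpha, beta, sigma, y, x, group, tau,
                                u = NULL, sigma_p = NULL, C_std = NULL,
                                prior_scales) {
  if (sigma <= 0) return(-Inf)
  mu <- alpha[group] + beta[group] * x
  if (!is.null(u)) mu <- mu + u
  lp <- sum(al_logpdf(y, mu, sigma, tau))
  lp <- lp + sum(stats::dnorm(alpha, 0, prior_scales$alpha_sd, log = TRUE))
  lp <- lp + sum(stats::dnorm(beta, 0, prior_scales$beta_sd, log = TRUE))
  lp <- lp + half_t_logpdf(sigma, prior_scales$sigma_df, prior_scales$sigma_scale)
  if (!is.null(u)) {
    if (is.null(sigma_p) || sigma_p < 0) return(-Inf)
    ch <- chol_safe(C_std)
    z <- forwardsolve(t(ch), u)
    n <- length(u)
    lp <- lp - 0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
                        2 * n * log(sigma_p) + sum(z^2) / sigma_p^2)
    lp <- lp + half_normal_logpdf(sigma_p, prior_scales$sigma_p_scale)
  }
  lp
}

#' Bayesian (phylogenetic) mixed-effects quantile regression
#'
#' Fits the tau-th conditional quantile of a response trait as a linear
#' function of a predictor trait, with a separate intercept and slope per
#' functional group and, optionally, a phylogenetic random effect with
#' Brownian covariance. The asymmetric Laplace working likelihood makes the
#' posterior mode of the linear predictor the tau-th conditional quantile.
#'
#' @param formula two-sided formula `y ~ x` naming the response and the single
#'   predictor in `data`.
#' @param data data.frame containing the model variables.
#' @param group optional name of a grouping column (factor-like) in `data`;
#'   omitted or NULL pools all observations into one group.
#' @param tau quantile level in (0, 1).
#' @param tree optional `ape::phylo`; enables the phylogenetic random effect.
#'   `data` must then have a `species` column matching tip labels.
#' @param C optional precomputed phylogenetic covariance (alternative to
#'   `tree`), with row names matching `data$species`.
#' @param chains,iter,warmup MCMC layout (defaults 4 chains of 10000
#'   iterations, 2000 discarded as warmup).
#' @param seed integer seed; chains use seed, seed+1, ...
#' @param priors a [pqreg_priors()] object.
#' @param warn warn when any reported parameter has split-Rhat > 1.01 or
#'   ESS < 400 (default TRUE).
#' @return object of class `pqreg`; see [summary.pqreg()], [coef.pqreg()],
#'   [predict.pqreg()], [plot.pqreg()], [rope.pqreg()].
#' @examples
#' set.seed(1)
#' d <- data.frame(x = runif(80, -8, -1))
#' d$y <- -10 + 3 * d$x + ral(80, 0, 1.5, 0.5)
#' fit <- pqreg(y ~ x, d, tau = 0.5, chains = 2, iter = 1200, warmup = 400,
#'              seed = 1, warn = FALSE)
#' coef(fit)
#' @export
pqreg <- function(formula, data, group = NULL, tau = 0.5, tree = NULL, C = NULL,
                  chains = 4, iter = 10000, warmup = 2000, seed = NULL,
                  priors = pqreg_priors(), warn = TRUE) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3,
            tau > 0, tau < 1, warmup < iter, chains >= 1)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- mf[[1]]
  if (ncol(mf) != 2) stop("formula must have exactly one predictor")
  x <- mf[[2]]
  n <- length(y)
  g <- if (is.null(group)) factor(rep("all", n))
  else droplevels(factor(data[[group]]))
  gi <- as.integer(g)
  G <- nlevels(g)
  if (any(table(gi) < 3)) stop("each group needs at least 3 observations")

  phylo <- !is.null(tree) || !is.null(C)
  C_std <- NULL
  if (phylo) {
    if (!("species" %in% names(data))) stop("phylogenetic fits need a 'species' column")
    sp <- canonical_species(data$species)
    if (is.null(C)) C <- phylo_vcv(tree)
    idx <- match(sp, canonical_species(rownames(C)))
    if (anyNA(idx)) stop("species missing from covariance: ",
                         paste(sp[is.na(idx)], collapse = ", "))
    C <- C[idx, idx]
    C_std <- C / max(diag(C))
  }
  ps <- resolve_priors(priors, y, x)

  if (is.null(seed)) seed <- sample.int(1e6, 1)
  keep <- iter - warmup
  par_names <- c(paste0("alpha.", levels(g)), paste0("beta.", levels(g)), "sigma",
                 if (phylo) "sigma_p")
  npar <- length(par_names)
  draws <- array(NA_real_, dim = c(keep, chains, npar),
                 dimnames = list(NULL, NULL, par_names))
  u_mean <- if (phylo) numeric(n) else NULL

  Lc <- if (phylo) t(chol_safe(C_std)) else NULL
  C_inv <- if (phylo) chol2inv(chol_safe(C_std)) else NULL

  for (ch in seq_len(chains)) {
    res <- pqreg_chain(y, x, gi, G, tau, phylo, C_std, Lc, C_inv, ps,
                       iter, warmup, seed + ch - 1L)
    draws[, ch, ] <- res$draws
    if (phylo) u_mean <- u_mean + res$u_mean / chains
  }

  diag_tab <- mcmc_diagnostics(draws)
  if (warn) {
    bad <- diag_tab[!is.na(diag_tab$rhat) &
                      (diag_tab$rhat > 1.01 | diag_tab$ess < 400), ]
    if (nrow(bad))
      warning("convergence concerns (Rhat > 1.01 or ESS < 400) for: ",
              paste(bad$parameter, collapse = ", "))
  }

  structure(list(call = match.call(), formula = formula, tau = tau,
                 phylo = phylo, groups = levels(g), n = n,
                 data = list(y = y, x = x, group = g,
                             species = if (phylo) canonical_species(data$species)),
                 draws = draws, u_mean = u_mean, diagnostics = diag_tab,
                 priors = priors, prior_scales = ps, C_std = C_std,
                 chains = chains, iter = iter, warmup = warmup, seed = seed),
            class = "pqreg")
}

## one MCMC chain; returns kept draws (matrix) and posterior-mean u
pqreg_chain <- function(y, x, gi, G, tau, phylo, C_std, Lc, C_inv, ps,
                        iter, warmup, seed, ess_sweeps = 5L) {
  set.seed(as.integer(seed))
  n <- length(y)
  idx_g <- split(seq_len(n), gi)

  # initial values from per-group least squares, intercept shifted to the
  # tau-th residual quantile
  alpha <- numeric(G); beta <- numeric(G)
  for (g in seq_len(G)) {
    ii <- idx_g[[g]]
    if (stats::var(x[ii]) > 0) {
      cf <- stats::coef(stats::lm(y[ii] ~ x[ii]))
      alpha[g] <- cf[1]; beta[g] <- cf[2]
    } else { alpha[g] <- mean(y[ii]); beta[g] <- 0 }
    r <- y[ii] - alpha[g] - beta[g] * x[ii]
    alpha[g] <- alpha[g] + stats::quantile(r, tau, names = FALSE)
  }
  mu_fix <- alpha[gi] + beta[gi] * x
  sigma <- max(mean(check_loss(y - mu_fix, tau)), 1e-3)
  u <- numeric(n)
  sigma_p <- if (phylo) 0.25 * stats::sd(y) else NULL
  q_u <- 0

  ll_obs <- function(mu) al_logpdf(y, mu, sigma, tau)

  # adaptation state
  ls_cb <- rep(log(0.1), G)                  # log scale per coef block
  R <- replicate(G, diag(c(stats::sd(y), stats::sd(y) / max(stats::sd(x), 1e-9)))^2 / 50,
                 simplify = FALSE)
  Rl <- lapply(R, chol)
  hist_cb <- array(NA_real_, dim = c(warmup, G, 2))
  ls_sigma <- log(0.2); ls_sp <- log(0.3)
  ls_rs <- log(0.2)           # joint (sigma_p, u) rescale scale
  w_u <- numeric(n)           # C_inv %*% u, maintained alongside u
  CiA_tr <- Q_tr <- NULL
  if (phylo) {
    # per-group design columns [1, x] restricted to the group, and their
    # products with C_inv, fixed for the whole chain
    CiA_tr <- lapply(seq_len(G), function(g) {
      A <- matrix(0, n, 2)
      A[idx_g[[g]], 1] <- 1
      A[idx_g[[g]], 2] <- x[idx_g[[g]]]
      C_inv %*% A
    })
    Q_tr <- lapply(seq_len(G), function(g) {
      ii <- idx_g[[g]]
      A <- matrix(0, n, 2)
      A[ii, 1] <- 1; A[ii, 2] <- x[ii]
      crossprod(A, CiA_tr[[g]])
    })
  }

  keep <- iter - warmup
  out <- matrix(NA_real_, keep, 2 * G + 1 + as.integer(phylo))
  u_acc <- numeric(n)
  acc_count <- c(coef = 0, sigma = 0, translate = 0, rescale = 0, sigma_p = 0)

  lp_group <- function(g, a, b) {
    ii <- idx_g[[g]]
    mu <- a + b * x[ii] + if (phylo) u[ii] else 0
    sum(al_logpdf(y[ii], mu, sigma, tau)) +
      stats::dnorm(a, 0, ps$alpha_sd, log = TRUE) +
      stats::dnorm(b, 0, ps$beta_sd, log = TRUE)
  }

  for (t in seq_len(iter)) {
    in_warm <- t <= warmup
    # --- (alpha_g, beta_g) blocks ---
    for (g in seq_len(G)) {
      cur <- c(alpha[g], beta[g])
      prop <- cur + exp(ls_cb[g]) * drop(crossprod(Rl[[g]], stats::rnorm(2)))
      la <- lp_group(g, prop[1], prop[2]) - lp_group(g, cur[1], cur[2])
      acc <- is.finite(la) && log(stats::runif(1)) < la
      if (acc) { alpha[g] <- prop[1]; beta[g] <- prop[2] }
      if (!in_warm && acc) acc_count[["coef"]] <- acc_count[["coef"]] + 1
      if (in_warm) {
        ls_cb[g] <- ls_cb[g] + (as.numeric(acc) - 0.3) / sqrt(t)
        hist_cb[t, g, ] <- c(alpha[g], beta[g])
        if (t >= 200 && t %% 100 == 0) {
          S <- stats::cov(hist_cb[max(1, t - 499):t, g, ]) + diag(1e-10, 2)
          R[[g]] <- S; Rl[[g]] <- chol(S)
        }
      }
    }
    mu_fix <- alpha[gi] + beta[gi] * x

    # --- sigma (log random walk) ---
    lsig <- log(sigma)
    prop <- lsig + exp(ls_sigma) * stats::rnorm(1)
    mu_all <- mu_fix + if (phylo) u else 0
    cur_lp <- sum(al_logpdf(y, mu_all, sigma, tau)) +
      half_t_logpdf(sigma, ps$sigma_df, ps$sigma_scale) + lsig
    new_sigma <- exp(prop)
    new_lp <- sum(al_logpdf(y, mu_all, new_sigma, tau)) +
      half_t_logpdf(new_sigma, ps$sigma_df, ps$sigma_scale) + prop
    acc <- log(stats::runif(1)) < new_lp - cur_lp
    if (acc) sigma <- new_sigma
    if (!in_warm && acc) acc_count[["sigma"]] <- acc_count[["sigma"]] + 1
    if (in_warm) ls_sigma <- ls_sigma + (as.numeric(acc) - 0.44) / sqrt(t)

    if (phylo) {
      # --- u and the coefficient/u ridge, several sweeps per iteration ---
      # (a) elliptical slice sampling of u under N(0, sigma_p^2 C_std):
      #     exact, tuning-free, but takes small steps when the likelihood is
      #     sharp, so it is repeated and interleaved with (b);
      # (b) likelihood-invariant Gibbs translation: shift (alpha_g, beta_g)
      #     by delta while moving u by -A_g delta, leaving every mu_i (and
      #     hence the likelihood) unchanged; the conditional over delta is
      #     exactly Gaussian (Gaussian u-prior + Gaussian coefficient
      #     priors), a rejection-free step along the coefficient/u ridge.
      loglik_u <- function(uu) sum(al_logpdf(y, mu_fix + uu, sigma, tau))
      for (sweep in seq_len(ess_sweeps)) {
        nu <- sigma_p * drop(Lc %*% stats::rnorm(n))
        ly <- loglik_u(u) + log(stats::runif(1))
        theta <- stats::runif(1, 0, 2 * pi)
        th_min <- theta - 2 * pi; th_max <- theta
        repeat {
          u_prop <- u * cos(theta) + nu * sin(theta)
          if (loglik_u(u_prop) > ly) { u <- u_prop; break }
          if (theta < 0) th_min <- theta else th_max <- theta
          theta <- stats::runif(1, th_min, th_max)
          if (th_max - th_min < 1e-12) break
        }
        w_u <- drop(C_inv %*% u)
        q_u <- sum(u * w_u)

        sp2 <- sigma_p^2 + 1e-12
        for (g in seq_len(G)) {
          ii <- idx_g[[g]]
          m <- c(sum(w_u[ii]), sum(w_u[ii] * x[ii]))   # A_g' C_inv u
          P <- diag(c(1 / ps$alpha_sd^2, 1 / ps$beta_sd^2)) + Q_tr[[g]] / sp2
          h <- c(-alpha[g] / ps$alpha_sd^2, -beta[g] / ps$beta_sd^2) + m / sp2
          Pc <- chol(P)
          delta <- drop(backsolve(Pc, backsolve(Pc, h, transpose = TRUE) +
                                    stats::rnorm(2)))
          alpha[g] <- alpha[g] + delta[1]
          beta[g] <- beta[g] + delta[2]
          u[ii] <- u[ii] - (delta[1] + delta[2] * x[ii])
          w_u <- w_u - drop(CiA_tr[[g]] %*% delta)
          q_u <- q_u - 2 * sum(delta * m) + sum(delta * (Q_tr[[g]] %*% delta))
          if (!in_warm) acc_count[["translate"]] <- acc_count[["translate"]] + 1
        }
        mu_fix <- alpha[gi] + beta[gi] * x

        # --- joint rescale of (sigma_p, u): the u-prior term is invariant,
        # so acceptance depends on the likelihood and the sigma_p prior ---
        eps <- exp(ls_rs) * stats::rnorm(1)
        cc <- exp(eps)
        la <- sum(al_logpdf(y, mu_fix + cc * u, sigma, tau)) -
          sum(al_logpdf(y, mu_fix + u, sigma, tau)) +
          half_normal_logpdf(cc * sigma_p, ps$sigma_p_scale) -
          half_normal_logpdf(sigma_p, ps$sigma_p_scale) + eps
        acc <- is.finite(la) && log(stats::runif(1)) < la
        if (acc) {
          sigma_p <- cc * sigma_p
          u <- cc * u
          w_u <- cc * w_u
          q_u <- cc^2 * q_u
        }
        if (!in_warm && acc) acc_count[["rescale"]] <- acc_count[["rescale"]] + 1
        if (in_warm) ls_rs <- ls_rs + (as.numeric(acc) - 0.44) / sqrt(t)
      }

      # --- sigma_p (log random walk) ---
      lsp <- log(sigma_p)
      prop <- lsp + exp(ls_sp) * stats::rnorm(1)
      sp_new <- exp(prop)
      lp_sp <- function(sp, lg) -n * lg - q_u / (2 * sp^2) +
        half_normal_logpdf(sp, ps$sigma_p_scale) + lg
      acc <- log(stats::runif(1)) < lp_sp(sp_new, prop) - lp_sp(sigma_p, lsp)
      if (acc) sigma_p <- sp_new
      if (!in_warm && acc) acc_count[["sigma_p"]] <- acc_count[["sigma_p"]] + 1
      if (in_warm) ls_sp <- ls_sp + (as.numeric(acc) - 0.44) / sqrt(t)
    }

    if (!in_warm) {
      k <- t - warmup
      out[k, ] <- c(alpha, beta, sigma, if (phylo) sigma_p)
      if (phylo) u_acc <- u_acc + u
    }
  }
  list(draws = out, u_mean = if (phylo) u_acc / keep else NULL,
       accept = acc_count / c(keep * G, keep, keep * G, keep, keep))
}
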