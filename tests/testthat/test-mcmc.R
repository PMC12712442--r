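test_that("the log posterior matches a literal term-by-term evaluation", {
  set.seed(12)
  n <- 5
  tr <- sim_tree(n, 1, seed = 2)
  C <- phylo_vcv(tr)
  C_std <- C / max(diag(C))
  y <- rnorm(n, -20, 5); x <- runif(n, -8, -2)
  group <- c(1L, 2L, 1L, 2L, 1L)
  alpha <- c(-18, -25); beta <- c(-1.2, 0.4)
  sigma <- 2.2; sigma_p <- 1.7
  u <- rnorm(n, 0, 1)
  ps <- pqreg:::resolve_priors(pqreg_priors(), y, x)

  got <- pqreg_log_posterior(alpha, beta, sigma, y, x, group, tau = 0.3,
                             u = u, sigma_p = sigma_p, C_std = C_std,
                             prior_scales = ps)
  # independent evaluation, term by term
  lik <- 0
  for (i in 1:n) {
    mu <- alpha[group[i]] + beta[group[i]] * x[i] + u[i]
    r <- (y[i] - mu) / sigma
    rho <- r * (0.3 - as.numeric(r < 0))
    lik <- lik + log(0.3 * 0.7 / sigma) - rho
  }
  Sig <- sigma_p^2 * C_std
  mvn <- -0.5 * (n * log(2 * pi) + determinant(Sig)$modulus[1] +
                   drop(t(u) %*% solve(Sig) %*% u))
  priors <- sum(dnorm(alpha, 0, ps$alpha_sd, log = TRUE)) +
    sum(dnorm(beta, 0, ps$beta_sd, log = TRUE)) +
    (dt(sigma / ps$sigma_scale, 3, log = TRUE) - log(ps$sigma_scale) + log(2)) +
    (dnorm(sigma_p, 0, ps$sigma_p_scale, log = TRUE) + log(2))
  expect_equal(got, lik + mvn + priors, tolerance = 1e-10)

  # non-phylogenetic structure: sum of AL terms plus the fixed-effect priors
  got0 <- pqreg_log_posterior(alpha, beta, sigma, y, x, group, tau = 0.3,
                              prior_scales = ps)
  mu_fix <- alpha[group] + beta[group] * x
  fixed_priors <- priors - (dnorm(sigma_p, 0, ps$sigma_p_scale, log = TRUE) + log(2))
  expect_equal(got0, sum(al_logpdf(y, mu_fix, sigma, 0.3)) + fixed_priors,
               tolerance = 1e-10)
})

test_that("split-Rhat and ESS separate mixed from unmixed chains", {
  set.seed(4)
  good <- matrix(rnorm(4000), ncol = 4)
  d <- rhat_ess(good)
  expect_lt(d$rhat, 1.01)
  expect_gt(d$ess, 1000)
  shifted <- good + rep(c(0, 5, 10, 15), each = 1000)
  expect_gt(rhat_ess(shifted)$rhat, 1.5)
  const <- matrix(1, 200, 4)
  dc <- rhat_ess(const)
  expect_true(is.na(dc$rhat))
  expect_lte(dc$ess, 10)
  expect_error(rhat_ess(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("a single-group median regression recovers its generating line", {
  d <- sim_qr_dataset(n = 300, alpha = 2, beta = -1.5, tau = 0.5, sigma = 1,
                      x_range = c(0, 10), seed = 5)
  fit <- pqreg(y ~ x, d$data, tau = 0.5, chains = 2, iter = 3000, warmup = 1000,
               seed = 2, warn = FALSE)
  b <- as.matrix(fit)[, "beta.all"]
  expect_gt(mean(b), -1.7); expect_lt(mean(b), -1.3)
  h <- hdi(b)
  expect_true(h[1] < -1.5 && -1.5 < h[2])
  # residual-sign fraction at the fitted line approximates tau
  expect_equal(mean(residuals(fit) < 0), 0.5, tolerance = 0.04)
})

test_that("the fitted 0.1-quantile line leaves about 10% of points below it", {
  d <- sim_qr_dataset(n = 500, alpha = 2, beta = -1.5, tau = 0.1, sigma = 1,
                      x_range = c(0, 10), seed = 6)
  fit <- pqreg(y ~ x, d$data, tau = 0.1, chains = 2, iter = 3000, warmup = 1000,
               seed = 3, warn = FALSE)
  expect_equal(mean(residuals(fit) < 0), 0.1, tolerance = 0.03)
})

test_that("the posterior is equivariant under rescaling of the response", {
  d <- sim_qr_dataset(n = 120, alpha = 2, beta = -1.5, tau = 0.5, sigma = 1,
                      x_range = c(0, 10), seed = 7)
  f1 <- pqreg(y ~ x, d$data, tau = 0.5, chains = 2, iter = 800, warmup = 300,
              seed = 11, warn = FALSE)
  d2 <- d$data; d2$y <- 10 * d2$y
  f2 <- pqreg(y ~ x, d2, tau = 0.5, chains = 2, iter = 800, warmup = 300,
              seed = 11, warn = FALSE)
  # identical RNG stream + scale-aware priors: draws scale exactly
  expect_equal(as.matrix(f2), 10 * as.matrix(f1), tolerance = 1e-8)
  expect_equal(rope(f2)$verdict, rope(f1)$verdict)
})

test_that("grouped fits expose coefficients, predictions and simulation", {
  d <- sim_qr_dataset(n = 240, alpha = c(0, 5, 10), beta = c(-2, -1, 0),
                      tau = 0.5, sigma = 0.8, x_range = c(0, 10), seed = 8)
  fit <- pqreg(y ~ x, d$data, group = "group", tau = 0.5, chains = 2,
               iter = 2500, warmup = 1000, seed = 4, warn = FALSE)
  cf <- coef(fit)
  expect_equal(rownames(cf), c("g1", "g2", "g3"))
  expect_equal(unname(cf[, "beta"]), c(-2, -1, 0), tolerance = 0.25)
  nd <- data.frame(x = c(0, 0, 0), group = c("g1", "g2", "g3"))
  expect_equal(predict(fit, nd), unname(cf[, "alpha"]))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(240L, 3L))
  tab <- rope(fit)
  expect_equal(tab$group, c("g1", "g2", "g3"))
  expect_true(all(tab$verdict %in% c("outside_rope", "inside_rope", "overlapping")))
  expect_s3_class(summary(fit), "data.frame")
})

test_that("phylogenetic and non-phylogenetic fits nest as sigma_p vanishes", {
  tr <- sim_tree(60, 1, seed = 19)
  d <- sim_qr_dataset(tree = tr, alpha = 0, beta = -1.5, tau = 0.5, sigma = 1,
                      sigma_p = 0, seed = 20)
  f_np <- pqreg(y ~ x, d$data, tau = 0.5, chains = 2, iter = 2500, warmup = 1000,
                seed = 5, warn = FALSE)
  pri <- pqreg_priors(sigma_p_factor = 1e-4)   # prior mass squeezes sigma_p to 0
  f_ph <- pqreg(y ~ x, d$data, tau = 0.5, tree = tr, chains = 2, iter = 2500,
                warmup = 1000, seed = 5, priors = pri, warn = FALSE)
  b_np <- mean(as.matrix(f_np)[, "beta.all"])
  b_ph <- mean(as.matrix(f_ph)[, "beta.all"])
  expect_equal(b_ph, b_np, tolerance = 0.1)
})
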