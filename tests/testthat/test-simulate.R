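test_that("simulated trees are ultrametric, reproducible and genus-clustered", {
  tr <- sim_tree(50, 1, seed = 12)
  expect_equal(ape::Ntip(tr), 50)
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
  expect_equal(write_newick(sim_tree(50, 1, seed = 12)), write_newick(tr))
  gen <- species_genus(tip_species(tr))
  expect_gt(length(unique(gen)), 5)
  # each multi-species genus is monophyletic by construction
  for (g in names(which(table(gen) > 1))) {
    tips <- which(gen == g)
    expect_true(ape::is.monophyletic(tr, tr$tip.label[tips]))
  }
})

test_that("Brownian trait simulation hits its configured moments", {
  tr <- sim_tree(40, 1, seed = 13)
  expect_equal(unname(sim_bm_traits(tr, 0, 1, 5, seed = 1)), rep(5, 40))
  # lambda = 0: iid tips with depth-proportional variance
  depth <- diag(phylo_vcv(tr))
  reps <- vapply(1:500, function(i)
    sim_bm_traits(tr, sigma2 = 2, lambda = 0, root = 0, seed = 100 + i)[1],
    numeric(1))
  expect_equal(unname(var(reps)), unname(2 * depth[1]), tolerance = 0.15)
})

test_that("correlated Brownian traits reproduce the contrast correlation", {
  tr <- sim_tree(300, 1, seed = 15)
  # rho = 1 with equal rates: traits are affine images of each other
  tw <- sim_correlated_traits(tr, c(1, 1), rho_evol = 1, seed = 3)
  px <- ape::pic(unname(tw$x), tr); py <- ape::pic(unname(tw$y), tr)
  expect_equal(cor(px, py), 1, tolerance = 1e-10)
  # rho = -0.5: contrast correlation concentrates near -0.5
  cors <- vapply(1:30, function(i) {
    z <- sim_correlated_traits(tr, c(1, 1), rho_evol = -0.5, seed = 400 + i)
    cor(ape::pic(unname(z$x), tr), ape::pic(unname(z$y), tr))
  }, numeric(1))
  expect_lt(abs(mean(cors) - (-0.5)), 0.1)
  # rho = 0: centered at zero
  cors0 <- vapply(1:30, function(i) {
    z <- sim_correlated_traits(tr, c(1, 1), rho_evol = 0, seed = 700 + i)
    cor(ape::pic(unname(z$x), tr), ape::pic(unname(z$y), tr))
  }, numeric(1))
  expect_lt(abs(mean(cors0)), 0.1)
})

test_that("group labels are phylogenetically clustered", {
  tr <- sim_tree(150, 1, seed = 16)
  g <- sim_group_labels(tr, seed = 2)
  expect_equal(sort(unique(as.character(g))),
               sort(c("deciduous_angiosperm", "evergreen_angiosperm", "gymnosperm")))
  lam <- pagel_lambda_ml(as.numeric(g)[match(rownames(phylo_vcv(tr)), names(g))],
                         phylo_vcv(tr))
  expect_gt(lam$estimate, 0.5)
})

test_that("QR datasets place the generating line at the tau-th quantile", {
  d <- sim_qr_dataset(n = 10000, alpha = 2, beta = -1.5, tau = 0.1, sigma = 2,
                      x_range = c(0, 10), seed = 17)
  resid <- d$data$y - (2 - 1.5 * d$data$x)
  expect_equal(mean(resid < 0), 0.1, tolerance = 0.01)
  # noiseless limit: exactly on the group lines
  d0 <- sim_qr_dataset(n = 50, alpha = c(1, 2), beta = c(-1, 0.5), tau = 0.5,
                       sigma = 1e-12, x_range = c(0, 1), seed = 18)
  gi <- as.integer(factor(d0$data$group))
  expect_equal(d0$data$y, c(1, 2)[gi] + c(-1, 0.5)[gi] * d0$data$x,
               tolerance = 1e-9)
  # with a tree and sigma_p > 0 the latent u is serialized and used
  tr <- sim_tree(60, 1, seed = 19)
  dp <- sim_qr_dataset(tree = tr, alpha = 0, beta = -1, tau = 0.5, sigma = 0.5,
                       sigma_p = 3, seed = 20)
  expect_equal(length(dp$truth$u), 60)
  resid_p <- dp$data$y - (dp$truth$alpha[as.integer(factor(dp$data$group))] +
                            dp$truth$beta[as.integer(factor(dp$data$group))] *
                            dp$data$x + dp$truth$u)
  expect_lt(abs(mean(resid_p < 0) - 0.5), 0.15)
})

test_that("raw measurement tables are deterministic given the seed", {
  truth <- data.frame(species = c("Aus aus", "Bus bus"),
                      lt50_true = c(-20, -35), p50_true = c(-3, -7))
  a <- sim_raw_measurement_tables(truth, seed = 21)
  b <- sim_raw_measurement_tables(truth, seed = 21)
  expect_identical(a, b)
  # rate decoys exist and would survive nothing: all rates 30 dropped
  expect_true(any(a$frost$rate_C_per_h > 9))
})
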