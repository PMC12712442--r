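test_that("Newick round-trips preserve topology, labels and lengths", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(ape::Ntip(tr), 3)
  rt <- read_newick(write_newick(tr))
  expect_equal(rt$tip.label, tr$tip.label)
  expect_equal(rt$edge.length, tr$edge.length, tolerance = 1e-9)
  tr2 <- sim_tree(40, 1, seed = 3)
  rt2 <- read_newick(write_newick(tr2))
  d1 <- ape::cophenetic.phylo(tr2); d2 <- ape::cophenetic.phylo(rt2)
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-8)
  expect_error(read_newick("(A:1,A:2);"), "duplicate")
})

test_that("grafting adds tips inside the genus clade, deterministically", {
  tr <- sim_tree(30, 1, seed = 11)
  genus <- species_genus(tip_species(tr))
  big <- names(which.max(table(genus)))
  newsp <- paste(big, "novus")
  g1 <- graft_species_to_genus(tr, newsp, seed = 4)
  g2 <- graft_species_to_genus(tr, newsp, seed = 4)
  expect_equal(ape::Ntip(g1$tree), 31)
  expect_equal(write_newick(g1$tree), write_newick(g2$tree))
  # new tip's closest relative is a congener
  d <- ape::cophenetic.phylo(g1$tree)
  lab <- gsub(" ", "_", newsp)
  nn <- names(which.min(d[lab, colnames(d) != lab]))
  expect_equal(species_genus(canonical_species(nn)), big)
  # ultrametric trees stay ultrametric after grafting
  expect_true(ape::is.ultrametric(g1$tree, tol = 1e-6))
  # absent genus: skipped with a warning, tree unchanged
  expect_warning(g3 <- graft_species_to_genus(tr, "Nullius species", seed = 1),
                 "no congeneric")
  expect_equal(g3$skipped, "Nullius species")
  expect_equal(ape::Ntip(g3$tree), 30)
})

test_that("pruning preserves pairwise distances among retained tips", {
  tr <- sim_tree(25, 1, seed = 2)
  keep <- tip_species(tr)[c(1, 5, 9, 13, 20)]
  pr <- prune_to_overlap(tr, keep)
  expect_equal(sort(pr$species), sort(keep))
  d_full <- ape::cophenetic.phylo(tr)
  rownames(d_full) <- colnames(d_full) <- tip_species(tr)
  d_pr <- ape::cophenetic.phylo(pr$tree)
  rownames(d_pr) <- colnames(d_pr) <- pr$species
  expect_equal(d_pr[keep, keep], d_full[keep, keep], tolerance = 1e-9)
  expect_error(prune_to_overlap(tr, c("No one", "At all")), "no overlap")
})

test_that("the Brownian covariance matches shared path lengths", {
  expect_equal(unname(phylo_vcv(read_newick("(A:1,B:1);"))),
               diag(2), tolerance = 1e-12)
  C <- phylo_vcv(read_newick("((A:1,B:1):1,C:2);"))
  expect_equal(unname(C[c("A", "B", "C"), c("A", "B", "C")]),
               rbind(c(2, 1, 0), c(1, 2, 0), c(0, 0, 2)), tolerance = 1e-12)
  # PSD on a random tree, and vcv-then-prune equals submatrix
  tr <- sim_tree(50, 1, seed = 6)
  C50 <- phylo_vcv(tr)
  expect_gt(min(eigen(C50, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  keep <- tip_species(tr)[1:20]
  pr <- prune_to_overlap(tr, keep)
  expect_equal(phylo_vcv(pr$tree)[keep, keep], C50[keep, keep], tolerance = 1e-9)
})

test_that("the lambda transform scales only the off-diagonal", {
  C <- rbind(c(2, 1), c(1, 2))
  expect_equal(lambda_transform(C, 1), C)
  expect_equal(lambda_transform(C, 0), diag(c(2, 2)))
  expect_equal(lambda_transform(C, 0.5), rbind(c(2, 0.5), c(0.5, 2)))
  expect_error(lambda_transform(C, 1.5), "lambda")
})

test_that("the GLS mean reduces to known closed forms", {
  # star tree: arithmetic mean
  x <- c(1, 4, 7, 10)
  expect_equal(phylo_weighted_mean(x, diag(4)), mean(x))
  # two tips, depths 1 and 3: inverse-variance weighting
  expect_equal(phylo_weighted_mean(c(0, 4), diag(c(1, 3))), 1.0)
  # constant trait: the constant, regardless of C
  C <- phylo_vcv(sim_tree(12, 1, seed = 8))
  expect_equal(phylo_weighted_mean(rep(3.3, 12), C), 3.3)
})
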