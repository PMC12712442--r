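## Synthetic data with known ground truth for every pipeline stage: pure-birth
## trees with clustered genera, (correlated) Brownian traits with a tunable
## Pagel's lambda, phylogenetically clustered functional groups,
## quantile-regression responses with asymmetric-Laplace noise, raw
## electrolyte-leakage curves, raw measurement tables whose curated output is
## known a priori, and occurrences over closed-form climate gradients.

#' Simulate a pure-birth tree with clustered genus labels
#'
#' Tips are labelled `GenusXXX spYYY`, with genera assigned to clades of at
#' most `genus_size` tips so that grafting into genera is exercised
#' realistically. The tree is ultrametric; deterministic given `seed`.
#'
#' @param n number of tips (>= 2).
#' @param birth_rate speciation rate of the pure-birth process.
#' @param seed integer RNG seed.
#' @param genus_size maximum clade size per genus (default 5).
#' @return `ape::phylo`.
#' @export
sim_tree <- function(n, birth_rate = 1, seed, genus_size = 5) {
  stopifnot(n >= 2)
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n, birth = birth_rate, death = 0)
  # minimal clades of <= genus_size tips, walked from the root
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  ntips_below <- function(nd) {
    if (nd <= n) return(1L)
    sum(vapply(kids[[as.character(nd)]], ntips_below, integer(1)))
  }
  clusters <- list(); stack <- n + 1L
  while (length(stack)) {
    nd <- stack[[1]]; stack <- stack[-1]
    if (nd <= n) { clusters <- c(clusters, list(nd)); next }
    if (ntips_below(nd) <= genus_size) {
      tips <- intersect(c(phangorn_descendants(tree, nd)), seq_len(n))
      clusters <- c(clusters, list(tips))
    } else stack <- c(stack, kids[[as.character(nd)]])
  }
  labels <- character(n)
  for (k in seq_along(clusters)) {
    tips <- clusters[[k]]
    labels[tips] <- sprintf("Genus%03d_sp%03d", k, seq_along(tips))
  }
  tree$tip.label <- labels
  tree
}

## one draw from MVN(mean, V) via Cholesky
rmvn1 <- function(mean, V) {
  drop(mean + t(chol_safe(V)) %*% stats::rnorm(length(mean)))
}

#' Simulate a Brownian trait with a given Pagel's lambda
#'
#' One draw from MVN(root 1, sigma2 * lambda-transformed vcv(tree)); lambda =
#' 1 is pure Brownian motion, lambda = 0 independent tips with
#' depth-proportional variances.
#'
#' @param tree `ape::phylo`.
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param lambda Pagel's lambda in \[0, 1\].
#' @param root root (ancestral) value.
#' @param seed integer RNG seed.
#' @return named trait vector (canonical species names, tip order).
#' @export
sim_bm_traits <- function(tree, sigma2 = 1, lambda = 1, root = 0, seed) {
  set.seed(as.integer(seed))
  C <- lambda_transform(phylo_vcv(tree), lambda)
  x <- if (sigma2 == 0) rep(root, nrow(C)) else rmvn1(rep(root, nrow(C)), sigma2 * C)
  stats::setNames(x, rownames(C))
}

#' Simulate two traits under correlated Brownian motion
#'
#' Per-branch increments are bivariate normal with correlation `rho_evol` and
#' variances `sigma2` per unit branch length, accumulated from the root; the
#' cross-trait correlation of phylogenetic independent contrasts converges to
#' `rho_evol`.
#'
#' @param tree `ape::phylo`.
#' @param sigma2 length-2 vector of Brownian rates.
#' @param rho_evol evolutionary correlation in \[-1, 1\].
#' @param root length-2 root values.
#' @param seed integer RNG seed.
#' @return list with named trait vectors `x` and `y`.
#' @export
sim_correlated_traits <- function(tree, sigma2 = c(1, 1), rho_evol = 0,
                                  root = c(0, 0), seed) {
  stopifnot(abs(rho_evol) <= 1, length(sigma2) == 2)
  set.seed(as.integer(seed))
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  vals <- matrix(NA_real_, nn, 2)
  vals[n + 1L, ] <- root
  S <- diag(sqrt(sigma2)) %*% matrix(c(1, rho_evol, rho_evol, 1), 2) %*%
    diag(sqrt(sigma2))
  L <- t(chol(S + diag(1e-12, 2)))
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    inc <- sqrt(tree$edge.length[e]) * drop(L %*% stats::rnorm(2))
    vals[child, ] <- vals[par, ] + inc
  }
  sp <- tip_species(tree)
  list(x = stats::setNames(vals[seq_len(n), 1], sp),
       y = stats::setNames(vals[seq_len(n), 2], sp))
}

#' Phylogenetically clustered functional-group labels
#'
#' A latent Brownian trait is simulated on the tree and cut at its tertiles
#' (or `k`-tiles); the resulting labels are strongly clustered on the
#' phylogeny, as real functional groups (e.g. gymnosperms vs angiosperms)
#' are.
#'
#' @param tree `ape::phylo`.
#' @param k number of groups (default 3).
#' @param labels group names (defaults to the three woody functional groups).
#' @param seed integer RNG seed.
#' @return named factor (canonical species names).
#' @export
sim_group_labels <- function(tree, k = 3,
                             labels = c("deciduous_angiosperm",
                                        "evergreen_angiosperm", "gymnosperm"),
                             seed) {
  stopifnot(length(labels) == k)
  latent <- sim_bm_traits(tree, sigma2 = 1, lambda = 1, root = 0, seed = seed)
  cuts <- stats::quantile(latent, probs = seq(0, 1, length.out = k + 1))
  cuts[1] <- -Inf; cuts[k + 1] <- Inf
  g <- cut(latent, cuts, labels = labels, include.lowest = TRUE)
  stats::setNames(g, names(latent))
}

#' Simulate a quantile-regression dataset with known truth
#'
#' y_i = alpha_g(i) + beta_g(i) x_i + u_i + AL(0, sigma, tau), so the
#' generating group line is exactly the tau-th conditional quantile given
#' (x, u). With a tree, x evolves by Brownian motion, groups are
#' phylogenetically clustered and u ~ MVN(0, sigma_p^2 C_std); without one,
#' x is uniform on the predictor range, groups are balanced and u = 0.
#'
#' @param n number of species (ignored when `tree` is given).
#' @param tree optional `ape::phylo`.
#' @param alpha,beta per-group intercepts (response units) and slopes; the
#'   defaults emulate group-specific resistance trade-off lines.
#' @param tau generating quantile level.
#' @param sigma AL scale (response units).
#' @param sigma_p phylogenetic SD (response units; needs `tree`).
#' @param x_range predictor range for the non-phylogenetic case (MPa-like).
#' @param seed integer RNG seed.
#' @return list with `data` (data.frame: species, x, group, y) and `truth`
#'   (generating parameters, including u).
#' @export
sim_qr_dataset <- function(n = 300, tree = NULL,
                           alpha = c(-30, -20, -10),
                           beta = c(-2.5, -1.5, -0.5),
                           tau = 0.5, sigma = 3, sigma_p = 0,
                           x_range = c(-12, -1), seed = 1) {
  stopifnot(length(alpha) == length(beta))
  G <- length(alpha)
  set.seed(as.integer(seed))
  if (!is.null(tree)) {
    n <- ape::Ntip(tree)
    sp <- tip_species(tree)
    x <- sim_bm_traits(tree, sigma2 = 1, lambda = 1,
                       root = mean(x_range), seed = seed + 1L)
    # rescale into the predictor range without changing tree structure
    x <- mean(x_range) + (x - mean(x)) / max(stats::sd(x), 1e-9) * diff(x_range) / 4
    g <- sim_group_labels(tree, k = G,
                          labels = paste0("g", seq_len(G)), seed = seed + 2L)
    gi <- as.integer(g)
    u <- if (sigma_p > 0) {
      C_std <- phylo_vcv(tree); C_std <- C_std / max(diag(C_std))
      set.seed(as.integer(seed) + 3L)
      rmvn1(rep(0, n), sigma_p^2 * C_std)
    } else numeric(n)
  } else {
    sp <- sprintf("Synth%03d_sp%03d", seq_len(n), seq_len(n))
    x <- stats::runif(n, x_range[1], x_range[2])
    gi <- rep_len(seq_len(G), n)
    g <- factor(paste0("g", gi))
    u <- numeric(n)
  }
  set.seed(as.integer(seed) + 4L)
  eps <- ral(n, 0, sigma, tau)
  y <- alpha[gi] + beta[gi] * x + u + eps
  list(data = data.frame(species = canonical_species(sp), x = x,
                         group = as.character(g), y = y,
                         stringsAsFactors = FALSE),
       truth = list(alpha = alpha, beta = beta, tau = tau, sigma = sigma,
                    sigma_p = sigma_p, u = u, group_levels = levels(factor(g))))
}

#' Simulate a raw electrolyte-leakage curve
#'
#' Logistic mean plus iid Gaussian noise, clipped to \[0, 100\]%.
#'
#' @param lt50,baseline,plateau,slope logistic parameters (see
#'   [fit_el_sigmoid()]).
#' @param temperatures exposure temperatures (degrees C).
#' @param noise_sd Gaussian noise SD in REL percentage points.
#' @param seed integer RNG seed.
#' @return data.frame with `temperature_C`, `rel_pct`.
#' @export
sim_el_curve <- function(lt50 = -20, baseline = 10, plateau = 90, slope = 0.5,
                         temperatures = seq(-45, 0, by = 5), noise_sd = 0,
                         seed = 1) {
  set.seed(as.integer(seed))
  mu <- el_logistic(temperatures, baseline, plateau, slope, lt50)
  rel <- pmin(pmax(mu + stats::rnorm(length(mu), 0, noise_sd), 0), 100)
  data.frame(temperature_C = temperatures, rel_pct = rel)
}

## the six frost cells in priority order
frost_cells <- frost_priority[order(frost_priority$category), c("organ", "method")]

#' Simulate raw frost and drought measurement tables
#'
#' Builds per-species raw measurement rows whose correct curated output is
#' known a priori: each species gets a random subset of (organ, method) cells
#' whose highest-priority cell averages exactly the true LT50 (two rows at
#' +/- 1 degree), plus decoy rows that the midwinter and rate filters must
#' drop; drought rows get tier cells averaging the true P50 plus r-shaped
#' decoys.
#'
#' @param truth data.frame with `species`, `lt50_true`, `p50_true`.
#' @param seed integer RNG seed.
#' @return list with `frost` and `drought` raw tables and `expected` (the
#'   species-level table curation must reproduce: lt50, lt50_category, p50,
#'   p50_tier).
#' @export
sim_raw_measurement_tables <- function(truth, seed) {
  stopifnot(all(c("species", "lt50_true", "p50_true") %in% names(truth)))
  set.seed(as.integer(seed))
  frost <- list(); drought <- list(); expected <- list()
  for (i in seq_len(nrow(truth))) {
    sp <- truth$species[i]; lt <- truth$lt50_true[i]; p50 <- truth$p50_true[i]
    cells <- sort(sample.int(6, size = sample(1:3, 1)))
    top <- cells[1]
    for (cat in cells) {
      val <- if (cat == top) lt else lt + stats::runif(1, 1, 5)
      frost[[length(frost) + 1]] <- data.frame(
        species = sp, organ = frost_cells$organ[cat],
        method = frost_cells$method[cat],
        value_C = c(val - 1, val + 1),
        date = "2019-01-15", lat = 45, rate_C_per_h = 2,
        age_class = "adult", stringsAsFactors = FALSE)
    }
    # decoys: out-of-window date, bad rate (must be dropped before averaging)
    frost[[length(frost) + 1]] <- data.frame(
      species = sp, organ = "branch", method = "EL", value_C = lt + 20,
      date = "2019-07-01", lat = 45, rate_C_per_h = 2, age_class = "adult",
      stringsAsFactors = FALSE)
    frost[[length(frost) + 1]] <- data.frame(
      species = sp, organ = "branch", method = "EL", value_C = lt - 20,
      date = "2019-01-20", lat = 45, rate_C_per_h = 30, age_class = "adult",
      stringsAsFactors = FALSE)

    tier <- sample.int(4, 1)
    tier_rows <- switch(tier,
      data.frame(organ = "stem", technique = c("centrifuge", "optical"),
                 p50_MPa = c(p50 - 0.2, p50 + 0.2)),
      data.frame(organ = "stem", technique = "bench_dehydration", p50_MPa = p50),
      data.frame(organ = "leaf", technique = "other", p50_MPa = p50),
      data.frame(organ = "stem", technique = "air_injection", p50_MPa = p50))
    tier_rows$species <- sp
    tier_rows$curve_shape <- "sigmoid"
    tier_rows$psi_tlp_MPa <- NA_real_
    drought[[length(drought) + 1]] <- tier_rows
    drought[[length(drought) + 1]] <- data.frame(
      organ = "stem", technique = "centrifuge", p50_MPa = p50 + 2,
      species = sp, curve_shape = "r_shaped", psi_tlp_MPa = NA_real_,
      stringsAsFactors = FALSE)
    expected[[i]] <- data.frame(species = canonical_species(sp), lt50 = lt,
                                lt50_category = top, p50 = p50,
                                p50_tier = tier, stringsAsFactors = FALSE)
  }
  list(frost = do.call(rbind, frost),
       drought = do.call(rbind, drought)[, c("species", "organ", "technique",
                                             "curve_shape", "p50_MPa",
                                             "psi_tlp_MPa")],
       expected = do.call(rbind, expected))
}

#' Simulate occurrences over closed-form climate gradients
#'
#' Each species gets a Gaussian point cloud around its range center, clipped
#' to the grid extent; the aridity-index layer increases linearly with
#' longitude and the minimum-temperature layer with latitude, so every range
#' summary has a computable truth.
#'
#' @param centers data.frame with `species`, `lon`, `lat`.
#' @param spread SD of the point cloud (degrees).
#' @param n_per_species points per species.
#' @param extent c(xll, yll, xur, yur) of the grid (degrees).
#' @param cellsize grid cell size (degrees, default 0.5).
#' @param seed integer RNG seed.
#' @return list with `occurrences` (data.frame species/lon/lat), `grids`
#'   (named list: `ai`, `tmin`), and `truth` (the two gradient functions).
#' @export
sim_occurrences_and_grids <- function(centers, spread = 2, n_per_species = 200,
                                      extent = c(-20, 30, 20, 60),
                                      cellsize = 0.5, seed = 1) {
  stopifnot(all(c("species", "lon", "lat") %in% names(centers)))
  set.seed(as.integer(seed))
  occ <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    lon <- stats::rnorm(n_per_species, centers$lon[i], spread)
    lat <- stats::rnorm(n_per_species, centers$lat[i], spread)
    keep <- lon > extent[1] & lon < extent[3] & lat > extent[2] & lat < extent[4]
    data.frame(species = centers$species[i], lon = lon[keep], lat = lat[keep],
               stringsAsFactors = FALSE)
  }))
  ai_fun <- function(lon, lat) 0.05 + (lon - extent[1]) * 0.03 + 0 * lat
  tmin_fun <- function(lon, lat) -40 + (lat - extent[2]) * 0.8 + 0 * lon
  ncols <- round((extent[3] - extent[1]) / cellsize)
  nrows <- round((extent[4] - extent[2]) / cellsize)
  grids <- list(
    ai = grid_from_function(ai_fun, extent[1], extent[2], cellsize, ncols, nrows),
    tmin = grid_from_function(tmin_fun, extent[1], extent[2], cellsize, ncols, nrows))
  list(occurrences = occ, grids = grids,
       truth = list(ai_fun = ai_fun, tmin_fun = tmin_fun))
}
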