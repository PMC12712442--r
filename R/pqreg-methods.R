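## S3 methods for fitted "pqreg" objects.

#' Extract posterior draws as a matrix
#'
#' @param x a `pqreg` fit.
#' @param ... unused.
#' @return matrix with one column per parameter, chains stacked.
#' @export
as.matrix.pqreg <- function(x, ...) {
  d <- x$draws
  out <- apply(d, 3, rbind)
  colnames(out) <- dimnames(d)[[3]]
  out
}

post_summary <- function(v, mass = 0.95) {
  h <- hdi(v, mass)
  c(mean = mean(v), sd = stats::sd(v), median = stats::median(v),
    hdi_lo = h[[1]], hdi_hi = h[[2]])
}

#' @export
print.pqreg <- function(x, ...) {
  cat(sprintf("Bayesian %squantile regression (tau = %.2f)\n",
              if (x$phylo) "phylogenetic " else "", x$tau))
  cat("  ", deparse(x$formula), " | groups: ", paste(x$groups, collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  n = %d, %d chains x %d iterations (%d warmup)\n",
              x$n, x$chains, x$iter, x$warmup))
  m <- as.matrix(x)
  b <- m[, grep("^beta\\.", colnames(m)), drop = FALSE]
  for (j in seq_len(ncol(b))) {
    h <- hdi(b[, j])
    cat(sprintf("  %s: %.3f [%.3f, %.3f]\n", colnames(b)[j],
                mean(b[, j]), h[1], h[2]))
  }
  invisible(x)
}

#' Posterior summary of a quantile-regression fit
#'
#' @param object a `pqreg` fit.
#' @param mass HDI mass (default 0.95).
#' @param ... unused.
#' @return data.frame: mean, sd, median, HDI bounds, Rhat, ESS per parameter.
#' @export
summary.pqreg <- function(object, mass = 0.95, ...) {
  m <- as.matrix(object)
  tab <- t(apply(m, 2, post_summary, mass = mass))
  tab <- data.frame(parameter = rownames(tab), tab, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- merge(tab, object$diagnostics, by = "parameter", sort = FALSE)
  out[match(colnames(m), out$parameter), ]
}

#' @export
coef.pqreg <- function(object, ...) {
  m <- colMeans(as.matrix(object))
  G <- length(object$groups)
  cf <- cbind(alpha = m[seq_len(G)], beta = m[G + seq_len(G)])
  rownames(cf) <- object$groups
  cf
}

#' Fitted tau-th quantile line
#'
#' For new data, the posterior-mean group line alpha_g + beta_g x (the
#' phylogenetic effect is species-specific and not extrapolated); without
#' `newdata`, the in-sample linear predictor including the posterior-mean
#' phylogenetic effect.
#'
#' @param object a `pqreg` fit.
#' @param newdata optional data.frame with the predictor column (and the
#'   grouping column when the model has groups).
#' @param ... unused.
#' @return numeric vector of fitted quantiles.
#' @export
predict.pqreg <- function(object, newdata = NULL, ...) {
  cf <- coef.pqreg(object)
  if (is.null(newdata)) {
    g <- as.integer(object$data$group)
    mu <- cf[g, "alpha"] + cf[g, "beta"] * object$data$x
    if (object$phylo) mu <- mu + object$u_mean
    return(unname(mu))
  }
  xname <- all.vars(object$formula)[2]
  x <- newdata[[xname]]
  if (length(object$groups) > 1) {
    gcol <- intersect(c("group", "functional_group"), names(newdata))
    g <- if (length(gcol)) as.character(newdata[[gcol[1]]])
    else stop("newdata needs a 'group' column for a grouped model")
    gi <- match(g, object$groups)
    if (anyNA(gi)) stop("unknown group level in newdata")
  } else gi <- rep(1L, length(x))
  unname(cf[gi, "alpha"] + cf[gi, "beta"] * x)
}

#' @export
residuals.pqreg <- function(object, ...) {
  object$data$y - predict.pqreg(object)
}

#' Simulate responses from a fitted quantile-regression model
#'
#' Draws new responses y* = alpha_g + beta_g x + u + AL(0, sigma, tau) at the
#' posterior means, reusing the observed design (and the posterior-mean
#' phylogenetic effects).
#'
#' @param object a `pqreg` fit.
#' @param nsim number of simulated response vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.pqreg <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  mu <- predict.pqreg(object)
  sig <- mean(as.matrix(object)[, "sigma"])
  out <- as.data.frame(replicate(nsim, mu + ral(length(mu), 0, sig, object$tau)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' ROPE decisions for the group slopes
#'
#' @param object a `pqreg` fit.
#' @param mass HDI mass (default 0.95).
#' @param rope_factor ROPE half-width as a fraction of SD(y) (default 0.1).
#' @return data.frame with one row per group: HDI and ROPE bounds and the
#'   verdict (`outside_rope` / `inside_rope` / `overlapping`).
#' @export
rope <- function(object, ...) UseMethod("rope")

#' @rdname rope
#' @param ... passed on.
#' @export
rope.pqreg <- function(object, mass = 0.95, rope_factor = 0.1, ...) {
  m <- as.matrix(object)
  y <- object$data$y
  out <- do.call(rbind, lapply(seq_along(object$groups), function(g) {
    rd <- rope_decision(m[, paste0("beta.", object$groups[g])], y,
                        mass = mass, rope_factor = rope_factor)
    data.frame(group = object$groups[g], tau = object$tau,
               phylo = object$phylo, hdi_lo = rd$hdi_lo, hdi_hi = rd$hdi_hi,
               rope_lo = rd$rope_lo, rope_hi = rd$rope_hi,
               verdict = rd$verdict, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Plot slope posteriors against the ROPE
#'
#' Point estimate (posterior median) and HDI per group, with the ROPE shaded
#' -- one panel of the conventional slope-vs-ROPE display.
#'
#' @param x a `pqreg` fit.
#' @param mass HDI mass.
#' @param rope_factor ROPE half-width factor.
#' @param ... passed to `plot`.
#' @return invisibly, the [rope.pqreg()] table that was drawn.
#' @export
plot.pqreg <- function(x, mass = 0.95, rope_factor = 0.1, ...) {
  tab <- rope.pqreg(x, mass, rope_factor)
  m <- as.matrix(x)
  med <- vapply(x$groups, function(g) stats::median(m[, paste0("beta.", g)]),
                numeric(1))
  k <- nrow(tab)
  xlim <- range(c(tab$hdi_lo, tab$hdi_hi, tab$rope_lo, tab$rope_hi))
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = sprintf("slope (tau = %.2f)", x$tau), ylab = "", ...)
  graphics::rect(tab$rope_lo[1], 0, tab$rope_hi[1], k + 1,
                 col = grDevices::adjustcolor("grey", 0.4), border = NA)
  graphics::abline(v = 0, lty = 3)
  graphics::segments(tab$hdi_lo, seq_len(k), tab$hdi_hi, seq_len(k), lwd = 2)
  graphics::points(med, seq_len(k), pch = 19)
  graphics::axis(2, at = seq_len(k), labels = tab$group, las = 1)
  invisible(tab)
}
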