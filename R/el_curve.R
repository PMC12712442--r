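## LT50 estimation from raw electrolyte-leakage (EL) curves.
## REL(T) = baseline + (plateau - baseline) / (1 + exp(s * (T - lt50)))
## with s > 0: leakage approaches `plateau` at very cold exposure temperatures
## and `baseline` at mild ones; lt50 is the inflection.

el_logistic <- function(temp, baseline, plateau, slope, lt50) {
  baseline + (plateau - baseline) / (1 + exp(slope * (temp - lt50)))
}

#' Fit a four-parameter logistic to an electrolyte-leakage curve
#'
#' Least-squares fit of relative electrolyte leakage (%) against exposure
#' temperature (degrees C), returning the inflection point LT50. Five starts
#' (LT50 started at the 0.1/0.3/0.5/0.7/0.9 temperature quantiles, baseline
#' and plateau at the REL extremes) are run through Levenberg-Marquardt least
#' squares; the best converged fit by residual sum of squares is kept. If no
#' start converges the best unconverged parameter set is returned with
#' `converged = FALSE`.
#'
#' @param temperature numeric vector of exposure minima (degrees C), at least
#'   5 distinct values.
#' @param rel numeric vector of relative electrolyte leakage (%, in
#'   \[0, 100\]), same length.
#' @param min_span minimum REL range (percentage points) required to consider
#'   that a damage transition was observed; curves flatter than this raise a
#'   flat-curve error. Default 30.
#' @return object of class `el_fit`: list with `lt50`, `baseline`, `plateau`,
#'   `slope`, `rss`, `converged`, `fitted`, `data`.
#' @examples
#' T <- seq(-40, 0, by = 5)
#' rel <- 10 + 80 / (1 + exp(0.5 * (T - (-20))))
#' fit_el_sigmoid(T, rel)$lt50
#' @export
fit_el_sigmoid <- function(temperature, rel, min_span = 30) {
  stopifnot(length(temperature) == length(rel), length(temperature) >= 5,
            !anyNA(temperature), !anyNA(rel),
            all(rel >= 0), all(rel <= 100))
  if (anyDuplicated(temperature)) stop("temperatures must be distinct")
  span <- diff(range(rel))
  if (span < min_span)
    stop("flat curve: REL spans only ", round(span, 1),
         " percentage points; no damage transition observed")
  df <- data.frame(temp = temperature, rel = rel)
  lo <- min(rel); hi <- max(rel)
  slope0 <- 4 / max(diff(range(temperature)) / 4, 1e-6)
  starts <- lapply(stats::quantile(temperature, c(.1, .3, .5, .7, .9), names = FALSE),
                   function(m) list(baseline = lo, plateau = hi,
                                    slope = slope0, lt50 = m))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(rel ~ baseline + (plateau - baseline) /
                          (1 + exp(slope * (temp - lt50))),
                        data = df, start = st,
                        lower = c(0, 0, 1e-4, min(temperature) - 20),
                        upper = c(100, 100, Inf, max(temperature) + 20),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      p <- as.list(stats::coef(fit))
      best <- list(par = p, rss = rss, converged = fit$convInfo$isConv %||% TRUE)
    }
  }
  if (is.null(best)) {
    # fall back to direct RSS minimization from the central start
    obj <- function(par) {
      mu <- el_logistic(temperature, par[1], par[2], exp(par[3]), par[4])
      sum((rel - mu)^2)
    }
    st <- starts[[3]]
    op <- stats::optim(c(st$baseline, st$plateau, log(st$slope), st$lt50), obj,
                       method = "Nelder-Mead",
                       control = list(maxit = 2000))
    best <- list(par = list(baseline = op$par[1], plateau = op$par[2],
                            slope = exp(op$par[3]), lt50 = op$par[4]),
                 rss = op$value, converged = op$convergence == 0)
  }
  p <- best$par
  if (p$baseline > p$plateau) { # enforce baseline < plateau orientation
    tmp <- p$baseline; p$baseline <- p$plateau; p$plateau <- tmp
    p$slope <- -p$slope
  }
  structure(list(lt50 = unname(p$lt50), baseline = unname(p$baseline),
                 plateau = unname(p$plateau), slope = unname(p$slope),
                 rss = best$rss, converged = isTRUE(best$converged),
                 fitted = el_logistic(temperature, p$baseline, p$plateau,
                                      p$slope, p$lt50),
                 data = df),
            class = "el_fit")
}

#' @export
print.el_fit <- function(x, ...) {
  cat("Electrolyte-leakage logistic fit\n")
  cat(sprintf("  LT50: %.2f C  (baseline %.1f%%, plateau %.1f%%, slope %.3f %%/C)\n",
              x$lt50, x$baseline, x$plateau, x$slope))
  cat(sprintf("  RSS: %.3g  converged: %s\n", x$rss, x$converged))
  invisible(x)
}

#' Fit all EL curves in a long-format table
#'
#' Fits one logistic per (species, sample_id) curve and averages LT50 within
#' species; failed or flat curves are reported, not fatal.
#'
#' @param x long-format data.frame with columns `species`, `sample_id`,
#'   `temperature_C`, `rel_pct`.
#' @return data.frame with `species`, `lt50_el`, `n_curves`; the report lists
#'   curves that could not be fit.
#' @export
fit_el_curves <- function(x) {
  stopifnot(all(c("species", "sample_id", "temperature_C", "rel_pct") %in% names(x)))
  x$species <- canonical_species(x$species)
  key <- interaction(x$species, x$sample_id, drop = TRUE)
  fits <- lapply(split(x, key), function(d) {
    f <- tryCatch(fit_el_sigmoid(d$temperature_C, d$rel_pct),
                  error = function(e) e)
    list(species = d$species[1], fit = f)
  })
  ok <- vapply(fits, function(f) inherits(f$fit, "el_fit"), logical(1))
  failed <- names(fits)[!ok]
  if (!any(ok)) {
    out <- data.frame(species = character(), lt50_el = numeric(),
                      n_curves = integer(), stringsAsFactors = FALSE)
    return(set_report(out, list(n_curves = length(fits), failed = failed)))
  }
  per <- data.frame(species = vapply(fits[ok], `[[`, character(1), "species"),
                    lt50 = vapply(fits[ok], function(f) f$fit$lt50, numeric(1)),
                    stringsAsFactors = FALSE)
  agg <- stats::aggregate(lt50 ~ species, data = per, FUN = mean)
  cnt <- stats::aggregate(lt50 ~ species, data = per, FUN = length)
  out <- data.frame(species = agg$species, lt50_el = agg$lt50,
                    n_curves = cnt$lt50, stringsAsFactors = FALSE)
  set_report(out, list(n_curves = length(fits), failed = failed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
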