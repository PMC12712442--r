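## Per-group ordinary least-squares panels for trait-vs-trait displays
## (wood density, conduit diameter, conductivity, height, SLA, leaf area
## against the resistance traits).

#' Per-group linear fits for bivariate trait panels
#'
#' Ordinary least squares of y on x within each group, with the usual t-test
#' on the slope. Groups with fewer than 3 complete pairs are skipped with a
#' warning; a group whose x values are all identical is an error (slope
#' undefined).
#'
#' @param y,x numeric vectors.
#' @param group factor-like vector, same length (NULL = one pooled group).
#' @return data.frame with `group`, `n`, `slope`, `intercept`, `r2`, `p`.
#' @export
group_line_fit <- function(y, x, group = NULL) {
  stopifnot(length(y) == length(x))
  if (is.null(group)) group <- rep("all", length(y))
  ok <- stats::complete.cases(y, x)
  y <- y[ok]; x <- x[ok]; group <- droplevels(factor(group[ok]))
  out <- list()
  for (g in levels(group)) {
    ii <- group == g
    if (sum(ii) < 3) {
      warning("group '", g, "' has fewer than 3 points; skipped")
      next
    }
    if (stats::var(x[ii]) == 0)
      stop("slope undefined for group '", g, "': no variation in x")
    fit <- stats::lm(y[ii] ~ x[ii])
    sm <- summary(fit)
    out[[g]] <- data.frame(group = g, n = sum(ii),
                           slope = unname(stats::coef(fit)[2]),
                           intercept = unname(stats::coef(fit)[1]),
                           r2 = sm$r.squared,
                           p = sm$coefficients[2, 4],
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(group = character(), n = integer(), slope = numeric(),
                      intercept = numeric(), r2 = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' All trait-vs-resistance panels of a species table
#'
#' Runs [group_line_fit()] of each growth/structure trait against each
#' resistance trait present in the table.
#'
#' @param tab curated species table.
#' @param responses resistance trait columns (default `lt50`, `p50`).
#' @param predictors trait columns to regress on them (defaults to those
#'   present among wood_density, conduit_diameter, ks, max_height, sla,
#'   leaf_area).
#' @param group grouping column name (default "group" when present).
#' @return data.frame of per-panel per-group fits.
#' @export
bivariate_panels <- function(tab, responses = c("lt50", "p50"),
                             predictors = c("wood_density", "conduit_diameter",
                                            "ks", "max_height", "sla", "leaf_area"),
                             group = if ("group" %in% names(tab)) "group" else NULL) {
  responses <- intersect(responses, names(tab))
  predictors <- intersect(predictors, names(tab))
  grp <- if (is.null(group)) NULL else tab[[group]]
  out <- list()
  for (r in responses) for (p in predictors) {
    fit <- tryCatch(
      suppressWarnings(group_line_fit(tab[[r]], tab[[p]], grp)),
      error = function(e) NULL)
    if (is.null(fit) || nrow(fit) == 0) next
    fit$response <- r; fit$predictor <- p
    out[[paste(r, p)]] <- fit
  }
  if (!length(out)) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("response", "predictor", "group", "n", "slope", "intercept", "r2", "p")]
}
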