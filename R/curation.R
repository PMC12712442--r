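## Curation of raw frost (LT50/LT0) and drought (P50) measurement tables into a
## one-row-per-species trait table. Frost tables carry columns
##   species, organ (branch/bud/leaf), method (EL/VS), value_C, date, lat,
##   hemisphere (optional), rate_C_per_h, age_class
## drought tables carry
##   species, organ (stem/leaf), technique, curve_shape, p50_MPa, psi_tlp_MPa.

frost_priority <- data.frame(
  category = 1:6,
  organ  = c("branch", "bud", "branch", "bud", "leaf", "leaf"),
  method = c("EL", "EL", "VS", "VS", "EL", "VS"),
  stringsAsFactors = FALSE
)

#' Keep only midwinter frost measurements
#'
#' Frost resistance is only comparable across species at maximum (midwinter)
#' hardiness, after autumn hardening and before spring dehardening.
#' Measurements outside a per-hemisphere month window, and measurements with
#' no usable date, are dropped. Hemisphere comes from the `hemisphere` column
#' ("N"/"S") when present, otherwise from the sign of `lat`; rows whose
#' hemisphere cannot be determined default to the northern window.
#'
#' @param x data.frame of frost measurements (see package overview).
#' @param window named list of month numbers per hemisphere; default
#'   December--February in the north, June--August in the south.
#' @return filtered data.frame; `curation_report()` lists the counts of rows
#'   dropped for missing dates and out-of-window dates.
#' @export
filter_midwinter <- function(x, window = list(N = c(12, 1, 2), S = c(6, 7, 8))) {
  stopifnot(is.data.frame(x), length(window$N) > 0, length(window$S) > 0)
  n0 <- nrow(x)
  if (n0 == 0L) return(set_report(x, list(n_in = 0L, dropped_no_date = 0L,
                                          dropped_out_of_window = 0L, n_out = 0L)))
  month <- suppressWarnings(as.integer(format(as.Date(x$date), "%m")))
  hemi <- if ("hemisphere" %in% names(x)) as.character(x$hemisphere) else rep(NA_character_, n0)
  if ("lat" %in% names(x)) {
    miss <- is.na(hemi) & !is.na(x$lat)
    hemi[miss] <- ifelse(x$lat[miss] < 0, "S", "N")
  }
  hemi[is.na(hemi)] <- "N"
  no_date <- is.na(month)
  in_window <- !no_date & mapply(function(m, h) m %in% window[[h]], month, hemi)
  out <- x[in_window, , drop = FALSE]
  set_report(out, list(
    n_in = n0,
    dropped_no_date = sum(no_date),
    dropped_out_of_window = sum(!no_date & !in_window),
    n_out = nrow(out)
  ))
}

#' Screen freezing/thawing rates
#'
#' Very slow temperature ramps can artificially harden tissue and very fast
#' ones can cause intracellular ice artifacts. Rows whose rate falls outside
#' `[lo, hi]` degrees C per hour are removed; the endpoints are kept, and rows
#' with a missing rate are retained but flagged in the report.
#'
#' @param x data.frame with a `rate_C_per_h` column.
#' @param lo,hi inclusive bounds in degrees C per hour (defaults 0.2 and 9).
#' @return filtered data.frame with a report.
#' @export
screen_rates <- function(x, lo = 0.2, hi = 9) {
  stopifnot(is.data.frame(x), lo < hi)
  rate <- x$rate_C_per_h
  missing_rate <- is.na(rate)
  bad <- !missing_rate & (rate < lo | rate > hi)
  out <- x[!bad, , drop = FALSE]
  set_report(out, list(n_in = nrow(x), dropped_rate = sum(bad),
                       flagged_missing_rate = sum(missing_rate), n_out = nrow(out)))
}

#' Select one frost-resistance value per species
#'
#' Within each species, measurements are first averaged within each
#' (organ, method) cell -- at most six cells: branch/bud/leaf by EL (LT50) and
#' VS (LT0). One value is then chosen by fixed priority:
#' 1 EL-branch, 2 EL-bud, 3 VS-branch, 4 VS-bud, 5 EL-leaf, 6 VS-leaf.
#' EL outranks VS because its protocols are more consistent across studies,
#' and leaves rank last to avoid biasing the dataset toward evergreens.
#'
#' @param x data.frame with `species`, `organ`, `method`, `value_C`.
#' @return data.frame with one row per species: `species`, `lt50`,
#'   `lt50_category` (which rule fired, 1--6). Species with no usable cell are
#'   omitted. Output is sorted by species, so it is independent of input order.
#' @export
select_frost_value <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("species", "organ", "method", "value_C")
  stopifnot(all(need %in% names(x)))
  x <- x[!is.na(x$value_C), , drop = FALSE]
  if (nrow(x) == 0L) {
    return(data.frame(species = character(), lt50 = numeric(),
                      lt50_category = integer(), stringsAsFactors = FALSE))
  }
  x$species <- canonical_species(x$species)
  cells <- stats::aggregate(value_C ~ species + organ + method, data = x, FUN = mean)
  cells <- merge(cells, frost_priority, by = c("organ", "method"))
  cells <- cells[order(cells$species, cells$category), , drop = FALSE]
  first <- !duplicated(cells$species)
  out <- data.frame(species = cells$species[first],
                    lt50 = cells$value_C[first],
                    lt50_category = cells$category[first],
                    stringsAsFactors = FALSE)
  out[order(out$species), , drop = FALSE]
}

#' Remove non-sigmoid vulnerability curves
#'
#' "r-shaped" vulnerability curves are symptomatic of the open-vessel artifact
#' and overestimate vulnerability; they are removed. Curves of unknown shape
#' are retained but counted in the report.
#'
#' @param x data.frame of embolism measurements with a `curve_shape` column.
#' @return filtered data.frame with a report.
#' @export
filter_curve_shape <- function(x) {
  stopifnot(is.data.frame(x), "curve_shape" %in% names(x))
  shape <- as.character(x$curve_shape)
  bad <- !is.na(shape) & shape == "r_shaped"
  out <- x[!bad, , drop = FALSE]
  set_report(out, list(n_in = nrow(x), dropped_r_shaped = sum(bad),
                       flagged_unknown_shape = sum(is.na(shape) | shape == "unknown"),
                       n_out = nrow(out)))
}

p50_tiers <- list(
  list(tier = 1L, source = "stem_standard",
       keep = function(x) x$organ == "stem" & x$technique %in% c("centrifuge", "optical", "microCT")),
  list(tier = 2L, source = "stem_bench_dehydration",
       keep = function(x) x$organ == "stem" & x$technique == "bench_dehydration"),
  list(tier = 3L, source = "leaf",
       keep = function(x) x$organ == "leaf"),
  list(tier = 4L, source = "stem_air_injection",
       keep = function(x) x$organ == "stem" & x$technique == "air_injection")
)

#' Select one embolism-resistance value per species
#'
#' Method priority: (1) mean of stem P50 from centrifuge-based and
#' non-invasive (optical, microCT) techniques; (2) mean stem P50 from
#' bench-top dehydration; (3) mean leaf P50; (4) mean stem P50 from air
#' injection. `psi_tlp_MPa`, when present, is carried through as the
#' species-level mean for the turgor-loss-point consistency filter.
#'
#' @param x data.frame of embolism measurements (curve-shape filter applied).
#' @return data.frame with one row per species: `species`, `p50`, `p50_tier`,
#'   `p50_source`, `psi_tlp`.
#' @export
select_p50_value <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("species", "organ", "technique", "p50_MPa")
  stopifnot(all(need %in% names(x)))
  x <- x[!is.na(x$p50_MPa), , drop = FALSE]
  x$species <- canonical_species(x$species)
  sp <- sort(unique(x$species))
  pick_one <- function(rows) {
    for (t in p50_tiers) {
      sel <- t$keep(rows)
      if (any(sel)) {
        return(list(p50 = mean(rows$p50_MPa[sel]), tier = t$tier, source = t$source))
      }
    }
    NULL
  }
  res <- lapply(sp, function(s) {
    rows <- x[x$species == s, , drop = FALSE]
    got <- pick_one(rows)
    if (is.null(got)) return(NULL)
    tlp <- if ("psi_tlp_MPa" %in% names(rows) && any(!is.na(rows$psi_tlp_MPa)))
      mean(rows$psi_tlp_MPa, na.rm = TRUE) else NA_real_
    data.frame(species = s, p50 = got$p50, p50_tier = got$tier,
               p50_source = got$source, psi_tlp = tlp, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(species = character(), p50 = numeric(), p50_tier = integer(),
                      p50_source = character(), psi_tlp = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}

#' Drop P50 values inconsistent with the turgor loss point
#'
#' A P50 less negative than the leaf water potential at turgor loss is
#' physiologically implausible (embolism would occur before turgor loss) and
#' is treated as a measurement artifact. Rows with missing psi_tlp are kept
#' and flagged.
#'
#' @param x per-species data.frame with `p50` and `psi_tlp` columns.
#' @return filtered data.frame with a report.
#' @export
tlp_consistency_filter <- function(x) {
  stopifnot(is.data.frame(x), all(c("p50", "psi_tlp") %in% names(x)))
  both <- !is.na(x$p50) & !is.na(x$psi_tlp)
  bad <- both & x$p50 > x$psi_tlp
  out <- x[!bad, , drop = FALSE]
  set_report(out, list(n_in = nrow(x), dropped_above_tlp = sum(bad),
                       flagged_missing_tlp = sum(is.na(x$psi_tlp)), n_out = nrow(out)))
}

#' Merge per-species trait sources into one species table
#'
#' Full outer join of the curated frost table, curated drought table, and any
#' further per-species tables (growth traits, climate summaries), keyed on the
#' canonical species binomial. Duplicate species within one source are an
#' error; the join report counts species per source and the frost--drought
#' overlap.
#'
#' @param frost data.frame with `species` (and typically `lt50`,
#'   `lt50_category`).
#' @param drought data.frame with `species` (and typically `p50`, ...).
#' @param ... further per-species data.frames with a `species` column.
#' @return one-row-per-species data.frame; `curation_report()` holds the join
#'   report.
#' @export
merge_species_table <- function(frost, drought, ...) {
  sources <- c(list(frost = frost, drought = drought), list(...))
  sources <- sources[!vapply(sources, is.null, logical(1))]
  if (is.null(names(sources)) || any(names(sources) == ""))
    names(sources)[names(sources) == ""] <-
      paste0("source", seq_len(sum(names(sources) == "")))
  sources <- lapply(names(sources), function(nm) {
    s <- sources[[nm]]
    stopifnot(is.data.frame(s), "species" %in% names(s))
    s$species <- canonical_species(s$species)
    dup <- unique(s$species[duplicated(s$species)])
    if (length(dup))
      stop("duplicate species in source '", nm, "': ", paste(dup, collapse = ", "))
    s
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "species", all = TRUE), sources)
  merged <- merged[order(merged$species), , drop = FALSE]
  rownames(merged) <- NULL
  counts <- vapply(sources, nrow, integer(1))
  overlap <- length(intersect(sources[[1]]$species, sources[[2]]$species))
  set_report(merged, list(species_per_source = counts,
                          overlap_frost_drought = overlap,
                          n_species = nrow(merged)))
}

#' Tabulate frost priority categories
#'
#' Counts species per frost selection category (1--6); the counts always sum
#' to the number of species with a frost value.
#'
#' @param x curated species table with `lt50_category`.
#' @return named integer vector of length 6.
#' @export
frost_category_counts <- function(x) {
  stopifnot("lt50_category" %in% names(x))
  tab <- table(factor(x$lt50_category, levels = 1:6))
  stats::setNames(as.integer(tab), paste0("category_", 1:6))
}
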