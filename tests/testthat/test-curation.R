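test_that("midwinter filter keeps in-window dates and logs dateless rows", {
  x <- rbind(
    frost_row(date = "2020-01-15"),            # N, Jan: kept
    frost_row(date = "2020-12-01"),            # N, Dec: kept
    frost_row(date = "2020-04-10"),            # N, Apr: dropped
    frost_row(date = "2020-07-10", lat = -35), # S, Jul: kept
    frost_row(date = "2020-01-10", lat = -35), # S, Jan: dropped
    do.call(rbind, replicate(3, frost_row(date = NA), simplify = FALSE)),
    frost_row(date = "2021-02-28"),
    frost_row(date = "2021-02-02"))
  out <- filter_midwinter(x)
  rep <- curation_report(out)
  expect_equal(nrow(out), 7 - 2)  # 10 rows, 3 dateless, 2 out of window
  expect_equal(rep$dropped_no_date, 3)
  expect_equal(rep$dropped_out_of_window, 2)
  expect_equal(rep$n_in, rep$n_out + rep$dropped_no_date + rep$dropped_out_of_window)
})

test_that("rate screen removes out-of-bound rates, keeps endpoints and missing", {
  x <- rbind(frost_row(rate = 0.1), frost_row(rate = 5), frost_row(rate = 9),
             frost_row(rate = 0.2), frost_row(rate = 9.5), frost_row(rate = NA))
  out <- screen_rates(x)
  expect_equal(out$rate_C_per_h, c(5, 9, 0.2, NA))
  expect_equal(curation_report(out)$dropped_rate, 2)
  expect_equal(curation_report(out)$flagged_missing_rate, 1)
})

test_that("frost priority selection follows the six-level order and averages cells", {
  x <- rbind(frost_row("A a", "branch", "EL", -30), frost_row("A a", "leaf", "EL", -25),
             frost_row("B b", "branch", "VS", -20), frost_row("B b", "bud", "EL", -18),
             frost_row("C c", "leaf", "VS", -8),
             frost_row("D d", "branch", "EL", -28), frost_row("D d", "branch", "EL", -32))
  out <- select_frost_value(x)
  got <- function(sp) out[out$species == sp, ]
  expect_equal(got("A a")$lt50, -30); expect_equal(got("A a")$lt50_category, 1)
  expect_equal(got("B b")$lt50, -18); expect_equal(got("B b")$lt50_category, 2)
  expect_equal(got("C c")$lt50, -8);  expect_equal(got("C c")$lt50_category, 6)
  expect_equal(got("D d")$lt50, -30); expect_equal(got("D d")$lt50_category, 1)
})

test_that("priority selection is order-independent and idempotent in category counts", {
  set.seed(42)
  specs <- sprintf("Genus%02d sp", 1:25)
  x <- do.call(rbind, lapply(specs, function(sp) {
    k <- sample(1:4, 1)
    organs <- sample(c("branch", "bud", "leaf"), k, replace = TRUE)
    methods <- sample(c("EL", "VS"), k, replace = TRUE)
    do.call(rbind, Map(function(o, m) frost_row(sp, o, m, runif(1, -40, -5)),
                       organs, methods))
  }))
  a <- select_frost_value(x)
  b <- select_frost_value(x[sample(nrow(x)), ])
  expect_equal(a, b)
  # categories partition the species set
  expect_equal(sum(frost_category_counts(a)), nrow(a))
  expect_equal(nrow(a), length(unique(canonical_species(x$species))))
})

test_that("curve-shape filter removes r-shaped curves and flags unknown", {
  x <- rbind(drought_row(shape = "sigmoid"), drought_row(shape = "r_shaped"),
             drought_row(shape = "unknown"),
             do.call(rbind, replicate(3, drought_row(shape = "r_shaped"),
                                      simplify = FALSE)),
             do.call(rbind, replicate(4, drought_row(shape = "sigmoid"),
                                      simplify = FALSE)))
  out <- filter_curve_shape(x)
  expect_equal(nrow(out), 6)
  expect_equal(curation_report(out)$dropped_r_shaped, 4)
  expect_equal(curation_report(out)$flagged_unknown_shape, 1)
})

test_that("P50 selection follows the four method tiers", {
  x <- rbind(drought_row("A a", technique = "centrifuge", p50 = -5.1),
             drought_row("A a", technique = "optical", p50 = -4.9),
             drought_row("B b", technique = "bench_dehydration", p50 = -3.0),
             drought_row("B b", technique = "air_injection", p50 = -2.0),
             drought_row("C c", technique = "air_injection", p50 = -2.4),
             drought_row("D d", organ = "leaf", technique = "other", p50 = -1.9))
  out <- select_p50_value(x)
  got <- function(sp) out[out$species == sp, ]
  expect_equal(got("A a")$p50, -5.0); expect_equal(got("A a")$p50_tier, 1)
  expect_equal(got("B b")$p50, -3.0); expect_equal(got("B b")$p50_tier, 2)
  expect_equal(got("C c")$p50, -2.4); expect_equal(got("C c")$p50_tier, 4)
  expect_equal(got("D d")$p50, -1.9); expect_equal(got("D d")$p50_tier, 3)
})

test_that("turgor-loss-point filter removes implausible P50 and keeps missing", {
  x <- data.frame(species = c("A a", "B b", "C c"),
                  p50 = c(-1.2, -3.5, -2.0), psi_tlp = c(-1.8, -1.8, NA))
  out <- tlp_consistency_filter(x)
  expect_equal(out$species, c("B b", "C c"))
  expect_equal(curation_report(out)$flagged_missing_tlp, 1)
})

test_that("species table merge joins on canonical names and reports overlap", {
  frost <- data.frame(species = c("a a", "B b", "C c", "D d", "E e"), lt50 = -20)
  drought <- data.frame(species = c("C  c", "d_d", "E e", "F f", "G g", "H h", "I i"),
                        p50 = -3)
  out <- merge_species_table(frost, drought)
  expect_equal(nrow(out), 9)
  expect_equal(curation_report(out)$overlap_frost_drought, 3)
  expect_true("A a" %in% out$species)
  # canonicalization unifies case/whitespace/underscores
  expect_equal(sum(out$species == "C c"), 1)
  # duplicate species in one source is fatal
  expect_error(merge_species_table(rbind(frost, frost[1, ]), drought),
               "duplicate species")
})

test_that("curation is idempotent and recovers simulated truth exactly", {
  set.seed(1)
  truth <- data.frame(species = sprintf("Genus%03d sp%03d", 1:40, 1:40),
                      lt50_true = runif(40, -45, -5),
                      p50_true = runif(40, -9, -1.5))
  raw <- sim_raw_measurement_tables(truth, seed = 9)
  fr <- screen_rates(filter_midwinter(raw$frost))
  frost_tab <- select_frost_value(fr)
  p50_tab <- tlp_consistency_filter(select_p50_value(filter_curve_shape(raw$drought)))
  merged <- merge_species_table(frost_tab, p50_tab)
  expect_equal(nrow(merged), 40)
  key <- match(raw$expected$species, merged$species)
  expect_equal(merged$lt50[key], raw$expected$lt50, tolerance = 1e-12)
  expect_equal(merged$lt50_category[key], raw$expected$lt50_category)
  expect_equal(merged$p50[key], raw$expected$p50, tolerance = 1e-12)
  expect_equal(merged$p50_tier[key], raw$expected$p50_tier)
  # re-running the frost selection on already-curated single values is a no-op
  again <- select_frost_value(data.frame(
    species = merged$species,
    organ = pqreg:::frost_priority$organ[merged$lt50_category],
    method = pqreg:::frost_priority$method[merged$lt50_category],
    value_C = merged$lt50))
  expect_equal(again$lt50, merged$lt50)
  expect_equal(again$lt50_category, merged$lt50_category)
})
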