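# Subcatchment leverage, mass-balance interpretation and critical sources.

lev_means <- function(values, areas, ids = sprintf("s%02d", seq_along(values))) {
  make_means(ids, "S1", values, area_km2 = areas)
}

test_that("the outlet is the largest catchment, ties broken by site id", {
  m <- lev_means(c(1, 2, 3), c(10, 100, 5000))
  expect_equal(select_outlet(m, "TN", group = 5), "s03")

  tied <- make_means(c("zeta", "alpha", "mid"), "S1", c(1, 2, 3),
                     area_km2 = c(500, 500, 10))
  expect_equal(select_outlet(tied, "TN", group = 5), "alpha")

  one <- lev_means(1, 10)
  expect_error(select_outlet(one, "TN", group = 5), "no outlet context")
})

test_that("leverage follows (C_i - C_out) * a_i / a_out and its percent form", {
  m <- make_means(c("sub", "out"), "S1", c(2, 1), area_km2 = c(10, 1000))
  lt <- leverage_table(m, "TN", group = 5)
  expect_equal(nrow(lt), 1L) # outlet excluded
  expect_equal(lt$raw_leverage_mgL, 0.01)
  expect_equal(lt$percent_leverage, 1)

  same <- make_means(c("sub", "out"), "S1", c(1, 1), area_km2 = c(10, 1000))
  expect_equal(leverage_table(same, "TN", group = 5)$raw_leverage_mgL, 0)

  # a critical source: percent leverage well over 100
  hot <- make_means(c("sub", "out"), "S1", c(300, 1), area_km2 = c(10, 1000))
  expect_equal(leverage_table(hot, "TN", group = 5)$percent_leverage, 299)
})

test_that("leverage is invariant to area scaling, row order and site labels", {
  set.seed(61)
  vals <- rlnorm(20)
  areas <- 10^runif(20, 0, 3)
  base <- leverage_table(lev_means(vals, areas), "TN", group = 5)
  scaled <- leverage_table(lev_means(vals, areas * 7.3), "TN", group = 5)
  expect_equal(base$raw_leverage_mgL, scaled$raw_leverage_mgL,
               tolerance = 1e-12)

  perm <- sample(20)
  shuffled <- leverage_table(
    lev_means(vals[perm], areas[perm], ids = sprintf("s%02d", (1:20)[perm])),
    "TN", group = 5
  )
  expect_equal(shuffled$raw_leverage_mgL, base$raw_leverage_mgL,
               tolerance = 1e-12)
})

test_that("adding a constant concentration shifts only the percent scale", {
  set.seed(62)
  vals <- rlnorm(15)
  areas <- 10^runif(15, 0, 3)
  base <- leverage_table(lev_means(vals, areas), "TN", group = 5)
  shifted <- leverage_table(lev_means(vals + 5, areas), "TN", group = 5)
  expect_equal(shifted$raw_leverage_mgL, base$raw_leverage_mgL,
               tolerance = 1e-12)
  expect_equal(shifted$percent_leverage,
               100 * shifted$raw_leverage_mgL / shifted$c_out_mgL,
               tolerance = 1e-12)
})

test_that("conservative networks balance exactly and read as neutral", {
  cfg <- synthetic_config(n_sites = 50, ecoregions = 5, surveys = "A",
                          conservative_outlet = TRUE, analytes = "TP",
                          seed = 63)
  m <- average_revisits(replace_nondetects(generate_survey_table(cfg)))
  lt <- leverage_table(m, "TP", group = 5, waterbody = "stream")
  expect_lt(abs(sum(lt$raw_leverage_mgL)), 1e-9)
  ls <- leverage_summary(lt)
  expect_equal(ls$net_interpretation, "neutral")
})

test_that("mean leverage sign drives the removal/production interpretation", {
  dil <- lev_means(c(4, 5, 6, 1), c(10, 10, 10, 1000)) # sources, diluted outlet
  expect_equal(leverage_summary(leverage_table(dil, "TN", group = 5))$net_interpretation,
               "removal")
  single <- lev_means(c(0.4, 1), c(50, 1000))
  s <- leverage_summary(leverage_table(single, "TN", group = 5))
  expect_lt(s$mean_percent_leverage, 0)
  expect_equal(s$net_interpretation, "production")
})

test_that("critical-source fraction accumulates the top sources to the flux share", {
  rows <- tibble::tibble(raw_leverage_mgL = c(75, 15, 10))
  expect_equal(critical_source_fraction(rows, 0.75), 1 / 3)

  uniform <- tibble::tibble(raw_leverage_mgL = rep(2, 100))
  expect_equal(critical_source_fraction(uniform, 0.75), 0.75)

  sinks <- tibble::tibble(raw_leverage_mgL = c(-1, -2))
  expect_true(is.na(critical_source_fraction(sinks, 0.75)))
})

test_that("strengthening the top source never increases the critical fraction", {
  set.seed(64)
  lev <- c(sort(rlnorm(30), decreasing = TRUE), -rlnorm(10))
  f_prev <- critical_source_fraction(tibble::tibble(raw_leverage_mgL = lev))
  for (boost in c(2, 5, 20, 100)) {
    lev2 <- lev
    lev2[1] <- lev2[1] * boost
    f_new <- critical_source_fraction(tibble::tibble(raw_leverage_mgL = lev2))
    expect_lte(f_new, f_prev + 1e-12)
    f_prev <- f_new
  }
})

test_that("default-structure networks concentrate flux in few source catchments", {
  cfg <- synthetic_config(n_sites = 400, ecoregions = 5, surveys = "A",
                          analytes = "TP", seed = 65)
  m <- average_revisits(replace_nondetects(generate_survey_table(cfg)))
  lt <- leverage_table(m, "TP", group = 5, waterbody = "stream")
  ls <- leverage_summary(lt)
  expect_lt(ls$critical_source_fraction_75, 0.25)
  expect_gt(ls$critical_source_fraction_75, 0)
})
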