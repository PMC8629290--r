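# Standardization, the PELT variance changepoint machinery, screening and
# threshold extraction.

test_that("group scaling gives population mean 0 / variance 1, ordered by area", {
  set.seed(51)
  m <- make_means(sprintf("s%02d", 1:20), "S1", rlnorm(20, 0, 1),
                  area_km2 = sample(1:1000, 20))
  ser <- scale_by_group(m, "TN", group = 5)
  z <- ser$entries$z
  expect_equal(mean(z), 0, tolerance = 1e-9)
  expect_equal(mean(z^2), 1, tolerance = 1e-9) # population convention
  expect_true(!is.unsorted(ser$entries$area_km2))

  two <- make_means(c("a", "b"), "S1", c(1, 3), area_km2 = c(5, 10))
  z2 <- scale_by_group(two, "TN", group = 5)$entries$z
  expect_equal(z2, c(-1, 1))

  const <- make_means(c("a", "b"), "S1", c(2, 2), area_km2 = c(5, 10))
  expect_error(scale_by_group(const, "TN", group = 5), "degenerate group")
})

test_that("segment cost is the zero-mean Gaussian -2 log-likelihood", {
  expect_equal(variance_cost(c(2, -2)), 2 * (log(2 * pi) + log(4) + 1))
  expect_true(is.finite(variance_cost(c(0, 0, 0)))) # floored variance
  set.seed(52)
  z <- rnorm(5000)
  expect_equal(variance_cost(z) / 5000, log(2 * pi) + 1, tolerance = 0.01)
})

test_that("exhaustive search matches enumerated toy answers", {
  toy <- c(1, -1, 1, -1, 3, -3, 3, -3)
  lax <- exhaustive_changepoints(toy, penalty = 10, min_seg_len = 4)
  expect_equal(lax$changepoint_indices, integer(0))
  tight <- exhaustive_changepoints(toy, penalty = 0.1, min_seg_len = 4)
  expect_equal(tight$changepoint_indices, 4L)
  expect_error(exhaustive_changepoints(rnorm(41)), "n > 40")
})

test_that("PELT equals the exhaustive oracle across random series and penalties", {
  set.seed(53)
  for (i in 1:60) {
    n <- sample(16:30, 1)
    sds <- sample(c(0.3, 1, 3), 2, replace = TRUE)
    z <- c(rnorm(ceiling(n / 2), 0, sds[1]), rnorm(floor(n / 2), 0, sds[2]))
    pen <- runif(1, 1, 25)
    p <- pelt_changepoints(z, penalty = pen, min_seg_len = 8)
    e <- exhaustive_changepoints(z, penalty = pen, min_seg_len = 8,
                                 max_changepoints = 3)
    expect_equal(p$total_cost, e$total_cost, tolerance = 1e-9)
    expect_equal(p$total_cost, oracle_objective(z, p$changepoint_indices, pen),
                 tolerance = 1e-9)
  }
})

test_that("a strong variance drop is located within 2 positions", {
  set.seed(55)
  z <- c(rnorm(50, 0, 3), rnorm(50, 0, 0.5))
  seg <- pelt_changepoints(z, min_seg_len = 10)
  expect_length(seg$changepoint_indices, 1L)
  expect_lte(abs(seg$changepoint_indices - 50L), 2L)
  expect_gt(seg$segment_variances[1], seg$segment_variances[2])
  # agrees with a direct single-changepoint scan of the objective
  scan <- vapply(10:90, function(k) {
    variance_cost(z[1:k]) + variance_cost(z[(k + 1):100])
  }, 0)
  expect_equal(seg$changepoint_indices, (10:90)[which.min(scan)])
})

test_that("series shorter than two minimum segments report too short", {
  seg <- pelt_changepoints(rnorm(5), min_seg_len = 3)
  expect_equal(seg$status, "too short")
  expect_length(seg$changepoint_indices, 0L)
})

test_that("raising the penalty never adds changepoints", {
  set.seed(55)
  z <- c(rnorm(40, 0, 3), rnorm(40, 0, 1), rnorm(40, 0, 0.3))
  counts <- vapply(c(0.5, 2, 5, 10, 20, 50, 200), function(pen) {
    length(pelt_changepoints(z, penalty = pen, min_seg_len = 10)$changepoint_indices)
  }, 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("screening retains genuine variance shifts", {
  set.seed(56)
  z <- c(rnorm(50, 0, 3), rnorm(50, 0, 0.5))
  seg <- pelt_changepoints(z, min_seg_len = 10)
  scr <- screen_false_positives(z, seg)
  expect_equal(scr$changepoint_indices, seg$changepoint_indices)
  expect_equal(nrow(scr$screened_out), 0L)
})

test_that("screening rejects a break triggered by one extreme point", {
  # find a null series where one injected outlier makes PELT break
  found <- FALSE
  for (s in 1:30) {
    set.seed(560 + s)
    z <- rnorm(120)
    z[60] <- 8
    seg <- pelt_changepoints(z, min_seg_len = 10)
    if (length(seg$changepoint_indices) > 0L) {
      found <- TRUE
      scr <- screen_false_positives(z, seg)
      expect_length(scr$changepoint_indices, 0L)
      expect_gt(nrow(scr$screened_out), 0L)
      expect_match(scr$screened_out$reason[1], "retention ratio")
      break
    }
  }
  expect_true(found)
})

test_that("screening is a no-op on empty changepoint sets", {
  set.seed(57)
  z <- rnorm(60)
  seg <- pelt_changepoints(z, penalty = 1e6, min_seg_len = 10)
  expect_identical(screen_false_positives(z, seg)$changepoint_indices,
                   seg$changepoint_indices)
})

test_that("collapse thresholds take the first downstream site's area, decreases only", {
  set.seed(58)
  n <- 60
  areas <- sort(10^runif(n, 0, 3))
  vals <- c(rnorm(30, 0, 3), rnorm(30, 0, 0.3))
  m <- make_means(sprintf("s%02d", 1:n), "S1", vals + 10, area_km2 = areas)
  ser <- scale_by_group(m, "TN", group = 5)
  seg <- pelt_changepoints(ser$entries$z, min_seg_len = 10)
  th <- collapse_threshold(ser, seg)
  expect_gt(nrow(th), 0L)
  k <- th$changepoint_index[1]
  expect_equal(th$changepoint_area_km2[1], ser$entries$area_km2[k + 1])
  expect_equal(th$direction[1], "decrease")
  expect_equal(th$upstream_variance[1], seg$segment_variances[1])
  expect_equal(th$downstream_variance[1], seg$segment_variances[2])

  # increasing-variance series: changepoints never become collapse thresholds
  m_inc <- make_means(sprintf("s%02d", 1:n), "S1", rev(vals) + 10,
                      area_km2 = areas)
  ser_inc <- scale_by_group(m_inc, "TN", group = 5)
  seg_inc <- pelt_changepoints(ser_inc$entries$z, min_seg_len = 10)
  th_inc <- collapse_threshold(ser_inc, seg_inc)
  expect_true(all(th_inc$direction == "increase"))
  expect_true(is.na(primary_collapse_threshold(th_inc)))
})

test_that("segmentation and thresholds are invariant to concentration scaling", {
  set.seed(59)
  n <- 80
  areas <- sort(10^runif(n, 0, 3))
  vals <- exp(c(rnorm(40, 0, 1.5), rnorm(40, 0, 0.3)))
  m1 <- make_means(sprintf("s%02d", 1:n), "S1", vals, area_km2 = areas)
  m2 <- make_means(sprintf("s%02d", 1:n), "S1", 1000 * vals, area_km2 = areas)
  p1 <- patch_size(m1, "TN", group = 5, min_seg_len = 10)
  p2 <- patch_size(m2, "TN", group = 5, min_seg_len = 10)
  expect_equal(p1$changepoint_area_km2, p2$changepoint_area_km2)
  expect_equal(p1$upstream_variance, p2$upstream_variance, tolerance = 1e-9)
})

test_that("groups with too few sites are reported not determinable", {
  m <- make_means(sprintf("s%02d", 1:8), "S1", rlnorm(8), area_km2 = 1:8)
  out <- patch_size(m, "TN", group = 5, min_seg_len = 10)
  expect_equal(out$status, "not determinable")
  expect_true(is.na(out$changepoint_area_km2))
})

test_that("an injected small-catchment patch is recovered near its area scale", {
  cfg <- synthetic_config(n_sites = 800, ecoregions = 5, surveys = "A",
                          patch_area_km2 = 100, patch_variance_ratio = 9,
                          source_fraction = 0, persistence_share = 0.6,
                          analytes = "TN", seed = 201)
  m <- average_revisits(replace_nondetects(generate_survey_table(cfg)))
  th <- primary_collapse_threshold(
    patch_size(m, "TN", group = 5, waterbody = "stream")
  )
  expect_gte(th, 100 / 3)
  expect_lte(th, 300)
})
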