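# Shared fixtures and independent oracles for the test suite.

# Build a site-survey means tibble from parallel vectors, with defaults.
make_means <- function(site_id, survey_id, mean_value_mgL,
                       waterbody = "stream", ecoregion = 5L,
                       area_km2 = NA_real_, analyte = "TN", n_visits = 1L) {
  tibble::tibble(
    site_id = site_id, survey_id = survey_id, waterbody = waterbody,
    ecoregion = as.integer(ecoregion), area_km2 = area_km2,
    analyte = analyte, mean_value_mgL = mean_value_mgL,
    n_visits = as.integer(n_visits)
  )
}

# Build a raw sample tibble (typed like read_survey_table output).
make_samples <- function(site_id, survey_id, value_mgL, visit = 1L,
                         date = as.Date("2010-07-01"), waterbody = "stream",
                         ecoregion = 5L, area_km2 = NA_real_, analyte = "TN",
                         detection_limit_mgL = 0.01) {
  tibble::tibble(
    site_id = site_id, survey_id = survey_id, visit = as.integer(visit),
    date = date, waterbody = waterbody, ecoregion = as.integer(ecoregion),
    area_km2 = area_km2, analyte = analyte, value_mgL = value_mgL,
    detection_limit_mgL = detection_limit_mgL
  )
}

# Write lines of a survey CSV (header included) to a temp file.
write_survey_lines <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(paste(survey_columns(), collapse = ","), rows), path)
  path
}

# Independent Spearman oracle: explicit average ranks, covariance formula
# evaluated with loops (no stats::cor).
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) {
      # average rank = count below + (ties including self + 1) / 2
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x)
  ry <- avg_rank(y)
  n <- length(x)
  mx <- sum(rx) / n
  my <- sum(ry) / n
  sxy <- 0
  sxx <- 0
  syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (rx[i] - mx) * (ry[i] - my)
    sxx <- sxx + (rx[i] - mx)^2
    syy <- syy + (ry[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# Hand-computed paired t statistic: mean difference / (sd / sqrt(n)).
oracle_paired_t <- function(a, b) {
  d <- b - a
  mean(d) / (sd(d) / sqrt(length(d)))
}

# Penalized objective of a segmentation, computed directly from first
# principles (independent of the package's cumulative-sum bookkeeping).
oracle_objective <- function(z, cps, penalty) {
  bounds <- c(0L, cps, length(z))
  total <- penalty * length(cps)
  for (k in seq_len(length(bounds) - 1L)) {
    seg <- z[(bounds[k] + 1L):bounds[k + 1L]]
    s2 <- max(mean(seg^2), 1e-12)
    total <- total + length(seg) * (log(2 * pi) + log(s2) + 1)
  }
  total
}
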