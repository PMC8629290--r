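# Subcatchment leverage: each subcatchment's influence on the nutrient flux
# at the group outlet, assuming constant specific discharge within the group
# so catchment area proxies discharge.

LEVERAGE_CAVEAT <- paste(
  "Leverage assumes constant specific discharge within the group;",
  "catchment area proxies discharge and no flow measurements are used."
)

# Collapse site-survey means to one concentration per site (mean across
# surveys), keeping sites with known area only.
site_level_means <- function(means, analyte, group, waterbody) {
  filter_group(means, group, waterbody) |>
    dplyr::filter(.data$analyte == !!analyte, !is.na(.data$area_km2)) |>
    dplyr::group_by(.data$site_id, .data$area_km2) |>
    dplyr::summarise(value_mgL = mean(.data$mean_value_mgL), .groups = "drop")
}

#' Select the group outlet site
#'
#' The outlet is the largest measured catchment in the group (area ties
#' broken by lexicographically smallest `site_id` for determinism); its
#' concentration and area are the reference against which every other
#' subcatchment's leverage is computed.
#'
#' @inheritParams scale_by_group
#' @return The outlet `site_id`.
#' @export
select_outlet <- function(means, analyte, group = "national",
                          waterbody = NULL) {
  sites <- site_level_means(means, analyte, group, waterbody)
  if (nrow(sites) < 2L) {
    stop_synoptic("no outlet context: need at least 2 sites with area ",
                  "and concentration")
  }
  sites <- dplyr::arrange(sites, dplyr::desc(.data$area_km2), .data$site_id)
  sites$site_id[1L]
}

#' Per-subcatchment leverage on the outlet flux
#'
#' Raw leverage of subcatchment *i* is
#' `(C_i - C_out) * (a_i / a_out)` (mg/L): the concentration excess over the
#' outlet, discharge-weighted by relative catchment area. Percent leverage
#' normalizes by the outlet concentration, `100 * raw / C_out`, i.e. the
#' subcatchment's contribution as a percentage of the outlet flux under the
#' constant specific-discharge assumption. Positive leverage marks a nutrient
#' source, negative a sink; values well over 100% are admissible and mark
#' critical source areas whose inputs must be removed or diluted in the
#' network. The outlet itself is excluded from the table.
#'
#' @inheritParams scale_by_group
#' @return A tibble with one row per non-outlet site: `group`, `waterbody`,
#'   `analyte`, `site_id`, `area_km2`, `c_mgL`, `outlet_site_id`,
#'   `c_out_mgL`, `area_out_km2`, `raw_leverage_mgL`, `percent_leverage`.
#'   The constant-discharge caveat is attached as `attr(, "caveat")`.
#' @export
leverage_table <- function(means, analyte, group = "national",
                           waterbody = NULL) {
  sites <- site_level_means(means, analyte, group, waterbody)
  outlet <- select_outlet(means, analyte, group, waterbody)
  out_row <- sites[sites$site_id == outlet, ]
  c_out <- out_row$value_mgL
  a_out <- out_row$area_km2
  if (c_out == 0) {
    stop_synoptic("outlet concentration is zero; cannot normalize ",
                  "(apply replace_nondetects() first)")
  }
  subs <- sites[sites$site_id != outlet, ] |>
    dplyr::arrange(.data$site_id)
  res <- tibble::tibble(
    group = as.character(group),
    waterbody = waterbody %||% NA_character_,
    analyte = analyte,
    site_id = subs$site_id,
    area_km2 = subs$area_km2,
    c_mgL = subs$value_mgL,
    outlet_site_id = outlet,
    c_out_mgL = c_out,
    area_out_km2 = a_out,
    raw_leverage_mgL = (subs$value_mgL - c_out) * (subs$area_km2 / a_out),
    percent_leverage = 100 * (subs$value_mgL - c_out) *
      (subs$area_km2 / a_out) / c_out
  )
  attr(res, "caveat") <- LEVERAGE_CAVEAT
  res
}

#' Critical-source-area fraction
#'
#' The fraction of subcatchments whose largest positive leverages jointly
#' account for `flux_share` of the total positive (source) leverage: sort the
#' positive raw leverages descending and find the smallest k whose cumulative
#' sum reaches `flux_share` of their total; the fraction is k divided by the
#' total number of subcatchments (sources and sinks).
#'
#' @param rows A leverage table from [leverage_table()].
#' @param flux_share Share of total source flux to account for, in `(0, 1]`
#'   (default 0.75).
#' @return The fraction in `(0, 1]`, or `NA` when no subcatchment has
#'   positive leverage.
#' @export
critical_source_fraction <- function(rows, flux_share = 0.75) {
  stopifnot(flux_share > 0, flux_share <= 1)
  pos <- sort(rows$raw_leverage_mgL[rows$raw_leverage_mgL > 0],
              decreasing = TRUE)
  if (length(pos) == 0L) {
    return(NA_real_)
  }
  k <- which(cumsum(pos) >= flux_share * sum(pos) - 1e-12)[1L]
  k / nrow(rows)
}

#' Group-level leverage summary and mass-balance interpretation
#'
#' Mean percent leverage estimates the network mass balance: a positive mean
#' implies in-network nutrient removal (more sources than the outlet flux
#' accounts for), a negative mean implies in-network production, and means
#' within `tolerance` percentage points of zero are called neutral
#' (conservative mixing) -- means of ~1% are indistinguishable from zero
#' under the method's assumptions, hence the dead-band.
#'
#' @param rows A leverage table from [leverage_table()].
#' @param tolerance Neutrality dead-band in percentage points (default 0.5).
#' @param flux_share Passed to [critical_source_fraction()] (default 0.75).
#' @return A one-row tibble: `group`, `waterbody`, `analyte`,
#'   `n_subcatchments`, `mean_percent_leverage`, `median_percent_leverage`,
#'   `net_interpretation` (`removal`/`production`/`neutral`),
#'   `frac_over_100pct`, `critical_source_fraction_75` (named after the
#'   default share; computed at `flux_share`).
#' @export
leverage_summary <- function(rows, tolerance = 0.5, flux_share = 0.75) {
  stopifnot(nrow(rows) >= 1L)
  mean_pct <- mean(rows$percent_leverage)
  interp <- if (mean_pct > tolerance) {
    "removal"
  } else if (mean_pct < -tolerance) {
    "production"
  } else {
    "neutral"
  }
  out <- tibble::tibble(
    group = rows$group[1L],
    waterbody = rows$waterbody[1L],
    analyte = rows$analyte[1L],
    n_subcatchments = nrow(rows),
    mean_percent_leverage = mean_pct,
    median_percent_leverage = median(rows$percent_leverage),
    net_interpretation = interp,
    frac_over_100pct = mean(rows$percent_leverage > 100),
    critical_source_fraction_75 = critical_source_fraction(rows, flux_share)
  )
  attr(out, "caveat") <- LEVERAGE_CAVEAT
  out
}
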