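# Reading, validating and normalizing long-format survey tables.

#' Canonical survey table columns
#'
#' The exchange format is a long (tidy) UTF-8 CSV with exactly these columns,
#' one analyte measurement per row. Empty strings encode missing values and
#' dates are ISO 8601 (`YYYY-MM-DD`).
#'
#' @return Character vector of column names in canonical order.
#' @export
survey_columns <- function() {
  c(
    "site_id", "survey_id", "visit", "date", "waterbody", "ecoregion",
    "area_km2", "analyte", "value_mgL", "detection_limit_mgL"
  )
}

valid_waterbodies <- c("lake", "stream")

#' Read a long-format survey table
#'
#' Parses and validates a survey CSV row by row. Structural problems (a
#' missing mandatory column) are hard errors; individual malformed rows
#' (unknown waterbody, negative concentration, unparseable numerics,
#' duplicated `(site_id, survey_id, visit, analyte)` keys, ...) are rejected
#' with a row-numbered diagnostic and the remaining rows are returned.
#'
#' @param path Path to a UTF-8 CSV file with header exactly
#'   `r paste(survey_columns(), collapse = ",")`.
#' @return A tibble of validated samples with typed columns (`visit` integer,
#'   `date` a `Date`, `ecoregion` integer with `NA` for unknown, numeric
#'   concentrations and areas). Rejected rows are attached as a tibble in
#'   `attr(, "rejections")` with columns `row` (1-based data row) and
#'   `reason`; see [rejections()].
#' @seealso [write_survey_table()], [replace_nondetects()]
#' @export
read_survey_table <- function(path) {
  if (!file.exists(path)) {
    stop_synoptic("survey table not found: ", path)
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(survey_columns(), names(raw))
  if (length(missing_cols) > 0L) {
    stop_synoptic(
      "missing mandatory column(s): ", paste(missing_cols, collapse = ", ")
    )
  }
  extra <- setdiff(names(raw), survey_columns())
  if (length(extra) > 0L) {
    stop_synoptic("unknown column(s): ", paste(extra, collapse = ", "))
  }
  validate_survey_rows(raw[survey_columns()])
}

# Row-wise validation of an all-character survey table. Returns the typed
# tibble of valid rows with a `rejections` attribute.
validate_survey_rows <- function(raw) {
  n <- nrow(raw)
  blank <- function(x) is.na(x) | x == ""
  num <- function(x) suppressWarnings(as.numeric(ifelse(blank(x), NA, x)))

  visit <- num(raw$visit)
  ecoregion_chr <- raw$ecoregion
  ecoregion <- suppressWarnings(as.numeric(ifelse(
    blank(ecoregion_chr) | ecoregion_chr == "unknown", NA, ecoregion_chr
  )))
  area <- num(raw$area_km2)
  value <- num(raw$value_mgL)
  dl <- num(raw$detection_limit_mgL)
  date <- as.Date(ifelse(blank(raw$date), NA, raw$date), format = "%Y-%m-%d")

  reason <- rep(NA_character_, n)
  flag <- function(bad, msg) {
    reason[is.na(reason) & bad] <<- msg
  }
  flag(blank(raw$site_id), "missing site_id")
  flag(blank(raw$survey_id), "missing survey_id")
  flag(blank(raw$visit) | is.na(visit) | visit != round(visit) | visit < 1,
       "visit must be a positive integer")
  flag(!blank(raw$date) & is.na(date), "date not ISO 8601 (YYYY-MM-DD)")
  flag(!raw$waterbody %in% valid_waterbodies,
       paste0("waterbody must be one of ", paste(valid_waterbodies, collapse = "|")))
  flag(!blank(ecoregion_chr) & ecoregion_chr != "unknown" &
         (is.na(ecoregion) | ecoregion != round(ecoregion)),
       "ecoregion must be an integer code or 'unknown'")
  flag(!blank(raw$area_km2) & (is.na(area) | area <= 0),
       "area_km2 must be a positive number when present")
  flag(blank(raw$analyte), "missing analyte")
  flag(blank(raw$value_mgL) | is.na(value), "value_mgL not numeric")
  flag(!is.na(value) & value < 0, "value_mgL must be non-negative")
  flag(!blank(raw$detection_limit_mgL) & (is.na(dl) | dl <= 0),
       "detection_limit_mgL must be a positive number when present")

  key <- paste(raw$site_id, raw$survey_id, raw$visit, raw$analyte, sep = "\r")
  flag(duplicated(key), "duplicate (site_id, survey_id, visit, analyte)")

  ok <- is.na(reason)
  samples <- tibble::tibble(
    site_id = raw$site_id[ok],
    survey_id = raw$survey_id[ok],
    visit = as.integer(visit[ok]),
    date = date[ok],
    waterbody = raw$waterbody[ok],
    ecoregion = as.integer(ecoregion[ok]),
    area_km2 = area[ok],
    analyte = raw$analyte[ok],
    value_mgL = value[ok],
    detection_limit_mgL = dl[ok]
  )
  attr(samples, "rejections") <- tibble::tibble(
    row = which(!ok), reason = reason[!ok]
  )
  samples
}

#' Rejected or excluded rows from an ingestion step
#'
#' @param x A tibble returned by [read_survey_table()] or
#'   [replace_nondetects()].
#' @return The diagnostics tibble attached by the producing step (empty if
#'   nothing was rejected).
#' @export
rejections <- function(x) {
  attr(x, "rejections") %||% tibble::tibble(row = integer(), reason = character())
}

#' Write a survey table in the canonical dialect
#'
#' Writes the exact canonical column order with ISO dates and empty strings
#' for missing values, so that reading and re-writing a canonical file is
#' byte-identical.
#'
#' @param samples A survey sample tibble (as from [read_survey_table()] or
#'   [generate_survey_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_survey_table <- function(samples, path) {
  fmt_num <- function(x) ifelse(is.na(x), "", vapply(x, as.character, ""))
  out <- tibble::tibble(
    site_id = samples$site_id,
    survey_id = samples$survey_id,
    visit = fmt_num(samples$visit),
    date = ifelse(is.na(samples$date), "", format(samples$date, "%Y-%m-%d")),
    waterbody = samples$waterbody,
    ecoregion = fmt_num(samples$ecoregion),
    area_km2 = fmt_num(samples$area_km2),
    analyte = samples$analyte,
    value_mgL = fmt_num(samples$value_mgL),
    detection_limit_mgL = fmt_num(samples$detection_limit_mgL)
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Replace nondetect zeroes with half the detection limit
#'
#' Monitoring programmes record measurements below the analytical detection
#' limit as zero. Zero concentrations break log transforms and percent
#' normalizations, so zeroes are replaced with `detection_limit_mgL / 2`, the
#' standard substitution. Records with a zero value but no recorded detection
#' limit cannot be substituted; they are excluded and flagged.
#'
#' @param samples A survey sample tibble.
#' @return The samples with zero values substituted. Attributes:
#'   `n_replaced` (count of substitutions) and `rejections` (excluded
#'   zero-value rows lacking a detection limit).
#' @export
replace_nondetects <- function(samples) {
  is_zero <- samples$value_mgL == 0
  can_fix <- is_zero & !is.na(samples$detection_limit_mgL)
  orphan <- is_zero & is.na(samples$detection_limit_mgL)
  out <- samples
  out$value_mgL[can_fix] <- out$detection_limit_mgL[can_fix] / 2
  excluded <- tibble::tibble(
    row = which(orphan),
    reason = rep("zero value with missing detection limit", sum(orphan))
  )
  out <- out[!orphan, , drop = FALSE]
  attr(out, "n_replaced") <- sum(can_fix)
  attr(out, "rejections") <- excluded
  out
}

#' Average repeat visits within a survey
#'
#' Some sites are sampled several times within one campaign to capture
#' seasonal and inter-annual variability; downstream analyses use the mean
#' concentration per site and survey. Site metadata (waterbody, ecoregion,
#' area) must be identical across a site's records within a survey; a
#' conflict is a hard error naming the offending sites rather than a silent
#' guess.
#'
#' @param samples A survey sample tibble with nondetects already replaced.
#' @return A tibble of site-survey means: one row per
#'   `(site_id, survey_id, analyte)` with `mean_value_mgL` and `n_visits`.
#' @export
average_revisits <- function(samples) {
  meta <- samples |>
    dplyr::distinct(
      .data$site_id, .data$survey_id, .data$waterbody, .data$ecoregion,
      .data$area_km2
    )
  dup <- meta |>
    dplyr::count(.data$site_id, .data$survey_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    stop_synoptic(
      "conflicting site metadata across visits for site(s): ",
      paste(unique(dup$site_id), collapse = ", ")
    )
  }
  samples |>
    dplyr::group_by(
      .data$site_id, .data$survey_id, .data$waterbody, .data$ecoregion,
      .data$area_km2, .data$analyte
    ) |>
    dplyr::summarise(
      mean_value_mgL = mean(.data$value_mgL),
      n_visits = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(
      "site_id", "survey_id", "waterbody", "ecoregion", "area_km2",
      "analyte", "mean_value_mgL", "n_visits"
    ) |>
    dplyr::arrange(.data$site_id, .data$survey_id, .data$analyte)
}

# Filter site-survey means to one analysis group.
# group: "national" or an ecoregion code; waterbody: NULL (both) or one class.
filter_group <- function(means, group = "national", waterbody = NULL) {
  out <- means
  if (!identical(group, "national")) {
    out <- dplyr::filter(out, !is.na(.data$ecoregion) &
                           .data$ecoregion == as.integer(group))
  }
  if (!is.null(waterbody)) {
    out <- dplyr::filter(out, .data$waterbody == !!waterbody)
  }
  out
}

#' Pair repeat sites between two survey campaigns
#'
#' Restricts two campaigns to the sites sampled in both (matched by
#' `site_id` string equality) for one analyte and analysis group, yielding
#' the paired panel used by change tests and persistence correlations.
#'
#' @param means Site-survey means from [average_revisits()].
#' @param survey_a,survey_b Survey identifiers to pair.
#' @param analyte Analyte to extract.
#' @param group `"national"` or an ecoregion code.
#' @param waterbody Optional `"lake"` or `"stream"` filter.
#' @return A tibble with columns `site_id`, `value_a_mgL`, `value_b_mgL`,
#'   sorted by `site_id`, with the pairing metadata attached as attributes
#'   (`survey_a`, `survey_b`, `analyte`, `group`, `waterbody`). Zero shared
#'   sites yields an empty panel with a warning.
#' @export
pair_repeat_sites <- function(means, survey_a, survey_b, analyte,
                              group = "national", waterbody = NULL) {
  sub <- filter_group(means, group, waterbody) |>
    dplyr::filter(.data$analyte == !!analyte)
  a <- dplyr::filter(sub, .data$survey_id == survey_a)
  b <- dplyr::filter(sub, .data$survey_id == survey_b)
  panel <- dplyr::inner_join(
    dplyr::select(a, "site_id", value_a_mgL = "mean_value_mgL"),
    dplyr::select(b, "site_id", value_b_mgL = "mean_value_mgL"),
    by = "site_id"
  ) |>
    dplyr::arrange(.data$site_id)
  if (nrow(panel) == 0L) {
    warning("no shared sites between '", survey_a, "' and '", survey_b,
            "' for ", analyte, " in group ", group, call. = FALSE)
  }
  attr(panel, "survey_a") <- survey_a
  attr(panel, "survey_b") <- survey_b
  attr(panel, "analyte") <- analyte
  attr(panel, "group") <- group
  attr(panel, "waterbody") <- waterbody
  panel
}
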