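# Spatial persistence: how strongly the spatial rank pattern of
# concentrations is conserved between survey campaigns.

#' Spearman rank correlation with average ranks
#'
#' Pearson correlation of the average-ranked data (ties receive average
#' ranks). Rank correlation compares only the ordering of sites, making the
#' persistence metric robust to the extreme values common in water chemistry.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return The rank correlation in `[-1, 1]`, or `NA` (with a warning) when
#'   either vector has zero rank variance.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    stop_synoptic("x and y must have equal length")
  }
  if (length(x) < 3L) {
    stop_synoptic("need at least 3 observations")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (pop_sd(rx) == 0 || pop_sd(ry) == 0) {
    warning("zero rank variance; rank correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  cor(rx, ry)
}

#' Spatial persistence of one analyte in one group
#'
#' Computes the rank correlation of repeat-site concentrations for every
#' pair of survey campaigns with at least `min_n` shared sites, then averages
#' the retained correlations. The mean is compared against the qualitative
#' threshold `sqrt(0.5)` (~0.71): above it, more than half of the spatial
#' pattern persists across campaigns.
#'
#' @param means Site-survey means from [average_revisits()].
#' @param analyte Analyte label.
#' @param group `"national"` or an ecoregion code.
#' @param waterbody Optional `"lake"` or `"stream"` filter.
#' @param surveys Survey sequence to consider; defaults to all present
#'   (all unordered pairs are evaluated).
#' @param min_n Minimum shared sites for a pair to count (default 10).
#' @return A `persistence_result`: list with `group`, `waterbody`, `analyte`,
#'   `pairs` (tibble `survey_a`, `survey_b`, `n_sites`, `rho`), `mean_rho`,
#'   `qualifies` (`mean_rho >= sqrt(0.5)`), `min_n` and `status`
#'   (`"ok"` or `"insufficient data"`).
#' @export
persistence <- function(means, analyte, group = "national", waterbody = NULL,
                        surveys = NULL, min_n = 10) {
  surveys <- surveys %||% sort(unique(means$survey_id))
  pairs <- list()
  if (length(surveys) >= 2L) {
    combos <- utils::combn(surveys, 2L)
    for (k in seq_len(ncol(combos))) {
      panel <- suppressWarnings(pair_repeat_sites(
        means, combos[1L, k], combos[2L, k], analyte,
        group = group, waterbody = waterbody
      ))
      rho <- if (nrow(panel) >= max(min_n, 3L)) {
        suppressWarnings(spearman_rho(panel$value_a_mgL, panel$value_b_mgL))
      } else {
        NA_real_
      }
      pairs[[k]] <- tibble::tibble(
        survey_a = combos[1L, k], survey_b = combos[2L, k],
        n_sites = nrow(panel), rho = rho
      )
    }
  }
  pairs <- dplyr::bind_rows(pairs)
  if (nrow(pairs) == 0L) {
    pairs <- tibble::tibble(
      survey_a = character(), survey_b = character(),
      n_sites = integer(), rho = numeric()
    )
  }
  retained <- pairs$rho[!is.na(pairs$rho)]
  mean_rho <- if (length(retained) > 0L) mean(retained) else NA_real_
  structure(
    list(
      group = as.character(group), waterbody = waterbody, analyte = analyte,
      pairs = pairs, mean_rho = mean_rho,
      qualifies = !is.na(mean_rho) && mean_rho >= sqrt(0.5),
      min_n = as.integer(min_n),
      status = if (is.na(mean_rho)) "insufficient data" else "ok"
    ),
    class = "persistence_result"
  )
}

#' @export
print.persistence_result <- function(x, ...) {
  cat("Spatial persistence:", x$analyte, "| group", x$group,
      if (!is.null(x$waterbody)) paste("|", x$waterbody) else "", "\n")
  if (x$status != "ok") {
    cat("  status:", x$status, "(min_n =", x$min_n, ")\n")
  } else {
    cat(sprintf("  mean rho = %.3f (%d pair%s); qualifies (>= sqrt(0.5)): %s\n",
                x$mean_rho, nrow(x$pairs), if (nrow(x$pairs) == 1) "" else "s",
                x$qualifies))
  }
  invisible(x)
}

#' Persistence across groups, waterbodies and analytes
#'
#' Convenience wrapper running [persistence()] over a grid of cells and
#' returning tidy per-pair and per-cell summary tibbles.
#'
#' @inheritParams persistence
#' @param groups Character vector of groups.
#' @param waterbodies Waterbody classes; defaults to all present.
#' @param analytes Analytes; defaults to all present.
#' @return A list of two tibbles: `pairs` (one row per survey pair per cell)
#'   and `summary` (one row per cell with `mean_rho`, `qualifies`, `min_n`,
#'   `status`).
#' @export
persistence_table <- function(means, groups = "national", waterbodies = NULL,
                              analytes = NULL, surveys = NULL, min_n = 10) {
  waterbodies <- waterbodies %||% sort(unique(means$waterbody))
  analytes <- analytes %||% sort(unique(means$analyte))
  pair_rows <- list()
  summary_rows <- list()
  for (g in groups) {
    for (w in waterbodies) {
      for (an in analytes) {
        res <- persistence(means, an, group = g, waterbody = w,
                           surveys = surveys, min_n = min_n)
        if (nrow(res$pairs) > 0L) {
          pair_rows[[length(pair_rows) + 1L]] <- dplyr::mutate(
            res$pairs, group = as.character(g), waterbody = w, analyte = an,
            .before = 1L
          )
        }
        summary_rows[[length(summary_rows) + 1L]] <- tibble::tibble(
          group = as.character(g), waterbody = w, analyte = an,
          mean_rho = res$mean_rho, qualifies = res$qualifies,
          min_n = res$min_n, status = res$status
        )
      }
    }
  }
  list(
    pairs = dplyr::bind_rows(pair_rows),
    summary = dplyr::bind_rows(summary_rows)
  )
}

#' Regression of lake on stream persistence across ecoregion cells
#'
#' Tests whether lake and stream persistence agree across ecoregion x analyte
#' cells (the no-difference expectation is slope 1, intercept 0, R^2 near 1)
#' by ordinary least squares of lake mean rank correlation on stream mean
#' rank correlation.
#'
#' @param cell_summary A persistence summary tibble (from
#'   [persistence_table()]`$summary`) containing both waterbody classes.
#' @return A list: `slope`, `intercept`, `r_squared`, `n_cells`, and the
#'   underlying `cells` tibble.
#' @export
lake_stream_persistence_regression <- function(cell_summary) {
  wide <- cell_summary |>
    dplyr::filter(!is.na(.data$mean_rho)) |>
    dplyr::select("group", "analyte", "waterbody", "mean_rho") |>
    tidyr::pivot_wider(names_from = "waterbody", values_from = "mean_rho")
  if (!all(c("lake", "stream") %in% names(wide))) {
    stop_synoptic("need both lake and stream persistence values")
  }
  cells <- wide[stats::complete.cases(wide[, c("lake", "stream")]), ]
  if (nrow(cells) < 3L) {
    stop_synoptic("need at least 3 ecoregion x analyte cells with both ",
                  "lake and stream persistence; got ", nrow(cells))
  }
  fit <- lm(lake ~ stream, data = cells)
  list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = summary(fit)$r.squared,
    n_cells = nrow(cells),
    cells = cells
  )
}
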