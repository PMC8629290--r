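# Patch size via variance collapse: standardize concentrations within a
# group, order by catchment area, and locate the area scale at which the
# site-to-site variance of the standardized series drops toward the regional
# mean. Changepoints come from a from-scratch PELT dynamic programme over a
# zero-mean Gaussian variance cost, verified against exhaustive enumeration,
# with a deterministic single-deletion screen replacing the manual
# false-positive review such analyses traditionally require.

VAR_FLOOR <- 1e-12

#' Standardize a group's concentrations and order by catchment area
#'
#' Concentrations are scaled by subtracting the group (e.g. ecoregion) mean
#' and dividing by the group standard deviation (population, divide-by-n
#' convention), so analytes with very different magnitudes are comparable;
#' the scaled series is ordered from smallest to largest catchment, ties in
#' area broken by `site_id` for determinism. Sites with missing area are
#' excluded.
#'
#' @param means Site-survey means from [average_revisits()].
#' @param analyte Analyte label.
#' @param group `"national"` or an ecoregion code.
#' @param waterbody Optional waterbody filter.
#' @return A `scaled_series`: list with `entries` (tibble `site_id`,
#'   `area_km2`, `z`, area-ordered), `group_mean_mgL`, `group_sd_mgL`,
#'   `group`, `waterbody`, `analyte`. `mean(z)` is 0 and the population
#'   variance of `z` is 1.
#' @export
scale_by_group <- function(means, analyte, group = "national",
                           waterbody = NULL) {
  sub <- filter_group(means, group, waterbody) |>
    dplyr::filter(.data$analyte == !!analyte, !is.na(.data$area_km2))
  # one value per site: average across surveys so repeat sites enter once
  sub <- sub |>
    dplyr::group_by(.data$site_id, .data$area_km2) |>
    dplyr::summarise(value = mean(.data$mean_value_mgL), .groups = "drop")
  if (nrow(sub) < 2L) {
    stop_synoptic("need at least 2 sites with area and concentration")
  }
  m <- mean(sub$value)
  s <- pop_sd(sub$value)
  if (s <= 0) {
    stop_synoptic("degenerate group: zero concentration variance")
  }
  entries <- sub |>
    dplyr::mutate(z = (.data$value - m) / s) |>
    dplyr::arrange(.data$area_km2, .data$site_id) |>
    dplyr::select("site_id", "area_km2", "z")
  structure(
    list(
      entries = entries, group_mean_mgL = m, group_sd_mgL = s,
      group = as.character(group), waterbody = waterbody, analyte = analyte
    ),
    class = "scaled_series"
  )
}

#' Segment cost: twice the negative Gaussian log-likelihood
#'
#' Cost of modelling a segment of the standardized series as zero-mean normal
#' with its maximum-likelihood variance `mean(z^2)` (floored at `1e-12` so
#' all-zero segments stay finite):
#' `n * (log(2*pi) + log(sigma2_hat) + 1)`.
#'
#' @param z_segment Numeric vector, length >= 2.
#' @return The segment cost.
#' @export
variance_cost <- function(z_segment) {
  n <- length(z_segment)
  stopifnot(n >= 2L)
  s2 <- max(mean(z_segment^2), VAR_FLOOR)
  n * (log(2 * pi) + log(s2) + 1)
}

# O(1) segment cost from a cumulative sum of squares (1-based inclusive i..j).
seg_cost_cs <- function(cs2, i, j) {
  len <- j - i + 1
  s2 <- max((cs2[j + 1L] - cs2[i]) / len, VAR_FLOOR)
  len * (log(2 * pi) + log(s2) + 1)
}

new_segmentation <- function(z, changepoints, penalty, min_seg_len,
                             status = "ok") {
  n <- length(z)
  bounds <- c(0L, changepoints, n)
  seg_var <- numeric(0)
  total <- penalty * length(changepoints)
  if (n > 0L && status == "ok") {
    cs2 <- c(0, cumsum(z^2))
    seg_var <- vapply(seq_len(length(bounds) - 1L), function(k) {
      max((cs2[bounds[k + 1L] + 1L] - cs2[bounds[k] + 1L]) /
            (bounds[k + 1L] - bounds[k]), VAR_FLOOR)
    }, 0)
    total <- total + sum(vapply(seq_len(length(bounds) - 1L), function(k) {
      seg_cost_cs(cs2, bounds[k] + 1L, bounds[k + 1L])
    }, 0))
  } else {
    total <- NA_real_
  }
  structure(
    list(
      changepoint_indices = as.integer(changepoints),
      segment_variances = seg_var,
      penalty_value = penalty,
      total_cost = total,
      min_seg_len = as.integer(min_seg_len),
      n = as.integer(n),
      status = status,
      screened_out = tibble::tibble(
        changepoint = integer(), reason = character()
      )
    ),
    class = "segmentation_result"
  )
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("Variance segmentation (n =", x$n, ", penalty =",
      format(x$penalty_value, digits = 4), ")\n")
  if (x$status != "ok") {
    cat("  status:", x$status, "\n")
  } else {
    cat("  changepoints after:",
        if (length(x$changepoint_indices)) paste(x$changepoint_indices, collapse = ", ") else "none",
        "\n  segment variances:",
        paste(format(x$segment_variances, digits = 3), collapse = ", "), "\n")
    if (nrow(x$screened_out) > 0L) {
      cat("  screened out:", nrow(x$screened_out), "changepoint(s)\n")
    }
  }
  invisible(x)
}

#' PELT changepoint detection for variance shifts
#'
#' Finds the segmentation of an ordered standardized series minimizing the
#' penalized objective `sum of segment costs + penalty * (number of
#' changepoints)` (cost from [variance_cost()]) by the pruned exact linear
#' time dynamic programme. The pruning constant is 0, valid because splitting
#' a segment never increases its total cost, so the result equals exhaustive
#' search. Changepoint index *k* means a new segment begins after position
#' *k*.
#'
#' @param z Numeric series (ordered, standardized).
#' @param penalty Penalty per changepoint; default is the BIC-scale
#'   `2 * log(n)`.
#' @param min_seg_len Minimum segment length (default 10); series shorter
#'   than `2 * min_seg_len` return status `"too short"`.
#' @return A `segmentation_result`: `changepoint_indices`,
#'   `segment_variances` (ML variances per segment), `penalty_value`,
#'   `total_cost`, `min_seg_len`, `status`.
#' @export
pelt_changepoints <- function(z, penalty = NULL, min_seg_len = 10) {
  n <- length(z)
  penalty <- penalty %||% (2 * log(max(n, 2L)))
  stopifnot(penalty > 0, min_seg_len >= 2L)
  if (n < 2L * min_seg_len) {
    return(new_segmentation(z, integer(), penalty, min_seg_len,
                            status = "too short"))
  }
  cs2 <- c(0, cumsum(z^2))
  # f[t + 1] = optimal objective for z[1..t]; f[1] = -penalty so the first
  # segment is not charged a changepoint.
  f <- rep(Inf, n + 1L)
  f[1L] <- -penalty
  last <- integer(n + 1L)
  # Candidate last-changepoint positions (0 = no changepoint). A candidate
  # dominated at time t (pruning inequality, K = 0) is only provably useless
  # once the dominating position t itself is usable, i.e. for t' >= t +
  # min_seg_len; until then it stays available (`expire` = pruning time +
  # min_seg_len). Without this grace period PELT with a minimum segment
  # length can miss the optimum.
  cands <- 0L
  expire <- Inf
  for (t in seq_len(n)) {
    if (t < min_seg_len) next
    live <- expire > t
    cands <- cands[live]
    expire <- expire[live]
    elig <- which(t - cands >= min_seg_len)
    costs <- f[cands[elig] + 1L] + vapply(
      cands[elig], function(tau) seg_cost_cs(cs2, tau + 1L, t), 0
    )
    best <- which.min(costs)
    f[t + 1L] <- costs[best] + penalty
    last[t + 1L] <- cands[elig[best]]
    newly_pruned <- elig[costs > f[t + 1L]]
    expire[newly_pruned] <- pmin(expire[newly_pruned], t + min_seg_len)
    if (t + min_seg_len <= n) {
      cands <- c(cands, t) # t becomes a candidate once a segment can follow
      expire <- c(expire, Inf)
    }
  }
  cps <- integer()
  t <- n
  while (last[t + 1L] > 0L) {
    cps <- c(last[t + 1L], cps)
    t <- last[t + 1L]
  }
  new_segmentation(z, cps, penalty, min_seg_len)
}

#' Exhaustive changepoint search (testing oracle)
#'
#' Minimizes the same penalized objective as [pelt_changepoints()] by
#' enumerating every admissible placement of up to `max_changepoints`
#' changepoints. Intended as an independent correctness oracle on small
#' series; refuses large inputs.
#'
#' @param z Numeric series, `length(z) <= 40`.
#' @param penalty Penalty per changepoint.
#' @param min_seg_len Minimum segment length.
#' @param max_changepoints Maximum changepoints to enumerate (<= 3).
#' @return A `segmentation_result` with the exact optimum.
#' @export
exhaustive_changepoints <- function(z, penalty = NULL, min_seg_len = 10,
                                    max_changepoints = 3) {
  n <- length(z)
  penalty <- penalty %||% (2 * log(max(n, 2L)))
  if (n > 40L) {
    stop_synoptic("exhaustive search refuses n > 40")
  }
  if (max_changepoints > 3L) {
    stop_synoptic("exhaustive search refuses max_changepoints > 3")
  }
  if (n < 2L * min_seg_len) {
    return(new_segmentation(z, integer(), penalty, min_seg_len,
                            status = "too short"))
  }
  cs2 <- c(0, cumsum(z^2))
  objective <- function(cps) {
    bounds <- c(0L, cps, n)
    if (any(diff(bounds) < min_seg_len)) {
      return(Inf)
    }
    sum(vapply(seq_len(length(bounds) - 1L), function(k) {
      seg_cost_cs(cs2, bounds[k] + 1L, bounds[k + 1L])
    }, 0)) + penalty * length(cps)
  }
  best_cps <- integer()
  best_obj <- objective(integer())
  positions <- seq_len(n - 1L)
  for (m in seq_len(max_changepoints)) {
    if (m > 0L && n < (m + 1L) * min_seg_len) break
    combos <- utils::combn(positions, m)
    for (k in seq_len(ncol(combos))) {
      obj <- objective(combos[, k])
      if (obj < best_obj - 1e-12) {
        best_obj <- obj
        best_cps <- combos[, k]
      }
    }
  }
  new_segmentation(z, best_cps, penalty, min_seg_len)
}

# ML variance (mean of squares) of a sub-vector, floored.
ml_var <- function(v) {
  max(mean(v^2), VAR_FLOOR)
}

#' Screen changepoints for single-point false positives
#'
#' A single extreme site can carve out a spurious variance changepoint. The
#' screen re-examines each changepoint after deleting the single largest
#' `|z|` value from either adjacent segment: if any such deletion (or the
#' undeleted data themselves) drops the between-segment variance ratio
#' `max(v1, v2) / min(v1, v2)` below `retention_ratio`, the changepoint is
#' rejected with a reason. This replaces, deterministically, the manual
#' review step such analyses otherwise require.
#'
#' @param series The `scaled_series` that was segmented (or a numeric
#'   vector).
#' @param segmentation A `segmentation_result` from [pelt_changepoints()].
#' @param retention_ratio Minimum surviving variance ratio (default 2).
#' @return A `segmentation_result` keeping only retained changepoints, with
#'   `screened_out` listing rejections.
#' @export
screen_false_positives <- function(series, segmentation,
                                   retention_ratio = 2) {
  z <- if (inherits(series, "scaled_series")) series$entries$z else series
  cps <- segmentation$changepoint_indices
  if (length(cps) == 0L || segmentation$status != "ok") {
    return(segmentation)
  }
  bounds <- c(0L, cps, length(z))
  retained <- logical(length(cps))
  reasons <- character(length(cps))
  for (k in seq_along(cps)) {
    up <- z[(bounds[k] + 1L):bounds[k + 1L]]
    down <- z[(bounds[k + 1L] + 1L):bounds[k + 2L]]
    ratios <- c(
      var_ratio(ml_var(up), ml_var(down)),
      var_ratio(ml_var(drop_largest(up)), ml_var(down)),
      var_ratio(ml_var(up), ml_var(drop_largest(down)))
    )
    if (min(ratios) < retention_ratio) {
      retained[k] <- FALSE
      reasons[k] <- sprintf(
        "variance ratio %.2f below retention ratio %.2f after single-point deletion",
        min(ratios), retention_ratio
      )
    } else {
      retained[k] <- TRUE
    }
  }
  out <- new_segmentation(z, cps[retained], segmentation$penalty_value,
                          segmentation$min_seg_len)
  out$screened_out <- tibble::tibble(
    changepoint = cps[!retained], reason = reasons[!retained]
  )
  out
}

var_ratio <- function(v1, v2) {
  max(v1, v2) / min(v1, v2)
}

drop_largest <- function(v) {
  if (length(v) <= 2L) {
    return(v) # never shrink a segment below the cost's minimum length
  }
  v[-which.max(abs(v))]
}

#' Variance-collapse thresholds from a screened segmentation
#'
#' For each retained changepoint, compares the upstream (smaller-area) and
#' downstream (larger-area) segment variances. Where variance decreases, the
#' catchment area of the first site of the downstream segment is reported as
#' a collapse threshold (the patch size); variance increases are reported
#' too but flagged by direction and never counted as collapse thresholds.
#'
#' @param series The `scaled_series` that was segmented.
#' @param segmentation A screened `segmentation_result`.
#' @return A tibble: `changepoint_index`, `changepoint_area_km2`,
#'   `direction` (`"decrease"`/`"increase"`), `upstream_variance`,
#'   `downstream_variance`. Collapse thresholds are the `"decrease"` rows.
#' @export
collapse_threshold <- function(series, segmentation) {
  stopifnot(inherits(series, "scaled_series"))
  cps <- segmentation$changepoint_indices
  if (length(cps) == 0L || segmentation$status != "ok") {
    return(tibble::tibble(
      changepoint_index = integer(), changepoint_area_km2 = numeric(),
      direction = character(), upstream_variance = numeric(),
      downstream_variance = numeric()
    ))
  }
  vars <- segmentation$segment_variances
  tibble::tibble(
    changepoint_index = cps,
    changepoint_area_km2 = series$entries$area_km2[cps + 1L],
    direction = ifelse(vars[-1L] < vars[-length(vars)],
                       "decrease", "increase"),
    upstream_variance = vars[-length(vars)],
    downstream_variance = vars[-1L]
  )
}

#' Primary collapse threshold (the patch size)
#'
#' Heavy-tailed concentration data can produce several variance decreases at
#' small scales where isolated clusters of extreme sites are carved out. The
#' patch size proper is the spatial scale above which the standardized series
#' stays collapsed toward the regional mean, i.e. the largest-area retained
#' decreasing changepoint.
#'
#' @param thresholds A patch-size tibble from [patch_size()] (or the
#'   `"decrease"` rows of [collapse_threshold()]).
#' @return The primary threshold in km2, or `NA` when no retained decreasing
#'   changepoint exists.
#' @export
primary_collapse_threshold <- function(thresholds) {
  dec <- thresholds[!is.na(thresholds$direction) &
                      thresholds$direction == "decrease", ]
  if ("retained" %in% names(dec)) {
    dec <- dec[!is.na(dec$retained) & dec$retained, ]
  }
  if (nrow(dec) == 0L) {
    return(NA_real_)
  }
  max(dec$changepoint_area_km2)
}

#' Patch-size analysis for one group and analyte
#'
#' Full variance-collapse pipeline: standardize and area-order the group's
#' concentrations ([scale_by_group()]), segment with [pelt_changepoints()],
#' screen single-point false positives, and extract collapse thresholds.
#' Groups with fewer than `2 * min_seg_len` sites are reported as not
#' determinable rather than failing.
#'
#' @inheritParams scale_by_group
#' @param penalty Penalty per changepoint; default `2 * log(n)`.
#' @param min_seg_len Minimum segment length (default 10).
#' @param retention_ratio Screening ratio (default 2).
#' @return A tibble with one row per changepoint (screened in or out):
#'   `group`, `waterbody`, `analyte`, `n_sites`, `status`,
#'   `changepoint_area_km2`, `direction`, `upstream_variance`,
#'   `downstream_variance`, `retained`, `reason`. A group with no
#'   changepoints (or too few sites) yields a single row with `NA`
#'   changepoint fields and the appropriate `status`.
#' @export
patch_size <- function(means, analyte, group = "national", waterbody = NULL,
                       penalty = NULL, min_seg_len = 10,
                       retention_ratio = 2) {
  base <- tibble::tibble(
    group = as.character(group),
    waterbody = waterbody %||% NA_character_,
    analyte = analyte,
    n_sites = 0L, status = "not determinable",
    changepoint_area_km2 = NA_real_, direction = NA_character_,
    upstream_variance = NA_real_, downstream_variance = NA_real_,
    retained = NA, reason = NA_character_
  )
  series <- tryCatch(
    scale_by_group(means, analyte, group = group, waterbody = waterbody),
    error = function(e) NULL
  )
  if (is.null(series)) {
    return(base)
  }
  n <- nrow(series$entries)
  base$n_sites <- n
  if (n < 2L * min_seg_len) {
    return(base)
  }
  seg <- pelt_changepoints(series$entries$z, penalty = penalty,
                           min_seg_len = min_seg_len)
  screened <- screen_false_positives(series, seg,
                                     retention_ratio = retention_ratio)
  kept <- collapse_threshold(series, screened)
  rows <- list()
  if (nrow(kept) > 0L) {
    rows[[1L]] <- dplyr::mutate(
      kept, retained = TRUE, reason = NA_character_
    )
  }
  if (nrow(screened$screened_out) > 0L) {
    rej <- collapse_threshold(series, seg)
    rej <- rej[rej$changepoint_index %in% screened$screened_out$changepoint, ]
    rej$retained <- FALSE
    rej$reason <- screened$screened_out$reason[
      match(rej$changepoint_index, screened$screened_out$changepoint)
    ]
    rows[[length(rows) + 1L]] <- rej
  }
  if (length(rows) == 0L) {
    base$status <- "no changepoints"
    return(base)
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$changepoint_index) |>
    dplyr::mutate(
      group = as.character(group),
      waterbody = waterbody %||% NA_character_,
      analyte = analyte, n_sites = n, status = "ok",
      .before = 1L
    ) |>
    dplyr::select(-"changepoint_index")
  out
}
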