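# Synthetic survey generator: lognormal water chemistry with controllable
# rank persistence, small-catchment patch variance, critical sources,
# nondetects and between-survey trends.

default_mu_log <- c(DOC = log(5), NO3 = log(0.2), TN = log(0.8), TP = log(0.05))
default_sigma_log <- c(DOC = 0.6, NO3 = 1.1, TN = 0.6, TP = 0.9)

#' Configuration for the synthetic survey generator
#'
#' Defines the statistical structure of a simulated monitoring programme.
#' Concentrations are lognormal: for site *i*, analyte *a*, survey *j*,
#' `log C = mu_log[a] + site_effect + survey_noise + source term +
#' log(trend_multipliers[j])`, where the permanent site effect carries a
#' fraction `persistence_share` of the log-scale variance (so the expected
#' between-survey Pearson correlation of log concentration equals the share,
#' and the expected Spearman correlation is
#' [expected_rank_persistence()]`(share)`). Sites with catchment area below
#' `patch_area_km2` have both variance components scaled by
#' `patch_variance_ratio`, producing the small-catchment variance inflation
#' that the patch-size analysis detects; a `source_fraction` of those small
#' sites are "critical sources" whose concentrations are multiplied by
#' `source_multiplier`.
#'
#' @param n_sites Sites per ecoregion x waterbody cell per survey.
#' @param ecoregions Integer ecoregion codes.
#' @param waterbodies Waterbody classes to simulate (`"stream"`, `"lake"`).
#' @param surveys Ordered character vector of survey campaign labels.
#' @param repeat_fraction Fraction of a cell's sites shared between
#'   consecutive surveys (in `[0, 1]`).
#' @param area_log10_range Length-2 numeric: catchment areas are sampled
#'   log10-uniformly on this range (km2).
#' @param persistence_share Fraction of log-concentration variance carried by
#'   the permanent site effect (in `[0, 1]`).
#' @param patch_area_km2 Area threshold below which extra variance is
#'   injected.
#' @param patch_variance_ratio Small- to large-catchment variance ratio of
#'   log concentration (`>= 1`; `1` disables the patch structure).
#' @param source_fraction Fraction of small-catchment sites made critical
#'   sources.
#' @param source_multiplier Concentration multiplier for critical sources
#'   (`> 1`).
#' @param trend_multipliers Named (by survey) or unnamed per-survey
#'   multiplicative concentration shifts; default all 1.
#' @param analytes Analyte labels to simulate.
#' @param mu_log,sigma_log Named per-analyte baseline lognormal parameters
#'   (natural-log scale); defaults are typical stream values in mg/L.
#' @param detection_limit_mgL Detection limit; generated values below it are
#'   written as zero with the limit recorded.
#' @param conservative_outlet If `TRUE`, each cell's outlet is a conservative
#'   mixture: its area is the sum of the subcatchment areas and its
#'   concentration the area-weighted mean of theirs, making the leverage
#'   zero-sum identity hold exactly (nondetect zeroing is skipped in this
#'   mode so the identity is not perturbed).
#' @param seed Integer seed; identical configurations generate identical
#'   tables.
#' @return A validated `synoptic_config` list.
#' @export
synthetic_config <- function(n_sites = 100,
                             ecoregions = c(5, 8, 9),
                             waterbodies = "stream",
                             surveys = c("SV1", "SV2"),
                             repeat_fraction = 1,
                             area_log10_range = c(-1, 4),
                             persistence_share = 0.6,
                             patch_area_km2 = 250,
                             patch_variance_ratio = 4,
                             source_fraction = 0.05,
                             source_multiplier = 10,
                             trend_multipliers = NULL,
                             analytes = c("DOC", "NO3", "TN", "TP"),
                             mu_log = NULL,
                             sigma_log = NULL,
                             detection_limit_mgL = 0.001,
                             conservative_outlet = FALSE,
                             seed = 1L) {
  surveys <- as.character(surveys)
  analytes <- as.character(analytes)
  if (is.null(trend_multipliers)) {
    trend_multipliers <- setNames(rep(1, length(surveys)), surveys)
  } else {
    trend_multipliers <- unlist(trend_multipliers)
    if (is.null(names(trend_multipliers))) {
      names(trend_multipliers) <- surveys
    }
  }
  mu_log <- fill_by_analyte(mu_log, analytes, default_mu_log, 0)
  sigma_log <- fill_by_analyte(sigma_log, analytes, default_sigma_log, 0.6)

  cfg <- list(
    n_sites = as.integer(n_sites), ecoregions = as.integer(ecoregions),
    waterbodies = waterbodies, surveys = surveys,
    repeat_fraction = repeat_fraction,
    area_log10_range = as.numeric(area_log10_range),
    persistence_share = persistence_share,
    patch_area_km2 = patch_area_km2,
    patch_variance_ratio = patch_variance_ratio,
    source_fraction = source_fraction,
    source_multiplier = source_multiplier,
    trend_multipliers = trend_multipliers,
    analytes = analytes, mu_log = mu_log, sigma_log = sigma_log,
    detection_limit_mgL = detection_limit_mgL,
    conservative_outlet = isTRUE(conservative_outlet),
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  structure(cfg, class = "synoptic_config")
}

fill_by_analyte <- function(x, analytes, defaults, fallback) {
  x <- unlist(x)
  out <- setNames(rep(fallback, length(analytes)), analytes)
  known <- intersect(analytes, names(defaults))
  out[known] <- defaults[known]
  if (!is.null(x)) {
    if (is.null(names(x))) {
      if (length(x) != length(analytes)) {
        stop_synoptic("per-analyte parameters must be named or match length")
      }
      names(x) <- analytes
    }
    out[names(x)] <- x
  }
  out
}

validate_synthetic_config <- function(cfg) {
  check <- function(ok, msg) if (!ok) stop_synoptic("invalid config: ", msg)
  check(cfg$n_sites >= 1, "n_sites must be >= 1")
  check(length(cfg$surveys) >= 1, "at least one survey required")
  check(!anyDuplicated(cfg$surveys), "survey ids must be unique")
  check(all(cfg$waterbodies %in% valid_waterbodies),
        "waterbodies must be lake|stream")
  check(cfg$repeat_fraction >= 0 && cfg$repeat_fraction <= 1,
        "repeat_fraction must be in [0, 1]")
  check(length(cfg$area_log10_range) == 2 &&
          diff(cfg$area_log10_range) > 0, "area_log10_range must increase")
  check(cfg$persistence_share >= 0 && cfg$persistence_share <= 1,
        "persistence_share must be in [0, 1]")
  check(cfg$patch_area_km2 > 0, "patch_area_km2 must be positive")
  check(cfg$patch_variance_ratio >= 1, "patch_variance_ratio must be >= 1")
  check(cfg$source_fraction >= 0 && cfg$source_fraction <= 1,
        "source_fraction must be in [0, 1]")
  check(cfg$source_multiplier > 1, "source_multiplier must be > 1")
  check(all(cfg$trend_multipliers > 0), "trend multipliers must be > 0")
  check(all(cfg$surveys %in% names(cfg$trend_multipliers)),
        "trend_multipliers must cover every survey")
  check(cfg$detection_limit_mgL > 0, "detection_limit_mgL must be positive")
  invisible(cfg)
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of
#'   [synthetic_config()].
#' @return A validated `synoptic_config`.
#' @export
read_synthetic_config <- function(path) {
  do.call(synthetic_config, yaml::read_yaml(path))
}

#' Expected Spearman correlation implied by a persistence share
#'
#' Two surveys' log concentrations at a shared site are bivariate normal with
#' Pearson correlation equal to the persistence share (the variance fraction
#' of the permanent site effect). For a bivariate normal with Pearson
#' correlation *r*, the population Spearman correlation is
#' `(6 / pi) * asin(r / 2)`; this is the recovery target for the persistence
#' analysis on generated data.
#'
#' @param persistence_share Share in `[0, 1]`.
#' @return The implied Spearman correlation.
#' @export
expected_rank_persistence <- function(persistence_share) {
  stopifnot(all(persistence_share >= 0), all(persistence_share <= 1))
  (6 / pi) * asin(persistence_share / 2)
}

#' Generate a synthetic survey table
#'
#' Deterministically (given `config$seed`) simulates the long-format survey
#' table described by a [synthetic_config()]: per-cell site panels with the
#' configured overlap between consecutive surveys, log10-uniform catchment
#' areas with one designated largest-area outlet per ecoregion x waterbody
#' cell, lognormal concentrations with a persistent site effect, patch and
#' source structure, nondetect zeroes, and per-survey trend multipliers.
#'
#' Site-level draws (areas, site effects, source flags) come from the
#' seed-initialized stream; each survey's sampling noise comes from a
#' sub-stream keyed by the survey index, so adding a survey does not disturb
#' earlier ones.
#'
#' @param config A [synthetic_config()].
#' @return A survey sample tibble in the canonical column order, one row per
#'   site x survey x analyte (visit 1).
#' @export
generate_survey_table <- function(config) {
  if (!inherits(config, "synoptic_config")) {
    config <- do.call(synthetic_config, config)
  }
  cfg <- config
  cells <- expand.grid(
    ecoregion = cfg$ecoregions, waterbody = cfg$waterbodies,
    stringsAsFactors = FALSE
  )
  cells <- cells[order(cells$ecoregion, cells$waterbody), , drop = FALSE]
  n_surv <- length(cfg$surveys)
  n_keep <- round(cfg$repeat_fraction * cfg$n_sites)

  # --- site registry (site-level randomness, one stream) -------------------
  set.seed(cfg$seed)
  registry <- list() # per cell: tibble of site attributes
  roster <- list()   # per cell: list of site-index vectors per survey
  share <- cfg$persistence_share
  for (ci in seq_len(nrow(cells))) {
    total_new <- cfg$n_sites + (n_surv - 1L) * (cfg$n_sites - n_keep)
    wb <- cells$waterbody[ci]
    eco <- cells$ecoregion[ci]
    area <- 10^runif(total_new, cfg$area_log10_range[1], cfg$area_log10_range[2])
    area[1] <- 10^cfg$area_log10_range[2] # designated outlet: largest area
    small <- area < cfg$patch_area_km2
    infl <- ifelse(small, sqrt(cfg$patch_variance_ratio), 1)
    effects <- matrix(rnorm(total_new * length(cfg$analytes)),
                      nrow = total_new)
    colnames(effects) <- cfg$analytes
    for (a in cfg$analytes) {
      effects[, a] <- effects[, a] * sqrt(share) * cfg$sigma_log[a] * infl
    }
    is_source <- small & runif(total_new) < cfg$source_fraction
    registry[[ci]] <- list(
      site_id = sprintf("%s-E%02d-%05d", toupper(substr(wb, 1, 2)), eco,
                        seq_len(total_new)),
      area = area, small = small, infl = infl, effects = effects,
      is_source = is_source
    )
    # survey rosters: first survey takes sites 1..n; later surveys keep the
    # first n_keep of the previous roster and draw fresh sites for the rest
    ros <- vector("list", n_surv)
    ros[[1]] <- seq_len(cfg$n_sites)
    nxt <- cfg$n_sites + 1L
    for (j in seq_len(n_surv)[-1]) {
      fresh <- cfg$n_sites - n_keep
      ros[[j]] <- c(
        ros[[j - 1L]][seq_len(n_keep)],
        if (fresh > 0L) seq.int(nxt, nxt + fresh - 1L) else integer()
      )
      nxt <- nxt + fresh
    }
    roster[[ci]] <- ros
  }

  # --- per-survey sampling noise (sub-stream per survey) -------------------
  rows <- list()
  for (j in seq_len(n_surv)) {
    set.seed((cfg$seed + 7919L * j) %% .Machine$integer.max)
    sv <- cfg$surveys[j]
    trend <- cfg$trend_multipliers[[sv]]
    date_j <- as.Date(sprintf("%d-07-01", 2000L + 2L * (j - 1L)))
    for (ci in seq_len(nrow(cells))) {
      reg <- registry[[ci]]
      idx <- roster[[ci]][[j]]
      n_i <- length(idx)
      for (a in cfg$analytes) {
        noise_sd <- sqrt(1 - share) * cfg$sigma_log[a] * reg$infl[idx]
        lc <- cfg$mu_log[a] + reg$effects[idx, a] +
          rnorm(n_i, 0, 1) * noise_sd +
          ifelse(reg$is_source[idx], log(cfg$source_multiplier), 0) +
          log(trend)
        value <- exp(lc)
        area_out <- reg$area[idx]
        if (cfg$conservative_outlet) {
          # outlet (registry site 1) becomes the conservative mixture of the
          # cell's other sampled sites: exact mass balance by construction
          pos <- match(1L, idx)
          if (!is.na(pos) && n_i > 1L) {
            others <- setdiff(seq_len(n_i), pos)
            area_out[pos] <- sum(area_out[others])
            value[pos] <- sum(value[others] * reg$area[idx][others]) /
              sum(reg$area[idx][others])
          }
        } else {
          nd <- value < cfg$detection_limit_mgL
          value[nd] <- 0
        }
        rows[[length(rows) + 1L]] <- tibble::tibble(
          site_id = reg$site_id[idx],
          survey_id = sv,
          visit = 1L,
          date = date_j,
          waterbody = cells$waterbody[ci],
          ecoregion = as.integer(cells$ecoregion[ci]),
          area_km2 = area_out,
          analyte = a,
          value_mgL = value,
          detection_limit_mgL = cfg$detection_limit_mgL
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- cfg
  out
}
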