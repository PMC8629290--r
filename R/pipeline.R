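# End-to-end pipeline driver: ingest or simulate, normalize, then run the
# temporal, persistence, patch-size and leverage stages with deterministic
# CSV outputs and a machine-readable manifest.

#' Pipeline run configuration
#'
#' Exactly one of `input` (a canonical survey CSV) or `synthetic` (arguments
#' for [synthetic_config()]) must be given.
#'
#' @param input Path to a survey CSV, or `NULL`.
#' @param synthetic A list of [synthetic_config()] arguments, or `NULL`.
#' @param out_dir Output directory (created if needed).
#' @param stages Stages to run, a subset of
#'   `c("temporal", "persistence", "patchsize", "leverage")`.
#' @param analytes,waterbodies Optional filters; default all present.
#' @param groups Groups to analyse; default `"national"` plus every
#'   ecoregion present in the data.
#' @param alpha,min_n,penalty,min_seg_len,retention_ratio,tolerance,flux_share
#'   Stage parameters (see the stage functions for meaning and defaults).
#' @param seed Seed applied to the synthetic generator when `synthetic` is
#'   used (overrides its `seed` entry).
#' @param log_level `"quiet"` or `"info"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, synthetic = NULL, out_dir = "synoptic-out",
                       stages = c("temporal", "persistence", "patchsize",
                                  "leverage"),
                       analytes = NULL, waterbodies = NULL, groups = NULL,
                       alpha = 0.05, min_n = 10, penalty = NULL,
                       min_seg_len = 10, retention_ratio = 2,
                       tolerance = 0.5, flux_share = 0.75,
                       seed = NULL, log_level = "info") {
  if (is.null(input) == is.null(synthetic)) {
    stop_synoptic("config error: exactly one of 'input' or 'synthetic' ",
                  "must be provided")
  }
  known <- c("temporal", "persistence", "patchsize", "leverage")
  if (!all(stages %in% known)) {
    stop_synoptic("config error: unknown stage(s): ",
                  paste(setdiff(stages, known), collapse = ", "))
  }
  structure(
    list(
      input = input, synthetic = synthetic, out_dir = out_dir,
      stages = stages, analytes = analytes, waterbodies = waterbodies,
      groups = groups, alpha = alpha, min_n = min_n, penalty = penalty,
      min_seg_len = min_seg_len, retention_ratio = retention_ratio,
      tolerance = tolerance, flux_share = flux_share, seed = seed,
      log_level = log_level
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

pipe_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) {
    message("[synoptic] ", ...)
  }
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in order -- ingest (or simulate), nondetect
#' replacement, revisit averaging, then temporal change tests, persistence,
#' patch size and leverage -- writing each stage's CSV into `out_dir`
#' together with `manifest.json` recording the configuration hash, seed,
#' record counts, stage outputs and machine-readable warnings. Identical
#' configurations produce identical outputs.
#'
#' @param config A [run_config()] (or a list of its arguments).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) {
    config <- do.call(run_config, config)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  warn_rows <- list()
  note <- function(stage, message) {
    warn_rows[[length(warn_rows) + 1L]] <<- tibble::tibble(
      stage = stage, message = message
    )
  }
  emit <- function(tbl, name) {
    path <- file.path(config$out_dir, name)
    readr::write_csv(tbl, path, na = "", progress = FALSE)
    outputs <<- c(outputs, name)
  }

  # --- ingest -------------------------------------------------------------
  if (!is.null(config$input)) {
    samples <- read_survey_table(config$input)
    pipe_log(config, "ingested ", nrow(samples), " records from ",
             config$input)
  } else {
    syn_args <- config$synthetic
    if (!is.null(config$seed)) {
      syn_args$seed <- config$seed
    }
    samples <- generate_survey_table(do.call(synthetic_config, syn_args))
    emit(samples, "samples.csv")
    pipe_log(config, "generated ", nrow(samples), " synthetic records")
  }
  n_ingested <- nrow(samples) + nrow(rejections(samples))
  n_rejected <- nrow(rejections(samples))
  for (r in seq_len(min(n_rejected, 50L))) {
    note("ingest", paste0("row ", rejections(samples)$row[r], ": ",
                          rejections(samples)$reason[r]))
  }

  # --- normalize ----------------------------------------------------------
  samples <- replace_nondetects(samples)
  n_excluded <- nrow(rejections(samples))
  if (n_excluded > 0L) {
    note("nondetects", paste0(n_excluded,
                              " zero-value record(s) lacked a detection limit"))
  }
  means <- average_revisits(samples)
  emit(means, "site_survey_means.csv")

  analytes <- config$analytes %||% sort(unique(means$analyte))
  waterbodies <- config$waterbodies %||% sort(unique(means$waterbody))
  groups <- config$groups %||%
    c("national", sort(unique(means$ecoregion[!is.na(means$ecoregion)])))
  groups <- as.character(groups)
  surveys <- sort(unique(means$survey_id))

  # --- temporal -----------------------------------------------------------
  if ("temporal" %in% config$stages && length(surveys) >= 2L) {
    changes <- summarize_changes(
      means, surveys = surveys, groups = groups, analytes = analytes,
      waterbodies = waterbodies, alpha = config$alpha
    )
    emit(changes, "temporal_changes.csv")
    sk <- attr(changes, "skipped")
    if (!is.null(sk) && nrow(sk) > 0L) {
      note("temporal", paste0(nrow(sk), " combination(s) skipped: ",
                              "fewer than 2 shared sites"))
    }
  } else if ("temporal" %in% config$stages) {
    note("temporal", "skipped: fewer than 2 surveys")
  }

  # --- persistence --------------------------------------------------------
  if ("persistence" %in% config$stages && length(surveys) >= 2L) {
    pers <- persistence_table(
      means, groups = groups, waterbodies = waterbodies,
      analytes = analytes, surveys = surveys, min_n = config$min_n
    )
    emit(pers$pairs, "persistence_pairs.csv")
    emit(pers$summary, "persistence_summary.csv")
    insufficient <- sum(pers$summary$status != "ok")
    if (insufficient > 0L) {
      note("persistence", paste0(insufficient,
                                 " cell(s) had insufficient shared sites"))
    }
  } else if ("persistence" %in% config$stages) {
    note("persistence", "skipped: fewer than 2 surveys")
  }

  # --- patch size ---------------------------------------------------------
  if ("patchsize" %in% config$stages) {
    patch_rows <- list()
    for (g in groups) {
      for (w in waterbodies) {
        for (an in analytes) {
          patch_rows[[length(patch_rows) + 1L]] <- patch_size(
            means, an, group = g, waterbody = w, penalty = config$penalty,
            min_seg_len = config$min_seg_len,
            retention_ratio = config$retention_ratio
          )
        }
      }
    }
    patches <- dplyr::bind_rows(patch_rows)
    emit(patches, "patch_thresholds.csv")
    nd <- sum(patches$status == "not determinable")
    if (nd > 0L) {
      note("patchsize", paste0(nd, " cell(s) not determinable: fewer than ",
                               2 * config$min_seg_len, " sites with area"))
    }
  }

  # --- leverage -----------------------------------------------------------
  if ("leverage" %in% config$stages) {
    lev_rows <- list()
    sum_rows <- list()
    for (g in groups) {
      for (w in waterbodies) {
        for (an in analytes) {
          tbl <- tryCatch(
            leverage_table(means, an, group = g, waterbody = w),
            error = function(e) NULL
          )
          if (is.null(tbl) || nrow(tbl) == 0L) {
            note("leverage", paste0("no outlet context for group ", g, " ",
                                    w, " ", an))
            next
          }
          lev_rows[[length(lev_rows) + 1L]] <- tbl
          sum_rows[[length(sum_rows) + 1L]] <- leverage_summary(
            tbl, tolerance = config$tolerance, flux_share = config$flux_share
          )
        }
      }
    }
    if (length(lev_rows) > 0L) {
      emit(dplyr::bind_rows(lev_rows), "leverage_sites.csv")
      emit(dplyr::bind_rows(sum_rows), "leverage_summary.csv")
    }
    note("leverage", LEVERAGE_CAVEAT)
  }

  # --- manifest -----------------------------------------------------------
  warns <- dplyr::bind_rows(warn_rows)
  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed %||% config$synthetic$seed %||% NA,
    counts = list(
      ingested = n_ingested, rejected = n_rejected, excluded = n_excluded,
      retained = nrow(samples), site_survey_means = nrow(means)
    ),
    stages = config$stages,
    outputs = outputs,
    warnings = if (nrow(warns) > 0L) {
      lapply(seq_len(nrow(warns)), function(i) as.list(warns[i, ]))
    } else {
      list()
    }
  )
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  pipe_log(config, "wrote ", length(outputs), " stage output(s) to ",
           config$out_dir)
  invisible(manifest)
}
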