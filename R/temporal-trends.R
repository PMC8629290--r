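# Paired change testing between consecutive survey campaigns.

#' Decide whether a paired panel should be log-transformed
#'
#' Concentration distributions are typically right-skewed; the conventional
#' remedy before a paired t-test is a log transform. The visual normality
#' checks used in practice (histograms, Q-Q plots) are replaced here by a
#' deterministic rule: transform when either survey's values have absolute
#' sample skewness above 1. Skewness of a constant sample is defined as 0.
#'
#' @param values_a,values_b The two surveys' concentration values.
#' @return `TRUE` if a log transform should be applied.
#' @export
needs_log_transform <- function(values_a, values_b) {
  abs(sample_skewness(values_a)) > 1 || abs(sample_skewness(values_b)) > 1
}

#' Paired t-test of change between two campaigns
#'
#' Two-sided paired t-test on the repeat-site panel, on the log scale when
#' [needs_log_transform()] fires (concentrations must then be positive, which
#' nondetect replacement guarantees). The percent change is always reported
#' on raw means, `100 * (mean_b - mean_a) / mean_a`, regardless of the test
#' scale. Zero variance of the paired differences makes the t statistic
#' undefined; such panels are reported with `p_value = 1` and a `degenerate`
#' flag rather than an error.
#'
#' @param panel A paired panel from [pair_repeat_sites()].
#' @param alpha Decision criterion for the `significant` flag (default 0.05).
#' @param transform `NULL` to decide via [needs_log_transform()] (the
#'   default), or `TRUE`/`FALSE` to force the scale.
#' @return A one-row tibble: `group`, `waterbody`, `analyte`, `survey_a`,
#'   `survey_b`, `n_pairs`, `transformed`, `t_stat`, `p_value`,
#'   `percent_change`, `significant`, `degenerate`, `alpha`.
#' @export
paired_change_test <- function(panel, alpha = 0.05, transform = NULL) {
  a <- panel$value_a_mgL
  b <- panel$value_b_mgL
  n <- length(a)
  if (n < 2L) {
    stop_synoptic("insufficient pairs: need at least 2, got ", n)
  }
  transformed <- transform %||% needs_log_transform(a, b)
  if (transformed) {
    if (any(a <= 0) || any(b <= 0)) {
      stop_synoptic(
        "non-positive concentrations cannot be log-transformed; ",
        "apply replace_nondetects() first"
      )
    }
    ta <- log(a)
    tb <- log(b)
  } else {
    ta <- a
    tb <- b
  }
  d <- tb - ta
  degenerate <- sd(d) <= .Machine$double.eps * max(1, abs(mean(d)))
  if (degenerate) {
    t_stat <- NA_real_
    p_value <- 1
  } else {
    ht <- t.test(tb, ta, paired = TRUE)
    t_stat <- unname(ht$statistic)
    p_value <- ht$p.value
  }
  tibble::tibble(
    group = as.character(attr(panel, "group") %||% NA_character_),
    waterbody = as.character(attr(panel, "waterbody") %||% NA_character_),
    analyte = as.character(attr(panel, "analyte") %||% NA_character_),
    survey_a = as.character(attr(panel, "survey_a") %||% NA_character_),
    survey_b = as.character(attr(panel, "survey_b") %||% NA_character_),
    n_pairs = n,
    transformed = transformed,
    t_stat = t_stat,
    p_value = p_value,
    percent_change = 100 * (mean(b) - mean(a)) / mean(a),
    significant = p_value < alpha,
    degenerate = degenerate,
    alpha = alpha
  )
}

#' Change tests for every consecutive survey pair, group and analyte
#'
#' Runs [paired_change_test()] over consecutive pairs of the survey sequence
#' for each requested group, waterbody and analyte, skipping (with a log
#' attribute) combinations with fewer than two shared sites. A
#' Benjamini-Hochberg adjusted p-value column is emitted alongside for
#' transparency, but the `significant` flag intentionally follows the
#' unadjusted per-test criterion, the convention for survey-scale reporting.
#'
#' @param means Site-survey means from [average_revisits()].
#' @param surveys Ordered survey sequence; defaults to sorted unique
#'   survey ids present.
#' @param groups Character vector of groups (`"national"` and/or ecoregion
#'   codes).
#' @param analytes Analytes to test; defaults to all present.
#' @param waterbodies Waterbody classes; defaults to all present.
#' @param alpha Decision criterion.
#' @return A tibble of change results sorted by group, waterbody, analyte and
#'   survey pair, with column `p_adj_bh` added. Skipped combinations are
#'   recorded in `attr(, "skipped")`.
#' @export
summarize_changes <- function(means, surveys = NULL, groups = "national",
                              analytes = NULL, waterbodies = NULL,
                              alpha = 0.05) {
  surveys <- surveys %||% sort(unique(means$survey_id))
  analytes <- analytes %||% sort(unique(means$analyte))
  waterbodies <- waterbodies %||% sort(unique(means$waterbody))
  if (length(surveys) < 2L) {
    stop_synoptic("need at least two surveys to test change")
  }
  results <- list()
  skipped <- list()
  for (g in groups) {
    for (w in waterbodies) {
      for (an in analytes) {
        for (k in seq_len(length(surveys) - 1L)) {
          panel <- suppressWarnings(pair_repeat_sites(
            means, surveys[k], surveys[k + 1L], an, group = g, waterbody = w
          ))
          if (nrow(panel) < 2L) {
            skipped[[length(skipped) + 1L]] <- tibble::tibble(
              group = as.character(g), waterbody = w, analyte = an,
              survey_a = surveys[k], survey_b = surveys[k + 1L],
              n_pairs = nrow(panel)
            )
            next
          }
          results[[length(results) + 1L]] <- paired_change_test(panel, alpha)
        }
      }
    }
  }
  out <- dplyr::bind_rows(results)
  if (nrow(out) > 0L) {
    out$p_adj_bh <- p.adjust(out$p_value, method = "BH")
    out <- out |>
      dplyr::arrange(.data$group, .data$waterbody, .data$analyte,
                     .data$survey_a, .data$survey_b) |>
      dplyr::relocate("p_adj_bh", .after = "p_value")
  }
  attr(out, "skipped") <- dplyr::bind_rows(skipped)
  out
}
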