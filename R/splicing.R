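# PSI estimation from cassette-exon junction evidence, differential splicing
# between two conditions, and quadrant classification of knockdown response
# against differentiation changes.

#' Estimate percent-spliced-in (PSI) from junction counts
#'
#' Replicates are pooled per event and condition.  With upstream and
#' downstream inclusion-junction counts `I1`, `I2` and exclusion count `E`,
#' the inclusion evidence is `m = (I1 + I2) / 2` and
#' `PSI = 100 * m / (m + E)`.  Events with zero pooled support are returned
#' with `psi = NA` and `evaluated = FALSE`.
#'
#' @param counts Junction tibble (`event_id`, `condition`, `replicate`,
#'   `I1`, `I2`, `E`).
#' @return Tibble `event_id`, `condition`, `psi` (percent), `support`
#'   (`I1 + I2 + E`), `evaluated`.
#' @export
estimate_psi <- function(counts) {
  counts |>
    group_by(.data$event_id, .data$condition) |>
    summarise(I1 = sum(.data$I1), I2 = sum(.data$I2), E = sum(.data$E),
              .groups = "drop") |>
    mutate(
      m = (.data$I1 + .data$I2) / 2,
      support = .data$I1 + .data$I2 + .data$E,
      evaluated = .data$support > 0,
      psi = ifelse(.data$evaluated, 100 * .data$m / (.data$m + .data$E), NA_real_)
    ) |>
    select("event_id", "condition", "psi", "support", "evaluated")
}

#' Differential splicing between two conditions
#'
#' Pools replicates per condition, estimates PSI in each, and reports
#' `delta_psi = psi_b - psi_a` in percent points.  The p-value is a
#' two-sided Fisher's exact test on the 2x2 table of rounded inclusion
#' evidence `m` versus exclusion `E` across conditions.  An event `passes`
#' when `p < p_cutoff` and `|delta_psi| >= delta_cutoff`; passing events are
#' classed `repressed_target` (positive `delta_psi`) or `activated_target`
#' (negative), all others `unchanged`.
#'
#' With the convention `a = control`, `b = knockdown`, a positive
#' `delta_psi` means the exon is included more once the regulator is
#' depleted, i.e. the regulator represses it.
#'
#' @param counts Junction tibble covering both conditions.
#' @param condition_a,condition_b Condition labels in `counts`.
#' @param p_cutoff,delta_cutoff Filter thresholds (raw p-value, percent
#'   points).
#' @return Tibble `event_id`, `psi_a`, `psi_b`, `delta_psi`, `p_value`,
#'   `passes`, `regulation_class`, `evaluated`.  Events unevaluable in
#'   either condition have `evaluated = FALSE` and never pass.
#' @export
diff_splice <- function(counts, condition_a, condition_b,
                        p_cutoff = 0.05, delta_cutoff = 15) {
  pooled <- counts |>
    filter(.data$condition %in% c(condition_a, condition_b)) |>
    group_by(.data$event_id, .data$condition) |>
    summarise(m = (sum(.data$I1) + sum(.data$I2)) / 2, E = sum(.data$E),
              .groups = "drop") |>
    mutate(side = ifelse(.data$condition == condition_a, "a", "b")) |>
    select(-"condition") |>
    pivot_wider(names_from = "side", values_from = c("m", "E"),
                values_fill = 0)
  for (col in c("m_a", "E_a", "m_b", "E_b")) {
    if (!col %in% names(pooled)) pooled[[col]] <- 0
  }
  pooled |>
    mutate(
      evaluated = (.data$m_a + .data$E_a) > 0 & (.data$m_b + .data$E_b) > 0,
      psi_a = ifelse(.data$evaluated, 100 * .data$m_a / (.data$m_a + .data$E_a), NA_real_),
      psi_b = ifelse(.data$evaluated, 100 * .data$m_b / (.data$m_b + .data$E_b), NA_real_),
      delta_psi = .data$psi_b - .data$psi_a,
      p_value = pmap_dbl(
        list(.data$m_a, .data$E_a, .data$m_b, .data$E_b, .data$evaluated),
        function(ma, ea, mb, eb, ok) {
          if (!ok) return(NA_real_)
          fisher.test(matrix(round(c(ma, ea, mb, eb)), nrow = 2,
                             byrow = TRUE))$p.value
        }),
      passes = .data$evaluated & !is.na(.data$p_value) &
        .data$p_value < p_cutoff & abs(.data$delta_psi) >= delta_cutoff,
      regulation_class = dplyr::case_when(
        .data$passes & .data$delta_psi > 0 ~ "repressed_target",
        .data$passes & .data$delta_psi < 0 ~ "activated_target",
        .default = "unchanged"
      )
    ) |>
    select("event_id", "psi_a", "psi_b", "delta_psi", "p_value", "passes",
           "regulation_class", "evaluated") |>
    arrange(.data$event_id)
}

#' Classify events by knockdown response versus differentiation change
#'
#' Joins a knockdown contrast (`delta_psi` = knockdown - control) with a
#' differentiation contrast (`delta_psi` = differentiated - progenitor) and
#' assigns each event to a quadrant: `repressed_neuronal` when both shifts
#' are at or above `+threshold` (the exon is de-repressed by knockdown and
#' gains inclusion in neurons), `activated_neuronal` when both are at or
#' below `-threshold`, `other` otherwise.
#'
#' @param kd_result,diff_result Tibbles from [diff_splice()].
#' @param threshold Percent-point cutoff applied to both axes.
#' @return Tibble `event_id`, `delta_psi_kd`, `delta_psi_diff`, `quadrant`.
#' @export
classify_quadrant <- function(kd_result, diff_result, threshold = 15) {
  inner_join(
    select(kd_result, "event_id", delta_psi_kd = "delta_psi"),
    select(diff_result, "event_id", delta_psi_diff = "delta_psi"),
    by = "event_id"
  ) |>
    mutate(quadrant = dplyr::case_when(
      .data$delta_psi_kd >= threshold & .data$delta_psi_diff >= threshold ~
        "repressed_neuronal",
      .data$delta_psi_kd <= -threshold & .data$delta_psi_diff <= -threshold ~
        "activated_neuronal",
      .default = "other"
    ))
}

#' Replicate concordance of PSI values
#'
#' Squared Pearson correlation of paired PSI vectors (R^2; sign-blind).
#'
#' @param psi_x,psi_y Numeric vectors of equal length >= 3.
#' @return R^2, or `NA` (with a warning) when either vector is constant.
#' @export
psi_concordance <- function(psi_x, psi_y) {
  stopifnot(length(psi_x) == length(psi_y), length(psi_x) >= 3)
  if (sd(psi_x) == 0 || sd(psi_y) == 0) {
    warn("psi_concordance() is undefined for constant PSI vectors")
    return(NA_real_)
  }
  cor(psi_x, psi_y)^2
}
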