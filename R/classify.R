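# Three-criterion constitutive-activity calling and five-group assignment.
#
# A receptor is called constitutively active when, in the relevant
# condition, its treatment effect is significant (RCBD ANOVA p < alpha) AND
# it meets at least one magnitude criterion:
#   1) baseline fractional change >= +2.0   (200% elevation over baseline)
#   2) baseline fractional change <= -0.40  (40% inhibition of baseline)
#   3) forskolin-condition fractional change <= -0.40
#                                           (40% inhibition of the forskolin
#                                            response)
# Significance is required per condition per criterion: a large forskolin
# inhibition whose own p-value misses alpha does not count (the thresholds
# are deliberately large to suppress false positives from receptor
# over-expression, and the significance gate is per comparison).
#
# Group decision table (criteria are written c1/c2/c3):
#   c2 & c3            -> A   inhibition of both baseline and forskolin response
#   c1 & c3            -> B   baseline stimulation + forskolin inhibition
#   c3 only            -> C   forskolin inhibition only
#   c1 & !c3           -> D   baseline stimulation only
#   none               -> E   no constitutive activity
#   c2 & !c3           -> OTHER (baseline-only inhibition; a pattern the
#                                five groups do not cover, kept distinct
#                                rather than coerced into A)
# c1 and c2 are mutually exclusive (one needs a positive, one a negative
# baseline change), so the table is total.

#' Configure the constitutive-activity classifier
#'
#' @param stimulation_threshold Minimum baseline mean fractional change for
#'   criterion 1. Default +2.0 (percent-change reading of "200% elevation":
#'   treated/control >= 3). Set `stimulation_as_fold = TRUE` to read the
#'   threshold as a fold-change ratio instead (ratio >= 2 when the threshold
#'   is 2), the alternative reading of the same phrase.
#' @param baseline_inhibition_threshold Maximum baseline fractional change
#'   for criterion 2; in (-1, 0). Default -0.40.
#' @param forskolin_inhibition_threshold Maximum forskolin-condition
#'   fractional change for criterion 3; in (-1, 0). Default -0.40.
#' @param alpha Per-condition significance level. Default 0.05. (The 0.01
#'   level is display-only, used for double-star annotation in reports.)
#' @param stimulation_as_fold Interpret `stimulation_threshold` as a
#'   fold-change ratio rather than a fractional change. Default `FALSE`.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(stimulation_threshold = 2.0,
                              baseline_inhibition_threshold = -0.40,
                              forskolin_inhibition_threshold = -0.40,
                              alpha = 0.05,
                              stimulation_as_fold = FALSE) {
  if (stimulation_threshold <= 0)
    stop("stimulation_threshold must be positive")
  if (baseline_inhibition_threshold <= -1 || baseline_inhibition_threshold >= 0)
    stop("baseline_inhibition_threshold must lie in (-1, 0)")
  if (forskolin_inhibition_threshold <= -1 || forskolin_inhibition_threshold >= 0)
    stop("forskolin_inhibition_threshold must lie in (-1, 0)")
  if (alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  structure(
    list(stimulation_threshold = stimulation_threshold,
         baseline_inhibition_threshold = baseline_inhibition_threshold,
         forskolin_inhibition_threshold = forskolin_inhibition_threshold,
         alpha = alpha,
         stimulation_as_fold = isTRUE(stimulation_as_fold)),
    class = "classifier_config"
  )
}

#' Evaluate the three constitutive-activity criteria for one receptor
#'
#' Threshold comparisons are "meets": >= for stimulation, <= for inhibition.
#' Each criterion also requires that condition's treatment p-value to be
#' below `alpha`.
#'
#' @param baseline_change,forskolin_change Mean fractional changes.
#' @param baseline_p,forskolin_p Treatment p-values from the RCBD ANOVA for
#'   the corresponding condition.
#' @param config A [classifier_config()].
#' @return A named logical vector `c(crit1, crit2, crit3)`.
#' @export
evaluate_criteria <- function(baseline_change, forskolin_change,
                              baseline_p, forskolin_p,
                              config = classifier_config()) {
  stim_ok <- if (config$stimulation_as_fold)
    (baseline_change + 1) >= config$stimulation_threshold
  else
    baseline_change >= config$stimulation_threshold
  c(crit1 = stim_ok && baseline_p < config$alpha,
    crit2 = baseline_change <= config$baseline_inhibition_threshold &&
      baseline_p < config$alpha,
    crit3 = forskolin_change <= config$forskolin_inhibition_threshold &&
      forskolin_p < config$alpha)
}

#' Assign the response group from criteria flags
#'
#' @param crit1,crit2,crit3 Logical criteria flags (see [evaluate_criteria()]).
#' @return One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`, `"OTHER"`.
#' @export
assign_group <- function(crit1, crit2, crit3) {
  if (crit2 && crit3) "A"
  else if (crit1 && crit3) "B"
  else if (crit3) "C"
  else if (crit1) "D"
  else if (crit2) "OTHER"
  else "E"
}

#' Classify every receptor in a screen
#'
#' End-to-end composition: stage-1/2 normalization, per-receptor
#' per-condition RCBD ANOVA treatment p-values, criteria evaluation, and
#' group assignment. Deterministic given the dataset.
#'
#' @param wells Well measurements for a full screen.
#' @param design A [screen_design()].
#' @param config A [classifier_config()].
#' @param error_term Passed to [rcbd_anova()].
#' @param validate Check the dataset against the design first and stop on
#'   violations. Default `TRUE`.
#' @param p_adjust Multiple-testing adjustment applied per condition across
#'   receptors (`"none"`, the published screen's choice and the default, or
#'   any method of [stats::p.adjust()], e.g. `"BH"`).
#' @return A data frame with one row per receptor: `receptor`,
#'   `baseline_change`, `forskolin_change`, `baseline_p`, `forskolin_p`,
#'   `crit1`, `crit2`, `crit3`, `constitutive`, `group`. Receptors whose
#'   summaries are unusable (fewer than 2 plates with both groups) get
#'   `group = "UNEVALUABLE"` and NA flags.
#' @examples
#' wells <- simulate_screen(archetype_profiles(), seed = 42)
#' classify_screen(wells)[, c("receptor", "group")]
#' @export
classify_screen <- function(wells, design = screen_design(),
                            config = classifier_config(),
                            error_term = c("residual", "interaction"),
                            validate = TRUE, p_adjust = "none") {
  error_term <- match.arg(error_term)
  if (validate) {
    v <- validate_dataset(wells, design)
    if (nrow(v))
      stop("dataset fails validation (", nrow(v),
           " violation(s)); see validate_dataset()")
  }
  norm_groups <- normalize_screen(wells, design)
  fc <- fractional_changes(norm_groups, design)
  receptors <- unique(fc$receptor)

  pull <- function(rec, cond, col) {
    val <- fc[fc$receptor == rec & fc$condition == cond, col]
    if (length(val)) val[[1L]] else NA
  }
  res <- data.frame(receptor = receptors, stringsAsFactors = FALSE)
  res$baseline_change <- vapply(receptors, pull, 0, cond = "BASELINE",
                                col = "mean_fractional_change")
  res$forskolin_change <- vapply(receptors, pull, 0, cond = "FORSKOLIN",
                                 col = "mean_fractional_change")
  usable <- vapply(receptors, pull, TRUE, cond = "BASELINE", col = "usable") &
    vapply(receptors, pull, TRUE, cond = "FORSKOLIN", col = "usable")

  res$baseline_p <- NA_real_
  res$forskolin_p <- NA_real_
  for (i in seq_along(receptors)) {
    if (!usable[i]) next
    res$baseline_p[i] <- treatment_p_for_receptor(
      wells, receptors[i], "BASELINE", design, error_term)$p_value
    res$forskolin_p[i] <- treatment_p_for_receptor(
      wells, receptors[i], "FORSKOLIN", design, error_term)$p_value
  }
  if (p_adjust != "none") {
    res$baseline_p[usable] <- stats::p.adjust(res$baseline_p[usable], p_adjust)
    res$forskolin_p[usable] <- stats::p.adjust(res$forskolin_p[usable], p_adjust)
  }

  res$crit1 <- res$crit2 <- res$crit3 <- NA
  res$constitutive <- NA
  res$group <- "UNEVALUABLE"
  for (i in seq_along(receptors)) {
    if (!usable[i]) next
    cr <- evaluate_criteria(res$baseline_change[i], res$forskolin_change[i],
                            res$baseline_p[i], res$forskolin_p[i], config)
    res$crit1[i] <- cr[["crit1"]]
    res$crit2[i] <- cr[["crit2"]]
    res$crit3[i] <- cr[["crit3"]]
    res$constitutive[i] <- any(cr)
    res$group[i] <- assign_group(cr[["crit1"]], cr[["crit2"]], cr[["crit3"]])
  }
  res
}
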