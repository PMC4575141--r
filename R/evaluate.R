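# Operating characteristics of the full pipeline on simulated screens with
# known truth: confusion matrices, per-group recall/precision, false-positive
# rate, and power curves against an effect-size sweep.

#' Measure pipeline operating characteristics on simulated screens
#'
#' Repeatedly simulates a screen from the given ground-truth profiles,
#' classifies it, and tallies assigned groups against true groups. Seeds are
#' a deterministic function of `(seed_base, replicate)`, so every replicate
#' is independently reproducible.
#'
#' An `OTHER` or `UNEVALUABLE` assignment counts as an error for every true
#' group (no archetype maps to either).
#'
#' @param profiles An [effect_profiles()] data frame with a `true_group`
#'   column, e.g. [archetype_profiles()].
#' @param design A [screen_design()].
#' @param sim A [simulation_config()] (its `seed` field is ignored here).
#' @param config A [classifier_config()].
#' @param n_seeds Number of simulated screens. Must be >= 1.
#' @param seed_base Integer from which per-replicate seeds are derived.
#' @return An object of class `evaluation_result`: a list with
#'   `confusion_matrix` (true group x assigned group counts),
#'   `per_group` (data frame of recall and precision per true group),
#'   `false_positive_rate` (fraction of true-E receptors assigned non-E;
#'   `NA` if no true-E receptors were simulated), `overall_recovery`
#'   (fraction of all receptors assigned their true group) and `settings`.
#' @examples
#' ev <- run_evaluation(archetype_profiles(), n_seeds = 3, seed_base = 7)
#' ev$confusion_matrix
#' @export
run_evaluation <- function(profiles, design = screen_design(),
                           sim = simulation_config(),
                           config = classifier_config(),
                           n_seeds = 100L, seed_base = 1L) {
  stopifnot(is.data.frame(profiles), "true_group" %in% names(profiles),
            n_seeds >= 1L)
  assigned_levels <- c(GROUP_LEVELS, "UNEVALUABLE")
  confusion <- matrix(0L, nrow = 5L, ncol = length(assigned_levels),
                      dimnames = list(true = c("A", "B", "C", "D", "E"),
                                      assigned = assigned_levels))
  for (s in seq_len(n_seeds)) {
    seed <- derive_seed(seed_base, s)
    wells <- simulate_screen(profiles, design, sim, seed = seed)
    cl <- classify_screen(wells, design, config, validate = FALSE)
    truth <- profiles$true_group[match(cl$receptor, profiles$receptor)]
    tab <- table(factor(truth, levels = rownames(confusion)),
                 factor(cl$group, levels = assigned_levels))
    confusion <- confusion + tab
  }
  row_tot <- rowSums(confusion)
  diag_hits <- vapply(rownames(confusion),
                      function(g) confusion[g, g], 0L)
  col_tot <- colSums(confusion)[rownames(confusion)]
  per_group <- data.frame(
    group = rownames(confusion),
    n_true = as.integer(row_tot),
    recall = ifelse(row_tot > 0, diag_hits / row_tot, NA_real_),
    precision = ifelse(col_tot > 0, diag_hits / col_tot, NA_real_),
    stringsAsFactors = FALSE
  )
  fpr <- if (row_tot[["E"]] > 0)
    1 - confusion["E", "E"] / row_tot[["E"]] else NA_real_
  structure(
    list(confusion_matrix = confusion,
         per_group = per_group,
         false_positive_rate = fpr,
         overall_recovery = sum(diag_hits) / sum(row_tot),
         settings = list(design = design, sim = sim, config = config,
                         n_seeds = n_seeds, seed_base = seed_base)),
    class = "evaluation_result"
  )
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("Pipeline evaluation over", x$settings$n_seeds, "simulated screens\n")
  print(x$confusion_matrix)
  cat(sprintf("overall recovery: %.3f", x$overall_recovery))
  if (!is.na(x$false_positive_rate))
    cat(sprintf("   false-positive rate (true E): %.3f", x$false_positive_rate))
  cat("\n")
  invisible(x)
}

#' Detection power against an effect-size sweep
#'
#' Simulates screens containing a single receptor whose baseline or
#' forskolin multiplier sweeps across the given values, and records the
#' fraction of replicates in which the receptor is called constitutively
#' active. At a null multiplier of 1 this fraction is the pipeline's
#' false-positive rate; far past a threshold it approaches 1; exactly at a
#' threshold it is intermediate.
#'
#' @param multipliers Positive effect multipliers to sweep.
#' @param which Which multiplier sweeps: `"baseline"` (the other is held at
#'   1) or `"forskolin"`.
#' @param design,sim,config,seed_base As in [run_evaluation()].
#' @param n_seeds Replicates per sweep value.
#' @return A data frame with columns `multiplier`, `true_fractional_change`,
#'   `detection_probability`, `n_seeds`.
#' @export
power_curve <- function(multipliers, which = c("forskolin", "baseline"),
                        design = screen_design(), sim = simulation_config(),
                        config = classifier_config(),
                        n_seeds = 100L, seed_base = 1L) {
  which <- match.arg(which)
  stopifnot(all(multipliers > 0), n_seeds >= 1L)
  detect <- numeric(length(multipliers))
  for (i in seq_along(multipliers)) {
    prof <- effect_profiles(
      "SWEEP",
      baseline_multiplier = if (which == "baseline") multipliers[i] else 1,
      forskolin_multiplier = if (which == "forskolin") multipliers[i] else 1)
    hits <- 0L
    for (s in seq_len(n_seeds)) {
      seed <- derive_seed(seed_base, (i - 1L) * n_seeds + s)
      wells <- simulate_screen(prof, design, sim, seed = seed)
      cl <- classify_screen(wells, design, config, validate = FALSE)
      hits <- hits + as.integer(isTRUE(cl$constitutive[cl$receptor == "SWEEP"]))
    }
    detect[i] <- hits / n_seeds
  }
  data.frame(multiplier = multipliers,
             true_fractional_change = multipliers - 1,
             detection_probability = detect,
             n_seeds = n_seeds)
}

# Deterministic per-replicate seed, kept inside 32-bit integer range.
derive_seed <- function(seed_base, index) {
  as.integer((as.numeric(seed_base) * 1000003 + index) %% 2147483647)
}
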