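# The published 40-receptor orphan-GPCR screen: group rosters as reported in
# the study's results, and the summary tallies computed from them.

GROUP_LEVELS <- c("A", "B", "C", "D", "E", "OTHER")

# Which magnitude criteria each group implies:
#   A -> {2,3}; B -> {1,3}; C -> {3}; D -> {1}; E -> {}; OTHER -> {2}.
INHIBITORY_GROUPS <- c("A", "B", "C", "OTHER")  # imply criterion 2 or 3
STIMULATORY_GROUPS <- c("B", "D")               # imply criterion 1

#' The published 40-receptor screen roster
#'
#' Per-receptor reported response groups for the 40 class-A orphan GPCRs of
#' the published CRE-luciferase screen, following the results-section
#' rosters: Group A (constitutive inhibition of both baseline and
#' forskolin-stimulated expression, 17 receptors, including GPR55 which the
#' abstract's list omits), Group B (GPR6, GPR12), Group C (7 receptors),
#' Group D (4 receptors, including GPR3 whose forskolin inhibition missed
#' significance at p = 0.072), and Group E (10 receptors with no
#' constitutive activity).
#'
#' @return A data frame with 40 rows and columns `receptor`,
#'   `reported_group`, `notes`.
#' @examples
#' table(published_fixture()$reported_group)
#' @export
published_fixture <- function() {
  path <- system.file("extdata", "published_screen.csv",
                      package = "crescreen", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  stopifnot(nrow(df) == 40L, !anyDuplicated(df$receptor),
            all(df$reported_group %in% c("A", "B", "C", "D", "E")))
  df
}

#' Summarize a screen's group assignments
#'
#' Tallies receptors per group and derives the headline screen statistics:
#' how many receptors are constitutively active (any group other than E),
#' how many are inhibitory (their group implies 40% inhibition of baseline
#' or of the forskolin response: groups A, B, C) and how many are
#' stimulatory (their group implies 200% baseline elevation: groups B, D),
#' with the corresponding percentages of the total.
#'
#' @param records A data frame with a `receptor` column and either a
#'   `reported_group` column (published roster) or a `group` column
#'   (output of [classify_screen()]). `UNEVALUABLE` receptors are excluded
#'   from the tallies; a missing/NA group is an error naming the receptor.
#' @return An object of class `screen_summary`: a list with `group_counts`
#'   (named integer vector over A..E and OTHER), `n_total`,
#'   `n_constitutive`, `pct_constitutive`, `n_inhibitory`, `pct_inhibitory`,
#'   `n_stimulatory`, `pct_stimulatory`.
#' @examples
#' summarize_screen(published_fixture())
#' @export
summarize_screen <- function(records) {
  stopifnot(is.data.frame(records), "receptor" %in% names(records))
  grp_col <- if ("reported_group" %in% names(records)) "reported_group" else "group"
  if (!grp_col %in% names(records))
    stop("records need a `reported_group` or `group` column")
  groups <- records[[grp_col]]
  bad <- is.na(groups) | !nzchar(groups)
  if (any(bad))
    stop("missing group for receptor(s): ",
         paste(records$receptor[bad], collapse = ", "))
  keep <- groups != "UNEVALUABLE"
  groups <- groups[keep]
  unknown <- setdiff(unique(groups), GROUP_LEVELS)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  if (!length(groups))
    stop("no evaluable receptors to summarize")

  counts <- table(factor(groups, levels = GROUP_LEVELS))
  n <- length(groups)
  n_const <- n - counts[["E"]]
  n_inh <- sum(counts[INHIBITORY_GROUPS])
  n_stim <- sum(counts[STIMULATORY_GROUPS])
  structure(
    list(group_counts = c(counts),
         n_total = n,
         n_constitutive = n_const,
         pct_constitutive = 100 * n_const / n,
         n_inhibitory = n_inh,
         pct_inhibitory = 100 * n_inh / n,
         n_stimulatory = n_stim,
         pct_stimulatory = 100 * n_stim / n),
    class = "screen_summary"
  )
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("Screen summary (", x$n_total, " receptors)\n", sep = "")
  cat("  group counts:",
      paste(names(x$group_counts), x$group_counts, sep = "=", collapse = " "),
      "\n")
  cat(sprintf("  constitutively active: %d (%.0f%%)\n",
              x$n_constitutive, x$pct_constitutive))
  cat(sprintf("  inhibitory: %d (%.0f%%)   stimulatory: %d (%.0f%%)\n",
              x$n_inhibitory, x$pct_inhibitory,
              x$n_stimulatory, x$pct_stimulatory))
  invisible(x)
}

#' Star annotation for a treatment p-value
#'
#' Figure-legend convention: `**` for p below 0.01, `*` for p below 0.05;
#' a non-significant comparison is annotated with its literal p-value
#' (the published figures print these individually, in red).
#'
#' @param p Numeric vector of p-values.
#' @param alpha Single-star threshold. Default 0.05.
#' @param alpha_strong Double-star threshold. Default 0.01.
#' @return Character vector of annotations.
#' @examples
#' star_annotation(c(0.004, 0.03, 0.072))
#' @export
star_annotation <- function(p, alpha = 0.05, alpha_strong = 0.01) {
  out <- format(round(p, 3L), trim = TRUE, nsmall = 3L)
  out[p < alpha] <- "*"
  out[p < alpha_strong] <- "**"
  out
}

#' Render a deterministic screen report
#'
#' Produces the tabular equivalent of the published bar charts — one row per
#' receptor and condition with the percent change over control and its star
#' annotation — plus a human-readable header built from a
#' [summarize_screen()] summary.
#'
#' @param summary A `screen_summary`.
#' @param classifications Output of [classify_screen()].
#' @return A list with `text` (character vector of report lines) and `table`
#'   (data frame `receptor`, `condition`, `percent_change`, `p_value`,
#'   `annotation`, `group`, ordered by group then receptor).
#' @export
render_report <- function(summary, classifications) {
  stopifnot(inherits(summary, "screen_summary"),
            is.data.frame(classifications))
  cl <- classifications[classifications$group != "UNEVALUABLE", , drop = FALSE]
  cl <- cl[order(match(cl$group, GROUP_LEVELS), cl$receptor), , drop = FALSE]
  tab <- data.frame(
    receptor = rep(cl$receptor, each = 2L),
    condition = rep(CONDITIONS, times = nrow(cl)),
    percent_change = as.vector(rbind(100 * cl$baseline_change,
                                     100 * cl$forskolin_change)),
    p_value = as.vector(rbind(cl$baseline_p, cl$forskolin_p)),
    group = rep(cl$group, each = 2L),
    stringsAsFactors = FALSE
  )
  tab$annotation <- star_annotation(tab$p_value)
  text <- c(
    sprintf("Constitutive-activity screen: %d receptors evaluated", summary$n_total),
    sprintf("  constitutively active: %d (%.0f%%)",
            summary$n_constitutive, summary$pct_constitutive),
    sprintf("  inhibitory: %d (%.0f%%); stimulatory: %d (%.0f%%)",
            summary$n_inhibitory, summary$pct_inhibitory,
            summary$n_stimulatory, summary$pct_stimulatory),
    sprintf("  group counts: %s",
            paste(names(summary$group_counts), summary$group_counts,
                  sep = "=", collapse = " ")),
    "",
    sprintf("%-20s %-10s %10s  %s", "receptor", "condition",
            "% change", "signif"),
    sprintf("%-20s %-10s %10.1f  %s", tab$receptor, tab$condition,
            tab$percent_change, tab$annotation)
  )
  list(text = text, table = tab)
}
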