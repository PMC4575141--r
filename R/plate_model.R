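# Core data model: well measurements, screen design, dataset validation.

CONDITIONS <- c("BASELINE", "FORSKOLIN")
EMPTY_CONSTRUCT <- "EMPTY"
DATASET_COLUMNS <- c("plate_id", "well", "construct", "condition", "rlu")

#' Describe the plate layout of a reporter screen
#'
#' A screen design records how each 96-well plate is organised: how many
#' treatment groups it carries, how many replicate wells each group has, how
#' many plates (statistical blocks) the screen spans, and which construct
#' label is the transfection negative control. The positive control is always
#' the empty-vector construct under forskolin stimulation; it anchors the
#' between-plate normalization.
#'
#' @param treatments_per_plate Number of (construct, condition) groups per
#'   plate. Default 12, i.e. two control groups plus five receptors measured
#'   under both conditions.
#' @param replicates_per_group Replicate wells per group. Must be at least 2
#'   so the treatment-by-block interaction has within-cell replication.
#'   Default 4.
#' @param n_plates Number of plates (blocks). Must be at least 2. Default 4.
#' @param control_construct Reserved label of the empty-vector control.
#' @return An object of class `screen_design` (a named list).
#' @examples
#' design <- screen_design()
#' design$replicates_per_group
#' @export
screen_design <- function(treatments_per_plate = 12L,
                          replicates_per_group = 4L,
                          n_plates = 4L,
                          control_construct = EMPTY_CONSTRUCT) {
  treatments_per_plate <- as.integer(treatments_per_plate)
  replicates_per_group <- as.integer(replicates_per_group)
  n_plates <- as.integer(n_plates)
  if (replicates_per_group < 2L)
    stop("replicates_per_group must be >= 2 (interaction term requires within-cell replication)")
  if (n_plates < 2L)
    stop("n_plates must be >= 2 (blocking requires at least two plates)")
  if (treatments_per_plate < 4L)
    stop("treatments_per_plate must accommodate both control groups plus at least one receptor")
  structure(
    list(
      treatments_per_plate = treatments_per_plate,
      replicates_per_group = replicates_per_group,
      n_plates = n_plates,
      control_construct = control_construct
    ),
    class = "screen_design"
  )
}

#' @export
print.screen_design <- function(x, ...) {
  cat("Screen design:", x$treatments_per_plate, "treatment groups/plate,",
      x$replicates_per_group, "replicates/group,", x$n_plates, "plates\n")
  cat("  negative control:", x$control_construct, "(BASELINE)\n")
  cat("  positive control:", x$control_construct, "(FORSKOLIN)\n")
  invisible(x)
}

#' Validate a plate dataset against a screen design
#'
#' Checks that every plate carries complete control groups (the empty-vector
#' baseline group and the forskolin positive control) and that every
#' (plate, construct, condition) cell has exactly the designed number of
#' replicate wells. Violations are reported, never raised: an empty report
#' means the dataset is analysable as a balanced blocked design.
#'
#' @param wells A data frame of well measurements with columns
#'   `plate_id`, `well`, `construct`, `condition`, `rlu`.
#' @param design A [screen_design()].
#' @return A data frame of violations with columns `plate_id`, `construct`,
#'   `condition`, `problem`, `observed`, `expected`; zero rows if the
#'   dataset is clean.
#' @export
validate_dataset <- function(wells, design = screen_design()) {
  check_wells(wells)
  violations <- empty_violations()

  r <- design$replicates_per_group
  ctrl <- design$control_construct

  # structural checks independent of the design
  bad_cond <- !wells$condition %in% CONDITIONS
  if (any(bad_cond)) {
    for (v in unique(wells$condition[bad_cond])) {
      violations <- add_violation(violations, NA_character_, NA_character_, v,
                                  "unknown condition label", sum(wells$condition == v), 0)
    }
  }
  neg <- wells$rlu < 0
  if (any(neg)) {
    violations <- add_violation(violations, NA_character_, NA_character_, NA_character_,
                                "negative rlu values", sum(neg), 0)
  }
  key <- paste(wells$plate_id, wells$well, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    for (d in dup) {
      parts <- strsplit(d, "\r", fixed = TRUE)[[1L]]
      violations <- add_violation(violations, parts[1L], NA_character_, NA_character_,
                                  paste0("duplicate well position ", parts[2L]),
                                  sum(key == d), 1)
    }
  }

  counts <- table(plate = wells$plate_id,
                  cell = paste(wells$construct, wells$condition, sep = "\r"))
  plates <- rownames(counts)
  for (p in plates) {
    for (cond in CONDITIONS) {
      cell <- paste(ctrl, cond, sep = "\r")
      n <- if (cell %in% colnames(counts)) counts[p, cell] else 0L
      if (n == 0L) {
        violations <- add_violation(violations, p, ctrl, cond,
                                    "missing control group", 0L, r)
      }
    }
  }
  for (p in plates) {
    for (cell in colnames(counts)) {
      n <- counts[p, cell]
      if (n > 0L && n != r) {
        parts <- strsplit(cell, "\r", fixed = TRUE)[[1L]]
        violations <- add_violation(violations, p, parts[1L], parts[2L],
                                    "replicate count differs from design", n, r)
      }
    }
  }
  rownames(violations) <- NULL
  violations
}

check_wells <- function(wells) {
  if (!is.data.frame(wells))
    stop("wells must be a data frame")
  missing <- setdiff(DATASET_COLUMNS, names(wells))
  if (length(missing))
    stop("wells is missing required column(s): ", paste(missing, collapse = ", "))
  if (!is.numeric(wells$rlu))
    stop("rlu must be numeric")
  invisible(wells)
}

empty_violations <- function() {
  data.frame(plate_id = character(), construct = character(),
             condition = character(), problem = character(),
             observed = numeric(), expected = numeric(),
             stringsAsFactors = FALSE)
}

add_violation <- function(df, plate_id, construct, condition, problem,
                          observed, expected) {
  rbind(df, data.frame(plate_id = plate_id, construct = construct,
                       condition = condition, problem = problem,
                       observed = as.numeric(observed),
                       expected = as.numeric(expected),
                       stringsAsFactors = FALSE))
}
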