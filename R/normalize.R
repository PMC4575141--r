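# Two-stage normalization:
#   stage 1 - every group mean on a plate is divided by that plate's
#             positive-control mean (empty vector + forskolin), removing the
#             shared plate scale so plates are comparable;
#   stage 2 - each treatment group is divided by its matched control in the
#             same condition (empty vector, +/- forskolin) and shifted by -1,
#             giving the fractional stimulation or inhibition. Zero means no
#             change from control; x100 gives percent change over control.
# Stage-2 ratios are formed within plate and then averaged across plates, so
# a per-plate multiplicative rescaling of the raw RLUs cancels exactly.

#' Normalize one plate by its forskolin positive control
#'
#' Collapses replicate wells to group means and divides every group mean by
#' the plate's positive-control mean (the empty-vector construct under
#' forskolin). The positive-control group itself therefore normalizes to
#' exactly 1 on every plate.
#'
#' @param wells Well measurements from a single plate.
#' @param design A [screen_design()].
#' @return A data frame with one row per (construct, condition) group:
#'   `plate_id`, `construct`, `condition`, `group_mean_rlu`,
#'   `normalized_value`; or `NULL` (with a warning naming the plate and
#'   reason) if the plate lacks a usable positive control.
#' @export
normalize_plate <- function(wells, design = screen_design()) {
  check_wells(wells)
  plate <- unique(wells$plate_id)
  if (length(plate) != 1L)
    stop("normalize_plate expects wells from exactly one plate; got ",
         length(plate))
  pc <- wells$rlu[wells$construct == design$control_construct &
                  wells$condition == "FORSKOLIN"]
  if (length(pc) == 0L) {
    warning("plate ", plate, " excluded: positive-control group missing")
    return(NULL)
  }
  pc_mean <- mean(pc)
  if (!is.finite(pc_mean) || pc_mean <= 0) {
    warning("plate ", plate, " excluded: positive-control mean not positive (",
            format(pc_mean), ")")
    return(NULL)
  }
  gm <- tapply(wells$rlu, list(wells$construct, wells$condition), mean)
  idx <- which(!is.na(gm), arr.ind = TRUE)
  out <- data.frame(
    plate_id = plate,
    construct = rownames(gm)[idx[, 1L]],
    condition = colnames(gm)[idx[, 2L]],
    group_mean_rlu = gm[idx],
    stringsAsFactors = FALSE
  )
  out$normalized_value <- out$group_mean_rlu / pc_mean
  out[order(out$construct, out$condition), , drop = FALSE]
}

#' Normalize every plate of a screen
#'
#' Applies [normalize_plate()] plate by plate; plates with a missing or
#' non-positive positive control are excluded and reported.
#'
#' @inheritParams normalize_plate
#' @return A normalized-group data frame across all usable plates, with an
#'   attribute `excluded_plates` (data frame of `plate_id`, `reason`).
#' @export
normalize_screen <- function(wells, design = screen_design()) {
  check_wells(wells)
  excluded <- data.frame(plate_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  pieces <- list()
  for (p in unique(wells$plate_id)) {
    res <- withCallingHandlers(
      normalize_plate(wells[wells$plate_id == p, , drop = FALSE], design),
      warning = function(w) {
        excluded <<- rbind(excluded, data.frame(
          plate_id = p, reason = conditionMessage(w), stringsAsFactors = FALSE))
        invokeRestart("muffleWarning")
      })
    if (!is.null(res)) pieces[[p]] <- res
  }
  out <- if (length(pieces)) do.call(rbind, pieces) else NULL
  if (is.null(out))
    stop("no usable plates after positive-control screening")
  rownames(out) <- NULL
  attr(out, "excluded_plates") <- excluded
  out
}

#' Pooled fractional change per receptor and condition
#'
#' For every receptor and condition, forms the within-plate ratio of the
#' receptor's normalized group value to the matched empty-vector control in
#' the same condition, subtracts 1, and averages the per-plate values.
#' Plates lacking either group (or with a non-positive control value) are
#' skipped and counted. A summary needs at least two usable plates to be
#' marked usable.
#'
#' @param groups Normalized groups from [normalize_screen()] (all plates).
#' @param design A [screen_design()].
#' @return A data frame with one row per (receptor, condition):
#'   `receptor`, `condition`, `mean_fractional_change`, `n_plates_used`,
#'   `n_plates_skipped`, `usable`, and a list-column `per_plate` of the
#'   per-plate fractional changes (named by plate).
#' @export
fractional_changes <- function(groups, design = screen_design()) {
  stopifnot(is.data.frame(groups),
            all(c("plate_id", "construct", "condition", "normalized_value")
                %in% names(groups)))
  ctrl <- design$control_construct
  receptors <- setdiff(unique(groups$construct), ctrl)
  out <- vector("list", length(receptors) * 2L)
  k <- 0L
  for (rec in receptors) {
    for (cond in CONDITIONS) {
      ctl <- groups[groups$construct == ctrl & groups$condition == cond, ]
      trt <- groups[groups$construct == rec & groups$condition == cond, ]
      common <- intersect(trt$plate_id, ctl$plate_id)
      ctl_v <- ctl$normalized_value[match(common, ctl$plate_id)]
      trt_v <- trt$normalized_value[match(common, trt$plate_id)]
      ok <- is.finite(ctl_v) & ctl_v > 0
      fc <- trt_v[ok] / ctl_v[ok] - 1
      names(fc) <- common[ok]
      n_all_plates <- length(unique(groups$plate_id))
      k <- k + 1L
      out[[k]] <- data.frame(
        receptor = rec, condition = cond,
        mean_fractional_change = if (length(fc)) mean(fc) else NA_real_,
        n_plates_used = length(fc),
        n_plates_skipped = n_all_plates - length(fc),
        usable = length(fc) >= 2L,
        stringsAsFactors = FALSE
      )
      out[[k]]$per_plate <- list(fc)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
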