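# Replicated randomized complete block ANOVA.
#
# Plates are blocks, transfected constructs are treatments, and the r
# replicate wells within each (treatment, block) cell supply a pure-error
# estimate, so the treatment-by-block interaction is estimable separately
# from residual error. The decomposition is the classical balanced two-way
# one:
#   SS_treatment   = r b sum_t (ybar_t  - ybar)^2
#   SS_block       = r t sum_b (ybar_b  - ybar)^2
#   SS_interaction = r   sum_tb (ybar_tb - ybar_t - ybar_b + ybar)^2
#   SS_residual    =     sum (y - ybar_tb)^2
# with F ratios against the pooled within-cell residual mean square
# (fixed-effects reading; an `error_term = "interaction"` switch gives the
# random-blocks alternative for the treatment F).

#' Replicated randomized complete block ANOVA
#'
#' Fits the balanced two-factor decomposition above and returns sums of
#' squares, degrees of freedom, mean squares, F statistics and p-values for
#' treatment, block, treatment:block interaction, residual and total.
#'
#' Degenerate data are flagged rather than erroring: if all observations are
#' equal every p-value is reported as 1 (`degenerate = "no_variance"`); if
#' the residual mean square is zero but some source has positive sum of
#' squares, that source's p-value is reported as 0
#' (`degenerate = "zero_residual"`).
#'
#' @param values Numeric response vector.
#' @param treatment,block Factors (or vectors coercible to factors) of the
#'   same length as `values`. The layout must be balanced with at least 2
#'   treatment levels, 2 blocks and 2 replicates per cell.
#' @param error_term Denominator for the treatment F: `"residual"` (pooled
#'   within-cell error; default) or `"interaction"` (random-blocks reading).
#' @return An object of class `rcbd_anova`: a list with `table` (data frame
#'   with one row per source), `degenerate` (`"none"`, `"no_variance"` or
#'   `"zero_residual"`) and `error_term`.
#' @examples
#' d <- expand.grid(trt = c("ctrl", "rx"), blk = paste0("p", 1:3), rep = 1:2)
#' d$y <- 10 + (d$trt == "rx") * 2 + as.integer(d$blk) + rnorm(nrow(d), sd = 0.5)
#' rcbd_anova(d$y, d$trt, d$blk)
#' @export
rcbd_anova <- function(values, treatment, block,
                       error_term = c("residual", "interaction")) {
  error_term <- match.arg(error_term)
  treatment <- factor(treatment)
  block <- factor(block)
  if (length(values) != length(treatment) || length(values) != length(block))
    stop("values, treatment and block must have equal length")
  t <- nlevels(treatment)
  b <- nlevels(block)
  if (t < 2L || b < 2L)
    stop("need at least 2 treatment levels and 2 blocks")
  counts <- table(treatment, block)
  if (length(unique(as.vector(counts))) != 1L)
    stop("unbalanced layout: run validate_dataset() to locate incomplete cells")
  r <- as.integer(counts[1L])
  if (r < 2L)
    stop("need at least 2 replicates per (treatment, block) cell")

  grand <- mean(values)
  cell <- tapply(values, list(treatment, block), mean)   # t x b matrix
  tmean <- rowMeans(cell)
  bmean <- colMeans(cell)

  ss_t <- r * b * sum((tmean - grand)^2)
  ss_b <- r * t * sum((bmean - grand)^2)
  ss_i <- r * sum((sweep(sweep(cell, 1L, tmean), 2L, bmean) + grand)^2)
  fitted_cell <- cell[cbind(as.integer(treatment), as.integer(block))]
  ss_r <- sum((values - fitted_cell)^2)
  ss_tot <- sum((values - grand)^2)

  df_t <- t - 1L
  df_b <- b - 1L
  df_i <- df_t * df_b
  df_r <- t * b * (r - 1L)
  df_tot <- length(values) - 1L

  ms <- c(ss_t / df_t, ss_b / df_b, ss_i / df_i, ss_r / df_r)
  ms_err_t <- if (error_term == "interaction") ms[3L] else ms[4L]
  df_err_t <- if (error_term == "interaction") df_i else df_r

  degenerate <- "none"
  if (ss_tot <= 0) {
    degenerate <- "no_variance"
    f <- rep(NA_real_, 3L)
    p <- rep(1, 3L)
  } else if (ms[4L] <= 0 || (error_term == "interaction" && ms_err_t <= 0)) {
    degenerate <- "zero_residual"
    ss3 <- c(ss_t, ss_b, ss_i)
    err3 <- c(ms_err_t, ms[4L], ms[4L])
    f <- ifelse(err3 > 0, c(ms[1L], ms[2L], ms[3L]) / err3, Inf)
    p <- ifelse(ss3 > 0, 0, 1)
  } else {
    f <- c(ms[1L] / ms_err_t, ms[2L] / ms[4L], ms[3L] / ms[4L])
    p <- stats::pf(f, c(df_t, df_b, df_i), c(df_err_t, df_r, df_r),
                   lower.tail = FALSE)
  }

  tab <- data.frame(
    source = c("treatment", "block", "interaction", "residual", "total"),
    sum_of_squares = c(ss_t, ss_b, ss_i, ss_r, ss_tot),
    df = c(df_t, df_b, df_i, df_r, df_tot),
    mean_square = c(ms, NA_real_),
    F_statistic = c(f, NA_real_, NA_real_),
    p_value = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, degenerate = degenerate,
                 error_term = error_term,
                 design = c(t = t, b = b, r = r)),
            class = "rcbd_anova")
}

#' @export
print.rcbd_anova <- function(x, ...) {
  cat("Randomized complete block ANOVA (",
      x$design["t"], " treatments x ", x$design["b"], " blocks x ",
      x$design["r"], " replicates)\n", sep = "")
  if (x$degenerate != "none")
    cat("  [degenerate data: ", x$degenerate, "]\n", sep = "")
  print(x$table, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Overall treatment p-value for one receptor-vs-control comparison
#'
#' Runs the RCBD ANOVA for a single receptor in a single condition: the
#' treatment factor has two levels (receptor vs empty-vector control), the
#' block factor is the plate, and the response is the plate-normalized
#' per-well value (each raw RLU divided by its plate's positive-control
#' mean). Analyzing stage-1 normalized wells keeps the full within-group
#' replication while removing the plate scale that the blocks would
#' otherwise absorb entirely.
#'
#' @param wells Well measurements across plates.
#' @param receptor Receptor label to test.
#' @param condition `"BASELINE"` or `"FORSKOLIN"`.
#' @param design A [screen_design()].
#' @param error_term Passed to [rcbd_anova()].
#' @return A list with `p_value` (the treatment p) and `anova`
#'   (the full `rcbd_anova` object).
#' @export
treatment_p_for_receptor <- function(wells, receptor,
                                     condition = c("BASELINE", "FORSKOLIN"),
                                     design = screen_design(),
                                     error_term = c("residual", "interaction")) {
  condition <- match.arg(condition)
  check_wells(wells)
  norm <- stage1_normalized_wells(wells, design)
  sub <- norm[norm$condition == condition &
              norm$construct %in% c(receptor, design$control_construct), ,
              drop = FALSE]
  plates_with_both <- names(which(tapply(
    sub$construct, sub$plate_id, function(x) length(unique(x)) == 2L)))
  if (length(plates_with_both) < 2L)
    stop("receptor ", receptor, " and its control must share at least 2 plates in ",
         condition)
  sub <- sub[sub$plate_id %in% plates_with_both, , drop = FALSE]
  res <- rcbd_anova(sub$norm_rlu, sub$construct, sub$plate_id,
                    error_term = error_term)
  list(p_value = res$table$p_value[res$table$source == "treatment"],
       anova = res)
}

# Stage-1 only: per-well RLU divided by its plate's positive-control mean.
# Plates without a usable positive control are dropped with a warning.
stage1_normalized_wells <- function(wells, design) {
  is_pc <- wells$construct == design$control_construct &
    wells$condition == "FORSKOLIN"
  pc_mean <- tapply(wells$rlu[is_pc], wells$plate_id[is_pc], mean)
  pc_mean <- pc_mean[is.finite(pc_mean) & pc_mean > 0]
  keep <- wells$plate_id %in% names(pc_mean)
  if (!all(keep))
    warning("dropping plate(s) without usable positive control: ",
            paste(setdiff(unique(wells$plate_id), names(pc_mean)), collapse = ", "))
  out <- wells[keep, , drop = FALSE]
  out$norm_rlu <- out$rlu / unname(pc_mean[out$plate_id])
  out
}
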