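# Shared fixture builders: all fixtures are constructed in code.

# A hand-built plate with explicit group means: each entry of `means` is the
# common RLU of the 4 replicate wells of one (construct, condition) group.
manual_plate <- function(plate_id, means, replicates = 4L) {
  stopifnot(is.data.frame(means),
            all(c("construct", "condition", "rlu") %in% names(means)))
  n <- nrow(means)
  data.frame(
    plate_id = plate_id,
    well = paste0(rep(LETTERS[seq_len(replicates)], times = n),
                  sprintf("%02d", rep(seq_len(n), each = replicates))),
    construct = rep(means$construct, each = replicates),
    condition = rep(means$condition, each = replicates),
    rlu = rep(means$rlu, each = replicates),
    stringsAsFactors = FALSE
  )
}

# Two-plate screen where a single receptor has the given group means; the
# positive control is EMPTY/FORSKOLIN.
manual_screen <- function(empty_base, empty_fsk, rec_base, rec_fsk,
                          receptor = "GPRX", scale = c(1, 1)) {
  plates <- lapply(seq_along(scale), function(i) {
    manual_plate(paste0("p", i), data.frame(
      construct = c("EMPTY", "EMPTY", receptor, receptor),
      condition = c("BASELINE", "FORSKOLIN", "BASELINE", "FORSKOLIN"),
      rlu = scale[i] * c(empty_base, empty_fsk, rec_base, rec_fsk),
      stringsAsFactors = FALSE))
  })
  do.call(rbind, plates)
}

# Random balanced two-factor layout for ANOVA oracle checks.
random_layout <- function(t, b, r, block_sd = 1, trt_sd = 1, noise_sd = 1) {
  d <- expand.grid(rep = seq_len(r), block = paste0("blk", seq_len(b)),
                   treatment = paste0("trt", seq_len(t)),
                   stringsAsFactors = FALSE)
  trt_eff <- stats::rnorm(t, sd = trt_sd)
  blk_eff <- stats::rnorm(b, sd = block_sd)
  d$y <- 50 + trt_eff[match(d$treatment, paste0("trt", seq_len(t)))] +
    blk_eff[match(d$block, paste0("blk", seq_len(b)))] +
    stats::rnorm(nrow(d), sd = noise_sd)
  d
}

# Independent least-squares oracle: sequential sums of squares from a
# full-rank design-matrix fit (balanced data, so sequential = classical).
lm_oracle <- function(d) {
  fit <- stats::anova(stats::lm(y ~ treatment + block + treatment:block,
                                data = d))
  list(ss = unname(fit$"Sum Sq"), df = unname(fit$Df),
       f = unname(fit$"F value"), p = unname(fit$"Pr(>F)"))
}
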