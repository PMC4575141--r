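# Synthetic plate-data generator with known ground truth.
#
# Generative model: the expected signal of a well is the product of
#   baseline_mean_rlu
#   x forskolin_ratio            (forskolin-condition wells only)
#   x effect multiplier          (construct x condition, 1 for empty vector)
#   x plate effect               (log-normal, one scalar per plate)
#   x well noise                 (log-normal, independent per well)
# Both random factors have expectation exactly 1 (log-mean = -sigma^2/2), so
# group means are unbiased for the product of design constants and effect
# multipliers, and the matched-control ratio structure of the downstream
# normalization is exact in expectation. Noise is multiplicative because
# luminescence readouts are positive with roughly constant coefficient of
# variation; the single per-plate scalar is precisely the structure that both
# RCBD blocking and positive-control normalization presuppose.

#' Configure the synthetic-data generator
#'
#' @param baseline_mean_rlu Expected empty-vector baseline signal in relative
#'   light units. Default 20000.
#' @param forskolin_ratio Expected positive-control / baseline-control signal
#'   ratio; the screen this generator emulates maintained roughly 5:1.
#'   Must exceed 1. Default 5.
#' @param plate_effect_sd Standard deviation, on the natural-log scale, of the
#'   per-plate multiplicative block effect. Default 0.3.
#' @param well_noise_cv Coefficient of variation of the per-well
#'   multiplicative log-normal noise. Default 0.15.
#' @param n_plates Number of plates (blocks) per batch. Default 4.
#' @param seed Integer random seed; simulation refuses to run without one.
#' @param effect_jitter_sd Optional per-plate log-normal jitter applied to a
#'   receptor's effect multipliers, mimicking unexplained plate-to-plate
#'   variability in receptor response. Default 0 (off).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(baseline_mean_rlu = 20000,
                              forskolin_ratio = 5,
                              plate_effect_sd = 0.3,
                              well_noise_cv = 0.15,
                              n_plates = 4L,
                              seed = NULL,
                              effect_jitter_sd = 0) {
  if (baseline_mean_rlu <= 0) stop("baseline_mean_rlu must be positive")
  if (forskolin_ratio <= 1) stop("forskolin_ratio must exceed 1")
  if (plate_effect_sd < 0 || well_noise_cv < 0 || effect_jitter_sd < 0)
    stop("dispersion parameters must be non-negative")
  structure(
    list(baseline_mean_rlu = baseline_mean_rlu,
         forskolin_ratio = forskolin_ratio,
         plate_effect_sd = plate_effect_sd,
         well_noise_cv = well_noise_cv,
         n_plates = as.integer(n_plates),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         effect_jitter_sd = effect_jitter_sd),
    class = "simulation_config"
  )
}

#' Ground-truth effect profiles for a set of receptors
#'
#' An effect profile gives a receptor's multiplicative effect on expected
#' baseline expression and on expected forskolin-stimulated expression,
#' relative to the matched empty-vector control. A multiplier m corresponds
#' to a fractional change of m - 1; the empty vector is (1, 1).
#'
#' @param receptor Character vector of receptor labels (must not use the
#'   reserved control label `EMPTY`).
#' @param baseline_multiplier,forskolin_multiplier Positive multipliers,
#'   recycled to the length of `receptor`.
#' @return A data frame with columns `receptor`, `baseline_multiplier`,
#'   `forskolin_multiplier`.
#' @export
effect_profiles <- function(receptor, baseline_multiplier = 1,
                            forskolin_multiplier = 1) {
  if (any(receptor == EMPTY_CONSTRUCT))
    stop("the label ", EMPTY_CONSTRUCT, " is reserved for the control construct")
  if (anyDuplicated(receptor))
    stop("receptor labels must be unique")
  if (any(baseline_multiplier <= 0) || any(forskolin_multiplier <= 0))
    stop("effect multipliers must be positive")
  data.frame(receptor = as.character(receptor),
             baseline_multiplier = rep_len(baseline_multiplier, length(receptor)),
             forskolin_multiplier = rep_len(forskolin_multiplier, length(receptor)),
             stringsAsFactors = FALSE)
}

#' Canonical effect archetypes for the five response groups
#'
#' One representative effect profile per response pattern, chosen so each
#' archetype sits well past the classifier's thresholds and is assigned to
#' its own group in the zero-noise limit:
#' \describe{
#'   \item{A}{(0.4, 0.4) — inhibits both baseline and forskolin-stimulated
#'     expression by 60\%.}
#'   \item{B}{(4.0, 0.5) — 300\% baseline stimulation with 50\% inhibition of
#'     the forskolin response.}
#'   \item{C}{(1.0, 0.5) — no baseline effect, 50\% forskolin inhibition.}
#'   \item{D}{(4.0, 1.0) — 300\% baseline stimulation only.}
#'   \item{E}{(1.0, 1.0) — null.}
#' }
#'
#' @param groups Which archetypes to return, a subset of `c("A","B","C","D","E")`.
#' @return An effect-profile data frame with an extra `true_group` column.
#' @export
archetype_profiles <- function(groups = c("A", "B", "C", "D", "E")) {
  groups <- match.arg(groups, c("A", "B", "C", "D", "E"), several.ok = TRUE)
  base <- c(A = 0.4, B = 4.0, C = 1.0, D = 4.0, E = 1.0)
  fsk  <- c(A = 0.4, B = 0.5, C = 0.5, D = 1.0, E = 1.0)
  out <- effect_profiles(paste0("ARCH_", groups),
                         baseline_multiplier = unname(base[groups]),
                         forskolin_multiplier = unname(fsk[groups]))
  out$true_group <- groups
  out
}

#' Simulate a reporter screen with known ground truth
#'
#' Generates a full plate dataset for the given receptor effect profiles
#' under the multiplicative log-normal model described above. Receptors are
#' batched onto plates: each plate carries the two control groups (empty
#' vector with and without forskolin) plus as many receptors, in both
#' conditions, as the design's `treatments_per_plate` allows; a batch spans
#' `n_plates` plates sharing the same receptors, and additional batches get
#' fresh plates. Identical seeds give identical datasets.
#'
#' @param profiles An [effect_profiles()] data frame.
#' @param design A [screen_design()].
#' @param sim A [simulation_config()].
#' @param seed Integer seed; overrides `sim$seed`. Mandatory (via either
#'   argument): reproducibility is part of the generator's contract.
#' @return A well-measurement data frame with columns
#'   `plate_id`, `well`, `construct`, `condition`, `rlu`.
#' @examples
#' wells <- simulate_screen(archetype_profiles(), seed = 1)
#' nrow(wells)  # 12 groups x 4 replicates x 4 plates
#' @export
simulate_screen <- function(profiles, design = screen_design(),
                            sim = simulation_config(), seed = sim$seed) {
  if (is.null(seed))
    stop("a seed is required: pass `seed` or set it in simulation_config()")
  stopifnot(is.data.frame(profiles),
            all(c("receptor", "baseline_multiplier", "forskolin_multiplier")
                %in% names(profiles)))
  capacity <- (design$treatments_per_plate - 2L) %/% 2L
  if (capacity < 1L)
    stop("design has no room for receptors beside the control groups")

  set.seed(as.integer(seed))
  n_batches <- ceiling(nrow(profiles) / capacity)
  batches <- split(seq_len(nrow(profiles)),
                   ceiling(seq_len(nrow(profiles)) / capacity))
  pieces <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    pieces[[b]] <- simulate_batch(profiles[batches[[b]], , drop = FALSE],
                                  design, sim, batch = b)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

simulate_batch <- function(profiles, design, sim, batch) {
  r <- design$replicates_per_group
  np <- sim$n_plates
  constructs <- c(EMPTY_CONSTRUCT, profiles$receptor)
  mult <- rbind(
    data.frame(construct = constructs,
               condition = "BASELINE",
               m = c(1, profiles$baseline_multiplier),
               stringsAsFactors = FALSE),
    data.frame(construct = constructs,
               condition = "FORSKOLIN",
               m = c(1, profiles$forskolin_multiplier),
               stringsAsFactors = FALSE)
  )
  # stable group order: controls first, then receptors, baseline before forskolin
  mult <- mult[order(match(mult$construct, constructs), mult$condition), ]
  n_groups <- nrow(mult)

  sig_p <- sim$plate_effect_sd
  plate_eff <- if (sig_p > 0)
    exp(stats::rnorm(np, mean = -sig_p^2 / 2, sd = sig_p)) else rep(1, np)
  sig_w <- sqrt(log1p(sim$well_noise_cv^2))

  rows <- vector("list", np)
  well_rows <- guard_row_letters(r)
  for (p in seq_len(np)) {
    m <- mult$m
    if (sim$effect_jitter_sd > 0) {
      sj <- sim$effect_jitter_sd
      jit <- exp(stats::rnorm(length(constructs), mean = -sj^2 / 2, sd = sj))
      jit[1L] <- 1  # controls are never jittered
      m <- m * jit[match(mult$construct, constructs)]
    }
    mu <- sim$baseline_mean_rlu *
      ifelse(mult$condition == "FORSKOLIN", sim$forskolin_ratio, 1) * m
    mu_wells <- rep(mu, each = r) * plate_eff[p]
    noise <- if (sig_w > 0)
      exp(stats::rnorm(n_groups * r, mean = -sig_w^2 / 2, sd = sig_w))
    else rep(1, n_groups * r)
    rows[[p]] <- data.frame(
      plate_id = sprintf("b%dp%d", batch, p),
      well = paste0(rep(well_rows, times = n_groups),
                    sprintf("%02d", rep(seq_len(n_groups), each = r))),
      construct = rep(mult$construct, each = r),
      condition = rep(mult$condition, each = r),
      rlu = mu_wells * noise,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

# Replicates occupy alternating rows, leaving guard rows dark (layout
# metadata only, never used in computation); designs with more than four
# replicates fall back to consecutive rows.
guard_row_letters <- function(r) {
  if (r <= 4L) c("A", "C", "E", "G")[seq_len(r)] else LETTERS[seq_len(r)]
}
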