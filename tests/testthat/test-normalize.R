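test_that("plate normalization divides by the positive-control mean", {
  plate <- manual_plate("p1", data.frame(
    construct = c("EMPTY", "EMPTY", "GPR6"),
    condition = c("BASELINE", "FORSKOLIN", "BASELINE"),
    rlu = c(20000, 100000, 50000), stringsAsFactors = FALSE))
  ng <- normalize_plate(plate)
  val <- function(con, cond)
    ng$normalized_value[ng$construct == con & ng$condition == cond]
  expect_identical(val("GPR6", "BASELINE"), 0.5)
  expect_identical(val("EMPTY", "FORSKOLIN"), 1)  # the control itself
  expect_identical(val("EMPTY", "BASELINE"), 0.2)
})

test_that("per-plate rescaling leaves normalized values and fractional changes unchanged", {
  wells <- simulate_screen(archetype_profiles(), seed = 7)
  fc1 <- fractional_changes(normalize_screen(wells))

  rescale <- function(wells, base) {
    plates <- unique(wells$plate_id)
    fac <- stats::setNames(base^seq_along(plates), plates)
    wells$rlu <- wells$rlu * fac[wells$plate_id]
    wells
  }
  # powers of two: exact in IEEE arithmetic, so bit-identical
  fc2 <- fractional_changes(normalize_screen(rescale(wells, 4)))
  expect_identical(fc1$mean_fractional_change, fc2$mean_fractional_change)
  # arbitrary factor: identical up to rounding of the scaled products
  fc7 <- fractional_changes(normalize_screen(rescale(wells, 7)))
  expect_equal(fc1$mean_fractional_change, fc7$mean_fractional_change,
               tolerance = 1e-12)
})

test_that("stage-1 division cancels in the baseline fractional change", {
  wells <- simulate_screen(archetype_profiles(), seed = 13)
  fc <- fractional_changes(normalize_screen(wells))
  # identity oracle: same quantity from raw group means, skipping stage 1
  gm <- stats::aggregate(rlu ~ plate_id + construct + condition, wells, mean)
  b <- gm[gm$condition == "BASELINE", ]
  for (rec in paste0("ARCH_", LETTERS[1:5])) {
    plates <- intersect(b$plate_id[b$construct == rec],
                        b$plate_id[b$construct == "EMPTY"])
    trt <- b$rlu[b$construct == rec][match(plates, b$plate_id[b$construct == rec])]
    ctl <- b$rlu[b$construct == "EMPTY"][match(plates, b$plate_id[b$construct == "EMPTY"])]
    raw <- mean(trt / ctl - 1)
    got <- fc$mean_fractional_change[fc$receptor == rec & fc$condition == "BASELINE"]
    expect_equal(got, raw, tolerance = 1e-12)
  }
})

test_that("trivial fractional-change arithmetic holds", {
  # treatment normalized 0.5 vs control 1.0 on both plates -> -0.5
  wells <- manual_screen(empty_base = 100000, empty_fsk = 100000,
                         rec_base = 50000, rec_fsk = 50000, scale = c(1, 3))
  fc <- fractional_changes(normalize_screen(wells))
  expect_identical(fc$mean_fractional_change, c(-0.5, -0.5))
  # treatment identical to control -> 0
  null_wells <- manual_screen(20000, 100000, 20000, 100000, scale = c(1, 2))
  fc0 <- fractional_changes(normalize_screen(null_wells))
  expect_identical(fc0$mean_fractional_change, c(0, 0))
})

test_that("raising a treatment group strictly raises its fractional change", {
  wells <- simulate_screen(archetype_profiles(), seed = 21)
  fc <- fractional_changes(normalize_screen(wells))
  base <- fc$mean_fractional_change[fc$receptor == "ARCH_C" &
                                    fc$condition == "BASELINE"]
  up <- wells
  sel <- up$construct == "ARCH_C" & up$condition == "BASELINE"
  up$rlu[sel] <- up$rlu[sel] * 1.05
  fc_up <- fractional_changes(normalize_screen(up))
  expect_gt(fc_up$mean_fractional_change[fc_up$receptor == "ARCH_C" &
                                         fc_up$condition == "BASELINE"], base)
})

test_that("plates without a usable positive control are excluded with a reason", {
  wells <- simulate_screen(archetype_profiles(), seed = 17)
  drop <- wells$plate_id == "b1p3" & wells$construct == "EMPTY" &
    wells$condition == "FORSKOLIN"
  ng <- normalize_screen(wells[!drop, ])
  excl <- attr(ng, "excluded_plates")
  expect_identical(excl$plate_id, "b1p3")
  expect_match(excl$reason, "positive-control")
  expect_false("b1p3" %in% ng$plate_id)
  # with only one usable plate left, summaries are unusable
  one <- wells[wells$plate_id %in% c("b1p1", "b1p2"), ]
  one <- one[!(one$plate_id == "b1p2" & one$construct == "EMPTY" &
               one$condition == "FORSKOLIN"), ]
  fc <- fractional_changes(normalize_screen(one))
  expect_true(all(!fc$usable))
  expect_true(all(fc$n_plates_used == 1L))
})

test_that("normalize_plate refuses multi-plate input and degenerate controls", {
  wells <- simulate_screen(archetype_profiles(), seed = 17)
  expect_error(normalize_plate(wells), "one plate")
  zero <- manual_plate("pz", data.frame(
    construct = c("EMPTY", "EMPTY"), condition = c("BASELINE", "FORSKOLIN"),
    rlu = c(100, 0), stringsAsFactors = FALSE))
  expect_warning(res <- normalize_plate(zero), "not positive")
  expect_null(res)
})
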