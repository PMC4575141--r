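# Oracle for all ANOVA checks: sequential sums of squares from a full-rank
# least-squares fit (stats::lm + stats::anova), which for balanced data equal
# the classical decomposition. The implementation under test never calls lm.

test_that("a fixed 2x3x2 table reproduces frozen oracle values", {
  d <- expand.grid(rep = 1:2, blk = paste0("p", 1:3), trt = c("ctrl", "rx"),
                   stringsAsFactors = FALSE)
  d$y <- c(11.964, 10.937, 9.784, 9.574, 12.316, 12.585,
           11.069, 9.746, 7.55, 7.757, 6.656, 10.938)
  res <- rcbd_anova(d$y, d$trt, d$blk)
  tab <- res$table
  # frozen from the least-squares projection oracle
  expect_equal(tab$sum_of_squares[1:4],
               c(15.06176133333337, 12.06002850000003,
                 3.47680016666666, 10.64994600000002), tolerance = 1e-10)
  expect_identical(tab$df, c(1L, 2L, 2L, 6L, 11L))
  expect_equal(tab$F_statistic[1:3],
               c(8.485542368008256, 3.397208352042351, 0.979385294535761),
               tolerance = 1e-10)
  expect_equal(tab$p_value[1:3],
               c(0.0268753264724657, 0.1031317239379521, 0.4284654345872205),
               tolerance = 1e-10)
  # the live oracle agrees with the frozen numbers
  orc <- lm_oracle(data.frame(y = d$y, treatment = d$trt, block = d$blk))
  expect_equal(tab$sum_of_squares[1:4], orc$ss, tolerance = 1e-12)
})

test_that("implementation matches the least-squares oracle across random balanced layouts", {
  set.seed(90210)
  grid <- expand.grid(t = c(2L, 3L, 12L), b = c(2L, 4L, 8L), r = c(2L, 4L))
  for (i in seq_len(nrow(grid))) {
    for (rep in 1:3) {
      d <- random_layout(grid$t[i], grid$b[i], grid$r[i])
      res <- rcbd_anova(d$y, d$treatment, d$block)$table
      orc <- lm_oracle(d)
      rel <- function(a, b) abs(a - b) / pmax(abs(b), 1e-12)
      expect_lt(max(rel(res$sum_of_squares[1:4], orc$ss)), 1e-8)
      expect_identical(res$df[1:4], orc$df)
      expect_lt(max(rel(res$F_statistic[1:3], orc$f[1:3])), 1e-8)
      expect_lt(max(rel(res$p_value[1:3], orc$p[1:3])), 1e-8)
    }
  }
})

test_that("sums of squares always decompose the total", {
  set.seed(77)
  for (i in 1:10) {
    d <- random_layout(sample(2:6, 1), sample(2:8, 1), sample(2:4, 1))
    tab <- rcbd_anova(d$y, d$treatment, d$block)$table
    parts <- sum(tab$sum_of_squares[1:4])
    total <- tab$sum_of_squares[5]
    expect_lt(abs(parts - total) / total, 1e-8)
    expect_identical(sum(tab$df[1:4]), tab$df[5])
    expect_true(all(tab$sum_of_squares >= 0))
    expect_true(all(tab$p_value[1:3] >= 0 & tab$p_value[1:3] <= 1))
  }
})

test_that("F and p are invariant to location and positive scale; SS to block relabeling", {
  set.seed(42)
  d <- random_layout(3, 4, 2)
  base <- rcbd_anova(d$y, d$treatment, d$block)$table
  shifted <- rcbd_anova(d$y + 100, d$treatment, d$block)$table
  scaled <- rcbd_anova(d$y * 3.7, d$treatment, d$block)$table
  expect_equal(base$F_statistic, shifted$F_statistic, tolerance = 1e-9)
  expect_equal(base$p_value, shifted$p_value, tolerance = 1e-9)
  expect_equal(base$F_statistic, scaled$F_statistic, tolerance = 1e-9)
  expect_equal(base$p_value, scaled$p_value, tolerance = 1e-9)

  relab <- c(blk1 = "z9", blk2 = "z1", blk3 = "z5", blk4 = "z2")
  perm <- rcbd_anova(d$y, d$treatment, relab[d$block])$table
  expect_equal(base$sum_of_squares, perm$sum_of_squares, tolerance = 1e-12)
})

test_that("degenerate data are flagged, not mangled", {
  d <- expand.grid(rep = 1:2, blk = c("p1", "p2"), trt = c("a", "b"))
  flat <- rcbd_anova(rep(5, 8), d$trt, d$blk)
  expect_identical(flat$degenerate, "no_variance")
  expect_true(all(flat$table$p_value[1:3] == 1))
  expect_true(all(flat$table$sum_of_squares == 0))

  # treatment effect with zero residual: p collapses to 0 for active sources
  y <- ifelse(d$trt == "b", 10, 5)
  det <- rcbd_anova(y, d$trt, d$blk)
  expect_identical(det$degenerate, "zero_residual")
  expect_identical(det$table$p_value[1], 0)   # treatment SS > 0
  expect_identical(det$table$p_value[2], 1)   # block SS = 0
})

test_that("unbalanced layouts are rejected toward the validator", {
  d <- expand.grid(rep = 1:2, blk = c("p1", "p2"), trt = c("a", "b"))
  d$y <- rnorm(nrow(d))
  expect_error(rcbd_anova(d$y[-1], d$trt[-1], d$blk[-1]), "validate_dataset")
  expect_error(rcbd_anova(d$y, d$trt, rep("p1", 8)), "2 blocks")
})

test_that("the interaction error term changes only the treatment F", {
  set.seed(5)
  d <- random_layout(3, 4, 3)
  res_r <- rcbd_anova(d$y, d$treatment, d$block, error_term = "residual")
  res_i <- rcbd_anova(d$y, d$treatment, d$block, error_term = "interaction")
  ms <- res_i$table$mean_square
  expect_equal(res_i$table$F_statistic[1], ms[1] / ms[3], tolerance = 1e-12)
  expect_equal(res_r$table$F_statistic[2:3], res_i$table$F_statistic[2:3],
               tolerance = 1e-12)
})

test_that("treatment_p_for_receptor analyses plate-normalized wells per condition", {
  sim0 <- simulation_config(plate_effect_sd = 0, well_noise_cv = 0)
  wells <- simulate_screen(archetype_profiles(), sim = sim0, seed = 1)
  # noise-free effect: treatment SS > 0, residual 0, degenerate significant
  res <- treatment_p_for_receptor(wells, "ARCH_A", "BASELINE")
  expect_identical(res$p_value, 0)
  expect_identical(res$anova$degenerate, "zero_residual")
  # noise-free null: no variance at all
  res_e <- treatment_p_for_receptor(wells, "ARCH_E", "BASELINE")
  expect_identical(res_e$p_value, 1)

  noisy <- simulate_screen(archetype_profiles(), seed = 77)
  res_a <- treatment_p_for_receptor(noisy, "ARCH_A", "BASELINE")
  expect_lt(res_a$p_value, 0.01)
  res_af <- treatment_p_for_receptor(noisy, "ARCH_A", "FORSKOLIN")
  expect_lt(res_af$p_value, 0.01)
})

test_that("null treatment p-values are approximately uniform (light check)", {
  prof <- effect_profiles("NULLREC")
  p <- vapply(1:200, function(s) {
    wells <- simulate_screen(prof, seed = 5000 + s)
    treatment_p_for_receptor(wells, "NULLREC", "BASELINE")$p_value
  }, 0)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
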