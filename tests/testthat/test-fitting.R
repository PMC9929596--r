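p_def <- op_params()

make_linear_experiment <- function() {
  # control with a linear growth trend; treated groups at fixed fold-changes
  days <- 0:50
  ctrl <- data.frame(group = "ctrl", day = days,
                     intake = 1 + 0.01 * days, fat = 2 + 0.03 * days)
  trt <- data.frame(group = "high", day = days,
                    intake = 1.6 * (1 + 0.01 * days),
                    fat = 1.2 * (2 + 0.03 * days))
  feeding_experiment(rbind(ctrl, trt), control = "ctrl",
                     controlled_window = c(0, 20),
                     recovery_window = c(21, 50))
}

test_that("normalization removes shared trends and maps control to 1", {
  norm <- normalize_to_control(make_linear_experiment())
  d <- norm$data
  expect_equal(d$intake[d$group == "ctrl"], rep(1, 51))
  expect_equal(d$fat[d$group == "ctrl"], rep(1, 51))
  expect_equal(d$intake[d$group == "high"], rep(1.6, 51))
  expect_equal(d$fat[d$group == "high"], rep(1.2, 51))
})

test_that("normalization errors name the coverage gap", {
  days <- 0:10
  dat <- rbind(data.frame(group = "ctrl", day = days, intake = 1, fat = 1),
               data.frame(group = "far", day = days + 20, intake = 1, fat = 1))
  exp <- feeding_experiment(dat, "ctrl", c(0, 5), c(6, 10))
  expect_error(normalize_to_control(exp), "does not cover group 'far'")
})

test_that("phase-point extraction: one diet point per group, pooled appetite
           days, control at (1, 1)", {
  e <- generate_feeding_experiment(p_def, feeding_design(seed = 3))
  pts <- extract_phase_points(normalize_to_control(e))
  expect_equal(nrow(pts$diet), 3)        # three controlled groups
  expect_equal(nrow(pts$appetite), 3 * 30)   # pooled recovery days
  ctrl <- pts$diet[pts$diet$group == "tube100", ]
  expect_equal(unname(c(ctrl$u, ctrl$F)), c(1, 1), tolerance = 1e-12)
  expect_true(all(pts$diet$u > 0) && all(pts$appetite$u > 0))
})

test_that("diet-line fit: exact on exact points, SDs flagged when unavailable", {
  two <- fit_diet_line(data.frame(u = c(0.5, 1.5), F = c(0.29, 1.85)))
  expect_equal(unname(coef(two)), c(1.56, 0.49), tolerance = 1e-10)
  expect_true(is.na(two$sd_a) && is.na(two$sd_b))
  u <- c(0.4, 1, 1.6)
  three <- fit_diet_line(data.frame(u = u, F = 1.56 * u - 0.49))
  expect_equal(unname(coef(three)), c(1.56, 0.49), tolerance = 1e-10)
  expect_false(is.na(three$sd_a))
  expect_error(fit_diet_line(data.frame(u = c(1, 1), F = c(0, 1))),
               "degenerate")
})

test_that("appetite-line fit recovers noiseless parameters and respects the
           intake ceiling", {
  u <- seq(0.35, 1.30, length.out = 39)
  pts <- data.frame(u = u, F = (1 / u) * (1.38 / u - 1)^(1 / 7.1))
  fit <- fit_appetite_line(pts)
  expect_equal(fit$c, 1, tolerance = 1e-6)
  expect_equal(fit$umax, 1.38, tolerance = 1e-6)
  expect_equal(fit$n, 7.1, tolerance = 1e-5)
  expect_gt(fit$umax, max(u))
  # boundary: the fitted curve collapses to zero fat at its own ceiling
  expect_lt(fit$c * (1 / fit$umax) * (1 / (1 - 1e-12) - 1)^(1 / fit$n), 0.05)
  expect_error(fit_appetite_line(pts[1:3, ]), "at least 4")
})

test_that("leptin-fat fit: exact quadratic recovery, AIC model choice, and
           scale invariance of the preference", {
  F <- seq(5, 45, length.out = 70)
  pts <- data.frame(fat = F, leptin = 0.016 * F^2 + 0.062 * F)
  fit <- fit_leptin_fat(pts)
  expect_equal(fit$a_q, 0.016, tolerance = 1e-10)
  expect_equal(fit$b_q, 0.062, tolerance = 1e-10)
  expect_identical(fit$preferred, "quadratic")
  # noisy scatter: preference invariant under rescaling both axes
  set.seed(5)
  pts$leptin <- pts$leptin * exp(rnorm(70, 0, 0.2))
  f1 <- fit_leptin_fat(pts)
  f2 <- fit_leptin_fat(data.frame(fat = 3.7 * pts$fat,
                                  leptin = 0.2 * pts$leptin))
  expect_identical(f1$preferred, f2$preferred)
  expect_equal(f1$delta_aic, f2$delta_aic, tolerance = 1e-8)
  expect_error(fit_leptin_fat(data.frame(fat = c(-1, 1, 2, 3, 4),
                                         leptin = 1:5)), "positive")
})

test_that("full pipeline on noiseless data recovers the generating lines and
           intersects at the control point", {
  d0 <- feeding_design(controlled_days = 600, recovery_days = 30,
                       growth_rate = 1, noise_sigma = 0, seed = 1)
  e0 <- generate_feeding_experiment(p_def, d0)
  fit <- fit_phase_portrait(e0)
  tr <- attr(e0, "truth")
  co <- coef(fit)
  expect_equal(unname(co["a"]), tr$a, tolerance = 1e-6)
  expect_equal(unname(co["b"]), tr$b, tolerance = 1e-6)
  expect_equal(unname(co["c"]), tr$c, tolerance = 1e-6)
  expect_equal(unname(co["umax"]), tr$umax, tolerance = 1e-6)
  expect_equal(unname(co["n"]), tr$n, tolerance = 1e-4)
  expect_equal(unlist(fit$operating_point), c(u = 1, F = 1),
               tolerance = 1e-6)
})

test_that("fitted lines intersect near (1, 1) for noisy control-calibrated data", {
  for (s in 1:5) {
    fit <- fit_phase_portrait(
      generate_feeding_experiment(p_def, feeding_design(seed = s)))
    expect_lt(abs(fit$operating_point$u - 1), 0.2)
    expect_lt(abs(fit$operating_point$F - 1), 0.2)
  }
})

test_that("feeding and scatter CSVs round-trip with bit-exact headers", {
  e <- generate_feeding_experiment(p_def, feeding_design(seed = 2))
  f <- tempfile(fileext = ".csv")
  write_feeding_experiment(e, f)
  expect_identical(readLines(f, n = 1),
                   "\"group\",\"day\",\"intake\",\"fat\",\"weight\"")
  back <- read_feeding_experiment(f, "tube100", c(0, 20), c(21, 50))
  expect_equal(back$data$intake, e$data$intake, tolerance = 1e-12)
  expect_equal(back$data$fat, e$data$fat, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  writeLines(c("grp,day,intake", "a,1,2"), bad)
  expect_error(read_feeding_experiment(bad, "a", c(0, 1), c(2, 3)),
               "header must be exactly")

  sc <- data.frame(fat = 1:5, leptin = (1:5)^2)
  f2 <- tempfile(fileext = ".csv")
  write_leptin_scatter(sc, f2)
  expect_equal(read_leptin_scatter(f2), sc)
  writeLines(c("fat,lep", "1,1"), f2)
  expect_error(read_leptin_scatter(f2), "header must be exactly")
})
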