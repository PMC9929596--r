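p_def <- op_params()

test_that("parameters map to the line they shape", {
  expect_identical(line_membership(c("aF", "gammaF", "gammaE")),
                   rep("diet", 3))
  expect_identical(line_membership(c("aL", "gammaL", "KL", "umax", "n")),
                   rep("appetite", 5))
  expect_error(line_membership("kappa"), "unknown parameter")
})

test_that("classification matches the worked intervention examples", {
  # exercise: raised energy expenditure -> opposing, no transient
  ex <- classify_intervention(p_def, tweak_params(p_def, gammaE = 0.0134))
  expect_identical(ex$line_shifted, "diet")
  expect_identical(c(ex$fat_direction, ex$intake_direction), c(-1, 1))
  expect_identical(ex$coherence, "opposing")
  expect_identical(ex$transient, "none")
  expect_true(ex$simulation_confirmed)
  # leptin resistance: KL up -> coherent rise with an intake overshoot
  lr <- classify_intervention(p_def, tweak_params(p_def, KL = 0.75))
  expect_identical(lr$line_shifted, "appetite")
  expect_identical(c(lr$fat_direction, lr$intake_direction), c(1, 1))
  expect_identical(lr$coherence, "coherent")
  expect_identical(lr$transient, "overshoot")
  expect_true(lr$simulation_confirmed)
  # satiety-inducing nutrients: umax down -> coherent fall with undershoot
  sn <- classify_intervention(p_def, tweak_params(p_def, umax = 1.6))
  expect_identical(c(sn$fat_direction, sn$intake_direction), c(-1, -1))
  expect_identical(sn$transient, "undershoot")
  expect_true(sn$simulation_confirmed)
})

test_that("diet-line perturbations are opposing and transient-free (property)", {
  for (param in c("aF", "gammaF", "gammaE")) {
    for (fac in c(0.8, 1.2)) {
      q <- do.call(tweak_params,
                   c(list(p_def),
                     stats::setNames(list(p_def[[param]] * fac), param)))
      res <- classify_intervention(p_def, q, confirm = FALSE)
      expect_identical(res$coherence, "opposing")
      expect_identical(res$transient, "none")
      expect_identical(res$fat_direction * res$intake_direction, -1)
    }
  }
})

test_that("appetite-line perturbations are coherent with a transient oriented
           by the intake change (property)", {
  for (param in c("aL", "gammaL", "KL", "umax")) {
    for (fac in c(0.8, 1.2)) {
      q <- do.call(tweak_params,
                   c(list(p_def),
                     stats::setNames(list(p_def[[param]] * fac), param)))
      res <- classify_intervention(p_def, q, confirm = FALSE)
      expect_identical(res$coherence, "coherent")
      expect_identical(res$fat_direction * res$intake_direction, 1)
      expect_identical(res$transient,
                       if (res$intake_direction > 0) "overshoot"
                       else "undershoot")
    }
  }
})

test_that("satiety-capped regime is insensitive to leptin resistance", {
  p_hi <- tweak_params(p_def, KL = 5.4)       # well above Kcrit = 2.7
  res <- classify_intervention(p_hi, tweak_params(p_hi, KL = 6.5),
                               cfg = sim_config(n_dynamics = 100),
                               confirm = FALSE)
  expect_true(res$satiety_capped)
  expect_identical(res$fat_direction, 0)
  expect_identical(res$intake_direction, 0)
})

test_that("the battery reproduces every published direction and transient", {
  bat <- intervention_battery()
  ref <- rodent_rule_table()
  m <- merge(bat, ref, by = "intervention", suffixes = c(".pred", ".obs"))
  expect_equal(nrow(m), nrow(ref))
  expect_identical(m$fat_sign.pred, m$fat_sign.obs)
  expect_identical(m$intake_sign.pred, m$intake_sign.obs)
  expect_identical(m$transient.pred, m$transient.obs)
  expect_true(all(m$sim_confirmed))
  f <- tempfile(fileext = ".csv")
  write_battery(bat, f)
  expect_equal(utils::read.csv(f)$intervention, bat$intervention)
})

test_that("identical parameter sets are rejected and mixed shifts reported", {
  expect_error(classify_intervention(p_def, p_def), "identical")
  both <- classify_intervention(
    p_def, tweak_params(p_def, gammaE = 0.0134, KL = 0.4), confirm = FALSE)
  expect_identical(both$line_shifted, "both")
})
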