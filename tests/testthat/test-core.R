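p_def <- op_params()

test_that("diet line rises and matches direct evaluation", {
  expect_equal(diet_line_intake(0, op_params(gammaE = 1e-12)), 5e-11,
               tolerance = 1e-6)
  # frozen from the bisection intersection oracle at the default rates
  expect_equal(diet_line_intake(0.5196899, p_def), 0.9621124,
               tolerance = 1e-6)
  F <- seq(0, 3, length.out = 50)
  expect_true(all(diff(diet_line_intake(F, p_def)) > 0))
  # published normalized fit, inverse form F = 1.56 u - 0.49: u=1 -> F=1.07
  expect_equal(1.56 * 1 - 0.49, 1.07)
  expect_error(diet_line_intake(-1, p_def), "non-negative")
})

test_that("appetite line falls, approaches the steep limit, is linear in KL", {
  # u -> umax from below drives fat to zero (like (umax - u)^(1/n))
  expect_lt(appetite_line_fat(p_def$umax * (1 - 1e-12), p_def, n = 7), 0.01)
  # steep finite n is within 1e-3 of the infinite-steepness value Fc*umax/u
  expect_equal(appetite_line_fat(1, p_def, n = 100), 0.5, tolerance = 1e-3)
  expect_equal(appetite_line_fat(0.8, tweak_params(p_def, KL = 1), n = 7),
               2 * appetite_line_fat(0.8, p_def, n = 7))
  u <- seq(0.1, 1.9, length.out = 40)
  expect_true(all(diff(appetite_line_fat(u, p_def, n = 7)) < 0))
  expect_error(appetite_line_fat(2.5, p_def, n = 7), "between 0 and umax")
  expect_error(appetite_line_fat(1, p_def), "finite Hill steepness")
})

test_that("appetite intake: piecewise steep limit, fixed point at finite n", {
  expect_equal(appetite_intake(0, p_def), p_def$umax)
  expect_equal(appetite_intake(0.5, p_def), 1.0)       # Fc*umax/F
  expect_equal(appetite_intake(0.25, p_def), 2)        # continuity at Fc
  # finite n solves u = umax/(1 + ((aL/(gammaL KL)) F u)^n)
  for (n in c(2, 7, 100)) {
    F <- 0.7
    u <- appetite_intake(F, p_def, n = n)
    expect_equal(u * (1 + ((p_def$aL / (p_def$gammaL * p_def$KL)) * F * u)^n),
                 p_def$umax, tolerance = 1e-8)
  }
  # pointwise convergence to the steep limit, monotone in n
  for (F in c(0.1, 0.2, 0.4, 0.8, 1.2)) {
    lim <- appetite_intake(F, p_def)
    gaps <- vapply(c(7, 100, 1000),
                   function(n) abs(appetite_intake(F, p_def, n = n) - lim),
                   numeric(1))
    expect_true(all(diff(gaps) < 1e-12))
    expect_lt(gaps[3], 1e-2)
  }
  F <- seq(0, 2, length.out = 60)
  expect_true(all(diff(appetite_intake(F, p_def, n = 7)) <= 0))
})

test_that("critical fat and critical resistance follow their defining relations", {
  expect_equal(critical_fat(p_def), 0.25)
  expect_equal(critical_fat(tweak_params(p_def, KL = 1e-9)), 5e-10)
  # Fc proportional to KL across the published sweep range
  KLs <- seq(0.35, 1.6, length.out = 7)
  Fcs <- vapply(KLs, function(k)
    critical_fat(tweak_params(p_def, aF = 0.01, KL = k)), numeric(1))
  expect_equal(Fcs, KLs * 1 / (1 * 2))
  expect_equal(kcrit(p_def), 2.7)
  # with no body energy cost the closed form reduces to aL umax^2 aF/(gL gF)
  expect_equal(kcrit(tweak_params(p_def, gammaE = 1e-12)), 3.2,
               tolerance = 1e-6)
  expect_equal(kcrit(tweak_params(p_def, aL = 3)), 3 * 2.7)
  expect_error(kcrit(structure(utils::modifyList(as.list(p_def),
                                                 list(gammaE = 0.09)),
                               class = "op_params")),
               "must exceed")
})

test_that("operating point: closed forms, regimes, and the numeric oracle agree", {
  st <- operating_point(p_def)
  # frozen from the independent bisection oracle
  expect_equal(st$Fst, 0.5196899, tolerance = 1e-6)
  expect_equal(st$ust, 0.9621124, tolerance = 1e-6)
  expect_identical(st$Lst, p_def$KL)     # exact in the above-critical regime
  expect_identical(st$regime, "above-critical")
  # strong leptin resistance pins intake at the satiety ceiling exactly
  st2 <- operating_point(tweak_params(p_def, KL = 5.4))
  expect_identical(st2$ust, p_def$umax)
  expect_equal(st2$Fst, 1.35)
  expect_equal(st2$Lst, 2.7)
  expect_identical(st2$regime, "satiety-capped")
  # leptin quasi-steady consistency at that point
  expect_equal(leptin_qss(1.35, 2, p_def), 2.7)
  # random draws: Lst = KL whenever above-critical
  set.seed(42)
  for (i in 1:50) {
    p <- random_op_params()
    s <- operating_point(p, check = FALSE)
    if (s$regime == "above-critical") expect_identical(s$Lst, p$KL)
    num <- operating_point_numeric(p)
    expect_lt(rel_err(s$Fst, num$Fst), 1e-8)
    expect_lt(rel_err(s$ust, num$ust), 1e-8)
  }
})

test_that("finite-steepness operating point is the numeric line intersection", {
  for (n in c(6, 7, 100)) {
    st <- operating_point(p_def, n = n)
    expect_equal(diet_line_intake(st$Fst, p_def), st$ust, tolerance = 1e-8)
    expect_equal(appetite_intake(st$Fst, p_def, n = n), st$ust,
                 tolerance = 1e-8)
  }
})

test_that("leptin nullclines: quadratic leptin line and piecewise fat line", {
  expect_equal(leptin_qss(0, 1, p_def), 0)
  expect_equal(leptin_qss(1, 2 * 0.7, p_def), 2 * leptin_qss(1, 0.7, p_def))
  # leptin line equals quasi-steady leptin composed with the diet line
  F <- seq(0, 3, length.out = 30)
  expect_equal(leptin_line(F, p_def),
               leptin_qss(F, diet_line_intake(F, p_def), p_def))
  expect_equal(leptin_line(0.5196899, p_def), 0.5, tolerance = 1e-5)
  # reduced quadratic coefficients reproduce the full expression
  a_q <- p_def$aL * p_def$gammaF / (p_def$gammaL * p_def$aF)
  b_q <- p_def$aL * p_def$gammaE / (p_def$gammaL * p_def$aF)
  expect_equal(leptin_line(F, p_def), a_q * F^2 + b_q * F)
  # fat line: plateau below KL, diminished-store branch above
  expect_equal(as.numeric(fat_line(0.3, p_def)), 1.35)
  hi <- fat_line(0.7, p_def)
  expect_equal(as.numeric(hi), -0.25)
  expect_true(attr(hi, "diminished"))
  expect_equal(as.numeric(fat_line(0, p_def, n = 7)),
               (p_def$aF * p_def$umax - p_def$gammaE) / p_def$gammaF,
               tolerance = 1e-12)
})

test_that("no positive intersection is reported explicitly", {
  bad <- structure(utils::modifyList(as.list(p_def), list(gammaE = 0.05)),
                   class = "op_params")
  expect_error(operating_point_numeric(bad), "no positive intersection")
})
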