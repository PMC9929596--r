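# Core constructions: diet line, appetite line, leptin/fat nullclines and
# the operating point in both regimes.

# (L/KL)^n computed in log space; cap the exponent so that very steep Hill
# terms saturate to a huge-but-finite number instead of overflowing.
hill_pow <- function(ratio, n) {
  out <- numeric(length(ratio))
  pos <- ratio > 0
  out[pos] <- exp(pmin(n * log(ratio[pos]), 700))
  out
}

#' Diet line: steady-state intake sustaining a given fat mass
#'
#' The diet line is the locus of `(F, u)` pairs at which fat gain from
#' feeding exactly balances fat-maintenance and body energy costs
#' (`dF/dt = 0` at fixed, controlled intake):
#' `u = (gammaF * F + gammaE) / aF`.  It rises: more controlled intake
#' sustains more steady-state fat.
#'
#' @param F fat mass (vectorised, `>= 0`).
#' @param p an [op_params] object.
#' @return Intake rate(s) `u`.
#' @examples
#' diet_line_intake(0.5197, op_params())   # ~ 0.962, the default operating point
#' @export
diet_line_intake <- function(F, p) {
  stopifnot(inherits(p, "op_params"))
  if (any(F < 0)) stop("fat mass F must be non-negative")
  (p$gammaF * F + p$gammaE) / p$aF
}

#' Diet line, inverse form: steady-state fat at a given controlled intake
#'
#' @param u controlled intake rate.
#' @param p an [op_params] object.
#' @return Fat mass `F = (aF * u - gammaE) / gammaF` (may be negative when
#'   intake cannot cover basal costs; callers decide how to treat that).
#' @export
diet_line_fat <- function(u, p) {
  stopifnot(inherits(p, "op_params"))
  (p$aF * u - p$gammaE) / p$gammaF
}

#' Appetite line: fat level at which ad-libitum intake equals u
#'
#' Inverting the leptin-feedback intake rule under quasi-steady leptin
#' gives the appetite line in the form fat-as-a-function-of-intake:
#' `F = (gammaL * KL / aL) * (1/u) * (umax/u - 1)^(1/n)`.
#' Defined for finite Hill steepness and `0 < u < umax` only; it falls
#' strictly with `u`.
#'
#' @param u intake rate(s) strictly inside `(0, umax)`.
#' @param p an [op_params] object with finite `n` (or use `n` to override).
#' @param n optional finite Hill steepness overriding `p$n`.
#' @return Fat mass(es).
#' @export
appetite_line_fat <- function(u, p, n = p$n) {
  stopifnot(inherits(p, "op_params"))
  if (is.infinite(n))
    stop("appetite_line_fat needs finite Hill steepness; ",
         "use appetite_intake() for the infinite-steepness limit")
  if (any(u <= 0) || any(u >= p$umax))
    stop("intake u must lie strictly between 0 and umax")
  (p$gammaL * p$KL / p$aL) * (1 / u) * (p$umax / u - 1)^(1 / n)
}

#' Critical fat level
#'
#' Below `Fc = KL * gammaL / (aL * umax)` the infinite-steepness appetite
#' line locks intake at the satiety maximum `umax`; `Fc` is proportional to
#' the leptin-resistance parameter `KL`, so resistant individuals mount the
#' full anti-starvation response at higher fat.
#'
#' @param p an [op_params] object.
#' @return Fat mass `Fc`.
#' @examples
#' critical_fat(op_params())  # 0.25 at the default rates
#' @export
critical_fat <- function(p) {
  stopifnot(inherits(p, "op_params"))
  p$KL * p$gammaL / (p$aL * p$umax)
}

#' Ad-libitum intake at a given fat level (appetite line, intake form)
#'
#' For infinite Hill steepness this is the piecewise form
#' `u = umax` for `F <= Fc`, `u = Fc * umax / F` above it.  For finite `n`
#' the intake solves the fixed point
#' `u = umax / (1 + ((aL/(gammaL*KL)) * F * u)^n)` by bracketed
#' root-finding on `(0, umax]`; the map is monotone so the fixed point is
#' unique.  Continuous and non-increasing in `F` in both cases.
#'
#' @param F fat mass(es), `>= 0`.
#' @param p an [op_params] object.
#' @param n Hill steepness (defaults to `p$n`; may be `Inf`).
#' @param tol root-finding tolerance.
#' @return Intake rate(s) in `(0, umax]`.
#' @examples
#' p <- op_params()
#' appetite_intake(0.5, p)    # 1.0: intake falls inversely with fat
#' appetite_intake(0.1, p)    # umax = 2: below the critical fat level
#' @export
appetite_intake <- function(F, p, n = p$n, tol = 1e-10) {
  stopifnot(inherits(p, "op_params"))
  if (any(F < 0)) stop("fat mass F must be non-negative")
  if (is.infinite(n)) {
    Fc <- critical_fat(p)
    return(ifelse(F <= Fc, p$umax, Fc * p$umax / F))
  }
  k <- p$aL / (p$gammaL * p$KL)
  vapply(F, function(f) {
    if (f == 0) return(p$umax)
    g <- function(u) u * (1 + hill_pow(k * f * u, n)) - p$umax
    lo <- 1e-12 * p$umax
    if (g(lo) >= 0) return(lo)  # pathological: essentially zero intake
    r <- tryCatch(
      stats::uniroot(g, c(lo, p$umax), tol = tol * p$umax),
      error = function(e)
        stop("appetite intake root-finding failed on (", lo, ", ", p$umax,
             ") at F = ", f, ": g(lo) = ", g(lo), ", g(umax) = ", g(p$umax),
             " [", conditionMessage(e), "]")
    )
    r$root
  }, numeric(1))
}

#' Critical leptin resistance
#'
#' `Kcrit` is the `KL` value at which the critical fat level meets the diet
#' line at `u = umax`, i.e. the resistance beyond which the operating point
#' pins intake at the satiety ceiling.  It is computed by solving the
#' defining equality `KL * gammaL / (aL * umax) = (aF*umax - gammaE)/gammaF`
#' numerically, then verified against the closed form
#' `aL * umax * (aF*umax - gammaE) / (gammaL * gammaF)`.
#'
#' @param p an [op_params] object.
#' @return Leptin concentration `Kcrit`.
#' @examples
#' kcrit(op_params())  # 2.7 at the default rates
#' @export
kcrit <- function(p) {
  stopifnot(inherits(p, "op_params"))
  if (p$aF * p$umax <= p$gammaE)
    stop("Kcrit undefined: aF * umax must exceed gammaE, otherwise no ",
         "positive-fat steady state exists at maximal intake")
  Fsat <- (p$aF * p$umax - p$gammaE) / p$gammaF
  # defining equality: Fc(KL*) = Fsat, solved for KL*
  g <- function(KL) KL * p$gammaL / (p$aL * p$umax) - Fsat
  hi <- 2 * Fsat * p$aL * p$umax / p$gammaL + 1
  root <- stats::uniroot(g, c(0, hi), tol = 1e-12 * hi)$root
  closed <- p$aL * p$umax * (p$aF * p$umax - p$gammaE) / (p$gammaL * p$gammaF)
  if (abs(root - closed) > 1e-8 * closed)
    stop("internal inconsistency: Kcrit defining equality and closed form ",
         "disagree (", root, " vs ", closed, ")")
  closed
}

#' Quasi-steady leptin at a given fat and intake
#'
#' Leptin clears fast relative to fat dynamics, so its quasi-steady level is
#' the bilinear `L = (aL/gammaL) * F * u`: production scales with both fat
#' mass and recent food intake.
#'
#' @param F fat mass(es).
#' @param u intake rate(s).
#' @param p an [op_params] object.
#' @return Leptin concentration(s).
#' @export
leptin_qss <- function(F, u, p) {
  stopifnot(inherits(p, "op_params"))
  if (any(F < 0) || any(u < 0)) stop("F and u must be non-negative")
  (p$aL / p$gammaL) * F * u
}

#' Leptin line: steady-state leptin at a given fat level
#'
#' Substituting the diet line into the quasi-steady leptin level yields the
#' quadratic leptin-fat relation
#' `L = (aL/(gammaL*aF)) * F * (gammaF*F + gammaE)`, the model's
#' explanation for the quadratic leptin-fat association seen in human
#' populations.  Identical to
#' `leptin_qss(F, diet_line_intake(F, p), p)`.
#'
#' @param F fat mass(es), `>= 0`.
#' @param p an [op_params] object.
#' @return Leptin concentration(s).
#' @export
leptin_line <- function(F, p) {
  stopifnot(inherits(p, "op_params"))
  if (any(F < 0)) stop("fat mass F must be non-negative")
  (p$aL / (p$gammaL * p$aF)) * F * (p$gammaF * F + p$gammaE)
}

#' Fat line: steady-state fat if leptin were held constant
#'
#' The second nullcline of the leptin-fat phase portrait: holding leptin at
#' `L`, steady-state fat is
#' `F = (aF/gammaF) * umax / (1 + (L/KL)^n) - gammaE/gammaF`; in the
#' infinite-steepness limit it is piecewise-constant with a step at
#' `L = KL`.  Negative values are mathematically valid solutions returned
#' as-is and flagged via the `"diminished"` attribute: they represent a
#' state of diminished fat stores in which lean mass would be broken down
#' to cover energy needs.
#'
#' @param L leptin concentration(s), `>= 0`.
#' @param p an [op_params] object.
#' @param n Hill steepness (defaults to `p$n`).
#' @return Fat mass(es) with logical attribute `"diminished"` marking
#'   negative entries.
#' @export
fat_line <- function(L, p, n = p$n) {
  stopifnot(inherits(p, "op_params"))
  if (any(L < 0)) stop("leptin L must be non-negative")
  if (is.infinite(n)) {
    hi <- (p$aF * p$umax - p$gammaE) / p$gammaF
    F <- ifelse(L <= p$KL, hi, -p$gammaE / p$gammaF)
  } else {
    F <- (p$aF / p$gammaF) * p$umax / (1 + hill_pow(L / p$KL, n)) -
      p$gammaE / p$gammaF
  }
  attr(F, "diminished") <- F < 0
  F
}

#' Operating point: intersection of the diet and appetite lines
#'
#' The steady state of the whole feedback system.  In the
#' infinite-steepness limit the solution is closed-form in two regimes:
#' \describe{
#'   \item{above-critical (`KL <= Kcrit`)}{`Fst` is the positive root of
#'     `gammaF F^2 + gammaE F - aF KL gammaL / aL = 0`,
#'     `ust = KL gammaL / (aL Fst)` and `Lst = KL` exactly.}
#'   \item{satiety-capped (`KL > Kcrit`)}{intake pins at the ceiling:
#'     `ust = umax`, `Fst = (aF umax - gammaE)/gammaF`,
#'     `Lst = (aL/gammaL) Fst umax`.}
#' }
#' For finite `n` the intersection of [diet_line_intake()] and
#' [appetite_intake()] is found numerically.  Unless `check = FALSE`, the
#' result is always cross-validated against the independent bisection
#' oracle [operating_point_numeric()] to relative `1e-8`.
#'
#' The boundary `KL = Kcrit` is assigned to the above-critical regime (the
#' two closed forms coincide there).
#'
#' @param p an [op_params] object.
#' @param n Hill steepness (defaults to `p$n`).
#' @param check cross-validate against the numeric oracle (default `TRUE`).
#' @return An object of class `"op_point"`: list with `Fst`, `ust`, `Lst`,
#'   `Fc`, `Kcrit`, `regime` (`"above-critical"` or `"satiety-capped"`),
#'   `n`, and the parameters used.
#' @examples
#' operating_point(op_params())
#' operating_point(op_params(KL = 5.4))  # satiety-capped: ust = umax
#' @export
operating_point <- function(p, n = p$n, check = TRUE) {
  stopifnot(inherits(p, "op_params"))
  Kc <- kcrit(p)
  Fc <- critical_fat(p)
  if (is.infinite(n)) {
    if (p$KL <= Kc) {
      disc <- p$gammaE^2 + 4 * p$gammaF * p$aF * p$KL * p$gammaL / p$aL
      Fst <- (-p$gammaE + sqrt(disc)) / (2 * p$gammaF)
      ust <- p$KL * p$gammaL / (p$aL * Fst)
      Lst <- p$KL
      regime <- "above-critical"
    } else {
      ust <- p$umax
      Fst <- (p$aF * p$umax - p$gammaE) / p$gammaF
      Lst <- (p$aL / p$gammaL) * Fst * p$umax
      regime <- "satiety-capped"
    }
  } else {
    sol <- operating_point_numeric(p, n)
    Fst <- sol$Fst; ust <- sol$ust; Lst <- sol$Lst
    regime <- if (Fst > Fc) "above-critical" else "satiety-capped"
  }
  if (Fst <= 0)
    stop("no positive-fat intersection of the diet and appetite lines")
  if (check) {
    num <- operating_point_numeric(p, n)
    if (abs(num$Fst - Fst) > 1e-8 * abs(Fst) ||
        abs(num$ust - ust) > 1e-8 * abs(ust))
      stop("closed-form operating point disagrees with numeric ",
           "intersection oracle: F ", Fst, " vs ", num$Fst,
           ", u ", ust, " vs ", num$ust)
  }
  structure(list(Fst = Fst, ust = ust, Lst = Lst, Fc = Fc, Kcrit = Kc,
                 regime = regime, n = n, params = p),
            class = "op_point")
}

#' Numeric-intersection oracle for the operating point
#'
#' Independent of the closed forms: brackets the root of
#' `diet_line_intake(F) - appetite_intake(F)` on
#' `(0, (aF umax - gammaE)/gammaF]` and bisects.  The diet line rises and
#' the appetite line falls, so the intersection is unique when it exists.
#'
#' @inheritParams operating_point
#' @param tol relative bisection tolerance.
#' @return List with `Fst`, `ust`, `Lst`.
#' @export
operating_point_numeric <- function(p, n = p$n, tol = 1e-12) {
  stopifnot(inherits(p, "op_params"))
  if (p$aF * p$umax <= p$gammaE)
    stop("no positive intersection: even maximal intake cannot cover basal ",
         "energy costs (aF*umax <= gammaE)")
  h <- function(F) diet_line_intake(F, p) - appetite_intake(F, p, n = n)
  F_hi <- (p$aF * p$umax - p$gammaE) / p$gammaF * (1 + 1e-9)
  lo <- 1e-12 * F_hi
  if (h(lo) >= 0)
    stop("no positive intersection: diet line already above the appetite ",
         "line at F -> 0 (is aF*umax > gammaE?)")
  r <- stats::uniroot(h, c(lo, F_hi), tol = tol * F_hi)
  Fst <- r$root
  ust <- appetite_intake(Fst, p, n = n)
  list(Fst = Fst, ust = ust, Lst = leptin_qss(Fst, ust, p))
}

#' @export
print.op_point <- function(x, digits = 6, ...) {
  cat("Operating point (", x$regime, " regime, n = ",
      if (is.infinite(x$n)) "infinite" else x$n, ")\n", sep = "")
  cat("  fat    Fst =", signif(x$Fst, digits), "\n")
  cat("  intake ust =", signif(x$ust, digits), "\n")
  cat("  leptin Lst =", signif(x$Lst, digits), "\n")
  cat("  critical fat Fc =", signif(x$Fc, digits),
      " Kcrit =", signif(x$Kcrit, digits), "\n")
  invisible(x)
}

#' @export
as.data.frame.op_point <- function(x, ...) {
  data.frame(Fst = x$Fst, ust = x$ust, Lst = x$Lst, Fc = x$Fc,
             Kcrit = x$Kcrit, regime = x$regime,
             n = if (is.infinite(x$n)) Inf else x$n)
}

#' Phase-portrait plot of the diet and appetite lines
#'
#' @param x an `op_point` object.
#' @param F_range fat range for the curves.
#' @param ... passed to [graphics::plot()].
#' @export
plot.op_point <- function(x, F_range = c(1e-3, 2 * x$Fst), ...) {
  p <- x$params
  F <- seq(F_range[1], F_range[2], length.out = 400)
  diet <- diet_line_intake(F, p)
  app <- appetite_intake(F, p, n = x$n)
  graphics::plot(F, diet, type = "l", col = "darkgreen",
                 xlab = "fat mass F", ylab = "food intake u",
                 ylim = range(0, diet, app), ...)
  graphics::lines(F, app, col = "darkorange")
  graphics::points(x$Fst, x$ust, pch = 19)
  graphics::legend("topright", legend = c("diet line", "appetite line",
                                          "operating point"),
                   col = c("darkgreen", "darkorange", "black"),
                   lty = c(1, 1, NA), pch = c(NA, NA, 19), bty = "n")
  invisible(x)
}
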