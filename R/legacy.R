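# Diet and appetite lines derived from two earlier leptin-based models of
# body-weight regulation, for structural comparison with the
# operating-point model.
#
# Parameter VALUES shipped here are representative synthetic sets chosen to
# exercise the structural properties (rising diet curve, falling appetite
# curve, a unique intersection); they are not the calibrated values of the
# original publications.  Both constructors accept user overrides so
# calibrated values can be supplied.

#' Parameters for the brain-leptin-transport model (Tam-type)
#'
#' A four-equation model in which plasma leptin (production `alphaL` per
#' unit fat, clearance `gammaL_t`) enters the brain through a saturable
#' carrier (`k1`, `k2`) plus linear diffusion (`k3`); brain leptin reduces
#' intake from its maximum `k4` with half-effect `k5`, and amplifies
#' energy expenditure (rate `k6` per unit body mass, amplification `k7`,
#' half-effect `k8`).  `rho_food` is the metabolizable energy density of
#' food, `rho_F` the energy density of fat, and fat-free mass `FFM` is
#' held constant.
#'
#' The default values are a synthetic representative set (see the package
#' vignette); override any subset via `...`.
#'
#' @param ... named overrides of the defaults.
#' @return Object of class `"tam_params"`.
#' @export
tam_params <- function(...) {
  p <- list(alphaL = 1, gammaL_t = 1, k1 = 1, k2 = 1, k3 = 0.1,
            k4 = 2, k5 = 1, k6 = 0.01, k7 = 0.5, k8 = 1,
            rho_food = 1, rho_F = 1, FFM = 4)
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0L)
    stop("unknown Tam-model parameter(s): ", paste(unknown, collapse = ", "))
  p <- utils::modifyList(p, over)
  if (any(unlist(p) <= 0)) stop("all Tam-model parameters must be positive")
  structure(p, class = "tam_params")
}

# Brain leptin at fat F under plasma quasi-steady state.
tam_brain_leptin <- function(F, tp) {
  Lp <- tp$alphaL * F / tp$gammaL_t
  Lp * tp$k1 / (Lp + tp$k2) + Lp * tp$k3
}

#' Diet and appetite curves of the brain-leptin-transport model
#'
#' Under plasma-leptin quasi-steady state, the diet curve is the intake
#' balancing leptin-amplified energy expenditure at fixed fat, and the
#' appetite curve is the brain-leptin-suppressed intake at a given fat.
#' The diet curve is nonlinear but approaches linear limits at very low fat
#' (no leptin amplification, slope `k6/rho_food`) and very high fat
#' (full amplification, slope `k6 (1 + k7)/rho_food`); both limits are
#' exposed via `tam_diet_limits()`.
#'
#' @param F_grid positive fat grid.
#' @param tp a [tam_params()] object.
#' @return Data frame with columns `F`, `u_diet`, `u_appetite`.
#' @export
tam_lines <- function(F_grid, tp = tam_params()) {
  stopifnot(inherits(tp, "tam_params"))
  if (any(F_grid <= 0)) stop("fat grid must be positive")
  Lb <- tam_brain_leptin(F_grid, tp)
  BM <- F_grid + tp$FFM
  u_diet <- BM * tp$k6 * (1 + Lb * tp$k7 / (Lb + tp$k8)) / tp$rho_food
  u_app <- tp$k4 * (1 - Lb / (Lb + tp$k5))
  data.frame(F = F_grid, u_diet = u_diet, u_appetite = u_app)
}

#' @rdname tam_lines
#' @param F fat value(s).
#' @return `tam_diet_limits()`: data frame with the low-fat and high-fat
#'   linear limits of the diet curve.
#' @export
tam_diet_limits <- function(F, tp = tam_params()) {
  data.frame(F = F,
             low = tp$k6 * (F + tp$FFM) / tp$rho_food,
             high = tp$k6 * (F + tp$FFM) * (1 + tp$k7) / tp$rho_food)
}

#' Parameters for the body-composition leptin-resistance model
#' (Jacquier-type)
#'
#' A three-equation model tracking fat mass (caloric density `rho_F`),
#' fat-free mass through the body-composition function
#' `Omega = gammaOmega (1 + alpha exp(kappa F))` with integration constant
#' `C`, energy expenditure (rate `eta`, basal `xi`), food caloric density
#' `cal_density`, plasma leptin (production `gammaL_j`, degradation
#' `deltaL`), a Hill leptin-receptor response (maximum `phiR`, half-point
#' `theta`, exponent `n_h`) with receptor density held fixed, and intake
#' production/decay `gamma_u`, `delta_u`.
#'
#' `C` is computed from a user-supplied reference state (`F_ref`,
#' `FFM_ref`), defaulting to fat 10 and fat-free mass 40 model units.
#' Default values are a synthetic representative set.
#'
#' @param ... named overrides of the defaults (including `F_ref`,
#'   `FFM_ref`).
#' @return Object of class `"jacquier_params"` (with the derived `C`).
#' @export
jacquier_params <- function(...) {
  p <- list(rho_FFM = 1.8, rho_F = 9.4, gammaOmega = 0.5, alpha = 0.3,
            kappa = 0.05, eta = 0.03, xi = 5, cal_density = 3.5,
            gammaL_j = 1, deltaL = 1, phiR = 2, theta = 10, n_h = 2,
            gamma_u = 6, delta_u = 1, F_ref = 10, FFM_ref = 40)
  over <- list(...)
  unknown <- setdiff(names(over), c(names(p), "C"))
  if (length(unknown) > 0L)
    stop("unknown Jacquier-model parameter(s): ",
         paste(unknown, collapse = ", "))
  p <- utils::modifyList(p, over)
  if (any(unlist(p[setdiff(names(p), c("F_ref", "FFM_ref"))]) <= 0))
    stop("all Jacquier-model rate parameters must be positive")
  if (is.null(over$C)) {
    p$C <- p$FFM_ref -
      p$gammaOmega * (p$kappa * p$F_ref + p$alpha * exp(p$kappa * p$F_ref)) /
        p$kappa
  } else {
    p$C <- over$C
  }
  structure(p, class = "jacquier_params")
}

#' Diet and appetite curves of the body-composition model
#'
#' The diet curve is the intake whose caloric content balances energy
#' expenditure at fat `F` (with fat-free mass tied to fat through the
#' body-composition function); the appetite curve is steady-state intake
#' under the leptin-receptor Hill response at quasi-steady plasma leptin.
#'
#' @param F_grid positive fat grid.
#' @param jp a [jacquier_params()] object.
#' @return Data frame with columns `F`, `u_diet`, `u_appetite`.
#' @export
jacquier_lines <- function(F_grid, jp = jacquier_params()) {
  stopifnot(inherits(jp, "jacquier_params"))
  if (any(F_grid <= 0)) stop("fat grid must be positive")
  u_diet <- jp$eta * (jp$gammaOmega * jp$rho_FFM * jp$alpha *
                        exp(jp$kappa * F_grid) +
                      jp$kappa * (jp$C * jp$rho_FFM +
                                  F_grid * jp$gammaOmega * jp$rho_FFM +
                                  F_grid * jp$rho_F + jp$xi)) /
    (jp$cal_density * jp$kappa)
  L <- jp$gammaL_j * F_grid / jp$deltaL
  num <- L^jp$n_h
  u_app <- jp$gamma_u * (num + jp$theta^jp$n_h) /
    (jp$delta_u * (num * (1 + jp$phiR) + jp$theta^jp$n_h))
  data.frame(F = F_grid, u_diet = u_diet, u_appetite = u_app)
}

#' Operating point of a model's diet/appetite curve pair
#'
#' Locates the intersection of the two curves by sign-change scan on the
#' grid followed by bracketed root-finding on the curve difference.  For
#' the operating-point model this equals [operating_point()].
#'
#' @param model `"operating-point"`, `"tam"` or `"jacquier"`.
#' @param params the matching parameter object ([op_params()],
#'   [tam_params()] or [jacquier_params()]).
#' @param F_grid fat grid on which to scan for an intersection (ignored for
#'   the operating-point model).
#' @param n Hill steepness for the operating-point model.
#' @return List with `F` and `u` at the intersection.
#' @export
compare_operating_points <- function(model = c("operating-point", "tam",
                                               "jacquier"),
                                     params,
                                     F_grid = seq(0.01, 50, length.out = 2000),
                                     n = NULL) {
  model <- match.arg(model)
  if (model == "operating-point") {
    stopifnot(inherits(params, "op_params"))
    st <- operating_point(params, n = if (is.null(n)) params$n else n)
    return(list(F = st$Fst, u = st$ust))
  }
  curves <- if (model == "tam") tam_lines(F_grid, params)
    else jacquier_lines(F_grid, params)
  d <- curves$u_diet - curves$u_appetite
  sgn <- sign(d)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flips) == 0L)
    stop("no intersection: the curve difference does not change sign on ",
         "the supplied fat grid")
  f <- function(F) {
    cv <- if (model == "tam") tam_lines(F, params) else jacquier_lines(F, params)
    cv$u_diet - cv$u_appetite
  }
  i <- flips[1]
  r <- stats::uniroot(f, c(F_grid[i], F_grid[i + 1]), tol = 1e-12)
  cv <- if (model == "tam") tam_lines(r$root, params)
    else jacquier_lines(r$root, params)
  list(F = r$root, u = cv$u_diet, n_crossings = length(flips))
}

#' Export model curves as CSV
#'
#' Columns `F, u_diet, u_appetite`, one file per model.
#'
#' @param curves output of [tam_lines()], [jacquier_lines()] or an
#'   equivalent data frame.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_model_curves <- function(curves, path) {
  stopifnot(all(c("F", "u_diet", "u_appetite") %in% names(curves)))
  utils::write.csv(curves, path, row.names = FALSE)
  invisible(path)
}
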