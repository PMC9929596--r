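# Local log-sensitivities of the steady state to each parameter, as a
# function of Hill steepness, via the implicit function theorem on the
# characteristic steady-state equations.

op_param_names <- c("aF", "gammaF", "gammaE", "aL", "gammaL", "KL", "umax")

#' Characteristic steady-state residual for one variable
#'
#' For each target variable the other two are eliminated algebraically,
#' leaving a single characteristic equation whose root is that variable's
#' steady state:
#' \describe{
#'   \item{F}{diet-line intake minus Hill intake at the leptin-line leptin:
#'     `(gammaF F + gammaE)/aF - umax/(1 + (leptin_line(F)/KL)^n)`.}
#'   \item{L}{`L - leptin_line(fat_line(L))`, with the finite-`n` fat line.}
#'   \item{u}{`u (1 + (L(u)/KL)^n) - umax` with `L(u)` evaluated on the
#'     diet line.}
#' }
#'
#' @param x positive trial value of the target variable.
#' @param target `"F"`, `"L"` or `"u"`.
#' @param p an [op_params] object.
#' @param n finite Hill steepness.
#' @return Residual value; zero at the steady state, changing sign across it.
#' @export
steady_state_residual <- function(x, target = c("F", "L", "u"), p, n) {
  target <- match.arg(target)
  stopifnot(inherits(p, "op_params"), is.finite(n))
  switch(target,
    F = {
      L <- (p$aL / (p$gammaL * p$aF)) * x * (p$gammaF * x + p$gammaE)
      (p$gammaF * x + p$gammaE) / p$aF -
        p$umax / (1 + hill_pow(L / p$KL, n))
    },
    L = {
      F <- (p$aF / p$gammaF) * p$umax / (1 + hill_pow(x / p$KL, n)) -
        p$gammaE / p$gammaF
      x - (p$aL / (p$gammaL * p$aF)) * F * (p$gammaF * F + p$gammaE)
    },
    u = {
      F <- (p$aF * x - p$gammaE) / p$gammaF
      L <- (p$aL / p$gammaL) * F * x
      x * (1 + hill_pow(L / p$KL, n)) - p$umax
    })
}

# Root of the characteristic residual, bracketed on the physical range.
solve_steady_state <- function(target, p, n, tol = 1e-13) {
  Fsat <- (p$aF * p$umax - p$gammaE) / p$gammaF
  g <- function(x) steady_state_residual(x, target, p, n)
  br <- switch(target,
    F = c(1e-12 * Fsat, Fsat * (1 + 1e-9)),
    L = c(1e-12, (p$aL / p$gammaL) * Fsat * p$umax * (1 + 1e-9)),
    # upper end is umax itself: the residual there is umax*(L/KL)^n >= 0,
    # and in the satiety-capped regime the root sits within machine
    # precision of umax
    u = c(p$gammaE / p$aF * (1 + 1e-12), p$umax))
  if (g(br[1]) * g(br[2]) > 0)
    stop("could not bracket the ", target, "-steady state on (",
         br[1], ", ", br[2], ")")
  stats::uniroot(g, br, tol = tol * br[2])$root
}

#' Log-sensitivity of a steady-state variable to a parameter
#'
#' The implicit-function-theorem value
#' `dlog(X*)/dlog(p) = -(dG/dp)/(dG/dX) * (p/X*)` evaluated at the root of
#' the characteristic residual `G`, with both partials obtained by central
#' differences of `G` (relative step `1e-6`).  Setting `fd_check = TRUE`
#' additionally re-solves the steady state at `p*(1±1e-4)` and returns the
#' finite-difference log-slope for cross-validation.
#'
#' @param target `"F"`, `"L"` or `"u"`.
#' @param param one of the seven rate parameters.
#' @param p an [op_params] object.
#' @param n finite Hill steepness.
#' @param fd_check also compute the finite-difference cross-check.
#' @return The log-sensitivity (with attribute `"fd"` when requested).
#' @examples
#' p <- op_params()
#' log_sensitivity("L", "KL", p, n = 100)   # ~1: steady-state leptin tracks KL
#' @export
log_sensitivity <- function(target, param, p, n, fd_check = FALSE) {
  stopifnot(param %in% op_param_names)
  x0 <- solve_steady_state(target, p, n)
  g <- function(x, q) steady_state_residual(x, target, q, n)
  hx <- 1e-6 * x0
  dG_dx <- (g(x0 + hx, p) - g(x0 - hx, p)) / (2 * hx)
  if (abs(dG_dx) < 1e-12)
    stop("singular point: characteristic residual is flat in ", target)
  p_mod <- function(val) {
    q <- as.list(p); q[[param]] <- val
    structure(q, class = "op_params")   # skip revalidation inside tight loop
  }
  hp <- 1e-6 * p[[param]]
  dG_dp <- (g(x0, p_mod(p[[param]] + hp)) -
            g(x0, p_mod(p[[param]] - hp))) / (2 * hp)
  val <- -(dG_dp / dG_dx) * (p[[param]] / x0)
  if (fd_check) {
    hrel <- 1e-4
    xp <- solve_steady_state(target, p_mod(p[[param]] * (1 + hrel)), n)
    xm <- solve_steady_state(target, p_mod(p[[param]] * (1 - hrel)), n)
    fd <- (log(xp) - log(xm)) / (log(1 + hrel) - log(1 - hrel))
    attr(val, "fd") <- fd
  }
  val
}

#' Sensitivity profile over steepness and parameters in two regimes
#'
#' Sweeps the log-sensitivity of all three steady-state variables to every
#' parameter over a grid of Hill steepness values, in two regions of
#' parameter space: the baseline set (operating point above the critical
#' fat level) and a high-resistance set in which `KL` is replaced by
#' `2*Kcrit` of the baseline, placing the operating point in the
#' satiety-capped regime.  Each value carries its finite-difference
#' cross-check.
#'
#' @param p baseline [op_params].
#' @param n_grid finite steepness values (default
#'   `c(2, 4, 7, 10, 20, 50, 100)`).
#' @param regimes subset of `c("baseline", "high-resistance")`.
#' @return Data frame with columns `target`, `parameter`, `n`, `regime`,
#'   `value`, `fd_check`.
#' @export
sensitivity_profile <- function(p, n_grid = c(2, 4, 7, 10, 20, 50, 100),
                                regimes = c("baseline", "high-resistance")) {
  stopifnot(inherits(p, "op_params"), all(is.finite(n_grid)))
  regimes <- match.arg(regimes, several.ok = TRUE)
  psets <- list()
  if ("baseline" %in% regimes) psets[["baseline"]] <- p
  if ("high-resistance" %in% regimes) {
    q <- as.list(p); q$KL <- 2 * kcrit(p)
    psets[["high-resistance"]] <- validate_op_params(q)
  }
  rows <- list()
  for (reg in names(psets)) {
    pr <- psets[[reg]]
    for (n in n_grid) {
      for (target in c("F", "L", "u")) {
        for (param in op_param_names) {
          v <- log_sensitivity(target, param, pr, n, fd_check = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(
            target = target, parameter = param, n = n, regime = reg,
            value = as.numeric(v), fd_check = attr(v, "fd"))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Write a sensitivity profile as tidy CSV
#'
#' Columns `target, parameter, n, regime, value, fd_check`.
#'
#' @param profile output of [sensitivity_profile()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_sensitivity_profile <- function(profile, path) {
  utils::write.csv(profile, path, row.names = FALSE)
  invisible(path)
}
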