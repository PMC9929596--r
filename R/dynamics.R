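# Time-domain simulation of the fat-leptin ODE system and classification of
# transient intake dynamics.

#' Simulation configuration
#'
#' @param n_dynamics finite Hill steepness used in simulation (default 100,
#'   steep enough to track the infinite-steepness analysis while keeping the
#'   right-hand side smooth).
#' @param t_end horizon in model time units (default 50).
#' @param dt_out output grid spacing (default 1).
#' @param rel_tol,abs_tol integrator tolerances.
#' @param leptin_mode `"dynamic"` integrates leptin explicitly;
#'   `"quasi-steady"` eliminates it algebraically (leptin clearance treated
#'   as instantaneous).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_dynamics = 100, t_end = 50, dt_out = 1,
                       rel_tol = 1e-8, abs_tol = 1e-10,
                       leptin_mode = c("dynamic", "quasi-steady")) {
  leptin_mode <- match.arg(leptin_mode)
  stopifnot(is.finite(n_dynamics), n_dynamics >= 1, t_end > 0,
            dt_out > 0, rel_tol > 0, abs_tol > 0)
  structure(list(n_dynamics = n_dynamics, t_end = t_end, dt_out = dt_out,
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 leptin_mode = leptin_mode),
            class = "sim_config")
}

#' Simulate fat, leptin and intake dynamics
#'
#' Integrates
#' `dF/dt = aF*u - gammaE - gammaF*F` and `dL/dt = aL*F*u - gammaL*L`
#' with the leptin-satiety intake rule
#' `u = umax / (1 + (L/KL)^n_dynamics)`.  Unless an explicit `L` is given
#' in `init`, leptin starts at its quasi-steady level for the initial
#' `(F, u)` pair — the state maintained by the feeding history that
#' produced the initial condition.  In quasi-steady mode leptin is
#' eliminated algebraically, so intake is always exactly on the appetite
#' line.
#'
#' @param p an [op_params] object (its `n` is ignored; the simulation
#'   steepness comes from `cfg`).
#' @param init list with fat `F` and intake `u` (and optionally leptin `L`)
#'   describing the state at time 0.
#' @param cfg a [sim_config()].
#' @return An object of class `"op_trajectory"`: a data frame with columns
#'   `time`, `F`, `L`, `u`, carrying the parameters, configuration and
#'   initial condition as attributes.
#' @examples
#' p <- op_params()
#' init <- refeeding_initial_condition(p, factor = 0.7)
#' traj <- simulate_dynamics(p, init, sim_config(t_end = 50))
#' detect_transient(simulate_dynamics(p, init, sim_config(t_end = 400)))
#' @export
simulate_dynamics <- function(p, init, cfg = sim_config()) {
  stopifnot(inherits(p, "op_params"), inherits(cfg, "sim_config"))
  if (is.null(init$F) || is.null(init$u))
    stop("init must provide fat 'F' and intake 'u'")
  F0 <- init$F
  u0 <- init$u
  if (F0 < 0) stop("initial fat must be non-negative")
  # u0 may exceed umax: a forced (tube-fed) intake history is a valid state
  # to recover from; only the ad-libitum trajectory itself is capped.
  if (u0 < 0) stop("initial intake must be non-negative")
  L0 <- if (!is.null(init$L)) init$L else leptin_qss(F0, u0, p)
  times <- seq(0, cfg$t_end, by = cfg$dt_out)
  n <- cfg$n_dynamics

  if (cfg$leptin_mode == "dynamic") {
    rhs <- function(t, y, parms) {
      u <- p$umax / (1 + hill_pow(y[2] / p$KL, n))
      list(c(p$aF * u - p$gammaE - p$gammaF * y[1],
             p$aL * y[1] * u - p$gammaL * y[2]))
    }
    sol <- deSolve::ode(y = c(F = F0, L = L0), times = times, func = rhs,
                        parms = NULL, rtol = cfg$rel_tol, atol = cfg$abs_tol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integrator failed; diagnostics: ",
           paste(utils::capture.output(deSolve::diagnostics(sol)),
                 collapse = "\n"))
    out <- as.data.frame(sol)
    out$u <- p$umax / (1 + hill_pow(out$L / p$KL, n))
  } else {
    rhs <- function(t, y, parms) {
      u <- appetite_intake(max(y[1], 0), p, n = n)
      list(c(p$aF * u - p$gammaE - p$gammaF * y[1]))
    }
    sol <- deSolve::ode(y = c(F = F0), times = times, func = rhs,
                        parms = NULL, rtol = cfg$rel_tol, atol = cfg$abs_tol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integrator failed; diagnostics: ",
           paste(utils::capture.output(deSolve::diagnostics(sol)),
                 collapse = "\n"))
    out <- as.data.frame(sol)
    out$u <- appetite_intake(pmax(out$F, 0), p, n = n)
    out$L <- leptin_qss(pmax(out$F, 0), out$u, p)
    out <- out[, c("time", "F", "L", "u")]
  }
  if (any(out$F < 0)) {
    warning("fat trajectory dipped below zero; clipped to 0")
    out$F <- pmax(out$F, 0)
  }
  structure(out[, c("time", "F", "L", "u")],
            params = p, config = cfg,
            init = list(F = F0, u = u0, L = L0),
            class = c("op_trajectory", "data.frame"))
}

#' Initial condition after a period of controlled over/under-feeding
#'
#' Following the recovery protocol, the pre-recovery state is built by
#' multiplying the steady-state intake by `factor` and reading fat off the
#' diet line: `u0 = factor * ust`, `F0 = (aF*u0 - gammaE)/gammaF`.
#'
#' @param p an [op_params] object.
#' @param factor positive multiple of the steady-state intake (1.4 models
#'   overfeeding, 0.7 underfeeding).
#' @return List with `F` and `u` suitable for [simulate_dynamics()].
#' @export
refeeding_initial_condition <- function(p, factor) {
  stopifnot(inherits(p, "op_params"))
  if (factor <= 0) stop("feeding factor must be positive")
  st <- operating_point(p, n = Inf, check = FALSE)
  u0 <- factor * st$ust
  F0 <- diet_line_fat(u0, p)
  if (F0 < 0)
    stop("controlled intake factor ", factor, " drives steady-state fat ",
         "negative (starvation regime outside the model)")
  list(F = F0, u = u0)
}

#' Classify the intake transient of a trajectory
#'
#' An intervention that starts off the (post-intervention) appetite line
#' produces a fast excursion of intake beyond its eventual steady state: an
#' overshoot when approaching from below, an undershoot from above.
#' Interventions starting on the appetite line relax monotonically.
#'
#' The classification compares the trajectory's intake extrema with its
#' final value, using the pre-perturbation intake (stored in the
#' trajectory's initial condition) to orient the comparison.  A trajectory
#' whose intake still changes by more than `1e-4` (relative) over the last
#' 10% of the horizon is reported `"inconclusive"` rather than guessed.
#'
#' @param traj an `op_trajectory` from [simulate_dynamics()].
#' @param eps_rel excursion threshold relative to the final intake
#'   (default 0.01, well below the ~80% overshoots the model produces and
#'   well above integrator noise).
#' @return One of `"overshoot"`, `"undershoot"`, `"monotone"`,
#'   `"inconclusive"`.
#' @export
detect_transient <- function(traj, eps_rel = 0.01) {
  stopifnot(inherits(traj, "op_trajectory"))
  u <- traj$u
  nt <- length(u)
  if (nt < 5) stop("trajectory too short to classify")
  tail_idx <- which(traj$time >= 0.9 * max(traj$time))
  settle <- diff(range(u[tail_idx])) / max(abs(u[nt]), .Machine$double.eps)
  if (settle > 1e-4) return("inconclusive")
  u_final <- u[nt]
  u0 <- attr(traj, "init")$u
  margin <- eps_rel * abs(u_final)
  over <- max(u[-nt]) > u_final + margin
  under <- min(u[-nt]) < u_final - margin
  if (u0 < u_final - margin) {
    if (over) "overshoot" else "monotone"
  } else if (u0 > u_final + margin) {
    if (under) "undershoot" else "monotone"
  } else {
    if (over) "overshoot" else if (under) "undershoot" else "monotone"
  }
}

#' Rescale leptin turnover without moving any steady state
#'
#' Multiplies `aL` and `gammaL` by the same factor, which leaves the
#' quasi-steady leptin level, both lines and the operating point exactly
#' unchanged while making leptin clearance faster.  Used to place the model
#' in its physiological regime, where leptin (half-life tens of minutes)
#' is much faster than both the daily output grid and fat dynamics.
#'
#' @param p an [op_params] object.
#' @param factor multiplicative speed-up of leptin turnover (default 25,
#'   roughly a 40-minute half-life when the output step is one day).
#' @return An [op_params] object.
#' @export
with_fast_leptin <- function(p, factor = 25) {
  stopifnot(inherits(p, "op_params"), factor > 0)
  q <- as.list(p)
  q$aL <- q$aL * factor
  q$gammaL <- q$gammaL * factor
  validate_op_params(q)
}

#' @export
print.op_trajectory <- function(x, ...) {
  cat("Operating-point model trajectory:", nrow(x), "time points over",
      max(x$time), "time units\n")
  init <- attr(x, "init")
  cat("  init: F =", signif(init$F, 5), " u =", signif(init$u, 5), "\n")
  cat("  final: F =", signif(x$F[nrow(x)], 5),
      " u =", signif(x$u[nrow(x)], 5), "\n")
  invisible(x)
}

#' @param x an `op_trajectory`.
#' @param ... passed on to [graphics::matplot()].
#' @rdname simulate_dynamics
#' @export
plot.op_trajectory <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$F, x$u), type = "l", lty = 1,
                    col = c("brown", "steelblue"),
                    xlab = "time", ylab = "fat / intake", ...)
  graphics::legend("topright", legend = c("fat F", "intake u"),
                   col = c("brown", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}

#' Read/write trajectories as CSV
#'
#' Columns `time, F, L, u`; deterministic, seedless.
#'
#' @param traj an `op_trajectory`.
#' @param path CSV path.
#' @return `path` invisibly (writer); a data frame (reader).
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("time", "F", "L", "u")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!nzchar(path) || !file.exists(path)) stop("no such file: '", path, "'")
  df <- utils::read.csv(path)
  need <- c("time", "F", "L", "u")
  if (!identical(names(df)[seq_along(need)], need))
    stop("trajectory CSV must have columns exactly: ",
         paste(need, collapse = ", "))
  df
}
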