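# Synthetic-data generators: controlled-feeding time series emulating
# tube-feeding/recovery experiments on growing rats, and leptin-fat
# population scatters with inter-individual parameter variation.

#' Design of a synthetic controlled-feeding experiment
#'
#' Emulates the tube-feeding protocol: groups fed a fixed fraction of the
#' control intake for a controlled phase, then returned to ad-libitum
#' feeding, on top of a shared multiplicative growth trend with lognormal
#' measurement noise.
#'
#' @param fractions positive feeding fractions, one tube-fed group each
#'   (default `c(0.4, 1, 1.6)`, i.e. 40/100/160% of control).
#' @param controlled_days length of the controlled phase (default 20).
#' @param recovery_days length of the ad-libitum recovery (default 30).
#' @param growth_rate shared multiplicative growth trend per day on fat and
#'   weight (default 1.005, about 0.5%/day as in young growing rats); it
#'   cancels under control normalization.
#' @param noise_sigma lognormal sigma of measurement noise on intake and
#'   fat (default 0.05).
#' @param seed integer seed; recorded in the output.
#' @param fat_measure_days optional vector of days on which fat is actually
#'   measured (other days get `NA`), mimicking sparse body-composition
#'   sampling; `NULL` (default) measures fat daily.
#' @param lean_mass baseline fat-free mass used to emit the weight column.
#' @param hill_n Hill steepness of the simulated ad-libitum appetite line
#'   (default 7.1, the steepness estimated from rat refeeding data; the
#'   finite curvature it puts near the satiety ceiling is what makes
#'   `umax` and `n` estimable from this protocol).
#' @return Object of class `"feeding_design"`.
#' @export
feeding_design <- function(fractions = c(0.4, 1, 1.6), controlled_days = 20,
                           recovery_days = 30, growth_rate = 1.005,
                           noise_sigma = 0.05, seed = 1,
                           fat_measure_days = NULL, lean_mass = 4,
                           hill_n = 7.1) {
  stopifnot(all(fractions > 0), controlled_days >= 1, recovery_days >= 1,
            controlled_days == round(controlled_days),
            recovery_days == round(recovery_days),
            growth_rate > 0, noise_sigma >= 0, lean_mass > 0,
            is.finite(hill_n), hill_n >= 1)
  structure(list(fractions = fractions, controlled_days = controlled_days,
                 recovery_days = recovery_days, growth_rate = growth_rate,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 fat_measure_days = fat_measure_days, lean_mass = lean_mass,
                 hill_n = hill_n),
            class = "feeding_design")
}

# Deterministic model series for one group: clamped intake during the
# controlled phase (fat relaxes along dF/dt = aF*u - gammaE - gammaF*F),
# then ad-libitum recovery with intake on the steep appetite line
# (quasi-steady leptin: daily measurements cannot resolve the fast leptin
# transient, so intake sits on the appetite line each day).
group_series <- function(p, frac, d, st, n_dyn) {
  Tc <- d$controlled_days
  Tr <- d$recovery_days
  u_clamp <- frac * st$ust
  F_eq <- diet_line_fat(u_clamp, p)
  if (F_eq < 0) {
    warning("clamped intake fraction ", frac,
            " drives steady-state fat negative; truncating at ~0")
    F_eq <- 1e-6
  }
  days_c <- 0:Tc
  F_c <- F_eq + (st$Fst - F_eq) * exp(-p$gammaF * days_c)
  rec <- simulate_dynamics(
    p, list(F = F_c[length(F_c)], u = u_clamp),
    sim_config(n_dynamics = n_dyn, t_end = Tr, dt_out = 1,
               leptin_mode = "quasi-steady"))
  data.frame(day = c(days_c, Tc + rec$time[-1]),
             intake = c(rep(u_clamp, Tc + 1), rec$u[-1]),
             fat = c(F_c, rec$F[-1]))
}

#' Generate a synthetic controlled-feeding experiment
#'
#' Simulates one tube-fed group per feeding fraction (the fraction-1 group,
#' fed 100% of control intake, is the control — as in the emulated
#' protocol, so tube-feeding artefacts cancel under normalization):
#' clamped intake during the controlled phase, model-driven ad-libitum
#' intake during recovery
#' (steepness `hill_n`, quasi-steady leptin — daily sampling cannot resolve
#' the fast leptin transient), a shared multiplicative growth trend on fat
#' and weight, and lognormal noise on intake and fat.  The emitted
#' container uses the exact CSV schema consumed by the fitting pipeline.
#'
#' The zero-noise fold-change line parameters implied by the design (the
#' generator ground truth the pipeline estimates) are attached as attribute
#' `"truth"`.  Every recovery day lies exactly on the fold-change appetite
#' line, `c = (gammaL*KL/aL)/(Fst*ust)`, `umax = umax/ust`, `n = hill_n`.
#' The diet points are exactly affine in relative intake; their slope is
#' the asymptotic `a = (aF/gammaF)*(ust/Fst)` only once the controlled
#' phase is long enough for fat to reach steady state — at finite phase
#' length `Tc` the end-of-phase fat has relaxed only by
#' `1 - exp(-gammaF*Tc)` of the way, and the exact finite-phase slope and
#' intercept are reported as `a_phase`, `b_phase` (what an unbiased
#' pipeline estimates under the protocol).
#'
#' @param p an [op_params] object (study conditions).
#' @param d a [feeding_design()].
#' @return A [feeding_experiment()] whose `data` carries columns
#'   `group, day, intake, fat, weight`, with attributes `design`, `seed`
#'   and `truth`.
#' @export
generate_feeding_experiment <- function(p, d = feeding_design()) {
  stopifnot(inherits(p, "op_params"), inherits(d, "feeding_design"))
  set.seed(d$seed)
  n_dyn <- d$hill_n
  st <- operating_point(p, n = n_dyn, check = FALSE)
  Tc <- d$controlled_days
  if (!any(abs(d$fractions - 1) < 1e-12))
    stop("fractions must include 1: the 100%-fed group is the control")

  groups <- stats::setNames(
    lapply(d$fractions, function(fr) group_series(p, fr, d, st, n_dyn)),
    paste0("tube", round(100 * d$fractions)))

  noisy <- lapply(names(groups), function(g) {
    gd <- groups[[g]]
    trend <- d$growth_rate^gd$day
    ne <- function(n) exp(stats::rnorm(n, 0, d$noise_sigma))
    fat_true <- gd$fat * trend
    out <- data.frame(
      group = g, day = gd$day,
      intake = gd$intake * ne(nrow(gd)),
      fat = fat_true * ne(nrow(gd)),
      weight = (gd$fat + d$lean_mass) * trend * ne(nrow(gd)))
    if (!is.null(d$fat_measure_days))
      out$fat[!out$day %in% d$fat_measure_days] <- NA_real_
    out
  })
  dat <- do.call(rbind, noisy)

  # zero-noise fold-change truth: appetite line exact for any phase length;
  # diet line exact asymptotically (a, b) and at the finite phase (a_phase,
  # b_phase, where relax = 1 - exp(-gammaF*Tc) is the fraction of the fat
  # relaxation completed)
  relax <- 1 - exp(-p$gammaF * Tc)
  a_inf <- (p$aF / p$gammaF) * st$ust / st$Fst
  b_inf <- (p$gammaE / p$gammaF) / st$Fst
  truth <- list(a = a_inf, b = b_inf,
                c = (p$gammaL * p$KL / p$aL) / (st$Fst * st$ust),
                umax = p$umax / st$ust, n = n_dyn,
                a_phase = a_inf * relax,
                b_phase = b_inf * relax - (1 - relax))
  exp_out <- feeding_experiment(dat, control = "tube100",
                                controlled_window = c(0, Tc),
                                recovery_window = c(Tc + 1,
                                                    Tc + d$recovery_days))
  attr(exp_out, "design") <- d
  attr(exp_out, "seed") <- d$seed
  attr(exp_out, "truth") <- truth
  exp_out
}

#' Design of a synthetic leptin-fat population
#'
#' @param N number of individuals (default 70).
#' @param varied which parameter varies between individuals (default
#'   `"KL"`, leptin resistance — the parameter that spreads individuals
#'   along the quadratic leptin line in the leptin-sensitive regime).
#' @param sigma_var lognormal sigma of the inter-individual parameter
#'   variation (default 0.5, giving roughly a 2.5-fold 95% range of fat).
#' @param noise_sigma lognormal measurement noise on leptin (default 0.1).
#' @param seed integer seed.
#' @return Object of class `"population_design"`.
#' @export
population_design <- function(N = 70, varied = "KL", sigma_var = 0.5,
                              noise_sigma = 0.1, seed = 1) {
  stopifnot(N >= 5, sigma_var >= 0, noise_sigma >= 0)
  if (!varied %in% c("aF", "gammaF", "gammaE", "aL", "gammaL", "KL", "umax"))
    stop("unknown varied parameter: ", varied)
  structure(list(N = as.integer(N), varied = varied, sigma_var = sigma_var,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "population_design")
}

#' Generate a synthetic leptin-fat population scatter
#'
#' Draws the varied parameter per individual from a lognormal around its
#' preset value, solves each individual's operating point in the
#' infinite-steepness limit, records steady-state `(fat, leptin)` and adds
#' lognormal measurement noise to leptin.  When only appetite-line
#' parameters vary, every operating point sits exactly on the quadratic
#' leptin line `L = (aL/(gammaL aF)) F (gammaF F + gammaE)`, so the
#' zero-noise scatter traces that curve; varying diet-line parameters
#' scatters points orthogonally to it.  Individuals whose drawn parameters
#' admit no positive steady state are skipped, with the count reported.
#'
#' @param p an [op_params] object (population-typical values).
#' @param d a [population_design()].
#' @return Data frame with columns `fat`, `leptin` and attributes `design`,
#'   `n_skipped`, `truth` (`a_q = aL*gammaF/(gammaL*aF)`,
#'   `b_q = aL*gammaE/(gammaL*aF)`).
#' @export
generate_leptin_population <- function(p, d = population_design()) {
  stopifnot(inherits(p, "op_params"), inherits(d, "population_design"))
  set.seed(d$seed)
  draws <- p[[d$varied]] * exp(stats::rnorm(d$N, 0, d$sigma_var))
  pts <- lapply(draws, function(v) {
    q <- as.list(p); q[[d$varied]] <- v
    st <- tryCatch(operating_point(validate_op_params(q), n = Inf,
                                   check = FALSE),
                   error = function(e) NULL)
    if (is.null(st)) return(NULL)
    c(F = st$Fst, L = st$Lst)
  })
  skipped <- sum(vapply(pts, is.null, logical(1)))
  if (skipped > 0L)
    message(skipped, " individual(s) had no positive steady state; skipped")
  pts <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  out <- data.frame(fat = pts[, "F"],
                    leptin = pts[, "L"] *
                      exp(stats::rnorm(nrow(pts), 0, d$noise_sigma)))
  attr(out, "design") <- d
  attr(out, "n_skipped") <- skipped
  attr(out, "truth") <- list(
    a_q = p$aL * p$gammaF / (p$gammaL * p$aF),
    b_q = p$aL * p$gammaE / (p$gammaL * p$aF))
  out
}

#' Serialize a generator design as YAML (provenance record)
#'
#' @param design a [feeding_design()] or [population_design()].
#' @param path YAML path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "feeding_design") ||
              inherits(design, "population_design"))
  rec <- c(list(type = class(design)[1]),
           lapply(unclass(design), function(v) if (is.null(v)) NA else v))
  yaml::write_yaml(rec, path)
  invisible(path)
}
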