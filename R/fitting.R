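# Normalized phase-portrait pipeline for controlled-feeding experiments and
# the quadratic leptin-fat population fit.

#' Controlled-feeding experiment container
#'
#' Bundles per-group daily series (intake, fat, optionally weight) with the
#' experimental design: which group is the untreated control, which day
#' window was tube-fed (controlled) and which is ad-libitum recovery.
#'
#' @param data data frame with columns `group`, `day`, `intake`, `fat`
#'   (optionally `weight`).  `fat` may be `NA` on unmeasured days.
#' @param control label of the control group.
#' @param controlled_window length-2 numeric, first and last day of the
#'   controlled-feeding phase.
#' @param recovery_window length-2 numeric, first and last day of ad-libitum
#'   recovery; must start after the controlled window ends.
#' @return An object of class `"feeding_experiment"`.
#' @export
feeding_experiment <- function(data, control, controlled_window,
                               recovery_window) {
  need <- c("group", "day", "intake", "fat")
  if (!all(need %in% names(data)))
    stop("data must have columns: ", paste(need, collapse = ", "))
  if (!control %in% data$group)
    stop("control group '", control, "' not present in data")
  stopifnot(length(controlled_window) == 2L, length(recovery_window) == 2L)
  if (controlled_window[1] > controlled_window[2] ||
      recovery_window[1] > recovery_window[2] ||
      recovery_window[1] <= controlled_window[2])
    stop("phase windows must be ordered and disjoint: controlled before recovery")
  structure(list(data = data, control = control,
                 controlled_window = as.numeric(controlled_window),
                 recovery_window = as.numeric(recovery_window),
                 normalized = FALSE),
            class = "feeding_experiment")
}

#' @export
print.feeding_experiment <- function(x, ...) {
  cat("Controlled-feeding experiment",
      if (x$normalized) "(fold-change relative to control)" else "", "\n")
  cat("  groups:", paste(unique(x$data$group), collapse = ", "),
      "(control:", x$control, ")\n")
  cat("  controlled days", x$controlled_window[1], "-", x$controlled_window[2],
      "; recovery days", x$recovery_window[1], "-", x$recovery_window[2], "\n")
  invisible(x)
}

# Linearly interpolate one group's series onto an integer-day grid.
# Missing values inside a series are bridged; constant extrapolation fills
# the (at most one-day) grid edges.
interp_group <- function(df, grid) {
  out <- data.frame(day = grid)
  for (col in intersect(c("intake", "fat", "weight"), names(df))) {
    ok <- !is.na(df[[col]])
    if (sum(ok) < 2L) {
      out[[col]] <- rep(if (any(ok)) df[[col]][ok][1] else NA_real_,
                        length(grid))
    } else {
      out[[col]] <- stats::approx(df$day[ok], df[[col]][ok], xout = grid,
                                  rule = 2)$y
    }
  }
  out
}

#' Normalize a feeding experiment to its control group
#'
#' Growing animals gain weight throughout an experiment; expressing every
#' series as a fold-change relative to the interpolated control series
#' removes the shared growth trend (and corrects for shared protocol
#' artefacts such as tube-feeding aversion).  Every group is first linearly
#' interpolated onto a common integer-day grid, then divided element-wise
#' by the interpolated control; the control becomes identically 1.
#'
#' @param exp a [feeding_experiment()].
#' @return A `feeding_experiment` in fold-change form (`normalized = TRUE`).
#' @export
normalize_to_control <- function(exp) {
  stopifnot(inherits(exp, "feeding_experiment"))
  if (exp$normalized) return(exp)
  dat <- exp$data
  ctrl <- dat[dat$group == exp$control, ]
  ctrl_range <- range(ctrl$day)
  groups <- unique(dat$group)
  out <- lapply(groups, function(g) {
    gd <- dat[dat$group == g, ]
    grid <- seq(ceiling(min(gd$day)), floor(max(gd$day)))
    if (min(grid) < ctrl_range[1] || max(grid) > ctrl_range[2])
      stop("control series does not cover group '", g, "': needs days ",
           min(grid), "-", max(grid), " but control spans ",
           ctrl_range[1], "-", ctrl_range[2])
    gi <- interp_group(gd, grid)
    ci <- interp_group(ctrl, grid)
    for (col in setdiff(names(gi), "day")) gi[[col]] <- gi[[col]] / ci[[col]]
    gi$group <- g
    gi
  })
  out <- do.call(rbind, out)
  structure(list(data = out, control = exp$control,
                 controlled_window = exp$controlled_window,
                 recovery_window = exp$recovery_window,
                 normalized = TRUE),
            class = "feeding_experiment")
}

#' Extract diet- and appetite-line points from a normalized experiment
#'
#' Diet points (one per controlled group, the control included and mapping
#' to (1, 1)): the phase-mean relative intake during controlled feeding —
#' tube-fed intake is constant, so the mean is the delivered fraction —
#' paired with the relative fat on the final controlled day, i.e. the fat
#' that intake sustains.  Appetite points (one per recovery day, pooled
#' over groups): relative fat paired with that day's relative ad-libitum
#' intake.
#'
#' @param norm_exp a normalized [feeding_experiment()].
#' @return Object of class `"phase_portrait_data"`: list with data frames
#'   `diet` (`u`, `F`, `group`) and `appetite` (`F`, `u`, `group`, `day`).
#' @export
extract_phase_points <- function(norm_exp) {
  stopifnot(inherits(norm_exp, "feeding_experiment"))
  if (!norm_exp$normalized)
    norm_exp <- normalize_to_control(norm_exp)
  dat <- norm_exp$data
  cw <- norm_exp$controlled_window
  rw <- norm_exp$recovery_window
  groups <- unique(dat$group)

  diet <- do.call(rbind, lapply(groups, function(g) {
    gd <- dat[dat$group == g & dat$day >= cw[1] & dat$day <= cw[2], ]
    if (nrow(gd) == 0L)
      stop("empty controlled window for group '", g, "'")
    data.frame(u = mean(gd$intake), F = gd$fat[which.max(gd$day)], group = g)
  }))

  appetite <- do.call(rbind, lapply(groups, function(g) {
    gd <- dat[dat$group == g & dat$day >= rw[1] & dat$day <= rw[2], ]
    if (nrow(gd) == 0L)
      stop("empty recovery window for group '", g, "'")
    data.frame(F = gd$fat, u = gd$intake, group = g, day = gd$day)
  }))

  structure(list(diet = diet, appetite = appetite),
            class = "phase_portrait_data")
}

#' @export
print.phase_portrait_data <- function(x, ...) {
  cat("Phase-portrait point sets:", nrow(x$diet), "diet points,",
      nrow(x$appetite), "appetite points\n")
  invisible(x)
}

#' Fit the diet line to phase-portrait points
#'
#' Ordinary least squares of relative fat on relative intake,
#' `F = a*u - b`, with `F` as the response.  With only two points the line
#' interpolates exactly and parameter SDs are flagged unavailable.
#'
#' @param points data frame with columns `u` and `F`.
#' @return Object of class `"dietline_fit"`: coefficients `a`, `b`, their
#'   SDs (`NA` when fewer than 3 points), residuals, and the underlying
#'   `lm` fit.
#' @export
fit_diet_line <- function(points) {
  stopifnot(is.data.frame(points), all(c("u", "F") %in% names(points)))
  if (nrow(points) < 2L) stop("need at least 2 diet points")
  if (diff(range(points$u)) < .Machine$double.eps^0.5)
    stop("degenerate diet points: all intakes equal")
  fit <- stats::lm(F ~ u, data = points)
  co <- stats::coef(fit)
  a <- unname(co["u"]); b <- unname(-co["(Intercept)"])
  if (a <= 0) warning("fitted diet line has non-positive slope")
  if (nrow(points) >= 3L) {
    se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
    sd_a <- unname(se["u"]); sd_b <- unname(se["(Intercept)"])
  } else {
    sd_a <- sd_b <- NA_real_
  }
  structure(list(a = a, b = b, sd_a = sd_a, sd_b = sd_b,
                 residuals = stats::residuals(fit), lm = fit,
                 n_points = nrow(points)),
            class = "dietline_fit")
}

#' @export
print.dietline_fit <- function(x, ...) {
  cat("Diet line F = a*u - b:\n")
  cat("  a =", signif(x$a, 4),
      if (is.na(x$sd_a)) "(SD unavailable: too few points)"
      else paste0("+/- ", signif(x$sd_a, 3)), "\n")
  cat("  b =", signif(x$b, 4),
      if (is.na(x$sd_b)) "" else paste0("+/- ", signif(x$sd_b, 3)), "\n")
  invisible(x)
}

#' @export
coef.dietline_fit <- function(object, ...) c(a = object$a, b = object$b)

#' Fit the appetite line to phase-portrait points
#'
#' Nonlinear least squares of `F = c * (1/u) * (umax/u - 1)^(1/n)` with
#' residuals in fat units.  The problem has local minima in `n`, so the
#' optimiser is multi-started over `n` in `{2, 5, 10, 20}` and the best
#' residual sum of squares wins.  Bounds keep `c > 0`, `n >= 1` and `umax`
#' above the largest observed intake (the line is undefined at
#' `u >= umax`).  Parameter SDs come from the Jacobian-based covariance.
#'
#' @param points data frame with columns `u` and `F` (relative units).
#' @param n_starts Hill steepness starting values.
#' @return Object of class `"appetiteline_fit"`: `c`, `umax`, `n`, their
#'   SDs, residuals, and the winning `nls` object.
#' @export
fit_appetite_line <- function(points, n_starts = c(2, 5, 10, 20)) {
  stopifnot(is.data.frame(points), all(c("u", "F") %in% names(points)))
  if (nrow(points) < 4L) stop("need at least 4 appetite points")
  u <- points$u; F <- points$F
  if (any(u <= 0)) stop("appetite points need positive intake")
  lower <- c(cc = 1e-10, umax = max(u) * (1 + 1e-6), n = 1)
  fits <- list(); diags <- character(0)
  for (n0 in n_starts) {
    start <- list(cc = stats::median(F * u), umax = max(u) * 1.15, n = n0)
    f <- tryCatch(
      minpack.lm::nlsLM(
        F ~ cc * (1 / u) * (umax / u - 1)^(1 / n),
        data = data.frame(u = u, F = F),
        start = start, lower = lower,
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) e)
    if (inherits(f, "error")) {
      diags <- c(diags, paste0("n0=", n0, ": ", conditionMessage(f)))
    } else {
      fits[[length(fits) + 1L]] <- f
    }
  }
  if (length(fits) == 0L)
    stop("appetite-line fit failed from every start:\n",
         paste(diags, collapse = "\n"))
  rss <- vapply(fits, function(f) sum(stats::residuals(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  co <- stats::coef(best)
  se <- tryCatch(sqrt(diag(stats::vcov(best))),
                 error = function(e) rep(NA_real_, 3))
  structure(list(c = unname(co["cc"]), umax = unname(co["umax"]),
                 n = unname(co["n"]),
                 sd_c = unname(se[1]), sd_umax = unname(se[2]),
                 sd_n = unname(se[3]),
                 residuals = stats::residuals(best), nls = best,
                 n_points = nrow(points), start_diagnostics = diags),
            class = "appetiteline_fit")
}

#' @export
print.appetiteline_fit <- function(x, ...) {
  cat("Appetite line F = c * (1/u) * (umax/u - 1)^(1/n):\n")
  cat("  c    =", signif(x$c, 4), "+/-", signif(x$sd_c, 3), "\n")
  cat("  umax =", signif(x$umax, 4), "+/-", signif(x$sd_umax, 3), "\n")
  cat("  n    =", signif(x$n, 4), "+/-", signif(x$sd_n, 3), "\n")
  invisible(x)
}

#' @export
coef.appetiteline_fit <- function(object, ...)
  c(c = object$c, umax = object$umax, n = object$n)

#' Fit both lines of the normalized phase portrait
#'
#' End-to-end estimator for a controlled-feeding experiment: normalizes to
#' the control, extracts diet and appetite points, and fits both lines.
#' The two fitted lines intersect at the experiment's operating point,
#' which for control-calibrated fold-change data lies near (1, 1).
#'
#' @param exp a [feeding_experiment()] (raw or normalized), or a
#'   `phase_portrait_data` object.
#' @param ... passed to [fit_appetite_line()].
#' @return Object of class `"op_phasefit"` with components `diet`
#'   (a `dietline_fit`), `appetite` (an `appetiteline_fit`), the point
#'   sets, and the fitted operating point.
#' @export
fit_phase_portrait <- function(exp, ...) {
  pts <- if (inherits(exp, "phase_portrait_data")) exp
    else extract_phase_points(normalize_to_control(exp))
  diet <- fit_diet_line(pts$diet)
  appetite <- fit_appetite_line(pts$appetite, ...)
  opt <- phasefit_operating_point(diet, appetite)
  structure(list(diet = diet, appetite = appetite, points = pts,
                 operating_point = opt),
            class = "op_phasefit")
}

# Intersection of the two fitted lines: solve diet F(u) = appetite F(u).
phasefit_operating_point <- function(diet, appetite) {
  g <- function(u) (diet$a * u - diet$b) -
    appetite$c * (1 / u) * (appetite$umax / u - 1)^(1 / appetite$n)
  hi <- appetite$umax * (1 - 1e-9)
  lo <- max(diet$b / diet$a, 1e-9) + 1e-9   # where the diet line crosses F=0
  if (lo >= hi || g(lo) * g(hi) > 0) return(list(u = NA_real_, F = NA_real_))
  r <- stats::uniroot(g, c(lo, hi), tol = 1e-12)
  list(u = r$root, F = diet$a * r$root - diet$b)
}

#' @export
print.op_phasefit <- function(x, ...) {
  cat("Normalized phase-portrait fit\n")
  print(x$diet); print(x$appetite)
  cat("Fitted operating point: u =", signif(x$operating_point$u, 4),
      ", F =", signif(x$operating_point$F, 4), "\n")
  invisible(x)
}

#' @export
coef.op_phasefit <- function(object, ...)
  c(a = object$diet$a, b = object$diet$b, c = object$appetite$c,
    umax = object$appetite$umax, n = object$appetite$n)

#' @export
residuals.op_phasefit <- function(object, ...)
  list(diet = object$diet$residuals, appetite = object$appetite$residuals)

#' @export
summary.op_phasefit <- function(object, ...) {
  co <- coef(object)
  sds <- c(object$diet$sd_a, object$diet$sd_b, object$appetite$sd_c,
           object$appetite$sd_umax, object$appetite$sd_n)
  data.frame(parameter = names(co), estimate = unname(co), sd = sds)
}

#' Predict fat on a fitted line
#'
#' @param object an `op_phasefit`.
#' @param newdata data frame with column `u`.
#' @param line `"diet"` or `"appetite"`.
#' @param ... unused.
#' @return Predicted relative fat.
#' @export
predict.op_phasefit <- function(object, newdata,
                                line = c("diet", "appetite"), ...) {
  line <- match.arg(line)
  u <- newdata$u
  if (line == "diet") {
    object$diet$a * u - object$diet$b
  } else {
    if (any(u <= 0 | u >= object$appetite$umax))
      stop("appetite line defined only for 0 < u < fitted umax")
    object$appetite$c * (1 / u) *
      (object$appetite$umax / u - 1)^(1 / object$appetite$n)
  }
}

#' @export
plot.op_phasefit <- function(x, ...) {
  pts <- x$points
  F_all <- c(pts$diet$F, pts$appetite$F)
  u_all <- c(pts$diet$u, pts$appetite$u)
  graphics::plot(pts$appetite$F, pts$appetite$u, col = "darkorange",
                 xlab = "relative fat", ylab = "relative intake",
                 xlim = range(F_all), ylim = range(u_all), ...)
  graphics::points(pts$diet$F, pts$diet$u, col = "darkgreen", pch = 19)
  ug <- seq(max(min(u_all) * 0.8, 0.05), x$appetite$umax * 0.999,
            length.out = 300)
  graphics::lines(predict(x, data.frame(u = ug), "appetite"), ug,
                  col = "darkorange")
  graphics::lines(x$diet$a * ug - x$diet$b, ug, col = "darkgreen")
  invisible(x)
}

#' Fit the leptin-fat population relation
#'
#' Least squares for the no-intercept quadratic `L = a_q F^2 + b_q F`
#' (the population-level prediction of intake-dependent leptin production)
#' against the linear alternative `L = c F`, compared by AIC in the
#' Gaussian-RSS form `N log(RSS/N) + 2k` (no additive constant; only AIC
#' differences are meaningful) and by Pearson r-squared between fitted and
#' observed leptin.
#'
#' @param points data frame with columns `fat` and `leptin`, `fat > 0`.
#' @return Object of class `"leptinfat_fit"`: quadratic coefficients `a_q`,
#'   `b_q` with SDs, linear coefficient `c_lin`, per-model `aic` and `r2`,
#'   `delta_aic` (quadratic minus linear) and `preferred`.
#' @export
fit_leptin_fat <- function(points) {
  stopifnot(is.data.frame(points), all(c("fat", "leptin") %in% names(points)))
  if (nrow(points) < 5L) stop("need at least 5 leptin-fat points")
  if (any(points$fat <= 0)) stop("fat values must be positive")
  F <- points$fat; L <- points$leptin
  quad <- stats::lm(L ~ 0 + I(F^2) + F)
  lin <- stats::lm(L ~ 0 + F)
  gauss_aic <- function(fit, k) {
    rss <- sum(stats::residuals(fit)^2)
    length(L) * log(rss / length(L)) + 2 * k
  }
  aic <- c(quadratic = gauss_aic(quad, 2), linear = gauss_aic(lin, 1))
  r2 <- c(quadratic = stats::cor(stats::fitted(quad), L)^2,
          linear = stats::cor(stats::fitted(lin), L)^2)
  se <- suppressWarnings(sqrt(diag(stats::vcov(quad))))
  structure(list(a_q = unname(stats::coef(quad)["I(F^2)"]),
                 b_q = unname(stats::coef(quad)["F"]),
                 sd_a_q = unname(se["I(F^2)"]), sd_b_q = unname(se["F"]),
                 c_lin = unname(stats::coef(lin)["F"]),
                 aic = aic, r2 = r2,
                 delta_aic = unname(aic["quadratic"] - aic["linear"]),
                 preferred = names(aic)[which.min(aic)],
                 quad = quad, lin = lin, n_points = nrow(points)),
            class = "leptinfat_fit")
}

#' @export
print.leptinfat_fit <- function(x, ...) {
  cat("Leptin-fat population fit (N =", x$n_points, ")\n")
  cat("  quadratic L = a*F^2 + b*F: a =", signif(x$a_q, 3), "+/-",
      signif(x$sd_a_q, 3), ", b =", signif(x$b_q, 3), "+/-",
      signif(x$sd_b_q, 3), "\n")
  cat("  linear    L = c*F:         c =", signif(x$c_lin, 3), "\n")
  cat("  AIC (quadratic, linear):", signif(x$aic, 6),
      " delta =", signif(x$delta_aic, 4), "\n")
  cat("  r2  (quadratic, linear):", signif(x$r2, 3), "\n")
  cat("  preferred:", x$preferred, "\n")
  invisible(x)
}

#' @export
coef.leptinfat_fit <- function(object, ...)
  c(a_q = object$a_q, b_q = object$b_q, c_lin = object$c_lin)

#' @export
predict.leptinfat_fit <- function(object, newdata, ...) {
  F <- newdata$fat
  if (object$preferred == "quadratic")
    object$a_q * F^2 + object$b_q * F
  else object$c_lin * F
}

#' @export
residuals.leptinfat_fit <- function(object, ...)
  list(quadratic = stats::residuals(object$quad),
       linear = stats::residuals(object$lin))

#' @export
plot.leptinfat_fit <- function(x, ...) {
  F <- stats::model.frame(x$quad)$F
  L <- stats::model.frame(x$quad)$L
  graphics::plot(F, L, xlab = "fat", ylab = "leptin", ...)
  Fg <- seq(min(F), max(F), length.out = 200)
  graphics::lines(Fg, x$a_q * Fg^2 + x$b_q * Fg, col = "firebrick")
  graphics::lines(Fg, x$c_lin * Fg, col = "grey40", lty = 2)
  graphics::legend("topleft", c("quadratic", "linear"),
                   col = c("firebrick", "grey40"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Feeding-experiment and leptin-scatter CSV I/O
#'
#' The feeding CSV schema has header exactly
#' `group,day,intake,fat,weight` (fat may be empty on unmeasured days); the
#' leptin scatter schema has header exactly `fat,leptin`.  Headers are
#' validated bit-exactly.
#'
#' @param exp a [feeding_experiment()].
#' @param path CSV path.
#' @return The writer returns `path` invisibly; readers return the
#'   container ([feeding_experiment()] needs the design arguments).
#' @export
write_feeding_experiment <- function(exp, path) {
  stopifnot(inherits(exp, "feeding_experiment"))
  df <- exp$data
  if (!"weight" %in% names(df)) df$weight <- NA_real_
  utils::write.csv(df[, c("group", "day", "intake", "fat", "weight")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feeding_experiment
#' @param control,controlled_window,recovery_window experiment design, as in
#'   [feeding_experiment()].
#' @export
read_feeding_experiment <- function(path, control, controlled_window,
                                    recovery_window) {
  if (!nzchar(path) || !file.exists(path)) stop("no such file: '", path, "'")
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  header <- gsub('"', "", header)
  if (!identical(header, c("group", "day", "intake", "fat", "weight")))
    stop("feeding CSV header must be exactly 'group,day,intake,fat,weight', got: ",
         paste(header, collapse = ","))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  feeding_experiment(df, control, controlled_window, recovery_window)
}

#' @rdname write_feeding_experiment
#' @param scatter data frame with columns `fat`, `leptin`.
#' @export
write_leptin_scatter <- function(scatter, path) {
  stopifnot(all(c("fat", "leptin") %in% names(scatter)))
  utils::write.csv(scatter[, c("fat", "leptin")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feeding_experiment
#' @export
read_leptin_scatter <- function(path) {
  if (!nzchar(path) || !file.exists(path)) stop("no such file: '", path, "'")
  header <- gsub('"', "", strsplit(readLines(path, n = 1L), ",")[[1]])
  if (!identical(header, c("fat", "leptin")))
    stop("leptin scatter CSV header must be exactly 'fat,leptin', got: ",
         paste(header, collapse = ","))
  utils::read.csv(path)
}
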