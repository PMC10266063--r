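#' Universal constants of the 3D Ising universality class
#'
#' Surface-tension exponent mu, correlation-length exponent
#' nu = mu/(d - 1), spatial dimensionality d, and the universal amplitude
#' ratio R^- = gamma0 xi0^(d-1) / (kB Tc).  These are held fixed in all
#' power-law fits: only the critical temperature and a nonuniversal
#' amplitude are free.
#'
#' @return Named list `mu`, `nu`, `dims`, `r_minus`.
#' @export
ising_constants <- function() {
  mu <- 1.26
  dims <- 3L
  list(mu = mu, nu = mu / (dims - 1), dims = dims, r_minus = 0.1024)
}

#' Reduced temperature
#'
#' `tau = 1 - T/Tc`, the dimensionless distance from the critical point.
#' Negative values (T above Tc) are supercritical.
#'
#' @param temperature Absolute temperature(s), K.
#' @param tc Critical temperature, K (> 0).
#' @export
reduced_temperature <- function(temperature, tc) {
  if (tc <= 0) stop("Tc must be positive")
  1 - temperature / tc
}

#' Combined coefficient of the width-based surface-tension estimate
#'
#' `R^- * (L/xi)^2`: the prefactor of `kB Tc / L^2` in the universal
#' surface-tension estimate.  With the tanh-profile ratio L/xi = 4 this is
#' 0.1024 * 16 = 1.6384, i.e. approximately 1.64.
#'
#' @param width_ratio Interface-width to correlation-length ratio
#'   (default 4, the tanh-profile value).
#' @param constants Universal constants (see [ising_constants()]).
#' @export
gamma_coefficient <- function(width_ratio = 4,
                              constants = ising_constants()) {
  constants$r_minus * width_ratio^2
}

#' Finite-size filter for near-critical state points
#'
#' Retains only state points whose implied correlation length is below a
#' fixed fraction of the box length along the slab normal; closer to the
#' critical point the correlation length approaches the box size and both
#' gamma and L are biased by finite-size effects.
#'
#' @param points data.frame with at least a column `xi` (implied
#'   correlation length, nm).
#' @param lx Box length along x, nm.
#' @param factor Threshold fraction (default 0.05).
#' @return List with `retained` and `excluded` data.frames; the excluded
#'   rows gain a `reason` column.
#' @export
finite_size_filter <- function(points, lx, factor = 0.05) {
  if (!"xi" %in% names(points)) stop("points need an `xi` column")
  keep <- points$xi < factor * lx
  excluded <- points[!keep, , drop = FALSE]
  if (nrow(excluded))
    excluded$reason <- sprintf("xi = %.3g nm >= %.3g nm (%.2g * Lx)",
                               excluded$xi, factor * lx, factor)
  retained <- points[keep, , drop = FALSE]
  if (nrow(retained) < 3)
    stop("fewer than 3 state points survive the finite-size filter ",
         "(xi < ", factor, " * Lx)")
  list(retained = retained, excluded = excluded)
}

powerlaw_model <- function(temperature, tc, amplitude, expo) {
  tau <- 1 - temperature / tc
  amplitude * ifelse(tau > 0, tau, NA_real_)^expo
}

#' Fit a critical power law with fixed universal exponent
#'
#' Weighted least squares of `y = amplitude * tau^mu` (surface tension,
#' `kind = "gamma"`) or `y = amplitude * tau^(-nu)` (correlation length or
#' interface width, `kind = "xi"`), with `tau = 1 - T/Tc`.  The exponent
#' is held at its universal value; only `Tc` and the nonuniversal
#' amplitude are free.  Weights are 1/SEM^2; points with zero or missing
#' SEM receive the median weight.
#'
#' @param temperature Temperatures, K.
#' @param y Observable values (> 0): gamma, xi, or L.
#' @param sem Optional per-point standard errors.
#' @param kind "gamma" (growth toward low T, exponent +mu) or "xi"
#'   (divergence toward Tc, exponent -nu).
#' @param constants Universal constants.
#' @return Object of class `critical_fit`: `tc`, `amplitude`, their
#'   standard errors and covariance, the exponent used, the fitted points,
#'   and the reduced chi-square.  Supports `print()`, `coef()`,
#'   `predict()`.
#' @export
fit_power_law <- function(temperature, y, sem = NULL,
                          kind = c("gamma", "xi"),
                          constants = ising_constants()) {
  kind <- match.arg(kind)
  ok <- is.finite(temperature) & is.finite(y) & y > 0
  temperature <- temperature[ok]
  y <- y[ok]
  if (!is.null(sem)) sem <- sem[ok]
  if (length(y) < 3)
    stop("insufficient data: need at least 3 positive points")
  expo <- if (kind == "gamma") constants$mu else -constants$nu
  w <- rep(1, length(y))
  if (!is.null(sem)) {
    w <- 1 / sem^2
    bad <- !is.finite(w)
    if (all(bad)) w <- rep(1, length(y))
    else if (any(bad)) w[bad] <- median(w[!bad])
  }
  tmax <- max(temperature)
  # grid search over Tc with closed-form amplitude, then local refinement
  sse_at <- function(tc) {
    tau <- 1 - temperature / tc
    f <- tau^expo
    a <- sum(w * y * f) / sum(w * f^2)
    sum(w * (y - a * f)^2)
  }
  grid <- tmax * (1 + 10^seq(-4, 0.7, length.out = 120))
  tc0 <- grid[which.min(vapply(grid, sse_at, numeric(1)))]
  tau0 <- 1 - temperature / tc0
  a0 <- sum(w * y * tau0^expo) / sum(w * tau0^(2 * expo))
  dat <- data.frame(temperature = temperature, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ amplitude * (1 - temperature / tc)^expo, data = dat,
      start = list(tc = tc0, amplitude = a0), weights = w,
      lower = c(tmax * (1 + 1e-9), 1e-300),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop("power-law fit did not converge: ",
                             conditionMessage(e)))
  est <- coef(fit)
  if (est[["tc"]] <= tmax)
    stop("fitted Tc is not above the highest data temperature")
  sm <- summary(fit)
  se <- sm$coefficients[, "Std. Error"]
  resid <- y - powerlaw_model(temperature, est[["tc"]], est[["amplitude"]],
                              expo)
  chi2 <- sum(w * resid^2) / max(length(y) - 2, 1)
  structure(list(tc = est[["tc"]], amplitude = est[["amplitude"]],
                 se = c(tc = unname(se["tc"]),
                        amplitude = unname(se["amplitude"])),
                 vcov = stats::vcov(fit), kind = kind, exponent = expo,
                 points = data.frame(temperature = temperature, y = y,
                                     weight = w),
                 reduced_chisq = chi2, constants = constants),
            class = "critical_fit")
}

#' @export
print.critical_fit <- function(x, ...) {
  lab <- if (x$kind == "gamma") "gamma0" else "xi0"
  cat(sprintf(
    "Critical power-law fit (%s, fixed exponent %+.3g):\n", x$kind,
    x$exponent))
  cat(sprintf("  Tc = %.4g +- %.2g K\n", x$tc, x$se[["tc"]]))
  cat(sprintf("  %s = %.4g +- %.2g\n", lab, x$amplitude,
              x$se[["amplitude"]]))
  cat(sprintf("  %d points, reduced chi-square %.3g\n",
              nrow(x$points), x$reduced_chisq))
  invisible(x)
}

#' @export
coef.critical_fit <- function(object, ...) {
  c(tc = object$tc, amplitude = object$amplitude)
}

#' @export
confint.critical_fit <- function(object, parm = c("tc", "amplitude"),
                                 level = 0.95, ...) {
  parm <- match.arg(parm, several.ok = TRUE)
  df <- max(nrow(object$points) - 2, 1)
  tq <- stats::qt(1 - (1 - level) / 2, df)
  est <- c(tc = object$tc, amplitude = object$amplitude)
  out <- cbind(est[parm] - tq * object$se[parm],
               est[parm] + tq * object$se[parm])
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2,
                                        1 - (1 - level) / 2) * 100)
  out
}

#' @export
predict.critical_fit <- function(object, newdata = NULL, ...) {
  temperature <- if (is.null(newdata)) object$points$temperature
    else if (is.data.frame(newdata)) newdata$temperature else newdata
  powerlaw_model(temperature, object$tc, object$amplitude, object$exponent)
}

#' Iterative finite-size-filtered critical fit
#'
#' Fits the power law, derives each point's implied correlation length,
#' applies the finite-size filter, refits on the retained points, and
#' iterates until the retained set is stable.  The implied xi comes from
#' the `xi` column when present (e.g. L/4 from interface fits); otherwise
#' it is derived from the provisional fit via the universal amplitude
#' ratio, `xi = sqrt(R^- kB Tc / gamma)`.
#'
#' @param table data.frame with columns `temperature` (K), `y`, optional
#'   `sem`, optional `xi` (nm).
#' @param lx Box length along x, nm.
#' @param kind Passed to [fit_power_law()].
#' @param factor Finite-size threshold fraction.
#' @param t0 Reference temperature for unit conversion when `y` is a
#'   surface tension in kB*T0/nm^2.
#' @param max_iter Maximum filter/refit cycles.
#' @return A `critical_fit` with extra fields `retained` and `excluded`.
#' @export
fit_critical <- function(table, lx, kind = c("gamma", "xi"), factor = 0.05,
                         t0 = 300, max_iter = 20) {
  kind <- match.arg(kind)
  constants <- ising_constants()
  tab <- as.data.frame(table)
  sem <- if ("sem" %in% names(tab)) tab$sem else NULL
  current <- seq_len(nrow(tab))
  excluded <- tab[0, , drop = FALSE]
  fit <- NULL
  for (it in seq_len(max_iter)) {
    sub <- tab[current, , drop = FALSE]
    fit <- fit_power_law(sub$temperature, sub$y,
                         if (!is.null(sem)) sem[current], kind, constants)
    if ("xi" %in% names(tab)) {
      xi_all <- tab$xi
    } else if (kind == "xi") {
      xi_all <- predict(fit, tab$temperature)
    } else {
      gamma_si <- gamma_to_si(tab$y, t0)
      xi_all <- sqrt(constants$r_minus * KB_SI * fit$tc / gamma_si) * 1e9
    }
    keep <- which(xi_all < factor * lx)
    if (length(keep) < 3)
      stop("fewer than 3 state points survive the finite-size filter")
    if (identical(sort(keep), sort(current))) break
    current <- keep
  }
  aug <- tab
  aug$xi_implied <- xi_all
  fit$retained <- aug[current, , drop = FALSE]
  fit$excluded <- aug[setdiff(seq_len(nrow(tab)), current), , drop = FALSE]
  fit$lx <- lx
  fit$factor <- factor
  fit
}

#' Data collapse and critical-regime extent
#'
#' Scales each series' surface tension by its fitted critical amplitude
#' and expresses temperature as tau = 1 - T/Tc; in the critical regime all
#' series collapse onto the universal curve tau^mu.  The extent tau* of
#' the regime is the largest tau below which every point deviates from
#' tau^mu by at most `rel_tol` (relatively); with no violations tau* is
#' the largest tau in the data.
#'
#' @param series A data.frame with columns `temperature`, `gamma` (and
#'   optionally `sem`), or a named list of such data.frames (one per block
#'   length).
#' @param fits A `critical_fit`, or list of fits matching `series`.
#' @param rel_tol Relative deviation tolerance (default 0.10).
#' @return List with `table` (series, temperature, tau, scaled gamma,
#'   deviation), `tau_star` per series, and `tau_star_pooled`.
#' @export
collapse_and_extent <- function(series, fits, rel_tol = 0.10) {
  if (is.data.frame(series)) {
    series <- list(series)
    fits <- list(fits)
  }
  if (is.null(names(series)))
    names(series) <- paste0("series", seq_along(series))
  mu <- ising_constants()$mu
  rows <- list()
  tau_star <- numeric(length(series))
  names(tau_star) <- names(series)
  for (i in seq_along(series)) {
    s <- series[[i]]
    f <- fits[[i]]
    tau <- reduced_temperature(s$temperature, f$tc)
    ratio <- s$gamma / f$amplitude
    dev <- abs(ratio - tau^mu) / tau^mu
    ok <- tau > 0 & is.finite(dev)
    rows[[i]] <- data.frame(series = names(series)[i],
                            temperature = s$temperature[ok],
                            tau = tau[ok], scaled_gamma = ratio[ok],
                            deviation = dev[ok])
    viol <- rows[[i]]$tau[rows[[i]]$deviation > rel_tol]
    tau_star[i] <- if (length(viol)) min(viol) else max(rows[[i]]$tau)
  }
  tab <- do.call(rbind, rows)
  viol_all <- tab$tau[tab$deviation > rel_tol]
  pooled <- if (length(viol_all)) min(viol_all) else max(tab$tau)
  list(table = tab, tau_star = tau_star, tau_star_pooled = pooled,
       rel_tol = rel_tol)
}

#' Predict the surface-tension curve from Tc and one interface width
#'
#' Uses the universal amplitude ratio of the 3D Ising class to turn a
#' critical temperature and a single interface-width measurement into the
#' full temperature dependence of the surface tension:
#' `xi_ref = L_ref/4`, `xi0 = xi_ref * tau_ref^nu`,
#' `gamma0 = R^- kB Tc / xi0^2`, and `gamma(T) = gamma0 tau^mu` --
#' equivalently `gamma(T) = 16 R^- kB Tc / L(T)^2 ~ 1.64 kB Tc / L(T)^2`.
#'
#' @param tc Critical temperature, K.
#' @param t_ref Temperature of the width measurement, K (< Tc).
#' @param l_ref Interface width at `t_ref`, nm.
#' @param t_grid Temperatures (K) at which to evaluate the predicted
#'   curve; defaults to a grid from `0.6 * tc` to just below Tc.
#' @param t0 Reference temperature for simulation-unit conversion, K.
#' @return Object of class `gamma_prediction` with `gamma0_si` (N/m),
#'   `gamma0_sim` (kB*T0/nm^2), `xi0` (nm), and a `curve` data.frame
#'   (temperature, tau, gamma_si, gamma_sim).  `predict()` evaluates the
#'   curve at new temperatures.
#' @export
gamma_from_universal_ratio <- function(tc, t_ref, l_ref, t_grid = NULL,
                                       t0 = 300) {
  if (t_ref >= tc) stop("reference temperature must be below Tc")
  if (l_ref <= 0) stop("interface width must be positive")
  cst <- ising_constants()
  tau_ref <- 1 - t_ref / tc
  xi_ref <- xi_from_width(l_ref)
  xi0 <- xi_ref * tau_ref^cst$nu
  gamma0_si <- cst$r_minus * KB_SI * tc / (xi0 * 1e-9)^2
  if (is.null(t_grid))
    t_grid <- seq(0.6 * tc, 0.999 * tc, length.out = 100)
  tau <- 1 - t_grid / tc
  gsi <- gamma0_si * ifelse(tau > 0, tau, NA_real_)^cst$mu
  structure(list(tc = tc, t_ref = t_ref, l_ref = l_ref, xi0 = xi0,
                 gamma0_si = gamma0_si,
                 gamma0_sim = gamma_from_si(gamma0_si, t0), t0 = t0,
                 curve = data.frame(temperature = t_grid, tau = tau,
                                    gamma_si = gsi,
                                    gamma_sim = gamma_from_si(gsi, t0))),
            class = "gamma_prediction")
}

#' @export
print.gamma_prediction <- function(x, ...) {
  cat("Surface-tension prediction from the universal amplitude ratio:\n")
  cat(sprintf("  Tc = %.4g K; width L = %.4g nm at T = %.4g K\n",
              x$tc, x$l_ref, x$t_ref))
  cat(sprintf("  xi0 = %.4g nm; gamma0 = %.4g N/m (%.4g kB*T0/nm^2)\n",
              x$xi0, x$gamma0_si, x$gamma0_sim))
  invisible(x)
}

#' @export
predict.gamma_prediction <- function(object, newdata = NULL,
                                     units = c("si", "sim"), ...) {
  units <- match.arg(units)
  temperature <- if (is.null(newdata)) object$curve$temperature
    else if (is.data.frame(newdata)) newdata$temperature else newdata
  tau <- 1 - temperature / object$tc
  g <- object$gamma0_si * ifelse(tau > 0, tau, NA_real_)^ising_constants()$mu
  if (units == "sim") g <- gamma_from_si(g, object$t0)
  g
}

#' Compare directly measured surface tensions with the predicted curve
#'
#' Per-temperature ratios and z-scores of measured gamma against the
#' universal-ratio prediction; the comparison is flagged consistent when
#' at least 80 percent of points lie within 2 SEM of the prediction.
#'
#' @param direct data.frame with `temperature`, `gamma`, `sem` (any
#'   consistent unit).
#' @param predicted A `gamma_prediction`, or a function of temperature
#'   returning gamma in the same unit as `direct`.
#' @param units Unit of `direct` when `predicted` is a
#'   `gamma_prediction`: "sim" (kB*T0/nm^2) or "si" (N/m).
#' @return List with `table` (temperature, gamma, sem, predicted, ratio,
#'   z), `frac_within_2sem`, and `consistent`.
#' @export
validate_prediction <- function(direct, predicted, units = c("sim", "si")) {
  units <- match.arg(units)
  pfun <- if (inherits(predicted, "gamma_prediction")) {
    function(tt) predict(predicted, tt, units = units)
  } else predicted
  pred <- pfun(direct$temperature)
  z <- (direct$gamma - pred) / direct$sem
  tab <- data.frame(temperature = direct$temperature,
                    gamma = direct$gamma, sem = direct$sem,
                    predicted = pred, ratio = direct$gamma / pred, z = z)
  frac <- mean(abs(z) <= 2, na.rm = TRUE)
  list(table = tab, frac_within_2sem = frac, consistent = frac >= 0.8)
}
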