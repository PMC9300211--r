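#' Two-state thermal melting analysis of chemical shifts
#'
#' A proton reporting on a two-state folding equilibrium follows a
#' sigmoid in temperature,
#' \deqn{\delta(T) = \delta_U + \frac{\delta_F - \delta_U}
#'   {1 + \exp(-\Delta H_m/R\,(1/T - 1/T_m))}}
#' with terminal shifts \eqn{\delta_U} (unfolded) and \eqn{\delta_F}
#' (folded), melting temperature \eqn{T_m} and unfolding enthalpy
#' \eqn{\Delta H_m} at \eqn{T_m}. As \eqn{T \to \infty} the observed
#' shift approaches \eqn{\delta_U}. R = 8.314 J/(K mol) throughout;
#' temperatures in kelvin.
#'
#' @name melting
NULL

GAS_R <- 8.314

#' One proton's shift-vs-temperature series
#'
#' @param proton character label.
#' @param T_K numeric temperatures (K), strictly increasing.
#' @param shift_ppm observed chemical shifts (ppm); NA cells allowed and
#'   dropped.
#' @return object of class `shift_melt_series`.
#' @export
shift_melt_series <- function(proton, T_K, shift_ppm) {
  keep <- is.finite(T_K) & is.finite(shift_ppm)
  T_K <- T_K[keep]
  shift_ppm <- shift_ppm[keep]
  if (any(T_K <= 0)) stop("temperatures must be positive kelvin")
  if (is.unsorted(T_K, strictly = TRUE)) {
    o <- order(T_K)
    T_K <- T_K[o]
    shift_ppm <- shift_ppm[o]
    if (anyDuplicated(T_K)) stop("duplicate temperatures in series ", proton)
  }
  structure(list(proton = proton, T_K = T_K, shift_ppm = shift_ppm),
            class = "shift_melt_series")
}

#' @export
print.shift_melt_series <- function(x, ...) {
  cat(sprintf("shift_melt_series '%s': %d points, %.0f-%.0f K, %.3f-%.3f ppm\n",
              x$proton, length(x$T_K), min(x$T_K), max(x$T_K),
              min(x$shift_ppm), max(x$shift_ppm)))
  invisible(x)
}

#' Read a variable-temperature shift table
#'
#' Delimited text; first column temperature in K, one column per proton
#' in ppm. Missing cells allowed.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return named list of [shift_melt_series].
#' @export
read_vt_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (ncol(tab) < 2L) stop("VT table needs a temperature column plus protons")
  T_K <- tab[[1L]]
  out <- lapply(names(tab)[-1L], function(p) {
    shift_melt_series(p, T_K, tab[[p]])
  })
  names(out) <- names(tab)[-1L]
  out
}

#' Write a variable-temperature shift table
#' @param series_set named list of [shift_melt_series] on a common grid.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_vt_table <- function(series_set, path, sep = "\t") {
  T_K <- series_set[[1L]]$T_K
  tab <- data.frame(T_K = T_K)
  for (s in series_set) {
    stopifnot(identical(s$T_K, T_K))
    tab[[s$proton]] <- s$shift_ppm
  }
  utils::write.table(format(tab, digits = 10), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

two_state_delta <- function(T_K, dU, dF, Tm, dHm) {
  dU + (dF - dU) / (1 + exp(-dHm / GAS_R * (1 / T_K - 1 / Tm)))
}

#' Fit the two-state melting sigmoid to one proton
#'
#' Nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nlsLM()])
#' of the two-state model. Robust initialisation: terminals from the
#' mean shift of the coldest and hottest 10% of points, Delta H_m
#' 25 kJ/mol, and three starts with T_m in the first, middle and last
#' third of the temperature range; the converged fit with the lowest
#' SSE wins.
#'
#' @param series a [shift_melt_series] with at least 5 temperatures.
#' @param init optional named list overriding the starting values
#'   (`dU`, `dF`, `Tm`, `dHm`).
#' @param min_amplitude smallest |shift change| (ppm) treated as a real
#'   transition (default 0.01).
#' @return object of class `two_state_fit`: `dU`, `dF`, `Tm`, `dHm`
#'   (J/mol, unfolding), `cov` (4x4), `residuals`, `sse`, `series`.
#' @export
fit_two_state <- function(series, init = NULL, min_amplitude = 0.01) {
  stopifnot(inherits(series, "shift_melt_series"))
  T_K <- series$T_K
  y <- series$shift_ppm
  if (length(T_K) < 5L) stop("need at least 5 temperature points")
  if (diff(range(y)) < min_amplitude) {
    stop("no transition detected: shift change ", signif(diff(range(y)), 3),
         " ppm below floor ", min_amplitude)
  }
  ncold <- max(1L, ceiling(0.1 * length(T_K)))
  # cold end is the folded side of the transition
  dF0 <- mean(y[seq_len(ncold)])
  dU0 <- mean(y[seq.int(length(y) - ncold + 1L, length(y))])
  tmin <- min(T_K)
  tspan <- diff(range(T_K))
  starts <- lapply(c(1 / 6, 1 / 2, 5 / 6), function(fr) {
    list(dU = dU0, dF = dF0, Tm = tmin + fr * tspan, dHm = 25000)
  })
  if (!is.null(init)) starts <- c(list(modifyList(starts[[2L]], init)), starts)
  dat <- data.frame(T_K = T_K, y = y)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ two_state_delta(T_K, dU, dF, Tm, dHm),
        data = dat, start = st,
        lower = c(dU = -Inf, dF = -Inf, Tm = tmin - 50, dHm = 1),
        upper = c(dU = Inf, dF = Inf, Tm = max(T_K) + 50, dHm = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("two-state fit did not converge from any start")
  cf <- stats::coef(best$fit)
  vc <- tryCatch(stats::vcov(best$fit), error = function(e) {
    matrix(NA_real_, 4, 4, dimnames = list(names(cf), names(cf)))
  })
  structure(list(proton = series$proton,
                 dU = unname(cf["dU"]), dF = unname(cf["dF"]),
                 Tm = unname(cf["Tm"]), dHm = unname(cf["dHm"]),
                 cov = vc, residuals = unname(stats::resid(best$fit)),
                 sse = best$sse, series = series),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(
    "two_state_fit%s: Tm = %.2f K, dHm = %.0f J/mol, dU = %.4f, dF = %.4f ppm (SSE %.3g)\n",
    if (is.null(x$proton)) "" else paste0(" '", x$proton, "'"),
    x$Tm, x$dHm, x$dU, x$dF, x$sse))
  invisible(x)
}

#' Predicted shift of a fitted two-state model
#' @param fit a `two_state_fit`.
#' @param T_K temperatures (K).
#' @return predicted shifts (ppm).
#' @export
predict_shift <- function(fit, T_K) {
  two_state_delta(T_K, fit$dU, fit$dF, fit$Tm, fit$dHm)
}

#' Folded molar fraction at a temperature
#'
#' \eqn{f(T) = 1/(1 + \exp(-\Delta H_m/R (1/T - 1/T_m)))}; f(T_m) = 0.5,
#' f -> 1 as T -> 0.
#'
#' @param fit a `two_state_fit` (or any list with `Tm`, `dHm`).
#' @param T_K temperature(s), K.
#' @return folded fraction(s) in `[0, 1]`.
#' @export
folded_fraction <- function(fit, T_K) {
  if (any(T_K <= 0)) stop("temperature must be positive kelvin")
  1 / (1 + exp(-fit$dHm / GAS_R * (1 / T_K - 1 / fit$Tm)))
}

#' Global (pooled) melting fit over several protons
#'
#' Stage 1 fits each proton individually; stage 2 rescales each series
#' to folded fraction using its own fitted terminals (normalisation to
#' the maximum shift change); stage 3 fits the two-state model with
#' terminals fixed at 0/1 to the pooled normalised points, giving one
#' shared (T_m, Delta H_m).
#'
#' Protons whose individual fit fails (e.g. no detectable shift change)
#' are excluded with a warning; at least two series must survive.
#'
#' @param series_set list of [shift_melt_series].
#' @param min_amplitude passed to [fit_two_state()].
#' @return object of class `global_melt_fit`: shared-fit fields as in
#'   `two_state_fit` (with `dU = 0`, `dF = 1` on the fraction-folded
#'   scale), plus `per_proton` (list of individual fits) and `excluded`
#'   (character).
#' @export
global_melt_fit <- function(series_set, min_amplitude = 0.01) {
  stopifnot(length(series_set) >= 1L)
  fits <- list()
  excluded <- character()
  for (s in series_set) {
    f <- tryCatch(fit_two_state(s, min_amplitude = min_amplitude),
                  error = function(e) e)
    if (inherits(f, "error")) {
      warning(sprintf("proton '%s' excluded from global fit: %s",
                      s$proton, conditionMessage(f)))
      excluded <- c(excluded, s$proton)
    } else {
      fits[[s$proton]] <- f
    }
  }
  if (length(fits) < 1L || (length(series_set) > 1L && length(fits) < 2L)) {
    stop("fewer than 2 protons survived individual fitting")
  }
  T_all <- unlist(lapply(fits, function(f) f$series$T_K))
  f_all <- unlist(lapply(fits, function(f) {
    (f$series$shift_ppm - f$dU) / (f$dF - f$dU)
  }))
  dat <- data.frame(T_K = T_all, y = f_all)
  tm0 <- stats::median(vapply(fits, function(f) f$Tm, 1))
  dh0 <- stats::median(vapply(fits, function(f) f$dHm, 1))
  fit <- minpack.lm::nlsLM(
    y ~ 1 / (1 + exp(-dHm / GAS_R * (1 / T_K - 1 / Tm))),
    data = dat, start = list(Tm = tm0, dHm = dh0),
    lower = c(Tm = min(T_all) - 50, dHm = 1),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  structure(list(proton = NULL, dU = 0, dF = 1,
                 Tm = unname(cf["Tm"]), dHm = unname(cf["dHm"]),
                 cov = stats::vcov(fit),
                 residuals = unname(stats::resid(fit)),
                 sse = sum(stats::resid(fit)^2),
                 per_proton = fits, excluded = excluded),
            class = c("global_melt_fit", "two_state_fit"))
}

#' @export
print.global_melt_fit <- function(x, ...) {
  cat(sprintf(
    "global_melt_fit: %d protons (%d excluded), Tm = %.2f K, dHm = %.0f J/mol\n",
    length(x$per_proton), length(x$excluded), x$Tm, x$dHm))
  invisible(x)
}

#' Folding free energy and folding constant
#'
#' Two routes, both exposed:
#' route `"shift"` evaluates the folding constant from the fitted curve,
#' \eqn{k_F(T) = (\delta_U - \delta(T)) / (\delta(T) - \delta_F)
#'   = \exp(\Delta H_m/R (1/T - 1/T_m))}, and
#' \eqn{\Delta G^\circ = -RT \ln k_F};
#' route `"hs"` uses tabulated enthalpy and entropy,
#' \eqn{\Delta G^\circ = \Delta H_m - T \Delta S_m} (enthalpy assumed
#' temperature-independent).
#'
#' @param fit for route `"shift"`, a `two_state_fit`; for route `"hs"`,
#'   a list/vector with `dHm` (J/mol) and `dSm` (J/(K mol)).
#' @param T_K temperature, K.
#' @param route `"shift"` or `"hs"`.
#' @return list with `dG` (J/mol) and, for route `"shift"`, `kF`.
#' @export
delta_g <- function(fit, T_K, route = c("shift", "hs")) {
  route <- match.arg(route)
  if (any(T_K <= 0)) stop("temperature must be positive kelvin")
  if (route == "hs") {
    dG <- fit$dHm - T_K * fit$dSm
    return(list(dG = dG, kF = exp(-dG / (GAS_R * T_K))))
  }
  kF <- exp(fit$dHm / GAS_R * (1 / T_K - 1 / fit$Tm))
  list(dG = -GAS_R * T_K * log(kF), kF = kF)
}

#' Folding constant from an observed shift and terminals
#'
#' \eqn{k_F = (\delta_U - \delta_{obs}) / (\delta_{obs} - \delta_F)};
#' errors when the observed shift falls outside the terminal range
#' (folded fraction outside `[0, 1]`).
#'
#' @param delta_obs observed shift (ppm).
#' @param dU,dF terminal shifts (ppm).
#' @return k_F (dimensionless).
#' @export
kf_from_shift <- function(delta_obs, dU, dF) {
  lo <- pmin(dU, dF)
  hi <- pmax(dU, dF)
  if (any(delta_obs < lo | delta_obs > hi)) {
    stop("observed shift outside the terminal range: folded fraction outside [0, 1]")
  }
  (dU - delta_obs) / (delta_obs - dF)
}

#' Van 't Hoff entropy and enthalpy from a fitted melt
#'
#' Converts the observed shifts to folding constants with the fit's own
#' terminals, \eqn{k_F = (\delta_U - \delta_{obs})/(\delta_{obs} -
#' \delta_F)}, keeps temperatures with folded fraction strictly inside
#' (0.02, 0.98), and regresses \eqn{\ln k_F} on \eqn{1/T}. With the
#' folding-constant convention the slope is \eqn{+\Delta H_m/R} and the
#' intercept \eqn{-\Delta S_m/R} in unfolding units; both are reported
#' as positive unfolding quantities for cross-checking against the
#' nonlinear fit. For exact two-state data the line is exact and
#' \eqn{\Delta S = \Delta H_m / T_m}.
#'
#' @param fit a `two_state_fit` carrying its fitted series.
#' @return list with `dS` (J/(K mol), intercept-derived), `dH` (J/mol,
#'   slope-derived), `dS_se`, `dH_se`, `n_used`.
#' @export
van_t_hoff_entropy <- function(fit) {
  if (is.null(fit$series)) stop("fit carries no data series")
  T_K <- fit$series$T_K
  y <- fit$series$shift_ppm
  f <- (y - fit$dU) / (fit$dF - fit$dU)
  keep <- is.finite(f) & f > 0.02 & f < 0.98
  if (sum(keep) < 4L) stop("fewer than 4 usable temperatures inside the transition")
  T_use <- T_K[keep]
  # ln kF = dHm/R * (1/T - 1/Tm)  =>  slope dHm/R, intercept -dHm/(R Tm)
  lnk <- log(f[keep] / (1 - f[keep]))
  reg <- stats::lm(lnk ~ I(1 / T_use))
  sl <- stats::coef(reg)[2L]
  ic <- stats::coef(reg)[1L]
  se <- sqrt(diag(stats::vcov(reg)))
  # folding lnk = dH/R / T - dS-ish; unfolding quantities reported positive:
  # lnk_F = -dG_unf... with our convention: lnk = dHm/R (1/T - 1/Tm), so
  # dH (unfolding) = R * slope, dS (unfolding) = -R * intercept
  list(dH = unname(GAS_R * sl), dS = unname(-GAS_R * ic),
       dH_se = unname(GAS_R * se[2L]), dS_se = unname(GAS_R * se[1L]),
       n_used = sum(keep))
}

#' Relative folding stability of two compounds from matched melts
#'
#' From shifts of the two compounds observed at the same temperatures
#' and their terminal shifts, the ratio of folding constants
#' \eqn{K = k_F^{(1)}/k_F^{(2)}} is the slope of the zero-intercept
#' regression of
#' \eqn{y_t = (\delta_{U1} - \delta_{1,t})(\delta_{2,t} - \delta_{F2})}
#' on
#' \eqn{x_t = (\delta_{1,t} - \delta_{F1})(\delta_{U2} - \delta_{2,t})},
#' the bilinear rearrangement of \eqn{k_{F1} = K k_{F2}} that avoids
#' dividing by near-zero shift differences. Then
#' \eqn{\Delta\Delta G = -R T_{m2} \ln K} with \eqn{T_{m2}} the
#' reference compound's melting temperature.
#'
#' Temperatures where either observed shift lies outside its terminals
#' are dropped with a warning.
#'
#' @param series1,series2 [shift_melt_series] on identical temperatures
#'   (compound 1 = the compound of interest, compound 2 = reference).
#' @param terminals1,terminals2 numeric `c(dU, dF)` per compound.
#' @param Tm2 reference compound melting temperature (K).
#' @return object of class `relative_stability`: `K_ratio`, `ddG`
#'   (J/mol), `slope_se`, `points` (data.frame of x, y).
#' @export
relative_folding <- function(series1, series2, terminals1, terminals2, Tm2) {
  stopifnot(inherits(series1, "shift_melt_series"),
            inherits(series2, "shift_melt_series"))
  if (!isTRUE(all.equal(series1$T_K, series2$T_K))) {
    stop("the two compounds must be observed at the same temperatures")
  }
  dU1 <- terminals1[1L]; dF1 <- terminals1[2L]
  dU2 <- terminals2[1L]; dF2 <- terminals2[2L]
  o1 <- series1$shift_ppm
  o2 <- series2$shift_ppm
  in1 <- o1 >= pmin(dU1, dF1) & o1 <= pmax(dU1, dF1)
  in2 <- o2 >= pmin(dU2, dF2) & o2 <= pmax(dU2, dF2)
  keep <- in1 & in2
  if (any(!keep)) {
    warning(sum(!keep), " temperature(s) dropped: shift outside terminals")
  }
  if (!any(keep)) stop("no usable temperatures: all shifts outside terminals")
  y <- (dU1 - o1[keep]) * (o2[keep] - dF2)
  x <- (o1[keep] - dF1) * (dU2 - o2[keep])
  reg <- stats::lm(y ~ x - 1)
  K <- unname(stats::coef(reg)[1L])
  # vcov warns on numerically perfect (noise-free) fits
  se <- suppressWarnings(sqrt(diag(stats::vcov(reg)))[1L])
  structure(list(K_ratio = K, ddG = -GAS_R * Tm2 * log(K),
                 slope_se = unname(se), Tm2 = Tm2,
                 points = data.frame(T_K = series1$T_K[keep], x = x, y = y)),
            class = "relative_stability")
}

#' @export
print.relative_stability <- function(x, ...) {
  cat(sprintf(
    "relative_stability: K_ratio = %.3f (se %.3g), ddG = %.3f kJ/mol at Tm2 = %.1f K\n",
    x$K_ratio, x$slope_se, x$ddG / 1000, x$Tm2))
  invisible(x)
}

#' Amide temperature coefficients and hydrogen-bonding class
#'
#' Linear regression of shift (ppm) on temperature (K) per proton; the
#' coefficient is the |slope| in ppb/K. Classes: below 3 ppb/K
#' "intramolecular H-bond", 3-5 ppb/K inclusive "dynamic equilibrium",
#' above 5 ppb/K "solvent exposed" (exact 3 and 5 fall in the middle
#' band).
#'
#' @param series_set list of [shift_melt_series], each with at least 3
#'   temperatures.
#' @return data.frame with `proton`, `coef_ppb_per_K`, `class`.
#' @export
temperature_coefficients <- function(series_set) {
  rows <- lapply(series_set, function(s) {
    if (length(s$T_K) < 3L) {
      stop("proton '", s$proton, "': need at least 3 temperatures")
    }
    sl <- unname(stats::coef(stats::lm(s$shift_ppm ~ s$T_K))[2L])
    coef_ppb <- abs(sl) * 1000
    cls <- if (coef_ppb < 3) "intramolecular H-bond"
           else if (coef_ppb <= 5) "dynamic equilibrium"
           else "solvent exposed"
    data.frame(proton = s$proton, coef_ppb_per_K = coef_ppb, class = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
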