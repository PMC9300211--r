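#' NOE build-ups and scalar-coupling restraints
#'
#' Cross-relaxation rates are extracted from NOESY build-up curves by
#' the initial-rate approximation (zero-intercept regression over the
#' linear regime), converted to distances against a fixed-distance
#' calibrant via sigma proportional to r^-6, and combined with
#' three-bond HN-HA couplings through a Karplus relation into the
#' population-averaged restraint set NAMFIS deconvolutes.
#'
#' @name restraints
NULL

#' One proton pair's NOE build-up
#'
#' @param pair character pair label (e.g. `"HA3-HA8"`).
#' @param tau_s mixing times, s, strictly increasing, all > 0.
#' @param intensity cross-peak intensities, arbitrary units.
#' @param reference logical: is this the calibration pair?
#' @return object of class `noe_buildup`.
#' @export
noe_buildup <- function(pair, tau_s, intensity, reference = FALSE) {
  stopifnot(length(tau_s) == length(intensity))
  if (length(tau_s) < 3L) stop("build-up '", pair, "' needs >= 3 mixing times")
  if (any(tau_s <= 0)) stop("mixing times must be positive")
  if (is.unsorted(tau_s, strictly = TRUE)) stop("mixing times must be strictly increasing")
  structure(list(pair = pair, tau_s = tau_s, intensity = intensity,
                 reference = isTRUE(reference)),
            class = "noe_buildup")
}

#' Read a build-up table
#'
#' Delimited text: first column mixing time in s, one column per proton
#' pair.
#'
#' @param path file path.
#' @param reference_pair column name of the calibration pair (optional).
#' @param sep field separator.
#' @return named list of [noe_buildup].
#' @export
read_buildup_table <- function(path, reference_pair = NULL, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  tau <- tab[[1L]]
  out <- lapply(names(tab)[-1L], function(p) {
    noe_buildup(p, tau, tab[[p]], reference = identical(p, reference_pair))
  })
  names(out) <- names(tab)[-1L]
  out
}

#' Write a build-up table
#' @param buildups named list of [noe_buildup] on one mixing-time grid.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_buildup_table <- function(buildups, path, sep = "\t") {
  tau <- buildups[[1L]]$tau_s
  tab <- data.frame(tau_s = tau)
  for (b in buildups) {
    stopifnot(identical(b$tau_s, tau))
    tab[[b$pair]] <- b$intensity
  }
  utils::write.table(format(tab, digits = 10), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Initial-rate cross-relaxation rate from a build-up
#'
#' Zero-intercept linear regression of intensity on mixing time over the
#' linear regime (the NOE intensity is zero at zero mixing time by
#' construction). If no window is given, the linear regime is the
#' largest prefix of mixing times (at least 3 points) whose
#' zero-intercept fit leaves every relative residual below
#' `linear_tol`. The reported standard error assumes noise
#' proportional to the intensity (cross-peak volumes carry relative,
#' not absolute, uncertainty), estimated from the relative residuals.
#'
#' @param b a [noe_buildup].
#' @param linear_window optional maximum mixing time (s) to include.
#' @param linear_tol relative-residual threshold for the automatic
#'   window (default 0.10).
#' @return list with `sigma` (intensity/s), `sigma_se`, `n_used`,
#'   `tau_max_used`.
#' @export
fit_initial_rate <- function(b, linear_window = NULL, linear_tol = 0.10) {
  stopifnot(inherits(b, "noe_buildup"))
  tau <- b$tau_s
  y <- b$intensity
  if (!is.null(linear_window)) {
    keep <- tau <= linear_window + 1e-9
    if (sum(keep) < 3L) stop("fewer than 3 points inside the window")
    ns <- sum(keep)
  } else {
    ns <- NA_integer_
    for (k in rev(seq_along(tau))) {
      if (k < 3L) break
      sl <- sum(y[1:k] * tau[1:k]) / sum(tau[1:k]^2)
      rel <- abs(sl * tau[1:k] - y[1:k]) / pmax(abs(y[1:k]), .Machine$double.eps)
      if (all(rel < linear_tol)) { ns <- k; break }
    }
    if (is.na(ns)) stop("no linear regime: no prefix of >= 3 points is linear")
  }
  tt <- tau[1:ns]
  yy <- y[1:ns]
  sl <- sum(yy * tt) / sum(tt^2)
  e <- yy - sl * tt
  # relative-noise error model: Var(sl) = sl^2 s_rel^2 sum(t^4)/sum(t^2)^2
  s_rel <- sqrt(sum((e / (sl * tt))^2) / max(ns - 1L, 1L))
  se <- abs(sl) * s_rel * sqrt(sum(tt^4)) / sum(tt^2)
  list(sigma = sl, sigma_se = se, n_used = ns, tau_max_used = tt[ns])
}

#' Calibrate cross-relaxation rates into distance restraints
#'
#' Isolated-spin-pair scaling sigma proportional to r^-6 against a
#' fixed-distance reference pair:
#' \eqn{r_{ij} = r_{ref} (\sigma_{ref}/\sigma_{ij})^{1/6}}.
#' Tolerances are `max(rel_tol * r, floor_A)`. Pairs with a
#' non-positive rate are skipped with a warning.
#'
#' @param rates named numeric vector of sigma per pair.
#' @param reference list/vector with `pair` (name) and `r_ref`
#'   (Angstrom; default 1.78, a geminal methylene pair).
#' @param rel_tol,floor_A tolerance rule (defaults 0.10 and 0.2).
#' @return data.frame of class `distance_restraints`: `pair`, `r_A`,
#'   `tol_A` (reference pair excluded).
#' @export
calibrate_distances <- function(rates, reference = list(pair = NULL, r_ref = 1.78),
                                rel_tol = 0.10, floor_A = 0.2) {
  ref_pair <- reference$pair
  if (is.null(ref_pair) || !ref_pair %in% names(rates)) {
    stop("reference pair missing from the rate table")
  }
  s_ref <- rates[[ref_pair]]
  if (!is.finite(s_ref) || s_ref <= 0) stop("reference rate must be positive")
  others <- setdiff(names(rates), ref_pair)
  rows <- list()
  for (p in others) {
    s <- rates[[p]]
    if (!is.finite(s) || s <= 0) {
      warning("pair '", p, "' skipped: non-positive rate")
      next
    }
    r <- reference$r_ref * (s_ref / s)^(1 / 6)
    rows[[p]] <- data.frame(pair = p, r_A = r,
                            tol_A = max(rel_tol * r, floor_A),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("distance_restraints", class(out))
  out
}

#' Karplus relation for three-bond couplings
#'
#' \eqn{J(\phi) = A \cos^2(\phi - 60^\circ) + B \cos(\phi - 60^\circ) + C}
#' with the backbone phase convention \eqn{\theta = \phi - 60^\circ}
#' relating the HN-N-CA-HA dihedral to phi. Default coefficients
#' (6.51, -1.76, 1.60) Hz, the Vuister-Bax parametrisation of
#' 3J(HN, HA).
#'
#' @param phi_deg backbone phi dihedral(s), degrees.
#' @param coeffs numeric `c(A, B, C)` in Hz.
#' @return 3J coupling(s), Hz.
#' @export
karplus_j <- function(phi_deg, coeffs = c(6.51, -1.76, 1.60)) {
  stopifnot(length(coeffs) == 3L, all(is.finite(coeffs)))
  ct <- cos(deg2rad(phi_deg - 60))
  coeffs[1L] * ct^2 + coeffs[2L] * ct + coeffs[3L]
}

#' Read / write restraint tables
#'
#' Delimited text with columns `key`, `value`, `tol` — distances in
#' Angstrom keyed by proton pair, couplings in Hz keyed by the residue's
#' phi dihedral label.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame `key`, `value`, `tol`.
#' @export
read_restraint_table <- function(path, sep = "\t") {
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_restraint_table
#' @param tab data.frame with `key`, `value`, `tol`.
#' @export
write_restraint_table <- function(tab, path, sep = "\t") {
  utils::write.table(format(tab, digits = 10), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a restraint set for NAMFIS
#'
#' @param distances data.frame `pair`, `r_A`, `tol_A` (as from
#'   [calibrate_distances()]).
#' @param jcouplings optional data.frame `dihedral`, `J_Hz`, `tol_Hz`
#'   (default J tolerance 0.5 Hz when the column is absent).
#' @return list of class `restraint_set`.
#' @export
restraint_set <- function(distances = NULL, jcouplings = NULL) {
  if (!is.null(distances)) {
    stopifnot(all(c("pair", "r_A", "tol_A") %in% names(distances)),
              all(distances$r_A > 0), all(distances$tol_A > 0))
  }
  if (!is.null(jcouplings)) {
    stopifnot(all(c("dihedral", "J_Hz") %in% names(jcouplings)))
    if (is.null(jcouplings$tol_Hz)) jcouplings$tol_Hz <- 0.5
  }
  n <- (if (is.null(distances)) 0L else nrow(distances)) +
       (if (is.null(jcouplings)) 0L else nrow(jcouplings))
  if (n < 1L) stop("restraint set is empty")
  structure(list(distances = distances, jcouplings = jcouplings),
            class = "restraint_set")
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("restraint_set: %d distance, %d J-coupling restraints\n",
              if (is.null(x$distances)) 0L else nrow(x$distances),
              if (is.null(x$jcouplings)) 0L else nrow(x$jcouplings)))
  invisible(x)
}
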