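# Shared fixtures and independent oracles used across the suite.

# small conformer made from explicit coordinates
toy_conformer <- function(xyz, labels, resno = NULL, model_id = 1L) {
  if (is.null(resno)) resno <- rep(1L, length(labels))
  conformer(model_id, data.frame(
    atom = labels, resno = resno, resid = "ALA",
    element = substr(labels, 1L, 1L),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE), check = FALSE)
}

# brute-force simplex grid search over a fixed sub-pool: minimum
# tolerance-weighted SSE at the given simplex resolution. Independent
# of the optimiser path: direct enumeration of grid points.
grid_sse_subpool <- function(restraints, poolobs, subset, step = 0.02,
                             coeffs = c(6.51, -1.76, 1.60), exponent = -6) {
  m <- length(subset)
  stopifnot(m == 3L)
  parts <- xbnmr:::namfis_sse_parts(restraints, poolobs, coeffs, exponent)
  parts <- xbnmr:::subset_parts(parts, subset)
  n_steps <- round(1 / step)
  best <- Inf
  for (i in 0:n_steps) {
    for (j in 0:(n_steps - i)) {
      p <- c(i, j, n_steps - i - j) * step
      sse <- xbnmr:::namfis_sse(p, parts)
      if (sse < best) best <- sse
    }
  }
  best
}

# brute-force grid over 2-conformer RDC ensembles: best chi2 at the
# given population resolution, tensor solved exactly at each grid point
grid_chi2_rdc_pair <- function(vectors_pair, D, sigma = NULL, step = 0.05,
                               Dmax = xbnmr:::DMAX_CH) {
  M1 <- t(vapply(vectors_pair[[1L]], build_design_row, numeric(5)))
  M2 <- t(vapply(vectors_pair[[2L]], build_design_row, numeric(5)))
  w <- if (!is.null(sigma) && all(sigma > 0)) 1 / sigma else rep(1, length(D))
  best <- Inf
  for (p1 in seq(0, 1, by = step)) {
    M <- p1 * M1 + (1 - p1) * M2
    Mw <- M * w
    s <- tryCatch(qr.solve(Mw, D * w), error = function(e) NULL)
    if (is.null(s)) next
    chi2 <- sum(((D - drop(M %*% s)) * w)^2)
    if (chi2 < best) best <- chi2
  }
  best
}

# default small noise-free dataset used by several tests
noise_free_config <- function(seed = 3L, ...) {
  generator_config(seed = seed, noise_shift = 0, noise_intensity = 0,
                   noise_rdc = 0, kappa = 0, ...)
}

default_pool_observables <- function(pool) {
  keys <- default_restraint_keys()
  pool_observables(pool, pairs = keys$pairs, phi_labels = keys$phi_labels)
}

# restraints generated directly from pool observables and known
# populations (bypasses the NOE simulation; exact averages)
exact_restraints <- function(poolobs, p, tol_r = 0.2, tol_j = 0.5) {
  avg <- predict_averages(p, poolobs)
  restraint_set(
    data.frame(pair = names(avg$r), r_A = unname(avg$r), tol_A = tol_r),
    data.frame(dihedral = names(avg$J), J_Hz = unname(avg$J), tol_Hz = tol_j))
}
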