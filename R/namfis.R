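#' NAMFIS-style ensemble deconvolution
#'
#' Population-averaged NOE distances and 3J couplings are deconvoluted
#' into a population-weighted subset of a rigid conformer pool: the
#' populations p (p_i >= 0, sum 1) minimise the tolerance-weighted sum
#' of squared residuals between observed and back-calculated averages,
#' with distance averaging over r^-6 (isolated spin pair, slow
#' tumbling) and linear averaging of Karplus-predicted couplings.
#'
#' @name namfis
NULL

#' Per-conformer observables for the restrained quantities
#'
#' Evaluates, for every conformer of the pool, the inter-proton distance
#' of every restrained pair and the phi dihedral of every restrained
#' coupling. Pair keys are two atom labels joined by `-` (e.g.
#' `"HA3-HA8"`); dihedral keys are `phi<resno>`, resolved to the
#' standard C(i-1)-N(i)-CA(i)-C(i) backbone atoms.
#'
#' @param pool list of [conformer] objects.
#' @param pairs character vector of pair keys.
#' @param phi_labels character vector of `phi<resno>` keys.
#' @return object of class `pool_observables`: list with `r` (n_conf x
#'   n_pairs matrix, Angstrom) and `phi` (n_conf x n_phi matrix,
#'   degrees), plus `model_ids`.
#' @export
pool_observables <- function(pool, pairs = character(), phi_labels = character()) {
  stopifnot(length(pool) >= 1L)
  pair_atoms <- lapply(pairs, function(p) strsplit(p, "-", fixed = TRUE)[[1L]])
  dihe_atoms <- lapply(phi_labels, function(lab) {
    n <- as.integer(sub("^phi", "", lab))
    if (is.na(n)) stop("unrecognised dihedral key: ", lab)
    c(paste0("C", n - 1L), paste0("N", n), paste0("CA", n), paste0("C", n))
  })
  r <- matrix(NA_real_, length(pool), length(pairs),
              dimnames = list(NULL, pairs))
  phi <- matrix(NA_real_, length(pool), length(phi_labels),
                dimnames = list(NULL, phi_labels))
  for (i in seq_along(pool)) {
    obs <- compute_observables(pool[[i]], distances = pair_atoms,
                               dihedrals = stats::setNames(dihe_atoms, phi_labels))
    if (length(pairs)) r[i, ] <- obs$distances
    if (length(phi_labels)) phi[i, ] <- obs$dihedrals
  }
  structure(list(r = r, phi = phi,
                 model_ids = vapply(pool, function(cf) cf$model_id, 1L)),
            class = "pool_observables")
}

#' Back-calculated population averages
#'
#' Distances average as \eqn{\langle r \rangle = (\sum_i p_i
#' r_i^{x})^{1/x}} with exponent x = -6 by default (configurable to
#' -3); couplings average linearly over the Karplus-predicted values.
#'
#' @param p populations on the simplex (length = pool size).
#' @param poolobs a [pool_observables].
#' @param coeffs Karplus coefficients, see [karplus_j()].
#' @param exponent distance-averaging exponent (default -6).
#' @return list with `r` (named, Angstrom) and `J` (named, Hz).
#' @export
predict_averages <- function(p, poolobs, coeffs = c(6.51, -1.76, 1.60),
                             exponent = -6) {
  stopifnot(length(p) == nrow(poolobs$r) || length(p) == nrow(poolobs$phi))
  if (abs(sum(p) - 1) > 1e-6 || any(p < -1e-12)) {
    stop("populations must lie on the simplex")
  }
  r_avg <- NULL
  if (ncol(poolobs$r)) {
    if (any(poolobs$r <= 0)) stop("non-positive distance in the pool")
    r_avg <- drop(p %*% poolobs$r^exponent)^(1 / exponent)
  }
  j_avg <- NULL
  if (ncol(poolobs$phi)) {
    j_avg <- drop(p %*% karplus_j(poolobs$phi, coeffs))
  }
  list(r = r_avg, J = j_avg)
}

# Weighted SSE and its gradient in p -------------------------------------

namfis_sse_parts <- function(restraints, poolobs, coeffs, exponent) {
  # precompute matrices so the objective is cheap inside the optimiser
  A <- NULL; r_obs <- NULL; r_tol <- NULL
  if (!is.null(restraints$distances) && nrow(restraints$distances)) {
    keys <- restraints$distances$pair
    miss <- setdiff(keys, colnames(poolobs$r))
    if (length(miss)) stop("pool lacks restrained pairs: ",
                           paste(miss, collapse = ", "))
    A <- poolobs$r[, keys, drop = FALSE]^exponent
    r_obs <- restraints$distances$r_A
    r_tol <- restraints$distances$tol_A
  }
  B <- NULL; j_obs <- NULL; j_tol <- NULL
  if (!is.null(restraints$jcouplings) && nrow(restraints$jcouplings)) {
    keys <- restraints$jcouplings$dihedral
    miss <- setdiff(keys, colnames(poolobs$phi))
    if (length(miss)) stop("pool lacks restrained dihedrals: ",
                           paste(miss, collapse = ", "))
    B <- karplus_j(poolobs$phi[, keys, drop = FALSE], coeffs)
    j_obs <- restraints$jcouplings$J_Hz
    j_tol <- restraints$jcouplings$tol_Hz
  }
  list(A = A, r_obs = r_obs, r_tol = r_tol,
       B = B, j_obs = j_obs, j_tol = j_tol, exponent = exponent)
}

namfis_sse <- function(p, parts) {
  sse <- 0
  if (!is.null(parts$A)) {
    pred <- drop(p %*% parts$A)^(1 / parts$exponent)
    sse <- sse + sum(((parts$r_obs - pred) / parts$r_tol)^2)
  }
  if (!is.null(parts$B)) {
    pred <- drop(p %*% parts$B)
    sse <- sse + sum(((parts$j_obs - pred) / parts$j_tol)^2)
  }
  sse
}

namfis_sse_grad <- function(p, parts) {
  g <- numeric(length(p))
  x <- parts$exponent
  if (!is.null(parts$A)) {
    s <- drop(p %*% parts$A)
    pred <- s^(1 / x)
    # d pred / d p_i = (1/x) s^(1/x - 1) A_i
    w <- -2 * (parts$r_obs - pred) / parts$r_tol^2 * (1 / x) * s^(1 / x - 1)
    g <- g + drop(parts$A %*% w)
  }
  if (!is.null(parts$B)) {
    pred <- drop(p %*% parts$B)
    w <- -2 * (parts$j_obs - pred) / parts$j_tol^2
    g <- g + drop(parts$B %*% w)
  }
  g
}

# one BFGS run in the z-parametrisation p = z^2 / sum(z^2)
namfis_one_start <- function(z0, parts) {
  n <- length(z0)
  fn <- function(z) {
    s2 <- sum(z^2)
    if (s2 < 1e-300) return(1e300)
    namfis_sse(z^2 / s2, parts)
  }
  gr <- function(z) {
    s2 <- sum(z^2)
    p <- z^2 / s2
    gp <- namfis_sse_grad(p, parts)
    # dp_j/dz_i = (2 z_i / s2) (delta_ij - p_j)
    (2 * z / s2) * (gp - sum(gp * p))
  }
  res <- stats::optim(z0, fn, gr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  p <- res$par^2 / sum(res$par^2)
  list(p = p, sse = namfis_sse(p, parts))
}

#' Fit conformer populations to a restraint set
#'
#' Minimises the tolerance-weighted SSE over the probability simplex by
#' quasi-Newton optimisation in a squared-variable parametrisation
#' (p_i = z_i^2 / sum z^2), from a uniform start plus `n_starts`
#' Dirichlet-random starts under a fixed seed. A single prune-and-refit
#' pass zeroes populations below `prune` and refits on the survivors.
#' Ties between solutions with equal SSE (to 1e-10) are broken by
#' fewest non-zero conformers, then lowest conformer index, so the
#' output is deterministic.
#'
#' @param restraints a [restraint_set].
#' @param poolobs a [pool_observables].
#' @param coeffs Karplus coefficients.
#' @param exponent distance-averaging exponent (default -6).
#' @param n_starts number of random restarts (default 10).
#' @param seed RNG seed for the restarts (default 1234).
#' @param prune population threshold below which conformers are dropped
#'   (default 0.01).
#' @return object of class `ensemble_solution`: `p` (full pool,
#'   pruned+renormalised), `sse`, `residuals` (data.frame key/type/
#'   obs/pred/tol), `selected` (indices with p above `prune`),
#'   `model_ids`.
#' @export
fit_populations <- function(restraints, poolobs, coeffs = c(6.51, -1.76, 1.60),
                            exponent = -6, n_starts = 10, seed = 1234,
                            prune = 0.01) {
  stopifnot(inherits(restraints, "restraint_set"),
            inherits(poolobs, "pool_observables"))
  n <- length(poolobs$model_ids)
  parts <- namfis_sse_parts(restraints, poolobs, coeffs, exponent)
  if (n == 1L) {
    p <- 1
    return(ensemble_solution_obj(p, parts, poolobs, restraints, coeffs, exponent))
  }
  starts <- list(rep(1 / sqrt(n), n))
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (k in seq_len(n_starts)) {
    d <- stats::rgamma(n, 1)   # Dirichlet(1) populations
    starts[[k + 1L]] <- sqrt(d / sum(d))
  }
  sols <- lapply(starts, function(z0) {
    tryCatch(namfis_one_start(z0, parts), error = function(e) NULL)
  })
  sols <- Filter(Negate(is.null), sols)
  if (!length(sols)) stop("population fit failed from every start")
  best <- pick_best_solution(sols)
  # prune and refit restricted to survivors
  keep <- which(best$p >= prune)
  if (length(keep) < n && length(keep) >= 1L) {
    if (length(keep) == 1L) {
      p2 <- numeric(n)
      p2[keep] <- 1
      best <- list(p = p2, sse = namfis_sse(p2, parts))
    } else {
      sub_parts <- subset_parts(parts, keep)
      z0 <- sqrt(best$p[keep] / sum(best$p[keep]))
      sub <- namfis_one_start(z0, sub_parts)
      p2 <- numeric(n)
      p2[keep] <- sub$p
      best <- list(p = p2, sse = sub$sse)
    }
  }
  ensemble_solution_obj(best$p, parts, poolobs, restraints, coeffs, exponent,
                        prune = prune)
}

subset_parts <- function(parts, keep) {
  out <- parts
  if (!is.null(out$A)) out$A <- out$A[keep, , drop = FALSE]
  if (!is.null(out$B)) out$B <- out$B[keep, , drop = FALSE]
  out
}

pick_best_solution <- function(sols, tol = 1e-10) {
  sses <- vapply(sols, function(s) s$sse, 1)
  cand <- which(sses <= min(sses) + tol)
  if (length(cand) > 1L) {
    nz <- vapply(sols[cand], function(s) sum(s$p > 1e-8), 1L)
    cand <- cand[nz == min(nz)]
    if (length(cand) > 1L) {
      # lowest occupied conformer index wins
      firsts <- vapply(sols[cand], function(s) which(s$p > 1e-8)[1L], 1L)
      cand <- cand[order(firsts)]
    }
  }
  sols[[cand[1L]]]
}

ensemble_solution_obj <- function(p, parts, poolobs, restraints, coeffs,
                                  exponent, prune = 0.01) {
  pred <- predict_averages(p, poolobs, coeffs, exponent)
  rows <- list()
  if (!is.null(restraints$distances) && nrow(restraints$distances)) {
    d <- restraints$distances
    rows[[1L]] <- data.frame(key = d$pair, type = "distance", obs = d$r_A,
                             pred = unname(pred$r[d$pair]), tol = d$tol_A)
  }
  if (!is.null(restraints$jcouplings) && nrow(restraints$jcouplings)) {
    j <- restraints$jcouplings
    rows[[2L]] <- data.frame(key = j$dihedral, type = "J", obs = j$J_Hz,
                             pred = unname(pred$J[j$dihedral]), tol = j$tol_Hz)
  }
  resid <- do.call(rbind, rows)
  resid$weighted <- (resid$obs - resid$pred) / resid$tol
  structure(list(p = p, sse = namfis_sse(p, parts), residuals = resid,
                 selected = which(p >= prune),
                 model_ids = poolobs$model_ids),
            class = "ensemble_solution")
}

#' @export
print.ensemble_solution <- function(x, ...) {
  cat(sprintf("ensemble_solution: %d/%d conformers populated, SSE = %.4g\n",
              length(x$selected), length(x$p), x$sse))
  for (i in x$selected) {
    cat(sprintf("  model %d: p = %.3f\n", x$model_ids[i], x$p[i]))
  }
  invisible(x)
}

#' Jackknife stability of fitted populations
#'
#' Refits the populations on `n_reps` random restraint subsets (each
#' leaving out a `fraction` share of the restraints) and summarises the
#' spread of every conformer's population. Deterministic under the
#' seed.
#'
#' @param restraints a [restraint_set].
#' @param poolobs a [pool_observables].
#' @param fraction share of restraints left out per replicate.
#' @param n_reps number of replicates (>= 2).
#' @param seed RNG seed.
#' @param ... passed to [fit_populations()].
#' @return data.frame with `conformer`, `median`, `iqr`, plus the full
#'   replicate matrix as attribute `"replicates"`.
#' @export
jackknife_stability <- function(restraints, poolobs, fraction = 0.2,
                                n_reps = 20, seed = 1234, ...) {
  if (n_reps < 2L) stop("need at least 2 replicates")
  nd <- if (is.null(restraints$distances)) 0L else nrow(restraints$distances)
  nj <- if (is.null(restraints$jcouplings)) 0L else nrow(restraints$jcouplings)
  ntot <- nd + nj
  n_drop <- floor(fraction * ntot)
  if (ntot - n_drop < 1L) stop("leave-out fraction removes every restraint")
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  drops <- lapply(seq_len(n_reps), function(k) {
    if (n_drop == 0L) integer() else sample.int(ntot, n_drop)
  })
  n <- length(poolobs$model_ids)
  reps <- matrix(NA_real_, n_reps, n)
  for (k in seq_len(n_reps)) {
    keep <- setdiff(seq_len(ntot), drops[[k]])
    dsub <- if (nd) restraints$distances[keep[keep <= nd], , drop = FALSE] else NULL
    jsub <- if (nj) restraints$jcouplings[keep[keep > nd] - nd, , drop = FALSE] else NULL
    if (!is.null(dsub) && !nrow(dsub)) dsub <- NULL
    if (!is.null(jsub) && !nrow(jsub)) jsub <- NULL
    rs <- restraint_set(dsub, jsub)
    sol <- fit_populations(rs, poolobs, ...)
    reps[k, ] <- sol$p
  }
  out <- data.frame(conformer = poolobs$model_ids,
                    median = apply(reps, 2L, stats::median),
                    iqr = apply(reps, 2L, stats::IQR))
  attr(out, "replicates") <- reps
  out
}

#' Population share of folded / halogen-bonded conformers
#'
#' @param solution an `ensemble_solution`.
#' @param labels list of `fold_label` objects aligned with the pool.
#' @return list with `folded_share`, `xb_share`.
#' @export
folded_share <- function(solution, labels) {
  stopifnot(length(labels) == length(solution$p))
  fold <- vapply(labels, function(l) isTRUE(l$folded), TRUE)
  xb <- vapply(labels, function(l) isTRUE(l$halogen_bonded), TRUE)
  list(folded_share = sum(solution$p[fold]), xb_share = sum(solution$p[xb]))
}

# seed bracketing without depending on withr ------------------------------

withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible()
}
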