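#' Residual dipolar coupling analysis
#'
#' RDCs (1D_CH) are extracted as the difference between the total
#' coupling measured under weak alignment (1T_CH) and the isotropic
#' scalar coupling (1J_CH), scaled by the number of equivalent protons.
#' Each coupling constrains the orientation of its C-H internuclear
#' vector through the traceless symmetric Saupe order matrix (5 free
#' elements), which is fitted linearly by singular value decomposition.
#' Fit quality is scored by the Cornilescu quality factor Q and the
#' design-matrix condition number; population-weighted sub-ensembles
#' sharing one alignment tensor are selected by a chi-square penalty.
#'
#' @name rdc
NULL

# D_max for a directly bonded C-H at 1.09 A; the tensor absorbs overall
# scale, so only the interpretation of tensor magnitude depends on it.
DMAX_CH <- -22700

#' RDC from measured couplings
#'
#' \eqn{D = (T - J)/n_H} with uncertainty
#' \eqn{\sqrt{\sigma_T^2 + \sigma_J^2}/n_H}.
#'
#' @param J scalar coupling 1J_CH, Hz.
#' @param T_Hz total coupling 1T_CH under alignment, Hz.
#' @param n_H multiplicity of the group (1 = CH, 2 = CH2, 3 = CH3).
#' @param sigma_J,sigma_T measurement uncertainties, Hz.
#' @return list with `D` (Hz) and `sigma` (Hz).
#' @export
rdc_from_couplings <- function(J, T_Hz, n_H = 1L, sigma_J = 0, sigma_T = 0) {
  if (!all(n_H %in% c(1L, 2L, 3L))) stop("multiplicity must be 1, 2 or 3")
  list(D = (T_Hz - J) / n_H, sigma = sqrt(sigma_T^2 + sigma_J^2) / n_H)
}

#' Read an RDC table
#'
#' Delimited text with columns `label`, `n_H`, `J_Hz`, `sigma_J`,
#' `T_Hz`, `sigma_T` (Hz), mirroring the layout of a coupled/uncoupled
#' HSQC measurement table; derives `D_Hz` and `sigma_D`.
#'
#' @param path file path.
#' @param sep field separator.
#' @return data.frame with the input columns plus `D_Hz`, `sigma_D`.
#' @export
read_rdc_table <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("label", "n_H", "J_Hz", "sigma_J", "T_Hz", "sigma_T")
  if (!all(need %in% names(tab))) {
    stop("RDC table needs columns: ", paste(need, collapse = ", "))
  }
  d <- rdc_from_couplings(tab$J_Hz, tab$T_Hz, tab$n_H, tab$sigma_J, tab$sigma_T)
  tab$D_Hz <- d$D
  tab$sigma_D <- d$sigma
  tab
}

#' @rdname read_rdc_table
#' @param tab data.frame with the six input columns.
#' @export
write_rdc_table <- function(tab, path, sep = "\t") {
  cols <- c("label", "n_H", "J_Hz", "sigma_J", "T_Hz", "sigma_T")
  utils::write.table(format(tab[, cols], digits = 10), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Design row of one internuclear unit vector
#'
#' Losonczi parametrisation: for direction cosines (c_x, c_y, c_z) the
#' row is (c_y^2 - c_x^2, c_z^2 - c_x^2, 2 c_x c_y, 2 c_x c_z,
#' 2 c_y c_z), so that D = D_max (row . s) for the Saupe 5-vector
#' s = (S_yy, S_zz, S_xy, S_xz, S_yz). Rows are invariant under
#' v -> -v (dipolar symmetry).
#'
#' @param v unit 3-vector (checked to 1e-9).
#' @return numeric length-5 row.
#' @export
build_design_row <- function(v) {
  if (abs(vnorm(v) - 1) > 1e-9) stop("internuclear vector must be unit length")
  c(v[2L]^2 - v[1L]^2, v[3L]^2 - v[1L]^2,
    2 * v[1L] * v[2L], 2 * v[1L] * v[3L], 2 * v[2L] * v[3L])
}

#' Cornilescu quality factor
#'
#' \eqn{Q = \mathrm{rms}(D_{obs} - D_{calc}) / \mathrm{rms}(D_{obs})};
#' Q below 30% conventionally indicates a good tensor fit.
#'
#' @param D_obs,D_calc observed and back-calculated RDCs, Hz.
#' @return Q (dimensionless).
#' @export
q_factor <- function(D_obs, D_calc) {
  sqrt(mean((D_obs - D_calc)^2)) / sqrt(mean(D_obs^2))
}

design_matrix <- function(vectors) {
  m <- t(vapply(vectors, build_design_row, numeric(5)))
  rownames(m) <- names(vectors)
  m
}

#' Reassemble the Saupe matrix from its 5-vector
#' @noRd
saupe_matrix <- function(s) {
  syy <- s[1L]; szz <- s[2L]
  sxx <- -syy - szz
  matrix(c(sxx, s[3L], s[4L],
           s[3L], syy, s[5L],
           s[4L], s[5L], szz), 3, 3, byrow = TRUE)
}

#' Alignment tensor from a Saupe 5-vector
#'
#' Eigen-decomposes the traceless symmetric matrix, orders eigenvalues
#' by |A_zz| >= |A_yy| >= |A_xx|, and derives the axial component
#' D_a = A_zz/2, the rhombic component D_r = (A_xx - A_yy)/3 and the
#' rhombicity R = D_r/D_a (|R| <= 2/3).
#'
#' @param s Saupe 5-vector (S_yy, S_zz, S_xy, S_xz, S_yz).
#' @return object of class `alignment_tensor`: `s`, `matrix`,
#'   `eigenvalues` (named A_xx, A_yy, A_zz), `axes` (columns =
#'   principal axes), `Da`, `Dr`, `rhombicity`.
#' @export
alignment_tensor <- function(s) {
  stopifnot(length(s) == 5L, all(is.finite(s)))
  m <- saupe_matrix(s)
  e <- eigen(m, symmetric = TRUE)
  o <- order(abs(e$values))   # |A_xx| <= |A_yy| <= |A_zz|
  ev <- e$values[o]
  names(ev) <- c("A_xx", "A_yy", "A_zz")
  Da <- ev[["A_zz"]] / 2
  Dr <- (ev[["A_xx"]] - ev[["A_yy"]]) / 3
  structure(list(s = s, matrix = m, eigenvalues = ev,
                 axes = e$vectors[, o, drop = FALSE],
                 Da = Da, Dr = Dr,
                 rhombicity = if (Da != 0) Dr / Da else NA_real_),
            class = "alignment_tensor")
}

#' @export
print.alignment_tensor <- function(x, ...) {
  cat(sprintf(
    "alignment_tensor: A_zz = %.3e, A_yy = %.3e, A_xx = %.3e (R = %.3f)\n",
    x$eigenvalues[["A_zz"]], x$eigenvalues[["A_yy"]],
    x$eigenvalues[["A_xx"]], x$rhombicity))
  invisible(x)
}

#' Fit an alignment tensor to RDCs by singular value decomposition
#'
#' Weighted linear least squares of D = D_max M s over the Saupe
#' 5-vector, solved through the SVD of the weighted design matrix.
#' Reports the Cornilescu quality factor
#' Q = rms(D_obs - D_calc) / rms(D_obs), the design-matrix condition
#' number sigma_max/sigma_min, and chi^2 = sum((D_obs - D_calc)/
#' sigma)^2.
#'
#' @param D observed RDCs, Hz (>= 5 values).
#' @param vectors list of unit 3-vectors, same order as `D`.
#' @param sigma per-observation uncertainties, Hz (used for chi^2; the
#'   fit weights are 1/sigma when all sigma > 0, else unweighted).
#' @param Dmax dipolar interaction constant (default `-22700` Hz for a
#'   1.09-Angstrom C-H; the tensor absorbs scale).
#' @return list of class `rdc_fit`: `tensor` ([alignment_tensor]),
#'   `report` (data.frame label/D_obs/D_calc/residual), `Q`,
#'   `condition_number`, `chi2`.
#' @export
svd_fit <- function(D, vectors, sigma = NULL, Dmax = DMAX_CH) {
  stopifnot(length(D) == length(vectors))
  if (length(D) < 5L) stop("need at least 5 RDCs to determine 5 tensor elements")
  M <- design_matrix(vectors)
  w <- if (!is.null(sigma) && all(sigma > 0)) 1 / sigma else rep(1, length(D))
  Mw <- M * w
  sv <- svd(Mw)
  if (min(sv$d) < 1e-10 * max(sv$d)) {
    null_dir <- sv$v[, which.min(sv$d)]
    stop("degenerate vector geometry: design rank < 5 (null direction ",
         paste(signif(null_dir, 3), collapse = ", "), ")")
  }
  s <- drop(sv$v %*% ((t(sv$u) %*% (w * D)) / sv$d)) / Dmax
  D_calc <- drop(M %*% s) * Dmax
  resid <- D - D_calc
  Q <- sqrt(mean(resid^2)) / sqrt(mean(D^2))
  chi2 <- if (!is.null(sigma) && all(sigma > 0)) sum((resid / sigma)^2)
          else sum(resid^2)
  labs <- names(vectors)
  if (is.null(labs)) labs <- paste0("v", seq_along(D))
  structure(list(tensor = alignment_tensor(s),
                 report = data.frame(label = labs, D_obs = D,
                                     D_calc = D_calc, residual = resid),
                 Q = Q, condition_number = max(sv$d) / min(sv$d),
                 chi2 = chi2),
            class = "rdc_fit")
}

#' @export
print.rdc_fit <- function(x, ...) {
  cat(sprintf("rdc_fit: %d RDCs, Q = %.4f, condition number = %.3f, chi2 = %.4g\n",
              nrow(x$report), x$Q, x$condition_number, x$chi2))
  invisible(x)
}

# simplex-constrained least squares min ||d - A p||, p >= 0, sum p = 1.
# Exact for small m by enumeration of support sets (the optimum restricted
# to its own support is the equality-constrained solution there).
simplex_lsq <- function(A, d) {
  m <- ncol(A)
  if (m == 1L) return(1)
  best_p <- NULL
  best_f <- Inf
  for (mask in seq_len(2^m - 1L)) {
    S <- which(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L)
    As <- A[, S, drop = FALSE]
    k <- length(S)
    kkt <- rbind(cbind(2 * crossprod(As), rep(1, k)), c(rep(1, k), 0))
    rhs <- c(2 * crossprod(As, d), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    ps <- sol[seq_len(k)]
    if (any(ps < -1e-10)) next
    ps[ps < 0] <- 0
    ps <- ps / sum(ps)
    f <- sum((d - drop(As %*% ps))^2)
    if (f < best_f - 1e-14) {
      best_f <- f
      best_p <- numeric(m)
      best_p[S] <- ps
    }
  }
  if (is.null(best_p)) stop("simplex least squares found no feasible support")
  best_p
}

#' Ensemble RDC fit: shared tensor, population weights
#'
#' Model: \eqn{D_k = D_{max} \sum_i p_i (row_k^{(i)} \cdot s)} with one
#' shared alignment tensor s over the candidate conformers. Solved by
#' alternating linear solves — for fixed p the tensor comes from
#' [svd_fit()] on the population-averaged design rows; for fixed s the
#' populations come from simplex-constrained least squares — iterated
#' to a chi-square change below `tol`, from `n_starts` seeded
#' Dirichlet-random starts plus the uniform start; best chi-square
#' wins. A single candidate reduces exactly to [svd_fit()].
#'
#' @param pool_vectors list over conformers; each element a named list
#'   of unit 3-vectors (one per observed label, identical names).
#' @param D observed RDCs, Hz, aligned with the vector labels of the
#'   first conformer.
#' @param sigma per-observation uncertainties, Hz.
#' @param candidate_ids indices into `pool_vectors` to fit over
#'   (default all).
#' @param Dmax see [svd_fit()].
#' @param n_starts,seed multi-start control.
#' @param tol convergence tolerance on chi-square (default 1e-8).
#' @param max_iter iteration cap per start (default 500).
#' @return list of class `ensemble_rdc_fit`: `p` (over candidates),
#'   `candidate_ids`, `tensor`, `fit` (an `rdc_fit` on the averaged
#'   rows), `chi2`, `converged`.
#' @export
ensemble_rdc_fit <- function(pool_vectors, D, sigma = NULL,
                             candidate_ids = seq_along(pool_vectors),
                             Dmax = DMAX_CH, n_starts = 10, seed = 1234,
                             tol = 1e-8, max_iter = 500, .design = NULL) {
  m <- length(candidate_ids)
  stopifnot(m >= 1L)
  if (is.null(.design)) {
    cands <- pool_vectors[candidate_ids]
    labs <- names(cands[[1L]])
    Ms <- lapply(cands, function(vl) {
      if (!identical(names(vl), labs)) {
        stop("every candidate conformer must supply every observed vector")
      }
      design_matrix(vl)
    })
  } else {
    Ms <- .design[candidate_ids]
  }
  if (m == 1L) {
    f <- svd_fit_rows(D, Ms[[1L]], sigma, Dmax)
    out <- list(p = 1, candidate_ids = candidate_ids, tensor = f$tensor,
                fit = f, chi2 = f$chi2, converged = TRUE)
    class(out) <- "ensemble_rdc_fit"
    return(out)
  }
  w <- if (!is.null(sigma) && all(sigma > 0)) 1 / sigma else rep(1, length(D))
  starts <- list(rep(1 / m, m))
  old <- withr_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (k in seq_len(n_starts)) {
    d <- stats::rgamma(m, 1)
    starts[[k + 1L]] <- d / sum(d)
  }
  Dw <- D * w
  best <- NULL
  for (p0 in starts) {
    p <- pmax(p0, 1e-6)
    p <- p / sum(p)
    chi_prev <- Inf
    ok <- FALSE
    failed <- FALSE
    for (it in seq_len(max_iter)) {
      Mavg <- Reduce(`+`, Map(`*`, Ms, p))
      # lean weighted least squares for the tensor step
      ls <- stats::.lm.fit(Mavg * w, Dw)
      if (any(is.na(ls$coefficients)) || ls$rank < 5L) { failed <- TRUE; break }
      s <- ls$coefficients / Dmax
      # per-conformer back-calculated D for the current tensor
      A <- vapply(Ms, function(Mi) drop(Mi %*% s) * Dmax, numeric(length(D)))
      p_new <- simplex_lsq(A * w, Dw)
      p_new <- pmax(p_new, 0)
      p_new <- p_new / sum(p_new)
      chi <- sum(((D - drop(A %*% p_new)) * w)^2)
      p <- p_new
      if (abs(chi_prev - chi) < tol) { ok <- TRUE; chi_prev <- chi; break }
      chi_prev <- chi
    }
    if (failed) next
    if (is.null(best) || chi_prev < best$chi2) {
      best <- list(p = p, chi2 = chi_prev, converged = ok)
    }
  }
  if (is.null(best)) stop("ensemble RDC fit did not converge from any start")
  # final tensor refit at the converged populations
  Mavg <- Reduce(`+`, Map(`*`, Ms, best$p))
  fit <- svd_fit_rows(D, Mavg, sigma, Dmax)
  structure(list(p = best$p, candidate_ids = candidate_ids,
                 tensor = fit$tensor, fit = fit, chi2 = fit$chi2,
                 converged = best$converged),
            class = "ensemble_rdc_fit")
}

# svd_fit on a precomputed design matrix (rows already averaged)
svd_fit_rows <- function(D, M, sigma = NULL, Dmax = DMAX_CH) {
  w <- if (!is.null(sigma) && all(sigma > 0)) 1 / sigma else rep(1, length(D))
  Mw <- M * w
  sv <- svd(Mw)
  if (min(sv$d) < 1e-10 * max(sv$d)) {
    stop("degenerate vector geometry: averaged design rank < 5")
  }
  s <- drop(sv$v %*% ((t(sv$u) %*% (w * D)) / sv$d)) / Dmax
  D_calc <- drop(M %*% s) * Dmax
  resid <- D - D_calc
  labs <- rownames(M)
  if (is.null(labs)) labs <- paste0("v", seq_along(D))
  structure(list(tensor = alignment_tensor(s),
                 report = data.frame(label = labs, D_obs = D,
                                     D_calc = D_calc, residual = resid),
                 Q = sqrt(mean(resid^2)) / sqrt(mean(D^2)),
                 condition_number = max(sv$d) / min(sv$d),
                 chi2 = if (!is.null(sigma) && all(sigma > 0))
                   sum((resid / sigma)^2) else sum(resid^2)),
            class = "rdc_fit")
}

#' @export
print.ensemble_rdc_fit <- function(x, ...) {
  cat(sprintf(
    "ensemble_rdc_fit: %d candidates, chi2 = %.4g, Q = %.4f (converged: %s)\n",
    length(x$p), x$chi2, x$fit$Q, x$converged))
  invisible(x)
}

#' Sub-ensemble model selection by penalised chi-square
#'
#' For m = 1..`max_size`, finds the best-fitting m-conformer
#' sub-ensemble (exhaustive over all subsets while
#' `choose(pool, m)` stays within `exhaustive_limit`; greedy forward
#' selection beyond) and scores it by chi^2 + lambda k with
#' k = 5 + (m - 1) free parameters. Because each size's chi-square is
#' a minimum over many candidate subsets, a plain AIC penalty
#' (lambda = 2) systematically overfits; the default lambda is the
#' extended-BIC form for best-subset selection,
#' `log(n_obs) + 2 log(n_pool)`, which accounts for the size of the
#' searched model space. `lambda = 2` (AIC) and `lambda = log(n_obs)`
#' (BIC) remain available by argument.
#'
#' @param pool_vectors,D,sigma,Dmax,seed see [ensemble_rdc_fit()].
#' @param max_size largest sub-ensemble to consider.
#' @param lambda penalty per free parameter; `NULL` (default) uses
#'   `log(length(D)) + 2 * log(length(pool_vectors))`.
#' @param n_starts multi-starts for each inner ensemble fit (default 3;
#'   the inner problems are small and smooth).
#' @param exhaustive_limit largest subset count searched exhaustively
#'   per size (default 3003 = choose(15, 5)... capped well above the
#'   pools used here).
#' @return list of class `rdc_model_selection`: `best` (the winning
#'   `ensemble_rdc_fit`), `best_size`, `table` (per-size data.frame
#'   with chi2, penalised score, member ids).
#' @export
model_select <- function(pool_vectors, D, sigma = NULL, max_size = 4,
                         lambda = NULL, Dmax = DMAX_CH, n_starts = 3,
                         seed = 1234, exhaustive_limit = 3003) {
  n <- length(pool_vectors)
  if (n < 1L) stop("empty conformer pool")
  if (is.null(lambda)) lambda <- log(length(D)) + 2 * log(n)
  max_size <- min(max_size, n)
  designs <- lapply(pool_vectors, design_matrix)
  rows <- list()
  fits <- list()
  for (m in seq_len(max_size)) {
    n_subsets <- choose(n, m)
    if (n_subsets <= exhaustive_limit) {
      subsets <- utils::combn(n, m, simplify = FALSE)
    } else {
      # greedy forward: extend the previous size's winner by each
      # remaining conformer
      prev <- if (m == 1L) integer() else fits[[m - 1L]]$candidate_ids
      subsets <- lapply(setdiff(seq_len(n), prev), function(i) sort(c(prev, i)))
    }
    best_m <- NULL
    for (S in subsets) {
      f <- tryCatch(
        ensemble_rdc_fit(pool_vectors, D, sigma, candidate_ids = S,
                         Dmax = Dmax, n_starts = n_starts, seed = seed,
                         .design = designs),
        error = function(e) NULL)
      if (is.null(f)) next
      if (is.null(best_m) || f$chi2 < best_m$chi2) best_m <- f
    }
    if (is.null(best_m)) stop("no fittable sub-ensemble of size ", m)
    fits[[m]] <- best_m
    rows[[m]] <- data.frame(
      size = m, chi2 = best_m$chi2,
      score = best_m$chi2 + lambda * (5 + m - 1),
      members = paste(best_m$candidate_ids, collapse = ","))
  }
  tab <- do.call(rbind, rows)
  best_size <- tab$size[which.min(tab$score)]
  structure(list(best = fits[[best_size]], best_size = best_size, table = tab),
            class = "rdc_model_selection")
}

#' @export
print.rdc_model_selection <- function(x, ...) {
  cat(sprintf("rdc_model_selection: best size = %d\n", x$best_size))
  print(x$table, row.names = FALSE)
  invisible(x)
}
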