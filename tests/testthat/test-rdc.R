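rand_unit <- function() { v <- rnorm(3); v / sqrt(sum(v^2)) }

test_that("RDC extraction matches the printed coupling differences", {
  # CH: D = T - J
  expect_equal(rdc_from_couplings(158.6, 107.7, 1L)$D, -50.9, tolerance = 1e-9)
  expect_equal(rdc_from_couplings(138.9, 196.4, 1L)$D, 57.5, tolerance = 1e-9)
  # CH3: D = (T - J)/3, printed to 1 d.p.
  expect_equal(round(rdc_from_couplings(416.6, 434.7, 3L)$D, 1), 6.0)
  # isotropic limit
  for (n in 1:3) expect_equal(rdc_from_couplings(145, 145, n)$D, 0)
  # uncertainty propagation
  expect_equal(rdc_from_couplings(100, 110, 2L, 0.3, 0.4)$sigma,
               sqrt(0.25) / 2, tolerance = 1e-12)
  expect_error(rdc_from_couplings(100, 110, 4L), "multiplicity")
})

test_that("design rows follow the Losonczi parametrisation and dipolar symmetry", {
  expect_equal(build_design_row(c(0, 0, 1)), c(0, 1, 0, 0, 0))
  expect_equal(build_design_row(c(1, 0, 0)), c(-1, -1, 0, 0, 0))
  set.seed(5)
  for (k in 1:10) {
    v <- rand_unit()
    expect_equal(build_design_row(v), build_design_row(-v), tolerance = 1e-12)
  }
  expect_error(build_design_row(c(1, 1, 0)), "unit")
})

test_that("SVD tensor fit recovers exact tensors and scores fits correctly", {
  set.seed(7)
  s_true <- c(4e-4, 9e-4, -2e-4, 5e-4, 1e-4)
  vecs <- replicate(8, rand_unit(), simplify = FALSE)
  names(vecs) <- paste0("v", 1:8)
  D <- vapply(vecs, function(v) sum(build_design_row(v) * s_true), 1) *
    xbnmr:::DMAX_CH
  fit <- svd_fit(D, vecs)
  expect_equal(fit$tensor$s, unname(s_true), tolerance = 1e-9)
  expect_lt(fit$Q, 1e-9)
  expect_lt(max(abs(fit$report$residual)), 1e-9)
  # tensor is traceless symmetric
  expect_equal(sum(diag(fit$tensor$matrix)), 0, tolerance = 1e-12)
  expect_equal(fit$tensor$matrix, t(fit$tensor$matrix), tolerance = 1e-15)
  # residuals orthogonal to the design column space (normal equations)
  M <- t(vapply(vecs, build_design_row, numeric(5)))
  expect_lt(max(abs(crossprod(M, fit$report$residual))), 1e-9 * max(abs(D)))
  # rhombicity bounded
  expect_lte(abs(fit$tensor$rhombicity), 2 / 3 + 1e-12)

  # quality factor definition, hand-checked: rms(2,2)/rms(10,10)
  expect_equal(q_factor(c(10, -10), c(8, -8)), 0.20, tolerance = 1e-12)

  # degenerate geometry: all vectors identical
  same <- replicate(6, c(0, 0, 1), simplify = FALSE)
  expect_error(svd_fit(rep(1, 6), same), "degenerate")
  expect_error(svd_fit(D[1:4], vecs[1:4]), "at least 5")
})

test_that("fit quality metrics are invariant under rotation and reordering", {
  set.seed(11)
  s_true <- c(4e-4, 9e-4, -2e-4, 5e-4, 1e-4)
  vecs <- replicate(9, rand_unit(), simplify = FALSE)
  names(vecs) <- paste0("v", 1:9)
  D <- vapply(vecs, function(v) sum(build_design_row(v) * s_true), 1) *
    xbnmr:::DMAX_CH + rnorm(9, 0, 2)
  fit <- svd_fit(D, vecs)

  # joint rotation of all vectors: same Q (the tensor rotates along)
  R <- xbnmr:::random_rotation()
  vecs_rot <- lapply(vecs, function(v) drop(R %*% v))
  fit_rot <- svd_fit(D, vecs_rot)
  expect_equal(fit_rot$Q, fit$Q, tolerance = 1e-9)
  expect_equal(fit_rot$chi2, fit$chi2, tolerance = 1e-6)
  expect_equal(sort(fit_rot$tensor$eigenvalues), sort(fit$tensor$eigenvalues),
               tolerance = 1e-9)
  expect_equal(fit_rot$report$D_calc, fit$report$D_calc, tolerance = 1e-9)

  # reordering observations: same Q and chi2
  o <- sample(9)
  fit_perm <- svd_fit(D[o], vecs[o])
  expect_equal(fit_perm$Q, fit$Q, tolerance = 1e-12)
  expect_equal(fit_perm$chi2, fit$chi2, tolerance = 1e-9)

  # column-orthonormal design has condition number 1
  I5 <- diag(5)
  fit_eye <- xbnmr:::svd_fit_rows(rnorm(5), I5)
  expect_equal(fit_eye$condition_number, 1, tolerance = 1e-12)
})

test_that("ensemble fit recovers populations and tensor from noise-free data", {
  cfg <- noise_free_config(seed = 43)
  gp <- generate_pool(cfg)
  vecs <- pool_ch_vectors(gp$pool)
  s_true <- cfg$saupe
  p_true <- c(0.6, 0.4)
  ids <- c(1L, 11L)
  Ms <- lapply(vecs[ids], function(vl) t(vapply(vl, build_design_row, numeric(5))))
  Mavg <- p_true[1L] * Ms[[1L]] + p_true[2L] * Ms[[2L]]
  D <- drop(Mavg %*% s_true) * xbnmr:::DMAX_CH
  ef <- ensemble_rdc_fit(vecs, D, candidate_ids = ids)
  expect_lt(max(abs(ef$p - p_true)), 1e-3)
  expect_lt(max(abs(ef$tensor$s - s_true)), 1e-6)
  expect_lt(ef$fit$Q, 1e-4)

  # single candidate reduces exactly to svd_fit
  D1 <- drop(Ms[[1L]] %*% s_true) * xbnmr:::DMAX_CH
  e1 <- ensemble_rdc_fit(vecs, D1, candidate_ids = 1L)
  f1 <- svd_fit(D1, vecs[[1L]])
  expect_equal(e1$tensor$s, f1$tensor$s, tolerance = 1e-12)
  expect_equal(e1$chi2, f1$chi2, tolerance = 1e-12)
})

test_that("alternating fit matches the brute-force population grid for pairs", {
  cfg <- generator_config(seed = 47)
  gp <- generate_pool(cfg)
  vecs <- pool_ch_vectors(gp$pool)
  set.seed(48)
  s_true <- cfg$saupe
  for (ids in list(c(1L, 11L), c(2L, 15L), c(3L, 7L))) {
    Ms <- lapply(vecs[ids], function(vl) t(vapply(vl, build_design_row, numeric(5))))
    Mavg <- 0.35 * Ms[[1L]] + 0.65 * Ms[[2L]]
    D <- drop(Mavg %*% s_true) * xbnmr:::DMAX_CH + rnorm(10, 0, 1)
    ef <- ensemble_rdc_fit(vecs, D, candidate_ids = ids, n_starts = 5)
    grid <- grid_chi2_rdc_pair(vecs[ids], D, step = 0.05)
    expect_lte(ef$chi2, grid + 1e-6)
  }
})

test_that("model selection prefers the smallest adequate sub-ensemble", {
  cfg <- noise_free_config(seed = 53, n_folded = 4, n_unfolded = 4)
  gp <- generate_pool(cfg)
  vecs <- pool_ch_vectors(gp$pool)
  # single-conformer truth, noise-free: size 1 wins and the penalty
  # makes the score strictly increase for larger sizes
  M1 <- t(vapply(vecs[[2L]], build_design_row, numeric(5)))
  D <- drop(M1 %*% cfg$saupe) * xbnmr:::DMAX_CH
  ms <- model_select(vecs, D, max_size = 3)
  expect_identical(ms$best_size, 1L)
  expect_identical(ms$best$candidate_ids, 2L)
  expect_true(all(diff(ms$table$score) > 0))
  # chi2 is non-increasing in ensemble size (nested models)
  expect_true(all(diff(ms$table$chi2) <= 1e-6))
  expect_error(model_select(list(), D), "empty")
})
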