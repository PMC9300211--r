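test_that("population averaging follows r^-6 and linear J rules", {
  gp <- generate_pool(generator_config(seed = 17, n_folded = 3, n_unfolded = 2))
  pobs <- default_pool_observables(gp$pool)

  # single conformer: averages equal that conformer's observables
  p <- c(1, 0, 0, 0, 0)
  avg <- predict_averages(p, pobs)
  expect_equal(unname(avg$r), unname(pobs$r[1L, ]), tolerance = 1e-12)
  expect_equal(unname(avg$J), unname(karplus_j(pobs$phi[1L, ])),
               tolerance = 1e-12)

  # two-distance hand check: (0.5 2^-6 + 0.5 4^-6)^(-1/6)
  toy <- structure(list(r = matrix(c(2, 4), 2, 1,
                                   dimnames = list(NULL, "a-b")),
                        phi = matrix(numeric(), 2, 0),
                        model_ids = 1:2),
                   class = "pool_observables")
  expect_equal(unname(predict_averages(c(0.5, 0.5), toy)$r), 2.24,
               tolerance = 0.01)

  # degenerate pool: identical conformers give the common value for any p
  same <- structure(list(r = matrix(3.1, 4, 1, dimnames = list(NULL, "a-b")),
                         phi = matrix(numeric(), 4, 0), model_ids = 1:4),
                    class = "pool_observables")
  for (pp in list(c(1, 0, 0, 0), rep(0.25, 4), c(0.1, 0.2, 0.3, 0.4))) {
    expect_equal(unname(predict_averages(pp, same)$r), 3.1, tolerance = 1e-12)
  }
  expect_error(predict_averages(c(0.7, 0.7), toy), "simplex")
})

test_that("population fitting recovers known mixtures from noise-free restraints", {
  gp <- generate_pool(generator_config(seed = 23))
  pobs <- default_pool_observables(gp$pool)
  p_true <- numeric(20)
  p_true[c(1, 4, 12)] <- c(0.7, 0.3, 0)   # stated mixture
  rs <- exact_restraints(pobs, p_true)
  sol <- fit_populations(rs, pobs)
  expect_lt(max(abs(sol$p - p_true)), 1e-3)
  expect_equal(sum(sol$p), 1, tolerance = 1e-8)
  expect_true(all(sol$p >= 0))

  # second mixture with more components
  p2 <- numeric(20)
  p2[c(2, 5, 11, 15)] <- c(0.4, 0.2, 0.25, 0.15)
  sol2 <- fit_populations(exact_restraints(pobs, p2), pobs)
  expect_lt(max(abs(sol2$p - p2)), 1e-3)

  # single-conformer pool: p = 1 and SSE is the direct residual
  one <- structure(list(r = pobs$r[1L, , drop = FALSE],
                        phi = pobs$phi[1L, , drop = FALSE],
                        model_ids = 1L),
                   class = "pool_observables")
  sol1 <- fit_populations(rs, one)
  expect_identical(sol1$p, 1)
  direct <- sum(((rs$distances$r_A - pobs$r[1L, rs$distances$pair]) /
                   rs$distances$tol_A)^2) +
    sum(((rs$jcouplings$J_Hz - karplus_j(pobs$phi[1L, rs$jcouplings$dihedral])) /
           rs$jcouplings$tol_Hz)^2)
  expect_equal(sol1$sse, direct, tolerance = 1e-9)
})

test_that("optimiser beats the brute-force simplex grid on every 3-conformer sub-pool", {
  gp <- generate_pool(generator_config(seed = 29, n_folded = 4, n_unfolded = 4))
  pobs <- default_pool_observables(gp$pool)
  p_true <- c(0.55, 0, 0.25, 0, 0, 0.20, 0, 0)
  rs <- exact_restraints(pobs, p_true)
  subsets <- utils::combn(8, 3, simplify = FALSE)
  for (S in subsets) {
    grid_best <- grid_sse_subpool(rs, pobs, S, step = 0.02)
    sub <- structure(list(r = pobs$r[S, , drop = FALSE],
                          phi = pobs$phi[S, , drop = FALSE],
                          model_ids = S),
                     class = "pool_observables")
    sol <- fit_populations(rs, sub, n_starts = 5)
    expect_lte(sol$sse, grid_best + 1e-9)
  }
})

test_that("solutions are simplex-valid, order-equivariant and duplicate-monotone", {
  gp <- generate_pool(generator_config(seed = 31, n_folded = 4, n_unfolded = 4))
  pobs <- default_pool_observables(gp$pool)
  p_true <- c(0.5, 0, 0.3, 0, 0.2, 0, 0, 0)
  rs <- exact_restraints(pobs, p_true)
  sol <- fit_populations(rs, pobs)

  # reordering the pool permutes the solution and keeps the SSE
  perm <- c(3, 1, 8, 2, 5, 4, 7, 6)
  pobs_perm <- structure(list(r = pobs$r[perm, , drop = FALSE],
                              phi = pobs$phi[perm, , drop = FALSE],
                              model_ids = pobs$model_ids[perm]),
                         class = "pool_observables")
  sol_perm <- fit_populations(rs, pobs_perm)
  expect_equal(sol_perm$sse, sol$sse, tolerance = 1e-6)
  expect_equal(sol_perm$p, sol$p[perm], tolerance = 1e-4)

  # duplicating a selected conformer never increases the optimum
  dup <- structure(list(r = rbind(pobs$r, pobs$r[1L, ]),
                        phi = rbind(pobs$phi, pobs$phi[1L, ]),
                        model_ids = c(pobs$model_ids, 99L)),
                   class = "pool_observables")
  sol_dup <- fit_populations(rs, dup)
  expect_lte(sol_dup$sse, sol$sse + 1e-9)
})

test_that("jackknife resampling is deterministic and tight on consistent data", {
  gp <- generate_pool(generator_config(seed = 37, n_folded = 3, n_unfolded = 3))
  pobs <- default_pool_observables(gp$pool)
  p_true <- c(0.6, 0, 0, 0.4, 0, 0)
  rs <- exact_restraints(pobs, p_true)

  jk1 <- jackknife_stability(rs, pobs, fraction = 0.2, n_reps = 8, seed = 7)
  jk2 <- jackknife_stability(rs, pobs, fraction = 0.2, n_reps = 8, seed = 7)
  expect_identical(jk1, jk2)
  # noise-free consistent data: every population is stable
  expect_lt(max(jk1$iqr), 0.02)
  # fraction 0: all replicates equal the full fit
  jk0 <- jackknife_stability(rs, pobs, fraction = 0, n_reps = 3, seed = 7)
  reps <- attr(jk0, "replicates")
  expect_equal(reps[1L, ], reps[2L, ], tolerance = 1e-12)
  expect_error(jackknife_stability(rs, pobs, n_reps = 1), "2 replicates")
})

test_that("folded-share summary recovers the generating folded fraction", {
  cfg <- noise_free_config(seed = 41)
  gp <- generate_pool(cfg)
  pobs <- default_pool_observables(gp$pool)
  rs <- exact_restraints(pobs, cfg$populations)
  sol <- fit_populations(rs, pobs)
  labs <- classify_pool(gp$pool)
  sh <- folded_share(sol, labs)
  q_true <- sum(cfg$populations[gp$truth$folded])
  expect_lt(abs(sh$folded_share - q_true), 0.05)
})
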