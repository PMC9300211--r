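test_that("pool readers round-trip the writers and report malformed models", {
  gp <- generate_pool(generator_config(seed = 11, n_folded = 2, n_unfolded = 1,
                                       populations = c(0.5, 0.3, 0.2)))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  xyz <- withr::local_tempfile(fileext = ".xyz")

  write_conformer_pool(gp$pool, pdb)
  back <- read_conformer_pool(pdb)
  expect_length(back, 3L)
  expect_identical(back[[1L]]$atoms$atom, gp$pool[[1L]]$atoms$atom)
  for (i in seq_along(back)) {
    expect_lt(max(abs(as.matrix(back[[i]]$atoms[, c("x", "y", "z")]) -
                      as.matrix(gp$pool[[i]]$atoms[, c("x", "y", "z")]))),
              1e-3)
  }

  write_conformer_pool(gp$pool, xyz)
  back2 <- read_conformer_pool(xyz)
  expect_lt(max(abs(as.matrix(back2[[2L]]$atoms[, c("x", "y", "z")]) -
                    as.matrix(gp$pool[[2L]]$atoms[, c("x", "y", "z")]))), 1e-6)

  # MODEL without ENDMDL names the offending model
  lines <- readLines(pdb)
  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines[-max(grep("^ENDMDL", lines))], bad)
  expect_error(read_conformer_pool(bad), "model 3")

  # duplicate atom label within a model
  atoms <- gp$pool[[1L]]$atoms
  atoms$atom[2L] <- atoms$atom[1L]
  expect_error(conformer(1L, atoms), "duplicate atom label")
})

test_that("distances, dihedrals and halogen-bond geometry follow the stated conventions", {
  cf <- toy_conformer(rbind(c(0, 0, 0), c(2.1, 0, 0), c(4.2, 0, 0)),
                      c("C1", "I1", "O1"))
  obs <- compute_observables(cf, xb = c("C1", "I1", "O1"))
  expect_equal(obs$xb$distance, 2.1, tolerance = 1e-12)
  expect_equal(obs$xb$angle, 180, tolerance = 1e-9)

  # bent geometry, hand-checked arccos of unit-vector dot product
  cf2 <- toy_conformer(rbind(c(0, 0, 0), c(2.1, 0, 0), c(4.1, 1.0, 0)),
                       c("C1", "I1", "O1"))
  obs2 <- compute_observables(cf2, xb = c("C1", "I1", "O1"))
  expect_equal(obs2$xb$angle, 153.4, tolerance = 0.1)

  # orthogonal frame: IUPAC sign convention gives -90 for this chirality
  cf3 <- toy_conformer(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1)),
                       c("A1", "B1", "C1", "D1"))
  d3 <- compute_observables(cf3, dihedrals = list(d = c("A1", "B1", "C1", "D1")))
  expect_equal(unname(d3$dihedrals["d"]), -90, tolerance = 1e-9)
  # mirrored chirality flips the sign
  cf4 <- toy_conformer(rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, -1)),
                       c("A1", "B1", "C1", "D1"))
  d4 <- compute_observables(cf4, dihedrals = list(d = c("A1", "B1", "C1", "D1")))
  expect_equal(unname(d4$dihedrals["d"]), 90, tolerance = 1e-9)

  # coplanar atoms give 0 or 180
  cf5 <- toy_conformer(rbind(c(1, 1, 0), c(0, 0, 0), c(2, 0, 0), c(3, -1, 0)),
                       c("A1", "B1", "C1", "D1"))
  d5 <- compute_observables(cf5, dihedrals = list(d = c("A1", "B1", "C1", "D1")))
  expect_lt(min(abs(d5$dihedrals["d"]), abs(abs(d5$dihedrals["d"]) - 180)), 1e-6)

  expect_error(compute_observables(cf, distances = list(c("C1", "Z9"))),
               "Z9")
})

test_that("geometry is symmetric and rigid-motion invariant; vectors rotate consistently", {
  gp <- generate_pool(generator_config(seed = 4, n_folded = 2, n_unfolded = 2))
  cf <- gp$pool[[1L]]
  spec <- list(distances = list(c("CA1", "CA10"), c("CA10", "CA1")),
               dihedrals = list(phi3 = c("C2", "N3", "CA3", "C3")),
               vectors = list(v = c("CA4", "HA4")),
               xb = c("CG3", "I3", "OE8"))
  obs <- do.call(compute_observables, c(list(cf), spec))
  expect_identical(obs$distances[["CA1-CA10"]], obs$distances[["CA10-CA1"]])

  set.seed(99)
  for (k in 1:5) {
    R <- xbnmr:::random_rotation()
    t <- rnorm(3, sd = 10)
    cf2 <- cf
    xyz <- as.matrix(cf$atoms[, c("x", "y", "z")]) %*% t(R)
    cf2$atoms$x <- xyz[, 1L] + t[1L]
    cf2$atoms$y <- xyz[, 2L] + t[2L]
    cf2$atoms$z <- xyz[, 3L] + t[3L]
    obs2 <- do.call(compute_observables, c(list(cf2), spec))
    expect_equal(obs2$distances, obs$distances, tolerance = 1e-9)
    expect_equal(obs2$dihedrals, obs$dihedrals, tolerance = 1e-9)
    expect_equal(obs2$xb$angle, obs$xb$angle, tolerance = 1e-9)
    expect_equal(obs2$ch_vectors$v, drop(R %*% obs$ch_vectors$v),
                 tolerance = 1e-9)
    expect_equal(sum(obs2$ch_vectors$v^2), 1, tolerance = 1e-9)
  }
})

test_that("fold classification separates hairpin, coil and halogen-bond geometries", {
  crit <- fold_criteria()
  spec <- fold_observable_spec(crit, xb_atoms = c("CG3", "I3", "OE8"))
  tmpl <- hairpin_template()

  hp <- build_chain(tmpl$phi, tmpl$psi, xb = TRUE, xb_dist = 3.2,
                    xb_angle = 145)
  lab <- classify_fold(do.call(compute_observables, c(list(hp), spec)), crit)
  expect_true(lab$folded)
  expect_true(lab$halogen_bonded)
  # defaults: vdW sum 3.50 A, minimum angle 140 deg -> 3.2 A / 145 deg bonded
  xb_row <- lab$criteria_report[lab$criteria_report$criterion == "xb_angle", ]
  expect_equal(xb_row$value, 145, tolerance = 1e-6)

  ext <- build_chain(rep(-120, 10), rep(120, 10))
  lab2 <- classify_fold(do.call(compute_observables, c(list(ext), spec)), crit)
  expect_false(lab2$folded)

  # deterministic and pure
  lab3 <- classify_fold(do.call(compute_observables, c(list(hp), spec)), crit)
  expect_identical(lab, lab3)

  # every configured criterion appears in the report
  expect_setequal(
    lab$criteria_report$criterion,
    c("turn_phi1", "turn_psi1", "turn_phi2", "turn_psi2",
      "mean_interstrand_CA", "n_hbond_proxies", "xb_distance", "xb_angle"))

  # geometry just outside the thresholds is not halogen bonded
  hp2 <- build_chain(tmpl$phi, tmpl$psi, xb = TRUE, xb_dist = 3.6,
                     xb_angle = 145)
  lab4 <- classify_fold(do.call(compute_observables, c(list(hp2), spec)), crit)
  expect_false(lab4$halogen_bonded)

  # config referencing an absent observable errors
  expect_error(classify_fold(compute_observables(hp), crit), "dihedral")
})
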