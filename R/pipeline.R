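#' Pipeline orchestration and reporting
#'
#' File-level stages tying the modules together: `simulate` writes a
#' full synthetic dataset with truth, `melt`/`noe`/`namfis`/`rdc` run
#' the analyses on their input tables, and `report` merges the stage
#' outputs into one summary placing the three independent estimates of
#' the folded population (melting curve, NOE/J ensemble, RDC ensemble)
#' side by side with the halogen-bond population and geometry. All
#' stage outputs are JSON; all randomness flows from the single seed in
#' the run configuration.
#'
#' @name pipeline
NULL

REPORT_SCHEMA <- "xbnmr-report/1"

#' Run configuration
#'
#' Defaults for every stage; values can be overridden by a YAML
#' configuration file (unknown keys are rejected) and per-call
#' arguments.
#'
#' @param seed integer seed (default 1).
#' @param outdir output directory (default `"xbnmr_out"`).
#' @param T_ref temperature (K) at which folded fractions are compared
#'   (default 274, the default melt truth's T_m).
#' @param Tm2,dHm2 melt truth of the reference compound in two-compound
#'   simulations (defaults 267.6 K, 26400 J/mol).
#' @param max_ensemble_size largest RDC sub-ensemble size (default 4).
#' @param r_ref calibration distance (default 1.78 Angstrom).
#' @param reference_pair calibration pair label (default `"HA6-HB6"`).
#' @param fold named list of [fold_criteria()] overrides (thresholds,
#'   residue pairs, halogen-bond atom triple via `xb_atoms`).
#' @param ... overrides of [generator_config()] fields (stored under
#'   `generator`).
#' @return list of class `run_config`.
#' @export
run_config <- function(seed = 1L, outdir = "xbnmr_out", T_ref = 274,
                       Tm2 = 267.6, dHm2 = 26400, max_ensemble_size = 4,
                       r_ref = 1.78, reference_pair = "HA6-HB6",
                       fold = list(), ...) {
  gen <- generator_config(seed = seed, ...)
  xb_atoms <- fold$xb_atoms %||% c("CG3", "I3", "OE8")
  fold$xb_atoms <- NULL
  criteria <- do.call(fold_criteria, fold)
  structure(list(seed = as.integer(seed), outdir = outdir, T_ref = T_ref,
                 Tm2 = Tm2, dHm2 = dHm2,
                 max_ensemble_size = max_ensemble_size, r_ref = r_ref,
                 reference_pair = reference_pair, criteria = criteria,
                 xb_atoms = xb_atoms, generator = gen),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML
#'
#' Top-level keys are [run_config()] arguments; keys under `generator`
#' are [generator_config()] arguments. Unknown keys are rejected with
#' their key path.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  top_ok <- c("seed", "outdir", "T_ref", "Tm2", "dHm2",
              "max_ensemble_size", "r_ref", "reference_pair", "fold",
              "generator")
  bad <- setdiff(names(raw), top_ok)
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  gen <- raw$generator
  raw$generator <- NULL
  if (!is.null(gen)) {
    gen_ok <- setdiff(names(formals(generator_config)), "seed")
    badg <- setdiff(names(gen), gen_ok)
    if (length(badg)) {
      stop("unknown configuration key(s): ",
           paste(paste0("generator.", badg), collapse = ", "))
    }
  }
  if (!is.null(raw$fold)) {
    fold_ok <- c(names(formals(fold_criteria)), "xb_atoms")
    badf <- setdiff(names(raw$fold), fold_ok)
    if (length(badf)) {
      stop("unknown configuration key(s): ",
           paste(paste0("fold.", badf), collapse = ", "))
    }
  }
  do.call(run_config, c(raw, gen))
}

write_stage_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Simulate a full synthetic dataset to disk
#'
#' Writes the conformer pool (multi-model PDB), VT shift tables for the
#' halogen-bonding compound and the reference compound, NOE build-up
#' and J-coupling tables, the RDC table, and a truth JSON.
#'
#' @param rc a [run_config].
#' @return named list of written paths plus the in-memory truth.
#' @export
stage_simulate <- function(rc) {
  dir.create(rc$outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- rc$generator
  gp <- generate_pool(cfg, criteria = rc$criteria)
  paths <- list(
    pool = file.path(rc$outdir, "pool.pdb"),
    vt1 = file.path(rc$outdir, "vt_compound1.tsv"),
    vt2 = file.path(rc$outdir, "vt_compound2.tsv"),
    buildups = file.path(rc$outdir, "noe_buildups.tsv"),
    jcouplings = file.path(rc$outdir, "jcouplings.tsv"),
    rdc = file.path(rc$outdir, "rdc.tsv"),
    truth = file.path(rc$outdir, "truth.json"))
  write_conformer_pool(gp$pool, paths$pool)
  m1 <- simulate_melt(cfg)
  m2 <- simulate_melt(cfg, Tm = rc$Tm2, dHm = rc$dHm2, seed_offset = 100L)
  write_vt_table(m1$series, paths$vt1)
  write_vt_table(m2$series, paths$vt2)
  noe <- simulate_noe(gp$pool, cfg$populations, cfg)
  write_buildup_table(noe$buildups, paths$buildups)
  jc <- simulate_jcouplings(gp$pool, cfg$populations, cfg)
  utils::write.table(format(jc, digits = 10), paths$jcouplings, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  rdc <- simulate_rdc(gp$pool, cfg$populations, cfg)
  write_rdc_table(rdc$table, paths$rdc)
  truth <- list(seed = cfg$seed,
                populations = cfg$populations,
                folded_share = sum(cfg$populations[gp$truth$folded]),
                xb_share = sum(cfg$populations[gp$truth$xb]),
                melt = m1$truth, melt_ref = m2$truth,
                noe = noe$truth, saupe = cfg$saupe,
                labels = gp$truth)
  write_stage_json(truth, paths$truth)
  c(paths, list(truth = truth))
}

#' Melting-analysis stage
#'
#' Per-proton and global two-state fits, folding thermodynamics at
#' `T_ref`, amide temperature coefficients, and — when the reference
#' compound's table is given — the relative stability: per-proton
#' product points pooled into one zero-intercept regression (the slope
#' K is common to all protons), with Delta Delta G referenced to the
#' second compound's global T_m.
#'
#' @param rc a [run_config].
#' @param vt_path VT shift table of the compound of interest.
#' @param vt2_path optional table of the reference compound.
#' @param out optional JSON output path.
#' @return list with `global`, `per_proton`, `dG`, `coefficients`, and
#'   optionally `relative`.
#' @export
stage_melt <- function(rc, vt_path, vt2_path = NULL, out = NULL) {
  series <- read_vt_table(vt_path)
  if (length(series) < 1L || length(series[[1L]]$T_K) < 5L) {
    stop("VT table needs at least one proton over at least 5 temperatures")
  }
  gf <- global_melt_fit(series)
  dg <- delta_g(gf, rc$T_ref)
  tc <- temperature_coefficients(series)
  res <- list(
    global = list(Tm = gf$Tm, dHm = gf$dHm,
                  dSm_TmRoute = gf$dHm / gf$Tm),
    per_proton = lapply(gf$per_proton, function(f) {
      list(proton = f$proton, dU = f$dU, dF = f$dF, Tm = f$Tm,
           dHm = f$dHm, sse = f$sse)
    }),
    dG = list(T_K = rc$T_ref, dG_J = dg$dG, kF = dg$kF,
              folded_fraction = folded_fraction(gf, rc$T_ref)),
    coefficients = tc)
  if (!is.null(vt2_path)) {
    series2 <- read_vt_table(vt2_path)
    gf2 <- global_melt_fit(series2)
    common <- intersect(names(gf$per_proton), names(gf2$per_proton))
    pts <- lapply(common, function(p) {
      f1 <- gf$per_proton[[p]]
      f2 <- gf2$per_proton[[p]]
      rf <- relative_folding(f1$series, f2$series,
                             c(f1$dU, f1$dF), c(f2$dU, f2$dF), gf2$Tm)
      rf$points
    })
    pooled <- do.call(rbind, pts)
    reg <- stats::lm(y ~ x - 1, data = pooled)
    K <- unname(stats::coef(reg)[1L])
    res$relative <- list(K_ratio = K,
                         ddG_J = -GAS_R * gf2$Tm * log(K),
                         Tm2 = gf2$Tm, n_protons = length(common))
  }
  if (!is.null(out)) write_stage_json(res, out)
  res
}

#' NOE stage: build-up fitting and distance calibration
#'
#' @param rc a [run_config].
#' @param buildup_path build-up table.
#' @param out optional JSON output path.
#' @return list with `rates` and `distances`.
#' @export
stage_noe <- function(rc, buildup_path, out = NULL) {
  buildups <- read_buildup_table(buildup_path,
                                 reference_pair = rc$reference_pair)
  rates <- vapply(buildups, function(b) fit_initial_rate(b)$sigma, numeric(1))
  dist <- calibrate_distances(rates, list(pair = rc$reference_pair,
                                          r_ref = rc$r_ref))
  res <- list(rates = as.list(rates), distances = dist)
  if (!is.null(out)) write_stage_json(res, out)
  res
}

#' NAMFIS stage: ensemble deconvolution with fold summary
#'
#' @param rc a [run_config].
#' @param pool_path conformer pool file.
#' @param distances data.frame from [stage_noe()] (or a restraint
#'   table).
#' @param jcouplings_path J-restraint table (`dihedral`, `J_Hz`,
#'   `tol_Hz`).
#' @param out optional JSON output path.
#' @return list with `populations`, `sse`, `selected`, `folded_share`,
#'   `xb_share`, `residuals`.
#' @export
stage_namfis <- function(rc, pool_path, distances, jcouplings_path = NULL,
                         out = NULL) {
  pool <- read_conformer_pool(pool_path)
  jc <- if (!is.null(jcouplings_path)) read_restraint_table(jcouplings_path)
        else NULL
  rs <- restraint_set(distances, jc)
  pairs <- distances$pair
  phis <- if (!is.null(jc)) jc$dihedral else character()
  pobs <- pool_observables(pool, pairs = pairs, phi_labels = phis)
  sol <- fit_populations(rs, pobs, seed = rc$seed)
  labs <- classify_pool(pool, rc$criteria, rc$xb_atoms)
  shares <- folded_share(sol, labs)
  res <- list(populations = sol$p, sse = sol$sse,
              selected = sol$selected,
              model_ids = sol$model_ids,
              folded_share = shares$folded_share,
              xb_share = shares$xb_share,
              residuals = sol$residuals)
  if (!is.null(out)) write_stage_json(res, out)
  res
}

#' Classify every conformer of a pool
#'
#' @param pool list of [conformer].
#' @param criteria a [fold_criteria].
#' @param xb_atoms halogen-bond atom triple.
#' @return list of `fold_label` objects.
#' @export
classify_pool <- function(pool, criteria = fold_criteria(),
                          xb_atoms = c("CG3", "I3", "OE8")) {
  spec <- fold_observable_spec(criteria, xb_atoms = xb_atoms)
  lapply(pool, function(cf) {
    classify_fold(do.call(compute_observables, c(list(cf), spec)), criteria)
  })
}

#' RDC stage: extraction, tensor fit, sub-ensemble selection
#'
#' Extracts RDCs from the coupling table, selects the best
#' sub-ensemble by penalised chi-square over the candidate conformers
#' (the NAMFIS-selected ones when given, the full pool otherwise), and
#' summarises fold and halogen-bond shares plus the
#' population-weighted halogen-bond geometry of the selected
#' conformers.
#'
#' @param rc a [run_config].
#' @param pool_path conformer pool file.
#' @param rdc_path RDC coupling table.
#' @param candidates optional candidate conformer indices.
#' @param out optional JSON output path.
#' @return list with `Q`, `condition_number`, `chi2`, `populations`
#'   (full pool), `best_size`, `selection_table`, `folded_share`,
#'   `xb_share`, `xb_geometry`.
#' @export
stage_rdc <- function(rc, pool_path, rdc_path, candidates = NULL, out = NULL) {
  pool <- read_conformer_pool(pool_path)
  tab <- read_rdc_table(rdc_path)
  vecs <- pool_ch_vectors(pool, max(pool[[1L]]$atoms$resno))
  # keep only observed labels, in table order
  vecs <- lapply(vecs, function(vl) vl[tab$label])
  if (!is.null(candidates)) {
    sub_vecs <- vecs[candidates]
    ms <- model_select(sub_vecs, tab$D_Hz, tab$sigma_D,
                       max_size = min(rc$max_ensemble_size, length(candidates)),
                       seed = rc$seed)
    sel_ids <- candidates[ms$best$candidate_ids]
  } else {
    ms <- model_select(vecs, tab$D_Hz, tab$sigma_D,
                       max_size = rc$max_ensemble_size, seed = rc$seed)
    sel_ids <- ms$best$candidate_ids
  }
  p_full <- numeric(length(pool))
  p_full[sel_ids] <- ms$best$p
  labs <- classify_pool(pool, rc$criteria, rc$xb_atoms)
  sol <- list(p = p_full)
  fold <- vapply(labs, function(l) isTRUE(l$folded), TRUE)
  xb <- vapply(labs, function(l) isTRUE(l$halogen_bonded), TRUE)
  xb_sel <- sel_ids[xb[sel_ids]]
  xb_geom <- NULL
  if (length(xb_sel)) {
    g <- vapply(xb_sel, function(i) {
      o <- compute_observables(pool[[i]], xb = rc$xb_atoms)
      c(o$xb$distance, o$xb$angle)
    }, numeric(2))
    w <- p_full[xb_sel] / sum(p_full[xb_sel])
    xb_geom <- list(distance_A = sum(w * g[1L, ]),
                    angle_deg = sum(w * g[2L, ]))
  }
  res <- list(Q = ms$best$fit$Q,
              condition_number = ms$best$fit$condition_number,
              chi2 = ms$best$chi2,
              populations = p_full, best_size = ms$best_size,
              selection_table = ms$table,
              folded_share = sum(p_full[fold]),
              xb_share = sum(p_full[xb]),
              xb_geometry = xb_geom)
  if (!is.null(out)) write_stage_json(res, out)
  res
}

#' Merge stage results into the consolidated report
#'
#' @param rc a [run_config].
#' @param melt,namfis,rdc stage result lists (or paths to their JSON
#'   outputs).
#' @param out optional JSON output path.
#' @return list of class `xbnmr_report`.
#' @export
stage_report <- function(rc, melt, namfis, rdc, out = NULL) {
  load_maybe <- function(x) {
    if (is.character(x)) jsonlite::read_json(x, simplifyVector = TRUE) else x
  }
  melt <- load_maybe(melt)
  namfis <- load_maybe(namfis)
  rdc <- load_maybe(rdc)
  rep <- list(
    schema = REPORT_SCHEMA,
    seed = rc$seed,
    T_ref = rc$T_ref,
    folded_fraction = list(
      melt = melt$dG$folded_fraction,
      namfis = namfis$folded_share,
      rdc = rdc$folded_share),
    xb = list(population = rdc$xb_share,
              namfis_population = namfis$xb_share,
              geometry = rdc$xb_geometry),
    melt = melt$global,
    relative = melt$relative,
    rdc_quality = list(Q = rdc$Q, condition_number = rdc$condition_number,
                       best_size = rdc$best_size))
  class(rep) <- "xbnmr_report"
  if (!is.null(out)) write_stage_json(unclass(rep), out)
  rep
}

#' @export
print.xbnmr_report <- function(x, ...) {
  cat("xbnmr report (", x$schema, ")\n", sep = "")
  cat(sprintf("  folded fraction at %.0f K: melt %.3f | NAMFIS %.3f | RDC %.3f\n",
              x$T_ref, x$folded_fraction$melt, x$folded_fraction$namfis,
              x$folded_fraction$rdc))
  cat(sprintf("  halogen-bond population (RDC): %.3f\n", x$xb$population))
  if (!is.null(x$xb$geometry)) {
    cat(sprintf("  halogen-bond geometry: I...O %.2f A, C-I...O %.1f deg\n",
                x$xb$geometry$distance_A, x$xb$geometry$angle_deg))
  }
  invisible(x)
}

#' Run the full pipeline in one call
#'
#' `simulate` -> `melt` -> `noe` -> `namfis` -> `rdc` -> `report`, all
#' under one seed, writing every stage JSON into the output directory.
#'
#' @param rc a [run_config].
#' @return the final `xbnmr_report`.
#' @export
run_pipeline <- function(rc = run_config()) {
  sim <- stage_simulate(rc)
  melt <- stage_melt(rc, sim$vt1, sim$vt2,
                     out = file.path(rc$outdir, "melt.json"))
  noe <- stage_noe(rc, sim$buildups, out = file.path(rc$outdir, "noe.json"))
  namfis <- stage_namfis(rc, sim$pool, noe$distances, sim$jcouplings,
                         out = file.path(rc$outdir, "namfis.json"))
  rdc <- stage_rdc(rc, sim$pool, sim$rdc, candidates = namfis$selected,
                   out = file.path(rc$outdir, "rdc.json"))
  stage_report(rc, melt, namfis, rdc,
               out = file.path(rc$outdir, "report.json"))
}

# ---------------------------------------------------------------------------
# Command line

cli_usage <- function() {
  paste(
    "usage: xbnmr <subcommand> [--key value ...]",
    "subcommands:",
    "  simulate --outdir DIR [--seed N] [--config FILE]",
    "  melt     --vt FILE [--vt2 FILE] --out FILE [--config FILE]",
    "  noe      --buildups FILE --out FILE [--config FILE]",
    "  namfis   --pool FILE --distances FILE --jcouplings FILE --out FILE",
    "  rdc      --pool FILE --rdc FILE --out FILE [--config FILE]",
    "  report   --melt FILE --namfis FILE --rdc FILE --out FILE",
    "  pipeline --outdir DIR [--seed N] [--config FILE]",
    sep = "\n")
}

parse_cli_args <- function(args) {
  if (!length(args)) stop("missing subcommand\n", cli_usage())
  sub <- args[1L]
  args <- args[-1L]
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    key <- args[i]
    if (!startsWith(key, "--")) stop("expected --flag, got '", key, "'")
    if (i + 1L > length(args)) stop("flag ", key, " needs a value")
    opts[[substring(key, 3L)]] <- args[i + 1L]
    i <- i + 2L
  }
  list(subcommand = sub, opts = opts)
}

cli_config <- function(opts) {
  rc <- if (!is.null(opts$config)) read_run_config(opts$config) else run_config()
  if (!is.null(opts$seed)) {
    seed <- as.integer(opts$seed)
    rc$seed <- seed
    rc$generator$seed <- seed
  }
  if (!is.null(opts$outdir)) rc$outdir <- opts$outdir
  rc
}

need_opt <- function(opts, key, sub) {
  if (is.null(opts[[key]])) {
    stop("subcommand '", sub, "' requires --", key)
  }
  opts[[key]]
}

#' In-process command-line entry point
#'
#' Thin dispatcher over the stage functions; the installed script
#' `inst/scripts/xbnmr` forwards `commandArgs(TRUE)` here. Returns the
#' process exit status instead of calling `quit()`, so it is usable
#' (and testable) in-process.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
xbnmr_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    parsed <- parse_cli_args(args)
    sub <- parsed$subcommand
    opts <- parsed$opts
    rc <- cli_config(opts)
    message("xbnmr ", sub, " (seed ", rc$seed, ")")
    switch(sub,
      simulate = { stage_simulate(rc); 0L },
      melt = {
        stage_melt(rc, need_opt(opts, "vt", sub), opts$vt2,
                   out = need_opt(opts, "out", sub))
        0L
      },
      noe = {
        stage_noe(rc, need_opt(opts, "buildups", sub),
                  out = need_opt(opts, "out", sub))
        0L
      },
      namfis = {
        dist <- read_restraint_table(need_opt(opts, "distances", sub))
        names(dist)[names(dist) == "key"] <- "pair"
        names(dist)[names(dist) == "value"] <- "r_A"
        names(dist)[names(dist) == "tol"] <- "tol_A"
        stage_namfis(rc, need_opt(opts, "pool", sub), dist,
                     opts$jcouplings, out = need_opt(opts, "out", sub))
        0L
      },
      rdc = {
        stage_rdc(rc, need_opt(opts, "pool", sub),
                  need_opt(opts, "rdc", sub),
                  out = need_opt(opts, "out", sub))
        0L
      },
      report = {
        stage_report(rc, need_opt(opts, "melt", sub),
                     need_opt(opts, "namfis", sub),
                     need_opt(opts, "rdc", sub),
                     out = need_opt(opts, "out", sub))
        0L
      },
      pipeline = { run_pipeline(rc); 0L },
      stop("unknown subcommand '", sub, "'\n", cli_usage()))
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
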