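#' Conformer objects
#'
#' A `conformer` is one rigid model of the peptide: an ordered atom table
#' with labels, residue numbering and Cartesian coordinates in Angstrom.
#' Pools of conformers (the theoretical input ensembles for NAMFIS and
#' RDC analysis) are plain lists of `conformer` objects in model order.
#'
#' @param model_id integer model index within its pool.
#' @param atoms data.frame with columns `atom` (label, unique within the
#'   model), `resno` (integer residue index), `resid` (residue name),
#'   `element`, and `x`, `y`, `z` (Angstrom).
#' @param check if `TRUE`, verify backbone completeness (every residue
#'   has N, CA and C atoms) as expected of the synthetic chains.
#' @return An object of class `conformer`.
#' @export
conformer <- function(model_id, atoms, check = TRUE) {
  stopifnot(is.data.frame(atoms))
  need <- c("atom", "resno", "resid", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(atoms$atom)) {
    dup <- atoms$atom[duplicated(atoms$atom)][1L]
    stop(sprintf("duplicate atom label '%s' in model %s", dup, model_id))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) {
    stop(sprintf("non-finite coordinates in model %s", model_id))
  }
  if (isTRUE(check)) {
    for (r in unique(atoms$resno)) {
      have <- atoms$atom[atoms$resno == r]
      bb <- paste0(c("N", "CA", "C"), r)
      if (!all(bb %in% have)) {
        stop(sprintf("model %s residue %d lacks backbone N/CA/C", model_id, r))
      }
    }
  }
  structure(list(model_id = as.integer(model_id), atoms = atoms),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("conformer: model %d, %d atoms, %d residues\n",
              x$model_id, nrow(x$atoms), length(unique(x$atoms$resno))))
  invisible(x)
}

#' Coordinates of one named atom
#' @noRd
atom_xyz <- function(conf, label) {
  i <- match(label, conf$atoms$atom)
  if (is.na(i)) {
    stop(sprintf("atom '%s' not found in model %d", label, conf$model_id))
  }
  as.numeric(conf$atoms[i, c("x", "y", "z")])
}

# ---------------------------------------------------------------------------
# Pool input/output

#' Read a conformer pool from a multi-model PDB or extended-XYZ file
#'
#' Multi-model PDB files (MODEL/ENDMDL delimited) are parsed through
#' [bio3d::read.pdb()]; the MODEL/ENDMDL bracketing is validated first so
#' a truncated model is reported by its index. The extended-XYZ dialect is
#' the package's own: per model, an atom-count line, a comment line
#' `model=<id>`, then one line per atom
#' `<label> <resno> <resid> <element> <x> <y> <z>`.
#'
#' Atom labels in the package convention carry the residue index
#' (e.g. `CA3`, `HN7`); elements are inferred from the label's leading
#' letters when the file does not carry them.
#'
#' @param path file path.
#' @param format `"pdb"` or `"xyz"`; default guessed from the extension.
#' @return list of [conformer] objects in model order.
#' @export
read_conformer_pool <- function(path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  if (format == "pdb") read_pool_pdb(path) else read_pool_xyz(path)
}

element_from_label <- function(label) {
  lead <- sub("[0-9].*$", "", label)
  # two-letter halogens etc. would need a lookup; synthetic chains use
  # single-letter elements plus iodine
  el <- substr(lead, 1L, 1L)
  ifelse(lead == "I", "I", el)
}

read_pool_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  opens <- grep("^MODEL", lines)
  closes <- grep("^ENDMDL", lines)
  if (length(opens) != length(closes)) {
    bad <- length(closes) + 1L
    stop(sprintf("unbalanced MODEL/ENDMDL records: model %d is not closed", bad))
  }
  if (length(opens) && any(closes < opens)) {
    stop("ENDMDL before MODEL: malformed multi-model PDB")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom
  nmod <- nrow(pdb$xyz)
  # bio3d keeps one atom table; per-model coordinates live in the xyz rows
  lapply(seq_len(nmod), function(m) {
    xyz <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)
    lab <- paste0(atom$elety, atom$resno)
    el <- atom$elesy
    if (is.null(el) || all(is.na(el)) || all(el == "")) {
      el <- element_from_label(atom$elety)
    }
    conformer(m, data.frame(
      atom = lab, resno = atom$resno, resid = atom$resid,
      element = el, x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
      stringsAsFactors = FALSE))
  })
}

read_pool_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pool <- list()
  i <- 1L
  m <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    m <- m + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("model %d: expected atom count, got '%s'", m, lines[i]))
    if (i + 1L + n > length(lines)) {
      stop(sprintf("model %d: truncated (declared %d atoms)", m, n))
    }
    comment <- lines[i + 1L]
    id <- sub(".*model=([0-9]+).*", "\\1", comment)
    id <- suppressWarnings(as.integer(id))
    if (is.na(id)) id <- m
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    if (any(vapply(parts, length, 1L) != 7L)) {
      stop(sprintf("model %d: atom lines need 7 fields", m))
    }
    tab <- do.call(rbind, parts)
    pool[[m]] <- conformer(id, data.frame(
      atom = tab[, 1L], resno = as.integer(tab[, 2L]), resid = tab[, 3L],
      element = tab[, 4L],
      x = as.numeric(tab[, 5L]), y = as.numeric(tab[, 6L]),
      z = as.numeric(tab[, 7L]), stringsAsFactors = FALSE))
    i <- i + 2L + n
  }
  if (!length(pool)) stop("no models found in ", path)
  pool
}

#' Write a conformer pool
#'
#' Writes the dialects [read_conformer_pool()] reads. PDB output goes
#' through [bio3d::write.pdb()] (3 decimal places, hence the documented
#' 1e-3 Angstrom round-trip precision); XYZ output keeps full precision.
#'
#' @param pool list of [conformer] objects.
#' @param path output path.
#' @param format `"pdb"` or `"xyz"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_conformer_pool <- function(pool, path, format = c("auto", "pdb", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.xyz$", path, ignore.case = TRUE)) "xyz" else "pdb"
  }
  stopifnot(length(pool) > 0L)
  if (format == "pdb") {
    at <- pool[[1L]]$atoms
    xyz <- do.call(rbind, lapply(pool, function(cf) {
      as.numeric(t(as.matrix(cf$atoms[, c("x", "y", "z")])))
    }))
    # strip the residue index back off the label for the PDB name column
    elety <- sub("[0-9]+$", "", at$atom)
    bio3d::write.pdb(file = path, xyz = xyz, resno = at$resno,
                     resid = at$resid, elety = elety, elesy = at$element)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (cf in pool) {
      writeLines(as.character(nrow(cf$atoms)), con)
      writeLines(sprintf("model=%d", cf$model_id), con)
      writeLines(sprintf("%-6s %3d %-4s %-2s %14.8f %14.8f %14.8f",
                         cf$atoms$atom, cf$atoms$resno, cf$atoms$resid,
                         cf$atoms$element, cf$atoms$x, cf$atoms$y,
                         cf$atoms$z), con)
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Observables

#' Geometric observables of one conformer
#'
#' Computes the observables the restraint and RDC machinery consumes:
#' Euclidean inter-atom distances, signed four-atom dihedrals (IUPAC
#' convention), unit bond vectors (from the bonded heavy atom to the
#' proton), and optionally the halogen-bond geometry of an atom triple
#' (C, I, O): the I...O distance and the C-I...O angle at iodine.
#'
#' @param conf a [conformer].
#' @param distances list of length-2 character vectors (atom label pairs).
#' @param dihedrals named list of length-4 character vectors.
#' @param vectors named list of length-2 character vectors
#'   `(heavy atom, proton)`.
#' @param xb optional length-3 character vector `(C, I, O)`.
#' @return An object of class `observable_set`: list with elements
#'   `distances` (named numeric, Angstrom), `dihedrals` (named numeric,
#'   degrees in (-180, 180]), `ch_vectors` (named list of unit
#'   3-vectors), and `xb` (list with `distance`, `angle`) or `NULL`.
#' @export
compute_observables <- function(conf, distances = list(), dihedrals = list(),
                                vectors = list(), xb = NULL) {
  d <- vapply(distances, function(p) {
    vnorm(atom_xyz(conf, p[2L]) - atom_xyz(conf, p[1L]))
  }, numeric(1))
  if (length(distances)) {
    names(d) <- vapply(distances, function(p) paste(p, collapse = "-"), "")
  }
  dh <- vapply(dihedrals, function(q) {
    dihedral4(atom_xyz(conf, q[1L]), atom_xyz(conf, q[2L]),
              atom_xyz(conf, q[3L]), atom_xyz(conf, q[4L]))
  }, numeric(1))
  vs <- lapply(vectors, function(p) {
    unit(atom_xyz(conf, p[2L]) - atom_xyz(conf, p[1L]))
  })
  xbg <- NULL
  if (!is.null(xb)) {
    stopifnot(length(xb) == 3L)
    cpos <- atom_xyz(conf, xb[1L])
    ipos <- atom_xyz(conf, xb[2L])
    opos <- atom_xyz(conf, xb[3L])
    xbg <- list(distance = vnorm(opos - ipos),
                angle = angle3(cpos, ipos, opos))
  }
  structure(list(distances = d, dihedrals = dh, ch_vectors = vs, xb = xbg),
            class = "observable_set")
}

#' @export
print.observable_set <- function(x, ...) {
  cat(sprintf("observable_set: %d distances, %d dihedrals, %d vectors%s\n",
              length(x$distances), length(x$dihedrals), length(x$ch_vectors),
              if (is.null(x$xb)) "" else
                sprintf(", XB d=%.2f A angle=%.1f deg",
                        x$xb$distance, x$xb$angle)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Fold / halogen-bond classification

#' Default fold-classification criteria
#'
#' Criteria for calling a conformer a folded beta-hairpin with a central
#' type II' turn, and for calling its halogen-bond geometry bonded:
#' \itemize{
#'   \item turn windows: residue i+1 (phi, psi) within 60+/-40, -120+/-40
#'     degrees; residue i+2 within -90+/-40, 0+/-40 (textbook type II'
#'     ideals, window half-width 40 degrees);
#'   \item mean interstrand CA-CA distance over the paired residues
#'     at most 5.5 Angstrom;
#'   \item at least `hbond_min_count` cross-strand N...O contacts at most
#'     3.5 Angstrom;
#'   \item halogen bond: I...O below the Bondi van der Waals sum
#'     1.98 + 1.52 = 3.50 Angstrom and C-I...O angle at least 140 degrees
#'     (the floor spans both preferred sigma-hole approach ranges seen in
#'     protein environments, ~145-150 and ~160-170 degrees).
#' }
#'
#' @param turn_res the two turn residues (i+1, i+2).
#' @param strand_pairs list of residue index pairs paired across strands.
#' @param hbond_pairs list of `(N-atom, O-atom)` label pairs used as
#'   cross-strand hydrogen-bond proxies.
#' @param ca_dist_max,hbond_dist_max,hbond_min_count,xb_dist_max,xb_angle_min
#'   thresholds as described above.
#' @param turn_windows named list of `(center, halfwidth)` pairs for
#'   `phi1`, `psi1`, `phi2`, `psi2` of the two turn residues.
#' @return list of class `fold_criteria`.
#' @export
fold_criteria <- function(turn_res = c(5L, 6L),
                          strand_pairs = list(c(4L, 7L), c(3L, 8L),
                                              c(2L, 9L), c(1L, 10L)),
                          hbond_pairs = NULL,
                          ca_dist_max = 5.5,
                          hbond_dist_max = 3.5,
                          hbond_min_count = 2L,
                          xb_dist_max = 3.50,
                          xb_angle_min = 140,
                          turn_windows = list(phi1 = c(60, 40),
                                              psi1 = c(-120, 40),
                                              phi2 = c(-90, 40),
                                              psi2 = c(0, 40))) {
  if (is.null(hbond_pairs)) {
    # antiparallel register about a turn at residues (t1, t2): the inner
    # H-bond pair plus the next ring outwards
    t1 <- turn_res[1L]
    hbond_pairs <- list(c(paste0("N", t1 + 2L), paste0("O", t1 - 1L)),
                        c(paste0("N", t1 - 1L), paste0("O", t1 + 2L)),
                        c(paste0("N", t1 + 4L), paste0("O", t1 - 3L)),
                        c(paste0("N", t1 - 3L), paste0("O", t1 + 4L)))
  }
  structure(list(turn_res = turn_res, strand_pairs = strand_pairs,
                 hbond_pairs = hbond_pairs, ca_dist_max = ca_dist_max,
                 hbond_dist_max = hbond_dist_max,
                 hbond_min_count = as.integer(hbond_min_count),
                 xb_dist_max = xb_dist_max, xb_angle_min = xb_angle_min,
                 turn_windows = turn_windows),
            class = "fold_criteria")
}

#' Observable request implied by a fold-criteria configuration
#'
#' Builds the `distances`/`dihedrals`/`xb` arguments for
#' [compute_observables()] needed to evaluate [classify_fold()].
#'
#' @param cfg a [fold_criteria] object.
#' @param xb_atoms optional `(C, I, O)` triple for the halogen-bond
#'   geometry.
#' @return list with `distances`, `dihedrals`, `xb`.
#' @export
fold_observable_spec <- function(cfg, xb_atoms = NULL) {
  t1 <- cfg$turn_res[1L]
  t2 <- cfg$turn_res[2L]
  dihedrals <- list(
    phi1 = c(paste0("C", t1 - 1L), paste0("N", t1), paste0("CA", t1),
             paste0("C", t1)),
    psi1 = c(paste0("N", t1), paste0("CA", t1), paste0("C", t1),
             paste0("N", t1 + 1L)),
    phi2 = c(paste0("C", t2 - 1L), paste0("N", t2), paste0("CA", t2),
             paste0("C", t2)),
    psi2 = c(paste0("N", t2), paste0("CA", t2), paste0("C", t2),
             paste0("N", t2 + 1L)))
  dist <- c(lapply(cfg$strand_pairs,
                   function(p) paste0("CA", p)),
            cfg$hbond_pairs)
  list(distances = dist, dihedrals = dihedrals, xb = xb_atoms)
}

in_window <- function(x, center, half) {
  # circular difference in degrees
  d <- ((x - center + 180) %% 360) - 180
  abs(d) <= half
}

#' Classify a conformer as folded / halogen bonded
#'
#' A conformer is folded when all configured criteria pass: the turn
#' residues' (phi, psi) fall in the type II' windows, the mean
#' interstrand CA-CA distance over the paired residues is below
#' threshold, and at least `hbond_min_count` cross-strand N...O proxies
#' are short. It is halogen bonded when the I...O distance is below the
#' van der Waals sum and the C-I...O angle is above the floor; without an
#' XB geometry in `obs` the conformer is never halogen bonded.
#'
#' @param obs an `observable_set` from [compute_observables()], holding
#'   every observable named by `cfg` (see [fold_observable_spec()]).
#' @param cfg a [fold_criteria] object.
#' @return list of class `fold_label` with `folded`, `halogen_bonded`,
#'   and a `criteria_report` data.frame (criterion, measured value, pass).
#' @export
classify_fold <- function(obs, cfg = fold_criteria()) {
  stopifnot(inherits(cfg, "fold_criteria"))
  w <- cfg$turn_windows
  need_dih <- c("phi1", "psi1", "phi2", "psi2")
  if (!all(need_dih %in% names(obs$dihedrals))) {
    stop("observable set lacks turn dihedrals: ",
         paste(setdiff(need_dih, names(obs$dihedrals)), collapse = ", "))
  }
  rep_rows <- list()
  ok_turn <- TRUE
  for (k in need_dih) {
    val <- obs$dihedrals[[k]]
    pass <- in_window(val, w[[k]][1L], w[[k]][2L])
    ok_turn <- ok_turn && pass
    rep_rows[[length(rep_rows) + 1L]] <-
      data.frame(criterion = paste0("turn_", k), value = val, pass = pass)
  }
  ca_keys <- vapply(cfg$strand_pairs,
                    function(p) paste(paste0("CA", p), collapse = "-"), "")
  if (!all(ca_keys %in% names(obs$distances))) {
    stop("observable set lacks interstrand CA distances: ",
         paste(setdiff(ca_keys, names(obs$distances)), collapse = ", "))
  }
  ca_mean <- mean(obs$distances[ca_keys])
  ok_ca <- ca_mean <= cfg$ca_dist_max
  rep_rows[[length(rep_rows) + 1L]] <-
    data.frame(criterion = "mean_interstrand_CA", value = ca_mean, pass = ok_ca)
  hb_keys <- vapply(cfg$hbond_pairs, function(p) paste(p, collapse = "-"), "")
  if (!all(hb_keys %in% names(obs$distances))) {
    stop("observable set lacks H-bond proxy distances: ",
         paste(setdiff(hb_keys, names(obs$distances)), collapse = ", "))
  }
  n_hb <- sum(obs$distances[hb_keys] <= cfg$hbond_dist_max)
  ok_hb <- n_hb >= cfg$hbond_min_count
  rep_rows[[length(rep_rows) + 1L]] <-
    data.frame(criterion = "n_hbond_proxies", value = n_hb, pass = ok_hb)
  folded <- ok_turn && ok_ca && ok_hb
  xb_bonded <- FALSE
  if (!is.null(obs$xb)) {
    ok_d <- obs$xb$distance < cfg$xb_dist_max
    ok_a <- obs$xb$angle >= cfg$xb_angle_min
    xb_bonded <- ok_d && ok_a
    rep_rows[[length(rep_rows) + 1L]] <-
      data.frame(criterion = "xb_distance", value = obs$xb$distance, pass = ok_d)
    rep_rows[[length(rep_rows) + 1L]] <-
      data.frame(criterion = "xb_angle", value = obs$xb$angle, pass = ok_a)
  }
  structure(list(folded = folded, halogen_bonded = xb_bonded,
                 criteria_report = do.call(rbind, rep_rows)),
            class = "fold_label")
}

#' @export
print.fold_label <- function(x, ...) {
  cat(sprintf("fold_label: folded=%s, halogen_bonded=%s\n",
              x$folded, x$halogen_bonded))
  print(x$criteria_report, row.names = FALSE)
  invisible(x)
}
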