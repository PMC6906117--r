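# S3 containers shared across the pipeline. Atoms live in a data frame
# (bio3d-style), one row per atom; a structure model wraps one coordinate
# set, a trajectory is an ordered list of models with identical atom order.

#' Construct a structure model
#'
#' A `structure_model` holds one set of atomic coordinates as a data frame
#' with one row per atom plus a model id and an optional box vector. This is
#' the common currency of the hydration and contact modules.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`, `x`, `y`, `z`, `occupancy`, `b`, `altloc`,
#'   `kind`. `kind` is one of `"protein"`, `"ligand"`, `"water"`, `"ion"`,
#'   `"other"`. Coordinates are in Angstrom.
#' @param model_id integer model number (1-based).
#' @param box optional length-3 numeric box vector in Angstrom.
#' @return an object of class `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L, box = NULL) {
  req <- c("serial", "name", "element", "resname", "resno", "chain",
           "x", "y", "z", "occupancy", "b", "altloc", "kind")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop_cavitherm(paste("atoms is missing columns:",
                         paste(missing_cols, collapse = ", ")),
                   "cavitherm_validation_error")
  if (nrow(atoms) == 0L)
    stop_cavitherm("structure model must contain at least one atom",
                   "cavitherm_empty_input_error")
  if (anyDuplicated(atoms$serial))
    stop_cavitherm("atom serial numbers must be unique within a model",
                   "cavitherm_validation_error")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop_cavitherm("atom coordinates must be finite",
                   "cavitherm_validation_error")
  if (!all(atoms$kind %in% c("protein", "ligand", "water", "ion", "other")))
    stop_cavitherm("unknown atom kind", "cavitherm_validation_error")
  if (!is.null(box)) stopifnot(length(box) == 3L, all(box > 0))
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 model_id = as.integer(model_id), box = box),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  k <- table(x$atoms$kind)
  cat(sprintf("<structure_model #%d> %d atoms (%s)\n", x$model_id,
              nrow(x$atoms),
              paste(sprintf("%s: %d", names(k), as.integer(k)),
                    collapse = ", ")))
  invisible(x)
}

#' Coordinates of a structure model as a matrix
#' @param model a [structure_model()].
#' @return numeric matrix with one row per atom and columns x, y, z.
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z")])
}

#' Construct a trajectory
#'
#' An ordered list of structure models with identical atom identity and
#' ordering, e.g. frames extracted from a simulation.
#'
#' @param frames list of [structure_model()] objects.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(frames) {
  if (!length(frames))
    stop_cavitherm("trajectory must contain at least one frame",
                   "cavitherm_validation_error")
  ref <- frames[[1L]]$atoms
  for (i in seq_along(frames)) {
    a <- frames[[i]]$atoms
    if (nrow(a) != nrow(ref) ||
        !identical(a$name, ref$name) || !identical(a$resno, ref$resno) ||
        !identical(a$resname, ref$resname))
      stop_cavitherm(sprintf("frame %d does not match frame 1 atom identity", i),
                     "cavitherm_validation_error")
  }
  structure(list(frames = frames, frame_count = length(frames)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms\n", x$frame_count,
              nrow(x$frames[[1L]]$atoms)))
  invisible(x)
}

#' Construct an ITC thermogram
#'
#' Holds one titration experiment: the injection protocol (volumes),
#' concentrations, temperature, and (optionally) per-injection heats and
#' control heats of dilution. Heats may be absent when the object describes
#' a protocol only (the forward model and the generator both take one).
#'
#' @param cell_volume_ul cell volume, microlitre.
#' @param temperature_K temperature, Kelvin.
#' @param cell_conc_M macromolecule concentration in the cell, mol/l.
#' @param syringe_conc_M ligand concentration in the syringe, mol/l.
#' @param injection_volumes_ul per-injection volumes, microlitre.
#' @param heats_uJ optional per-injection heats, microjoule.
#' @param control_heats_uJ optional per-injection heats of dilution, microjoule.
#' @param pre_injection_ul volume of the discarded pre-injection, microlitre.
#' @param metadata free-form list (ground-truth parameters, seed, ...).
#' @return an object of class `thermogram`.
#' @export
thermogram <- function(cell_volume_ul, temperature_K, cell_conc_M,
                       syringe_conc_M, injection_volumes_ul,
                       heats_uJ = NULL, control_heats_uJ = NULL,
                       pre_injection_ul = 0, metadata = list()) {
  if (cell_volume_ul <= 0 || any(injection_volumes_ul <= 0) ||
      pre_injection_ul < 0)
    stop_cavitherm("volumes must be positive", "cavitherm_validation_error")
  if (temperature_K <= 0)
    stop_cavitherm("temperature must be positive", "cavitherm_validation_error")
  if (length(injection_volumes_ul) < 2L)
    stop_cavitherm("at least 2 injections required", "cavitherm_validation_error")
  n <- length(injection_volumes_ul)
  if (!is.null(heats_uJ) && length(heats_uJ) != n)
    stop_cavitherm("heats length must equal injection count",
                   "cavitherm_validation_error")
  if (!is.null(control_heats_uJ) && length(control_heats_uJ) != n)
    stop_cavitherm("control heats length must equal injection count",
                   "cavitherm_validation_error")
  structure(list(cell_volume_ul = cell_volume_ul,
                 temperature_K = temperature_K,
                 cell_conc_M = cell_conc_M,
                 syringe_conc_M = syringe_conc_M,
                 injection_volumes_ul = injection_volumes_ul,
                 heats_uJ = heats_uJ,
                 control_heats_uJ = control_heats_uJ,
                 pre_injection_ul = pre_injection_ul,
                 metadata = metadata),
            class = "thermogram")
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf(
    "<thermogram> %d x %.3g ul into %g ul cell, M0=%.3g M, X0=%.3g M, T=%g K%s\n",
    length(x$injection_volumes_ul), x$injection_volumes_ul[1L],
    x$cell_volume_ul, x$cell_conc_M, x$syringe_conc_M, x$temperature_K,
    if (is.null(x$heats_uJ)) " (protocol only)" else ""))
  invisible(x)
}

#' Construct a nonbonded parameter set
#'
#' Per-(residue name, atom name) partial charges and Lennard-Jones
#' parameters, plus the global Coulomb prefactor and interaction cutoff.
#' Pair energies use Lorentz-Berthelot combining rules.
#'
#' @param table data frame with columns `resname`, `name`, `charge_e`,
#'   `sigma_A`, `epsilon_kJmol`.
#' @param coulomb_constant Coulomb prefactor, kJ mol^-1 Angstrom e^-2.
#' @param cutoff_A interaction cutoff, Angstrom.
#' @return an object of class `nonbonded_params`.
#' @export
nonbonded_params <- function(table, coulomb_constant = .COULOMB_KJ_A_E2,
                             cutoff_A = 10) {
  req <- c("resname", "name", "charge_e", "sigma_A", "epsilon_kJmol")
  if (!all(req %in% names(table)))
    stop_cavitherm(paste("params table needs columns:",
                         paste(req, collapse = ", ")),
                   "cavitherm_validation_error")
  if (any(table$sigma_A <= 0))
    stop_cavitherm("lj sigma must be positive", "cavitherm_validation_error")
  if (any(table$epsilon_kJmol < 0))
    stop_cavitherm("lj epsilon must be non-negative",
                   "cavitherm_validation_error")
  if (cutoff_A <= max(table$sigma_A))
    stop_cavitherm("cutoff must exceed the largest sigma",
                   "cavitherm_validation_error")
  structure(list(table = as.data.frame(table, stringsAsFactors = FALSE),
                 coulomb_constant = coulomb_constant, cutoff_A = cutoff_A),
            class = "nonbonded_params")
}

#' Resolve nonbonded parameters for every atom of a model
#'
#' Looks each atom up by (residue name, atom name), falling back to a
#' wildcard residue name `"*"` if present in the table.
#'
#' @param model a [structure_model()].
#' @param params a [nonbonded_params()].
#' @return data frame with one row per atom: `charge_e`, `sigma_A`,
#'   `epsilon_kJmol`.
#' @export
resolve_params <- function(model, params) {
  tab <- params$table
  key <- paste(tab$resname, tab$name, sep = "\r")
  akey <- paste(model$atoms$resname, model$atoms$name, sep = "\r")
  idx <- match(akey, key)
  wild <- is.na(idx)
  if (any(wild)) {
    wkey <- paste("*", model$atoms$name[wild], sep = "\r")
    idx[wild] <- match(wkey, key)
  }
  if (anyNA(idx)) {
    bad <- unique(paste(model$atoms$resname[is.na(idx)],
                        model$atoms$name[is.na(idx)]))
    stop_cavitherm(paste("no nonbonded parameters for atoms:",
                         paste(bad, collapse = "; ")),
                   "cavitherm_lookup_error")
  }
  data.frame(charge_e = tab$charge_e[idx], sigma_A = tab$sigma_A[idx],
             epsilon_kJmol = tab$epsilon_kJmol[idx])
}

#' Default pipeline configuration
#'
#' Central knobs shared across modules, with the package defaults: water
#' residue names, cavity cutoff, bulk distance, hydrogen-bond criteria, fit
#' options and the random seed. All distances are Angstrom, energies kJ/mol.
#'
#' @param ... named overrides of any default.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    water_resnames = c("HOH", "WAT", "SOL", "TIP"),
    ligand_resnames = c("TAU", "AEP", "ACE", "MES", "LIG"),
    ion_resnames = c("NA", "CL", "K", "MG", "CA", "ZN", "IOD"),
    protein_resnames = "CAG",    # pseudo-protein cage of synthetic pockets
    cavity_cutoff_A = 5.0,
    bulk_distance_A = 10.0,
    hbond_distance_A = 3.5,
    hbond_angle_deg = 120,
    vdw_cutoff_A = 4.0,
    fix_n = FALSE,
    fix_n_value = NA_real_,
    drop_first_injection = TRUE,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop_cavitherm(paste("unknown config keys:", paste(unknown, collapse = ", ")),
                   "cavitherm_config_error")
  cfg[names(dots)] <- dots
  if (cfg$cavity_cutoff_A <= 0 || cfg$bulk_distance_A <= 0 ||
      cfg$hbond_distance_A <= 0 || cfg$vdw_cutoff_A <= 0)
    stop_cavitherm("all cutoffs must be positive", "cavitherm_config_error")
  class(cfg) <- "pipeline_config"
  cfg
}
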