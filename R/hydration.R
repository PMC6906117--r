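# Cavity-water census and energetics: per-water Lennard-Jones + Coulomb
# potential energies under a plain cutoff, the bulk-water reference, and the
# desolvation penalty score comparing bound and ligand-free states.

#' Define a binding cavity
#'
#' Either a shell around selected residues (`residue_shell`: a water is in
#' the cavity when its oxygen lies within `cutoff_A` of any atom of the
#' selected residues) or a sphere around a fixed point (`point_sphere`).
#' All distance tests are inclusive (<=).
#'
#' @param mode `"residue_shell"` or `"point_sphere"`.
#' @param chain chain id for residue selection (NULL = any chain).
#' @param resnos residue numbers of the binding-site residues.
#' @param center length-3 center point, Angstrom (point_sphere).
#' @param cutoff_A cavity cutoff radius, Angstrom (default 5).
#' @return object of class `cavity_definition`.
#' @export
cavity_definition <- function(mode = c("residue_shell", "point_sphere"),
                              chain = NULL, resnos = NULL, center = NULL,
                              cutoff_A = 5) {
  mode <- match.arg(mode)
  if (cutoff_A <= 0)
    stop_cavitherm("cavity cutoff must be positive", "cavitherm_validation_error")
  if (mode == "residue_shell" && is.null(resnos))
    stop_cavitherm("residue_shell mode needs residue numbers",
                   "cavitherm_validation_error")
  if (mode == "point_sphere" && (is.null(center) || length(center) != 3L))
    stop_cavitherm("point_sphere mode needs a length-3 center",
                   "cavitherm_validation_error")
  structure(list(mode = mode, chain = chain, resnos = resnos,
                 center = center, cutoff_A = cutoff_A),
            class = "cavity_definition")
}

# water residues of a model as (resname, resno, chain) keys; a water id is
# "chain/resno"
.water_ids <- function(model) {
  a <- model$atoms
  unique(paste(a$chain[a$kind == "water"], a$resno[a$kind == "water"],
               sep = "/"))
}

.water_oxygens <- function(model) {
  a <- model$atoms
  w <- a$kind == "water" & toupper(a$element) == "O"
  if (!any(a$kind == "water")) return(a[w, , drop = FALSE])
  ox <- a[w, , drop = FALSE]
  ids <- paste(a$chain[a$kind == "water"], a$resno[a$kind == "water"], sep = "/")
  if (!all(unique(ids) %in% paste(ox$chain, ox$resno, sep = "/")))
    stop_cavitherm("a water residue lacks an oxygen atom",
                   "cavitherm_validation_error")
  ox
}

#' Find cavity waters in a frame
#'
#' A water belongs to the cavity iff its oxygen lies within the cavity
#' cutoff (inclusive) of any selector atom (residue_shell) or of the center
#' (point_sphere).
#'
#' @param frame a [structure_model()].
#' @param cavity a [cavity_definition()].
#' @return character vector of water ids (`"chain/resno"`), possibly empty.
#' @export
find_cavity_waters <- function(frame, cavity) {
  stopifnot(inherits(frame, "structure_model"),
            inherits(cavity, "cavity_definition"))
  ox <- .water_oxygens(frame)
  if (!nrow(ox)) return(character(0))
  op <- as.matrix(ox[, c("x", "y", "z")])
  if (cavity$mode == "point_sphere") {
    d <- sqrt(rowSums(sweep(op, 2, cavity$center)^2))
  } else {
    a <- frame$atoms
    sel <- a$resno %in% cavity$resnos
    if (!is.null(cavity$chain)) sel <- sel & a$chain %in% cavity$chain
    if (!any(sel))
      stop_cavitherm("cavity selector resolves to zero atoms",
                     "cavitherm_selection_error")
    sp <- as.matrix(a[sel, c("x", "y", "z")])
    d <- apply(op, 1L, function(p)
      sqrt(min(rowSums(sweep(sp, 2, p)^2))))
  }
  paste(ox$chain, ox$resno, sep = "/")[d <= cavity$cutoff_A]
}

#' Pairwise nonbonded energy between two atoms
#'
#' `u = 4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ] + f q_i q_j / r` with
#' Lorentz-Berthelot combining (arithmetic-mean sigma, geometric-mean
#' epsilon) and `f = 1389.35458 kJ mol^-1 Angstrom e^-2`; zero beyond the
#' cutoff.
#'
#' @param atom_i,atom_j single-row data frames (or lists) with `x`, `y`,
#'   `z`, `resname`, `name`.
#' @param params a [nonbonded_params()].
#' @return energy in kJ/mol.
#' @export
pair_energy <- function(atom_i, atom_j, params) {
  look <- function(a) {
    tab <- params$table
    i <- which(tab$resname == a$resname & tab$name == a$name)
    if (!length(i))
      stop_cavitherm(paste("no parameters for", a$resname, a$name),
                     "cavitherm_lookup_error")
    tab[i[1L], ]
  }
  pi_ <- look(atom_i); pj <- look(atom_j)
  r <- sqrt((atom_i$x - atom_j$x)^2 + (atom_i$y - atom_j$y)^2 +
            (atom_i$z - atom_j$z)^2)
  if (r == 0)
    stop_cavitherm("coincident atoms: r = 0", "cavitherm_singularity_error")
  if (r > params$cutoff_A) return(0)
  sig <- (pi_$sigma_A + pj$sigma_A) / 2
  eps <- sqrt(pi_$epsilon_kJmol * pj$epsilon_kJmol)
  sr6 <- (sig / r)^6
  4 * eps * (sr6^2 - sr6) + params$coulomb_constant *
    pi_$charge_e * pj$charge_e / r
}

# full pairwise energy matrix for one frame (upper+lower, diag 0), with the
# cutoff applied and intra-residue pairs zeroed
.energy_matrix <- function(frame, params) {
  a <- frame$atoms
  p <- resolve_params(frame, params)
  xyz <- coords(frame)
  r <- as.matrix(stats::dist(xyz))
  if (any(r[upper.tri(r)] == 0))
    stop_cavitherm("coincident atoms in frame", "cavitherm_singularity_error")
  sig <- outer(p$sigma_A, p$sigma_A, "+") / 2
  eps <- sqrt(outer(p$epsilon_kJmol, p$epsilon_kJmol))
  qq <- outer(p$charge_e, p$charge_e)
  diag(r) <- Inf
  sr6 <- (sig / r)^6
  u <- 4 * eps * (sr6^2 - sr6) + params$coulomb_constant * qq / r
  u[r > params$cutoff_A] <- 0
  same_res <- outer(paste(a$chain, a$resno, a$resname),
                    paste(a$chain, a$resno, a$resname), "==")
  u[same_res] <- 0
  u
}

#' Potential energy of one water in a frame
#'
#' Sum of pairwise nonbonded energies between the atoms of the water and
#' every atom outside it, with water-water pair energies halved (each pair
#' split evenly between the two waters) so that per-water energies sum to
#' the total water-water energy. Intra-water pairs are excluded.
#'
#' @param frame a [structure_model()].
#' @param water_id water id `"chain/resno"` (as returned by
#'   [find_cavity_waters()]).
#' @param params a [nonbonded_params()].
#' @return energy in kJ/mol.
#' @export
water_potential_energy <- function(frame, water_id, params) {
  .per_water_energies(frame, params, water_id)[[water_id]]
}

# energies of several waters at once (one energy matrix evaluation)
.per_water_energies <- function(frame, params, water_ids = NULL) {
  a <- frame$atoms
  ids <- paste(a$chain, a$resno, sep = "/")
  is_w <- a$kind == "water"
  if (is.null(water_ids)) water_ids <- unique(ids[is_w])
  if (!all(water_ids %in% ids[is_w]))
    stop_cavitherm("unknown water id", "cavitherm_lookup_error")
  u <- .energy_matrix(frame, params)
  weight <- matrix(1, nrow(a), nrow(a))
  ww <- outer(is_w, is_w, "&")
  weight[ww] <- 0.5
  uw <- u * weight
  out <- lapply(water_ids, function(wid) {
    rows <- which(ids == wid & is_w)
    sum(uw[rows, -rows, drop = FALSE])
  })
  setNames(out, water_ids)
}

#' Bulk-water reference energy
#'
#' Mean per-water potential energy over all (frame, water) pairs whose
#' oxygen lies farther than `bulk_distance_A` from every non-water atom.
#' In a pure water box every water qualifies.
#'
#' @param traj a [trajectory()] (or a single [structure_model()]).
#' @param params a [nonbonded_params()].
#' @param bulk_distance_A bulk distance threshold, Angstrom (default 10).
#' @return mean energy, kJ/mol.
#' @export
bulk_reference_energy <- function(traj, params, bulk_distance_A = 10) {
  if (inherits(traj, "structure_model")) traj <- trajectory(list(traj))
  vals <- numeric(0)
  for (frame in traj$frames) {
    a <- frame$atoms
    ox <- .water_oxygens(frame)
    if (!nrow(ox)) next
    solute <- a[a$kind != "water", , drop = FALSE]
    if (nrow(solute)) {
      sp <- as.matrix(solute[, c("x", "y", "z")])
      dmin <- apply(as.matrix(ox[, c("x", "y", "z")]), 1L, function(p)
        sqrt(min(rowSums(sweep(sp, 2, p)^2))))
      ox <- ox[dmin > bulk_distance_A, , drop = FALSE]
    }
    if (!nrow(ox)) next
    ids <- paste(ox$chain, ox$resno, sep = "/")
    vals <- c(vals, unlist(.per_water_energies(frame, params, ids)))
  }
  if (!length(vals))
    stop_cavitherm("no waters beyond the bulk distance in any frame",
                   "cavitherm_no_bulk_error")
  mean(vals)
}

#' Hydration summary of a trajectory
#'
#' Per-frame cavity-water census and energetics: counts via
#' [find_cavity_waters()], the mean count `N_bar`, the mean per-water
#' potential energy `E_bar_kJmol` over all (frame, cavity water) pairs, and
#' the index of the median-count frame (the frame whose count is closest to
#' the median of the count distribution; ties go to the lowest frame
#' index), recorded for snapshot export.
#'
#' @param traj a [trajectory()].
#' @param cavity a [cavity_definition()].
#' @param params a [nonbonded_params()].
#' @param state_label state label, e.g. `"apo"` or a ligand name.
#' @return object of class `hydration_summary`: `state`, `counts`, `N_bar`,
#'   `E_bar_kJmol`, `median_frame`, `cavity`.
#' @export
hydration_summary <- function(traj, cavity, params, state_label = "apo") {
  stopifnot(inherits(traj, "trajectory"))
  counts <- integer(traj$frame_count)
  evals <- numeric(0)
  for (f in seq_len(traj$frame_count)) {
    wid <- find_cavity_waters(traj$frames[[f]], cavity)
    counts[f] <- length(wid)
    if (length(wid))
      evals <- c(evals,
                 unlist(.per_water_energies(traj$frames[[f]], params, wid)))
  }
  med <- median(counts)
  median_frame <- which.min(abs(counts - med))   # lowest index on ties
  structure(list(state = state_label, counts = counts,
                 N_bar = mean(counts),
                 E_bar_kJmol = if (length(evals)) mean(evals) else NA_real_,
                 median_frame = median_frame, cavity = cavity),
            class = "hydration_summary")
}

#' @export
print.hydration_summary <- function(x, ...) {
  cat(sprintf(
    "<hydration_summary> %s: N_bar = %.3g waters, E_bar = %.4g kJ/mol over %d frames (median frame %d)\n",
    x$state, x$N_bar, x$E_bar_kJmol, length(x$counts), x$median_frame))
  invisible(x)
}

#' Build a hydration summary from reported state averages
#'
#' Wraps externally obtained averages (e.g. published per-state water
#' counts and per-water energies) in a `hydration_summary` so they can be
#' fed to [desolvation_score()].
#'
#' @param N_bar mean cavity-water count.
#' @param E_bar_kJmol mean per-water potential energy, kJ/mol.
#' @param state_label state label.
#' @return a `hydration_summary` (no per-frame data).
#' @export
hydration_summary_from_averages <- function(N_bar, E_bar_kJmol,
                                            state_label) {
  structure(list(state = state_label, counts = NULL, N_bar = N_bar,
                 E_bar_kJmol = E_bar_kJmol, median_frame = NA_integer_,
                 cavity = NULL),
            class = "hydration_summary")
}

#' Desolvation penalty score
#'
#' `D = N_bar_holo * E_bar_holo - N_bar_apo * E_bar_apo` (kJ/mol): the
#' difference in total cavity-water stabilization between the bound and
#' ligand-free states. Positive D means the bound state has lost water
#' stabilization relative to the ligand-free cavity. Both summaries must
#' come from the same cavity definition.
#'
#' @param apo hydration summary of the ligand-free state.
#' @param holo hydration summary of the bound state.
#' @return object of class `desolvation_score`: `D_kJmol`, `component_apo`,
#'   `component_holo` (each `N_bar * E_bar`), `states`.
#' @export
desolvation_score <- function(apo, holo) {
  stopifnot(inherits(apo, "hydration_summary"),
            inherits(holo, "hydration_summary"))
  if (!is.null(apo$cavity) && !is.null(holo$cavity) &&
      !identical(apo$cavity, holo$cavity))
    stop_cavitherm("summaries use different cavity definitions",
                   "cavitherm_validation_error")
  comp <- function(s) if (s$N_bar == 0) 0 else s$N_bar * s$E_bar_kJmol
  ca <- comp(apo); ch <- comp(holo)
  structure(list(D_kJmol = ch - ca, component_apo = ca, component_holo = ch,
                 states = c(apo = apo$state, holo = holo$state),
                 note = paste("state-difference score: D = N_holo*E_holo -",
                              "N_apo*E_apo; the bulk reference energy does",
                              "not enter this score")),
            class = "desolvation_score")
}

#' @export
print.desolvation_score <- function(x, ...) {
  cat(sprintf("<desolvation_score> %s vs %s: D = %+.2f kJ/mol\n",
              x$states[["holo"]], x$states[["apo"]], x$D_kJmol))
  invisible(x)
}
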