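# Synthetic solvated binding pockets with ground-truth labels: a spherical
# cage of neutral pseudo-protein LJ spheres, cavity waters inside the cage,
# bulk waters in an outer shell, and an optional ligand at the centroid.
# Waters are SPC/E-like 3-site models; all placements are seeded rejection
# sampling with a 2.4 A minimum heavy-atom separation.

.WATER_Q_O <- -0.8476
.WATER_Q_H <- 0.4238
.WATER_SIG_O <- 3.166
.WATER_EPS_O <- 0.650
.CAGE_SIG <- 3.4
.CAGE_EPS <- 0.36
.MAX_PLACEMENT_ATTEMPTS <- 10000L

# LJ parameters by element for ligand atoms
.LIG_LJ <- list(C = c(3.40, 0.36), N = c(3.25, 0.71), O = c(3.00, 0.65),
                S = c(3.55, 1.05), P = c(3.74, 0.84))

.rand_unit <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}

# O + 2 H at 1.0 A, 109.47 deg, random orientation around `o`
.water_sites <- function(o) {
  u1 <- .rand_unit()
  repeat {
    w <- .rand_unit()
    perp <- w - sum(w * u1) * u1
    if (sqrt(sum(perp^2)) > 1e-6) { perp <- perp / sqrt(sum(perp^2)); break }
  }
  half <- .TET / 2
  h1 <- o + (cos(half) * u1 + sin(half) * perp)
  h2 <- o + (cos(half) * u1 - sin(half) * perp)
  rbind(o, h1, h2)
}

#' Generate a labeled solvated-pocket system
#'
#' Builds a spherical cage of fixed neutral pseudo-protein atoms (radius
#' `cavity_radius + cage_margin`), places `n_cavity_waters` waters with
#' their oxygens inside `cavity_radius` of the cage centroid and
#' `n_bulk_waters` in the shell `[shell_inner, shell_outer]`, and
#' optionally a ligand at the centroid. Oxygen placement is rejection
#' sampling under a 2.4 Angstrom minimum separation from every previously
#' placed heavy atom; exceeding the attempt bound raises a packing error.
#' Frames replicate the configuration (optionally with a seeded rigid
#' whole-system jitter), so ground-truth labels hold in every frame.
#'
#' @param n_cavity_waters number of cavity waters.
#' @param n_bulk_waters number of bulk waters.
#' @param cavity_radius cavity radius, Angstrom (default 6).
#' @param shell_inner,shell_outer bulk shell bounds, Angstrom. `shell_inner`
#'   must exceed the cage radius by at least 2 Angstrom; the default places
#'   the shell beyond 10 Angstrom of every cage atom so shell waters also
#'   qualify as bulk under the default bulk-distance criterion.
#' @param ligand optional ligand name (see [ligand_template()]) or a
#'   `ligand_template` object.
#' @param n_frames number of (replicated) trajectory frames.
#' @param jitter_sd if positive, each frame after the first receives a rigid
#'   random rotation about the origin scaled by this value plus a random
#'   translation of this standard deviation (Angstrom); rigid moves leave
#'   energies and relative geometry unchanged.
#' @param cage_margin gap between cavity radius and cage, Angstrom.
#' @param cutoff_A nonbonded interaction cutoff recorded in the parameters.
#' @param seed integer RNG seed (mandatory).
#' @return list of class `pocket_system`: `trajectory`, `params`
#'   ([nonbonded_params()]), `cavity` ([cavity_definition()]), `labels`
#'   (list with `cavity_resnos`, `bulk_resnos`), `metadata`.
#' @export
generate_pocket_system <- function(n_cavity_waters, n_bulk_waters,
                                   cavity_radius = 6, shell_inner = 18.5,
                                   shell_outer = 24, ligand = NULL,
                                   n_frames = 1L, jitter_sd = 0,
                                   cage_margin = 2, cutoff_A = 10, seed) {
  if (missing(seed)) stop_cavitherm("seed is required", "cavitherm_config_error")
  if (n_cavity_waters < 0 || n_bulk_waters < 0)
    stop_cavitherm("water counts must be non-negative",
                   "cavitherm_validation_error")
  cage_radius <- cavity_radius + cage_margin
  if (n_bulk_waters > 0 && shell_inner < cage_radius + 2)
    stop_cavitherm("shell_inner must exceed the cage radius by >= 2 A",
                   "cavitherm_validation_error")
  set.seed(seed)

  lig <- NULL
  if (!is.null(ligand)) {
    lig <- if (inherits(ligand, "ligand_template")) ligand
           else ligand_template(ligand)
    lx <- as.matrix(lig$atoms[, c("x", "y", "z")])
    lx <- sweep(lx, 2, colMeans(lx))          # center at origin
  }

  placed <- if (!is.null(lig)) lx else matrix(numeric(0), ncol = 3)
  draw_o <- function(sampler) {
    for (a in seq_len(.MAX_PLACEMENT_ATTEMPTS)) {
      p <- sampler()
      if (!nrow(placed) ||
          min(sqrt(rowSums(sweep(placed, 2, p)^2))) >= 2.4)
        return(p)
    }
    stop_cavitherm("rejection sampling failed: packing density too high",
                   "cavitherm_packing_error")
  }
  in_ball <- function() cavity_radius * runif(1)^(1 / 3) * .rand_unit()
  in_shell <- function() {
    r <- (runif(1) * (shell_outer^3 - shell_inner^3) + shell_inner^3)^(1 / 3)
    r * .rand_unit()
  }
  o_cavity <- t(vapply(seq_len(n_cavity_waters), function(i) {
    p <- draw_o(in_ball); placed <<- rbind(placed, p); p
  }, numeric(3)))
  o_bulk <- t(vapply(seq_len(n_bulk_waters), function(i) {
    p <- draw_o(in_shell); placed <<- rbind(placed, p); p
  }, numeric(3)))

  # cage: near-uniform Fibonacci lattice on the sphere, ~2 A spacing
  n_cage <- max(32L, ceiling(4 * pi * cage_radius^2 / 4))
  gold <- pi * (3 - sqrt(5))
  k <- seq_len(n_cage)
  zc <- 1 - (2 * k - 1) / n_cage
  rc <- sqrt(pmax(0, 1 - zc^2))
  cage_xyz <- cage_radius * cbind(rc * cos(gold * k), rc * sin(gold * k), zc)

  rows <- list()
  serial <- 0L
  add_atoms <- function(names, elements, xyz, resname, resno, chain, kind) {
    serials <- serial + seq_along(names)
    serial <<- serial + length(names)
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serials, name = names, element = elements, resname = resname,
      resno = resno, chain = chain, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      occupancy = 1, b = 0, altloc = "", kind = kind,
      stringsAsFactors = FALSE)
  }
  add_atoms(sprintf("C%d", seq_len(n_cage)), rep("C", n_cage), cage_xyz,
            "CAG", 1L, "P", "protein")
  if (!is.null(lig))
    add_atoms(lig$atoms$name, lig$atoms$element, lx, lig$resname, 2L, "L",
              "ligand")
  resno0 <- 100L
  nw <- n_cavity_waters + n_bulk_waters
  o_all <- rbind(o_cavity, o_bulk)
  for (i in seq_len(nw))
    add_atoms(c("O", "H1", "H2"), c("O", "H", "H"), .water_sites(o_all[i, ]),
              "SOL", resno0 + i, "W", "water")
  atoms <- do.call(rbind, rows)

  frames <- vector("list", n_frames)
  frames[[1L]] <- structure_model(atoms, model_id = 1L)
  for (f in seq_len(n_frames)[-1]) {
    a <- atoms
    if (jitter_sd > 0) {
      ax <- .rand_unit(); ang <- rnorm(1, sd = jitter_sd / 10)
      K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
                  3, 3, byrow = TRUE)
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
      tr <- rnorm(3, sd = jitter_sd)
      xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
      a$x <- xyz[, 1] + tr[1]; a$y <- xyz[, 2] + tr[2]; a$z <- xyz[, 3] + tr[3]
    }
    frames[[f]] <- structure_model(a, model_id = f)
  }

  ptab <- data.frame(
    resname = c("SOL", "SOL", "SOL", "CAG"),
    name = c("O", "H1", "H2", "*ANY"),
    charge_e = c(.WATER_Q_O, .WATER_Q_H, .WATER_Q_H, 0),
    sigma_A = c(.WATER_SIG_O, 1.0, 1.0, .CAGE_SIG),
    epsilon_kJmol = c(.WATER_EPS_O, 0, 0, .CAGE_EPS),
    stringsAsFactors = FALSE)
  # cage atoms have distinct names; expand the wildcard row explicitly
  ptab <- ptab[ptab$name != "*ANY", ]
  ptab <- rbind(ptab, data.frame(resname = "CAG",
                                 name = sprintf("C%d", seq_len(n_cage)),
                                 charge_e = 0, sigma_A = .CAGE_SIG,
                                 epsilon_kJmol = .CAGE_EPS))
  if (!is.null(lig)) {
    ljl <- t(vapply(lig$atoms$element,
                    function(e) .LIG_LJ[[e]] %||% c(3.4, 0.3), numeric(2)))
    ptab <- rbind(ptab, data.frame(resname = lig$resname,
                                   name = lig$atoms$name,
                                   charge_e = lig$atoms$charge_e,
                                   sigma_A = ljl[, 1],
                                   epsilon_kJmol = ljl[, 2]))
  }
  params <- nonbonded_params(ptab, cutoff_A = cutoff_A)

  labels <- list(
    cavity_resnos = if (n_cavity_waters) resno0 + seq_len(n_cavity_waters)
                    else integer(0),
    bulk_resnos = if (n_bulk_waters)
      resno0 + n_cavity_waters + seq_len(n_bulk_waters) else integer(0))
  structure(list(
    trajectory = trajectory(frames), params = params,
    cavity = cavity_definition(mode = "point_sphere", center = c(0, 0, 0),
                               cutoff_A = cavity_radius),
    labels = labels,
    metadata = list(seed = seed, n_cavity_waters = n_cavity_waters,
                    n_bulk_waters = n_bulk_waters,
                    cavity_radius = cavity_radius,
                    shell_inner = shell_inner, shell_outer = shell_outer,
                    cage_radius = cage_radius, n_frames = n_frames,
                    jitter_sd = jitter_sd,
                    ligand = if (is.null(lig)) NULL else lig$name)),
    class = "pocket_system")
}

#' Write a pocket system to disk
#'
#' Emits the trajectory as a multi-model PDB, the nonbonded parameters as a
#' delimited table, and the ground truth (labels, generating parameters,
#' seed) as a JSON sidecar.
#'
#' @param sys a `pocket_system` from [generate_pocket_system()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_pocket_system <- function(sys, dir) {
  stopifnot(inherits(sys, "pocket_system"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trajectory = file.path(dir, "trajectory.pdb"),
             params = file.path(dir, "params.csv"),
             truth = file.path(dir, "truth.json"))
  write_pdb(sys$trajectory, paths[["trajectory"]])
  write_params_table(sys$params, paths[["params"]])
  jsonlite::write_json(list(labels = sys$labels, metadata = sys$metadata,
                            cavity = unclass(sys$cavity)),
                       paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
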