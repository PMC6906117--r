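# Idealized heavy-atom ligand templates for the four alkanesulfonate-class
# ligands: taurine, its phosphonate analogue 2-AEP, and the extended
# analogues ACES and MES. Geometries use standard bond lengths (C-S 1.79,
# S-O 1.45, C-P 1.80, P-O 1.51, C-N 1.47, C-C 1.53 Angstrom) on an
# idealized tetrahedral backbone; they are templates for synthetic systems
# and contact typing, not refined structures.

.TET <- 109.47 * pi / 180

# zigzag backbone: successive bond directions alternate +/- half the
# tetrahedral angle about x, so consecutive bonds subtend 109.47 deg
.chain_positions <- function(lengths) {
  theta <- (pi - .TET) / 2
  pos <- matrix(0, nrow = length(lengths) + 1L, ncol = 3)
  for (i in seq_along(lengths)) {
    dir <- c(cos(theta), sin(theta) * (-1)^(i - 1L), 0)
    pos[i + 1L, ] <- pos[i, ] + lengths[i] * dir
  }
  pos
}

# three substituent positions around `center`, tetrahedral to the incoming
# bond direction `axis`, at distance `len`
.tripod <- function(center, axis, len) {
  a <- axis / sqrt(sum(axis^2))
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * a) * a; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  ang <- pi - .TET
  t(vapply(c(0, 2 * pi / 3, 4 * pi / 3), function(phi) {
    center + len * (cos(ang) * a + sin(ang) * (cos(phi) * e1 + sin(phi) * e2))
  }, numeric(3)))
}

.template_atoms <- function(names, elements, xyz, charges) {
  data.frame(name = names, element = elements,
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             charge_e = charges, stringsAsFactors = FALSE)
}

#' Idealized ligand template
#'
#' Heavy-atom template for one of the supported ligands: atoms with
#' idealized coordinates and smeared formal charges, plus a bond list.
#' The headgroup (sulfonate or phosphonate) carries the net formal charge
#' of -1 (central atom +0.8, each terminal oxygen -0.6); the amine is kept
#' neutral, so every template sums to -1 e. The convention is recorded in
#' the `charge_convention` metadata field.
#'
#' @param name one of `"taurine"`, `"2-AEP"`, `"ACES"`, `"MES"`.
#' @return object of class `ligand_template`: `name`, `resname`, `atoms`
#'   (name, element, x, y, z, charge_e), `bonds` (atom index pairs),
#'   `charge_convention`.
#' @export
ligand_template <- function(name) {
  headgroup <- function(chain_xyz, o_len) {
    # chain_xyz rows: backbone ending at the headgroup central atom
    nb <- nrow(chain_xyz)
    axis <- chain_xyz[nb, ] - chain_xyz[nb - 1L, ]
    list(oxygens = .tripod(chain_xyz[nb, ], axis, o_len))
  }
  if (name == "taurine") {
    # N-C-C-S(O3): 2-aminoethanesulfonate
    chain <- .chain_positions(c(1.47, 1.53, 1.79))   # N,C1,C2,S
    hg <- headgroup(chain, 1.45)
    xyz <- rbind(chain, hg$oxygens)
    atoms <- .template_atoms(
      c("N", "C1", "C2", "S", "O1", "O2", "O3"),
      c("N", "C", "C", "S", "O", "O", "O"), xyz,
      c(0, 0, 0, 0.8, -0.6, -0.6, -0.6))
    bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(4, 6), c(4, 7))
    resname <- "TAU"
  } else if (name == "2-AEP") {
    # N-C-C-P(O3): phosphonate analogue of taurine
    chain <- .chain_positions(c(1.47, 1.53, 1.80))   # N,C1,C2,P
    hg <- headgroup(chain, 1.51)
    xyz <- rbind(chain, hg$oxygens)
    atoms <- .template_atoms(
      c("N", "C1", "C2", "P", "O1", "O2", "O3"),
      c("N", "C", "C", "P", "O", "O", "O"), xyz,
      c(0, 0, 0, 0.8, -0.6, -0.6, -0.6))
    bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(4, 6), c(4, 7))
    resname <- "AEP"
  } else if (name == "ACES") {
    # acetamido-extended aminoethanesulfonate: heavy-atom backbone
    # ND-CC(=OC)-CM-NE-C1-C2-S(O3), amide C-N 1.35
    chain <- .chain_positions(c(1.35, 1.53, 1.47, 1.47, 1.53, 1.79))
    hg <- headgroup(chain, 1.45)
    # amide carbonyl O on CC, perpendicular off-chain
    oc <- chain[2, ] + c(0, 0, 1.23)
    xyz <- rbind(chain, oc, hg$oxygens)
    atoms <- .template_atoms(
      c("ND", "CC", "CM", "NE", "C1", "C2", "S", "OC", "O1", "O2", "O3"),
      c("N", "C", "C", "N", "C", "C", "S", "O", "O", "O", "O"), xyz,
      c(0, 0, 0, 0, 0, 0, 0.8, 0, -0.6, -0.6, -0.6))
    bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 7),
                   c(2, 8), c(7, 9), c(7, 10), c(7, 11))
    resname <- "ACE"
  } else if (name == "MES") {
    # morpholine ring (N + 4C + ring O) with N-CH2-CH2-SO3 arm
    ring_r <- 1.47 / (2 * sin(pi / 6))   # planar hexagon, ~1.47 A edges
    ang <- seq(0, by = pi / 3, length.out = 6)
    ring <- cbind(ring_r * cos(ang), ring_r * sin(ang), 0)
    # ring order: N, CR1, CR2, OR, CR3, CR4 (O opposite N)
    narm <- ring[1, ]
    arm_dir <- narm / sqrt(sum(narm^2))
    c1 <- narm + 1.47 * arm_dir
    c2 <- c1 + 1.53 * c(arm_dir[1] * cos(0.6) - arm_dir[2] * sin(0.6),
                        arm_dir[1] * sin(0.6) + arm_dir[2] * cos(0.6), 0)
    sdir <- (c2 - c1) / sqrt(sum((c2 - c1)^2))
    s <- c2 + 1.79 * sdir
    os <- .tripod(s, s - c2, 1.45)
    xyz <- rbind(ring, c1, c2, s, os)
    atoms <- .template_atoms(
      c("N", "CR1", "CR2", "OR", "CR3", "CR4", "C1", "C2", "S",
        "O1", "O2", "O3"),
      c("N", "C", "C", "O", "C", "C", "C", "C", "S", "O", "O", "O"), xyz,
      c(0, 0, 0, 0, 0, 0, 0, 0, 0.8, -0.6, -0.6, -0.6))
    bonds <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 6), c(6, 1),
                   c(1, 7), c(7, 8), c(8, 9), c(9, 10), c(9, 11), c(9, 12))
    resname <- "MES"
  } else {
    stop_cavitherm(paste("unsupported ligand:", name),
                   "cavitherm_unsupported_ligand_error")
  }
  # connectivity must be one component
  g <- split(c(bonds[, 2], bonds[, 1]), c(bonds[, 1], bonds[, 2]))
  seen <- rep(FALSE, nrow(atoms)); queue <- 1L; seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in g[[as.character(v)]] %||% integer(0))
      if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  stopifnot(all(seen))
  structure(list(name = name, resname = resname, atoms = atoms,
                 bonds = bonds,
                 charge_convention = paste(
                   "net -1 e on the anionic headgroup (+0.8 central atom,",
                   "-0.6 per terminal oxygen); amine neutral")),
            class = "ligand_template")
}
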