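# constructed complex: a glutamine-like residue plus a taurine molecule
make_complex <- function(lig_shift = c(0, 0, 0)) {
  prot <- make_atoms(c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2"),
                     c("N", "C", "C", "O", "C", "C", "C", "O", "N"),
                     "GLN", 30,
                     rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.3, 0),
                           c(1.8, 2.4, 0), c(2.0, -1.3, 0.5),
                           c(3.5, -1.5, 0.5), c(4.0, -2.9, 0.6),
                           c(3.2, -3.85, 0.6), c(5.3, -3.1, 0.7)),
                     chain = "A")
  tpl <- ligand_template("taurine")
  lx <- as.matrix(tpl$atoms[, c("x", "y", "z")])
  lx <- sweep(lx, 2, -c(7.0, -3.0, 0.6) - lig_shift)  # place near NE2
  lig <- make_atoms(tpl$atoms$name, tpl$atoms$element, "TAU", 900, lx,
                    chain = "A", serial = 100 + seq_len(nrow(lx)))
  structure_model(rbind(prot, lig))
}

test_that("hydrogen bonds obey the distance criterion in hydrogen-free mode", {
  # ligand sulfonate O placed 2.9 A from the backbone N
  prot <- make_atoms(c("N", "O"), c("N", "O"), "GLY", 10,
                     rbind(c(0, 0, 0), c(3.0, 3.0, 3.0)))
  lig <- make_atoms(c("O1", "C1"), c("O", "C"), "TAU", 900,
                    rbind(c(2.9, 0, 0), c(4.3, 0.8, 0)),
                    serial = 10:11)
  model <- structure_model(rbind(prot, lig))
  hb <- find_hbonds(model, "TAU")
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$ligand_atom, "O1")
  expect_equal(hb$partner_atom, "N")
  expect_equal(hb$distance_A, 2.9, tolerance = 1e-9)
  expect_true(is.na(hb$angle_deg))
  # same pair at 5.0 A: not reported
  lig2 <- lig; lig2$x[1] <- 5.0
  far <- structure_model(rbind(prot, lig2))
  expect_equal(nrow(find_hbonds(far, "TAU")), 0L)
  expect_error(find_hbonds(model, "XXX"),
               class = "cavitherm_selection_error")
})

test_that("explicit hydrogens enforce the donor-H-acceptor angle", {
  geom <- function(h_angle_deg) {
    # donor N at origin, H on the x axis, acceptor O at 2.9 A from N placed
    # so the N-H...A angle at H equals h_angle_deg
    h <- c(1.0, 0, 0)
    th <- h_angle_deg * pi / 180
    # direction from H making angle th with (N - H) = (-1, 0, 0)
    acc <- h + 1.95 * c(cos(pi - th), sin(pi - th), 0)
    prot <- make_atoms(c("N", "H"), c("N", "H"), "GLY", 10,
                       rbind(c(0, 0, 0), h))
    lig <- make_atoms("O1", "O", "TAU", 900, matrix(acc, 1), serial = 5L)
    structure_model(rbind(prot, lig))
  }
  crit <- hbond_criteria(hydrogen_free = FALSE)
  hb_good <- find_hbonds(geom(150), "TAU", crit)
  expect_equal(nrow(hb_good), 1L)
  expect_equal(hb_good$angle_deg, 150, tolerance = 1e-6)
  expect_equal(nrow(find_hbonds(geom(100), "TAU", crit)), 0L)
})

test_that("van der Waals contacts exclude hydrogen-bonded pairs", {
  model <- make_complex()
  hb <- find_hbonds(model, "TAU")
  vdw <- find_vdw_contacts(model, "TAU")
  expect_gt(nrow(vdw), 0L)
  expect_true(all(vdw$distance_A <= 4.0))
  if (nrow(hb)) {
    overlap <- merge(as.data.frame(hb)[c("ligand_atom", "partner_atom",
                                         "partner_resno")],
                     as.data.frame(vdw)[c("ligand_atom", "partner_atom",
                                          "partner_resno")])
    expect_equal(nrow(overlap), 0L)
  }
  # reports are deterministic and order-stable
  expect_identical(find_vdw_contacts(model, "TAU"), vdw)
  # a ring-carbon pair at 3.8 A is a vdW contact
  prot <- make_atoms("CD1", "C", "PHE", 50, matrix(c(0, 0, 0), 1))
  lig <- make_atoms("C1", "C", "TAU", 900, matrix(c(3.8, 0, 0), 1),
                    serial = 2L)
  m2 <- structure_model(rbind(prot, lig))
  expect_equal(nrow(find_vdw_contacts(m2, "TAU")), 1L)
  lig3 <- lig; lig3$x <- 4.5
  expect_equal(nrow(find_vdw_contacts(structure_model(rbind(prot, lig3)),
                                      "TAU")), 0L)
})

make_ca_model <- function(xyz, chain = "A") {
  structure_model(make_atoms(rep("CA", nrow(xyz)), rep("C", nrow(xyz)),
                             "ALA", seq_len(nrow(xyz)), xyz, chain = chain))
}

test_that("superposition of a model onto itself is the identity", {
  set.seed(2)
  m <- make_ca_model(matrix(rnorm(3 * 40, sd = 8), ncol = 3))
  s <- superpose(m, m)
  expect_equal(s$rmsd_A, 0, tolerance = 1e-9)
  expect_equal(s$rotation, diag(3), tolerance = 1e-9)
  expect_equal(s$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(s$n_atoms_matched, 40L)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
})

test_that("superposition recovers an applied rigid transform", {
  set.seed(3)
  xyz <- matrix(rnorm(3 * 30, sd = 6), ncol = 3)
  m <- make_ca_model(xyz)
  R90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- make_ca_model(xyz %*% t(R90) +
                           matrix(c(4, -2, 9), 30, 3, byrow = TRUE))
  s <- superpose(m, moved)
  expect_equal(s$rmsd_A, 0, tolerance = 1e-9)
  expect_equal(s$rotation %*% R90, diag(3), tolerance = 1e-9)
  # agrees with the bio3d reference implementation
  ref_rmsd <- bio3d::rmsd(as.vector(t(xyz)),
                          as.vector(t(coords(moved))), fit = TRUE)
  expect_equal(s$rmsd_A, ref_rmsd, tolerance = 1e-6)
  expect_error(superpose(make_ca_model(xyz[1:2, ]),
                         make_ca_model(xyz[1:2, ])),
               class = "cavitherm_underdetermined_error")
})

test_that("rmsd under isotropic noise matches its closed-form expectation", {
  # with iid N(0, sigma) noise on each coordinate the expected rmsd is
  # close to sigma * sqrt(3) for many atoms
  set.seed(11)
  xyz <- matrix(rnorm(3 * 200, sd = 10), ncol = 3)
  m <- make_ca_model(xyz)
  sigma <- 0.5
  rmsds <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    noisy <- make_ca_model(xyz + matrix(rnorm(length(xyz), sd = sigma),
                                        ncol = 3))
    superpose(m, noisy)$rmsd_A
  }, 0)
  expect_lt(abs(mean(rmsds) - sigma * sqrt(3)) / (sigma * sqrt(3)), 0.1)
})

test_that("rmsd is invariant under rigid pre-transformation of either input", {
  set.seed(4)
  xyz <- matrix(rnorm(3 * 25, sd = 5), ncol = 3)
  noisy <- xyz + matrix(rnorm(length(xyz), sd = 0.8), ncol = 3)
  base <- superpose(make_ca_model(xyz), make_ca_model(noisy))$rmsd_A
  th <- 1.1
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3,
              byrow = TRUE)
  pre <- superpose(make_ca_model(xyz %*% t(R) + 7),
                   make_ca_model(noisy))$rmsd_A
  expect_equal(pre, base, tolerance = 1e-9)
})

test_that("conserved-water matching is greedy, capped and oracle-equal at small n", {
  w_at <- function(pos, resnos, chain = "W")
    structure_model(do.call(rbind, lapply(seq_len(nrow(pos)), function(i)
      make_water(pos[i, ], resnos[i], chain))))
  pos <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 5, 0))
  a <- w_at(pos, 1:3)
  m <- conserved_waters(a, a)
  expect_equal(nrow(m$matched), 3L)
  expect_equal(m$matched$distance_A, rep(0, 3))
  # one water displaced by 2 A under a 1 A radius: unmatched on both sides
  pos_b <- pos; pos_b[2, 1] <- pos_b[2, 1] + 2
  b <- w_at(pos_b, 11:13)
  m2 <- conserved_waters(a, b, match_radius_A = 1)
  expect_equal(nrow(m2$matched), 2L)
  expect_true("W/2" %in% m2$unmatched_a)
  expect_true("W/12" %in% m2$unmatched_b)
  # matching count never exceeds min of the two water counts; greedy equals
  # exhaustive search for random small sets
  set.seed(31)
  for (k in 1:10) {
    na <- sample(3:6, 1); nb <- sample(3:6, 1)
    pa <- matrix(runif(3 * na, 0, 6), ncol = 3)
    pb <- matrix(runif(3 * nb, 0, 6), ncol = 3)
    ga <- w_at(pa, seq_len(na))
    gb <- w_at(pb, seq_len(nb))
    got <- conserved_waters(ga, gb, match_radius_A = 1.5)
    expect_lte(nrow(got$matched), min(na, nb))
    best <- oracle_water_matching(pa, pb, 1.5)
    expect_equal(nrow(got$matched), best$count)
  }
})
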