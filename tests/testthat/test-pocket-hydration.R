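test_that("cavity census matches generator labels exactly", {
  sys <- generate_pocket_system(n_cavity_waters = 5, n_bulk_waters = 20,
                                seed = 41)
  got <- find_cavity_waters(sys$trajectory$frames[[1L]], sys$cavity)
  expect_setequal(as.integer(sub("W/", "", got)), sys$labels$cavity_resnos)
  # a frame without waters gives an empty census
  cage_only <- sys$trajectory$frames[[1L]]
  cage_only <- structure_model(
    cage_only$atoms[cage_only$atoms$kind != "water", ])
  expect_identical(find_cavity_waters(cage_only, sys$cavity), character(0))
})

test_that("the cavity boundary is inclusive and enlarging it never shrinks the census", {
  atoms <- rbind(make_water(c(5, 0, 0), 1),       # exactly at the cutoff
                 make_water(c(0, 5.001, 0), 2),   # just outside
                 make_water(c(1, 0, 0), 3))
  frame <- structure_model(atoms)
  cav <- cavity_definition("point_sphere", center = c(0, 0, 0), cutoff_A = 5)
  got <- find_cavity_waters(frame, cav)
  expect_setequal(got, c("W/1", "W/3"))
  for (cut in c(2, 4, 5, 6, 8)) {
    small <- find_cavity_waters(frame, cavity_definition(
      "point_sphere", center = c(0, 0, 0), cutoff_A = cut))
    big <- find_cavity_waters(frame, cavity_definition(
      "point_sphere", center = c(0, 0, 0), cutoff_A = cut + 1))
    expect_true(all(small %in% big))
  }
})

test_that("residue-shell cavities resolve selectors or fail loudly", {
  sys <- generate_pocket_system(n_cavity_waters = 3, n_bulk_waters = 0,
                                seed = 8)
  frame <- sys$trajectory$frames[[1L]]
  shell <- cavity_definition("residue_shell", resnos = 1L,
                             cutoff_A = sys$metadata$cage_radius + 1)
  got <- find_cavity_waters(frame, shell)   # every cavity water is within
  expect_setequal(as.integer(sub("W/", "", got)), sys$labels$cavity_resnos)
  expect_error(find_cavity_waters(frame,
                                  cavity_definition("residue_shell",
                                                    resnos = 999L)),
               class = "cavitherm_selection_error")
})

test_that("pair energies follow the closed forms and are symmetric", {
  par <- nonbonded_params(data.frame(
    resname = c("A", "B"), name = c("X", "Y"),
    charge_e = c(1, -1), sigma_A = c(3, 3), epsilon_kJmol = c(0, 0)),
    cutoff_A = 12)
  at <- function(resname, name, x) list(resname = resname, name = name,
                                        x = x, y = 0, z = 0)
  # pure Coulomb: +1/-1 at 10 A
  expect_equal(pair_energy(at("A", "X", 0), at("B", "Y", 10), par),
               -138.935458, tolerance = 1e-9)
  # LJ root: neutral atoms at r = sigma_ij
  par2 <- nonbonded_params(data.frame(
    resname = c("A", "B"), name = c("X", "Y"),
    charge_e = c(0, 0), sigma_A = c(3.0, 3.4), epsilon_kJmol = c(0.5, 0.7)),
    cutoff_A = 12)
  expect_equal(pair_energy(at("A", "X", 0), at("B", "Y", 3.2), par2), 0,
               tolerance = 1e-12)
  # beyond the cutoff the interaction vanishes
  expect_equal(pair_energy(at("A", "X", 0), at("B", "Y", 12.5), par2), 0)
  expect_error(pair_energy(at("A", "X", 0), at("B", "Y", 0), par2),
               class = "cavitherm_singularity_error")
  # symmetry over random pairs
  set.seed(7)
  for (k in 1:50) {
    a1 <- at("A", "X", runif(1, 2, 11)); a1$y <- runif(1, -3, 3)
    a2 <- at("B", "Y", runif(1, -2, 2)); a2$z <- runif(1, -3, 3)
    expect_equal(pair_energy(a1, a2, par2), pair_energy(a2, a1, par2),
                 tolerance = 1e-12)
  }
})

test_that("per-water energies halve water-water terms and sum to brute-force totals", {
  # an isolated water has zero potential energy
  lone <- structure_model(make_water(c(0, 0, 0), 1))
  expect_equal(water_potential_energy(lone, "W/1", water_params()), 0)
  # dimer: each water carries half the interaction, sum equals the total
  dimer <- structure_model(rbind(make_water(c(0, 0, 0), 1),
                                 make_water(c(0, 2.8, 0), 2)))
  p <- water_params()
  e1 <- water_potential_energy(dimer, "W/1", p)
  e2 <- water_potential_energy(dimer, "W/2", p)
  tot <- oracle_group_energy(dimer, p, seq_len(6))
  expect_equal(e1, e2, tolerance = 1e-12)
  expect_equal(e1 + e2, tot, tolerance = 1e-9)
})

test_that("summed per-water energies equal the naive double loop on generated frames", {
  sys <- generate_pocket_system(n_cavity_waters = 8, n_bulk_waters = 25,
                                ligand = "taurine", seed = 55)
  frame <- sys$trajectory$frames[[1L]]
  p <- sys$params
  a <- frame$atoms
  expect_lte(nrow(a), 500)
  w_idx <- which(a$kind == "water")
  ids <- unique(paste(a$chain[w_idx], a$resno[w_idx], sep = "/"))
  e <- vapply(ids, function(id) water_potential_energy(frame, id, p), 0)
  # waters-only subframe: sum of per-water energies = total water-water energy
  wf <- structure_model(a[w_idx, , drop = FALSE])
  ew <- vapply(ids, function(id) water_potential_energy(wf, id, p), 0)
  brute_ww <- oracle_group_energy(wf, p, seq_len(nrow(wf$atoms)))
  expect_equal(sum(ew), brute_ww, tolerance = 1e-9 * abs(brute_ww))
  # full frame: add each water's full share of the water-solute energy
  brute_ws <- oracle_group_energy(frame, p, w_idx,
                                  which(a$kind != "water"))
  expect_equal(sum(e), brute_ww + brute_ws,
               tolerance = 1e-9 * abs(brute_ww + brute_ws))
})

test_that("energies and censuses are invariant under rigid transformation", {
  sys <- generate_pocket_system(n_cavity_waters = 6, n_bulk_waters = 10,
                                seed = 77)
  frame <- sys$trajectory$frames[[1L]]
  id <- paste0("W/", sys$labels$cavity_resnos[1])
  e0 <- water_potential_energy(frame, id, sys$params)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  tr <- c(5, -3, 11)
  a <- frame$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + tr[1]; a$y <- xyz[, 2] + tr[2]; a$z <- xyz[, 3] + tr[3]
  moved <- structure_model(a)
  expect_equal(water_potential_energy(moved, id, sys$params), e0,
               tolerance = 1e-9 * abs(e0))
  cav_moved <- cavity_definition("point_sphere",
                                 center = as.vector(R %*% c(0, 0, 0)) + tr,
                                 cutoff_A = sys$cavity$cutoff_A)
  expect_setequal(find_cavity_waters(moved, cav_moved),
                  find_cavity_waters(frame, sys$cavity))
})

test_that("bulk reference averages far waters and errors when none exist", {
  # pure water box: every water qualifies, so the bulk reference equals the
  # plain mean per-water energy
  set.seed(5)
  pos <- matrix(runif(3 * 12, -8, 8), ncol = 3)
  keep <- rep(TRUE, nrow(pos))
  for (i in 2:nrow(pos))
    if (min(sqrt(rowSums(sweep(pos[seq_len(i - 1), , drop = FALSE], 2,
                               pos[i, ])^2))) < 2.4) keep[i] <- FALSE
  pos <- pos[keep, , drop = FALSE]
  atoms <- do.call(rbind, lapply(seq_len(nrow(pos)),
                                 function(i) make_water(pos[i, ], i)))
  box <- structure_model(atoms)
  p <- water_params()
  ids <- paste0("W/", seq_len(nrow(pos)))
  all_e <- vapply(ids, function(id) water_potential_energy(box, id, p), 0)
  expect_equal(bulk_reference_energy(box, p, bulk_distance_A = 10),
               mean(all_e), tolerance = 1e-12)
  # pocket without bulk waters: typed no-bulk error
  sys <- generate_pocket_system(n_cavity_waters = 4, n_bulk_waters = 0,
                                seed = 3)
  expect_error(bulk_reference_energy(sys$trajectory, sys$params, 10),
               class = "cavitherm_no_bulk_error")
})

test_that("hydration summaries average the census and record the median frame", {
  sys <- generate_pocket_system(n_cavity_waters = 7, n_bulk_waters = 5,
                                n_frames = 10, seed = 13)
  hs <- hydration_summary(sys$trajectory, sys$cavity, sys$params, "apo")
  expect_equal(hs$N_bar, 7)                 # frozen waters: exact
  expect_equal(hs$counts, rep(7L, 10))
  expect_equal(hs$median_frame, 1L)         # ties -> lowest index
  expect_true(is.finite(hs$E_bar_kJmol))
  expect_error(hydration_summary(trajectory(sys$trajectory$frames[0]),
                                 sys$cavity, sys$params),
               class = "cavitherm_validation_error")
})

test_that("the median-count frame rule picks the distribution median, lowest index first", {
  sys <- generate_pocket_system(n_cavity_waters = 3, n_bulk_waters = 0,
                                n_frames = 5, seed = 19)
  frames <- sys$trajectory$frames
  # push one cavity water out of the cavity in frames 4 and 5
  for (f in 4:5) {
    a <- frames[[f]]$atoms
    w <- a$resno == sys$labels$cavity_resnos[1] & a$kind == "water"
    a$x[w] <- a$x[w] + 50
    frames[[f]] <- structure_model(a, model_id = f)
  }
  hs <- hydration_summary(trajectory(frames), sys$cavity, sys$params, "apo")
  expect_equal(hs$counts, c(3L, 3L, 3L, 2L, 2L))
  expect_equal(median(hs$counts), 3)
  expect_equal(hs$median_frame, 1L)
})

test_that("the desolvation score is a state difference with the right algebra", {
  apo <- hydration_summary_from_averages(20.2, -93.4, "apo")
  tau <- hydration_summary_from_averages(17.5, -94.4, "taurine")
  d <- desolvation_score(apo, tau)
  expect_equal(d$D_kJmol, 17.5 * (-94.4) - 20.2 * (-93.4), tolerance = 1e-12)
  # self-comparison is zero, swapping states flips the sign
  expect_equal(desolvation_score(apo, apo)$D_kJmol, 0)
  expect_equal(desolvation_score(tau, apo)$D_kJmol, -d$D_kJmol)
  # mismatched cavity definitions are rejected
  s1 <- generate_pocket_system(n_cavity_waters = 2, n_bulk_waters = 0,
                               seed = 1)
  s2 <- generate_pocket_system(n_cavity_waters = 2, n_bulk_waters = 0,
                               cavity_radius = 5, seed = 1)
  h1 <- hydration_summary(s1$trajectory, s1$cavity, s1$params, "a")
  h2 <- hydration_summary(s2$trajectory, s2$cavity, s2$params, "b")
  expect_error(desolvation_score(h1, h2),
               class = "cavitherm_validation_error")
})
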