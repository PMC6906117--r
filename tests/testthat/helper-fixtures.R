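# Small in-code fixtures: hand-built atoms/models and a standard synthetic
# recovery scenario shared by the fit tests.

make_atoms <- function(name, element, resname, resno, xyz, chain = "A",
                       kind = NULL, serial = NULL) {
  n <- length(name)
  if (is.null(kind))
    kind <- ifelse(resname %in% c("HOH", "WAT", "SOL", "TIP"), "water",
                   ifelse(resname %in% c("TAU", "AEP", "ACE", "MES", "LIG"),
                          "ligand", "protein"))
  data.frame(serial = serial %||% seq_len(n), name = name, element = element,
             resname = resname, resno = resno,
             chain = rep_len(chain, n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, b = 0, altloc = "", kind = rep_len(kind, n),
             stringsAsFactors = FALSE)
}

# a single 3-site water at the given oxygen position (fixed orientation);
# serials derived from resno so waters can be rbind-ed safely
make_water <- function(o, resno, chain = "W") {
  xyz <- rbind(o, o + c(0.9572, 0, 0), o + c(-0.24, 0.927, 0))
  make_atoms(c("O", "H1", "H2"), c("O", "H", "H"), "SOL", resno, xyz,
             chain = chain, serial = (resno - 1L) * 3L + 1:3)
}

water_params <- function(cutoff_A = 10) {
  nonbonded_params(data.frame(
    resname = "SOL", name = c("O", "H1", "H2"),
    charge_e = c(-0.8476, 0.4238, 0.4238),
    sigma_A = c(3.166, 1, 1), epsilon_kJmol = c(0.650, 0, 0)),
    cutoff_A = cutoff_A)
}

# the standard parameter-recovery scenario: weak-endothermic-analogue truth,
# c = n * M0 * Ka ~ 20, 17 injections, syringe loaded for a final molar
# ratio of ~2 (the usual titration design), noise at 1% of the peak heat.
# Without a dilution heat there is no control experiment to subtract, so
# the fitted isotherm carries exactly the stated noise.
recovery_truth <- function() binding_params(n = 0.8, Ka = 1 / 2.85e-6,
                                            dH_kJmol = 4.74)

recovery_thermogram <- function(seed, noise_frac = 0.01,
                                dilution_heat_uJ = 0) {
  truth <- recovery_truth()
  M0 <- 20 / (truth$n * truth$Ka)
  proto <- default_protocol(cell_conc_M = M0, syringe_conc_M = 10 * M0)
  clean <- single_site_model(truth, proto)
  tg <- generate_isotherm(truth, proto,
                          noise_sd_uJ = noise_frac * max(abs(clean)),
                          dilution_heat_uJ = dilution_heat_uJ, seed = seed)
  if (dilution_heat_uJ == 0) tg$control_heats_uJ <- NULL
  tg
}
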