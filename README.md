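# cavitherm

Tools for dissecting why a substrate-binding protein (SBP) prefers one
small ligand over chemically similar analogues, from two complementary
directions:

1. **Binding thermodynamics from isothermal titration calorimetry (ITC).**
   Raw power traces or per-injection heat tables are turned into fitted
   single-site parameters (stoichiometry *n*, association constant *K*a,
   enthalpy ΔH) with derived *K*d = 1/*K*a, ΔG = −RT ln *K*a and
   ΔS = (ΔH − ΔG)/T, and cross-ligand difference tables
   ΔΔH = ΔH_ligand − ΔH_ref and ΔΔS = ΔS_ligand − ΔS_ref.
2. **Binding-cavity hydration.** For structure/trajectory frames, a census
   of cavity waters, per-water potential energies (Lennard-Jones + Coulomb
   with Lorentz–Berthelot combining and a plain cutoff), a bulk-water
   reference, and a desolvation penalty score
   D = N̄_holo·Ē_holo − N̄_apo·Ē_apo comparing the total cavity-water
   stabilization of bound and ligand-free states.

Around that core the package provides protein–ligand contact chemistry
(hydrogen bonds and van der Waals contacts), Kabsch superposition with
RMSD, conserved-water matching between superposed complexes, PDB and
delimited-table I/O, and a synthetic-data module that generates ITC
thermograms and labeled solvated-pocket configurations with known ground
truth, so every stage is testable without external data.

The motivating system is the taurine-specific periplasmic SBP of an ABC
importer and its alkanesulfonate analogues (the phosphonate analogue
2-AEP, the extended sulfonates ACES and MES), but nothing in the code is
specific to that protein.

## The models

**Single-site isotherm.** With cumulative injected volume *v*ᵢ into a cell
of volume *V*₀, effective concentrations follow the standard overflow-cell
approximation Mᵢ = M₀(1 − vᵢ/2V₀), Xᵢ = X₀(vᵢ/V₀)(1 − vᵢ/2V₀); the
cumulative heat is

    Q_i = (n M_i ΔH V0 / 2) [ S − sqrt(S² − 4 X_i/(n M_i)) ],
    S   = 1 + X_i/(n M_i) + 1/(n Ka M_i)

and per-injection heats carry the displaced-volume correction
δQᵢ = Qᵢ − Qᵢ₋₁ + (dVᵢ/V₀)(Qᵢ + Qᵢ₋₁)/2. Fits use Levenberg–Marquardt
least squares with *K*a parameterized in log space; *n* may be held fixed,
and the first injection is dropped by default (the usual discard of the
diffusion-contaminated first peak).

**Per-water potential energy.** For water *w*,
E_w = Σ u(a, j) over atoms *a* of *w* and atoms *j* outside *w*, with
u = 4ε[(σ/r)¹² − (σ/r)⁶] + f q_i q_j / r (f = 1389.35458 kJ mol⁻¹ Å e⁻²)
and water–water pair energies split half/half between the two waters so
that per-water energies sum exactly to the total.

## Worked example

```r
library(cavitherm)

# --- ITC: simulate a weak-binder titration (Kd = 2.85 uM, n = 0.8,
#     dH = +4.74 kJ/mol, c = n*M0*Ka = 20, 17 x 2.4 ul injections) and fit
truth <- binding_params(n = 0.8, Ka = 1 / 2.85e-6, dH_kJmol = 4.74)
M0    <- 20 / (truth$n * truth$Ka)
proto <- default_protocol(cell_conc_M = M0, syringe_conc_M = 10 * M0)
tg    <- generate_isotherm(truth, proto, noise_sd_uJ = 0.1, seed = 42)
tg$control_heats_uJ <- NULL          # no dilution heat in this simulation
fit_single_site(tg, ligand = "MES")
#> <binding_fit> MES: Kd = 3.01e-06 M, n = 0.809, dH = 4.759 kJ/mol, dS = 122 J/mol/K (T = 298 K)

# --- hydration: ligand-free vs bound synthetic pockets
apo  <- generate_pocket_system(n_cavity_waters = 8, n_bulk_waters = 20,
                               n_frames = 5, seed = 11)
holo <- generate_pocket_system(n_cavity_waters = 5, n_bulk_waters = 20,
                               ligand = "taurine", n_frames = 5, seed = 11)
h_apo  <- hydration_summary(apo$trajectory,  apo$cavity,  apo$params,  "apo")
h_holo <- hydration_summary(holo$trajectory, holo$cavity, holo$params, "taurine")
desolvation_score(h_apo, h_holo)
#> <desolvation_score> taurine vs apo: D = -95.03 kJ/mol
```

The fit recovers the generating parameters (Kd 3.0 vs 2.85 µM, n 0.81 vs
0.80, ΔH 4.76 vs 4.74 kJ/mol) from a noisy 17-point isotherm. The
desolvation score is the change in total cavity-water stabilization
(mean count × mean per-water energy) on binding: a positive score means
the bound cavity has lost water stabilization relative to the ligand-free
one. Published per-state averages can be fed in directly through
`hydration_summary_from_averages()`.

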