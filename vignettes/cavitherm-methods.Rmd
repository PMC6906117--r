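---
title: "Methods: binding thermodynamics and cavity hydration in cavitherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binding thermodynamics and cavity hydration in cavitherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cavitherm)
```

cavitherm quantifies ligand specificity of a substrate-binding protein
from two sides: the thermodynamics of binding measured by isothermal
titration calorimetry (ITC), and the hydration of the binding cavity in
bound and ligand-free states. This vignette records the models, the
conventions behind every numerical choice, and what the synthetic test
systems do and do not emulate.

## The single-site titration model

An ITC experiment titrates ligand (syringe concentration $X_0$) into a
macromolecule solution (cell concentration $M_0$, cell volume $V_0$) in a
series of injections, measuring the heat evolved per injection. In an
overflow cell each injection displaces liquid, so effective concentrations
after cumulative injected volume $v_i$ follow the standard instrument
approximation

$$M_i = M_0\left(1 - \frac{v_i}{2V_0}\right), \qquad
  X_i = X_0\,\frac{v_i}{V_0}\left(1 - \frac{v_i}{2V_0}\right).$$

For a single class of $n$ identical sites with association constant $K_a$
and molar enthalpy $\Delta H$, the cumulative heat is the closed-form
one-site expression

$$Q_i = \frac{n M_i \Delta H V_0}{2}
  \left[\,S - \sqrt{S^2 - \tfrac{4X_i}{nM_i}}\,\right], \qquad
  S = 1 + \frac{X_i}{nM_i} + \frac{1}{nK_aM_i},$$

and the per-injection heat carries the displaced-volume correction
$\delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$.
The displacement convention is not uniquely defined across instruments;
cavitherm uses the first-order forms above consistently in both the model
and its independent test oracle, which re-derives $\delta Q_i$ by tracking
moles in the cell and solving each injection's binding equilibrium
numerically. The two routes agree to well below 0.1% over wide parameter
ranges (`single_site_model()` vs the suite's mass-balance simulator).

Derived quantities use $K_d = 1/K_a$, $\Delta G = -RT\ln K_a$
($R = 8.314$ J/mol/K) and $\Delta S = (\Delta H - \Delta G)\cdot 1000/T$
(J/mol/K, energies in kJ/mol). Reported $(K_d, \Delta H, \Delta S)$
triples from external sources are sometimes mutually inconsistent under
this relation; `binding_fit()` accepts an explicit $\Delta S$ and flags
such triples (`dS_consistent = FALSE`) rather than silently recomputing
or discarding them. Cross-ligand tables (`compare_ligands()`) difference
whatever $\Delta H$/$\Delta S$ the fits carry.

## Fitting

`fit_single_site()` preprocesses (control subtraction when control heats
are present, then dropping injection 1 by default — the conventional
discard of the diffusion-contaminated first peak) and minimizes the
residual sum of squares over the free parameters among $(n, K_a, \Delta H)$
by Levenberg–Marquardt (the `minpack.lm` engine), with $K_a$ parameterized
on the natural-log scale to preserve positivity. Initialization is taken
from the data: $\Delta H$ from the mean molar heat of the first two
retained injections, $n$ from the molar ratio at the steepest change of
the isotherm, and $K_a$ from $10/(M_0 \times \text{transition width})$ in
molar-ratio units. Standard errors come from the Jacobian at the optimum
(delta method for $K_a$); fixed parameters carry none. Isotherms with no
detectable transition (all-zero or flat heats) abort with a typed
degenerate-data error instead of returning the initializer. Convergence:
at most 500 iterations, relative tolerances $10^{-12}$.

Peak integration (`integrate_peaks()`) uses trapezoidal integration of
power minus baseline over half-open windows $[t_i, t_{i+1})$ — half-open
because the sample at the next injection time already contains the next
peak's onset. The default baseline interpolates linearly between
pre-injection medians (the final 10% of each preceding window), which
makes the result invariant to constant power offsets.

## Synthetic thermograms

`generate_isotherm()` adds a constant per-injection heat of dilution and
seeded Gaussian noise to the forward model, and produces a matching
control series (dilution heat plus independent noise), recording the
ground truth in metadata. The default protocol is seventeen 2.4 µl
injections after a 0.5 µl pre-injection into a 200 µl cell at 298 K — a
standard small-cell titration design. The parameter-recovery study
conditions are a weak endothermic binder ($n = 0.8$, $K_d = 2.85$ µM,
$\Delta H = +4.74$ kJ/mol), cell concentration chosen so the Wiseman
parameter $c = nM_0K_a$ is 20, syringe loaded at $10\times$ the cell
concentration (final molar ratio ≈ 1.8, the usual design target), and
noise at 1% of the largest heat. Because no dilution heat is simulated in
that scenario, no control series is subtracted — subtracting a redundant
zero-mean control would raise the effective noise by $\sqrt{2}$ beyond
the stated 1% condition. Under these conditions the median recovery error
over 50 seeded replicates is ≈ 4% for $K_d$ and well under 1% for
$\Delta H$ and $n$; single replicates can exceed 5% for $K_d$, which is
why the recovery criterion is a median.

## Cavity waters and their energetics

A cavity is defined geometrically (`cavity_definition()`): either a
sphere around a point or, for real structures, a shell of given cutoff
(default 5.0 Å) around user-listed binding-site residues. A water belongs
to the cavity when its oxygen lies within the cutoff — inclusive (≤), as
are all distance criteria in the package — of the selector. The
residue-shell default is deliberately ligand-independent so bound and
ligand-free states are counted against the same geometry; for the
motivating system the natural selector is the set of binding-site residues
(30, 61, 79, 84, 106, 132, 205).

Per-water potential energies use the pairwise nonbonded form
$u = 4\varepsilon_{ij}[(\sigma_{ij}/r)^{12} - (\sigma_{ij}/r)^6] +
f q_iq_j/r$ with Lorentz–Berthelot combining ($\sigma$ arithmetic mean,
$\varepsilon$ geometric mean), $f = 1389.35458$ kJ mol⁻¹ Å e⁻², and a
plain cutoff (default 10 Å) — no Ewald summation and no long-range
correction. The package analyzes static configurations and must be
exactly testable against a naive double loop, which a mesh-based
electrostatics scheme would preclude; absolute energies therefore differ
from what a periodic MD engine reports, and outputs should be compared
within the package's own convention only. Water–water pair energies are
split half/half between the two waters, so per-water energies sum exactly
to the total water–water energy; intra-water pairs are excluded. Whether
to include protein/ligand terms in a per-water energy is not a settled
convention; cavitherm includes them (each water carries its full
interaction with the solute), and the test suite pins both conventions
down by checking waters-only subsystems and full frames separately.

`hydration_summary()` reports per-frame counts, their mean $\bar N$, the
mean per-water energy $\bar E$ over all (frame, cavity-water) pairs, and
the index of the snapshot frame whose count is closest to the median of
the count distribution, lowest index on ties — the frame a figure of "the
typical hydration state" should show. `bulk_reference_energy()` averages
per-water energies over waters farther than a threshold (default 10 Å)
from every non-water atom.

The desolvation penalty (`desolvation_score()`) is the state difference

$$D = \bar N_\text{holo}\bar E_\text{holo} -
      \bar N_\text{apo}\bar E_\text{apo} \quad \text{(kJ/mol)},$$

the change in total cavity-water stabilization on binding; positive $D$
means the bound cavity has lost water stabilization. Note that although a
bulk reference is computed and reported alongside, the score itself is a
difference against the ligand-free cavity, not against bulk — the score's
metadata says so explicitly. $D$ is zero for a state against itself and
antisymmetric under swapping the states, and both summaries must share a
cavity definition.

## Synthetic pocket systems

`generate_pocket_system()` builds a labeled toy system: a spherical cage
of fixed, neutral Lennard-Jones pseudo-protein atoms ($\sigma$ 3.4 Å,
$\varepsilon$ 0.36 kJ/mol) at cavity radius + 2 Å; 3-site SPC/E-like
waters ($q_O = -0.8476$ e, $q_H = +0.4238$ e, $\sigma_O = 3.166$ Å,
$\varepsilon_O = 0.650$ kJ/mol, hydrogens non-LJ) with oxygens placed by
seeded rejection sampling (minimum heavy-atom separation 2.4 Å, at most
10,000 attempts per particle) inside the cavity and in an outer shell;
and optionally an idealized ligand at the centroid. The default shell
(18.5–24 Å) lies beyond 10 Å of every cage atom so shell waters also
qualify as bulk under the default bulk-distance criterion. Three-site
waters were chosen over four-site ones to avoid virtual-site bookkeeping;
the hydration machinery is parameter-agnostic, and the neutral cage
isolates water–water and water–ligand energetics in tests.

What the generator emulates: the *bookkeeping* of a solvated pocket —
labeled cavity/bulk membership, resolvable per-atom parameters, exact
ground truth for censuses and pairwise-energy sums, frozen or rigidly
jittered frames (rigid moves change no energy or count). What it does not
emulate: equilibrium liquid water. Random packings at 2.4 Å minimum
separation are not Boltzmann configurations, so per-water energies of
synthetic systems can be positive and the dilute far shell is not
condensed bulk water. Consequently, passing tests demonstrate the
correctness of the census, energy and scoring machinery, not agreement
with equilibrium hydration energetics of a real protein — the latter
requires long explicit-solvent MD of the real complexes, which is outside
this package's scope. For the same reason the absolute published
per-state averages (≈ 20 waters at ≈ −93 kJ/mol, bulk ≈ −92 kJ/mol)
cannot be regenerated here; the package instead reproduces the *score
arithmetic* from reported state averages
(`hydration_summary_from_averages()`), and validates its machinery
against exact oracles.

Ligand templates (`ligand_template()`) provide idealized heavy-atom
geometries for taurine (2-aminoethanesulfonate), its phosphonate analogue
2-AEP, and the extended analogues ACES and MES, with standard bond
lengths (C–S 1.79 Å, S–O 1.45 Å, C–P 1.80 Å, P–O 1.51 Å, C–N 1.47 Å,
C–C 1.53 Å). Formal charge is smeared over the anionic headgroup
(+0.8 on the central S/P, −0.6 per terminal oxygen, net −1; amine kept
neutral) — a deliberate simplification recorded in each template's
metadata, adequate for contact typing and toy energetics but not for
force-field work.

## Contact chemistry and superposition

Hydrogen-bond detection defaults to hydrogen-free mode — donor/acceptor
heavy-atom pairs within 3.5 Å — because deposited crystal structures
rarely include hydrogens; this is documented as a weaker criterion than
the angle rule. With explicit hydrogens, a D–H···A angle of at least 120°
is additionally required (hydrogens located within 1.25 Å of the donor in
the same residue). Donor/acceptor typing covers backbone N (donor) and
O/OXT (acceptor), side-chain heteroatoms per residue, water oxygens
(both), and ligand atoms by element (O and S accept, N donates). Van der
Waals contacts are heavy-atom pairs within 4.0 Å not already reported as
hydrogen bonds. All reports are sorted by distance and deterministic.

Superposition is the standard covariance/SVD (Kabsch) construction with
reflection correction, matching atoms by (chain, residue number, atom
name); insertion codes are unsupported. Conserved-water matching is
greedy nearest-neighbor under a match radius (default 1.0 Å), each water
used at most once, ties by smaller distance then lower residue number —
greedy rather than optimal assignment for determinism and speed, with
brute-force equivalence verified in the suite at small water counts.

## Formats, configuration, degenerate inputs

PDB I/O (multi-MODEL trajectories, fixed columns, 3-decimal coordinates)
is delegated to `bio3d` for parsing, with cavitherm adding the altloc
policy (keep blank/'A', drop others — deterministic single-conformer
analysis), element inference from atom-name prefixes when columns 77–78
are empty, and residue-name-based classification into
protein/ligand/water/ion/other (water names default HOH/WAT/SOL/TIP;
all sets configurable; residue numbering is taken verbatim from the
file). ITC tables, parameter tables and config files are flat delimited
text with `# key = value` headers. All readers reject empty input with
typed errors; overflowing coordinates, unresolvable atoms, zero-length
selections, mismatched lengths, non-positive $K_a$ and coincident atoms
each raise their own error class.

`run_pipeline()` executes the requested stages (ITC, hydration, contacts)
independently and deterministically given a `pipeline_config()` and its
seed; every report embeds the config hash and seed. JSON output is
lossless; TSV/markdown round to reporting precision ($K_d$ 2 significant
figures, energies 1 decimal). Seeds are mandatory arguments to both
generators — there is no hidden global randomness.

## Problem sizes

The validation suite and the reproduction script run at deliberately
modest sizes chosen to exercise every code path exactly: titration
oracles over 100 random parameter draws, recovery medians over 50 seeded
replicates of 17-injection thermograms, pocket systems of ≤ 500 atoms
across ≤ 10 frames with exact double-loop energy checks at $10^{-9}$
relative tolerance, and exhaustive water-matching checks at ≤ 8 waters.

## Known limitations

- Plain-cutoff electrostatics: absolute energies are not comparable to
  Ewald/PME results from MD engines.
- Synthetic pockets are packing constructions, not equilibrium water.
- Hydrogen-free hydrogen-bond detection over-reports relative to
  angle-filtered detection; it is the honest default for structures
  without hydrogens.
- Single-site binding only: no multi-site, sequential or competitive
  models, and no global multi-experiment fits.
- Water identity across frames is taken from residue identifiers;
  exchange events are not tracked.
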