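---
title: "Models and conventions behind coform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind coform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coform)
```

coform implements the desk-side half of a cocrystal screening campaign:
given quantities that upstream tools produce — electrostatic-potential
surface extrema, crystal-structure-prediction (CSP) energy tables,
pairwise-interaction exports, DSC/TGA observables — it computes the
screening verdicts and solid-form thermodynamics a formulation scientist
actually argues from. This vignette records the models, the conventions
chosen where the methods literature leaves them open, and what the
synthetic-data generators do and do not emulate.

## MEP-based screening

The molecular electrostatic potential (MEP) mapped on an electron-density
isosurface exposes a molecule's hydrogen-bonding machinery: local maxima
(positive potential) mark donor sites, local minima mark acceptor sites.
`sites_from_extrema()` converts extremum values $V$ (kJ/mol) into
dimensionless H-bond parameters,

$$\alpha_i = k_\alpha V^{max}_i, \qquad \beta_j = -k_\beta V^{min}_j,$$

with both calibration constants defaulting to $1/52$ mol/kJ — a package
convention chosen so that a strong donor extremum near $+52$ kJ/mol maps
to $\alpha = 1$; both constants are arguments, and any published
calibration can be substituted.

`pairing_energy()` estimates a phase's electrostatic interaction energy by
matching the strongest donors with the strongest acceptors:
$E = -\sum_k \alpha_{(k)} \beta_{(k)}$ over the
$\min(\#\text{donors}, \#\text{acceptors})$ sorted pairs. By the
rearrangement inequality the sorted matching maximizes
$\sum \alpha\beta$, so no other assignment is more stabilizing; the test
suite verifies this against exhaustive enumeration of all matchings.
Unpaired sites contribute nothing — no penalty term is applied, the
simplest defensible reading of an interaction-energy estimate.

The formation energy gain of an $m{:}n$ cocrystal is

$$\Delta E_{MEP} = E_{CC} - (m\,E_{API} + n\,E_{coformer}),$$

where $E_{CC}$ pools the sites of $m$ API copies and $n$ coformer copies
(literal replication, no symmetry reduction) and the component terms are
single-molecule pairings. Pure-phase energies are treated extensively,
i.e. per stoichiometric unit. Because every value occurs with multiplicity
$m$ (or $n$) in the pooled set, the pooled optimum of the pure components
equals $m E_{API} + n E_{coformer}$, and the mixed optimum can only
improve on it: $\Delta E_{MEP} \le 0$ always, with zero meaning no
heteromeric preference. The default decision threshold of $-11$ kJ/mol
corresponds to the literature's ≈50% formation-probability anchor;
`screen_stoichiometries()` additionally flags the most negative ratio as
preferred. We do not attempt to map $\Delta E_{MEP}$ onto a full
probability curve — one anchor point does not determine one.

## Molecular complementarity

`vdw_box()` measures the rectangular box enclosing the molecular van der
Waals volume: every atom sphere is sampled with a deterministic Fibonacci
lattice (default 400 points/atom), the covariance of the pooled surface
cloud gives principal axes, and peak-to-peak projections give the sorted
extents $S \le M \le L$. The construction is deterministic (no RNG) and
rotation/translation invariant to within the sampling resolution — about
0.02 Å at the default density; tests enforce 0.05 Å over random rigid
motions. A caveat worth knowing: because the principal axes re-orient as
the molecule grows, the *sorted* extents are not element-wise monotone
under atom addition; monotonicity holds along any fixed axes, which the
`axes` argument exposes and the tests check. An exact support-function
box optimization would remove the sampling tolerance but not this
re-orientation effect, and is unnecessary at the 0.05 Å level the screen
operates on.

`mc_screen()` compares five descriptor differences between API and
coformer — $\Delta S/L$, $\Delta M/L$, $\Delta S$, $\Delta$dipole,
$\Delta f_{NO}$ (fraction of N and O atoms, hydrogens included by default;
a heavy-atom variant is exposed since the convention differs between
tools) — each against a configurable $[\text{lower}, \text{upper}]$ band
on the absolute difference, passing overall only when every enabled
descriptor passes. The shipped bands (`mc_default_thresholds()`) are
editable literature-style defaults, not fitted values; the screen's known
sensitivity to the input conformation (an extended conformer can fail
$\Delta S/L$ where a folded one passes) is demonstrated in the tests.
Dipole moments are inputs — stored on the molecule, supplied directly, or
computed from user-provided point charges via $|\sum_i q_i \mathbf{r}_i|$
(1 e·Å = 4.8032 D); no wavefunction work is done here.

## Crystal energy landscapes

Landscape tables carry one row per predicted structure: lattice energy
per formula unit (negative-stable convention — the CSV schema states the
units so the unsigned axes common in landscape figures cannot be
misread), density, space group, $Z'$, intramolecular penalty, and reduced
stoichiometry. `formation_energy()` subtracts the stoichiometry-weighted
lattice energies of each component's most stable polymorph;
`feasible_set()` applies a strict $\Delta E_{form} < 0$ cutoff (exact
zeros are reported as marginal rather than silently included), sorts the
feasible structures, and reports the rank-1/rank-2 margin that indicates
how isolated the predicted global minimum is. Formation-energy cutoffs
are applied per formula unit; per-molecule normalization would rescale
all margins by the formula-unit size without reordering anything.

`stoichiometry_normalize()` implements the coformer correction used to
compare, say, 1:1 and 1:2 cocrystals of the same API on one scale:
subtract the coformer's reference lattice energy once per excess coformer
molecule. Entries differing in API count are rejected — no single-species
correction makes them comparable. `aggregate_pairwise()` condenses
CrystalExplorer-style pairwise interaction exports into per-partner sums
and strongest contacts, averaging over symmetry-independent central
molecules when they are tagged.

## Thermal analysis

`heat_of_fusion_rule()` applies the Burger–Ramberger heuristic to two
melting events: if the higher-melting form has the *lower* fusion
enthalpy the pair is enantiotropic (the higher-melting form is the
high-temperature form); if it also has the higher enthalpy the pair is
monotropic. Because the rule is a heuristic operating on measured
quantities, the verdict is demoted to indeterminate when the enthalpy
difference is within the combined stated uncertainties, or when the
melting points coincide.

For an enantiotropic pair, `transition_thermo()` estimates the
solid–solid transition from melting data alone by intersecting the two
Gibbs-energy lines under a $\Delta C_p = 0$ assumption:

$$\Delta H_{t} = \Delta H_{fus}^{low} - \Delta H_{fus}^{high}, \qquad
  \Delta S_{t} = \frac{\Delta H_{fus}^{low}}{T_{fus}^{low}} -
                 \frac{\Delta H_{fus}^{high}}{T_{fus}^{high}}, \qquad
  T_{t} = \Delta H_{t} / \Delta S_{t}.$$

The neglected heat-capacity difference typically biases $T_t$ by a few
kelvin; for the sulfaguanidine/flavone cocrystal pair (171.3 °C /
52.0 kJ/mol vs 174.6 °C / 47.5 kJ/mol) the construction gives 139.2 °C.
We deliberately do not introduce a $\Delta C_p$ correction term: the
melting data alone do not constrain it. `et_diagram()` serializes the
event structure (transition point below both melting points for
enantiotropic pairs) and raises a named inconsistency error when a forced
estimate violates the ordering.

`solvate_stoichiometry()` converts a desolvation mass-loss fraction $w$
into moles of solvent per mole of host,
$x = w M_{host} / ((1-w) M_{solvent})$, reporting both the raw value and
the one-decimal rounding conventionally used to name the solvate
(1.0 → monosolvate, 0.5 → hemisolvate). The map is strictly increasing
and exactly invertible (`mass_loss_fraction()`), which the tests exploit.

Trace extraction follows instrument-software conventions: DSC heat flow
in mW (endotherm up) against a linear baseline estimated by iterative
robust fitting; peaks detected above $5\sigma$ of the residual noise plus
a 5%-of-tallest-excursion floor (so a featureless noisy trace yields no
events); onset by intersecting the tangent at the steepest point of the
leading edge with the baseline; enthalpy by trapezoidal integration of
the baseline-subtracted peak, converted to kJ/mol with sample mass, molar
mass, and heating rate. TGA mass loss is the difference of windowed
plateau means divided by the initial mass, warning (but proceeding) when
an endpoint is still drifting.

## Synthetic data

The generators produce inputs with the statistical structure each stage
assumes, with the seed recorded in every output and the programmed ground
truth returned alongside, so tests compare against the construction:

* `gen_site_sets()` draws uniform extremum magnitudes (default
  10–60 kJ/mol, spanning weak contacts to strong donors) and computes the
  reference $\Delta E_{MEP}$ by exhaustive matching — an oracle
  independent of the sorted-pairing implementation.
* `gen_landscape()` places a programmed number of structures below the
  feasibility cutoff with a programmed rank-1/rank-2 gap, remaining
  structures above it, densities uniform on 1.2–1.7 g/cm³ and
  intramolecular penalties on 0–18 kJ/mol — ranges typical of organic
  molecular crystals.
* `gen_dsc_trace()` builds Gaussian endotherms (default width 1 K) on a
  gently sloping baseline. For a Gaussian the tangent-at-inflection onset
  is exactly two standard deviations below the apex, so the apex is
  placed at $T_{onset} + 2\sigma_{peak}$ and the extractor's onset
  convention recovers the programmed value by construction. Peak areas
  encode molar enthalpies through the same mass/molar-mass/heating-rate
  conversion the extractor inverts.
* `gen_tga_trace()` uses logistic mass-loss steps (default width 2 K).

Real DSC endotherms are asymmetric and heating-rate dependent, real CSP
energy distributions are far from uniform, and real landscapes contain
correlated energy/density structure; none of that is emulated. Passing
round-trip tests therefore demonstrates that the extraction and
bookkeeping are correct under the stated conventions — not that the
package would recover parameters from arbitrarily pathological
instrument output.

All generators draw from a locally seeded RNG stream and restore the
caller's `.Random.seed`, so embedding them in a larger seeded analysis
does not perturb it.

## Problem sizes and numerical choices

The shipped test suite exercises: 1,000 random site-set pairs for the
$\Delta E_{MEP} \le 0$ bound plus a few hundred exhaustive-matching
comparisons (site counts ≤ 6 per side, where enumeration is exact and
fast); 100 seeded landscapes for programmed-count/gap recovery; 100
noisy DSC and TGA traces (1% peak-height and 0.1% initial-mass noise)
for round-trip parameter recovery, requiring median enthalpy error below
3% and mass-loss deviation below 0.002; and 50 random rigid motions for
box-descriptor invariance at 0.05 Å. These sizes were chosen so the full
property battery runs in well under a minute per stage while leaving the
statistical assertions (medians over 100 seeds) meaningful.

Ties in sorted donor/acceptor parameters are broken by input order, which
cannot change the energy (equal values give equal products). Stoichiometries
are reduced by gcd on construction. Degenerate inputs have defined
behaviour throughout: empty site lists are rejected at construction but a
molecule may be all-donor or all-acceptor (its self-energy is then zero);
a flat DSC trace returns an empty event list; exact-zero formation
energies are "marginal", not feasible.

## Known limitations

* $\Delta E_{MEP}$ ignores site geometry, steric accessibility, and
  cooperativity; it is a ranking heuristic, not an energy model.
* The complementarity bands ship as editable defaults; verdicts are only
  as meaningful as the bands supplied.
* The $\Delta C_p = 0$ transition-temperature estimate inherits a
  few-kelvin bias; the printed uncertainty of the underlying DSC data
  should always accompany it.
* Landscape analysis trusts the ingested lattice energies; no structure
  matching or re-ranking is attempted.
* MCHBP scores are ingested and echoed, never computed — they require a
  structural database this package does not touch.
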