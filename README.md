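# coform

Virtual cocrystal screening and solid-form thermodynamics for
pharmaceutical materials science.

Most active pharmaceutical ingredients (APIs) are screened against
candidate coformers long before anyone grows a crystal: cheap molecular
descriptors and post-processed quantum-chemistry or crystal-structure-
prediction (CSP) outputs rank the pairs worth taking into the lab, and
once a cocrystal exists, DSC and TGA measurements settle which polymorph
is stable where and whether a new form is a solvate. coform implements
that desk-side workflow as a tested R package for formulation and
solid-state scientists:

* **MEP screening** — hydrogen-bond donor/acceptor parameters
  (α, β) from electrostatic-potential surface extrema, the optimal
  donor–acceptor pairing energy E = −Σ α·β, and the cocrystal formation
  energy gain across stoichiometric ratios,

  ΔE_MEP = E_CC − (m·E_API + n·E_coformer) ≤ 0,

  with the −11 kJ/mol ≈ 50%-probability threshold as the default verdict
  line (`sites_from_extrema()`, `pairing_energy()`, `delta_E_MEP()`,
  `screen_stoichiometries()`).
* **Molecular complementarity** — the S ≤ M ≤ L box enclosing the van der
  Waals volume via principal axes of a deterministic surface point cloud,
  dipole and N/O-fraction polarity descriptors, and a configurable
  pass/fail band screen (`vdw_box()`, `mc_screen()`).
* **Crystal energy landscapes** — formation energies against the most
  stable pure-component polymorphs, the ΔE_form < 0 feasibility cutoff
  with ranking margins, stoichiometry-corrected stability comparisons,
  and aggregation of pairwise intermolecular interaction tables
  (`formation_energy()`, `feasible_set()`, `stoichiometry_normalize()`,
  `aggregate_pairwise()`).
* **Thermal analysis** — the Burger–Ramberger heat-of-fusion rule,
  transition enthalpy/entropy/temperature from melting data
  (ΔCp = 0 Gibbs-line intersection: T_t = ΔH_t/ΔS_t with
  ΔS_t = H_low/T_low − H_high/T_high), energy/temperature diagram
  bookkeeping, solvate stoichiometry from TGA mass loss, and peak/step
  extraction from raw traces (`heat_of_fusion_rule()`,
  `transition_thermo()`, `solvate_stoichiometry()`,
  `extract_fusion_data()`, `extract_mass_loss()`).
* **Synthetic data + reporting** — seeded generators for every input the
  pipeline consumes (`gen_site_sets()`, `gen_landscape()`,
  `gen_dsc_trace()`, `gen_tga_trace()`) and a cross-method report from
  one YAML config (`run_screen()`), plus a thin `coform` command-line
  front end in `inst/exec/`.

Quantum chemistry, CSP structure generation, and database propensity
scoring stay upstream: coform ingests their tabulated outputs.
See `vignette("coform-methods")` for models, conventions, and limits.

## Worked example

The sulfaguanidine/flavone cocrystal system has two 1:1 polymorphs with
printed melting data: form I melts at 171.3 °C (ΔH_fus 52.0 kJ/mol),
form II at 174.6 °C (47.5 kJ/mol).

```r
library(coform)

I_CC  <- fusion_datum("I_CC", 171.3, 52.0, u_T = 0.1, u_H = 0.3)
II_CC <- fusion_datum("II_CC", 174.6, 47.5, u_T = 0.1, u_H = 0.1)

heat_of_fusion_rule(I_CC, II_CC)
#> <heat-of-fusion rule: enantiotropic, high-T form II_CC>

transition_thermo(I_CC, II_CC)
#> <I_CC -> II_CC: H_trans 4.50 kJ/mol, S_trans 10.91 J/(mol K), T_trans 412.4 K (139.2 C)>
```

The higher-melting form II has the lower fusion enthalpy, so the pair is
enantiotropic: form I is the stable form at room temperature and
converts to form II at the estimated transition point of ≈139 °C (the
ΔCp = 0 construction; the few-kelvin bias of that assumption is
discussed in the vignette).

A TGA mass loss identifies a solvate: a 1:1 dapsone/flavone cocrystal
(host 470.54 g/mol) losing 13.1% as *t*-butanol (74.12 g/mol) is a
monosolvate:

```r
solvate_stoichiometry(0.131, 470.54, 74.12)
#> <solvate stoichiometry: 0.957 mol/mol (reported 1.0)>
```

MEP screening of a donor-rich API against an acceptor-only coformer
prefers the coformer-rich ratio (energies in kJ/mol):

```r
api <- sites_from_extrema(maxima = c(52, 40), minima = -30,
                          molecule_label = "dapsone")
fl  <- sites_from_extrema(minima = c(-80, -20), molecule_label = "flavone")
screen_stoichiometries(api, fl, c("1:1", "1:2", "2:1"))
#>   stoichiometry  E_CC  E_API E_FL delta_E_MEP likely preferred
#> 1           1:1 -1.98 -0.577    0       -1.41  FALSE     FALSE
#> 2           1:2 -2.72 -0.577    0       -2.14  FALSE      TRUE
#> 3           2:1 -2.86 -0.577    0       -1.70  FALSE     FALSE
```

And a landscape with seven structures programmed below the feasibility
cutoff and a 7.8 kJ/mol gap between the two best is recovered exactly:

```r
g <- gen_landscape(seed = 1, n_structures = 30, n_feasible = 7, gap_12 = 7.8)
feasible_set(g$landscape)
#> <feasible set: 7 structure(s) below cutoff; best dE_form -15.09 kJ/mol; rank-1/2 margin 7.80 kJ/mol>
```

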