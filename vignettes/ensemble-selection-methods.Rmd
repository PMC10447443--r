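---
title: "Chemical-shift-driven ensemble selection: model, parameters and design"
author: "ShiftEnsemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chemical-shift-driven ensemble selection: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ShiftEnsemble)
```

## The problem and the model

Amorphous molecular solids have no unit cell: any single modelled structure
is at best one draw from the ensemble the material actually realizes. NMR
resonances of such solids are broad, approximately Gaussian distributions
whose centers and widths can be fitted from 1D/2D spectra. Given an
MD-generated ensemble of *local molecular environments* — a central molecule
plus all molecules with at least one atom within a cutoff of any central
atom — and per-site chemical-shift predictions with uncertainties, the
question is which environments are statistically compatible with the
measured shift distributions.

ShiftEnsemble treats each atomic site as a two-Gaussian comparison. With
experimental distribution $(\delta_{\exp}, \sigma_{\exp})$ and prediction
$(\delta_{\mathrm{pred}}, \sigma_{\mathrm{pred}})$,

$$Z = \frac{|\delta_{\exp} - \delta_{\mathrm{pred}}|}
           {\sqrt{\sigma_{\exp}^2 + \sigma_{\mathrm{pred}}^2}}, \qquad
  p_{\mathrm{val}}(Z) = \sqrt{\tfrac{2}{\pi}} \int_Z^\infty
     e^{-x^2/2}\,dx = \operatorname{erfc}(Z/\sqrt{2}),$$

the two-tailed tail mass of the joint Gaussian: the probability of a
discrepancy at least this large under the null hypothesis that the
predicted shift is drawn from the experimental distribution. A large
prediction uncertainty widens the denominator and *raises* the p-value, so
raw p-values would systematically favour unreliable predictions. The
penalty

$$p_i = \frac{p_{\mathrm{val}}}{\max\!\left(1,\;
        \sigma_{\mathrm{pred}} / \sigma^0_{\mathrm{pred}}\right)}$$

divides by the prediction uncertainty expressed in units of the site's
*first-quartile* uncertainty $\sigma^0_{\mathrm{pred}}$ over the whole
ensemble, capped below at one: predictions no worse than the reference are
untouched, the rest are strictly penalized. Site probabilities combine as a
geometric mean

$$p_j = \left(\prod_{i=1}^{n} p_i\right)^{1/n},$$

which (unlike a product) does not shrink with the number of sites, and
(unlike an arithmetic mean) is annihilated by any site that is impossible
to reconcile. The *NMR ensemble* is $\{j : p_j > t\}$ with $t = 0.33$ by
default, or alternatively the best fixed fraction of environments; both
selection rules are provided because the two need not coincide exactly.

Assumptions worth stating: experimental distributions are Gaussian (fitted
linewidths), prediction errors are Gaussian with known per-prediction
widths, and sites are treated as independent in the geometric mean.
Selection is *independent* per environment — the method deliberately does
not reweight the ensemble to reproduce experimental averages; it biases the
MD ensemble toward compatibility to expose systematic structural
differences.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| environment cutoff | 7 | Å | first-plus-second coordination shell of a mid-size organic molecule; inclusion at the boundary is closed (≤) |
| selection threshold | 0.33 | probability | default strict `>`; top-fraction mode available |
| shielding offsets | H 30.78, C 170.04 | ppm | δ = offset − shielding referencing convention |
| σ⁰ quartile | first (25%) | — | `stats::quantile` type 7 (linear interpolation), configurable by passing `refUncertainties` |
| H-bond criteria | 2.5 Å, 130° | — | O–H⋯X motif, X ∈ {O, N} |
| density grid | 31³ nodes, 12 Å, σ = 0.5 Å | — | 0.4 Å spacing; unnormalized Gaussians so an always-occupied node reads 1 |
| G(r) weighting | c_i c_j Z_i Z_j | — | X-ray-like; normalized so G → 1; D(r) = 4πρr(G − 1) |

Equivalent protons: assignment tables are per resonance, so by default
predictions sharing a site label within an environment are averaged (mean
shift, mean uncertainty) before matching; a per-atom mode
(`equivalentProtons = "perAtom"`) treats each prediction separately.

Missing predictions: an environment lacking a prediction for an included
site aborts scoring by default; `onMissing = "skip"` drops it with a
warning. Silent dropping is never the default because it biases the
selection toward environments with convenient coverage.

## The synthetic generator

The generator exists so every stage can be validated against known ground
truth without external data. It emulates:

* **periodic amorphous packings** — random insertion with rejection below a
  2.0 Å interatomic floor, in a cubic cell;
* **a flexible molecule** — a 13-atom species with one rotatable backbone
  torsion (planted at +60° / −60° for conformer classes A/B), a hydroxyl
  donor, and carbonyl-O and amine-N acceptors: the smallest species
  exercising dihedral, H-bond, density-map and shift analyses at once;
* **planted hydrogen bonds** — carbonyl bonds as C2-symmetric dimers (both
  members donate and accept, 1.9 Å H⋯O on the O–H axis), nitrogen bonds by
  placing a partner molecule's N at the donor's ideal acceptor position
  (the partner stays unbonded, so a planted fraction of 1 uses an all-O2
  split). Planted contacts sit well inside the detection criteria; pair
  members are exempt from the insertion floor down to 1.55 Å;
* **MD snapshot cadence** — frames are the base packing plus independent
  Gaussian jitter (sd 0.05 Å), far below the detection tolerances, so
  planted labels persist across frames;
* **shift statistics** — per-site class means with Gaussian prediction
  noise (0.3 × experimental width) and log-normal uncertainties (median
  0.5 × width, sdlog 0.4), so the quartile cap is genuinely exercised;
  experimental widths follow the ranges typical of amorphous organic
  solids (¹³C 2–6 ppm, C–H ¹H 0.6–1 ppm, OH 1.8 ppm). The "experimental"
  centers are the class-A, non-bonded means; class B is displaced by 3.5
  joint standard deviations on six sites.

What it does **not** emulate: force-field dynamics (frames are jitter, not
trajectories — no diffusion, no conformational interconversion), realistic
densities (packings are dilute enough that accidental hydrogen bonds are
rare), correlated prediction errors, or any relationship between
conformation and packing energy. Passing tests therefore demonstrate the
correctness of the machinery — extraction, scoring, selection, census,
alignment, maps, energies — not that the method will resolve any particular
real material; on real data the discriminating power depends entirely on
how far the structural subpopulations separate in shift space relative to
linewidths and prediction uncertainty.

Default study conditions: 2 trajectories × 25 frames × 32 molecules (1600
environments) in a 24 Å cell, planted conformer fractions 0.5/0.5,
hydrogen-bond fraction 0.3 split evenly between acceptors. The
parameter-recovery study uses 10⁴ geometry-free environments with a 20%
planted fraction; the bookkeeping study uses 8010 snapshots × 128
three-atom molecules. These sizes keep the complete validation suite at
minutes on a single CPU while still crossing the production scale
(a million environments) where it matters.

## Numerical choices

* **Minimum image**: component-wise fractional wrap for orthorhombic cells
  (exact); wrap plus a 27-image search otherwise, exact whenever the
  shortest lattice vector exceeds twice the distance of interest — the
  regime the extraction contract requires. Tests verify against a 5³
  brute-force enumeration.
* **Boundary inclusion**: `≤ cutoff + 1e-9 Å`; the guard absorbs
  Cartesian↔fractional round-trip noise so inclusion at exactly the cutoff
  is deterministic.
* **Unwrapping**: the central molecule is made contiguous about its first
  atom; each member is made contiguous and then rigidly shifted to the
  image minimizing its closest contact with the central molecule. Any
  choice preserving minimum-image contacts is acceptable; this one is
  deterministic.
* **Geometric mean** in log space, with any zero site probability
  short-circuited to exactly 0 (no `log(0)`).
* **p-values** via `2 * pnorm(z, lower.tail = FALSE)`; the test suite holds
  this to the quadrature of the defining integral at 1e-10.
* **Selection ties**: threshold mode is strict `>`; top-fraction mode
  ranks by probability with ties broken by environment order
  (deterministic, documented, and irrelevant for continuous scores).
* **Alignment**: Kabsch superposition (SVD with a determinant correction to
  enforce a proper rotation) on the named central-molecule atoms; at least
  three non-collinear atoms are required, and the reference frame is the
  first environment of the set. Difference maps always use the same
  reference for both sets.
* **Dihedral convention**: IUPAC right-handed signed torsion in
  (−180°, 180°]; an angle of exactly −180° is reported as +180°. Histogram
  bins are right-closed, so the periodic seam lives in the outermost bins.
* **Overlap/JS binning**: Freedman–Diaconis on the pooled support (sample
  range ∪ center ± 4σ), floored at 20 bins; JS divergence uses base-2
  logarithms so it is bounded by 1; an all-identical sample still bins
  against the Gaussian because the pooled support is never degenerate.
* **RDF**: histogramming is restricted to r ≤ half the smallest
  perpendicular cell width, where the minimum image is exact; self-pairs
  use N(N−1)/2 counting.
* **Energy backend contract**: deterministic total energy (kJ/mol) of a
  finite cluster; the built-in 12-6 pair potential (depth ε = 1 kJ/mol at
  r₀ = 3.4 Å by default) makes formation energies exactly the sum of pair
  terms involving central atoms, which is what the tests check in closed
  form.

## Open design points, resolved

* The selection threshold and the top-1% rule are both first-class; the
  package takes no position on which is canonical.
* σ⁰ interpolation ("first quartile" admits several conventions): linear
  interpolation, overridable by supplying precomputed reference
  uncertainties.
* G(r)/D(r) conventions are explicit configuration (Z-weighted partials,
  Keen-style D(r)); no attempt is made to match any particular
  experimental reduction chain, and comparisons with measured curves go
  through `curveResidual` on whatever convention the reference used.
* Molecule membership comes from input metadata when present; otherwise
  bond perception by 1.2 × summed covalent radii, logged.

## Limitations

Scoring assumes per-site independence, which overstates the information
content of strongly correlated sites. The geometry-free manifest mode
exercises scoring statistics but no geometry. The jitter trajectory model
cannot produce conformer interconversion within a trajectory. The toy
energy backend is a validation device, not chemistry: real formation-energy
analyses require an external single-point backend through
`externalCommandBackend` (or any `EnergyBackend` subclass). Periodic cells
must be right-handed and, for exact minimum-image guarantees beyond the
orthorhombic case, not extremely skewed relative to the cutoff.
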