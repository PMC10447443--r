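# ShiftEnsemble

Ensemble structure determination of amorphous molecular solids from NMR
chemical shifts. Amorphous solids have no single representative periodic
structure: their NMR spectra are broad distributions, and an MD-generated
ensemble of local molecular environments must be confronted with those
distributions as a whole. ShiftEnsemble scores every local molecular
environment of an MD-derived ensemble by the probability that its predicted
¹H/¹³C chemical shifts are drawn from the experimentally measured shift
distributions, selects the best-matching subset (the "NMR ensemble"), and
characterizes it structurally — hydrogen bonds, dihedral conformer
populations, least-RMSD-aligned 3D atomic density maps, radial distribution
functions, and formation energies through a pluggable single-point energy
backend.

The package is aimed at solid-state NMR crystallographers and molecular
modellers working on amorphous organic solids (for instance amorphous drug
formulations), who have periodic MD snapshots, machine-learned or DFT
chemical-shift predictions with per-site uncertainties, and fitted
experimental peak positions and linewidths.

## The scoring model

A *local molecular environment* is a central molecule plus every molecule
with at least one atom within 7 Å of any central atom (minimum-image,
inclusive). For atomic site *aᵢ* of the central molecule of environment *j*,
the experimental shift distribution is a Gaussian (δ_exp, σ_exp) and the
prediction a Gaussian (δ_pred, σ_pred). The match is scored by

  Z = |δ_exp − δ_pred| / √(σ_exp² + σ_pred²)

  p_val(Z) = √(2/π) ∫_Z^∞ exp(−x²/2) dx   (the two-tailed p-value,
  erfc(Z/√2))

  p_i = p_val / max(1, σ_pred / σ⁰_pred)

where σ⁰_pred is the *first quartile* of all prediction uncertainties for
that site across the whole ensemble — predictions more uncertain than the
site's reference are strictly penalized, so unreliable predictions cannot
masquerade as good matches. The environment probability is the geometric
mean over all matched ¹H and ¹³C sites,

  p_j = (∏ᵢ p_i)^(1/n),

and the NMR ensemble is everything with p_j above a threshold (default
0.33, roughly the best 1% in the original study) or, alternatively, a fixed
top fraction. Shieldings are converted to shifts by δ = offset − σ with
per-element offsets (¹H: 30.78 ppm, ¹³C: 170.04 ppm by default).

Everything downstream — hydrogen-bond census (O–H⋯X with X ∈ {O, N},
H⋯X < 2.5 Å, O–H–X angle > 130°), dihedral histograms, per-element density
maps on a 31×31×31 grid with 12 Å sides (0.4 Å spacing, σ = 0.5 Å
Gaussians), X-ray-weighted G(r)/D(r), and formation energies
E(environment) − E(environment minus central) — runs on either the full or
the selected ensemble so the two can be contrasted.

A fully self-contained synthetic-data generator (`generateEnsemble`,
`generateShifts`) produces periodic amorphous packings of a 13-atom toy
molecule with planted conformer and hydrogen-bond subpopulations and
matching shift tables, so the entire pipeline is testable without any
external data.

## Worked example

```r
library(ShiftEnsemble)

ens    <- generateEnsemble(nTrajectories = 1, nFramesPerTrajectory = 10,
                           nMolecules = 24, cellSide = 24,
                           hbondFraction = 0.3, seed = 42)
shifts <- generateShifts(ens$manifest, seed = 43)
envs   <- extractAllEnvironments(ens$snapshots, cutoff = 7)
sel    <- scoreEnvironments(shifts$predictions, shifts$distributions,
                            threshold = 0.33)
sel
#> EnsembleSelection: 140 / 240 environments selected (58.33%, p > 0.33)

round(hbondCensus(envs, ens$topology), 3)
#>    O1    N1    O2  none
#> 0.000 0.125 0.167 0.708
```

240 environments (10 frames × 24 molecules) were extracted and 140 pass the
probability threshold — the generator plants half of the molecules in the
conformer class whose site means the synthetic "experimental" distributions
describe, and those are the environments the score retains. The census rows
are the fraction of central hydroxyl donors bonded to each acceptor site
(12.5% to the amine nitrogen, 16.7% to the carbonyl oxygen, 70.8% unbonded
— matching the planted 30% hydrogen-bond fraction). A dihedral histogram of
the selected ensemble concentrates at the planted +60° backbone torsion:

```r
h <- dihedralHistogram(selectedOnly, ens$topology, "backbone")
h[h$count > 0, c("lower", "upper", "count")]
#>    lower upper count
#> 23    40    50     5
#> 24    50    60    67
#> 25    60    70    65
#> 26    70    80     3
```

`runPipeline(pipelineConfig(seed = 1), "out/")` runs the same stages end to
end and writes the selection table, census, histograms, density maps (cube
format) and G(r)/D(r) curves with provenance. A thin command-line wrapper
lives at `inst/scripts/run-pipeline.R`.

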