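# holoflex

Quantitative analysis of CaMKII-alpha holoenzyme conformational ensembles.

The CaMKII holoenzyme is a 12-meric (rarely 14-meric) assembly: a rigid
central hub ring (~55 Å radius) with each kinase domain tethered on an
intrinsically disordered linker. Single-particle EM shows a continuum of
conformations rather than one structure, summarised by two per-subunit
measurements — the **kinase radius of extension** r (hub centre to the
domain's outer edge, i.e. centre distance + 22.5 Å) and the **clockwise
neighbour separation** s (centre-to-centre). Operational thresholds
classify the activation-incompetent minority states: s < 45 Å (one kinase
diameter, steric contact) marks a dimeric kinase pair, r < 100 Å marks the
hub-docked compact conformation.

`holoflex` provides, for researchers modelling flexible multivalent
assemblies and for validating single-particle geometry pipelines:

* a **calibrated, seeded ensemble generator** (`generateEnsemble()`):
  radii from a truncated-Gaussian mixture (extended N(127, 15) on
  [100, 175], compact N(88, 5) on [77, 100), p_compact = 0.025),
  separations from a paired/unpaired mixture split exactly at 45 Å, pair
  arrangements sampled uniformly among matchings on the subunit cycle with
  a calibrated categorical pair count, and a 3.5% tetradecamer fraction;
* the **measurement rules** (`measureEnsemble()`, `kinaseRadius()`,
  `clockwiseSeparations()`) on coordinates or pass-through tables;
* **ensemble statistics** (`geometrySummary()`,
  `pairCountDistribution()`, `radiusSeparationCorrelation()`): moment
  Gaussian fits, 5 Å histograms, whisker quartiles, strict threshold
  fractions, per-particle pair counts;
* **closed-form physical models**: random-coil linker extension
  b√N (`randomCoilExtension()`), linker decomposition of the mean radius
  (`meanLinkerExtension()`), and the torus-volume local concentration
  V = (πr²)(2πR) with R = 126 Å, r = 49 Å giving ~3.3 mM for 12 kinase
  domains (`localConcentration()`);
* a **2D image round trip** (`renderParticle()`, `detectParticle()`) at
  4.37 Å/px in 128² boxes;
* **three-filter FRET correction** (`correctFret()`:
  FRETc = raw − 0.02093·donor − 0.09484·acceptor, donor normalisation,
  4.8× detection-efficiency conversion, closed 4–11× acceptor-excess
  gate) validated on synthetic scenes with known ground truth;
* **variable-slope dose-response fitting** (`fitHill()`, `foldChange()`)
  as parameter recovery on simulated activation data.

## Worked example

```r
library(holoflex)

cfg <- ensembleConfig(nParticles = 1000, seed = 42)  # calibrated defaults
ens <- generateEnsemble(cfg)
tab <- measureEnsemble(ens)

geometrySummary(tab$radius_A, thresholds = 100)
#> GeometrySummary: n=12058  mean=127.04  sd=15.05 A
#>   whiskers: min 77.4 | q25 116.9 | median 127.1 | q75 137.1 | max 174.3
#>   fraction below 100 A: 2.60%

geometrySummary(tab$separation_A, thresholds = 45)
#> GeometrySummary: n=12058  mean=58.04  sd=14.47 A
#>   whiskers: min 21.0 | q25 49.1 | median 59.8 | q75 68.3 | max 101.5
#>   fraction below 45 A: 20.04%

pairCountDistribution(ens)
#> PairCountDistribution over 1000 particles
#>     0     1     2     3     4     5     6     7
#> 0.116 0.246 0.188 0.150 0.175 0.105 0.020 0.000

meanLinkerExtension(mean(tab$radius_A))   # 27.04 A mean linker extension
randomCoilExtension()                     # 23.48 A random-coil expectation
localConcentration()                      # 3.34 mM local kinase concentration
```

Read: the synthetic basal ensemble reproduces the measured kinase-radius
distribution (mean ~127 Å, s.d. ~15 Å, range 77–175 Å, 2.6% compact), the
separation distribution (mean ~58 Å, 20% within steric contact), and the
pair-count categorical (~12% zero pairs, ~58% with 1–3 pairs, 2% fully
paired). Subtracting the hub radius (55 Å) and kinase diameter (45 Å) from
the mean radius gives a ~27 Å mean linker extension, consistent with the
~23.5 Å random-coil expectation for a 45-residue chain; confining 12
kinase domains to the torus spanned by the radius extremes yields a ~3.3 mM
local concentration.

See `vignettes/holoenzyme-ensembles.Rmd` for the full model description,
calibration rationale and numerical choices.

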