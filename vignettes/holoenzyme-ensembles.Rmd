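---
title: "Modelling and measuring CaMKII holoenzyme conformational ensembles"
author: "holoflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and measuring CaMKII holoenzyme conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holoflex)
```

## The system and the model

CaMKII-alpha assembles into holoenzymes of twelve (rarely fourteen) subunits.
The C-terminal hub domains form a rigid central ring (~55 Å radius, ~25 Å
pore), while each N-terminal kinase domain hangs off the hub on an
intrinsically disordered variable linker. In single-particle EM projections
the holoenzyme therefore appears as a central hub surrounded by peripheral
kinase densities at variable distance, and the basal-state ensemble is a
continuum of conformations rather than one structure.

Two per-subunit quantities summarise that continuum:

* the **kinase radius of extension** — hub centre to kinase-domain centre,
  plus an appended 22.5 Å (the average kinase-domain radius), so the value
  reaches the domain's outer edge;
* the **clockwise neighbour separation** — centre-to-centre distance from a
  kinase density to its nearest neighbour in the clockwise direction.

Three operational thresholds classify states. Neighbours separated by less
than 45 Å (one kinase diameter) are in steric contact and counted as a
**dimeric pair**; a radius below 100 Å (hub radius + kinase diameter) marks
the hub-docked **compact** conformation; both comparisons are strict (`<`),
following the operational definitions. Per particle, the number of
separations below 45 Å gives the **pair count** (0–6 for a 12-mer).

## The synthetic generator

`generateEnsemble()` draws holoenzymes whose statistics are calibrated to
the published basal-state measurements. The layers are:

* **Oligomer state.** Bernoulli(`pTetradecamer` = 0.035) per particle:
  the observed 14-mer fraction is below 4%, and we centre it at 3.5%.
* **Pair arrangement.** The pair count is categorical over 0..6 with
  default probabilities (0.10, 0.25, 0.20, 0.15, 0.165, 0.11, 0.025); the
  arrangement of that many disjoint pairs on the ring is sampled uniformly
  over all matchings of that size on the cycle graph, by explicit
  enumeration (the 12- and 14-cycles have few matchings per size, so
  enumeration is cheap and exactly uniform). The masses at 0, 1–3 combined,
  and 6 pairs match the reported ~10%, ~60% and ~2.5%; the 4- and 5-pair
  masses are not individually reported and are calibration choices
  constrained by the ~20% overall paired-separation fraction
  (the categorical's mean of 2.46 pairs / 12 separations = 20.5%).
* **Radii.** A two-component truncated-Gaussian mixture: extended
  N(127, 15) on [100, 175) and compact N(88, 5) on [77, 100), with compact
  probability 0.025. A single Gaussian at the reported moments would put
  ~4.6% of mass below 100 Å, contradicting the observed <3%; the mixture
  reproduces mean ≈ 127 Å, s.d. ≈ 15 Å, the full 77–175 Å range, and a
  compact fraction of ~2.5%. Because the component supports split exactly
  at 100 Å, the compact label and the threshold classification coincide by
  construction.
* **Separations** (separation-explicit mode). Paired edges draw from
  N(36, 5) truncated to [20, 45), unpaired from N(62.5, 11) truncated to
  [45, 110]. The hard support split at 45 Å makes threshold classification
  recover the generated pair labels with zero error — a deliberate
  idealisation (real densities straddle the threshold) that turns the
  downstream classification tests into pure sampling tests. The mixture
  reproduces mean ≈ 58 Å and s.d. ≈ 14.5 Å.

The calibrated mixture moments (numeric integration of the truncated
densities) are: radii 127.2 / 15.0 Å, separations 58.0 / 14.5 Å — inside
the reported ~127 (±16) and ~58 (±15).

### Angular mode

For image-level work the generator can realise full 2D coordinates
(`mode = "angular"`). Paired edges get an angular gap ~N(19.5°, 2.5°) — at
the mean radius this corresponds to a ~36 Å chord; unpaired gaps are drawn
around the equal share of the residual angle with 6° jitter and rescaled so
all gaps sum to exactly 360°, closing the ring (non-positive gaps trigger a
bounded resample). Kinase centres sit at polar radius `radius − 22.5 Å`;
separations are then recomputed by the law of cosines.

The 6° jitter is a realism choice with a measurable consequence: because a
separation shares the radii of its two subunits, angular mode couples
radius and separation mechanically. A variance decomposition at the mean
geometry (chord sensitivity sin(θ/2) per radius vs ρ·cos(θ/2) per radian of
gap) puts the pooled Pearson correlation near 0.2–0.3 for 6° jitter, i.e.
inside the (0, 0.35] band consistent with the weak reported correlation
(0.2, read as no meaningful dependence); much smaller jitter would drive
the correlation well above it. Separation-explicit mode samples radii and
separations independently, so its correlation is ~0 by construction — the
two modes bracket the real measurement.

## Measurement rules

`measureEnsemble()` is the single entry point. Separation-explicit tables
pass through unchanged (the generator already holds the measured
quantities); angular ensembles are re-measured from coordinates:
`kinaseRadius()` appends 22.5 Å to the hub-centre distance, and
`clockwiseSeparations()` orders the centres about their centroid and takes
consecutive distances, closing the ring. "Clockwise" is fixed in image
convention (y increases downward), which maps to decreasing mathematical
polar angle; the statistics are direction-symmetric, so the convention only
affects per-edge labels. All measurements are rigid-motion invariant.

The EM analysis excluded densities that could not be clearly resolved
(883 usable separations of a possible ~984); the synthetic path has no
unresolved densities, so no exclusion rule applies by default, but a
per-subunit `dropout` probability (default 0) can emulate it, and the
image pipeline flags merged peaks for the same purpose.

## Statistics

`geometrySummary()` reports the moment-based Gaussian parameters (the
descriptive "fit" is parameterised directly by the sample mean and n−1
s.d. — no optimisation), whisker quartiles, 5 Å histograms (right-open
bins anchored at 0 Å; the anchor is our choice, the width matches the
~4.37 Å pixel), and strict threshold fractions. `pairCountDistribution()`
classifies particles by thresholded separations; chains of consecutive
short separations could in principle exceed the 6-pair matching bound, so
the count is capped at floor(n/2) with a warning (generated matchings never
trigger it). `radiusSeparationCorrelation()` is Pearson, matching a linear
scatter-map readout; no significance test is attached because none is
defined for the original value.

## Physical models

* `randomCoilExtension()`: random-walk end-to-end scaling b√N with
  b = 3.5 Å. The linker spans residues 301–344 (44 residues inclusive),
  but the published arithmetic uses 45; the default follows that usage and
  the count is configurable. 3.5·√45 = 23.5 Å.
* `meanLinkerExtension()`: mean radius − 55 Å (hub) − 45 Å (kinase
  diameter); 127 Å ⇒ 27 Å, in random-coil agreement with the 23.5 Å above.
* `torusVolume()` / `localConcentration()`: the kinase occupancy volume is
  a torus with R = (77+175)/2 = 126 Å and r = (175−77)/2 = 49 Å
  (`torusFromRadiusBounds()`); V = 2π²Rr² ≈ 5.97×10⁶ Å³, and 12 domains in
  that volume give ~3.3 mM — the local-concentration scale that makes even
  a 200–600 µM Kd kinase-domain dimerisation significantly populated. No
  mass-action pairing model is implemented: the mapping from Kd and local
  concentration to the ~20% paired fraction is not specified by the source
  analysis, and a naive equilibrium over-predicts pairing.

## Image round trip

`renderParticle()` draws a particle at 4.37 Å/px in a 128² box: hub
annulus (outer 55 Å, pore 12.5 Å), kinase domains as isotropic Gaussian
blobs (σ = 10 Å), additive Gaussian noise (σ = 0.05 relative).
`detectParticle()` smooths, takes the hub centre as the intensity-weighted
centroid of the central disc, finds kinase peaks as local maxima outside a
50 Å exclusion radius, and refines them to sub-pixel positions. Peaks
closer than 20 Å merge into one (paired domains can fuse at high noise);
the result is then flagged partial rather than erroneous, mirroring the
"clearly resolved" criterion. Noise-free round trips recover every centre
within one pixel, and the full generate → render → detect → measure chain
reproduces the coordinate-path mean radius and separation within 2 Å at
default noise (200 particles in the shipped test).

## FRET correction

`correctFret()` implements the three-filter sensitized-emission
subtraction: FRETc = raw − 0.02093·donor − 0.09484·acceptor, applied to
background-subtracted channels (background is the median of a blank
region), with negative pixels retained. The coefficients are rounded-up
cross-bleed estimates: on scenes mixed with smaller true bleed-through the
correction can only under-estimate true FRET, never create it.
`normalizedFret()` divides mean FRETc by mean donor intensity (valid under
acceptor excess, enforced by the closed 4–11× gate after converting GFP
intensities to abundance with the 4.8× detection-efficiency factor).
The original description is ambiguous about which fluorophore is the
donor (the filter set implies GFP-donor, the cell analysis labels mGFP the
acceptor); all formulas here are written against donor/acceptor *roles*,
and `acceptorDonorRatio()` takes the GFP role as an argument
(default: acceptor), so either reading is a configuration change.
`synthFretScene()` builds the exact linear mixture the correction assumes,
with disc-shaped cells and known per-cell ground truth — it emulates bleed
linearity, not cellular morphology, photobleaching or spectral unmixing,
so passing tests validate the arithmetic and gating, not microscope
physics.

## Dose-response fitting

`fitHill()` fits the four-parameter logistic with variable slope in
log10-dose by Levenberg–Marquardt, reporting standard errors from the fit
(EC50 errors delta-method-propagated from log10 EC50). The slope-start
sign is taken from the dose–response correlation so activation and
inhibition curves both converge; flat data are flagged unidentifiable
rather than fitted. `foldChange()` compares two fits (EC50 ratio, Hill
difference) with propagated errors. Only recovery of known synthetic
parameters is validated — at 2% CV and 10 doses the EC50 and slope biases
are below 2% over 500 replicate fits; the experimental EC50/Hill tables
are deliberately out of scope.

## Worked example

```{r example}
cfg <- ensembleConfig(nParticles = 1000, seed = 42)
ens <- generateEnsemble(cfg)
tab <- measureEnsemble(ens)

geometrySummary(tab$radius_A, thresholds = 100)
geometrySummary(tab$separation_A, thresholds = 45)
pairCountDistribution(ens)

meanLinkerExtension(mean(tab$radius_A))
localConcentration()
```

## Problem sizes and numerical choices

The shipped tests use 1,000-particle ensembles (≈12,000 subunits) for
distribution recovery, 4,000 dodecamers for the pair-count categorical,
500 angular particles for the correlation band, 200 rendered particles for
the image pipeline, 10⁵ draws for moment oracles, 10⁶ rejection samples
for the torus-volume cross-check and 500 replicate Hill fits — sizes at
which Monte-Carlo error is comfortably below every tolerance asserted.
Truncated Gaussians are sampled by inverse-CDF (exact, vectorised, no
rejection); extreme-tail draws that round onto a support bound are clamped.
Matchings are enumerated, not rejection-sampled. Angular rescaling retries
up to 100 times before erroring. All lengths are in Å, config angles in
degrees (radians internally), concentrations in mM.

## Limitations

The generator is 2D (particles lie in a preferred orientation plane) with
no excluded-volume interactions between kinase domains, no Ca²⁺/CaM-bound
state, no atomic detail, and 14-mers reuse the 12-mer per-subunit
distributions (no 14-mer-specific geometry is reported). The hard support
splits at 45 Å and 100 Å idealise distributions that overlap in real data,
so classification-recovery results on synthetic ensembles bound, but do
not measure, classification error on micrographs. Rendering emulates blob
geometry and additive noise only — no CTF, stain model or classification
artefacts.
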