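---
title: "Locating neurosteroid photolabeling sites by middle-down MS: methods and design"
author: "photolabelMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating neurosteroid photolabeling sites by middle-down MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photolabelMS)
```

## The problem

Photoaffinity labeling maps small-molecule binding sites on membrane
proteins: a photoactivatable analogue of the ligand (here, diazirine- and
trifluoromethylphenyl-diazirine-bearing analogues of the neurosteroid
allopregnanolone, named KK123, KK200 and KK202) is bound to the receptor
in native membranes and crosslinked by UV light, covalently adding the
reagent mass to one residue of its binding pocket. For GABA-A receptors
the pockets lie in the transmembrane domain (TMD), so the evidence arrives
on large, hydrophobic tryptic peptides — whole TM helices of 20-36
residues — analyzed as intact units ("middle-down" MS) rather than as
short bottom-up peptides. Labeling is sparse (well under a few percent of
copies), adducts are prone to neutral loss during fragmentation, and the
unlabeled peptide dominates the signal. The pipeline in this package
implements the identification, localization and quantification logic this
regime requires:

1. **MS1 screening** (`screenLabeled`, `findDoublets`): candidate labeled
   peptides are theoretical peptide + adduct masses matched to ion
   features within a ppm tolerance. Two orthogonal filters suppress false
   matches: the *delayed-retention criterion* — a covalent sterol adduct
   makes the peptide more hydrophobic, so the genuine labeled form must
   elute later than its unlabeled counterpart — and, for click-tagged
   reagents, *heavy/light doublets*: a stable-isotope pair in the tag
   makes every labeled feature appear as two co-eluting features at a
   fixed neutral-mass spacing.
2. **MS2 localization** (`localizeSite`, `overlayVerify`): b/y
   fragment-ion ladders are computed for every candidate placement of the
   adduct along the peptide, matched at an absolute fragment tolerance,
   and the placement(s) best supported by the matched ions define the
   reported residue interval.
3. **Quantification** (`efficiencyFromRun`, `competitionReduction`):
   labeling efficiency is the area of the labeled peptide's extracted-ion
   chromatogram (XIC) as a percentage of the unlabeled peptide's, and
   competition ("protection") by excess unmodified ligand is the percent
   reduction of that efficiency between arms.
4. **Reporting** (`assignCluster`, `renderReport`): localized residues are
   mapped by pure coordinate lookup onto annotated structural clusters
   (the three binding-site classes: the beta3(+)/alpha1(-) intersubunit
   site and the alpha1 and beta3 intrasubunit sites).

The package also implements the electrophysiology summary quantities used
to characterize the same receptors (potentiation response ratio, direct
activation on an open-probability scale, constitutive open probability),
and a seeded synthetic-data generator so that every stage is testable
against ground truth without any external download.

## Mass bookkeeping

All arithmetic is monoisotopic (high-resolution orbitrap regime) with
positive-mode protonation, $m/z = (M + z\,m_p)/z$, proton mass
$m_p = 1.00728$ Da, water $18.01056$ Da, and a fixed five-decimal residue
table (`residueMasses()`). Tryptic digestion cleaves C-terminal to K or R
except before proline — the conventional rule; the analyzed TMD peptides
are consistent with it — with up to three missed cleavages by default.

The adduct registry (`defaultAdducts()`) carries the reagent
variable-modification masses: KK123 372.16, KK200 462.27, KK202 500.31,
and the click-tagged KK123 forms 672.4322 (light) / 682.44 (heavy) Da.
Two registry choices deserve note:

* The KK123 mass is internally inconsistent in the source measurements:
  the stated modification mass (372.16) back-calculates ~0.11 Da lighter
  than the reported labeled precursor. The registry keeps the stated
  modification mass; the worked-example check therefore tolerates a
  residual of a few hundredths of an m/z unit at $z = 4$.
* The heavy-light doublet spacing defaults to the difference of the tag
  masses, $682.44 - 672.4322 = 10.0078$ Da, rather than the nominal
  "10.07": the printed masses are the more precise statement, and at 30
  ppm on a ~3.2 kDa peptide both values match the same doublets. The
  nominal spacing is available via `defaultAdducts(nominalPairDelta =
  TRUE)`.
* No mass is given anywhere for the NEM-then-DTT cysteine adduct; the
  registry uses the sum of the NEM (+125.04768) and DTT (+154.01226)
  monoisotopic additions, +279.05994 Da, as an explicit package
  convention, overridable in the JSON config.

## Search parameters

`searchParams()` collects the tunables, with defaults chosen for the
30-ppm / 0.1-Da acquisition regime:

| parameter | default | unit | role |
|---|---|---|---|
| `precursorTolPpm` | 30 | ppm | MS1 mass matching and doublet spacing |
| `fragmentTolDa` | 0.1 | Da | absolute MS2 fragment matching (no ppm mode at MS2) |
| `minRetentionDelayMin` | 1.0 | min | delayed-retention criterion; the direction of the shift is physical, the magnitude is not specified upstream, and observed shifts are around ten minutes, so 1 min separates genuine shifts from apex jitter |
| `coelutionTolMin` | 0.2 | min | "identical retention time" for doublet partners, read as apex agreement within 0.2 min |
| `chargeRange` | 2-6 | — | precursor charges enumerated at MS1 |
| `pairAbsTolDa` | 0.01 | Da | absolute floor on the doublet mass-difference tolerance |
| `intensityFloorFactor` | 5 | — | feature calling floor, 5x the median nonzero XIC intensity (scale-free) |

Fragment charges at MS2 default to $1..\min(z_{prec}-1, 3)$; doubly
charged b/y ions of these large peptides are routinely informative.

## Localization semantics

For a peptide of length $L$ with one adduct, `localizeSite` builds the
b/y ladder for every candidate placement $1..L$ (an ion carries the
adduct exactly when the placement falls inside its residue span), matches
each theoretical ion to the nearest peak within the fragment tolerance,
and scores each placement by the number of *distinct* peaks explained —
one peak satisfying several isobaric ions counts once. The reported
interval is the minimal interval covering all placements that achieve the
maximal score; ties are reported as the union interval (e.g. "G308 or
R309", "VKA 278-280") rather than forcing an arbitrary residue, and
one-sided bracketing evidence is accepted.

Neutral loss requires care. A fragment that loses the adduct during
fragmentation reappears at exactly the unmodified fragment mass — which
is also the mass of the genuinely adduct-free ion. Two consequences are
built into the scoring:

* a peak explainable as a neutral-loss ion of a given placement carries
  zero localization weight for that placement (it still supports peptide
  identity, and is tallied separately);
* if **no** placement matches any adduct-bearing ion, the spectrum
  contains no site evidence at all and the whole peptide $[1, L]$ is
  returned. Without this rule a spectrum of pure neutral-loss ions would
  be misread as adduct-free evidence and "localized" to an arbitrary
  terminus.

When adduct-bearing evidence exists, adduct-free matches do discriminate:
an adduct-free ion only matches placements outside its span, which is the
set-intersection ("site-defining ion pair") logic — an adduct-bearing
y9 next to an adduct-free y8 pins the site to the single bracketed
residue.

`overlayVerify` checks a localization against a light/heavy tag spectrum
pair: every common matched adduct-bearing fragment must differ by the tag
spacing divided by the fragment charge, every adduct-free fragment
matched in the light spectrum must reappear unshifted in the heavy one,
and at least one adduct-bearing fragment must be common — otherwise the
verdict is "inconsistent".

## Quantification

Efficiency compares labeled and unlabeled XIC areas *at the same charge
state* (the one with the largest unlabeled feature area), avoiding
ionization-efficiency confounds between charge states; no correction is
applied between the labeled and unlabeled forms themselves — the metric
is a raw area ratio, as upstream. Integration is trapezoidal over the
detected feature's bounds after subtracting a constant baseline, the 10th
percentile of the chromatogram window (robust, deterministic, and
irrelevant to ratios on clean data). A labeled form with no detectable
feature reports 0% flagged "not detected"; a missing unlabeled reference
is an error, since the denominator is undefined. Competition reduction is
computed from the arm means, $100\,(\bar e_{ctl} - \bar e_{comp})/\bar
e_{ctl}$, with per-replicate reductions also emitted; replicate summaries
are mean ± SD (n-1) with n recorded, and inferential testing is out of
scope.

## The synthetic generator

`generateRun` emulates the LC-MS structure the method relies on, not the
full physics of an orbitrap run:

* MS1 features are Gaussian elution profiles at the theoretical
  monoisotopic m/z (centroid model; no isotope envelopes, no profile
  peaks), with the labeled/unlabeled area ratio equal to the configured
  efficiency and the labeled apex shifted later by a configurable delay
  (default 10 min — a plain shift, not a hydrophobicity regression, since
  only the direction of the effect is established).
* Heavy/light pairing emits co-eluting duplicates offset by
  pairDelta$/z$ at a 1:1 mixing ratio by default; the light and heavy
  forms share one fragmentation pattern, as the two tag isotopologues
  co-fragment identically.
* MS2 spectra at the labeled apex contain each b/y ladder ion with
  probability `ladderCompleteness`, neutral-loss companions of emitted
  adduct-bearing ions with probability `neutralLossFraction`, and
  `noisePeaks` uniform-m/z, log-uniform-intensity noise peaks.
* The default study conditions are the four receptor TMD peptides with
  their labeled residues and observed 3 uM efficiencies (0.19-0.77%),
  spread along the gradient; the efficiency range exercised in the
  recovery tests spans 0.06-3.0%, the observed span at 15 uM.
* Everything is driven by one integer seed; identical seeds give
  byte-identical output files.

Because the generator emits exactly the signal classes the pipeline
searches for, passing recovery tests demonstrates the correctness of the
inference logic under the stated noise model — not robustness to
co-eluting isobaric interference, isotope-envelope misassignment,
chimeric MS2 spectra or detector saturation, none of which are simulated.

`generateEphysTable` draws per-cell peak currents under the two-electrode
voltage-clamp sign convention (agonist currents inward/negative at -60
mV; the picrotoxin shift positive). Effects are drawn from normal
distributions truncated at zero; the location parameter is solved (by
`uniroot` on the truncated-normal mean) so that the configured effect is
the *population mean of the truncated draws* — otherwise a configured
ratio of 4.2 with SD 3.3 would generate a population mean ~0.3 higher
than configured and the recovery check would measure the bias of the
generator instead of the estimator.

## Electrophysiology formulas

For peak currents measured per cell: potentiation ratio
$I_{GABA+mod}/I_{GABA}$; direct activation $I_{mod}/I_{GABA_{sat}+prop}$
(a fraction on the open-probability scale; a flag switches the
denominator to a saturating-GABA column for the percent-of-GABA display
convention, both of which circulate); constitutive open probability
$P_{o,const} = I_{pic}/(I_{pic} - I_{GABA+prop})$, anchored between the
picrotoxin ($P_o \approx 0$) and saturating GABA + propofol
($P_o \approx 1$) responses and lying in $[0,1]$ under the sign
convention. All are scale-invariant in the recorded currents. Summaries
are mean ± SD (n-1 denominator; a single cell reports SD 0 with a flag).

## Numerical and testing choices

* Tolerances: mass round trips are exact to 1e-9; worked-example
  precursors are checked to ±0.05 m/z (the registry masses are printed to
  2-4 decimals); recovered efficiencies to 10% relative; recovered group
  means to three standard errors.
* Localization is verified against a brute-force oracle (naive
  enumeration of every placement with substring-sum fragment masses) on
  1000 random peptides of length ≤ 12 — exact agreement required. Site
  recovery uses 500 seeded single-peptide runs at ladder completeness 0.6
  with 20 noise peaks (interval must contain the truth in ≥ 99%) and 100
  runs at completeness 1.0 with no noise (single-residue exactness in
  100%). Efficiency recovery uses 20 seeded runs log-spaced over
  0.06-3.0%. These problem sizes keep the default test run to about a
  minute while leaving the binomial margins meaningful.
* Feature bounds are the nearest flanking local minima of the XIC;
  adjacent features may share a boundary point but not interiors.
* Doublet assignment is greedy by combined mass + retention error with a
  deterministic ascending-m/z tie-break, after an internal sort — the
  result is invariant to input order. The heavy/light intensity ratio is
  recorded but never filtered on (1:1 mixing is typical but not
  guaranteed).
* Degenerate inputs: empty runs give empty chromatograms and no features
  (not errors); empty control arms, zero denominators, unknown residues
  and out-of-range placements are rejected with informative errors.

## Limitations

Centroided data only; no isotope-envelope deconvolution, charge
inference, cross-run alignment, open modification search, FDR estimation
or de novo sequencing. One adduct per peptide. b/y ions only. Cluster
assignment is sequence-coordinate lookup against a shipped annotation
table — no structural modeling. The bundled `exampleSubunits()` sequences
are synthetic scaffolds: real TMD tryptic peptides at their native
coordinates embedded in GAS-repeat linkers, suitable for exercising the
pipeline but not for biological inference outside those peptides.
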