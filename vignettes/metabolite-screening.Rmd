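---
title: "Screening plant extracts for drug metabolites: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening plant extracts for drug metabolites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoscreen)
```

## The problem

Plants growing in water or soil that carries pharmaceutical residues take
those compounds up through their roots, translocate them toward the leaves,
and metabolize them — typically by hydroxylation, demethylation and
conjugation with amino acids. Detecting such metabolites in a hydroponic
model experiment (plants dosed with chlorinated antidepressants: sertraline,
clomipramine, trazodone) poses a chain of analytical questions that
`phytoscreen` answers computationally, starting from centroided
high-resolution LC-MS peak tables:

1. *What might be there?* Enumerate plausible metabolites from
   biotransformation rules (`transform_rules` functions), or load an
   explicit suspect list.
2. *Is it there?* Match suspects against observed features by exact mass
   and isotope envelope (`assemble_envelopes()`, `match_suspects()`).
3. *What else is there?* Flag unexplained features whose isotope envelopes
   betray chlorine (`detect_halogenated()`) — chlorinated drugs pass their
   halogen to every metabolite, so the isotope pattern is a tracer that
   finds metabolites nobody predicted.
4. *Is it really that compound?* Confirm by MS² neutral losses, fragments
   shared with the parent drug, and diagnostic conjugate ions
   (`annotate_losses()`, `shared_fragments()`, `flag_diagnostics()`).
5. *Did the plant make it?* Classify provenance against a growing-medium
   (GM) control — the dosing solution incubated without plants — and a
   negative control (`classify_provenance()`).

## Exact-mass arithmetic

All masses derive from a frozen in-package table of monoisotopic atomic
masses (IUPAC values to at least 6 decimals; C, H, N, O, F, P, S, Cl, Br,
I, Na, K) so results are bit-stable and independent of external libraries.
The protonated ion is modeled as

$$ m/z\,[\mathrm{M+H}]^+ = M_{\text{mono}} + m_\mathrm{H} - m_e $$

with the electron mass $m_e = 0.00054858$ Da subtracted: at four decimal
places the correction is visible (sertraline computes to 306.0811 with it,
306.0816 without). Mass error is the signed ppm deviation
$(m_{\text{meas}} - m_{\text{theor}})/m_{\text{theor}} \times 10^6$. Only
the [M+H]⁺ adduct is modeled; positive-ion electrospray of these amines
produces essentially no other adduct, and the adduct definition is a single
constant an advanced user can extend.

One wrinkle worth knowing: published tables of this kind round theoretical
m/z to 4 decimals *before* computing the printed ppm column. Reproducing a
printed ppm value to one decimal therefore requires rounding the
theoretical value first; `ppm_error()` itself never rounds.

## Isotope patterns and the chlorine signature

`isotope_pattern()` convolves per-element isotope distributions (frozen
abundance table: ³⁵Cl 0.7576 / ³⁷Cl 0.2424, ¹²C 0.9893 / ¹³C 0.0107, …)
exactly, using binary exponentiation per element, merging terms that agree
to 10⁻⁵ Da and discarding terms below 10⁻¹⁵ of the maximum. Isotopologues
are then aggregated into unit-spaced nominal bins (offset = rounded mass
difference from the lightest isotopologue; bin mass = abundance-weighted
mean), which is the resolution at which an envelope is read off a
chromatogram. Fine isotope structure and peak-shape simulation are
deliberately out of scope. The default pruning threshold, 10⁻⁴ of the base
peak, keeps patterns compact without ever dropping the base peak.

The chlorine signature is the binomial over Cl isotopes only: A:A+2 =
1:0.320 for one Cl and 1:0.640:0.102 for two. The field's "3:1" and
"9:6:1" mnemonics are roundings of these values (9.8:6.3:1); all scoring
uses the exact binomials.

`envelope_match_score()` operationalizes what a mass spectrometrist does by
eye. Each expected peak earns credit 1 if an observed peak sits within
`mz_tol` of its offset from the base peak and within `intensity_tol` of its
relative intensity; intensity excess beyond the tolerance decays credit
proportionally; missing peaks earn 0; the score is the mean credit. Two
defaults matter:

* `mz_tol = 0.005` Da — tight on purpose. The two-¹³C satellite sits at
  +2.0067 Da, a ³⁷Cl peak at +1.9970 Da; 9.7 mDa apart. A loose tolerance
  would let carbon-rich chlorine-free compounds impersonate monochloro
  species. 0.005 Da separates the two while comfortably absorbing the
  sub-ppm relative jitter of peaks within one envelope.
* `intensity_tol = 0.15` — absorbs both area noise and the modest ¹³C
  contribution that rides on top of a ³⁷Cl peak when scoring an observed
  envelope against the pure-chlorine signature.

Observed peaks with no expected counterpart are not penalized: when scoring
against a pure-Cl signature the ¹³C satellites are expected bystanders.
When a *suspect formula* is available, matching scores against the full
elemental pattern of the protonated ion instead of the pure-Cl signature,
which is strictly more exact.

## Suspect enumeration

Built-in rules encode the transformations this compound class undergoes:
hydroxylation (+O, up to twice), N-demethylation (net −CH₂, up to twice —
modeled as a delta because loss of a methyl from N–CH₃ leaves −CH₂ in the
sum formula), amide conjugation with amino acids (+AA − H₂O; default set
{Phe, Tyr}, extensible to the full proteinogenic set), and the cleavage of
trazodone to meta-chlorophenylpiperazine — a product-type rule bound to the
exact trazodone formula, because no element delta expresses a ring-system
cleavage. Conjugation is capped at one per chain via a rule group.

`enumerate_candidates()` applies rules breadth-first to depth 3 by default
(hydroxy-demethyl conjugates need three steps), collapsing formulas reached
by different orders into one candidate while keeping all chains as
provenance, skipping silently any application that would drive an element
count negative, and ordering deterministically by mass then chain. Depth 3
over the three parents yields 62 candidates — small enough that matching
cost is irrelevant, broad enough to cover every observed metabolite
formula.

The package also ships `inst/extdata/suspects_reconstructed.csv`, a
*reconstructed* literature suspect list (the detected species plus common
human/animal metabolites such as norsertraline and N-oxides). It is a
synthetic stand-in built for examples and tests, not a copy of any
published supplementary table.

## Matching and species calling

`assemble_envelopes()` chains co-eluting centroids (RT within 0.05 min)
spaced by k·1.00336 or k·1.99705 Da (k = 1, 2) into features via
union-find; the lowest-m/z member is the monoisotopic peak. A match then
requires |ppm| ≤ 5 — the defensible window given that observed mass errors
for true compounds in this kind of data span roughly 0.5–4.8 ppm — *and*
envelope score ≥ 0.7. A singleton feature can never reach 0.7 against a
chlorinated candidate, so exact mass alone never suffices; this is what
makes 200 random noise peaks per sample harmless.

One candidate matched at several retention times separated by more than
0.1 min (`species_rt_gap`) is reported as structural isomers — distinct
species. Two candidates matching one feature (e.g. two conjugates sharing
one sum formula) are both reported and flagged ambiguous; there is no
silent winner, exactly as an analyst would report an isobaric pair.

## Provenance classification

For each species the classifier uses the compartment pattern and the ratio
of root area to GM-control area:

| evidence | call |
|---|---|
| detected in negative control | `contamination_suspect` |
| administered compound | `parent` |
| absent from GM control | `true_metabolite` |
| root/GM ≥ 100 | `metabolite_dominant` |
| 5 ≤ root/GM < 100 | `mixed` |
| root/GM < 5 | `transformation_leaning` |

The thresholds 100 and 5 are interpretation, not measurement: they separate
ratios in the hundreds (plant metabolism dominant, medium contribution
marginal) from ratios of a few tens (both mechanisms clearly contribute)
from ratios near unity (transformation in the medium followed by uptake is
the simpler reading). Both are configurable, and the ratio itself is always
reported so a reader can apply their own cutoffs.

## Quantification

External calibration is an ordinary least-squares line (`stats::lm`) of
area on standard concentration; `quantify()` inverts it and rescales by
extraction volume over tissue mass (defaults 2 mL and 1 g, the scale of a
small hydroponic extract). Replicate summaries use the sample SD (n − 1);
RSD is printed as an integer percentage but kept at full precision
internally. Negative back-calculated concentrations clip to zero with a
warning flag. Matrix effects, recoveries and detection limits are out of
scope.

## The synthetic data generator

`generate_dataset()` emulates the experiment at desk scale: 3 culture
replicates each of root and leaf extract, one GM control, one negative
control. Each compound present in a compartment contributes its full
[M+H]⁺ isotope envelope down to 0.5 % relative abundance. Defaults encode
the emulated study's published evidence:

* **Mass error**: one calibration shift per envelope drawn from
  N(0, 2 ppm), plus 0.3 ppm per-peak centroiding scatter, total clamped at
  ±4.8 ppm — the largest mass error in the emulated study's detection
  table. Sharing the shift across an envelope mirrors how TOF calibration
  error behaves (isotopologue *spacings* are far more precise than absolute
  masses), and the clamp encodes that every reported detection lay inside a
  5 ppm window.
* **Area noise**: log-normal with CV 0.2 per compound and sample (the
  scale of the reported biological RSDs, 14–27 %), plus 5 % per-peak
  envelope noise — within the 0.15 intensity tolerance at 3σ.
* **Abundance patterns**: root/leaf base areas encode the observed
  translocation (sertraline root-retained, trazodone leaf-accumulating);
  GM areas are the root base area divided by the targeted root/GM ratios
  (51, 378, 491, 1.84, 25), so the recomputed ratios land near those
  values; parents get twice the root area in the GM (it is the dosing
  solution). Absolute areas are arbitrary units — only ratios and presence
  patterns are anchored, since no raw areas are published.
* **Noise**: 200 uniform-random peaks per sample, rejection-sampled to
  stay ≥ 20 ppm from every true isotopologue *and* every enumerable
  suspect m/z. This makes "zero false positives" a designed property of
  the study conditions rather than luck, mirroring the fact that the
  real study's noise did not collide with its suspects.

Everything flows from one seeded Mersenne–Twister stream; a fixed seed
reproduces the dataset byte-for-byte, and the generator restores the
caller's RNG state.

What the generator does **not** emulate — and therefore what passing tests
do *not* demonstrate about real data: chromatographic peak shapes and
profile spectra (input is already centroided), retention-time drift across
batches, matrix-dependent ionization suppression, in-source fragmentation,
adducts beyond [M+H]⁺, and isobaric interferences closer than 20 ppm.
Real-extract concentrations and chromatograms are emulated, not
recomputed; no raw data are available to recompute them from.

## Problem sizes and runtime

The reference configuration — 14 compounds, 8 samples, ~2000 peaks, 62
candidates — runs the full pipeline in a few seconds on one core; the test
suite (519 assertions, including two full end-to-end recoveries) runs in
about half a minute. Generator tests use a reduced noise load (50 peaks per
sample) where the full load adds nothing to the property under test.

## Known limitations

* Demethylation as a bare −CH₂ delta cannot distinguish N- from
  O-demethylation, and rule chains are sum-formula provenance, not
  structures; positional isomers are distinguished only by retention time.
* The envelope assembler assumes centroids; shoulders and split peaks in
  poorly centroided data would fragment envelopes.
* Diagnostic MS² ions are empirical masses (165.1 for a phenylalanine
  conjugate, 181.1 for tyrosine, …), not formulas; they confirm, they do
  not identify ab initio.
* The provenance thresholds are explicit interpretation; a species with a
  root/GM ratio near a cutoff should be reported with its ratio, not just
  its label.
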