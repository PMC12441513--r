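---
title: "Methods and design choices in herbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in herbnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

## The problem

Oral administration of a multi-herb formula exposes the body to hundreds of
constituents; what circulates is a mixture of unmodified *prototypes* and
their phase-I/II *metabolites* (methylated, hydroxylated, reduced,
sulfated, glucuronidated or hydrolysed forms). Identifying both from
UHPLC-HRMS runs of extract, plasma and brain tissue requires chaining
several well-established steps — feature extraction, spectral networking,
fragmentation-rule filtering, and mass-shift metabolite prediction — whose
published descriptions are usually scattered across vendor software.
`herbnet` makes the whole chain explicit, parameterized and testable.

## Mass arithmetic

All theoretical values derive from one isotope-mass table (C 12 exactly,
H 1.00782503, N 14.00307401, O 15.99491462, S 31.97207117 Da; CODATA/AME
values) and the electron-corrected proton mass 1.00727646688 Da. Charged
species therefore use $m/z = (M \pm m_p)/|z|$ with the electron mass
accounted for; this convention reproduces the bundled reference tables'
printed theoretical masses at 4 decimal places (the alternative H-atom
convention is ~0.0011 Da off, far outside the tables' precision). One entry
in the bundled metabolite table sits exactly on a 4-dp rounding boundary
(the protonated C16H12O5 ion computes to 285.07575); we report the value
rounded half-even.

Adduct deltas ([M+NH4]+ = +18.033826, [M+HCOO]- = +44.998203,
[M+H-H2O]+ = −17.003288 Da) are derived once from the isotope table rather
than stored as opaque constants, and a test asserts that derivation.
Display precision is 4 dp for m/z and 2 dp for ppm; internal arithmetic is
full double precision. The ppm sign convention is
(measured − theoretical)/theoretical × 10⁶.

## Feature finding

The chain mirrors a standard MZmine configuration, with these defaults
(counts are detector counts, rt in minutes):

| parameter | default | role |
|---|---|---|
| MS¹ / MS² noise | 1000 / 100 | centroids below are ignored |
| min consecutive scans | 5 | trace survival |
| min intensity, consecutive scans | 3000 | trace summit requirement |
| min absolute height | 7000 | feature apex requirement |
| m/z tolerance | max(0.005 Da, 10 ppm) | trace joining |
| chromatographic threshold | 90% | valley-split depth (below) |
| peak duration | (0, 1] min | resolved segment span |
| isotope filter | max(0.001 Da, 5 ppm), 0.01 min | ¹³C spacing 1.00336 Da |
| join aligner | max(0.001 Da, 5 ppm), 0.1 min | weights m/z 3 : rt 1 |

Two points were genuinely open and are fixed here as package policy:

* **"Chromatographic threshold 90%"** is read as a *valley depth* rule: a
  trace splits at an interior local minimum only when the valley falls below
  (1 − 0.90) of the lower adjacent apex. A twin-peak trace with a 5% valley
  splits; a 50% saddle does not. The rule is covered by a golden test so
  the choice is explicit and revisitable.
* **Dual tolerances** "x Da or y ppm" take the more permissive bound,
  the usual MZmine reading.

Ties in the greedy join alignment break by higher score, then smaller
|Δm/z|, then sample order, making alignment deterministic. The MS² scan
assigned to a feature is the one whose precursor is within the align
tolerance and whose rt lies inside the feature's duration, highest precursor
intensity first. Rows without MS² are dropped, since every downstream step
needs fragments. No gap-filling or smoothing is applied.

## Molecular networking

The modified cosine works on √-transformed intensities (the convention of
public spectral-networking platforms; configurable to `"none"`). Fragment
pairs may match directly (|Δm/z| ≤ 0.02 Da) or shifted by the precursor
difference, letting structural analogues align. The one-to-one matching is
greedy by descending intensity product; a property test holds it within 5%
of the exhaustive optimum over a thousand random ≤ 6-peak spectra, and a
brute-force enumerator in the test suite is the independent oracle. Edges
require cosine ≥ 0.70 **and** ≥ 6 matched fragments; a *cluster* is a
connected component with ≥ 2 nodes. No top-K edge pruning or component-size
cap is applied, so the accounting is reproducible from first principles.
Cluster annotation propagation only ever adds flagged *hypotheses* — a
library or reference-standard annotation is never overwritten, and clusters
with conflicting annotated classes propagate `"ambiguous"`.

## The fragmentation rule engine

Rules are data (a CSV users can edit): diagnostic ions, neutral losses and
serial losses, each with class, polarity, tolerance and weight. Diagnostic
ions weigh 2, losses 1, and the serial CH₃ loss of anthraquinones weighs 2
because it is that class's most distinctive signature. A spectrum's class is
the arg-max of summed satisfied-rule weights, accepted only when the score
reaches 2 *and* leads the runner-up by ≥ 1 — the margin prevents oscillating
assignments; ties are reported as unclassified with both candidates. The
engine applies the filtering qualitatively described for these compound
families as a reproducible, documented score.

Tolerances: 0.01 Da against theoretical fragment positions. The bundled
tables' printed worked-example fragments deviate from exact masses by up to
~0.03 Da (4-dp printing and instrument calibration), so tests that use
printed fragment values state a 0.03 Da tolerance explicitly.

Isomer disambiguation by elution order (e.g. two asarone isomers sharing a
formula) is left to the retention-time columns of the library; the engine
itself never guesses modification sites.

## In-vivo identification

"Present in dosed, absent in blank" is made precise as: XIC apex in the
dosed run ≥ 7000 counts (reusing the feature-finder height) **and** blank
apex < 5% of the dosed apex, both configurable and logged per call. XIC
windows are ±5 ppm, matching the error envelope within which essentially
all library compounds were annotated.

Metabolite prediction enumerates multisets (order is chemically
meaningless) of ledger transformations to depth 2 — the depth the bundled
metabolite table actually requires (e.g. sulfation + methylation) —
deduplicated by resulting formula and pruned when any element count would
go negative. Matching a predicted mass to a dosed-only feature additionally
requires *evidence*: ≥ 1 fragment shared with the prototype's observed
spectrum at 0 or the chain mass shift, or a rule-engine class check that
positively supports the prototype's class. Features already attributed to a
detected prototype (m/z within 5 ppm *and* rt within 0.2 min of the library
entry) are removed from the metabolite search space first — without this,
every isomeric prototype pair would surface as a spurious "metabolite".
Isomeric candidates with one formula (e.g. a sulfated acid vs its
methylated-then-sulfated homologue) are all reported, never merged; pathway
edges colliding on one formula are flagged ambiguous.

## The synthetic generator

`simulate_spectrum()` builds MS² spectra from class templates: a cumulative
neutral-loss cascade applied to the precursor plus fixed diagnostic ions —
glucuronide/glycoside cleavage with an H₂O/CO cascade and the
retro-Diels–Alder ion for flavonoids, a 7-step CH₂ ladder for
sesquiterpenes, ring-cleavage ions for indole alkaloids, serial CH₃ losses
for anthraquinones, and so on. Intensities are a fixed descending profile
(base peak 10⁵) because only ordering matters downstream. m/z jitter is
Gaussian (sd 1.5 ppm, clamped at 5 ppm); chromatographic peaks are
symmetric triangles of 0.3 min at 0.05-min scan spacing — the simplest
shape satisfying every feature-finder filter. MS¹ noise stays below the
1000-count detection threshold unless a test raises it deliberately.
Identical seeds give byte-identical output, and changing only the seed
changes noise, never the planted ground truth.

What the generator does *not* emulate — chromatographic tailing, matrix
effects, in-source fragmentation, isotope envelopes beyond the single ¹³C
satellite, co-eluting isobars at real densities — bounds what green tests
mean: they certify the pipeline's logic and bookkeeping, not its behaviour
on raw instrument files.

## Problem sizes used in the test suite

The classification corpus uses 50 spectra per class over the seven classes
with distinctive templates; the cosine-optimality property runs 1000 seeded
trials at ≤ 6 peaks; the end-to-end study plants 10 prototypes, 6 depth-≤2
metabolites and 4 decoys over five matrices (~500 scans each). These sizes
give stable pass/fail behaviour at interactive runtimes while exercising
every code path; all are plain arguments and scale up freely.

## Known limitations

* mzML support is read-only, centroid-only, and delegated to `mzR`;
  profile data must be peak-picked upstream.
* The rule engine covers the fourteen-class vocabulary unevenly: classes
  without distinctive published fragmentation behaviour (e.g. aromatic
  aldehydes) carry only generic water/CO rules and will often classify as
  `unclassified`.
* Chain naming renders net elemental deltas; it does not distinguish, say,
  hydroxylation from N-oxidation, and never assigns modification sites.
* Network accounting reproduces the *procedure*, not any particular
  published node count, which depends on the full raw dataset and external
  library content.
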