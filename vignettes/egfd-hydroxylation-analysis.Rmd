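---
title: "Methods: consensus scanning, MS/MS localization, and kinetics of EGFD hydroxylation"
author: "asphkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus scanning, MS/MS localization, and kinetics of EGFD hydroxylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asphkit)
```

# Scope

asphkit models the three readouts used to characterize substrates of
aspartate/asparagine-β-hydroxylase (AspH): sequence-level consensus
scanning, fragment-level localization and quantitation of the
hydroxylation mass shift, and solution kinetics of substrate turnover.
This vignette records the models, the parameters that matter, the
numerical choices, and the deliberate limitations.

# Consensus-motif scanning

## The two rules

Both rules describe a window anchored by the cysteine pair that closes
a disulfide-bridged macrocycle of 10 residues (C3–C4 in EGFD ordinal
numbering):

* **revised** (10 residues): `C . [DN] . . . . [FY] . C` — acceptor D/N
  at ring position 3, aromatic F/Y at ring position 8;
* **legacy** (12 residues): the same ring followed by `. C`, i.e. the
  historical C4-X-C5 suffix.

The legacy pattern is the revised pattern extended by two positions, so
legacy hits are a subset of revised hits by construction;
`classify_sites()` turns this into the `both` / `revised_only` flag and
treats a legacy-only site as an internal-consistency error.

Design choices that were genuinely open:

* **Wildcards are unrestricted.** `X` positions admit any canonical
  residue, including C, D/N and F/Y: the consensus literature describes
  them as arbitrary proteinogenic residues, and restricting them would
  silently drop real substrates.
* **Whole-sequence scanning.** Matches are reported anywhere in the
  sequence, not only inside annotated EGFDs — non-EGFD proteins with a
  surface 10-residue macrocycle can be genuine substrates (the LU-domain
  case). Domain annotations, when supplied, only *label* hits and attach
  the domain's C4–C5 spacing.
* **Overlapping hits are all reported** (the scanner uses a lookahead so
  windows sharing a cysteine are not suppressed); deduplication is by
  (accession, rule, ring start).
* **Sequence-level only.** The scanner does not verify that a disulfide
  physically bridges the two cysteines; disulfide connectivity is a
  biochemical property outside sequence analysis.
* **Exact 10-residue rings only.** Longer Cys-bridged rings (e.g. the
  insert-bearing fibulin-5 EGFD1 case) are not matched; no tolerance for
  longer rings is implemented because no validated rule for them exists.

Coordinates are 1-based inclusive throughout, matching UniProt residue
numbering. `c4_c5_spacing()` counts residues strictly *between* the
fourth and fifth cysteine of a domain, so the legacy `C4-X-C5` suffix
corresponds to spacing 1 and the worked `C4-E-Y-C5` pattern to
spacing 2.

# MS/MS evidence

## Masses and fragments

All masses are monoisotopic (proton 1.00727646688 Da, water
18.0105646863 Da); hydroxylation is the single-oxygen delta
+15.9949146221 Da, the "~16 Da" step seen in annotated spectra. Only b
and y series are generated — the ion types used in the spectra this
analysis models — at charges 1..`max_charge`. A fragment carries the
delta of every modification it spans, which forces the sum rule
`m/z(b_i) + m/z(y_(n-i)) = M + 2·proton` at charge 1; the tests verify
it to < 1e-6 Da.

Synthetic cyclic assay peptides (chloroacetyl/Cys thioether bridged) are
handled at intact-mass level only through the constant
`THIOETHER_CYCLIZATION_DELTA` (−35.976678 Da, loss of HCl on
macrocyclization); fragment prediction inside a macrocycle is out of
scope.

## Peak matching and shift localization

`match_peaks()` assigns each theoretical ion to the nearest observed
peak inside a ppm tolerance (default **10 ppm**, typical for
high-resolution QTOF data; the tolerance is a user parameter). One peak
may satisfy at most one ion; candidate pairs are ranked by absolute ppm
error with ties broken toward the lower series index.

`localize_site()` matches the observed peaks once against the *combined*
candidate set — every ion in unshifted and shifted form — so a peak
supports exactly one candidate. Each classified ion then constrains the
site: a shifted `b_i` implies site ≤ i, an unshifted `b_i` implies
site ≥ i+1, and symmetrically for y ions; the reported interval is the
intersection, with width 1 reported as a unique position.

Two safeguards deal with residue-mass degeneracies (e.g. Gly+Gly and Asn
differ by < 1 ppb, so cross-series coincidences occur in real peptides):

* an evidence ion is discarded as **ambiguous** when an *unmatched*
  candidate implying a different positional constraint lies within half
  the match tolerance of it — in that situation the peak's assignment
  was effectively a coin flip;
* if after this filter an ion is still classified both shifted and
  unshifted, or the interval bounds cross, localization fails with an
  inconsistency error naming the offending ions (the pipeline wrapper
  `run_localize()` reports such spectra as `inconsistent` rows rather
  than aborting).

The guard is deliberately conditional on the coincident candidate being
unmatched: with a complete ion series both members of a coincident pair
are matched, the evidence set is self-consistent, and nothing is
discarded — preserving width-1 localization on clean data.

## Site occupancy

Occupancy is the standard label-free estimator
`100·Ih/(Ih + Ib)` from the hydroxylated and base peptide intensities.
It is defined only when the base peptide was detected; `Ih = Ib = 0` is
an error, and a missing base intensity is reported as `not_estimable`
rather than 0 %. The estimator is scale invariant, so it is unaffected
by overall signal level. Aggregation across charge states or
peptidoforms is left to the caller (sum intensities per site before
calling); the package does not impose an aggregation rule.

# Kinetics

## Progress curves

`simulate_progress()` solves the integrated Michaelis–Menten relation

$$K_m \ln(S_0/S) + (S_0 - S) = k_{cat} \cdot E_{active} \cdot t$$

for S(t) by bracketed root-finding on `[S0·1e-14, S0]` with tolerance
`1e-10·S0`; the bracket is guaranteed because the left side is monotone
in S with opposite signs at the ends. Assumptions: constant active
enzyme, no cosubstrate depletion, no product inhibition. In the
pseudo-first-order regime (Km ≥ 100·S0) the simulation reproduces the
closed form `100·(1 − exp(−kcat·E·t/Km))` to within 0.1 percentage
points, which the tests check.

## Initial rates and fitting

`initial_rate()` takes the least-squares slope of product concentration
versus time over the initial window, forced through the first qualifying
point. The window is **conversion ≤ 15 %** by default with at least 3
points: a stated window is needed because "initial rate" alone is not
operational, and at 15 % the curvature bias is below typical replicate
noise. For high-precision work (e.g. the noiseless round-trip test, which
requires < 2 % recovery error) sample earlier times or pass a smaller
window.

`fit_michaelis_menten()` fits `v = vmax·S/(Km+S)` by
Levenberg–Marquardt with starting values `vmax0 = 1.5·max(v)` and `Km0`
= substrate concentration at half the maximum observed rate
(interpolated; median substrate as fallback). Convergence tolerances are
1e-12 on both parameter and objective change with a 200-iteration cap;
non-convergence raises an error carrying the starting values, and a
non-positive estimate flags the fit invalid rather than silently
reporting it.

## Derived quantities and rounding

`kcat = vmax/(E_total · active_fraction)` uses the active-site-titration
corrected enzyme concentration; the default preparation is 0.1 µM total
with active fraction 0.951 ± 0.143. Errors on kcat and kcat/Km propagate
in quadrature from the vmax/Km standard errors and the active-fraction
SD — a documented convention, since error propagation for these derived
quantities is rarely stated explicitly in assay reports.

Human-facing rounding in `mm_fit_report()` follows the conventions of
kinetics tables in this field: kcat to 2 decimal places, Km and
efficiency to 2 significant figures, with the efficiency computed from
the *rounded* kcat (that is how such tables are typically assembled; raw
unrounded values are always retained alongside). Note that published
efficiency values are not always self-consistent with their own rounded
kcat and Km — the package therefore never asserts against externally
printed efficiencies that cannot be reproduced from the printed inputs.

# Synthetic data

The generators emit the exact formats the analysis consumes (FASTA +
TSV, MGF, CSV) plus a JSON manifest, and every dataset ships a truth
table sufficient to score the downstream stage. Regeneration under a
fixed seed is byte-identical (fixed-precision writers, binary-mode
connections).

* **Proteomes** (`generate_proteome()`): uniform residue composition
  (chosen so background collision statistics are analytically
  checkable), with exact legacy windows, revised-only windows (the
  legacy C5 slot is forced non-cysteine), and near-misses (acceptor E/Q
  or aromatic W/L) planted at non-overlapping positions. Accidental
  background motifs are allowed and left for the oracle to count — the
  tests treat them as expected extra hits, not failures.
* **Spectra** (`simulate_msms_dataset()`): one hydroxylation per
  peptide, all singly charged b/y peaks, Gaussian ppm noise on m/z
  (default 2 ppm SD), per-peak dropout. Defaults: peptide lengths 8–16
  (tryptic range), 50 spectra.
* **Intensity pairs** (`simulate_lfq()`): lognormal total abundance
  split by the true occupancy, channel-wise lognormal noise
  parameterized by CV with mean 1 (so CV = 0 reproduces truth exactly).
* **Time courses** (`simulate_time_course_dataset()`): noiseless
  integrated-MM curves plus additive Gaussian noise on conversion,
  clipped to [0, 100].

What the generators do **not** emulate — and what passing tests
therefore do not demonstrate about real data: chimeric spectra and
coeluting peptides, isotope envelopes, retention time, intensity-
dependent peak detection, non-uniform proteome composition, enzyme
inactivation and cosubstrate depletion over long incubations, and
biological variation in occupancy between tissues.

# Problem sizes in the test suite

The suite runs the scanners against a brute-force window oracle on
1,000 random sequences of length up to 500; localization soundness on
150 spectra at 30 % dropout (plus 120 in the unit tests); occupancy
recovery on 200 pairs at CV 0.2; and Km recovery on 100 seeded
replicates at 5 % rate noise. These sizes give stable pass/fail behavior
for the stated properties while keeping the default run fast; the
generators scale to larger studies by argument.

# Known limitations

* The scanner reports sequence-level candidates; the presence of the
  motif does not imply hydroxylation in vivo (observed occupancies vary
  from none to complete), and disulfide connectivity is not predicted.
* Localization assumes one modification per peptide; multiply modified
  peptides are out of scope.
* The kinetics module ignores cosubstrate (2OG, Fe(II), ascorbate)
  consumption and enzyme inactivation, so simulated conversions at long
  incubation times overestimate real ones; only short-time behavior
  should be compared quantitatively.
* Occupancy compares ionization of a modified and an unmodified peptide
  and inherits the usual label-free caveat that their response factors
  are assumed equal.
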