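---
title: "Methods: label-free MS1 quantitation of cross-linked peptides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free MS1 quantitation of cross-linked peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkquant)
```

## The quantitation model

Cross-linking/mass spectrometry identifies pairs of protein residues
bridged by a reagent — here BS³, whose fully reacted spacer has the
elemental composition C₈H₁₀O₂ (138.068 Da) and spans Cα–Cα distances up
to roughly 30 Å. Label-free quantitation of the cross-linked peptides is
done at the MS1 level: for each identified precursor, the intensities of
its first three isotope peaks (M, M+1, M+2) are traced across the
chromatographic run, a peak is integrated, and the per-replicate areas
are compared.

The obstacle is representational: MS1-filtering machinery is built for
linear peptides. `linkquant` therefore converts every cross-linked
peptide pair into a mass-equivalent linear form before anything else
happens. The two peptides are concatenated with one extra lysine between
them, and that lysine carries a modification of

$$\Delta_{K\_xlink} = m_\text{spacer} - m_{K} + m_{H_2O} \approx 27.983\ \text{Da},$$

so the linear peptide's mass satisfies

$$m_\text{linear} = \Sigma m_\text{res}(\alpha) + \Sigma m_\text{res}(\beta)
  + m_K + \Delta_{K\_xlink} + m_{H_2O}
  = m_\alpha + m_\beta + m_\text{spacer} = m_\text{cross-linked}.$$

The identity holds algebraically, not approximately: the package derives
$\Delta_{K\_xlink}$ from the same residue table it sums peptides with, so
`verify_mass_equivalence()` returns essentially floating-point noise
(the residual ~3e-7 Da stems from the 5-decimal residue constants versus
the elemental water mass). The pipeline still asserts < 1e-4 Da on every
PSM as a guard against malformed modification bookkeeping.

**Assumptions.** Monoisotopic masses throughout (high-resolution Orbitrap
data); centroided MS1 spectra (profile mode is rejected); non-cleavable
cross-linker chemistry (the bridge survives into the precursor, so MS1
quantitation sees one species); charge states 3–7 as separate features
quantified independently.

### Canonical ordering and feature identity

A *cross-linking feature* — the quantitation unit — is the unique
combination of linearized modified sequence, charge state, and protein
linkage sites. Which peptide comes first in the linear sequence is not
chemically meaningful, so the package orders peptides lexicographically
(ties broken by the smaller link site). Any deterministic rule would do;
this one needs no external state, and it guarantees that the same
cross-link observed with swapped peptide roles in different runs
collapses onto one feature key.

Modification positions remap as follows: first-peptide positions are
unchanged (0 = linear N-terminus), second-peptide position $p$ maps to
$|\alpha| + 1 + p$, and a second-peptide *N-terminal* modification is
placed on that peptide's first residue — position 0 has no home in the
interior of a linear sequence. A collision (two modifications landing on
one position) is treated as malformed input and rejected rather than
silently merged.

## XIC extraction and peak integration

For each feature, the package extracts one trace per isotope: in every
MS1 spectrum, all centroids within ±0.055 m/z of the isotope position
$m/z_0 + k \cdot 1.003355/z$ are summed ($k = 0,1,2$). The defaults —
tolerance 0.055 m/z, three isotopes, instrument range m/z 400–1600 —
mirror the transition settings of the acquisition design the package
emulates. Precursors outside the instrument range are flagged
unquantifiable instead of raising an error, because one out-of-range
feature should not abort a batch.

Peak picking on the isotope-summed trace is deliberately deterministic,
replacing the interactive boundary curation that such workflows often
rely on:

- the trace is smoothed with a centered 5-point moving average *for the
  search only*; the raw trace is what gets integrated;
- the apex is the local maximum nearest the seed retention time within a
  ±2 min window, with candidates below 5% of the in-window maximum
  discarded (an isolated noise centroid forms a genuine local maximum,
  and "nearest" alone would let it outrank a real peak half a minute
  away);
- boundaries extend from the apex until the smoothed trace falls below
  1% of the apex height (`boundary_fraction = 0.01`) or rises again (a
  valley between partially resolved peaks);
- the area is the trapezoidal integral of the raw summed trace between
  the boundaries. With a 1% boundary threshold a Gaussian peak loses
  ~0.24% of its analytic area to truncation, comfortably inside the 1%
  recovery tolerance the tests enforce.

### Retention-time alignment and match-between-runs

Features picked in at least two runs anchor a robust linear fit
(`MASS::rlm`) of each run's apex times onto the reference run (the one
with the most anchors); runs with fewer than three shared anchors fall
back to the identity with a warning. A linear map is sufficient for the
synthetic validation worlds, whose RT distortions are shifts and jitter;
nonlinear warping is out of scope. For a run lacking an identification of
a feature, the seed is the median of the identified runs' apexes mapped
through the alignment — every feature thus yields one result per run,
possibly zero-area, which is what makes "quantified across all
replicates" a meaningful filter.

A feature counts as *quantified* in a run when its area exceeds the
run's noise floor (the median of the lowest decile of positive centroid
intensities) times its own peak width. An explicit rule is needed here
because the workflow has no manual review step to fall back on.

## Reproducibility statistics

CVs are computed as $100 \cdot s/\bar{x}$ with the sample ($n-1$)
standard deviation — the natural choice at $n = 10$ replicates. A residue
pair's CV is the *median* of its member-feature CVs (midpoint convention
for even counts); the package also reports means alongside, since the two
summaries differ under skew. Two filters precede the CV summary:

- **Co-elution**: a residue pair is removed when one of its features
  shares the unordered peptide-sequence pair and charge with a feature of
  a different residue pair and their integration boundaries overlap in
  any run. Such alternative linkage positions on the same peptides are
  isobaric; unless chromatography separates them, their XICs are the same
  trace and neither can be quantified independently. "Fully separated" is
  operationalized as zero overlap of [start, end] boundaries — no numeric
  margin, because the boundary rule already stops at 1% of apex.
- **Complete quantitation**: only pairs whose every member feature is
  above the noise floor in all runs are kept, so CVs are never computed
  over a mixture of real areas and missing-value stand-ins.

Saturation curves (mean unique pairs over all size-$k$ run subsets) are
computed exhaustively while $\binom{n}{k}$ is small (always true at
$n = 10$) and by seeded Monte Carlo above that. The observation-frequency
histogram and overlap counts are straightforward set partitions.
CV-versus-intensity binning uses unit-width bins of $\log_2$ median area
and reports per-bin median CVs, omitting empty bins.

## Structure validation

Cα coordinates come from standard PDB ATOM records (one chain, altloc
resolved by highest occupancy then file order). Pairs with a measured
distance ≥ 30 Å are removed, as are decoy matches; the threshold is the
theoretical BS³ limit. Pairs involving residues unresolved in the crystal
cannot be falsified and are **retained** (flagged with a missing
distance) — removing them would punish crystallographic disorder rather
than implausible chemistry. A sequence-to-structure numbering offset is
configurable (default 0), since UniProt and PDB numbering frequently
disagree. The random distance baseline draws unordered pairs of linkable
residues (K/S/T/Y and the N-terminus) uniformly, without replacement
within a draw and with replacement across draws.

Decoy FDR is reported as $100 \cdot d / N$ over unique matches, with both
counts attached: at 5 decoys among 242 pairs this is 2.07%. Published
workflows sometimes round or use $2d/N$-style estimators; the package
exposes the counts so any convention can be recomputed.

## The synthetic world

`simulate_truth()` defines the study conditions under which the package
validates itself; its defaults are the conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| replicate design | injection: CV 14%, RT jitter sd 0.1 min; reaction: CV 32%, jitter 0.3 min | the two replica-level noise regimes of label-free QCLMS (instrument-only versus full sample prep) |
| runs | 10 | standard replicate count for saturation/CV analysis |
| MS1 cycle | 3 s | typical Orbitrap MS1 cadence |
| gradient | 24 min | long enough for well-separated peaks at desk scale |
| peak σ | 0.1 min | ~10 points per peak at the 3 s cycle |
| charges | 3–5 drawn from the 3–7 window | keeps precursors inside m/z 400–1600 |
| base areas | log-uniform 10⁵–10⁷ | two decades of dynamic range |
| identification probability | 0.7 per run | exercises match-between-runs without starving alignment |

Between-replica noise is multiplicative log-normal with
$\sigma = \sqrt{\log(1 + \mathrm{cv}^2)}$, where the target CV is first
inflated by $1/c_4(n)$ so the *expected sample* CV of $n$ replicates hits
the target. Every world plants one pair of co-eluting alternative-linkage
variants (same peptides, same charge, same apex — isobaric and
inseparable by construction), one separated variant pair (4 min apart,
which the co-elution filter must retain), and one feature absent from one
run (which the complete-quantitation filter must catch). Toy structure
coordinates start uniform in a 22 Å sphere and each pair's free residue
is then placed at a controlled distance — 33–44 Å for the configured
violators, 8–22 Å otherwise — so the distance filter's removals are known
exactly. The isotope envelope uses a crude mass heuristic
(M+1/M ≈ 0.0005·mass, capped; M+2 analogous) that is deliberately
non-physical: quantitation sums the isotopes, so only the total matters.

What the generator does *not* emulate — chromatographic tailing, dynamic
exclusion, interference from unrelated co-eluting analytes, profile-mode
peak shapes, nonlinear RT distortion, intensity-dependent detector
effects — bounds what the passing tests show: they demonstrate that the
algorithms are correct against a controlled ground truth, not that the
defaults are optimal on any particular instrument's data.

## Problem sizes and numerical choices

The package's own validation runs use 52-pair, 10-replicate worlds for
CV parameter recovery and intensity-dependent CV anticorrelation, a
12-pair, 6-replicate world for filter exactness, and small noiseless
worlds for area-recovery and mzML round trips — sizes chosen so the whole
suite exercises every code path in about a minute on one core. Mass
comparisons use 1e-4 Da (linearization identity) and 1e-3 Da (printed
constants); area recovery uses 1% relative; recovered median pair CVs are
checked within ±5 percentage points of the generator targets, a band
that comfortably covers the sampling noise of a median over ~50 pairs of
10-replicate sample CVs.

Degenerate inputs are handled explicitly rather than by convention: CVs
over fewer than two values or a non-positive mean are undefined (NA with
a warning); an all-zero XIC yields a zero-area, unmatched peak result;
single-run alignment is the identity; empty intensity bins are omitted;
residue pairs are unordered-canonicalized everywhere so (i, j) and (j, i)
never diverge.

## Known limitations

- Quantitation is raw-area based; no between-run normalization is
  applied (CVs are computed on raw areas by design).
- The `.ssl` modification dialect (signed 5-decimal bracketed deltas) is
  self-consistent and round-trips bit-exactly, but is not guaranteed
  byte-identical to any other tool's rendering.
- Cleavable cross-linkers and MS2-based quantitation are out of scope;
  mono-links and loop-links are carried as modification masses but not
  quantified as separate species.
- RT alignment is linear; strongly nonlinear gradients would need
  warping that the package does not implement.
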