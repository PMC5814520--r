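# linkquant

Label-free MS1 quantitation of cross-linked peptides.

## The problem

Cross-linking/mass spectrometry (CLMS) converts spatial proximity of
protein residues into covalent bonds: an amine-reactive reagent such as
BS³ bridges lysine (and serine/threonine/tyrosine) side chains up to
roughly 30 Å apart (Cα–Cα), the protein is digested with trypsin, and the
linked peptide pairs are identified by LC-MS. Quantifying those
cross-linked peptides across replicates — label-free, from the MS1
precursor signal — is what turns CLMS into a probe of conformational
change. The catch is that mainstream MS1-filtering quantitation tools only
understand *linear* peptides.

`linkquant` implements a complete workflow around the linearization trick
that solves this: a cross-linked peptide pair (peptides α and β joined by
the BS³ spacer, composition C₈H₁₀O₂) is rewritten as the single linear
sequence

```
pepα + K + pepβ
```

where the inserted lysine carries a `K_xlink` modification of

```
Δ(K_xlink) = m(spacer) − m(K residue) + m(H₂O) ≈ 27.983 Da
```

so that the linear form's monoisotopic mass is *exactly* the mass of the
cross-linked species: inserted-K residue + Δ(K_xlink) − H₂O = spacer. Any
tool built for linear peptides — and this package's own XIC machinery —
can then quantify it.

Around that core the package provides:

- **Mass bookkeeping** (`peptide_mass`, `default_modifications`):
  monoisotopic residue masses, BS³ chemistry (mono-links BS3-OH
  +156.078 Da and BS3-NH2 +155.094 Da, loop-link +138.068 Da) derived
  from elemental compositions.
- **Linearization** (`to_linear_form`, `linearize_psms`): canonical,
  order-invariant linear forms with modification remapping and an
  asserted mass-equivalence check (< 1e-4 Da).
- **Spectral-library input** (`make_ssl`, `write_ssl`, `read_ssl`): the
  tab-separated `.ssl` spectrum sequence list (file, scan, charge,
  modified sequence, score-type, score), one record per PSM.
- **MS1 quantitation** (`extract_xic`, `pick_peak`, `align_rt`,
  `quantify_features`): per-isotope extracted ion chromatograms (M, M+1,
  M+2; ±0.055 m/z) from centroided mzML, deterministic peak picking with
  trapezoidal integration, robust RT alignment, and match-between-runs.
- **Reproducibility statistics** (`cv_percent`, `pair_cv_table`,
  `saturation_curve`, `observation_frequency`, `overlap_counts`,
  `cv_by_intensity_bins`): per-feature CVs (sample sd / mean), residue-pair
  CVs as the median of member-feature CVs, plus the co-elution and
  complete-quantitation filters.
- **Structure validation** (`load_ca_coords`, `distance_filter`,
  `random_distance_distribution`, `decoy_fdr`): Cα–Cα distances from PDB,
  removal of pairs at ≥ 30 Å and of decoy matches, a random-pair distance
  baseline.
- **Synthetic worlds** (`simulate_truth`, `simulate_runs`,
  `render_world`): fully specified replicate acquisitions with known
  ground truth, so the entire pipeline is testable without raw data.

## Worked example

Simulate an injection-replica experiment (20 residue pairs, 10 runs,
14% target CV) and run the full pipeline:

```r
library(linkquant)

truth <- simulate_truth(n_pairs = 20, n_runs = 10,
                        experiment = "injection", seed = 42)
runs  <- simulate_runs(truth)
pdb   <- tempfile(fileext = ".pdb"); write_toy_pdb(truth, pdb)

res <- run_pipeline(pipeline_config(truth$psms, runs, pdb = pdb,
                                    experiment = "injection", seed = 42))
summary(res)
```

```
Label-free cross-link quantitation result (injection)
  residue pairs: 23 identified -> 17 within distance limit -> 15 after co-elution filter -> 14 quantified in all runs
  median pair CV 13.7%  (mean 13.6%)
  decoy FDR: 13.04% (3 of 23 unique pairs)
  saturation: 11.9 pairs at k=1 -> 17.0 at k=10
```

Reading the output: 23 unique residue pairs were identified (20 targets
plus 3 decoy matches — the high decoy FDR is an artifact of the tiny
simulated search space). The distance filter removes the decoys and the
three pairs planted beyond 30 Å; the co-elution filter removes the two
planted alternative-linkage variants that share peptide sequences, charge
and retention time; one more pair is lost because one of its features is
absent from one run. The recovered median residue-pair CV of 13.7% sits
on the 14% noise level the generator injected. Per-pair detail lives in
`res$pair_cvs`:

```
  res_pair n_features median_area  pair_cv
1   18-211          1    514249.7 11.62059
2  298-461          1    167282.1 14.32760
3  298-464          1   2289558.3 15.38251
4   37-406          1    123307.7 16.87269
```

A thin command-line front end with `simulate`, `linearize`, `makelib`,
`validate-structure` and `run` subcommands is installed under
`inst/scripts/linkquant.R`.

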