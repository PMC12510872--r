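# msnforest

Automated generation of multi-stage fragmentation (MS^n) mass-spectral
libraries from pooled-compound flow-injection acquisitions — for
metabolomics and natural-product researchers who have plates of reference
compounds and want open, machine-readable spectral libraries out of them
with no manual spectrum curation.

Compound identification in untargeted LC–MS hinges on spectral library
matching, and open libraries cover only a sliver of known chemical space.
Pooling up to ten reference compounds per well and acquiring
data-dependent MS^n (MS^2–MS^5) trees for every well in both ion modes
makes library acquisition cheap; what remains is the data processing.
`msnforest` implements that processing end to end:

- **Metadata curation** — SMILES/InChI standardization (salt stripping,
  metal disconnection, neutralization, two passes), InChIKey/formula/
  monoisotopic-mass descriptors, rejects reporting, unique per-well sample
  identifiers, acquisition-sequence generation.
- **Scan ingestion** — mzML (via Bioconductor's `mzR`) and a JSON scan
  dialect for text-only fixtures; full precursor chains are reconstructed
  for MS^n scans.
- **MS^n tree building** — scans grouped into precursor-lineage forests;
  deeper scans attach only where the *entire* chain matches, so isobaric
  fragments cannot cross-link trees from different pooled compounds.
- **Sample-constrained annotation** — tree roots are matched against the
  compounds known to be in the injected well (found via the sample
  identifier embedded in the file name), as exact adduct masses:
  `m/z = (k·M + Δ) / |z|` with electron-mass-corrected deltas, within
  `max(0.005 Th, 10 ppm)`.
- **Quality control** — noise filtering (factor 2.5 on the scan noise
  floor, all MS levels), background-ion windows (m/z 149.72, 173.52
  ± 0.015), precursor isolation purity from the flanking MS^1 scans with
  isotope attribution and a 90 % chimera flag, minimum-two-signal export
  filter.
- **Spectral merging** — per-energy consensus (`SAME_ENERGY`),
  cross-energy merges (`ALL_ENERGIES`), and whole-tree pseudo-MS^2
  composites (`ALL_MSN_TO_PSEUDO_MS2`), via base-peak-normalized binning
  (0.005 Th, max aggregation).
- **Export and evaluation** — MGF / MSP / JSON libraries that round-trip
  exactly; weighted-cosine library search (`w = m/z^0 · I^0.5`, score
  ≥ 0.6, ≥ 4 matched signals); InChIKey-first-block overlap statistics
  (UpSet semantics); Tanimoto similarity on radius-2 circular
  fingerprints.
- **Simulation** — a synthetic DDA acquisition module emulating the whole
  schema (top-3 MS^2 at 20/60/assisted eV, top-5 MS^3, top-2 MS^4/MS^5,
  intensity gates, repeat triggers, isotopes, chimeras, background,
  noise) with ground truth, so the full pipeline is testable offline.

See the methods vignette (`vignettes/msn-library-generation.Rmd`) for the
model, parameter and design details.

## Worked example

Curate six pooled compounds (two wells), generate the acquisition
sequence, simulate the runs, and build the library:

```r
library(msnforest)

meta <- data.frame(
  name   = c("caffeine", "aspirin", "ibuprofen", "glucose", "alanine", "salicin"),
  smiles = c("Cn1cnc2c1c(=O)n(C)c(=O)n2C", "CC(=O)Oc1ccccc1C(=O)O",
             "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "OCC1OC(O)C(O)C(O)C1O",
             "C[C@@H](N)C(=O)O.Cl", "OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O"),
  library_code = "DEMO", plate = "1", well = rep(c("A1", "A2"), each = 3))

cur <- curate_compounds(meta)
cur$curated[, c("name", "formula", "monoisotopic_mass", "unique_sample_id")]
#>        name   formula monoisotopic_mass unique_sample_id
#> 1  caffeine C8H10N4O2         194.08038        DEMO_1_A1
#> 2   aspirin    C9H8O4         180.04226        DEMO_1_A1
#> 3 ibuprofen  C13H18O2         206.13068        DEMO_1_A1
#> 4   glucose   C6H12O6         180.06339        DEMO_1_A2
#> 5   alanine   C3H7NO2          89.04768        DEMO_1_A2
#> 6   salicin  C13H18O7         286.10525        DEMO_1_A2

seqd <- generate_sequence(unique_wells(cur$curated), "2026-05-01", "FIMSN")
seqd$filename
#> [1] "20260501_DEMO_1_A1_FIMSN_positive" "20260501_DEMO_1_A2_FIMSN_positive"
#> [3] "20260501_DEMO_1_A1_FIMSN_negative" "20260501_DEMO_1_A2_FIMSN_negative"

sim <- simulate_plate(sim_config(seed = 42), cur$curated, seqd, "scans")
res <- build_library(cur$curated, sim$files, "library")
res$report$files[, c("file", "n_scans", "n_trees", "n_annotated_roots", "n_entries")]
#>                                         file n_scans n_trees n_annotated_roots n_entries
#> 1 20260501_DEMO_1_A1_FIMSN_positive.scanjson     170       5                 5       197
#> 2 20260501_DEMO_1_A2_FIMSN_positive.scanjson     187       4                 4       224
#> 3 20260501_DEMO_1_A1_FIMSN_negative.scanjson     195       5                 5       233
#> 4 20260501_DEMO_1_A2_FIMSN_negative.scanjson     119       3                 3       143
```

Every injection yields a handful of annotated MS^2 roots (one per
compound-adduct ion above the intensity gates) and a few hundred library
entries — best scans, consensus and merged spectra for every node of every
tree. The report summarizes detection:

```r
round(res$report$coverage_pct, 1)
#> [1] 83.3     # 5 of 6 compounds; alanine's ions fall below the m/z 115 scan range
res$report$polarity_overlap$pattern_counts
#> positive&negative
#>                 5
```

Libraries land in `library/library_positive.mgf` (and `.msp`, `.json`,
plus the negative-mode files). A tree can be inspected as text:

```r
print(build_trees(read_scans(sim$files[1]))[[1]])
#> MS2 m/z 181.0500  [9 scans, energies 20/45/60]
#>   MS3 m/z 122.6560  [3 scans, energies 20/40/60]
#>     MS4 m/z 94.9959  [3 scans, energies 20/40/60]
#>     MS4 m/z 97.7223  [3 scans, energies 20/40/60]
#>   MS3 m/z 159.3316  [3 scans, energies 20/40/60]
#>   ...
```

(Simulated fragment m/z values are random mass losses — the simulator
exercises the pipeline's bookkeeping, not fragmentation chemistry.)

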