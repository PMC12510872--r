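---
title: "Automated MSn spectral library generation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated MSn spectral library generation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Compound annotation in untargeted mass spectrometry leans on spectral
library matching, and library coverage is the bottleneck. Multi-stage
fragmentation (MS^n^) — iteratively isolating product ions and fragmenting
them again (MS^2^ → MS^3^ → …) — yields spectral *trees* that carry far
more substructure information than a single MS^2^ spectrum, but open MS^n^
reference data are scarce. A practical way to build such libraries at scale
is to pool up to ten reference compounds per well, acquire flow-injection
data-dependent MS^n^ runs for every well in both ion modes, and then let
software do all of the downstream work. `msnforest` implements that
downstream pipeline end to end:

1. **Metadata curation** — structure standardization, salt stripping,
   descriptor computation, unique sample-identifier assignment and
   acquisition-sequence generation.
2. **Scan ingestion** — mzML (via `mzR`) and a JSON scan dialect
   ("scanjson") used for text-only fixtures and simulation.
3. **Tree building** — scans are assembled into precursor-lineage trees
   rooted at MS^2^ precursors.
4. **Sample-constrained annotation** — tree roots are matched against the
   *known composition of the injected well* using exact adduct masses;
   nothing is searched against an open database.
5. **Quality control** — denoising, background-ion removal, precursor
   isolation purity scoring, chimera flagging, minimum-signal filtering.
6. **Spectral merging** — per-energy consensus, cross-energy merges, and a
   pseudo-MS^2^ composite of each whole tree.
7. **Export and evaluation** — MGF/MSP/JSON library output, weighted-cosine
   library search, and InChIKey-based library-overlap (UpSet) statistics.

A synthetic acquisition module simulates the whole DDA schema so that every
stage is testable without any instrument data.

# Metadata curation

Input tables carry one row per compound with a structure (SMILES or InChI,
detected by the `InChI=` prefix) and the pooling position
(library/plate/well). Curation proceeds per record:

* **Salt/solvate stripping.** The canonical SMILES is split at top-level
  `.` disconnections and the largest fragment by heavy-atom count is kept.
  Ties go to the larger monoisotopic mass, then to the lexicographically
  smaller canonical SMILES, so output is deterministic.
* **Metal disconnection.** Covalently drawn alkali-metal salts (Li/Na/K
  bonded to neutral O or S, e.g. `CC(=O)O[Na]`) are split into their ionic
  form first, so the usual strip-and-neutralize pass can remove the
  counter-ion. This is the pinned subset of metal-disconnection rules; the
  common dotted salt notation never needs it.
* **Neutralization** via OpenBabel's charge-neutralization transform.
* **Two passes.** Strip + neutralize runs twice, because some salts only
  become separable after the first normalization.

The pipeline is idempotent: re-curating an already curated structure is a
no-op (tested property). Unparseable or descriptor-failing records are
diverted to a rejects table with reason codes (`empty_structure`,
`unparseable`, `descriptor_failure`) — reported, never silently dropped.

Descriptors per compound: canonical SMILES, isomeric SMILES (absent when no
stereocentre survives), InChI, InChIKey, molecular formula, monoisotopic
mass, and an atom-contribution logP (metadata only; never used in
matching). The monoisotopic mass is summed from most-abundant-isotope
atomic masses of the formula and is verified in the test suite against an
independent exact-mass oracle to 1e-4 Da.

Structure conversions run through the OpenBabel command line rather than
the in-process R binding, because the binding was found to discard
stereochemistry during SMILES parsing and to return corrupted InChI
strings; the batch converter tracks records by synthetic titles and retries
stragglers individually so one malformed structure cannot shadow the rest.

**Duplicate analysis** groups compounds either by the full 27-character
InChIKey (stereochemistry-aware) or by its first 14-character connectivity
block. Both counts are reported wherever coverage is summarized, since
sourcing statistics are usually quoted with stereochemistry and
cross-library overlaps without it.

**Sample identifiers** are `LIBRARY_PLATE_WELL`, upper-cased and
`_`-delimited. The acquisition sequence (per plate: all wells positive,
then all wells negative) embeds the identifier in every file name, and
annotation later recovers the well from the file name alone using
*delimiter-guarded* substring matching — the identifier must be bounded by
non-alphanumeric characters, so `P_1_A1` can never fire inside `P_1_A11`.
A file name matching two identifiers is a hard error.

# Tree building

All MS^≥2^ scans of one injection are grouped by precursor lineage:

* MS^2^ scans whose precursor m/z agree within `mz_tol` (default 0.01 Th —
  safely tight against isolation windows of ≥ 1.2 Th) form one root.
* Deeper scans attach to the node whose *full path* matches their complete
  precursor chain at every stage, not just the immediate precursor, so
  isobaric fragments at deeper levels cannot cross-link trees of different
  compounds in a 10-compound well.
* Scans with no matching parent become flagged single-node orphan trees;
  nothing is dropped (scan count is conserved — tested property).

Grouping is single-linkage on sorted m/z with a gap larger than the
tolerance starting a new group; this makes the forest invariant to scan
order (tested property). A node's representative m/z is the TIC-weighted
mean over member scans, which is stable under repeat triggers. Flow
injection means no chromatographic deconvolution: all scans of a file are
one "feature" per precursor, and retention time is provenance only.

# Annotation

For each candidate compound of the well and each polarity-matching adduct,
the expected ion m/z is

$$ m/z = \frac{k\,M + \Delta}{|z|} $$

with multimer count $k$, neutral monoisotopic mass $M$ and a signed mass
delta $\Delta$ that *includes the electron mass* (proton delta
1.007276 Da): at 10 ppm below m/z 200 the electron mass is larger than the
matching window. The default adduct set (editable CSV shipped with the
package) is [M+H]^+^, [M+Na]^+^, [M+NH~4~]^+^, [M+K]^+^, [2M+H]^+^ and the
in-source water loss [M+H−H~2~O]^+^ in positive mode; [M−H]^−^,
[M+HCOO]^−^, [M+Cl]^−^ and [2M−H]^−^ in negative mode.

A root is annotated when `|observed − expected| ≤ max(0.005 Th, 10 ppm)`
(the "0.005 or 10 ppm" convention, composed as the more permissive bound).
All matches are kept, ranked by absolute ppm error; isomeric candidates
yield multiple annotations flagged ambiguous. Cross-well leakage is
impossible by construction and verified by a contamination fixture.

# Quality control

* **Denoising.** Threshold = `noise_factor × noise_floor`, noise factor
  2.5 at every MS level. The noise floor is the scan's minimum raw peak
  intensity, *fixed when the scan record is constructed*. Thresholding
  against the stored floor (rather than re-deriving the minimum after each
  pass) makes denoising idempotent and lets it commute with background
  removal; on a raw scan the first application is identical to
  "2.5 × lowest signal". With a factor > 1 the minimal peak itself is
  always removed, and an all-equal-intensity scan empties completely —
  such spectra fail the two-signal filter anyway.
* **Background removal.** Exclusion windows (full width 0.03 Th) centred
  at the two reproducible background signals m/z 149.72 and 173.52,
  applied at every MS level; the window list is a CSV and can be extended
  from blank injections.
* **Precursor isolation purity.** For the MS^1^ scans immediately
  preceding and following an MS^2^ selection, purity is the fraction of
  ion current inside `precursor ± isolation_width/2` attributable to the
  precursor: the nearest peak within ±0.01 Th plus its isotope peaks at
  `+k·1.00335` Th (k = 1..3, charge-1 spacing, same tolerance). The final
  score is the mean over the available one or two MS^1^ scans
  (`ms1_scans_used` records which); entries under 90 % are flagged
  chimeric but still exported with their flag. The isotope treatment and
  the 90 % threshold are declared package decisions, configurable and
  surfaced in the output metadata.
* **Minimum-signal filter.** Only spectra with ≥ 2 peaks above the noise
  threshold are exported.

# Spectral merging

The merging primitive normalizes every source spectrum to base peak 100,
pools all peaks, and groups them greedily in ascending m/z (single linkage,
gap > 0.005 Th starts a new group — the same tolerance used by spectral
matching). A merged peak takes the intensity-weighted mean m/z and the
**maximum** normalized member intensity; max (rather than sum or mean,
both selectable) preserves fragments that are prominent at any single
collision energy, which is the point of multi-energy merges.

Per tree node the pipeline exports, where available:

* `SINGLE_BEST_SCAN` — highest-TIC scan per collision energy (TIC ties go
  to the earlier scan number);
* `SAME_ENERGY` — consensus over repeat triggers of one energy (requires
  ≥ 2 scans; exactly one distinct energy is listed);
* `ALL_ENERGIES` — merge across energies, using the same-energy consensus
  when present, else the best scan;
* `ALL_MSN_TO_PSEUDO_MS2` (root only) — the union of the all-energies
  spectra of every node in the subtree, after trimming each node's
  residual precursor signal (everything at and above the node's own
  precursor m/z), so the composite is a pure fragment spectrum recorded at
  MS level 2. Intensities are *not* re-weighted by tree level; the
  composite is checked against a brute-force union-and-re-bin oracle in
  the tests.

# Matching and overlap

Library search restricts candidates by precursor agreement
(`max(0.005 Th, 10 ppm)`), removes precursor signals from both sides,
scores with a weighted cosine ($w = m/z^0 \cdot I^{0.5}$, square-root
intensity weighting), and keeps hits with score ≥ 0.6 and ≥ 4 matched
signals, ranked by score with configurable top-k (optionally deduplicated
by compound before ranking — both behaviors are exposed). Peaks are paired
greedily by ascending |Δm/z| with ties to the larger intensity product,
each peak used once. Greedy pairing can in principle fall short of the
optimal assignment; the tests compare it against an exhaustive-assignment
oracle on 1,000 random ≤ 6-peak pairs built as jittered shared peaks plus
independent extras (the ambiguity structure of real matched spectra) and
require equality in ≥ 95 % of trials and never a greedy score above the
optimum — an adversarially dense variant checks the bound alone.

Library overlap reduces InChIKeys to their first block and counts every
non-empty source-membership pattern (UpSet semantics); pattern counts must
sum to the union size (tested). Structure similarity uses the Tanimoto
coefficient on circular (extended-connectivity, radius 2) fingerprints
folded to 2048 bits.

# The simulator

`simulate_well()` emulates the acquisition schema: survey MS^1^ scans with
compound adduct ions (per-adduct ionization probabilities), isotope
envelopes (M+1 at 5–30 %, M+2 at 0–10 % — enough to exercise purity
attribution), lognormal noise, the two background ions, and optional
chimeric contaminants injected into isolation windows. DDA selection takes
the top-3 eligible precursors per cycle above the minimum-intensity gates
(6×10^5^/2×10^5^ for MS^2^ in positive/negative, 2×10^4^/1×10^4^ deeper),
fragments each at 20/60 eV plus a per-precursor "assisted" energy drawn
from 15–75 eV in 15 eV steps (represented as a plain numeric energy; no
assisted-energy optimization logic is simulated), and retriggers each
precursor three times before dynamic exclusion. From the assisted MS^2^
scan the top-5 signals (m/z ≥ 90) seed MS^3^ at 20/40/60 eV; the 40 eV
scan seeds top-2 MS^4^; the 40 eV MS^4^ seeds top-2 MS^5^ at 40/60 eV with
fragments above m/z 150. Isolation widths are 1.2/2/2.2/3 Th for
MS^2^–MS^5^. Deeper stages are triggered once per precursor tree to keep
desk-scale runs tractable.

Fragment m/z values are random mass losses (always below the precursor,
within the scanned range) — deliberately *not* chemically realistic
fragmentation. That is sufficient to exercise tree assembly, merging,
matching and annotation, and it is the simulator's main limitation:
passing tests demonstrate the pipeline's bookkeeping and numerics on
realistic scan *structure*, not annotation performance on real
fragmentation chemistry. Observed m/z values carry 1 ppm mass error; a
ground-truth table lists every (compound, adduct) tree actually emitted,
which is the denominator for recovery statistics.

# Problem sizes and numerical choices

The validation harness (`simulation_recovery()`, also used by
`scripts/acceptance.R`) runs 2 plates × 4 wells × 10 compounds in both
polarities — 16 injection files, roughly 10,000 scans — and requires
≥ 95 % recovery of emitted (compound, adduct) pairs with zero cross-well
leakage; these sizes keep a full run in the low minutes on one CPU while
still covering every pipeline stage at realistic per-file scan counts.
Other fixed choices: chain-matching tolerance 0.01 Th; binning/matching
tolerance 0.005 Th; all tie-breaks deterministic (documented above), so
identical inputs give identical libraries; scan files and libraries are
written with 17 significant digits so write→read round-trips are exact.

# Known limitations

* No LC feature detection or cross-sample alignment; flow injection only.
* No vendor raw-file reading (convert to mzML first) and no profile-mode
  centroiding; the mzML writer emits the minimal subset the reader needs.
* OpenBabel canonicalization, InChI generation and ECFP4-folded
  fingerprints differ bit-for-bit from other toolkits (e.g. different
  canonical SMILES strings); all within-package comparisons are
  self-consistent.
* External database enrichment (drug/natural-product lookups) is a no-op
  hook: the curation interface accepts an enrichment function but ships
  none, and no network access is ever required.
* Chimeric spectra are flagged and exported, never deconvolved.
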