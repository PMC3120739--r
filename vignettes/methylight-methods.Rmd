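---
title: "Methods: bisulfite modelling, assay validation and MethyLight quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bisulfite modelling, assay validation and MethyLight quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylightr)
```

This vignette documents the models implemented in `methylightr`, the
conventions the package commits to where the underlying biology or common
laboratory practice leaves room for interpretation, and the design and
limits of the synthetic data generators used throughout the test suite.

## 1. The bisulfite conversion model

Sodium bisulfite deaminates cytosine to uracil, which amplifies and
sequences as thymine; 5-methylcytosine is resistant. In mammalian DNA,
methylation occurs essentially only at CpG dinucleotides, so the package
models conversion as a deterministic map with two idealized assumptions:

* **unmethylated**: every `C` becomes `T`;
* **methylated**: `C` immediately followed by `G` is retained, every other
  `C` becomes `T`.

Both maps are idempotent (a converted sequence contains no convertible
cytosine that would change again), a property the test suite checks on
random sequences.

Because conversion acts on single strands and the two strands of a CpG are
each methylatable independently, one double-stranded region yields four
templates: `{sense, antisense} x {methylated, unmethylated}`. The antisense
template is the conversion of the reverse complement of the given sequence.
After conversion the strands are no longer complementary wherever the
original sequence had a non-CpG cytosine on either strand — the basis for
strand-specific assay design — and the test suite verifies this
non-complementarity property directly.

**Terminal cytosine.** A `C` at the 3' end of a sequence has no following
base, so its CpG status is undecidable from the sequence alone. The package
treats it as non-CpG (it converts under both assumptions) and emits a
warning, because silently guessing "CpG" would fabricate a retained
cytosine. Callers working with windows clipped out of a larger region
should extend the window by one base instead.

## 2. Coordinates: TSS-relative numbering

Amplicon positions are given relative to the transcription start site in
the convention universal in promoter biology: `+1` is the first transcribed
base, `-1` the base immediately upstream, and **there is no position 0**.
`tss_to_offset()` rejects 0 with an error rather than silently shifting.

Internally the package linearizes a TSS coordinate `t` to
`t' = t` for `t > 0` and `t' = t + 1` for `t < 0`, which makes interval
lengths the ordinary inclusive difference `end' - start' + 1`. Under this
arithmetic the classic-assay coordinates `(+238, +307)` span 70 bp and the
MSP region `(+133, +283)` spans 151 bp, matching their conventional
descriptions. The novel assay's coordinates `(+157, +272)` compute to
**116 bp inclusive**, although that assay is conventionally called
"115-bp". The discrepancy is one base and could reflect an exclusive
endpoint, an off-by-one in the reported coordinates, or a naming rounded
from a draft design; the sequence data needed to adjudicate is not
available, so the package does not pick a side: `amplicon_interval()`
reports the computed inclusive length, `assay()` carries a separate
`nominal_length`, and printing shows the computed value.

Within the package all string indices are **1-based inclusive**, the native
R convention. Worked positions in external descriptions of string
algorithms are often 0-based; the package deliberately does not mix
conventions, and every exported function documents its indexing.

`interval_overlap()` is strand-agnostic: it compares genomic footprints,
which is the quantity of interest when asking whether two assays
interrogate the same stretch of the island.

## 3. The oligo annotation dialect

Published MethyLight primer/probe sequences are commonly written in a
mixed-case dialect: lowercase for bases whose identity is fixed after
conversion, uppercase `C`/`G` for bases **derived from a CpG cytosine**,
i.e. the positions that discriminate methylated from unmethylated template.
`parse_oligo()` accepts this dialect directly (as well as an explicit index
vector for plain-case sequences), strips typographic decoration (spaces,
digits, brackets, primes), and records the discriminating positions.

A subtlety the package handles explicitly: a marked base is not always the
base that physically faces the template's methylatable cytosine.

* A reverse primer is written 5'→3' on the opposite strand and is searched
  as its reverse complement on the template. A marked `C` in the written
  sequence whose next base is `g` denotes a CpG whose *G partner* — after
  reverse complementing — pairs with the template's retained `C`. The
  sensitive position is therefore the partner base, not the marked one.
* A probe annealing in the reverse-complement orientation behaves the same
  way; a probe annealing as-is uses its marked positions directly
  (a marked `G` preceded by `c` maps to that `c`).

`locate_oligo()` normalizes marked positions to the template-facing
sensitive base for whichever orientation a hit is found in, so
`mismatch_at_cpg` counts real discriminating mismatches.

**Probe orientation.** TaqMan probes may be synthesized against either
strand of the amplicon. Some published probe sequences (including the
classic-assay probe shipped in `inst/extdata/assays.yml`) contain
unconverted non-CpG cytosines when read as-is, which is only consistent
with annealing to the *opposite* strand of the PCR product. The package
therefore searches probes in **both** orientations by default
(`search: auto`) and keeps the better hit; forward primers default to
as-is, reverse primers to reverse-complement, and any oligo can override
via `search:` in the assay YAML.

**Amplicon extent** runs from the forward primer's 5' base to the position
the reverse primer's 5' base maps to — the outermost coordinates of the
product. A probe that is not strictly inside the primers triggers a
warning, not an error, because overlap with a primer is a design smell
rather than an impossibility.

`specificity_report()` classifies an assay against the four templates:

* **methylation-specific** — perfect match on the methylated target-strand
  template, and on the unmethylated template every oligo either fails to
  hit or mismatches at exactly its discriminating positions;
* **methylation-neutral** — identical perfect hits on both assumptions
  (expected for the CpG-free reference assay);
* **not-specific** — anything else.

## 4. Clone sequencing QC

Bisulfite cloning-sequencing validates both the methylation status of a
sample and the completeness of conversion. `score_clone()` compares a clone
read to the *unconverted* reference positionally (gap-free; reads with
indels are rejected with an error, since placing gaps is an alignment
problem out of scope here) and classifies each reference cytosine:

* CpG cytosine read as `C` → **retained** (methylation signal);
* CpG cytosine read as `T` → converted (unmethylated at that site);
* non-CpG cytosine read as `T` → **converted** (bisulfite worked);
* non-CpG cytosine read as `C` → unconverted (incomplete treatment).

`aggregate_clones()` pools raw counts across clones — percentages of
per-clone percentages would weight clones unequally if lengths ever
differed, and pooled counts match how such results are conventionally
reported — and expresses retention and conversion as percentages rounded
**half-up to one decimal** (`round_half_up()`), the rounding used in
laboratory reporting; R's default banker's rounding would turn
223/224 = 99.55% into 99.5 rather than the conventional 99.6.

`call_sample()` applies thresholds: retention ≥ 90% → "fully-methylated",
≤ 10% → "unmethylated", otherwise "partially-methylated"; pooled non-CpG
conversion below 70% flags the sample for incomplete conversion but does
not suppress the call — flagging is reversible downstream, exclusion is
not.

## 5. Quantification: relative copy number

Duplicate wells are averaged on the Ct scale (Ct is already logarithmic;
averaging linearized quantities would answer a different question), with a
flag when replicate spread exceeds 1.5 cycles. With amplification
efficiency `E` (default 2, perfect doubling):

`RCN = E^-(Ct_target - Ct_reference)`

A not-detected target well is parsed from the literal `ND` into an explicit
missing state; a sample whose target replicates are all ND quantifies as
RCN 0 with an `all-replicates-not-detected` flag — "no methylated copies
observed" is a measurement, not missing data. Results are standardized to
the fully methylated positive control so it reads exactly 1.0. A batch is
rejected when the unmethylated negative control shows target amplification
earlier than `max_cycles - margin` (default 45 − 5 = 40) or when the
positive control fails, because either invalidates every RCN in the run.

## 6. Diagnostic calibration

The decision rule is `score >= cutoff ⇒ test-positive`. `roc_points()`
evaluates the rule at the midpoints between consecutive distinct scores
plus the boundary cutoffs 0 and ∞, which covers every achievable
(sensitivity, specificity) pair without tying behaviour to the accidental
score values. Properties the implementation commits to:

* trapezoidal AUC equals the Mann–Whitney probability that a random
  positive outscores a random negative, ties counted ½ (verified against
  an independent pairwise computation and against `pROC` in the test
  suite);
* the operating cutoff maximizes the Youden index
  `J = sensitivity + specificity - 1`, with ties broken toward higher
  specificity and then higher cutoff (prefer the more conservative test
  when the data cannot distinguish);
* **accuracy** is reported as the Youden index itself. This matches the
  published accuracy figures the package reproduces (70.5% sensitivity and
  84.5% specificity reported with 55.0% accuracy is only consistent with
  `sens + spec - 1`, not with the proportion-correct definition).

For 2×2 association, tables are oriented gold-standard status by rows and
test result by columns (`a` = true positive, `d` = true negative). The
odds ratio is `ad/bc` with a Woolf log-normal confidence interval, adding
the Haldane–Anscombe 0.5 correction to every cell only when a zero cell
makes the estimate degenerate. The association p-value uses Pearson's
chi-square *without* continuity correction when **all expected counts
exceed 5** (strictly), otherwise the two-sided Fisher exact test. The
strict inequality is a deliberate choice: at an expected count of exactly
5 the chi-square approximation is marginal, and the exact test is always
valid, so the boundary goes to Fisher.

## 7. Synthetic data generators

The package cannot ship patient data, so `fixture_spec()` defines a seeded
generative model whose defaults are the package's study conditions and are
**never tuned against test outcomes**.

* `simulate_island()` builds a CpG-island-like region of length
  `island_length` (default 175) by filling non-overlapping dinucleotide
  slots: each slot is `CG` with probability `cpg_density` (default 0.16,
  in the range typical of CpG islands) and otherwise a random non-`CG`
  pair, with cross-boundary `CG`s rejected so the CpG count is exactly
  Binomial(L/2, density) and every CpG is a deliberate one.
* `simulate_clones()` converts the island per-site and per-clone: each CpG
  cytosine is retained with `retention_prob` (default 0.99, a heavily
  methylated sample) and each non-CpG cytosine converts with
  `conversion_efficiency` (default 0.95). Independence across sites is a
  simplification — real methylation is spatially correlated along a
  molecule — so the generator is suitable for testing estimator
  calibration, not for simulating epigenomic structure.
* `simulate_ct_table()` emits a duplicate-well Ct table for `n_pos`
  methylation-positive and `n_neg` negative samples, a fully methylated
  control (ΔCt 0) and an unmethylated control (target not detected).
  Positives sit `pos_delta_ct` (default 2) cycles above the reference
  baseline; negatives are ND by default or shifted by `delta_ct_shift`.
  Gaussian Ct noise (`ct_noise_sd`, default 0.3 cycles, typical
  well-to-well qPCR precision) is the only noise source; inhibitors,
  pipetting dropouts and efficiency drift are out of scope.
* `build_assay_fixture()` "deconverts" an assay back into a plausible
  genomic region: the normalized oligo sequences are embedded (forward
  site, probe site in whichever orientation makes all of its cytosines
  CpG, reverse-complemented reverse site) with spacers drawn from
  `{A, T, C}` that never end in `C`, so no junction CpGs are created and
  the spacers salt the region with conversion-sensitive non-CpG
  cytosines. By construction the methylated sense template contains the
  oligo sites exactly, which is what makes the shipped published assays
  testable end to end without the real promoter sequence.

Sub-seeds for the island, clones, Ct table and fixture are derived from the
user seed by a fixed affine map modulo a large prime, so the artifacts are
independently reproducible and byte-identical across runs (verified in the
suite). Problem sizes used in the tests (e.g. 16 clones, 20+20 samples, a
50-clone grid for parameter recovery) are the package's own choices sized
so that binomial standard errors make the assertions sharp.

## 8. Known limitations

* Conversion is deterministic and complete; partial conversion is modelled
  only in the clone generator, not in the template model.
* Non-CpG methylation (CHG/CHH), relevant in plants and some stem cells,
  is not modelled.
* Oligo placement uses exact string matching with a mismatch count, not a
  thermodynamic model; melting temperature and secondary structure are out
  of scope.
* Clone scoring is positional; reads must be pre-aligned and gap-free.
* The ROC machinery assumes a binary gold standard and a scalar score.
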