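# methylightr

In-silico bisulfite conversion, MethyLight assay validation and DNA
methylation quantification in R.

## The problem

Aberrant methylation of the *p16* (*CDKN2A*) CpG island is an early event in
carcinogenesis and a candidate biomarker for predicting malignant
transformation of epithelial dysplasia. MethyLight — real-time quantitative
methylation-specific PCR (MSP) with a TaqMan probe — detects methylated
templates in bisulfite-treated DNA and quantifies them against a CpG-free
reference gene (*COL2A1*). Designing and validating such assays is an
exercise in sequence arithmetic on *converted* DNA: bisulfite treatment
deaminates unmethylated cytosine to uracil (read as thymine after PCR) while
5-methylcytosine at CpG sites is retained, so one double-stranded region
becomes **four** possible single-stranded templates ({sense, antisense} ×
{methylated, unmethylated}) that are no longer complementary (C≡G → U/T≠G).

`methylightr` is for molecular epidemiologists and assay designers who need
to:

* model the four bisulfite templates of a region and check
  primer/probe designs for methylation specificity against all of them;
* do amplicon coordinate arithmetic in transcription-start-site (TSS)
  relative numbering (+1 is the first transcribed base, there is no 0) and
  quantify amplicon overlaps between assays;
* QC bisulfite clone sequencing: CpG retention (methylation signal) and
  non-CpG conversion (bisulfite efficiency), pooled across clones;
* turn replicate qPCR Ct tables into standardized relative copy numbers
  (RCN) and calibrate an RCN cutoff against a gold standard.

## The model in brief

**Conversion.** For a strand *s*, under the unmethylated assumption every
C → T; under the methylated assumption C at CpG sites is retained and every
other C → T. Antisense templates convert the reverse complement.

**Quantification.** With duplicate wells averaged on the Ct scale,

RCN = 2^(−ΔCt), ΔCt = Ct(methylated target) − Ct(reference gene),

standardized to the fully methylated positive control (RKO-type), so the
control reads exactly 1. A not-detected target is an explicit state that
quantifies as RCN 0 with a flag. A run is rejected when the negative control
amplifies the methylation target early or the positive control fails.

**Calibration.** With the rule *score ≥ cutoff ⇒ test-positive*, the ROC
curve is enumerated over all distinct thresholds; AUC is the trapezoidal
area (equal to the Mann–Whitney probability, ties counted half); the
operating cutoff maximizes the Youden index, and

accuracy = sensitivity + specificity − 1.

2×2 association is summarized by the odds ratio (a·d)/(b·c) with a Woolf
log-normal confidence interval, and a chi-square (all expected counts > 5)
or Fisher exact two-sided p-value.

## Worked example

The package ships the three published assays (70-bp classic, 115-bp novel,
COL2A1 reference) in `inst/extdata/assays.yml` with their printed oligo
annotation (uppercase = CpG-derived discriminating base):

```r
library(methylightr)
assays <- read_assays(system.file("extdata", "assays.yml", package = "methylightr"))
a115 <- assays[["ML-115bp-novel"]]
print(a115)
#> <assay> ML-115bp-novel (sense strand)
#> <oligo> ML-Primer-F2 [forward] 20 nt, 3 discriminating CpG base(s)
#> <oligo> ML-Primer-R2 [reverse] 20 nt, 4 discriminating CpG base(s)
#> <oligo> ML-Probe-2 [probe] 20 nt, 3 discriminating CpG base(s)

# place it on the four bisulfite templates of a synthetic fixture region
fx  <- build_assay_fixture(a115, seed = 7)
specificity_report(a115, bisulfite_templates(fx))$verdict
#> [1] "methylation-specific"

# published TSS-relative coordinates: lengths and overlaps
print(amplicon_interval(157, 272, "sense"))
#> <amplicon_interval> +157 ~ +272 (sense strand, 116 bp)
interval_overlap(amplicon_interval(157, 272), amplicon_interval(133, 283))
#> [1] 116    # the novel amplicon is fully contained in the MSP amplicon
interval_overlap(amplicon_interval(238, 307), amplicon_interval(133, 283))
#> [1] 46     # the classic amplicon only partially overlaps it
```

(The +157 ~ +272 interval computes to 116 bp inclusive although the assay is
conventionally named "115-bp"; the package reports both the computed and the
nominal length.)

Quantification and calibration on a seeded synthetic batch:

```r
spec <- fixture_spec(seed = 11, n_pos = 20, n_neg = 20)
sim  <- simulate_ct_table(spec)
res  <- quantify_batch(sim$wells, target = "p16M",
                       positive_id = sim$positive_id,
                       negative_id = sim$negative_id)
merged <- merge(res, sim$labels, by = "sample_id")
roc  <- roc_points(merged$rcn_standardized, merged$label)
best <- youden_cutoff(roc)
c(auc = auc_trapezoid(roc), best$accuracy)
#> AUC 1.000; cutoff 0.1141; sens 1.00; spec 1.00; accuracy 1.00

accuracy_youden(0.705, 0.845)
#> [1] 0.55
odds_ratio_ci(contingency_2x2(6, 2, 6, 16))$or
#> [1] 8
```

A command-line interface covering the same workflow (subcommands `convert`,
`design-check`, `clone-qc`, `quantify`, `roc`, `simulate`) is installed as
`exec/methylightr`.

## Documentation

See the methods vignette (`vignettes/methylight-methods.Rmd`) for the
models, conventions (coordinate system, oligo annotation dialect, rounding),
generator design, and known limitations.
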