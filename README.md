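# itcombine

Intersect-then-combine (ITC) post-processing and benchmarking of somatic
SNV/indel calls from tumour–normal sequencing.

## What it does, and for whom

Somatic callers disagree — with each other, and with themselves when the
reads are aligned by a different pipeline. Pipeline-specific alignment
artifacts dominate the false positives, while the two callers' missed calls
are largely complementary. `itcombine` is for analysts who run **two
alignment pipelines** (e.g. BWA/GATK and Novoalign-based) and **two somatic
callers** (Mutect2 from GATK 3.5, Strelka v1) on a tumour–normal pair and
want a principled way to merge the four call sets:

1. **Filter** each caller's VCF with tuned admission rules — notably
   re-admitting Mutect2 `alt_allele_in_normal` failures when the normal alt
   fraction is ≤ 7% *and* the tumour/normal VAF ratio exceeds 5
   (T/N = VAF_T / VAF_N), and taking Strelka tier 1+2 calls with
   QSS_NT > 25 (SNV) / QSI_NT > 35 (indel).
2. **Intersect** each caller's calls across the two aligners (matching on
   normalized `chrom:pos:ref:alt` keys, with left-alignment so divergent
   indel spellings still match).
3. **Combine**: union the two per-caller intersections.

A benchmarking engine scores any call set against a truth set restricted to
confident regions:

    Sens = TP / (TP + FN)        FPR/Mb = FP / n_ref × 10⁶

where `n_ref` is the confident-∩-target region size after subtracting truth
loci. A synthetic dilution-series generator (mini reference with repeat
runs, binomial allele sampling across a 100% → 0.2% purity series,
pipeline-specific vs shared false positives, caller-dialect VCF output,
jittered indel representations) makes the whole workflow testable with no
sequencing data.

## Worked example

Simulate a small study, run the ITC workflow per dilution point, and
benchmark (also available as `itc simulate|filter|combine|benchmark`
subcommands via `itc_cli()` / `inst/scripts/itc`):

```r
library(itcombine)

cfg <- sim_config(genome_length = 50000L, n_snv = 120L, n_indel = 30L,
                  purities = c(1, 0.4, 0.1, 0.02), seed = 7L)
simulate_study(cfg, "demo")

ref <- "demo/reference.fa"
sets <- lapply(cfg$purities, function(p) {
  pd <- sprintf("demo/purity_%g", 100 * p)
  run_combine(file.path(pd, "mutect2_bwa.vcf"),
              file.path(pd, "mutect2_novoalign.vcf"),
              file.path(pd, "strelka_snv_bwa.vcf"),
              file.path(pd, "strelka_snv_novoalign.vcf"),
              vclass = "SNV", out = file.path(pd, "itc_snv.vcf"),
              reference = ref)
})
truth <- truth_set(read_truth_variants("demo/truth.tsv"),
                   confident = "demo/confident.bed",
                   target = "demo/target.bed", reference = ref)
evaluate_dilution_series(sets, cfg$purities, truth)
```

which prints:

```
       label purity  tp fp  fn unclassified sensitivity fpr_per_mb
1 purity_100   1.00 119  1   1            0       0.992         NA
2  purity_40   0.40 115  0   5            0       0.958         NA
3  purity_10   0.10  84  2  36            0       0.700         NA
4   purity_2   0.02   6  2 114            0       0.050       58.4
```

One row per dilution point: sensitivity falls as tumour DNA is diluted
(expected het VAF = purity/2, so at 2% purity most variants sit below the
3-alt-read detection floor), and FPR/Mb is reported only for the most
diluted sample — in the concentrated samples apparent "false positives"
are dominated by genuine private mutations, so the rate is withheld there.
`run_benchmark()` on the pure sample adds the FN breakdown
(low-coverage / allele-dropout / other) from a pileup table and prints

```
BenchmarkResult<SNV>: TP=119 FP=1 FN=1 unclassified=0 | Sens=99.2% FPR/Mb=29.197 (n_ref=34250 bp)
```

`overlap_stats()` and `three_way()` expose the cross-aligner and
cross-caller count partitions (with percentages computed as
`100·x_only/(x_only+shared)`, one decimal, half-up) that the combine step
also writes to its `--stats-out` TSV.

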