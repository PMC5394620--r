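---
title: "Intersect-then-combine somatic call filtering: model, parameters and design"
author: "itcombine authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intersect-then-combine somatic call filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Somatic SNV and indel calling from tumour–normal pairs is dominated by two
error sources that behave differently: alignment artifacts, which are largely
specific to the alignment pipeline that produced them, and caller-model
errors, which are largely specific to the caller. `itcombine` implements a
post-processing strategy that exploits this asymmetry: run two alignment
pipelines (e.g. BWA/GATK and Novoalign-based) and two somatic callers
(Mutect2 as shipped with GATK 3.5, Strelka v1), then

1. **filter** each caller's output with tuned admission rules,
2. **intersect** each caller's calls across the two aligners — a call must
   survive both alignments, which removes most pipeline-specific false
   positives at a small sensitivity cost, and
3. **combine** (union) the two per-caller intersections — the callers
   disagree mostly on complementary true positives, so the union recovers
   sensitivity while the FP rate stays low.

Performance is reported as sensitivity and false positives per megabase,

$$\mathrm{Sens} = \frac{TP}{TP+FN}, \qquad
  \mathrm{FPR/Mb} = \frac{FP}{n_{\mathrm{ref}}} \times 10^{6},$$

where $n_{\mathrm{ref}}$ is the size of the *reference regions*: confident
(known homozygous-reference or known-variant) intervals intersected with the
capture target, with every truth-variant footprint subtracted. A call is a
TP if it matches a truth variant on (chrom, pos, ref, alt) after
normalization, an FP if it lies inside the reference regions, and
*unclassified* (ignored) outside them, where the truth is unknown.

## Admission rules

Two policies are built in. All score comparisons are strict (`>`); the
normal-allele-fraction bound is inclusive ("up to 7%").

| parameter | default mode | optimized mode | meaning |
|---|---|---|---|
| rescue_filters | clustered_events, homologous_mapping_event | same | Mutect2 internal filters forgiven outright (germline variants cluster) |
| max_normal_af | — | 0.07 | max alt fraction in the normal for re-admitted `alt_allele_in_normal` failures |
| min_tn_ratio | — | 5 | tumour VAF / normal VAF must exceed this |
| tlod_min | 6.3 | 6.3 | Mutect2 TLOD gate, applied only when a TLOD is present |
| qss_nt_min | 15 | 25 | Strelka SNV score cut-off |
| qsi_nt_min | 30 | 35 | Strelka indel score cut-off |
| include_tier2 | no | yes | tier-2 alt support may rescue a record with no tier-1 alt reads |

The **T/N ratio** `tn_ratio(t, n) = t/n` is made total by convention:
`+Inf` when the normal VAF is zero and the tumour VAF positive (passes any
finite threshold), `0` when the tumour VAF is zero. It guards the relaxed
normal-allele bound against admitting germline variants: a germline het
leaks into both samples at similar VAF (ratio near 1), while a genuine
somatic variant with a trace of normal contamination shows a high ratio.

Design choices where the published description left room:

* The T/N rule is applied **uniformly to every Mutect2 candidate**, not only
  to re-admitted `alt_allele_in_normal` failures; `tn_ratio_all = FALSE`
  selects the narrower reading.
* Records failing internal filters other than the forgiven set stay
  rejected in every mode — the optimized rule *replaces* the caller's
  internal normal-allele criterion, it does not bypass the rest.
* Strelka's optimized mode still requires the internal filters to pass;
  "tier 2" only changes which read counts may establish alt support. This
  is also what makes the default policy a special case of the optimized one
  (cut-off 15, tier 2 off), a property the test suite asserts.
* The TLOD gate uses `>=` and is skipped when no TLOD value is present,
  since merged or foreign records may lack one.
* An optional proximity filter (off by default; window 100 bp, 2
  neighbours) removes clusters of nearby calls, a known artifact signature.
  The parameters are package choices; no published values exist.

## Variant matching and normalization

Matching is by exact (chrom, pos, ref, alt) keys. Around repetitive
sequence the same indel admits several spellings (an insertion can be
anchored at either end of a repeat run, or padded with shared flanking
bases), and different callers genuinely emit different spellings. When a
reference is supplied, every record is canonicalized first: shared terminal
bases are trimmed (extending left from the reference when an allele
empties) and the result is left-shifted until minimal — the classic
left-alignment loop. The operation is idempotent and haplotype-preserving,
and the test suite checks it against a brute-force oracle that enumerates
all equivalent representations of random indels on a repeat-rich toy
genome. Without a reference, matching degrades to exact equality and a
warning is emitted once. MNVs are matched atomically; multiallelic caller
records are decomposed into biallelic records, while multiallelic *truth*
rows are rejected (they are excluded from evaluation).

Coordinates are 1-based for variants (VCF) and 0-based half-open for
regions (BED); conversion happens only at I/O boundaries. A call is
assigned to regions by its 1-based start position; how boundary-straddling
calls were treated in the original analysis is not recorded, so this choice
is documented rather than asserted.

## The synthetic stated world

The generator emulates a dilution experiment: a pure "tumour" cell line
diluted into its matched "normal" in 11 steps (100%, 80%, 60%, 40%, 20%,
10%, 5%, 2%, 1%, 0.5%, 0.2% tumour DNA), sequenced to mean coverage 100x.
At purity $p$ a heterozygous truth variant has expected VAF $p/2$, a
homozygous one $p$. Per truth variant the generator draws depth
$\sim\mathrm{Pois}(100)$ and alt reads $\sim\mathrm{Binom}(depth, VAF)$
once per dilution point (all four pipelines resequence the same library);
each (caller, aligner) pipeline then emits the call iff the alt count
reaches `detection_alt_threshold` (3) *and* an independent per-pipeline
detection coin (`detection_prob` = 0.95) passes. Sensitivity before
filtering therefore follows a closed form — binomial tail times coin rate —
which the tests verify.

Other defaults of the stated world, chosen once and not revisited:

* **Genome**: 200 kb single chromosome, 15% of it in 8–30 bp homopolymer
  and dinucleotide runs so indel representation jitter has substrate;
  exon-like target tiles (350 bp every 500 bp) and confident regions with
  occasional gaps, truth placed inside target∩confident.
* **Truth**: 500 SNVs and 50 indels (1–3 bp), two-thirds heterozygous.
* **False positives**: `fp_rate_per_mb` = 150 per pipeline, of which
  `shared_fp_fraction` = 25% are placed identically in both aligners' sets
  for a caller. A real exome study accumulates tens of FPs per pipeline
  over ~37 Mb; on a 0.13 Mb synthetic evaluation region the *rate* is
  scaled up so the *absolute counts* (~20 per set) are comparable, because
  the set-algebra statistics live on absolute counts.
* **Scores**: true-call scores grow linearly with the sampled alt count
  (so dilution genuinely degrades them through the score cut-offs); FP
  scores are uniform over threshold ± 10 so admission rules are exercised
  on both sides. These distributions are package inventions — no published
  score distributions exist.
* **Planted filters**: a fraction (15%) of true Mutect2 calls carries
  `alt_allele_in_normal` with normal alt fractions drawn across the 7%
  boundary, and 5% carry `clustered_events`, giving an exactly enumerable
  admission oracle. 4% of true Strelka calls have tier-2-only alt support.
* **Jitter**: with probability 30% a Strelka indel is emitted right-shifted
  through its repeat and/or padded with a shared trailing base — an
  equivalent, non-canonical spelling (verified by haplotype equality at
  generation time).

What the generator does **not** emulate: read-level errors and mapping
(there are no FASTQ/BAM), coverage unevenness beyond Poisson, correlated
FPs between *callers*, germline leakage structure beyond the planted
normal-alt counts, and drift mutations in the least-diluted samples. A
green synthetic test therefore establishes the correctness of the set
algebra, the admission logic and the metric accounting — not that the
tuned thresholds are optimal for any real dataset. Consistent with the
drift caveat, the dilution evaluator reports FPR/Mb only for the
most-diluted point and withholds it elsewhere.

Randomness is split into purpose-specific streams (reference, truth,
per-purity calls) derived from one master seed, so changing one parameter
perturbs only its own stream and every output is byte-reproducible; the
study writer emits an md5 manifest that the determinism tests compare.

## Numerical conventions

* Percentages are reported to one decimal, rounding half away from zero —
  the convention that reproduces all sixteen published cross-aligner
  overlap percentages from their printed counts.
* Overlap percentages use the denominator `x_only + shared` (each
  operand's own total); zero denominators yield 0.
* Intersections keep the first operand's record body (representation,
  depths, score) and merge provenance; the ITC driver orders operands by
  lexicographic aligner label, and records are written sorted by (chrom,
  pos, ref, alt), so outputs are byte-stable.
* `vaf()` returns 0 with a warning at zero depth; `sensitivity()` is `NA`
  when there is no truth to recover; `fpr_per_mb()` refuses a zero-sized
  region set.
* Replicate-comparison summaries use type-7 quantiles.

## Limitations

Only the two supported dialects are read (Mutect2/GATK 3.5 and Strelka v1;
not GATK4 Mutect2 or Strelka2, whose filter vocabularies differ). The
combiner is fixed at exactly two aligners per caller (any number of
callers). Normalization performs left-alignment and trimming only — no
haplotype-aware equivalence of complex variant clusters. Precision is
emitted as a secondary report column; the primary metrics are sensitivity
and FPR/Mb, which remain interpretable when the truth set is incomplete.
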