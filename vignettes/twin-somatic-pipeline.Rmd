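---
title: "Detecting somatic mutations in monozygotic twin pairs: model and methods"
author: "twinsom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting somatic mutations in monozygotic twin pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Monozygotic co-twins inherit one germline genome, so a variant present in
one twin's tissue and absent from the other's must be post-zygotic. That
makes discordant twin pairs a natural experiment for somatic mosaicism:
each twin is the other's matched control, exactly as a tumor/normal pair,
but the variants of interest sit at allele fractions of roughly 1–10%
in 30–200× exome-style data. At those fractions a true mutation is
supported by a handful of reads, and sequencing error (~0.1–1% per base),
misalignment of homologous sequence, soft-clipped or multi-mapped reads,
and indel-realignment slippage all produce convincing-looking impostors.
The package therefore treats a paired caller's output as the *beginning*
of the analysis: every candidate is pushed through region-level,
site-level, and read-level filters, and survivors are confirmed by
ultra-deep amplicon resequencing against an explicit error model.

## Pipeline model

### Filter cascade

Candidates (`chrom, pos, ref, alt` with caller metrics) pass five
filters. All five are evaluated for every candidate; the cascade order
only decides which filter is *recorded* as the excluding one, so the
retained set is invariant under reordering (a property the test suite
asserts).

| filter | rule | default |
|---|---|---|
| `mcr` | site inside a multi-copy region (BED) | exclude |
| `indel_window` | site within ±`indel_window` bp of an indel, endpoints included | 10 bp |
| `quality_depth` | mean alt base quality (`bq`, MuTect-style) or somatic quality score (`qss`, Strelka-style) and site depth, both inclusive | `bq ≥ 20`, `qss ≥ 20`, `dp ≥ 30` |
| `homology` | best non-self flank hit must stay below the threshold | `< 160` |
| `control_identity` | any qualified co-twin alt call (`BQ ≥ 20`, `mapQ ≥ 30`) excludes | ≥ 1 call |

The homology score deserves detail. The ±100 bp flank (a 201-mer) is
scored against every same-length window of the genome on both strands
with `score = matches − mismatches`, excluding windows overlapping the
flank's own footprint; the maximum is the second-best score. A perfect
self-hit on a full-length flank scores 201 under this convention, a copy
with *k* mismatches scores `201 − 2k`, and unrelated sequence scores far
below zero, so the classical `< 160` exclusion threshold keeps its
meaning: a score of 160 corresponds to a ~90%-identical copy somewhere
else, which is enough to cross-map reads. Gapped alignment is not
attempted — the surrogate is exact, deterministic, and reproducible —
and precomputed scores from an external aligner can be supplied instead
(`run_cascade(homology_scores = ...)`). Flanks truncated at contig ends
are scored on the available bases and flagged.

The control-identity rule is deliberately *stricter* than the callers'
own behavior: paired callers tolerate one or two alt base-calls in the
control at default settings, and precisely those sites are removed here,
on the reasoning that a single qualified alt call in the co-twin is more
plausibly a shared artifact than a coincidence. A site with zero control
coverage is retained but flagged, since absent evidence is vacuous.

### Read-level reliability (RBSM) and HC selection

For each surviving site, every alt-supporting base-call is classified
against seven criteria; a call passing all of them is a Reliable
Base-call supporting a Somatic Mutation:

1. base quality ≥ 25 — i.e. the call's own error probability is below
   the amplicon validation threshold;
2. read mapping quality ≥ 30;
3. the call sits more than 10 aligned query bases from both read ends
   (cycle-end chemistry and adapter bleed-through concentrate errors
   there); the boundary is exclusive: offset 11 from an end passes;
4. no other mismatch to the reference and no indel operation within ±15
   query bases on the same read (a local mismatch cluster marks
   misalignment, not mutation); the candidate base itself does not count
   against its own read;
5. no XA alternative-alignment tag;
6. no soft-clip operation anywhere in the CIGAR;
7. not attributable to indel realignment.

Criterion (vii) is the one judgement call: "explained by realignment
error" is not an algorithm. It is operationalized as *fail if the read
is marked as indel-realigned, or any read of the local pileup carries an
indel operation within ±15 bp of the site*. This is a conservative,
machine-checkable proxy, kept behind a single predicate so users can
substitute their own. A consequence the tests account for: removing an
indel-carrying read from a pileup can *raise* other reads' verdicts, so
count monotonicity under read removal holds only on indel-free pileups.

A site is high-confidence iff `RBSM count ≥ 2` (two independent reliable
observations) **and** its ±15 bp context contains no short tandem repeat
or poly-A/T run. The original procedure confirmed this by eye in a
genome viewer; here the two conditions are the complete, reproducible
definition — no visual step exists.

The SeqContext detector's parameters are the package's own choices (the
contexts are named in the field, their detection thresholds are not):
tandem unit length 1–6, at least 4 contiguous copies, minimum total run
length 8 bp, homopolymer A/T run ≥ 8, window ±15 bp, all configurable.
The total-length floor exists because "unit 1, 4 copies" alone would
flag any 4-base homopolymer — present in essentially every window — so
unit-1 repeats effectively require 8 copies, coinciding with the
homopolymer rule; poly-T is included by strand symmetry.

### Amplicon validation

Validation resequences each HC site to ~200,000× and counts qualified
base-calls (`mapQ ≥ 60`, `BQ ≥ 20`). The allele fraction
`AAF = 100·alt/total` (percent, denominator includes "other"-base calls)
is compared against the error rate implied by Phred quality 25:

$$\mathrm{AAF} > 100 \cdot 10^{-25/10} = 0.316\,\%$$

with a strict inequality, as the threshold *is* the assumed error rate.
Under the package's uniform-miscall model only a third of miscalls hit
the specific alt base, so a pure-error site has expected alt fraction
0.105% — the threshold is conservative by about 3× against its own error
model, and the suite verifies a < 0.1% false-validation rate over 1000
null sites. The co-twin's AAF is *not* part of the validation rule; it
is reported separately as `control_clean` (below threshold), so either
convention can be audited. Per-site Fisher exact tests on ref/alt counts
between the twins quantify the same contrast inferentially.

### Supporting statistics

* **Monozygosity concordance** restricts both co-twins' genotype tables
  to "putatively credible" sites — depth in [80, 90], genotype quality
  at the conventional 99 ceiling, site quality ≥ 1000 — and reports the
  percentage of identical diploid genotypes. Genotypes are called by a
  minimal binomial-likelihood caller written here (alt-call probability
  `e`, 0.5, `1−e` for hom-ref/het/hom-alt; GQ is the capped Phred gap to
  the runner-up; QUAL the Phred-scaled posterior against hom-ref), since
  no installed package calls genotypes directly from allele-count tables.
* **Post hoc threshold analysis**: one-sided t-tests comparing BQ and DP
  between validated and unvalidated HC candidates, and the sensitivity /
  specificity of a `DP > 60` rule. Welch's unequal-variance form is the
  default — group sizes are typically very unbalanced (7 vs 21 in the
  motivating data) — with the pooled-variance Student form available via
  `var_equal = TRUE`. Reconstructing the test from the published group
  summaries gives a p-value on the order of 10⁻⁷ under the Student form
  and 10⁻⁵ under Welch, so the choice is consequential and both are
  exposed; the suite checks the reconstruction at magnitude level only,
  as the per-candidate values live in unpublished supplementary data.
* **Mutation spectrum**: substitutions collapsed to their
  pyrimidine-reference representative (`G>A ↦ C>T` etc.), six classes.

## The synthetic data generator

Real twin exomes are access-restricted, so the generator is a first-class
module, not a test convenience. It emulates exactly the features the
pipeline consumes:

* a reference contig with planted STRs, poly-A/T runs, ~98%-identical
  duplicated blocks, and annotated MCR intervals (all exported as BED);
* paired read sets from one shared germline: heterozygous plants at
  expected fraction 0.5, homozygous at 1.0, in *both* twins; somatic
  plants only in their carrier, with binomially sampled alt reads at the
  true allele fraction (read length 100, depth 30–200× regimes);
* Phred-faithful per-base qualities and substitution errors
  (`P(error) = 10^{-Q/10}`, uniform over the three other bases; default
  quality mix ≈ Q30 mean error);
* artifact structure: soft-clipped reads, XA-tagged multi-mappers with
  reduced mapQ, edge-concentrated errors, and indel loci where a fraction
  of overlapping reads carry a deletion plus a flanking mismatch cluster.
  Indel artifacts are planted at *loci* rather than i.i.d. per read
  because criterion (vii) fails every alt call near any indel-bearing
  read: realignment artifacts cluster at positions in real data, and an
  i.i.d. per-read rate would veto a large fraction of genuinely clean
  sites;
* `wes_artifact` plants — alt reads present in the discovery data over a
  true allele fraction of zero — so the validation stage has genuine
  false positives to reject;
* amplicon count tables: `alt ~ Binomial(depth, aaf + (1−aaf)·e/3)`
  under the uniform-miscall model, totals equal to depth.

Reads are emitted pre-aligned at their true positions: the filters
operate on alignment *features* (CIGAR, tags, qualities), not on mapping
itself, so a mapping step would only add noise that is not under test.
Coordinates are 1-based closed internally; BED export converts to
0-based half-open; contigs are `chr`-prefixed. Every stochastic function
takes an explicit seed and restores the caller's RNG state — there is no
implicit global seed — and fixed seeds give bit-identical output.

What the generator does **not** emulate, and what passing tests
therefore cannot show: capture-induced bias against non-reference
alleles (exposed as an optional `alt_downsample` factor, default 1 — the
bias is real in hybrid-capture data but unquantified, so no default is
invented), GC-dependent coverage, paired-end insert-size structure,
PCR-duplicate families and oxidative damage signatures, and indel
*calling* (indels appear only as artifact context). Results on real
exomes will be correspondingly less clean than on synthetic fixtures.

## Detectability

The `RBSM ≥ 2` rule has a hard binomial limit. A site at allele fraction
*f* and depth *d* has about `0.8·d` usable covering reads (the ±10 bp
edge rule discards ~20% at read length 100), so
`P(RBSM ≥ 2) ≈ 1 − (1−f)^{0.8d} − 0.8df(1−f)^{0.8d−1}` for clean reads.
At `f = 0.05, d = 60` this is only ~0.70; it first exceeds 0.99 deeper
into the regime, e.g. ~0.997 at `f = 0.10, d = 100` and ~0.9995 at
`f = 0.10, d = 120`. The property suite asserts the > 0.99 detection
rate at the latter parameters, where the binomial bound actually
supports it, and the analysis scripts occasionally show a clean planted
site failing with RBSM 1 at depth 85 — that is this tail, not a defect.
The same arithmetic is why depth, not base quality, separates validated
from unvalidated candidates in the post hoc analysis.

## Numerical and design choices

* Thresholds printed as `≥` are inclusive (`bq = 20`, `dp = 30` pass);
  the validation threshold is strict (`AAF = 0.316%` fails).
* The indel window is closed: a candidate exactly 10 bp from an indel is
  excluded, 11 bp is retained.
* Degenerate inputs fail loudly: zero amplicon coverage, zero-margin
  Fisher tables, single-class threshold-performance labels, and empty
  credible-site sets are errors, not silent zeros or NAs.
* `excluding_filter` reports the first failing filter in the configured
  order; this is a labelling convention only (see order-invariance
  above).
* The genotype caller's GQ is capped at 99 and QUAL at 99999;
  likelihoods are computed in log space, so deep hom-ref sites cannot
  underflow into spurious variant calls.
* Candidate direction: the pipeline processes one (case, control)
  orientation per run; the reverse direction is the same computation
  with roles swapped, as mutations can occur in either twin.
* Problem sizes: the bundled demonstration uses a 60 kb contig at depth
  100 with 20 candidates (10 clean / 10 decoys); the acceptance script
  simulates 1200 germline SNVs on 150 kb at depth 85. These sizes are
  chosen so that every stage is exercised with comfortable statistical
  margins while a full run stays interactive on one core.

## Limitations

The homology surrogate is ungapped, so a duplicated block interrupted by
an insertion scores lower than a gapped aligner would report — the
`< 160` rule is slightly more permissive here than with true BLAT
scores; supplying external scores closes the gap. Criterion (vii) is a
proxy and will over-exclude sites near genuine heterozygous indels in
the co-twin pair. The binomial genotype caller is adequate for the
concordance check it serves but is not a general-purpose caller (no
priors, no multi-allelic sites). And all empirical guarantees quoted
here are statements about the generator's data regime; on real data the
filters' thresholds are the auditable, overridable part
(`run_config(thresholds = ...)`), and re-tuning them is expected.
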