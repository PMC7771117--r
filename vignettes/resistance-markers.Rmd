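---
title: "Detecting resistance markers from pooled RNA-Seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting resistance markers from pooled RNA-Seq: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fastdr)
```

This vignette is the package's own account of what it computes, which
assumptions that rests on, and where the design was genuinely open and a
choice had to be made.

## What the data are

The input is RNA-Seq from a *pooled* population sample — many individuals
sequenced together — aligned against cDNA references rather than a
genome: the target-gene transcript for the target-site branch, the set of
detoxification-gene transcripts for the expression branch. Pooling is
what makes the read-level variant fraction meaningful: the fraction of
reads carrying an allele at a transcript position is used as a proxy for
that allele's frequency in the population. That proxy is imperfect —
individuals contribute unequal amounts of RNA, and allele-specific
expression can bias it — which is an intrinsic limitation of the design,
not of the implementation; larger pools make it better.

## Target-site branch

### Pileup semantics

`build_pileup()` projects each alignment through its CIGAR string: `M`,
`=` and `X` consume query and reference and contribute base counts; `I`
and `S` consume query only; `D` and `N` consume reference only and
contribute neither counts nor coverage. The published workflow extracts
bases "by position", which is well defined only for ungapped alignments;
full CIGAR projection generalizes it and degenerates to the same counts
for ungapped reads, so it is the strictly safer reading. Three further
rules keep the counts honest:

* secondary/supplementary records (FLAG 0x100/0x800) are excluded, so one
  sequenced read is never counted twice;
* `N` read bases count toward neither base counts nor coverage;
* deletions do not appear in coverage denominators — a frequency is
  always "variant reads over base-bearing reads".

Base qualities are ignored throughout: the decision rule the branch
implements has no quality term, and adding one would change the
published thresholds' meaning. Whether overlapping mates of a read pair
should be collapsed is not specified by the decision rule either; each
record is counted independently here, which slightly overcounts coverage
in overlapping-pair data.

### SNP and differential rules

A position is a SNP when counted coverage is at least `min_coverage`
(default 30) **and** at least two distinct bases are observed. The
variant is the most frequent non-reference base; ties break
alphabetically for determinism, and remaining non-reference bases are
kept in a diagnostics column rather than dropped. Both thresholds are
inclusive (`>=`), following the workflow's wording ("coverage ≥ 30",
"difference ≥ 40%") over the looser "> 40%" phrasing that also appears in
summaries of it; at realistic coverages the boundary cases are
vanishingly rare.

A candidate site is *differential* when both pools reach `min_coverage`
and the same variant base differs in frequency by at least
`delta_threshold` (default 40) percentage points in either direction.
Candidates where the other pool lacks coverage are reported in a separate
`incomparable` section instead of being silently dropped — published
survey tables leave such cells blank without stating a rule, and
discarding them invisibly would hide real signal.

Frequencies are computed exactly and rounded only at report time (two
decimals), so a printed value like 51.06 is reproducibly `24/47` and not
an accumulation of intermediate roundings.

### Codons, translation, numbering

References are assumed to be coding sequences in frame from base 1, so
position $p$ belongs to codon $\lfloor (p-1)/3 \rfloor + 1$. Each variant
is translated against the reference background; when two SNPs fall in the
same codon they are translated independently (and are easy to spot, since
they share a residue index in the output) — joint phasing of co-codon
variants is out of scope. Substitutions to a stop codon are kept and
flagged `nonsense`; synonymous changes are flagged and excluded from the
mutation report.

Published mutation coordinates live on a designated canonical species per
target (the house-fly sodium channel, for instance, which is why the
*kdr* substitution is always "L1014F"). How the original pipeline moved
between a study species' own numbering and the canonical one is not
mechanized anywhere we could follow, and was most likely manual curation;
this package makes the convention executable with a global
Needleman–Wunsch alignment (BLOSUM62, gap open 10, gap extend 0.5 —
conventional protein-alignment defaults, since nothing in the published
material pins them down) whose aligned residue pairs form a strictly
increasing partial map. Residues that fall in gaps are reported
`not_mappable` rather than guessed.

### Replicates

Two published presentations exist side by side: per-replicate frequencies
with their arithmetic mean, and a single pooled-sample frequency. Both
are exposed. The known-mutation scan defaults to per-replicate calling
with a mean (`replicates = "mean"`) and offers `"pool"`; the
differential-SNP comparison always pools replicate pileups within a
group, because the 40-point rule is defined on one case/control pair of
frequencies and summing pileups is the faithful way to make one pair out
of replicates.

## Metabolic branch

Counting is deliberately simple: one count per primary mapped record.
An EM-based multi-mapping model would be better for closely related
paralogs (detoxification families have many) but would make counts
non-deterministic functions of the input order and is explicitly not
attempted; a fractional `1/k` mode is available for sensitivity analysis.

Normalization is median-of-ratios: sample $j$'s size factor is the median
over genes of $K_{gj} / (\prod_j K_{gj})^{1/m}$, over genes with a
positive geometric mean and a positive count in sample $j$. The test is a
per-gene negative-binomial Wald test on
$\log_2(\hat\mu_{\text{case}} / \hat\mu_{\text{ctrl}})$ of normalized
means, with:

* gene-wise dispersion $\alpha$ by method of moments on normalized
  counts, pooling within-group variances, floored at $10^{-8}$ — no
  shrinkage across genes, which costs power at 3 replicates but keeps
  every gene's estimate independent and transparent;
* delta-method standard error
  $\mathrm{SE} = \sqrt{(1/\mu_A + \alpha)/n_A + (1/\mu_B + \alpha)/n_B} / \ln 2$;
* a continuity adjustment of 0.5 normalized counts added to both group
  means *only* when one of them is zero, and only in the fold-change and
  SE computation — never in dispersion estimation, where it would bias
  $\alpha$ downward;
* a single-replicate group triggers a warning and a dispersion-floor
  (effectively Poisson) fallback rather than an error.

The overexpression filter applies the published criterion literally:
`log2FC > 1` and **raw** `p < 0.01`. Whether that criterion was ever
meant to be FDR-adjusted is unknowable from the text, so the
Benjamini–Hochberg adjusted value is carried alongside in every results
table for users who want the stricter reading, and a two-sided `|log2FC|`
variant of the filter is a flag. The reported `FC`, `log2FC` and CI
columns satisfy `FC = 2^log2FC` and `CI = log2FC ± 1.96·SE` exactly.

This branch is a native equivalent of the RSEM + DESeq2 stack the
original workflow delegated to. Numeric agreement with DESeq2's shrunken,
outlier-filtered output is *not* promised and not a goal; the size-factor
step, where the definitions do coincide, is cross-checked against DESeq2
in the test suite, and the estimator as a whole is validated by
simulation recovery.

## Simulators and what passing them means

`simulate_reads()` draws read start positions uniformly over the
reference with independent per-base substitution errors (default
$10^{-3}$), emitting full-match alignments at their true positions. It
deliberately does not model an expression profile, splicing, quality
strings, or mapping failure: the validation design it serves measures
variant recovery at a stated coverage, and uniform coverage makes that
coverage an actual parameter instead of an emergent property. Coverage
consequently ramps down within a read length of the reference ends — at
100× mean coverage roughly 1% of positions sit below the calling floor,
which is the main reason end-to-end sensitivity is below 100%.

`spike_variants()` draws distinct positions from the covered range,
frequencies uniform on `[0.05, 0.95]` (the published "random frequencies"
are unspecified; this range spans the detectable spectrum and is
configurable), and a random alternate base. The default exact-count mode
rewrites `round(f·cov)` covering reads, so the realized fraction is known
exactly and a variant rounding to zero altered reads is recorded as *not
inserted* — the same failure mode the original spike-in tool exhibited on
low-coverage loci. A binomial mode trades that determinism for realism.

`simulate_counts()` draws NB counts (Poisson at dispersion 0) at a shared
per-gene baseline (log-normal around ~300 counts) times the true fold
change in the case group, 172 genes and two groups of three replicates by
default, matching the published validation design; true fold changes
default to $2^{U[-3,3]}$.

`evaluate_tr()` implements the published metric definitions verbatim,
including the one that deserves a health warning: its "specificity" is
detected-inserted over all-detected, i.e. a *precision*, not a
true-negative rate. It is reported under both names. The ROC score
variable was never stated; the alternate-base read count is used here
(monotone in both coverage and frequency) and the AUC is trapezoidal over
the detected candidate set. Frequency and fold-change accuracy are
squared Pearson correlations between detected and true values.

Passing these simulations shows that the calling and estimation machinery
recovers truth under the stated noise model at the stated scale. It does
not show robustness to misalignment, splicing artifacts, uneven
expression coverage, or pooled-RNA composition bias — none of which the
generators emulate.

## Fixtures

The bundled target-gene sequences are synthetic, and say so in their ids
and filenames: real target cDNAs live in public databases and are not
redistributed here. They are deterministic random sense-codon sequences
of realistic length (5164 codons for the ryanodine receptor, 2100 for the
sodium channel, 500 for the nAChR β1 subunit) with the codons at
published mutation residues chosen so the published nucleotide change
reproduces the published substitution — codon 4946 of the RyR fixture is
`GGA`, so G→A at cDNA position 14837 gives G4946E. One published sodium-
channel row (position 6155, G→C, labelled A2052G) is internally
inconsistent with the codon convention every other row obeys — the middle
base of an alanine codon is C, so ref G → variant C at that offset can
only encode Gly→Ala; the fixture realizes G2052A at that position. The
bundled canonical proteins are the fixtures' own translations, making the
default numbering map the identity; tests build offset and indel variants
from them to exercise non-trivial maps.

## Numerical and degenerate-input choices

* Frequencies: exact rationals internally, 2-decimal rendering in
  reports; percentages throughout the TR branch, proportions in the
  spike-in truth.
* Zero coverage is `NA`, never 0: "no variant observed" and "nothing
  observable" stay distinct everywhere.
* Variant-base ties break alphabetically; co-optimal alignment traceback
  follows `pairwiseAlignment`'s deterministic high-road preference.
* Catalog rows that violate invariants (residue ≤ 0, identical
  amino acids, unknown target) are rejected row-wise with a warning so a
  user-extended catalog degrades gracefully; malformed SAM mandatory
  fields are a hard error with a line number, since silently skipping
  corrupt alignments would bias counts.
* All simulators take an explicit seed and restore the caller's RNG
  state; identical configuration and inputs produce byte-identical
  reports.

## Validation scale

The shipped validation runs use 150 bp reads at 100× mean coverage over
the three bundled fixtures (~23 kb, ~15,500 reads), 600 spiked variants,
and a 172 × 6 count matrix at dispersion 0.05 — the scale of the original
validation design, which a laptop handles in well under a minute per run.
`scripts/acceptance.R` re-derives every reported quantity from scratch at
exactly this scale.

## Known limitations

Indels are projected correctly through pileups but never called as
variants; the method is single-nucleotide by construction. Co-codon SNPs
are not phased. Detoxification-gene *amplification* — a third resistance
mechanism — is invisible to expression data of this kind. The
pooled-frequency proxy inherits RNA-composition bias. And the catalog is
only as good as its curation: a scan can annotate what is in it, and will
honestly report everything else as novel.
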