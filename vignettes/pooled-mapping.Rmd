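---
title: "Mapping recessive mutations from pooled sequencing with poolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive mutations from pooled sequencing with poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The mapping problem and the model behind the scan

An F2 incross of two heterozygous carriers segregates a recessive lesion
1:2:1. Phenotyped mutants are all homozygous for the lesion-bearing
haplotype; their wildtype siblings are a 1 (+/+) : 2 (+/-) mixture. When
the cross is made between two strain backgrounds, every strain-diagnostic
SNP is heterozygous in the F1 and segregates at expected frequency 0.5 in
any unselected pool of F2 chromosomes. Selection on the mutant phenotype
perturbs this only near the lesion: at a marker at recombination fraction
$r$ from the causative locus, each of the $2n$ chromosomes in a pool of $n$
mutants carries the lesion-strain allele with probability $1 - r$, so the
expected mutant-pool allele frequency decays from 1 at the lesion toward
0.5 with genetic distance, while the sibling pool stays at
$(0 \cdot 1 + 0.5 \cdot 2)/3 = 1/3$ for the lesion allele and 0.5
elsewhere. These closed-form expectations are exactly what the test suite
checks the simulator against.

The scan statistic is deliberately simple, matching how such pools are
analyzed in practice:

1. per retained marker, the raw mutant-pool frequency
   $f_i = a_i / (a_i + r_i)$ from alternate/reference read counts;
2. the folded score $F_i = \max(f_i, 1 - f_i)$ — the strain of origin of
   the lesion is unknown per marker, and folding makes the statistic
   orientation-free (an unlinked marker has $E[F] \approx 0.56$ at 50x
   depth, not 0.5, because of sampling noise around 0.5 — the peak must be
   judged against this folded-binomial baseline, which stays below 0.60
   under the default design);
3. a sliding window of 50 neighboring loci: $W_i$ is the arithmetic mean
   of $F$ over the marker-count window centered on $i$. Windows are marker
   counts, not physical distances, so marker density sets the physical
   span.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_mutant_pool`, `n_wildtype_pool` | 108, 108 | larvae | the standard pooled design this package targets |
| `mean_depth` | 50 | reads/marker/pool | typical informative-site depth for pooled RNA-seq |
| `seq_error_rate` | 0.005 | per base | Illumina-like; symmetric ref/alt flips |
| `window` | 50 | markers | averages out read-sampling noise (SE ≈ 0.005 at 50x) while spanning ~25 cM at default marker density |
| `min_depth` (wildtype pool) | 20 | reads | below this, allele-frequency estimates are too noisy to certify a marker |
| `wt_af_min`, `wt_af_max` | 0.2, 0.8 | frequency | retains sites segregating in the sibling pool; rejects monomorphic/artifact sites |
| `peak_threshold` | 0.98 | fraction of peak | interval = run of markers with $W \ge 0.98 \times$ peak (see below) |
| `alpha`, `min_fold` | 0.05, 0.5 | — | BH-adjusted significance and direction for the reduced-expression flag |

## What the simulator emulates — and what it does not

`simulate_genome()` + `simulate_cross()` generate the full experiment with
ground truth (`cross_truth`): 25 chromosomes of 50 Mb / 100 cM (a
zebrafish-like ~2500 cM map), 200 strain-diagnostic markers per
chromosome, meiosis with Poisson crossover counts (mean = genetic length /
100, no interference, no obligate chiasma), uniform breakpoints on the
genetic map, and a constant cM/Mb within each chromosome. Pools are filled
by phenotype (homozygotes into the mutant pool, subject to a configurable
phenotyping error that caps the peak below 1), reads are Poisson-depth /
binomial-allele draws with symmetric error, and expression counts are
Poisson (optionally negative binomial) with one planted reduced-expression
gene near the lesion (baseline mean 500, fold 0.2).

The simulator does not model read-level artifacts (alignment bias,
duplicated reads, base-quality structure), linked marker ascertainment
from RNA-seq coverage (markers are uniform, not exon-clustered), crossover
interference, or segregation distortion. Passing tests therefore certify
the analysis logic under the stated sampling model — not robustness to
alignment artifacts or to strongly non-uniform marker density, which real
transcriptome-derived markers exhibit.

## Numerical and design choices

**Window centering and edges.** The window is centered on each marker (for
even sizes it extends one marker further to the right); markers within
half a window of a chromosome end get no value, and windows never span
chromosome boundaries or zero-depth ("no-data") markers — the latter are
excluded so a coverage hole cannot dilute the peak. Centered windows avoid
the positional bias a trailing window would introduce.

**Folded vs raw averaging.** The profile folds before averaging by
default; `statistic = "raw"` is available when the lesion strain is known
genome-wide and polarization is meaningful.

**Interval delimitation.** The boundary rule is a threshold on the
windowed profile around the peak. The default is *relative*
(0.98 × peak height) rather than an absolute cut: under the default
design a 50-marker window spans ~25 cM, so even at the lesion the window
averages in recombinant haplotypes and its expectation is ~0.94 (one minus
the mean Haldane recombination fraction over ±12.5 cM) — an absolute 0.98
cut would delimit an empty or single-marker interval in a typical run. A
2% drop from the peak corresponds to ~4 windowed standard errors at the
default depth, so the relative rule is noise-robust while staying tight.
`threshold_mode = "absolute"` (clamped to the peak) is available for
dense-marker designs where the peak does reach fixation. Ties at the peak
resolve to the longest plateau, then the lowest genomic coordinate. A run
whose edge touches the first or last windowed marker of its chromosome is
extended to the chromosome's terminal marker: the unwindowed flank carries
no evidence of decline, and truncating there would systematically exclude
near-telomeric lesions. A profile whose windowed range is under 0.01 is
reported as "no linkage detected" rather than an arbitrary peak.

**Coordinates.** Marker tables, VCF and reports are 1-based inclusive; BED
output is 0-based half-open; converters are exercised in both directions
by the tests.

**Variant classification.** Genomic positions map into the spliced CDS
strand-aware; SNVs are translated with the standard nuclear code; indels
are left-aligned against the reference before CDS mapping, then classed by
length mod 3 (frameshift vs in-frame). Intronic positions within ±2 bp of
an exon boundary are splice_site; start-codon loss is reported at missense
severity; indels straddling an exon/intron junction are splice_site with a
warning. Severity ranks nonsense > frameshift > stop_loss > missense >
in-frame indel > splice > synonymous > noncoding — a total, deterministic
order so reports are stable.

**Expression screen.** "Significantly reduced" is operationalized as a
two-sided binomial test of the gene's mutant-pool count against its
expectation under equal expression (library-size split), BH-adjusted, with
a fold-change direction filter (≤ 0.5). The test is deliberately simple
and swappable; with two libraries and no replicates a dispersion-aware
test has nothing to estimate dispersion from.

## Validation design and problem sizes

The suite validates three ways: forced outcomes (an error-free,
recombination-suppressed cross must put the causative marker at exactly
1.0 and the peak window at exactly 1.0), oracle equivalence (windows vs a
naive per-window mean for w ∈ {1, 2, 3, 7, 50}; codon classification vs a
full-sequence translate-and-compare over all 64 × 9 substitutions, both
strands), and parameter recovery (50 crosses at the default design with
the lesion planted at a random marker: the interval must lie on the
planted chromosome in every run and contain the lesion in ≥ 95%).
Segregation expectations (unlinked 0.5; sibling-pool lesion allele 1/3)
are checked over 200 seeded crosses on a compact 6-marker genome within 3
Monte-Carlo standard errors — the expectation is per-marker and does not
depend on genome size, so the small genome simply keeps the experiment
quick.

## Known limitations

- Interval width at the default design is several Mb, set by the window's
  ~25 cM genetic span; real experiments narrow it with denser markers
  (the window then spans fewer cM), not by changing the statistic.
- No confidence interval accompanies the peak (no bootstrap or QTL-seq
  style CI); the delimitation threshold is a descriptive rule.
- One transcript per gene model: isoform-aware consequences are out of
  scope, as is protein-impact scoring.
- The expression screen assumes pooled counts and two libraries; it is not
  a replacement for replicated differential expression.
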