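---
title: "Gene-centric functional profiling of stool metagenomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric functional profiling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpksm)
```

## The problem

Shotgun metagenomes of stool carry two complementary signals about the gut
microbiome (GM) of a host: *who is there* (taxonomic composition) and *what
they can do* (the gene content of the community). In metabolic liver disease
(MASLD and its progression to fibrosis and cirrhosis), the microbial
production of metabolites such as butyrate, short-chain alcohols,
trimethylamine and methane is of direct clinical interest, and the genes
encoding the terminal enzymes of these pathways can be quantified directly
from reads — independently of which taxa carry them.

`rpksm` implements that gene-centric workflow as a set of composable,
tibble-in/tibble-out functions:

1. **Family construction** — extract candidate genes from annotated
   pangenome FASTA by header patterns, filter, align, and delimit a gene
   family around an experimentally validated reference enzyme.
2. **Quantification** — turn per-sample tabular protein alignments of reads
   against family members into counts and RPKSM values.
3. **Taxonomic post-processing** — clean and threshold relative-abundance
   profiles, and compute the clades shared across cohorts.
4. **Differential testing** — Mann-Whitney tests with Benjamini-Hochberg
   (BH) adjustment, cross-cohort consistency calls, and a universal
   single-copy gene (USCG) negative control.
5. **Genome/plasmid screening** — call gene presence from profile-scan
   tables and classify per-clade prevalence as core / accessory / highly
   accessory; count plasmids carrying each gene.
6. **Synthetic data** — generate every input format above with known
   ground truth, so each stage is testable end to end without downloads.

## The abundance statistic

For a gene family $f$ with $S_f$ member genes of mean length
$\bar{L}_f$ kilobases (nucleotide basis; amino-acid lengths are converted
$\times 3$), and a sample $s$ with library size $N_s$ reads of which
$c_{fs}$ map best to members of $f$:

$$\mathrm{RPKSM}_{fs} = \frac{c_{fs}}{\bar{L}_f \cdot S_f \cdot N_s/10^6}$$

This is the familiar RPKM normalization with one extra factor, the family
size $S$, so that families with many subunits or paralogs are comparable to
single-gene families. Two readings of the "per kilobase" basis are
possible; the default divides by the *mean* member length, because a
*total*-length basis together with the explicit $S$ factor would penalize
family size twice. The total-length basis remains available via
`compute_rpksm(..., length_basis = "total")` for comparison.

Counting is strictly one read, one family: hits with E-value
$\ge 10^{-10}$ are discarded (the threshold is strict, `< 1E-10`), then
exactly one hit per read survives — lowest E-value, ties broken by highest
bit score, then lexicographically smallest gene id, so results are
deterministic. Reads whose best gene belongs to no family are kept in an
`unassigned` bucket, which makes read conservation checkable:
family counts + unassigned = retained reads.

## Family construction choices

The extraction procedure matches candidate headers case-insensitively
against include patterns, with exclude patterns taking precedence (so a
spurious "butyrate kinase 2" can be matched away from a "butyrate kinase"
family). Length filtering keeps sequences within $[0.5, 1.5]\times$ the
reference length (inclusive bounds; the fractions are configurable — the
symmetric default is the least surprising reading of a bare "filtered by
length" step). The gap filter removes alignment rows with $\ge 30\%$ gap
columns — the boundary itself is excluded.

Two desk-scale substitutions are deliberate:

* **Alignment.** Instead of invoking an external multiple aligner, the
  package star-aligns every candidate onto the reference with global
  pairwise alignment (BLOSUM62) and projects each onto the reference's
  columns, dropping insertions relative to the reference. This is exact
  for substitution-only divergence and adequate for the point of the
  alignment here — gap fractions and p-distances — but it is not a general
  progressive aligner and will underestimate homology across large
  insertions.
* **Tree.** Family delimitation uses a neighbor-joining tree on
  p-distances (computed over gap-free column pairs, negative NJ branch
  lengths clamped to zero) rather than a maximum-likelihood
  reconstruction. The delimitation contract is distance-based either way,
  and NJ preserves exactly the information the rule consumes.

The delimitation rule itself had to be made concrete: the family is the
*largest clade containing the reference* in the midpoint-rooted tree such
that every leaf's path distance to the reference is at most `d_max`
(default 0.6 substitutions per site). The reference is then removed from
the membership and $S$ recomputed, so a validated reference that is not a
genuine pangenome member never inflates the family. With fewer than three
sequences no tree exists and membership falls back to direct p-distance to
the reference.

## Statistical testing

Group comparisons are two-sided Mann-Whitney tests reporting
$U = \min(U_a, U_b)$. The p-value is exact (full enumeration) when
$n_a + n_b \le 12$ with no ties — the switchover keeps enumeration
desk-fast — and otherwise the normal approximation with tie and continuity
corrections. When every observation is identical across both groups the
test is degenerate and $p = 1$ is reported.

BH adjustment is applied *within each cohort's batch of features* for
discovery comparisons: the adjustment family is "all features of one table
in one cohort comparison", the conservative, reproducible reading. A
feature is called **consistent-significant** across cohorts when its
direction of change (from group medians) agrees and is non-flat in every
cohort, and $q < \alpha$ in at least two cohorts; agreeing directions with
fewer significant cohorts give **trend-only**. A configurable exemption
list removes named cohorts from the significance count (for designs where
one cohort lacks a healthy-control arm, e.g. an early-vs-advanced fibrosis
comparison) without waiving the direction requirement.

The **USCG control** compares the five universal single-copy genes (argS,
dnaA, rpoA, rpoB, rpoC) between groups; because every bacterial cell
carries one copy of each, any group difference flags a normalization or
compositional artifact. One design choice matters here: the control is a
single procedure, so its pass/fail decision uses a *single* BH adjustment
pooled over all its (family, cohort) tests (`q_control`). Splitting the
adjustment into three per-cohort batches would give the whole control a
null failure rate near $1-(1-\alpha)^3 \approx 14\%$; the pooled family
keeps it near $\alpha$. The per-cohort `q` values are still reported for
inspection.

Fold changes are ratios of group medians (case/control); $0/0$ is flagged
`flat` and $x/0$ reported as infinite rather than dropped.

## Taxonomic post-processing

Cleaning removes clades labelled `unclassified` (any rank prefix) and
clades whose mean abundance is zero across all samples of any cohort —
*unless* the clade is present exclusively in one comparison group of some
cohort, in which case it is retained globally as a potential clear group
marker. Retention thresholds are strict means per cohort: genera
$> 0.5\%$, species $> 0.2\%$, computed over all of a cohort's samples with
both groups pooled (the rule text does not say per-group; pooled is the
plain reading). Because thresholds act per cohort, a clade can survive in
one cohort and not another; the shared-clade set is the intersection of
survivors across cohorts, and its summed relative abundance is reported
per cohort. Both filters are idempotent.

## Genome and plasmid screening

Presence of a gene on a replicon (genome or plasmid) requires at least one
scan hit with profile coverage strictly above 90\%
(`(hmm_to - hmm_from + 1) / profile_length`, 1-based inclusive profile
coordinates), full-sequence E-value $< 0.01$ and independent E-value
$< 0.01$. Multiple ORF hits on the same replicon collapse to one presence
call. Genomes enter prevalence calculations only with completeness
strictly above 95\% and all five USCGs present, and clades only with
strictly more than 100 retained genomes. Prevalence classes follow the
three printed brackets plus an explicit absent state:
core $p > 0.8$; accessory $0.2 \le p \le 0.8$ (closed at both ends —
the only reading consistent with three contiguous brackets and a separate
0\% class); highly accessory $0 < p < 0.2$; absent $p = 0$. Plasmid
collections are curated before counting: partial sequences, unassignable
hosts and sequencing internal controls are excluded, and each plasmid
counts once per gene regardless of copy number.

## What the synthetic generator emulates — and what it does not

The generator produces every file dialect the pipeline consumes: annotated
protein FASTA pangenomes (with spurious-name, fragment and far-divergent
decoys), 12-column tabular read alignments, merged MetaPhlAn-style taxon
tables, genome/plasmid metadata, and HMMER3-style per-domain scan tables.
Its defaults mirror the three-cohort case/control study design the package
models (554 stool metagenomes: 117/121, 72/14 and 105/125 per cohort).

True read counts are Poisson with mean
$a_{fs} \cdot S_f \cdot \bar{L}_f \cdot N_s / 10^6$, where $a_{fs}$ is the
family baseline times the group fold change — chosen as the *simplest*
model under which expected RPKSM equals $a_{fs}$ exactly, making parameter
recovery a sharp test. An optional overdispersion multiplier gamma-mixes
the mean for users who want heavier-tailed counts. Contamination is
injected at known rates, not learned: sub-threshold hits (E-value
$\ge 10^{-10}$) that the E-value filter must remove, and duplicate
secondary hits that best-hit filtering must remove. Screen carriers are
assigned as exact counts (`round(prevalence x n_retained)` genomes sampled
without replacement) so configured prevalences are realized up to
rounding; independent Bernoulli sampling is available via
`stochastic_prevalence = TRUE`.

The generator is a stand-in, not a model of real data: it simulates no
read sequences, sequencing errors, host contamination, strain variation,
compositional coupling between families, or correlated taxa. Passing the
recovery tests therefore demonstrates that the *bookkeeping and
statistical machinery* are correct under known truth — not that the
pipeline's biological conclusions transfer to any particular real cohort.

## Numerical conventions, degenerate inputs, problem sizes

* Every boundary in the pipeline is strict or inclusive exactly as its
  rule is printed: 30\% gaps excluded, E-value $= 10^{-10}$ excluded,
  coverage $= 0.90$ excluded, completeness $= 95.0$ excluded, prevalence
  0.80 and 0.20 both accessory, clade size 100 excluded.
* All thresholds live in `pipeline_config()`; stages receive them from
  there, and the run log echoes the full configuration.
* Determinism: every stochastic step derives from a single integer seed;
  identical configurations yield byte-identical output files. Tie-breaks
  (best-hit selection, BH order preservation) are deterministic.
* Degenerate inputs fail loudly and early: empty groups, empty reference
  sequences, ambiguous gene-to-family maps, malformed table rows (with
  line numbers), coordinate violations (with ORF ids), and invalid
  configurations (all violations listed at once).
* Test-suite problem sizes were chosen to make Monte-Carlo error small
  relative to the tolerances checked: 20 families $\times$ 10 samples with
  $\gtrsim 500$ reads per family for RPKSM recovery; 1,000 null and 500
  shifted features for error rates; 100 simulated families for
  delimitation recovery; 100 replicate control runs (simulated at the
  count level) for the USCG pass rate; 230-genome clades for prevalence
  recovery.

## Known limitations

* The star aligner and NJ tree are desk-scale instruments; for real
  pangenomes with indel-rich families, users should import externally
  computed alignments and treat the internal aligner as a fallback.
* The one-read-one-family rule discards genuinely multi-family reads
  (e.g. promiscuous domains); the unassigned bucket does not distinguish
  "no family" from "ambiguous".
* Prevalence at genus and species rank is computed from the same presence
  calls; rank-specific genome subsets are supported only through the
  clade labels supplied in the genome metadata.
* The Mann-Whitney/BH machinery assumes independent samples; repeated
  samples per subject (present in one emulated cohort) are treated as
  independent, as in the design being reproduced.
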