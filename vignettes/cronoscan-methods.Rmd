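---
title: "Methods: quantifying position-dependent consequences of Titin truncations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying position-dependent consequences of Titin truncations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cronoscan)
```

## The problem

Truncating variants in Titin (*TTN* in human, *ttna* in zebrafish) cause
dilated cardiomyopathy and skeletal myopathy, but their severity depends
strongly on where along the gene they fall: truncations in the C-terminal
two-thirds of the protein (from amino acid 14,760 of the human
meta-transcript onwards) dominate severe disease, while N-terminal
truncations are better tolerated in skeletal muscle. Alternative splicing
explains only part of this asymmetry -- thousands of N-terminal amino acids
sit in constitutive exons. The mechanistic candidate is an internal
alternative promoter (the *Cronos* promoter, in the intron upstream of
zebrafish exon 116 / human exon 240) that produces a C-terminal isoform and
rescues tissue that retains it.

`cronoscan` implements the computational procedures this model rests on, as
testable package functions driven by a synthetic-data module, so the whole
chain runs end to end without any external sequencing accession:

1. exon-level percent-spliced-in (PSI) from exon-exon junction reads;
2. splice-aware truncation-consequence calling;
3. nonsense-mediated decay (NMD) from allelic imbalance in heterozygotes;
4. internal-promoter detection from intronic read accumulation;
5. positional cohort comparison around the promoter boundary;
6. CRISPR/Cas9 guide design by PAM scanning.

## PSI from junction reads

For an internal exon with upstream-junction reads $I_5$, downstream-junction
reads $I_3$ and skip-junction reads $X$,

$$\hat\psi = \frac{I_5 + I_3}{I_5 + I_3 + 2X},$$

and for a terminal exon, with its single inclusion junction $I$,
$\hat\psi = I/(I+2X)$. The factor 2 reflects the bookkeeping of the two read
classes: a transcript that includes the exon contributes evidence at *both*
inclusion junctions, while a transcript that skips it contributes at the one
skip junction, so the skip count must be doubled for the two event classes to
be weighed equally. The paired generative model in the synthetic module draws
$I_5, I_3 \sim \text{Pois}(d\,\psi)$ and $X \sim \text{Pois}(d(1-\psi))$ at
junction depth $d$; under it $\hat\psi$ is consistent for $\psi$. We
deliberately match generator and estimator this way -- an assumption, stated
here, rather than a property of any particular sequencing protocol.

Estimates whose denominator $I_5+I_3+2X$ falls below `min_denominator`
(default 15 reads) are **no-calls**, not zeros; absent junctions (the missing
inclusion junction of a first/last exon) are likewise recorded as absent
(`"."` in the TSV), never as observed zeros. Per-exon summaries across
samples take the median over passing estimates only. Precision at the study
depth: at $d = 10^4$ a single $\hat\psi$ has a standard error of roughly
0.004 at $\psi = 0.5$ and 0.0004 at $\psi = 0.996$, so near-constitutive
exons are recovered to three decimals while mid-range exons carry visible
single-draw noise; accuracy claims in the tests are therefore stated on mean
error where the single-draw noise exceeds the claimed bound.

```{r psi-demo}
estimate_psi(500L, 480L, 0L)          # constitutive exon, zero exclusion
jc <- simulate_junction_counts(sim_config(seed = 42, psi_true = 0.996,
                                          depth = 10000L))
estimate_psi(jc$I5, jc$I3, jc$X)
```

## Truncation-consequence rules

A variant is called truncating by mechanism, not annotation:

* **Nonsense / frameshift.** Coding substitutions that create a stop, and
  coding indels whose length change is not a multiple of 3, truncate. The
  protein change is obtained by re-translating the mutated CDS and reported
  in the compact `p.E15193GfsX8` style (first divergent residue, its mutant
  replacement, and the 1-based offset of the new stop), matching the
  nomenclature commonly printed for such lines rather than the three-letter
  `fsTer` dialect.
* **Splice acceptor (-1/-2): exon skipping.** The verdict is purely
  phase-based: skipping truncates iff the exon's coding length is not a
  multiple of 3. In-frame skips that would create a novel stop at the new
  junction are still called non-truncating -- the rule is phase-only by
  design -- with a note in the call's detail text.
* **Splice donor (+1/+2): intron retention.** The retained-intron CDS is
  translated in silico from the canonical start. A stop before the canonical
  stop is a premature termination codon (truncating); a stop-free in-frame
  intron reading is a read-through, i.e. a pure insertion (non-truncating).
  This branch exists because retention is *not* always truncating,
  especially where introns are short and in frame.

Variants touching both a splice dinucleotide and adjacent coding bases are
classified by the splice model (tie-break recorded in the output). Indels
are normalized by trimming shared suffix then prefix down to a one-base
anchor; full repeat-aware left-alignment against the genome is not attempted
-- the synthetic variants have a single encoding, and real pipelines
normalize upstream. In-frame indels are never truncating under the stated
dispatch even when re-translation would disagree; the detail text says so.

## NMD from allelic imbalance

In a heterozygote both alleles are transcribed equally, so the surviving
mutant transcript fraction is estimated by the mutant:wild-type read ratio
$r$ in amplicon sequencing across the variant. Reads are assigned by exact
match to 21-nt discriminating windows centered on the variant (configurable
half-width; exact matching is adequate for ~100 bp amplicons, so no
realignment is attempted); reads matching neither or both windows are
ambiguous and excluded. We report $100r$ (percent of wild-type) and
$100(1-r)$ (percent degraded), with a 95% interval obtained by transforming
the Wilson score interval on $p = r/(1+r)$. The classified-read floor
defaults to 100 for synthetic work; targeted assays typically use 600 to
10,000 reads, and the generator's default of 10,000 reads at true
$r = 0.225$ with 0.1% base error reproduces that regime. Replicates are
pooled by summation before estimation (the default; an average-based pooling
was considered and rejected since the replicates are exchangeable reads).

Isoform class abundance (internal-promoter isoform vs full-length) is
compared with a length-normalized density ratio
$(c_a/\ell_a)/(c_b/\ell_b)$ over isoform-specific regions, the count-based
analogue of a qPCR ratio.

## Internal-promoter detection

Read accumulation immediately upstream (5', strand-aware) of an internal
exon is the promoter signature. For each internal exon we score the
`window_size` bases (default 500) of the upstream intron adjacent to the
exon's acceptor edge -- at *higher* genomic coordinates for minus-strand
genes -- as

$$\text{fold} = \frac{\text{mean window depth}}{\text{median intronic depth} + 1},$$

with the per-gene intronic median as background (absorbing library-depth
differences) and a pseudocount of 1 guarding empty tracks. Windows with
fold $\ge$ 5 are called. The original observation was made by eye; the
window/pseudocount/threshold triple is this package's formalization, all
three configurable, and declared rather than fitted. Epigenomic support
(DNase accessibility, H3K4me3) is annotated as binary half-open interval
overlap with supplied BED peaks -- qualitative evidence, so no
coverage weighting.

Below a mapped TSS, the internal initiator is the first ATG scanning from
the TSS toward the exon whose distance $d$ to the exon's 5' edge satisfies
$d \bmod 3 = $ exon phase, so that translation runs in frame into the exon;
`aa_offset` counts the complete codons between the ATG and the exon
(7 codons for the zebrafish window the generator reproduces). Kozak-context
ranking was considered and not implemented: the biological claim needs only
frame compatibility, and a context score would add an unvalidated dial.

## Positional cohort analysis

Truncating variants are classified N or C relative to the promoter boundary
(default aa 14,760, *inclusive* on the C side, per "from aa 14,760
onwards"); variants in the Novex-3-exclusive terminal exon are excluded from
C:N ratios but retained for prevalence comparisons, since that exon belongs
to a minor isoform whose truncation is expected to be benign. Cohort
prevalences are compared with a pooled two-proportion z-test, two-sided,
without continuity correction (the correction is exposed as a flag; the
degenerate all-zero table returns p = 1). The published cohort p-values
cannot be recomputed here because the underlying cohorts are external; the
test itself is verified against the 1-df chi-square identity
$z^2 = \chi^2$ to $10^{-9}$.

## Guide design

Candidate guides are every 23-mer window, on either strand, whose final two
bases are GG (20-nt protospacer + NGG PAM); overlapping candidates are all
reported, with no greedy suppression. Uniqueness is exact 23-mer matching
over both genome strands -- the "single genome match" criterion -- with no
mismatch-tolerant off-target scoring, and the full 23-mer including the PAM
must match (the stricter of the two readings). Ranking prefers unique
sites, then protospacers beginning GG (T7 transcription), then genomic
position, stably.

## The synthetic gene and what the tests do (and do not) show

`make_toy_gene()` builds a plus-strand "mini-titin": 12 exons by default
(45-120 coding bases each), a clean CDS (ATG start, single terminal stop,
no internal stop), GT..AG introns, an internal-promoter intron whose last
110 bases contain exactly one ATG planted in frame ~7 codons upstream of the
designated exon (default exon 9), and a Novex-3-role minor isoform sharing
exons 1-2 and ending in its own exclusive terminal exon inside intron 2.
`mirror_gene()` reflects the whole construct onto the minus strand;
strand-symmetry tests require every downstream call to be invariant under
this reflection. Default study conditions: junction depth 10,000; NMD ratio
0.225 over 10,000 reads at 0.1% base error; coverage background 10x with
10-fold promoter accumulation over a 500 bp window; cohorts of 250/400/1500/199
subjects with C-side mixes echoing the published ratio structure (30:1-like
for end-stage disease down to N-only for athletes). Scale choices (a ~1 kb
CDS, kilobase introns) keep the full suite within minutes on one core while
exercising every code path; they are miniatures, not downsampled real data.

What the generator does *not* emulate: non-uniform coverage within exons,
PCR duplicates and UMIs, indel sequencing errors, realistic base-quality
profiles, allele-specific transcription, splice-site strength, or NMD escape
rules (e.g. last-exon effects). Passing tests therefore demonstrate the
correctness of the estimators and rules under their stated models, not
robustness to those real-data artifacts.

## Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; GFF/VCF/BED
  1-based conventions are converted at the I/O boundary only.
* PSI with every junction absent, or below the read floor, is a no-call;
  raising the floor can only remove calls (tested monotonicity).
* A zero wild-type read count makes the NMD ratio undefined (error), not
  infinite; low but nonzero coverage flags a warning instead.
* Weighted medians over run-length coverage reproduce the per-base
  expansion exactly, including zero-depth gaps.
* Intron windows shorter than `window_size` are truncated and flagged.
* Ranking and summaries are stable under input permutation; ties are broken
  by explicit, documented keys.

## Known limitations

Orthologous amino-acid positions are projected through a supplied exon-level
interval map with linear interpolation -- cross-species alignment is out of
scope, so the map's quality bounds the projection's. The acceptor rule is
phase-only and the in-frame indel rule is category-only, by design; both
record their re-translation disagreements in detail text rather than
changing the verdict. Compound heterozygotes and multi-allelic records are
processed per alternate allele with no phasing.
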