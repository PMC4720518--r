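# cronoscan

Truncating variants in Titin (*TTN*; zebrafish *ttna*) cause cardiomyopathy
and skeletal myopathy with a strong positional pattern: truncations in the
C-terminal two-thirds of the protein (from amino acid 14,760 of the human
meta-transcript onwards) dominate severe disease, while N-terminal
truncations are comparatively tolerated. An internal alternative promoter
(the *Cronos* promoter, in the intron upstream of zebrafish exon 116 /
human exon 240) producing a C-terminal isoform can explain the asymmetry.

`cronoscan` implements, as a tested R package plus a set of analysis
scripts, the computational procedures behind that model:

* **PSI quantification** from exon–exon junction reads:
  ψ = (I5 + I3) / (I5 + I3 + 2X), with a read-sufficiency no-call filter
  (denominator ≥ 15 by default), per-exon medians across samples, and
  constitutive amino-acid tallies (ψ > 0.9).
* **Truncation-consequence calling**: nonsense and frameshift truncate;
  splice-acceptor (−1/−2) variants truncate only if the skipped exon's
  coding length ≢ 0 (mod 3); splice-donor (+1/+2) variants truncate only if
  in-silico translation of the retained intron hits a premature stop.
  Protein changes in `p.E15193GfsX8`-style nomenclature.
* **NMD estimation** from allelic imbalance in heterozygote amplicon reads:
  ratio r = mutant/wild-type, percent degraded = 100(1 − r), Wilson-based
  95% interval; plus length-normalized isoform abundance ratios.
* **Internal-promoter detection**: fold = mean depth of the 500 bp
  upstream-intron window over (median intronic depth + 1), threshold 5,
  strand-aware; BED peak annotation; in-frame internal initiator ATG search.
* **Positional cohort analysis**: N/C classification against the boundary
  (aa 14,760, inclusive C side), Novex-3 exclusion, C:N ratio summaries and
  a pooled two-proportion z-test.
* **Guide design**: both-strand 23-mer protospacer+NGG scan, exact
  genome-uniqueness counting, 5'-GG (T7) prioritized ranking.
* **Synthetic data**: a seeded generator for every consumed data type
  (miniature Titin-like gene with internal-promoter intron and
  Novex-3-role isoform, junction counts, heterozygote amplicons, coverage
  tracks, cohort tables), so the whole pipeline runs without downloads.

## Worked example

```r
library(cronoscan)

# PSI of a constitutive exon: zero exclusion reads
estimate_psi(500L, 480L, 0L)
#> PSI = 1.000 (denominator 980)

# NMD from a simulated heterozygote amplicon (true mutant:wild-type 0.225)
cfg <- sim_config(seed = 3, nmd_ratio_true = 0.225, nmd_n_reads = 10000L)
amp <- simulate_het_amplicon(cfg)
estimate_nmd(assign_reads(amp$reads, amp$ref_window, amp$alt_window))
#> mutant:wild-type ratio 0.237 (95% CI 0.225-0.249), 76.3% degraded, n=9810
```

The ratio says the mutant transcript survives at ~24% of wild-type — about
76% of it is removed by nonsense-mediated decay, squarely in the 20–25%
band expected for these truncations.

The numbered scripts under `analysis/` run the full chain on the synthetic
gene and write tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

`analysis/05_promoter.R`, for instance, prints the promoter scan

```
promoter scan (window 500 bp, pseudocount 1, threshold 5):
 exon_index window_mean_depth background_depth fold_score peak_h3k4me3_synthetic
          9           100.168               10   9.106182                   TRUE
internal initiator: ATG at 4478, 7 codons upstream of exon 9 (in frame)
```

— the designated exon (and only it) is called, with the in-frame initiator
methionine found 7 codons upstream, mirroring the zebrafish geometry; and
`analysis/06_cohort.R` classifies the six engineered-line positions
(1697, 3048, 9693 vs 17996, 21215, 32003) as 3 N / 3 C against the 14,760
boundary.

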