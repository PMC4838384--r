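# vlincCAGE

Quantification and functional annotation of very long intergenic
non-coding RNAs (vlincRNAs) from 5'-capped tag data.

## The problem

VlincRNAs are intergenic transcripts of 50 kb and more (median ~83 kb).
Their 5' ends are imprecise and often buried in LTR retroelements where
5'-tag reads align poorly, so the classical CAGE practice of counting
tags around the transcription start site under-detects them. This
package implements the *internal* counting strategy — strand-specific
5'-tag counts across the whole transcript body after masking gene exons
and rRNA repeats, exploiting post-transcriptional recapping — and the
systems-level analyses built on top of it:

* RPKM-style normalization per kilobase of masked length and per 1 M
  (genes) / 100 M (vlincRNAs) informative reads:
  `raw / (informative · length) · 10⁹` or `· 10¹¹`;
* promoter / LTR / transcription-factor / distal annotation of vlincRNAs;
* standalone vlincRNA **gene** construction: a vlincRNA is standalone
  when each side has no same-strand gene within 50 kb or all such genes
  are separated from it by an insulator element lying wholly in the gap;
  standalone transcripts merge strand-specifically into genes;
* neighbor co-expression: vlincRNA–gene and gene–gene pairs classified
  into four configurations (same-strand upstream/downstream,
  opposite-strand head-to-head/tail-to-tail) and eight distance bins,
  summarized by two-stage median Spearman correlations, stratified by
  insulator separation;
* cancer/pluripotency statistics centred on **RMECN** — the ratio of a
  vlincRNA's maximum expression across cancer samples to its maximum
  across normal samples — with a label-permutation test, tag-mass
  fractions, top-N class enrichment, and differentiation-time-course
  trend tests;
* miRNA validated-target anti-correlation profiling and pluripotency-TF
  (OCT4/SOX2/NANOG) correlation and peak-enrichment analyses;
* a two-level GO enrichment: per-vlincRNA term lists from correlated /
  anti-correlated gene sets (|ρ| ≥ 0.35, unadjusted p < 0.05), then
  subset-versus-background enrichment over those custom annotations with
  BH-FDR control;
* a synthetic-data generator (Gaussian copula over log-normal marginals,
  planted rank correlations, 5'-peaked tag emission) so the complete
  pipeline runs and validates itself with no downloads.

Written for computational RNA biologists working with CAGE-style
compendia (FANTOM-type alignments, ChromHMM promoter/insulator tracks,
RepeatMasker repeats, ChIP-seq peaks, miRTarBase-style target lists).

## Worked example

```r
library(vlincCAGE)
res <- runPipeline(simulationConfig(seed = 1), outDir = tempfile("vlinc"))
cat(pipelineReport(res), sep = "\n")
```

Abridged output of exactly this call:

```
vlincCAGE pipeline report
seed: 1  config: 0064b8bd

== standalone designation ==
  far_both_sides: 58
  far_one_insulator_other: 8
  not_standalone: 14
  vlincRNA genes after merge: 66

== neighbor correlation (median rho; all-stratum cells) ==
  pair_type         configuration     bin median_rho n_pairs
 vlinc_gene         same_upstream   0-1kb 0.38632954       9
 vlinc_gene       same_downstream   0-1kb 0.40655738       9
 vlinc_gene opposite_tail_to_tail   0-1kb 0.35604335      15
 vlinc_gene opposite_head_to_head   0-1kb 0.43312031      13
 vlinc_gene       same_downstream 30-40kb 0.33653793       4
  gene_gene         same_upstream   0-1kb 0.15437622      16
  gene_gene       same_downstream   0-1kb 0.15437622      16
  gene_gene opposite_tail_to_tail   0-1kb 0.02325646      16
  gene_gene opposite_head_to_head   0-1kb 0.11858850      20

== class metrics ==
  median RMECN LTR 1.784 nonLTR 0.947 ratio 1.884
  label permutation p = 0.01493
  max-in-cancer Fisher p = 0.0576
  top-N cancer enrichment p = 0.201 (k = 10, expected 8.0)
  time-course trend: decrease (p = 0.1915684)

== regulators ==
  miRNA: median real rho -0.383, random 0.005, KS p 7.77e-05
  TF flank enrichment p = 0.004975

== GO enrichment (top rows) ==
     term     p_raw p_adj ExpCount Count Size
 GO:L2_28 0.2250000     1    0.225     1    1
 GO:L2_14 0.4038462     1    0.450     1    2
 GO:L1_02 1.0000000     1    0.225     0    1
 GO:L2_13 1.0000000     1    0.225     0    1
 GO:L2_19 1.0000000     1    0.225     0    1
```

Reading it: the designation block partitions the 80 simulated vlincRNAs
into the standalone clearance categories plus the blocked ones, and
strand-specific merging yields the 66 vlincRNA genes. The correlation
rows show the planted contrast — vlincRNA–gene pairs correlate far more
strongly with their adjacent neighbors (median ρ 0.36–0.43 at 0–1 kb)
than gene–gene controls do (0.02–0.15). The RMECN block recovers the
simulated 2× LTR boost in cancer/stem samples (median ratio 1.88 at
this small fixture; the dedicated 600-vlincRNA acceptance fixture pins
it much tighter), the miRNA block recovers the planted −0.4 target
coupling (real −0.383 versus random 0.005, one-sided KS p = 7.8e-05),
and the GO block lists the top enrichment rows of the LTR subset — here
an unremarkable table, as nothing is planted at GO level in the default
world.

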