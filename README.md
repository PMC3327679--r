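# loopomics

Integrative analysis of matched **mRNA, miRNA and protein** microarray data
from a two-condition design (a drug-sensitive cell line vs its resistant
derivative), culminating in the enumeration and classification of
**miRNA–mRNA–protein regulatory loops**.

Expression changes of a miRNA and one of its predicted targets can combine in
only a few ways. Writing $s_{\text{miR}}, s_{\text{mRNA}}, s_{\text{prot}} \in \{+1,-1\}$
for the signs of the three log2 fold changes (resistant vs sensitive), the
package classifies each triplet over a predicted target relation as:

* **type A (coherent)** — $s_{\text{mRNA}} = -s_{\text{miR}}$ and
  $s_{\text{prot}} = s_{\text{mRNA}}$: the miRNA degrades the mRNA and the
  loss propagates to the protein;
* **type B (incoherent)** — $s_{\text{mRNA}} = s_{\text{miR}}$ and
  $s_{\text{prot}} = -s_{\text{miR}}$: translational repression without decay;
* **type C (incoherent)** — all three co-directional: the expression pattern
  does not support a miRNA action on the target;
* **unclassified** — the remaining pattern, which the taxonomy does not
  define.

Upstream of the classifier the package provides the full per-layer analysis:
normexp background correction, lowess and rank-invariant two-channel
normalization, a variance-stabilizing (calibrated arsinh) transform for
single-channel intensities, the 60% below-background signal filter, dye-swap
aware technical-replicate collapse, empirical-Bayes moderated t-statistics
with Benjamini–Hochberg FDR control

$$\tilde s^2 = \frac{d_0 s_0^2 + d\,s^2}{d_0 + d}, \qquad
  t = \frac{\widehat{\log_2\mathrm{FC}}}{\sqrt{\tilde s^2\,(1/n_1+1/n_2)}},$$

hypergeometric gene-set enrichment, anti-correlation pairing of DE miRNAs
with predicted targets, the mRNA–protein core intersection, genomic miRNA
clustering (< 1000 kb), and Cytoscape SIF export of the post-transcriptional
and pre-translational networks. A synthetic three-layer generator with
planted ground truth makes every stage testable end to end.

## Worked example

Generate a synthetic study at the default design — 10,000 gene probes, 800
miRNAs, a 725-antibody panel, 3 biological × 4 technical replicates with dye
swaps, planted loops 38/34/28 by type at |log2FC| = 1.5 — and run the whole
pipeline:

```r
library(loopomics)
m <- demo_pipeline(seed = 1)
print(m$loops)
#> loop_table: 99 loops (A=37 coherent, B=34, C=28 incoherent, 0 unclassified)
m$recovery$per_type
#>      loop_type planted called
#> 1            A      38     37
#> 2            B      34     34
#> 3            C      28     28
#> 4 unclassified       0      0
unlist(m$row_counts)
#>     features_in   features_kept         de_mrna        de_mirna      de_protein
#>           10000            9546             697              52             348
#>      pair_links      core_genes           loops enrichment_rows  mirna_clusters
#>             211             115              99              16               2
```

Reading: of 10,000 probes, 9,546 survive the below-background filter; the
three layers call 697 / 52 / 348 differential features (700 / 47 / 336 were
planted); 211 predicted miRNA–target pairs have both ends differential; 115
genes are altered at both the mRNA and protein level; and 99 of the 100
planted loops are recovered with the correct type, none spurious. The per-layer
model summaries show the moderation at work:

```r
summary(m$de$protein)
#> Differential expression, protein layer
#>   725 features, 725 tested; FDR <= 0.1, |logFC| >= 0
#>   up: 160  down: 188  ns: 377
#>   prior: d0 = 24.42, s0_sq = 0.06019
```

A single sign pattern can be queried directly — the classic configuration of
an up-regulated miRNA whose target drops at both levels:

```r
classify_loop(1, -1, -1)
#>   loop_type coherence
#> 1         A  coherent
```

All outputs (normalized matrices, per-layer DE tables, enrichment tables,
pair links, core genes, the loop table with per-type counts, SIF networks and
a YAML manifest) are written under the run directory; `inst/exec/loopomics`
wraps the same functions as a command-line tool with `simulate`, `run`,
`demo` and `classify-loop` verbs.

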