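# txlandscape

Analysis of the bacterial primary transcriptome and translatome:
transcription start site (TSS) mapping from differential RNA-seq
(dRNA-seq), 5'-UTR and leaderless-mRNA classification, promoter −10/−35
architecture, and ribosome-profiling-based translation efficiency with
translational buffering — implemented as an R package plus a numbered
analysis workflow, validated end to end on synthetic data with planted
ground truth.

## The problem

In bacteria such as the antibiotic-producing actinomycetes, transcription
and translation are regulated independently: transcript abundance can rise
while ribosome occupancy stays flat ("translational buffering"), and a
large fraction of mRNAs start translation without a 5' leader. Dissecting
this requires (i) nucleotide-resolution TSS maps, from paired
TEX-treated/untreated 5'-end libraries (TEX degrades processed
5'-monophosphate RNAs, enriching primary transcripts), and (ii) matched
mRNA (RNA-seq) and ribosome-protected-fragment (RPF, Ribo-seq) counts
across growth phases.

The core quantities:

* **TSS calling** — cluster TEX+ 5'-end peaks within 100 bp, sub-cluster
  by positional standard deviation (sd < 10, n−1 divisor; e.g.
  sd(100, 114) = 9.9 keeps two peaks together, sd(100, 114, 128) = 14
  splits the third off), drop (sub-)clusters with < 3 reads, take each
  sub-cluster's maximum peak, prune close peaks, and require TEX− support
  within ±5 bp.
* **Classification** — primary (P) / secondary (S) within −500..+150 of a
  start codon, internal (I), antisense (A), intergenic (N); 5'-UTR < 9 nt
  → leaderless, > 150 nt → long leader.
* **Promoters** — TANNNT (−10) and NTGACC (−35) consensus hexamers,
  spacer length between them, promoter G+C, translation-initiation-region
  composition.
* **Expression / TE** — median-of-ratios normalization, expressed-gene
  cutoff from the secondary-metabolic reference set, differential flags
  (|FC| ≥ 2 and p < 0.05 in ≥ 2 phase contrasts, pooled-dispersion NB
  test), TE = (RPF + 1)/(mRNA + 1).
* **Buffering** — slope of ΔlogTE on ΔlogmRNA (0 = none, −1 = complete),
  16 × 16 = 256 combinatorial mRNA × RPF pattern groups, II/ID/DI/DD
  trend groups, and RPF subunit-stoichiometry ratios within operons.

A synthetic-data generator (`sim_config()`, `simulate_dataset()`) plants
all of these signals — TSS positions, promoter spacers, fold-changes, a
buffering slope, operon stoichiometries — so every stage can be checked
against known truth.

## Worked example

The analysis workflow is a sequence of thin drivers over the package:

```sh
Rscript analysis/01_simulate.R       # genome, profiles, counts -> results/data/
Rscript analysis/02_call_tss.R       # TSS calling + truth comparison
Rscript analysis/03_classify_annotate.R
Rscript analysis/04_promoters.R
Rscript analysis/05_expression_te.R
Rscript analysis/06_buffering.R
```

On the default configuration (seed 1, 50 genes, 100 kb) this prints,
among other things:

```
50 TSSs called from 97 nonzero TEX+ positions
vs planted truth (n = 50): precision = 1, recall = 1

5'-UTRs: median 46.5 nt; leaderless 24%, long leaders 12%
purine at +1: 92%

spacers 15-20 nt: 98% of 50
mean promoter G+C: 64.7% (genome-wide 71.9%)

expressed-gene cutoff (reference-set median at M): 148.5; expressed: 49/50

buffering slope by contrast (planted -0.5):
 contrast          r      slope  n
      M:T -0.8983712 -0.4939319 50
      M:L -0.9636636 -0.5235764 50
      M:S -0.9494150 -0.4749805 50

stoichiometry recovery (max relative error per operon):
 operon_id  rel_error
    op_atp 0.15250633
    op_rpl 0.06189769
```

That is: the caller recovers every planted TSS with no false positives;
the leaderless fraction and +1 purine bias match their planted rates
within binomial noise; planted promoter spacers are recovered on the
15–20 nt range; promoter G+C is depressed relative to the genome (the
planted AT-rich hexamers); the regression of TE changes on mRNA changes
recovers the planted buffering slope of −0.5 in every phase contrast; and
the 1:4 and 1:10:2:1:3:1:3:1 operon RPF ratios are recovered within
6–15% relative error. Per-stage tables land under `results/`.

The same pipeline runs from files alone (`read_fasta()`, `read_gff()`,
`read_bedgraph()`, `read_counts()` consume standard FASTA / GFF3 /
bedGraph / TSV), or in one call via `run_all()`, which writes a JSON run
manifest with versions, seed and all thresholds.

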