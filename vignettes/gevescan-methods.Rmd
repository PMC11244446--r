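---
title: "Detecting endogenized viral elements from the methylome: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting endogenized viral elements from the methylome: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gevescan)
```

# The problem

Some protists that methylate their own gene bodies — a 5-methylcytosine (5mC)
pattern otherwise familiar from plants and invertebrates — also carry large
genomic insertions derived from giant viruses (Nucleocytoviricota),
adintoviruses and related mobile elements. These insertions are kept
transcriptionally silent by dense cytosine methylation. The analytical
opportunity is a context split within the CpG dinucleotide: on actively
transcribed host gene bodies, methylation concentrates in the *symmetric
CGC/GCG trinucleotide family* (a CpG followed by C, equivalently preceded by
G on the other strand), while CG methylation *outside* that family
(`CG_other`, the "non-CGC/GCG" signal) marks silenced sequence —
transposable elements (TEs), silent promoters, and, most strikingly,
contiguous multi-kilobase blocks of endogenized viral DNA. `gevescan` turns
that contrast into an explicit, reproducible pipeline.

# Site model and context classification

Per-cytosine methylation calls carry read counts $(m_i, n_i)$ — methylated
and total reads — at a cytosine on a specific strand. Every level the
package reports is the **weighted methylation level**

$$\bar{L} \;=\; \frac{\sum_i m_i}{\sum_i n_i},$$

the pooled-count estimator, rather than a mean of per-site fractions. It is
robust to coverage variation and is exact for pooled binomial sampling; the
generator's overdispersed coverage (negative binomial) deliberately
stresses the difference between the two estimators.

A site's context is read on its own strand from the flanking bases
$(u, C, d_1, d_2)$ at offsets $-1, 0, +1, +2$ (minus-strand sites are read
on the reverse complement):

* CG iff $d_1 = G$; CHG iff $d_1 \neq G$ and $d_2 = G$; CHH otherwise;
* within CG, `CG_sym` iff $d_2 = C$ (mCGC) **or** $u = G$ (GmCG), else
  `CG_other`;
* `ambiguous` when an `N` or a chromosome edge leaves the class
  undecidable. A flank is only "required" if its value could change the
  outcome: `NCGC` is still `CG_sym` because the downstream C decides alone.

`CG_sym`/`CG_other` partition all fully resolved CG sites, and the family is
closed under strand complementation — both properties are exercised as
tests. Sites are scored per strand; no CpG-pair merging is performed, since
family membership is strand-symmetric by construction while the flanks
differ. CHG/CHH levels are computed only as QC (methylation in this system
is expected to be CG-confined).

# Windowed segmentation into hypermethylation islands

The island detector reproduces, as an algorithm, what was originally a
visual demarcation of non-CGC/GCG methylation blocks:

1. **Track** (`window_track`): tile each chromosome with fixed windows
   (default 10 kb) and score each window with the pooled `CG_other` level.
   Windows with fewer than `min_sites_per_window` (default 10) sites are
   *missing*: they never seed an island but are bridgeable, so assembly
   gaps do not split real blocks.
2. **Calling** (`call_islands`): flag windows with level $\ge \theta$;
   merge runs of flagged windows across at most `max_gap_windows` (default
   1) unflagged-or-missing windows; discard merged spans shorter than
   `min_island_bp` (default 10 kb, one window). $\theta$ defaults to 0.4,
   the midpoint between the ~0.2 `CG_other` background and the ~0.7–0.9
   hypermethylated mode; no numeric cutoff is inherited from the
   literature, so $\theta$ is an explicit, documented parameter.
3. **Refinement** (`refine_boundaries`): from each island edge, extend
   outward in `subwindow_bp` (default 1 kb) steps while the adjacent
   sub-window's pooled level stays $\ge \theta$; then trim inward while the
   edge sub-window falls below $\theta_{site}$ (default $= \theta$) or has
   no sites. The greedy rule is deterministic and idempotent — refining a
   refined island changes nothing — which is why it was preferred over an
   HMM: the original demarcation was manual, and the simplest reproducible
   formalisation is also the most testable one. Refined islands shorter
   than `min_island_bp` are dropped, which in practice removes fragments
   that collapse onto a single methylated TE.

Raising $\theta$ can only shrink the total island footprint
(monotonicity), island calling is invariant to input record order, and
identical inputs give byte-identical outputs; all three are asserted in the
test suite.

On a clean background (islands at $p = 0.8$ versus background `CG_other`
at $p = 0.2$, coverage 10) the detector recovers $\ge 95\%$ of implanted
island bases while touching $\le 1\%$ of the background. The full synthetic
genome is deliberately harder: its background contains genuinely
hypermethylated 1–3-kb features (young TEs, silent-gene promoters), so a
borderline window occasionally enters an island. End-to-end performance is
therefore summarised by the base-level Jaccard index against ground truth
($\ge 0.9$ at defaults), not by per-window purity.

# Island classification

Classification is a first-match decision list over gene-architecture
features and marker-gene evidence. Genes are assigned to an island when at
least half of their span overlaps it (a symmetric, order-independent rule).
Features: mean exons per gene, gene density per 10 kb, island length, TE
base fraction (interval union), and marker hits per class from the
intersection of the domain-hit table with a shipped, editable marker
catalog (`inst/extdata/marker_catalog.tsv` — VLTF3, A32 ATPase, D5
primase and NCLDV major capsid for giant viruses; DNA polymerase B,
capsids and Dam methylase for adintoviruses; tyrosine recombinase and the
Plavaka transposase for the giant tandem repeats). Rules, in order:

1. any giant-virus marker **and** mean exons/gene $\le 2$ → `GEVE`;
2. any adintovirus required marker **and** length $\le 60$ kb →
   `adintovirus` (complete adintovirus insertions run around 30 kb);
3. any Plavaka/tyrosine-recombinase marker → `plavaka`;
4. TE fraction $\ge 0.6$ with no viral marker of any kind → `te_rich`;
5. otherwise `unclassified`.

The thresholds are declared approximations — the original discrimination
combined homology searches with manual curation — and every evaluated rule
is logged per island. Islands lacking both marker sets are provably
insensitive to the relative order of rules 2 and 3.

# Silencing and reactivation

* **Promoter methylation**: the promoter is 1 kb upstream of the TSS on
  the gene strand (a declared default; the source analysis does not state
  one), truncated at contig edges rather than dropped. All CG contexts are
  pooled. Genes with fewer than 5 covered promoter sites are excluded;
  deciles are assigned by rank with ties broken by gene id, so the
  assignment is stable and reproducible.
* **Decile × DE response**: a gene is differentially expressed iff
  `padj < 0.01` (strict, matching the upstream FDR convention) and
  $|\log_2 FC| > 0$ (no fold-change floor by default — only the FDR is
  stated upstream); direction is the sign of the fold change.
* **Reactivation categories**: `Broad` if any baseline (control or
  developmental) condition reaches 1 TPM; else `Aza` if any
  demethylating-treatment condition does; else `No`. All baseline-labelled
  conditions count — the alternative reading (a subset of developmental
  time points) is not adopted.
* **Domain enrichment**: two-sided Fisher exact test per domain under the
  minimum-likelihood convention — the sum of hypergeometric point
  probabilities $\le$ the observed table's probability, with a $10^{-7}$
  relative tolerance absorbing floating-point ties — with
  Benjamini–Hochberg q-values across domains (raw p retained). The default
  background is the in-set genes plus all genes overlapping no island.

# The synthetic methylome

`simulate_methylome()` generates the study conditions the package is
validated under. Defaults (all configurable via `sim_config()`):

| Quantity | Default | Notes |
|---|---|---|
| genome | 2 Mb chromosome + 120 kb unplaced contig | exercises the placement census |
| spike-ins | 20 kb unmethylated + 3 kb methylated contig | conversion QC |
| host `CG_sym` / `CG_other` | 0.70 / 0.20 | gene-body context split |
| island methylation | 0.80, all CG contexts | uniform hypermethylation |
| TE methylation | $0.9 - 0.02\,d$ for divergence $d$ | young TEs most methylated |
| host exons/gene | Poisson, mean 7.2 | intron-rich host architecture |
| island genes | 1–2 exons, ~2 kb pitch | intron-poor, gene-dense |
| coverage | NB(mean 20, size 5) | overdispersed |
| conversion error | 0.005 | false-methylation floor |
| treatment factor | 0.33 | global CG ~0.45 → ~0.15 |

Implanted islands (three GEVE, two adintovirus, two Plavaka on the
chromosome, plus one GEVE on the unplaced contig; 20–80 kb) share the host
base composition, so detection can only come from the methylation signal,
never from sequence. Island marker genes receive the catalog domains;
roughly a third of the remaining GEVE genes carry a JmjC domain, giving
the enrichment test a realistic positive. Promoter methylation is a
continuum (active hosts 0.02–0.40, silent hosts 0.50–0.85, island genes
0.65–0.95, TE-ORF genes from their TE), and the probability of
up-regulation under treatment increases deterministically with the true
promoter-methylation rank via a low-discrepancy sequence — so the decile
response is reproducibly, strictly increasing in the top deciles without
depending on binomial luck. Reactivated ("Aza") fractions default to 0.26
(GEVE), 0.32 (adintovirus), 0.20 (Plavaka) and 0.50 (TE ORFs).

What the generator does **not** emulate: sequence homology between viral
insertions (detection here is purely epigenomic; a homology-based detector
would need different truth), realistic TE sequence models, read-level
artifacts (mapping bias, PCR duplicates), partial methylation haplotypes,
and biological replicate variance beyond resampling noise. Passing the
end-to-end tests therefore demonstrates the pipeline's statistical
machinery and its behaviour under the stated signal structure — not
performance on any real genome.

# Numerical and degenerate-input choices

* Internal coordinates are 0-based half-open everywhere; 1-based formats
  (GFF3, CGmap, RepeatMasker) are converted only at parse/write
  boundaries.
* CGmap strand: Watson base `C` → plus, `G` → minus, per the upstream
  caller's format.
* Zero-coverage sites are dropped at parse time and counted; empty pools
  give `NA` levels flagged by zero site counts, never division by zero.
* Multi-isoform genes use the longest mRNA's exons (ties: first in file
  order) — the isoform convention is not stated upstream, so it is an
  explicit, configurable choice here rather than a guess.
* Deciles: `ceiling(rank * 10 / n)` over the stable (level, gene id)
  order.
* Genes shorter than the body bin count are skipped (with a counter) in
  metagene profiles; a site lands in exactly one half-open bin.
* Refinement trimming always leaves at least one sub-window, so a refined
  interval is never empty; the length filter then decides survival.

# Problem sizes

The shipped validation runs on the 2-Mb default genome (~215,000 CG
sites, four methylome replicates), one complete pipeline execution, and a
smaller 0.4-Mb configuration for determinism and file round-trip checks.
These sizes give every estimator thousands of informative sites per
stratum while keeping a full test run around a minute.

# Known limitations

* Island refinement is greedy at a fixed 1-kb step; boundary error is
  bounded by about one sub-window per edge, and hypermethylated features
  directly abutting an island (a young TE at the fence) can be annexed.
* The classifier is rule-based; it will not separate a degenerate GEVE
  that lost all marker genes from an unclassified hypermethylated block.
* Fisher enrichment treats genes as exchangeable; gene length or
  GC-related detection bias is not modelled.
* The treatment comparison summarises replicate global levels (mean and
  range); it is a QC-grade comparison, not an inferential test.
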