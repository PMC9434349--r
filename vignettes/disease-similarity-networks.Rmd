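---
title: "Gene-based disease similarity networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based disease similarity networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disnet)
```

## The model

`disnet` treats a disease as the set of genes curated as associated with
it. Two diseases are similar to the extent that their gene sets overlap,
measured by the Jaccard index
$J(a,b) = |G_a \cap G_b| / |G_a \cup G_b|$ — the fraction of shared genes
among all genes implicated in either disease. The package builds the
weighted, undirected network whose nodes are disease terms and whose edge
weights are these similarities. Pairs sharing no gene get **no edge**
rather than a zero-weight edge: absent pairs carry information (most
disease pairs share nothing), and spurious zero-weight edges would distort
the modularity null model downstream.

Communities of mutually similar diseases are found by maximising weighted
modularity with a resolution parameter $\gamma$:

$$Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} - \gamma\,\frac{s_i s_j}{2m}\right]\delta(c_i, c_j),$$

where $w_{ij}$ are Jaccard weights, $s_i$ node strengths and $2m$ the
total strength. $Q$ compares the weight inside communities with its
expectation under a strength-preserving random null; $\gamma$ scales the
null term and thereby the granularity of the optimum (larger $\gamma$,
more and smaller communities). The default is $\gamma = 1$, the classical
modularity; it is exposed in every interface for sensitivity analyses.

The gene sets of a community are summarised three ways, mirroring how the
downstream biology is read: the **union** over member diseases, the
**pairwise overlaps** between communities, and the **exclusive** genes
found in exactly one community's union, with the exclusive proportion
$100\,|excl_c|/|union_c|$ reported to two decimals. The union reading of
"genes of a community" is the only one consistent with an exclusivity
complement: exclusive sets partition the genes that communities do not
share, and the coverage identity
$\bigcup_c excl_c \,\cup\, \bigcup_{c<c'} overlap_{cc'} = \bigcup_c union_c$
is enforced by tests.

Community-exclusive gene sets are tested for pathway over-representation
with the one-sided hypergeometric upper tail
$P(X \ge k)$ for $X \sim \mathrm{Hyp}(N, K, n)$, evaluated in log space,
with Benjamini–Hochberg step-up control of the false discovery rate at
0.05. Correction is applied **per source tag** (e.g. GO molecular
functions and Reactome pathways separately), matching how per-source
enrichment listings are conventionally reported; a `correctionScope =
"global"` switch pools all sources. Published analyses of this kind often
use the g:Profiler service, whose default g:SCS correction differs from
BH; adjusted p-values from that service are therefore comparable only in
spirit, not digit by digit.

Rare de novo loss-of-function variants are mapped onto community gene
sets. The filter keeps variants that are flagged de novo, of consequence
class stop gain, stop loss, frameshift deletion or frameshift insertion
(VEP vocabulary, normalised by the package), with genotype quality ≥ 99,
minor allele frequency < 1%, parental reference-call fraction > 95% and
parental variant-call fraction < 1%. Community counting is
**overlapping**: a gene can belong to several communities' unions, so a
variant can count toward several communities and the per-community shares
need not sum to 100. The share denominator is all filtered variants,
including those mapping to no community.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `minScore` | 0 | association-score cutoff in [0,1]; 0 keeps unscored records |
| `resolution` ($\gamma$) | 1 | granularity of modularity optimisation |
| `seed` | 42 | drives all optimiser randomness |
| `nRestarts` | 25 | independent optimiser starts (first from singletons, rest from random partitions) |
| `gqMin` | 99 | genotype-quality floor |
| `mafMax` | 0.01 | rarity ceiling (exclusive) |
| `parentRefMin`, `parentAltMax` | 0.95, 0.01 | parental call-fraction thresholds |
| `minSize`, `maxSize` | 3, 2000 | pathway size bounds after background intersection (conventional ORA bounds) |
| `fdrThreshold` | 0.05 | significance level on adjusted p-values |
| `minVariantCount` | 2 | recurrence threshold for gene ranking |

The default enrichment background is the set of all genes appearing in the
loaded association table — the universe from which the disease gene sets
were drawn; a custom gene list can be substituted.

## Numerical and algorithmic choices

**Leiden implementation.** The optimiser alternates queue-based local
moving (candidate targets: neighbouring communities, the current one, and
an empty community), refinement, and graph aggregation, until no improving
move. Refinement uses deterministic greedy max-gain merging of singleton
nodes within their community — a deliberate deviation from the randomized
proportional merging of the original algorithm, bought for bitwise
reproducibility. Gains below $10^{-12}$ (in $Q$ units) are treated as
noise and do not trigger moves; ties go to the first community reaching
the maximal gain in scan order. Because single-node moves cannot cross
every energy barrier, the optimiser restarts 25 times — once from the
all-singleton partition, then from random partitions — and keeps the best
result; on a sweep of ~1,000 random graphs of up to 8 nodes this attains
the exhaustively verified optimum in every case. After convergence, any
community left internally disconnected is split into its connected
components, which can only increase $Q$ and yields the guarantee that
reported communities are connected. Community labels are canonicalised by
first appearance over nodes in sorted order, so relabelling or reordering
the input cannot change the output.

**Degenerate inputs.** Edgeless networks have undefined modularity and are
an error. Diseases with empty gene sets are excluded from the network (and
reported); isolated nodes are kept as their own singleton communities and
contribute nothing to $Q$. A single-edge network optimally merges both
endpoints ($Q = 0$; the singleton alternative scores $-0.5$).

**Hypergeometric and BH.** The upper-tail p-value is computed through the
log-space distribution function (`phyper(..., log.p = TRUE)`) for
stability at extreme tails; tests verify it against direct combinatorial
enumeration for every configuration with $N \le 30$ at $10^{-10}$. BH is
the standard step-up procedure; tests verify it against an independent
hand-written step-up reference.

**Consequence normalisation.** `frameshift_variant` is split into
deletion/insertion by ref/alt allele lengths. Rows lacking allele
information are classed as frameshift deletions (the commoner frameshift
class) and flagged in the filter report, so the choice is visible rather
than silent. Missing MAF passes the rarity filter — de novo calls often
lack a population frequency — and each such pass is counted in the report.
Missing genotype-quality or parental fields also pass their criteria,
because upstream de novo call sets are typically pre-filtered for exactly
these quantities; the thresholds re-apply whenever the fields exist.

## The synthetic model

The generators emulate the statistical structure the analysis assumes:
intra-community gene sharing exceeding inter-community sharing. Each of 3
communities owns a core pool of 300 genes; a shared pool of 100 and a
decoy pool of 500 are global. Each of 8 diseases per community samples 100
genes: 80% from its community core, 10% shared, 10% decoy. The 100
genes-per-disease scale was chosen once as a desk-size stand-in for
typical curated per-term gene counts; together with the pool sizes it
yields a clear Jaccard contrast (within-community pairs share mostly core
genes, between-community pairs only shared/decoy spillover). Planted
pathways draw at least 70% of their genes from one community's used core
genes; decoy pathways draw uniformly from all genes. Variant tables give
planted "hot" genes fixed counts, draw the remainder uniformly from a
weighted community mixture, use the published consequence-class mix for
rare de novo LoF SNVs (stop gain 43.32%, frameshift deletion 36.51%,
frameshift insertion 17.71%, remainder stop loss), and keep clean rows
strictly inside every filter threshold so that an optional contamination
fraction is what exercises the filters.

What the synthetic model deliberately does **not** reproduce: DisGeNET's
heavy-tailed gene-degree distribution, unevenness of curation depth across
diseases, real MAF spectra, or linkage between consequence class and gene.
Passing tests therefore demonstrate correctness of the machinery — exact
Jaccard computation, optimal community detection at small scale, correct
set algebra and test statistics, faithful filtering — not that any
particular biological community structure will be recovered from real
data, where annotation unevenness can over- or under-state similarity.

Generator purity: every generator is a deterministic function of its
config; sub-seeds are derived from the master seed per generator, so the
association table does not change when the variant generator is also
called.

## Problem sizes and determinism

The shipped tests run the exhaustive-partition oracle on graphs of up to 8
nodes (Bell(8) = 4,140 partitions), the planted-recovery check over 100
generator seeds at the 3×8-disease scale, and enrichment detection over
100 seeds; the full suite completes in about two minutes on one CPU. The
`runPipeline` report excludes timestamps, and all orderings are canonical,
so identical configurations produce byte-identical reports; permuting
input rows or relabelling disease ids changes nothing but the labels.

## Known limitations

- Modularity optimisation at desk scale is exhaustively verifiable; on
  large real networks the optimiser is a well-tested heuristic, not a
  proof of optimality.
- The exclusive/overlap decomposition treats every disease term equally;
  duplicate terms for the same condition (kept as separate nodes, as the
  merge-group annotation records) can inflate a community's union.
- Adjusted p-values are BH; results from services using other corrections
  will differ numerically.
- The parental call-fraction criterion is applied as read-level fractions
  when the fields exist; other operationalisations of "seen as reference
  in the parents" are possible and upstream-dependent.
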