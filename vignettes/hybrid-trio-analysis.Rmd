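---
title: "Expression-level dominance analysis of unreplicated hybrid-parent trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-level dominance analysis of unreplicated hybrid-parent trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridELD)
```

## The problem

When two species are crossed, a gene in the hybrid can express at the
mid-parent value (additively), like one parent only (expression-level
dominance, ELD), beyond both parents (transgressively), or indistinguishably
from both. Classifying every gene this way — and asking whether the
classification is inherited from F1 to F2 — is the standard analysis for
transcriptome studies of newly formed hybrids and allopolyploids. hybridELD
implements that analysis for the hardest common design: four *unreplicated*
pooled libraries (maternal parent P1, paternal parent P2, F1, F2), plus a
parallel small-RNA layer and miRNA–target coupling.

## The statistical model

**Exact two-library test.** With a single library per group there is no
within-group variance to estimate, so significance comes from the exact
conditional (Audic–Claverie) test. Under a common underlying rate, the count
$y$ in library 2 given the count $x$ in library 1 with library sizes
$n_1, n_2$ follows

$$p(y \mid x) = \left(\frac{n_2}{n_1}\right)^{y}
\frac{(x+y)!}{x!\,y!\,(1+n_2/n_1)^{x+y+1}},$$

which is a negative binomial with size $x+1$ and success probability
$n_1/(n_1+n_2)$; the package evaluates tails through `pnbinom`, which is
numerically stable for library sizes in the tens of millions. The two-sided
p-value doubles the smaller tail, with the observed point included in both
tails, and clips at 1.

Two consequences of that convention are worth knowing. First, the test is
*not* exactly symmetric in its argument order: the two orders differ by up
to twice the conditional point mass at the observation (the package fixes
the order per comparison, so results are deterministic). Second, the test
assumes Poisson sampling within a library. Biological overdispersion makes
it anticonservative — a known, unavoidable property of unreplicated designs
that users should weigh when interpreting mid-parent calls (see
*Limitations*).

**Multiple testing and the DE decision.** P-values are BH-adjusted per
comparison family. A gene is called differential when $q \le \alpha$
(default $\alpha = 0.001$ for genes) **and** its fold change strictly
exceeds 2 on pseudocount-shifted normalized counts: a fold change of
exactly 2 is not differential. The miRNA layer uses the small-RNA
convention $q < 0.05$ (strict) with median-of-ratios size factors.

**Twelve bins.** The three pairwise relations (P1 vs P2, hybrid vs P1,
hybrid vs P2), each GT/LT/NS, map to the canonical twelve bins:
additivity = {I, XII}, ELD toward P1 = {II, XI}, ELD toward P2 = {IV, IX},
transgressive up = {V, VI, VIII}, transgressive down = {III, VII, X},
all-NS = NO_CHANGE. Exactly 13 of the 27 possible triples are internally
consistent; the other 14 (for example hybrid above one parent and below
the other while the parents do not differ) are reported AMBIGUOUS rather
than forced into a bin, because silently mis-binning would corrupt the
inheritance counts downstream.

**Mid-parent additivity.** The MPV is the mean of the parents' normalized
counts. To keep the exact test applicable, the MPV is materialized as a
pseudo-library: per-gene round-half-even of the normalized mid-parent
count, at a pseudo-library size equal to the rounded mean of the two
*parents'* normalized library sizes (the pseudo-library is a mid-parent
construct, so the parents — not all four samples — define its depth). No
fold gate applies here: nonadditivity is a significance-only call, per the
convention of the field.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `fdr_gene` | 0.001 | BH threshold for gene comparisons (rule: $q \le$) |
| `fdr_mirna` | 0.05 | BH threshold for miRNAs (rule: $q <$, strict) |
| `fc_threshold` | 2 | fold gate, strict ">" |
| `min_fpkm_expressed` | 1 | FPKM at or above which a gene counts as expressed |
| `pseudocount` | 1 | added to normalized counts before log2 fold change |

The FPKM presence cutoff of 1 is the conventional detection floor for
bulk RNA-seq of this depth; the source analyses never state theirs, so it
is exposed rather than hidden.

## What the simulator states, and what a green test means

`simulate_trio()` generates the world the analysis assumes: per-gene
baseline abundance $\lambda \sim \mathrm{LogNormal}(\log 30, 1)$ in CPM
units, four libraries of $10^7$ fragments, NB counts with dispersion
$\phi = 0.05$ (variance $\mu + \phi\mu^2$; $\phi = 0$ gives Poisson), and
planted categories at fixed proportions: 30% conserved, 10% additive,
12.5% ELD toward each parent, 10% transgressive each way, and 3.75%
exclusive to each sample. Those proportions echo the shape reported for
hybrid fish livers — about a third of genes undifferentiated between the
parents, ELD genes roughly a quarter, additivity an explicit minority —
and are fixed once; they are not tuned per test. Diverged means differ by
`fold_effect` (default 8) with random parent polarity; hybrids sit at a
parent's value (ELD), the arithmetic mid-parent (additive), or
`fold_effect` beyond the more extreme parent (transgressive). Each gene's
F2 category repeats its F1 category with probability `f2_inherit_prob`
(default 0.9); otherwise it is re-drawn among categories compatible with
the already-fixed parental means (sample-exclusive genes always inherit,
since their recipe also pins the parent columns).

**Truth labels are classifier-semantic, not recipe names.** The truth
table records both the planted recipe and the *expected* classification:
the bin/group the fold-gated caller would output on the true means with
zero sampling noise. The two differ for one recipe by geometry, not by
bug: an exactly mid-parent hybrid always lies within 2-fold of its higher
parent (the ratio $(1+\delta)/(2\delta)$ is strictly between ½ and 1 for
any $\delta > 1$), so a planted-additive gene can never satisfy bin I/XII
under a strict 2-fold gate and is *expected* to classify as ELD toward the
high parent. Recovery tests therefore measure what they should — the
stochastic layer's fidelity to the deterministic semantics — by comparing
observed calls to the expected group. A green 90% recovery establishes
that the pipeline reproduces its own noise-free decision function under
the stated noise; it does not establish that the twelve-bin scheme
identifies biological mechanism, nor that real libraries meet the model.

The miRNA layer plants repression: coupled miRNAs transfer their true
log2 fold change versus MPV ($m$) onto their targets as
$-\beta m + \varepsilon$, $\varepsilon \sim N(0, \sigma)$, with defaults
$\beta = 1$, $\sigma = 0.25$; decoy links from uncoupled miRNAs keep the
map many-to-many without touching any mean. What the generator does *not*
emulate: gene-length bias in counts (lengths are drawn independently of
abundance), GC or positional effects, correlated dispersion across
samples, partial pooling of individuals within a library, and any
sequence-level reality.

## Numerical choices

- **Rounding.** MPV pseudo-counts use round-half-even (R's `round`) so the
  exact test stays integer-valued with no directional bias. Reported
  percentages use round-half-away-from-zero at 2 decimals — the only
  convention that reproduces published percentage tables from their
  printed numerators.
- **Boundaries.** All threshold comparisons mirror printed inequality
  directions: $q \le 0.001$ and fold $> 2$ for genes, $q < 0.05$ for
  miRNAs; a q exactly at the miRNA threshold is additive.
- **Size factors.** Genes with any zero count are excluded from the
  median-of-ratios (the geometric mean is undefined at zero); factors are
  renormalized to geometric mean 1. With no gene positive everywhere the
  input is rejected as degenerate rather than silently rescaled.
- **Determinism.** One root seed; the miRNA stream derives from it by a
  fixed offset, so the gene layer is reproducible with or without the
  miRNA layer. Output floats are serialized at 6 significant digits and
  rows sorted by id, making runs byte-comparable.
- **Degenerate inputs.** Correlation requires ≥ 3 pairs and nonzero
  variance on both axes; enrichment skips terms absent from the
  background rather than reporting uninformative p = 1 rows into the BH
  family.

## Design choices where the design was open

- **Test choice.** The exact conditional test is the standard instrument
  for unreplicated pooled libraries of this era; dispersion-modeled NB
  tests need replicates the design does not have.
- **Fold-change substrate.** Fold changes are computed on size-factor
  normalized counts, not FPKM: within a gene, length cancels in any
  self-ratio, so the two choices are observationally equivalent per gene
  and the count scale avoids a second normalization.
- **Percentage denominator.** Study-style percentages divide by the
  co-expressed gene count; with that denominator all nine published
  Results percentages reproduce exactly from their printed numerators.
- **Inheritance bookkeeping check.** The perfect-inheritance acceptance
  setting uses Poisson noise, a raised expression floor
  (baseline log-mean $\log 150$, log-sd 0.5) and only boundary-safe
  categories, because the check targets the set-intersection logic; any
  category whose recipe sits near the fold-gate boundary would leak
  sampling noise into a bookkeeping test.
- **Enrichment scope.** Upper-tail only, BH across all terms globally
  (not per namespace), background defaulting to the co-expressed set —
  all configurable at the call site.

## Limitations

- With one library per group, "significance" quantifies sequencing-depth
  noise only. NB overdispersion at $\phi = 0.05$ roughly triples the
  nominal z-scale of the mid-parent test at typical depths, so absolute
  nonadditive *counts* on real data are optimistic even though category
  *comparisons* (which share the miscalibration) remain informative.
- The twelve-bin classifier's output depends on the fold gate: genuinely
  additive genes with well-separated parents are expected to land in the
  ELD bins, an intrinsic property of fold-gated classification worth
  remembering when reading published bin tallies.
- GO terms are opaque identifiers; no ancestor propagation is applied, so
  enrichment follows whatever closure the annotation input already has.
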