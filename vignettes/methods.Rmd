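---
title: "Models and methods behind nscarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nscarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nscarray)
```

nscarray implements the downstream analysis of a three-condition
neurosphere transcriptome design: control cultures receiving FGF-2/EGF
daily (Ctr) against cultures supplemented every 2 (C2) or every 4 (C4)
days, profiled on a ~45,101-probe microarray with one array per
condition. This vignette explains each model, its assumptions, the
tunable parameters, and the design decisions taken where the methodology
left genuine choices open.

## Fold-change classification

With a single array per condition there is no within-group variance, so
differential expression is a pure fold-change criterion on the
GCRMA-normalized log2 intensities (normalization is upstream of this
package). For probe $i$ and conditions $t$ (treatment) and $c$
(control),

$$\delta_i = x_{it} - x_{ic}, \qquad
\text{call}_i = \begin{cases}
\text{up} & \delta_i \ge \theta\\
\text{down} & \delta_i \le -\theta\\
\text{similar} & \text{otherwise,}
\end{cases}$$

with $\theta = 1$ log2 unit (two-fold) by default. The bounds are
*inclusive*: a probe changed by exactly one-fold in log2 is
differential. Comparisons are always treatment-versus-control with Ctr
designated as control; swapping the pair exchanges up and down calls
exactly, and the three calls always partition the probe set.

Probe-level calls are collapsed to genes by the *any-probe* rule: a gene
is differential when at least one of its probes is. Nothing in the
method prescribes a collapsing rule, so both probe- and gene-level
counts are exposed (`glance()` on a call set; `differential_genes()`).

Scatter summaries report, per comparison, the counts of similar and
different probes, their percentages against a caller-supplied
`total_transcripts` denominator (default: the number of matrix rows, so
the 45,101-transcript convention is reproducible on the full array), and
the Pearson correlation of the two columns over all probes. A
zero-variance column makes the correlation undefined; it is reported as
`NA` with a warning, never silently as 0.

## Background and heat-map filters

Enrichment needs a background of *expressed, varying* genes: probes
whose max-minus-min across the three samples is at least 1 log2 unit
(inclusive), mapped to genes with at least one qualifying probe. The
global heat map uses a stricter filter — range at least 2 *and* FDR
q strictly below 0.01. The per-probe q-values are an input, not a
computation of this package: with one array per condition no
variance-based per-probe test is possible, so whatever external
procedure produced them (or the synthetic generator's truth-linked
placeholders) is taken as given.

## UPGMA clustering

Profiles (samples or filtered probes) are clustered agglomeratively
under the one-minus-Pearson-correlation distance with unweighted
average linkage (UPGMA): the distance between two clusters is the
arithmetic mean of all leaf-pair distances, and at every step the
closest pair merges. Merge heights are therefore non-decreasing
(ultrametric). Implementation is the Lance–Williams update
$d(A \cup B, C) = \tfrac{|A| d(A,C) + |B| d(B,C)}{|A| + |B|}$,
which is algebraically the unweighted mean.

Two numerical choices are deliberate:

* **Ties** (two pairs at the same minimal distance) are broken by the
  lexicographically smallest pair of cluster labels, where a merged
  cluster carries its smallest leaf label. This makes output
  deterministic and testable; general-purpose clustering routines leave
  tie order unspecified.
* **Zero-variance profiles** abort with an error naming the profile:
  $1 - r$ is undefined there, and imputing a conventional distance would
  silently corrupt the tree.

The result is `hclust`-compatible, so `cutree()`, `plot()` and
`ape::as.phylo()` work; Newick export uses the ultrametric convention
(leaf depth = half the merge distance).

## Enrichment statistics

Gene Ontology annotations are first *back-propagated*: each gene's term
set is closed over `is_a` edges up to its namespace root, so a gene
annotated to a leaf counts for every ancestor. The closure is reflexive
(the annotated term itself counts — a gene annotated to a term must
count for that term), honours only `is_a` edges (richer OBO relations
are ignored on read), treats namespaces independently, and rejects
cyclic files outright at load time.

For a term or gene set with $K$ annotated genes among the $N$ background
genes, a study set of $n$ genes containing $k$ annotated ones is scored
by the upper-tail hypergeometric probability

$$p = P(X \ge k) = \sum_{i = k}^{\min(K, n)}
\frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}},$$

computed in log space (log-gamma factorials combined by log-sum-exp) so
it does not underflow at genome scale. Multiplicity is controlled by the
Benjamini–Hochberg step-up rule,
$q_{(i)} = \min_{j \ge i} p_{(j)} \, m / j$ capped at 1, with
significance at $q \le \alpha$, $\alpha = 0.05$.

Open choices, decided as follows:

* **BH scope.** The correction is applied within each GO namespace
  separately — each namespace is its own ontology with its own root,
  matching the per-ontology propagation framing — and across all tested
  sets for flat pathway enrichment. The methodology itself does not say
  which scope was used.
* **Untestable terms.** Terms with $K = 0$ in the background are not
  tested and do not count toward $m$; untestable hypotheses would only
  dilute the correction.
* **Study/background mismatch.** Study genes outside the background are
  dropped with a warning rather than an error, since range filters
  legitimately shrink the background.
* **Reporting.** All tested terms are returned with their counts, $p$,
  $q$ and member study genes, so results can be re-thresholded
  downstream; pathway results carry the study genes inside each set.

KEGG-style gene sets use identical statistics with no propagation step.
Term-frequency summaries count study genes per term after closure,
excluding the namespace root (to which every annotated gene trivially
belongs).

## Comparative-CT quantification

Replicate Ct values (triplicate by design) are arithmetically averaged
per condition and gene *before* normalisation — the classic
comparative-CT convention — then

$$\Delta C_t = \overline{Ct}_\text{gene} - \overline{Ct}_\text{Gapdh},
\qquad \Delta\Delta C_t = \Delta C_t^{\text{cond}} - \Delta C_t^{\text{ctrl}},
\qquad \log_2 \text{FC} = -\Delta\Delta C_t.$$

Amplification efficiency is assumed to be exactly 2 per cycle;
efficiency-corrected models and melt-curve QC are out of scope. The sign
convention makes positive fold changes mean higher expression in the
treated condition. A plate offset hitting every well of a condition
cancels in $\Delta C_t$ (gauge invariance). Genes missing replicates are
quantified from the remaining wells with a warning.

Validation genes are selected exactly as the wet-lab filter prescribes:
|log2 FC| ≥ 1 in *both* the C2 and C4 comparisons and q < 0.01.
Concordance between platforms is the coefficient of determination
$R^2 = 1 - SS_\text{res}/SS_\text{tot}$ of the OLS fit of qPCR on
microarray fold changes (at least 3 pairs, non-degenerate x); note $R^2$
measures fit, not direction.

## The synthetic study

`simulate_study()` generates every pipeline input from one seed. Its
defaults *are* the emulated study conditions and are not tuned
per-analysis:

| parameter | default | rationale |
|---|---|---|
| `n_probes` | 45,101 | the array's transcript count |
| `samples` | Ctr, C2, C4 | the three supplementation regimes |
| `n_de_c4`, `n_de_c2` | 312, 38 | the reported scale of perturbation; C2 planted as a strict subset of C4, making the C2–C4 contrast meaningful |
| `prop_up` | 180/312 | the reported up/down split in C4 |
| `effect_size` | 1.5 | minimum planted |log2 FC|, safely above the call threshold of 1 |
| `effect_size_spread` | 1.0 | per-gene magnitudes uniform on [1.5, 2.5]: real perturbations produce a spread of strong and moderate changes, and only the stronger half exceeds the heat-map range-2 filter |
| `noise_sd` | 0.1 | per-cell log2 technical noise of a well-normalized array; gives call sensitivity ≈ Φ((δ−θ)/(σ√2)) > 0.999 |
| `n_varying` | 4,000 | probes with anti-symmetric sub-threshold C2/C4 offsets (±w/2, w ∈ [1.0, 1.2]): expressed-but-not-differential transcripts that populate the range-1 background (~3,000 genes) without crossing the call threshold |
| `rho` | 0.4 | fraction of differential genes drawn from the planted term, the planted-enrichment strength |
| `ct_noise_sd` | 0.2 | cycles of qPCR technical noise; with triplicates the recovered fold-change error stays well inside 3σ |

The truth table records the full planted shift per probe (including the
sub-threshold filler offsets), so at `noise_sd = 0` every downstream
stage recovers truth exactly: calls at θ = 1, enrichment counts, and
ΔΔCT fold changes to machine precision. Emitted q-values are
*truth-linked placeholders* (< 0.01 for planted differential probes,
≥ 0.01 otherwise) standing in for an external per-probe FDR procedure;
this is recorded in the written study's metadata.

What the generator does **not** emulate: probe-level intensity
distributions and GC effects (it starts where GCRMA ends), correlated
noise between probes of a gene, batch or spatial artifacts, annotation
incompleteness and evidence codes, and biological replication. Passing
tests therefore demonstrate the correctness of the statistical
machinery under the stated generative model — not robustness to the
messiness of real arrays.

## Problem sizes used in the tests

The oracle suites run exhaustively where enumeration is cheap (every
hypergeometric configuration with N ≤ 12; 1,000 random
Benjamini–Hochberg vectors up to m = 1,000; 100 random DAGs up to 50
terms; 40 random matrices up to 10 profiles) and by simulation where a
rate is being estimated (200 replicates each for the null
false-positive rate and the planted-term recovery rate, on a
2,000-gene background). The end-to-end check runs the full 45,101-probe
design through every stage; unit tests use a 1,500-probe configuration
of the same generator, which exercises identical code paths at a
fraction of the cost.

## Known limitations

* With one array per condition the fold-change criterion cannot
  separate biological from technical variation; the q-value input is
  trusted, not derived.
* Enrichment p-values on back-propagated annotations are correlated
  across nested terms; no parent–child decorrelation (elim/weight
  schemes) is attempted, matching the plain hypergeometric methodology.
* The comparative-CT model assumes perfect doubling per cycle; strongly
  deviating amplification efficiencies bias fold changes.
* UPGMA on one-minus-correlation is undefined for flat profiles; such
  profiles are an error by design, so callers must pre-filter constant
  probes (the heat-map range filter does this naturally).
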