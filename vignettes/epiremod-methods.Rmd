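---
title: "epiremod: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{epiremod: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiremod)
options(epiremod.quiet = TRUE)
```

`epiremod` implements the quantitative core of a multiome + Hi-C +
methylome analysis of transcription-factor-driven reprogramming: linking
distal accessible elements to genes, scoring TF targets, and measuring
3D-genome and methylation remodeling. This vignette documents the
statistical models, every tunable that matters, the synthetic world the
tests rely on, and the design choices made where the methodology was
genuinely open. No empirical claim is made here that the test suite does
not itself compute.

## 1. Enhancer–gene pair (EGP) linking

### Model

A candidate pair is a distal accessible peak and a gene on the same
chromosome whose peak-center-to-TSS distance $d$ satisfies
$5\,\mathrm{kb} \le d \le 500\,\mathrm{kb}$ (both bounds inclusive —
"at least" / "no more than"). Counts are aggregated into metacells,
normalized per modality to counts-per-10k and `log1p`-transformed, and
each pair receives the Pearson correlation $r$ of accessibility versus
expression across metacells.

Sparse single-cell counts attenuate correlations; aggregating $k$
similar cells before correlating removes most sampling noise while
preserving between-aggregate biological variation. Metacells are built
by farthest-point seeding in an embedding followed by each seed claiming
its $k$ nearest *unassigned* cells, giving disjoint memberships and a
deterministic result under a seed. When no embedding is supplied one is
built from the data: the top ~200 most overdispersed features of *each*
modality, per-feature rank transform, truncated SVD (10 dimensions).
Using both modalities matters: an expression-only embedding collapses
exactly the accessibility-specific variation that bounds the peak–gene
correlation, and measured $r$ then overshoots the true coupling
(we observed planted 0.7 inflate to ~0.9 in such a configuration).

### Empirical null and FDR

Correlation magnitudes in sparse genomics data depend on covariates
(GC content, overall accessibility), so significance is assessed against
an *empirical* null: for each tested peak, `n_bg` background peaks are
drawn from the same quantile bins of GC fraction and mean accessibility
(nearest non-empty bin as fallback) and correlated against the same
gene. The two-sided empirical p-value is

$$p = \frac{1 + \#\{|r_\mathrm{null}| \ge |r|\}}{n_\mathrm{valid} + 1},$$

which is bounded below by $1/(n_{bg}+1)$ and never exactly zero.
Benjamini–Hochberg is applied across all tested pairs jointly (not per
gene); zero-variance ("untestable") pairs are excluded from the FDR
denominator. Classification follows the field's thresholds: positive if
$r > 0.35$ and $q < 0.1$; negative if $r < -0.35$ and $q < 0.1$;
otherwise non-correlated. The negative threshold is the only
self-consistent reading of the published rule set (a literal "r < 0.35"
would swallow both other classes); it is exposed as an argument.

Defaults: `k = 50` cells per metacell, `n_bg = 100`, thresholds as
above. Note an arithmetic consequence worth knowing: with
`n_bg = 100` the smallest attainable p is $1/101 \approx 0.0099$, so
after BH a true link can only reach $q < 0.1$ if the tested universe is
at most roughly ten times the number of true links. Either raise
`n_bg` or restrict the candidate universe when working at larger scale.

## 2. TF target scoring

Only positively correlated links carry evidence. The gene linkage score
is

$$L(g) = \sum_{\text{links } i \in g,\ \mathrm{TF}(i)} r_i^2 \;+\;
  \mathbf{1}[\text{promoter TF evidence}],$$

i.e. a promoter hit counts as a link with $r = 1$. $L$ is additive over
disjoint link subsets and zero-preserving (genes without evidence are
retained at $L = 0$).

Enrichment of TF evidence among a gene's $m$ linked peaks (of which $x$
carry evidence) is the exact hypergeometric upper tail
$P(X \ge x)$ drawing $m$ from a population of the $m$ linked peaks
pooled with $m \cdot n_{bg\_sets}$ GC-matched background peaks
(default `n_bg_sets = 25`). This parameterization reduces to the stated
ingredients (matched background + hypergeometric test) and admits an
exact combinatorial oracle, which the test suite checks to 1e-12.
Promoter evidence contributes to $L$ but not to the draw count. Genes
with $m < 3$ are flagged `low_confidence` rather than dropped — with
very few pairs the tail probability is too coarse to rank.

## 3. Hi-C statistics

**Pair filtering.** Keep pairs with both mapq strictly above 30; drop
intra-chromosomal pairs on the same restriction fragment or separated by
less than 1 kb; drop exact positional duplicates (first kept).

**Balancing.** Iterative proportional correction to uniform row sums
(tolerance 1e-6 on the row-sum CV, max 500 iterations), after masking
bins with coverage below 2% of the median. For symmetric non-negative
matrices this converges to the same diagonal scaling as Knight–Ruiz.

**Distance decay.** Mean contact per log-spaced distance bin; the
normalized curve $P(s)$ divides each bin's contact mass by the total, so
it sums exactly to 1 and is invariant to global rescaling. The
per-bin-distance mean profile doubles as the expected model $E(s)$ for
all obs/exp statistics.

**Compartments.** First eigenvector of the Pearson correlation matrix of
obs/exp, bins labeled A/B by sign, oriented so A has the higher mean of
a user-supplied covariate track (gene density, accessibility; the
synthetic tests use the planted labels as track). Without a track the
orientation is arbitrary and flagged. Compartment strength is reported
two ways:

- `strength` — ratio of *mean* obs/exp within compartments (A–A plus
  B–B) to mean obs/exp between (A–B), over pairs separated by at least
  10 Mb. This is the primary statistic: it equals 1 on structureless
  data regardless of how many bins end up in each class.
- `strength_raw` — the ratio of raw observed-count sums, as sometimes
  quoted. This version is confounded by the within/between pair-count
  composition (an arbitrary labeling of a structureless matrix does not
  give 1), which is why it is emitted for inspection only.

A $5 \times 5$ saddle (mean obs/exp over eigenvector-quantile pairs,
short-range pairs excluded) is also returned.

**Insulation and TADs.** The score at bin $b$ is
$\log_2$ of the mean contacts in the $w \times w$ square spanning
$[b-w, b) \times [b, b+w)$ divided by the chromosome-wide mean of that
statistic (default $w = 10$ bins; edge bins are missing). Boundaries are
local minima with topographic prominence of at least 0.2 log2 units; of
two minima closer than $w$ bins the deeper wins, ties to the left. The
window and prominence are conventions, not values fixed by the source
methodology, and are arguments.

**Average TAD enrichment.** Each TAD's log2 obs/exp submatrix, flanked
by one TAD length per side, is rescaled to a fixed grid by NA-aware
bilinear interpolation and averaged; TADs shorter than 3 bins are
skipped. One property to be aware of: when TADs tile most of the
chromosome, the self-derived $E(s)$ itself absorbs much of the TAD
signal (at short range most pairs *are* intra-TAD), so interior
enrichment measured against it underestimates the true boost — with a
multiplier of 1.5 tiling a 200-bin chromosome the self-normalized
interior reads ~0.11 log2 instead of 0.58. `aggregate_tads` therefore
accepts an external `expected`; the recovery tests supply the
generator's analytic decay, and real-data users can supply a decay
pooled over larger regions.

**APA.** Mean of $\log_2((\mathrm{obs}+1)/(E(s)+1))$ over
$(2W+1)^2$ windows centered on anchor pairs (default $W = 10$); the
center enrichment is the central $3\times3$ mean minus the average of
the four $3\times3$ corner blocks. Pairs closer than $2W+1$ bins or
within $W$ of a chromosome end are excluded and counted. The pseudocount
of 1 (used in all log2 ratios) avoids $-\infty$ and biases the statistic
slightly toward 0 where expected counts are small — visible as planted
$\log_2 2 = 1$ loops reading ~0.9.

**Per-pair scores.** The published per-pair statistic uses an external
kNN-normalized score with no published formula; we substitute
$\log_2\frac{\sum\mathrm{obs}+1}{\sum E(s)+1}$ over the bins covered by
a 10-kb window centered on the pair. Same monotone intent, exact and
testable; paired region-set comparisons use the two-sided (paired)
Wilcoxon test.

## 4. Methylation

Sites must be in CpG context with total coverage $\ge 10$ (inclusive).
Per-region methylation is the *unweighted mean of per-CpG fractions* —
robust to coverage imbalance and matching "average methylation" per
region; a pooled-count mode (`sum meth / sum total`) is available behind
a flag since the convention is not universal. Profiles bin CpGs by
signed distance from the feature midpoint (strand ignored; `n_bins` must
be odd so a central bin exists).

## 5. The synthetic world

The generator is a stated world, not a tuning knob: its defaults encode
the scenario the statistics are validated against, chosen once.

- **Contact maps.** $E[i,j] = \mathrm{depth}\cdot|i-j|^{-\alpha}$
  (default depth 500 at 1 bin, $\alpha = 1$), times $c$ for same-label
  and $1/c$ for different-label bins (alternating 20-bin A/B blocks),
  times $f$ for intra-TAD pairs (10 quasi-evenly spaced, jittered
  boundaries), times a $3\times3$ Gaussian patch peaking at $\ell$ at
  each of 50 loop anchors (separations 25–80 bins, clear of edges and of
  the APA window extent). Observed counts are Poisson, symmetrized.
  Poisson counts make analytic expectations available for every test.
- **Multiome.** Each cell carries a latent state
  $(u_1, u_2) \sim U(0,1)^2$ mimicking a maturation axis. Planted genes
  respond linearly to $u_1$; each planted peak responds to
  $\rho u_1 + \sqrt{1-\rho^2}\, u_2$, so the rate-level correlation is
  exactly $\rho$ and survives aggregation. Planted programs alternate
  up/down sign so library size is independent of the latent state —
  without this, CP10K normalization alone induces $|r| \approx 0.14$
  between *unlinked* features, swamping the null. Unlinked features are
  feature-specific Poisson noise. The layout gives each planted link its
  own locus (TSS spacing 1.2 Mb, peak at 50 kb) and places most
  unlinked peaks in gene-free deserts, yielding ~350 candidate pairs of
  which the 50 planted links are a minority; as noted in §1, the
  empirical-p floor makes a much larger null universe incompatible with
  $q < 0.1$ calls at `n_bg = 100`. A configurable extra fraction of
  cells is emitted with one QC metric planted outside its keep range.
- **Methylome.** CpGs on a 25-bp grid, level
  $m_0 - (m_0 - m_1)\exp(-d^2/2\sigma^2)$ around feature centers
  (defaults $m_0 = 0.8$, $m_1 = 0.3$, $\sigma = 150$ bp), coverage
  Poisson(30), methylated counts Binomial; 5% of sites are planted with
  coverage below 10 and 5% with non-CpG context to exercise the filters.
- **ChIP universe.** Controlled counts of condition-specific and shared
  peaks (shared = identical coordinates) with sequences scrubbed of
  accidental motif matches before planting an exact number of copies on
  random strands — so the motif counter's answer has a known truth.

What the generator does **not** emulate: doublets beyond QC-range
planting, batch effects, chromatin-state covariance between neighboring
peaks, trans contacts, replication-timing gradients, bisulfite
conversion errors, or read-level artifacts. A green test therefore
establishes that the statistics recover the signal they define on data
matching their assumptions — not robustness to every real-world
pathology.

All randomness flows from the single `seed` in `sim_config()`; the
generators save and restore the caller's RNG state, and identical
configs are bit-identical.

## 6. Numerical conventions

- Coordinates are 0-based half-open (BED dialect) everywhere; promoter
  windows and TSS windows are $[t-w, t+w)$.
- Motif scanning: column frequencies smoothed with a uniform 0.25
  pseudo-frequency ($f' = (f + 0.25)/2$), log2 odds against a uniform
  background, threshold = `score_fraction` (default 0.8) times the
  maximal attainable score; non-overlapping matches chosen greedily left
  to right, ties to the leftmost start then the + strand; `N` scores as
  its background expectation; non-ACGTN characters are an error. For a
  consensus motif at the default fraction only exact matches pass.
- BH adjustment is reimplemented (`bh_adjust`) and cross-checked in the
  tests against `stats::p.adjust` and a hand-computed table.
- All log2 contact ratios use a pseudocount of 1; masked bins propagate
  as NA and are excluded from means.
- Ties in farthest-point seeding and greedy assignment are resolved by
  index order, making metacell construction deterministic.

## 7. Known limitations

- The compartment eigenvector needs an external covariate to orient A
  vs B; on featureless input the orientation is arbitrary (flagged).
- The per-pair contact score is a plain obs/exp ratio, not a kNN
  rescaling; absolute values are not comparable to scores produced by
  kNN-normalizing tools, only orderings are.
- `gene_target_enrichment` treats background draws as exchangeable with
  linked peaks; strong residual covariate structure in real data would
  require finer matching than the default 20 quantile bins.
- The orchestrator (`run_pipeline`) wires the synthetic world end to
  end; applying the statistics to external data means calling the module
  functions directly on objects read with the provided parsers.
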