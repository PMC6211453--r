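---
title: "The clipHMM model: coverage, diagnostic events, and segmentation"
author: "clipHMM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The clipHMM model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

clipHMM identifies protein-RNA interaction sites from CLIP-seq data
of any flavour by segmenting per-gene read profiles with a
non-homogeneous hidden Markov model (NHMM). This vignette is the
package's own account of the model, its assumptions, the tunable
parameters, the numerical choices, and what the simulation-based
validation does and does not establish.

## States and emissions

Every gene is an independent chain over its positions with four
hidden states: `P` (peak: CLIP enriched over background), `B1`
(background enriched over CLIP), `B2` (both channels at the gene's
expression level), and `N` (essentially no coverage). The emission
probability at position $i$ is the product of a coverage term and a
diagnostic-event term, multiplied over all libraries.

### Coverage model

Coverage $X_i^w$ in library $w$ is negative binomial with variance
$\sigma^2(\mu) = \mu + c\mu^2$, $c \ge 0$, and a log mean that is
additive in a per-library log size factor $l_w$, a per-gene
expression coefficient $\beta_g$, and a shared enrichment coefficient
$\beta_{G+1} \ge 0$:

$$\log \mu^{u}_{i} = \begin{cases}
l_u + \beta_g + \beta_{G+1} & s = P\\
l_u + \beta_g - \beta_{G+1} & s = B1\\
l_u + \beta_g & s = B2\\
l_u + \beta_0 & s = N
\end{cases}$$

for a CLIP library $u$; background libraries use the same lines with
the sign of $\beta_{G+1}$ flipped in `P` and `B1`. The mirrored signs
make the model symmetric: exchanging the roles of the CLIP and
background channels exactly swaps the `P` and `B1` emission values (a
property the test suite checks). $\beta_0$ absorbs residual reads in
unexpressed regions.

Size factors are estimated once, before fitting, as the log of the
median over genes of the gene's mean per-position coverage, excluding
genes with no coverage in that library; they are stored on the log
scale so the linear predictor stays additive and enter the GLM as a
fixed offset rather than a fitted coefficient.

Fitting maximizes the state-posterior-weighted NB likelihood by
iteratively reweighted least squares (IRLS), alternating with a 1-D
bounded maximum-likelihood update of $c$ (optimized on
$\log c \in [\log 10^{-6}, \log 10^3]$, with an explicit Poisson
branch when the Poisson likelihood is at least as good). Design
choices that matter:

* The design matrix has one indicator column per gene, an intercept
  column active only in state `N`, and one enrichment column with
  entries $\{+1, -1, 0\}$ by role and state. The normal equations
  $X^\top W X$ are then sparse (essentially block-diagonal plus two
  dense rows/columns) and are solved with `Matrix`'s sparse Cholesky;
  a dense-design reference implementation in the test suite agrees to
  $10^{-6}$.
* Observations are aggregated: within a gene, library and state, all
  positions with the same count are one weighted row. This is exact
  (the working response depends only on the count) and shrinks the
  system by orders of magnitude.
* Each state's observations are additionally weighted by the inverse
  of the state's total posterior mass, so rare states (typically `P`)
  are fitted as well as abundant ones.
* Observation weights of positions with zero coverage in every
  library are scaled down so they contribute at most 10x the mass of
  covered positions; this keeps the `N`-dominated rows from swamping
  the system while leaving emissions untouched.
* IRLS stops when the largest coefficient change is below $10^{-4}$
  (at most 50 inner iterations, 5 outer $\beta$/$c$ alternations),
  with step-halving so the weighted log-likelihood never decreases.
  Coefficients are clamped to $[-30, 30]$: genes with no reads would
  otherwise drift to $-\infty$.
* The enrichment coefficient is projected to $\ge 0$ after every
  update, which resolves the label ambiguity between `P` and `B1`.

When computing emissions (not when fitting), any $\beta_g < \beta_0$
is replaced by $\beta_0 + \beta_{G+1} + 10^{-5}$ so every expressed
state implies more coverage than `N`; this only matters in early
iterations for genes with very few reads.

### Diagnostic-event model

At each position the reads of a library may carry diagnostic events:
one of 12 substitutions, a deletion of one of the 4 bases, or a
5'/3' read end. We track all $M = 18$ categories plus an implicit
"no event" slot so each per-position count vector sums to the read
coverage. Both read ends are encoded because different protocols put
the informative truncation on different ends; the mixture learns
which (if either) matters.

The count vectors $Y_i^u$ of the replicates at a position share one
latent event-rate vector $q$ drawn from a Dirichlet, giving the
closed-form replicate-coupled likelihood

$$p(Y_i^1,\dots,Y_i^U \mid s) = \sum_{k=1}^{K} \mu_k
\left(\prod_u \binom{N_u}{Y_i^u}\right)
\frac{B(\alpha^{(k)} + \sum_u Y_i^u)}{B(\alpha^{(k)})}$$

with $B$ the multivariate Beta function and $K = 10$ components by
default (fewer only when there are fewer training positions than
components). The hierarchical construction absorbs both
position-to-position rate variation within a class and
replicate-level overdispersion.

Two mixtures are fitted: the peak mixture on CLIP-library event
vectors at current peak positions, and the background mixture on
background-library event vectors at the same positions (sequencing
errors and structured noise live there). In emissions, state `P`
scores CLIP events under the peak mixture; all other states score
them under the background mixture; background-library events are
scored under the background mixture in every state (a state-constant
factor kept so the reported evidence is the full-data evidence). If
no background libraries exist, the background mixture falls back to
CLIP events at non-peak covered positions — an extension beyond the
replicate-matched design, flagged in the documentation.

EM details: responsibilities in log space; Dirichlet concentrations
updated by the standard fixed-point iteration with $\alpha$ floored
at $10^{-6}$; four uniform-random initializations
($\alpha \sim U(0.5, 2)$, uniform weights) plus the previous
iteration's solution as a warm start, each run briefly, with the best
refined to convergence. Training positions are subsampled to at most
$10^6$ covered positions (never binding at the package's default
scale), duplicate count vectors are collapsed with multiplicities,
and special functions are evaluated on the unique count values per
category only — the fit cost then depends on the diversity of event
patterns, not the genome size. Positions where two or more genes
overlap are excluded from training (events are strand-specific, an
antisense gene would dilute the signal), as are likely SNP positions
(below).

### Transitions

The probability of remaining in the current state between adjacent
positions is $f(X_i) = \mathrm{plogis}(w_0 + w_1 \log(1 + X_i))$ with
$X_i$ the total coverage over all libraries; leaving probability is
split evenly over the three other states. High-coverage regions
therefore resist state flipping while sparse regions stay flexible.
$(w_0, w_1)$ are fitted to the posterior self-transition mass by
mini-batch stochastic gradient descent (decaying step, fixed epochs,
covariate centred internally to decorrelate intercept and slope, an
epoch that lowers the full-batch objective is rolled back with a
halved step). The initial state distribution is uniform; $f$ is
clamped to $[10^{-6}, 1 - 10^{-6}]$ so log-transitions stay finite.

## Model fitting

The outer loop alternates a forward-backward E-step over all genes
(compiled, scaled-probability implementation; exact to $10^{-10}$
against brute-force path enumeration on small instances) with
M-steps for the GLM, the two event mixtures and the transition
logistic. At least 5 and at most 10 outer iterations are run, with
early stopping once the relative change of the total log-evidence
drops below $10^{-3}$.

Because the event mixtures are refit on *hard-assigned* peak
positions (posterior argmax) rather than posterior-weighted data —
and before any segmentation exists, on the top-coverage 1% of
positions as provisional peaks — the procedure is a generalized EM
with approximate M-steps: the log-evidence trace is near-monotone but
can fluctuate by up to roughly 1% on small data sets. The test suite
asserts overall improvement and bounded fluctuation rather than
strict monotonicity.

## Read filtering and masking

* Reads with more than 2 mismatches are discarded; reads must match
  the gene's strand when strand information is available.
* Conversions in the first or last two bases of a read are ignored
  (likely mis-mapped ends); deletions and read-end events are never
  offset-dropped.
* A position is masked as a likely SNP when the pooled background
  coverage is $\ge 20$ and $\ge 20\%$ of those reads carry a
  conversion. The thresholds are applied to the pooled background
  rather than per library — with typical background depths a
  per-library rule would rarely fire at the stated constants. Masked
  positions keep their coverage but contribute no event counts and no
  event emission term.
* Positions in genes overlapping annotated miRNA genes are zeroed
  entirely (coverage and events), the default guard against the
  extreme pileups of mature miRNAs.

Coordinates are 1-based closed internally, following the
IRanges/GRanges containers the package is built on; BED output is
0-based half-open, and GTF input is consumed through `rtracklayer`.
"Coverage" counts full read footprints (every position a read
overlaps), since the coverage model describes per-position profile
height rather than fragment starts. Insertions are not event
categories. Multi-mapper policy is left to the upstream aligner.

## Peak calling

Peaks are maximal runs of `P` in the Viterbi path (ties between
equally likely states break toward the fixed order
`P < B1 < B2 < N`). An optional additive log-penalty on the peak
state (CLI flag, default 0, $-5$ recommended for eCLIP) shrinks calls
to their high-confidence cores; decoded penalized runs are
sub-intervals of the unpenalized ones.

* **Summit**: the position with the largest CLIP-event log-odds
  (peak mixture minus background mixture).
* **Score**: the summed log-likelihood ratio of `P` against the best
  competing state, position-wise. "Best competing" is the max, not
  the sum, over non-peak states — a per-position max is the natural
  decoding counterpart and is what the score examples assume.
* **p-value**: expected mean and variance of CLIP coverage under the
  expression-matched non-enriched state (`B2` — the null that keeps
  the gene's expression but removes enrichment) are summed over the
  peak's positions and CLIP libraries; the p-value is the upper tail
  of a negative binomial moment-matched to those sums (Poisson when
  the variance does not exceed the mean). Bonferroni correction uses
  the number of candidate peaks in the run; reported peaks satisfy
  $p_{\mathrm{adj}} \le 0.05$.
* **Random controls**: `shuffleControl()` re-places each peak
  uniformly within its gene (same width and strand) and returns a
  scorer's values on the shuffled intervals.

## The simulator

`simulateClipData()` emulates the benchmark conditions the model is
validated under: a random genome with planted motif instances drawn
from a sharp PUM2-like PWM (consensus TGTANATA; matches are called at
log2-odds $\ge 3$ with pseudocount $5\times 10^{-5}$, forward strand
only), log-normal base expressions $\exp(\mathcal{N}(10, 4))$,
negative-binomial replicate counts with variance $\mu + 0.1\mu^2$,
and six uniform-fragment libraries: two backgrounds, two CLIP, two
held-out. CLIP libraries keep only motif-overlapping reads with
retention probability proportional to the read's best motif score's
position within the genome-wide score range, plant an A>T conversion
at the 4th motif base in 50% of crosslink-covering reads, and admix
held-out reads so that 10% of the final CLIP library is non-specific.
(The literal published retention sentence — discard when a uniform
draw is *below* the read's best score — inverts the stated intent of
favouring strong motifs; both behaviours are implemented,
`retention = "literal"` selects the inverted one.) Defaults are 200
genes of 1.5-2.5 kb, 36-bp reads, $2\times 10^5$ fragments per
library, and on average 2 planted sites per gene — desk-scale
stand-ins for the published chromosome-scale setting, chosen so a
full study runs in minutes on one CPU.

What the simulator does *not* emulate — splicing and isoforms,
paired-end reads, sequencing errors beyond the planted conversions,
mappability and GC structure, strand mixtures, PCR duplicates — sets
the limits of what passing tests show: they demonstrate correct
inference under the model's own generative assumptions plus planted
signal, not robustness to every artefact of real libraries. Real-data
idiosyncrasies (UMI handling, multi-mappers, fragment-length biases)
are upstream of this package.

Every simulation is reproducible: the same seed and configuration
give byte-identical SAM/FASTA/GTF/BED output.

## Validation scale and known limitations

The test suite exercises the full study at 200 genes (the scale also
used by `scripts/acceptance.R`) and smaller 15-50-gene versions for
component tests; exhaustive-enumeration checks of the HMM use
instances of up to 6 positions where all $4^6$ paths can be summed
directly.

Known limitations:

* One shared dispersion $c$ across libraries and states; no
  GC/mappability covariates.
* The null for peak p-values conditions on the fitted expression of
  the gene; genes whose expression is itself mis-estimated (near-zero
  coverage) can yield optimistic p-values for isolated read stacks.
* Hard-assigned event-mixture training makes the outer loop a
  generalized EM (see above).
* No differential binding between conditions, and no FDR alternative
  to Bonferroni.
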