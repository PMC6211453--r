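# clipHMM

Protocol-agnostic peak calling for CLIP-seq data with a four-state
non-homogeneous hidden Markov model.

## The problem

CLIP-seq experiments (PAR-CLIP, HITS-CLIP, iCLIP, eCLIP and variants)
sequence RNA fragments that were crosslinked to a protein of interest.
Binding sites appear as read pileups, but pileup height is badly
confounded: highly expressed transcripts accumulate reads whether or
not they are bound, local biases inflate some regions in every
library, and counts are overdispersed across biological replicates.
The crosslink chemistry leaves a second, more specific trace —
*diagnostic events* such as T>C conversions (PAR-CLIP), deletions
(HITS-CLIP) or read truncations (iCLIP/eCLIP) — but which event type
is informative differs by protocol.

clipHMM addresses both problems at once: it jointly models read
coverage in all CLIP and background/input libraries with a
negative-binomial GLM that absorbs library size, gene expression and
overdispersion, and it learns the relevant diagnostic-event signature
directly from the data with a Dirichlet-multinomial mixture, so the
same model applies to any CLIP flavour without protocol-specific
tuning.

## The model

Each gene's positions are segmented by an HMM with four states: peak
(`P`), background higher than CLIP (`B1`), background equal to CLIP
(`B2`), and no coverage (`N`). Two emission terms are multiplied at
every position *i*:

**Coverage.** Counts in library *w* are negative binomial with
variance `mu + c*mu^2` and state-dependent log mean; for a CLIP
library *u* with per-gene expression `beta_g`, enrichment
`beta_{G+1} >= 0`, background intercept `beta_0` and log size factor
`l_u`:

    log mu = l_u + beta_g + beta_{G+1}   if state = P
             l_u + beta_g - beta_{G+1}   if state = B1
             l_u + beta_g                if state = B2
             l_u + beta_0                if state = N

with the enrichment signs mirrored for background libraries. The
coefficients are fitted by posterior-weighted sparse IRLS (one
indicator column per gene keeps the normal equations sparse),
alternating with 1-D maximum likelihood for the shared dispersion
`c`.

**Diagnostic events.** The count vector of the 18 event categories
(12 substitutions, 4 deletions, 5'/3' read ends) plus a "no event"
slot is modelled as a K=10 Dirichlet-multinomial mixture whose latent
event-rate vector is shared by all replicates at a position. The
peak-state mixture is trained on CLIP-library events at peak
positions, the background mixture on background-library events at the
same positions, by EM with random restarts plus a warm start.

Transition probabilities depend on local coverage through a logistic
function — the segmentation is stiffer where more data are available.
Peaks are maximal Viterbi runs of the `P` state, scored by the
log-likelihood ratio against the best competing state, and filtered
by a negative-binomial tail p-value on total CLIP coverage
(Bonferroni-corrected, `p_adj <= 0.05`).

The package also ships the benchmark simulator: log-normal gene
expressions `exp(N(10, 4))`, NB replicate counts with variance
`mu + 0.1 mu^2`, CLIP libraries filtered to motif-overlapping reads
with score-dependent retention, A>T conversions planted at the 4th
motif base in 50% of crosslink-covering reads, and 10% non-specific
read admixture.

## Worked example

```r
library(clipHMM)

cfg     <- simConfig(n_genes = 50, n_reads = 5e4, seed = 42)
sim     <- simulateClipData(cfg)
tensors <- readClipData(sim$readsets, sim$roles, sim$genes)
model   <- emFit(tensors, seed = 1)
model
#> ClipModel: 8 EM iterations
#>   final log-evidence: -1565846.25
#> CoverageGLM: 50 genes, beta0 = -1.905, enrichment = 1.151, c = 0.8687
#>   library log sizes: bg1=1.06, bg2=0.95, clip1=-2.13, clip2=-1.79
#> TransitionModel: stay prob = plogis(4.759 + 0.113 * log1p(cov))

peaks <- callPeaks(tensors, model)
peaks[1:3]
#> GRanges object with 3 ranges and 5 metadata columns:
#>       seqnames    ranges strand |     gene_id    summit site_score      p_value
#>   [1]   simchr 5903-5960      + |     gene003      5932   237.5111 2.24006e-113
#>   [2]   simchr 5996-6031      + |     gene003      6019    57.2597  3.05649e-15
#>   [3]   simchr 8559-8594      + |     gene004      8559    31.0790  4.56094e-12
```

The fitted enrichment (`beta = 1.15`) says peak positions carry about
`exp(2 * 1.15) ~ 10x` more CLIP than background signal after size and
expression normalization. On this 50-gene simulation the model calls
71 peaks; 74.6% of their summits fall exactly on a planted crosslink
site, and the fitted per-gene expression coefficients rank-correlate
with the true simulated abundances at Spearman rho = 0.947:

```r
mean(peaks$summit %in% GenomicRanges::start(sim$truth$sites))
cor(geneCoefficients(coverageModel(model))[names(sim$truth$abundance)],
    sim$truth$abundance, method = "spearman")
```

Real data enter through `runPipeline()` (SAM/BAM alignments + GTF
annotation, BED6+ peaks out) or the thin command-line wrapper
`inst/scripts/cliphmm.R` with subcommands `run`, `simulate`,
`score-motifs` and `shuffle-control`.

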