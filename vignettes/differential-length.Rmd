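---
title: "Testing differential transcript length in nanopore direct RNA sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing differential transcript length in nanopore direct RNA sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanolen)
```

## The problem

Nanopore direct RNA sequencing reads native transcripts from the 3'
poly(A) end toward the 5' end, so the aligned span of each read on its
transcript is a direct measurement of the length of the molecule that was
sequenced. Processes that shorten RNA — notably 5'→3' exonucleolytic decay
after decapping or endonucleolytic cleavage, as seen under oxidative
stress — shift the distribution of those per-read lengths. The question
this package answers is: *for which transcripts is read length
systematically different between two conditions?*

The statistical difficulty is that reads are not independent samples:
reads from the same sequencing library share library-level effects
(RNA quality, capture efficiency, pore behaviour on that flow cell), so a
library that happens to produce slightly shorter reads contributes
hundreds of correlated observations. A test that ignores this structure is
badly anticonservative — it mistakes replicate-level noise for a condition
effect, and deep libraries dominate the estimate.

## The model

For each transcript (or gene) with read-length vector $Y$, the core model
is a linear mixed model with the condition as a fixed effect and the
library identifier as a random intercept:

$$Y = \beta_0 + \beta_{cond}\,cond + u_{lib} + \epsilon,
\qquad u_{lib} \sim N(0, \sigma^2_{lib}),\quad
\epsilon \sim N(0, \sigma^2).$$

$\beta_{cond}$ is the mean length difference (treated minus control, so
negative values mean shortening in the treated condition), in nucleotides
on the raw scale. With the `logscale` option, lengths are
log2-transformed before fitting and $\beta_{cond}$ is directly a log2
fold change. Significance is assessed with a Wald test on
$\hat\beta_{cond}$. Two simpler models are available: an ordinary
regression equivalent to the pooled two-sample t-test (which, like the
LMM, accepts extra per-library covariates), and the Wilcoxon rank-sum
test (condition only, no covariates). P-values are adjusted across
features by Benjamini–Hochberg step-up (Bonferroni is available behind
the `adjust` option).

### The Wald reference distribution

With only a handful of libraries per condition — three versus three is
typical — the reference distribution of the Wald statistic matters a
great deal. The effective sample size for the condition contrast is the
number of *libraries*, not the number of reads, so treating
$\hat\beta/\widehat{SE}$ as standard normal ignores the uncertainty in
$\hat\sigma^2_{lib}$ and is markedly anticonservative: in the simulation
design below, the normal-reference Wald test under maximum likelihood
rejects a true null about 17% of the time at the 5% level. The package
therefore defaults to the Satterthwaite degrees-of-freedom approximation
under REML (as implemented in `lmerTest`), which holds the empirical
type-I error at its nominal level (about 4.5–5% in the same design).
Both choices are exposed: `fit_lmm(..., reml = FALSE,
df_method = "normal")` gives the ML/normal variant for comparison.

### Degenerate fits

When the estimated library variance is zero (a singular fit) the mixed
model is not identified as such; the model then degenerates exactly to
the fixed-effects regression, so the package refits by OLS and flags the
result `singular_fallback` rather than dropping the feature or reporting
an unstable fit. Features whose fit fails outright are kept in the output
with a `failed: …` status so that filtering is never silent.

## From alignments to the length table

`extract_read_lengths()` converts transcriptome-space BAM/SAM alignments
into the canonical per-read table. Three conventions matter:

* **Length is the reference-aligned span** (`three_p - five_p` in 0-based
  half-open transcript coordinates), not the basecalled read length.
  Soft-clipped bases, adapter sequence and the poly(A) tail are thereby
  excluded; what remains is the templated span on the transcript, which
  is the quantity that decay shortens. The alternative (query length)
  would conflate tail-length and adapter variation with RNA length.
* **Only primary, mapped alignments** are used, so a multi-mapping read
  contributes exactly one observation.
* **Filters are explicit and logged.** `join_polya_pass()` keeps only
  reads whose poly(A) estimation QC tag is `PASS` — reads absent from
  the poly(A) table are dropped, since an unknown tail status is not a
  pass. `filter_by_adapter()` keeps reads whose 5' adapter certifies a
  complete 5' end. `filter_min_reads()` requires at least `min_reads`
  (default 5) reads *per condition*: the threshold is applied on both
  sides because a two-group test with an empty or near-empty side is
  meaningless. All filters are idempotent and the read-level filters
  commute.

## The simulation engine

`sim_scenario()` / `run_simulation_study()` implement the generative
model used to characterize the tests, which is the fitting model itself:

* true length $L$ (default 1000 nt); because both variance components
  scale with $L$, the results are insensitive to this choice and a
  single value suffices;
* per-library random intercept $\sim N(0, (0.10\,L)^2)$;
* condition means $L$ (control) and $L \times prop$ (treated), where
  $prop \in (0,1]$ is the shortening proportion and $prop = 1$ is the
  null;
* per-read residual noise $\sim N(0, (0.20\,\mu_c)^2)$ around the
  condition mean $\mu_c$. We read "SD 20% of the expected length mean"
  as the condition-specific mean (shortened reads are proportionally
  less variable); the grand-mean reading is available via
  `resid_reference = "grand"`;
* 3 control + 3 treated libraries, `count` reads per library, 1000
  genes per scenario; lengths are truncated at 1 nt by resampling,
  which at these variance fractions essentially never triggers.

Two reproducibility devices are worth knowing about. Each gene draws
from its own RNG substream (L'Ecuyer-CMRG) spawned from the scenario
seed, so per-gene data do not depend on evaluation order. And across the
cells of a study grid, a gene re-uses the same standardized draws
(common random numbers): its library effects and residual stream are
held fixed while the read depth or shortening proportion changes, so
power and bias comparisons across cells measure the design change, not
independent sampling noise. Read depths are nested — the depth-50 data
are the first 50 draws of the depth-200 data.

The validation suite runs this engine at the design above over read
depths {10, 50, 100, 200} and proportions {0.5, 0.7, 0.9, 1.0} with 1000
genes per cell (the problem size used throughout this package's checks),
and verifies: empirical type-I error within three binomial Monte Carlo
standard errors of 0.05 for the LMM at every depth; mean estimate within
5% of $L(prop-1)$ at depths ≥ 50, with per-gene absolute error shrinking
as depth grows; and power non-decreasing in depth, non-increasing in
proportion. The same null is also run through the t-test and Wilcoxon:
with a 10% library SD these read-level tests reject far above the
nominal level (empirically around 50–60%), which is precisely the
motivation for the random effect — the package reports them honestly
rather than hiding the comparison.

### What the generator does and does not emulate

The simulation is length-only: it produces the read-length vector the
tests consume, under normal library and residual noise. It does not
emulate nanopore basecalling error, alignment artifacts, 3'-end
variation, coverage bias along the transcript, or non-normal length
distributions (e.g. the bimodality of a partially degraded pool). A pass
on simulated data therefore demonstrates that the statistics behave as
designed under their own assumptions — controlled false positives,
unbiased effect recovery — not that real libraries satisfy those
assumptions. The synthetic alignment fixtures (below) add the
coordinate-level plumbing but share the same simplification.

## Transcript anatomy

**Meta-length.** To compare fragmentation across transcripts of very
different lengths, each transcript is divided into 20 equal bins indexed
0–19 and a read's 5' and 3' templated ends are assigned bin
coordinates; the meta-length is the spanned bin count as a percentage of
full length: $(bin_3 - bin_5 + 1) \times 5\%$. The $+1$ makes a
full-length read exactly 100% and a read within one bin 5% — the
bin-difference-only alternative would map full-length reads to 95%. The
3' bin is computed on the last covered base (`three_p - 1`), respecting
half-open coordinates. Meta-length is invariant under joint scaling of
the transcript length and the read's end positions (its 5' start and its
last covered base — scaling the exclusive end instead would push
boundary-adjacent 3' ends into the next bin), and is always a multiple
of 5 between 5 and 100.

**TSS calling.** Read 5' ends are pooled across libraries; within the
annotated 5' UTR (positions strictly upstream of the CDS start), the
position with the highest 5'-end count is called as the TSS provided it
has at least five supporting reads at that position. Ties are broken
toward the 5'-most position, favouring the longest plausible start.
Features without a UTR annotation are skipped and counted.

**5'-end composition.** For each read, reference transcript bases at
offsets around the 5' end (default ±10 nt) are tallied into per-offset
A/C/G/T frequencies; offsets outside the transcript are skipped rather
than padded, so totals shrink near boundaries. Composition is computed
on the reference sequence, not the basecalled read, so basecalling error
does not enter; uracil is reported as T.

## Synthetic fixtures

`generate_fixtures()` writes a complete, fully known mini-experiment:
per-library indexed transcriptome BAMs (3'-anchored reads with a
per-condition 5' truncation distribution), the transcript FASTA,
annotation, metadata, an adapter read-ID list, and a truth table of every
intended span. `extract_read_lengths()` reproduces the truth table record
for record, and the default spec (six transcripts, 3+3 libraries, treated
reads losing on average 30% of each transcript from the 5' end versus 2%
in controls) is recovered end-to-end as uniformly negative, significant
length differences.

## A worked example

```{r example, eval = FALSE}
dir <- tempfile()
paths <- generate_fixtures(default_fixture_spec(count = 50), dir,
                           seed = 42)
tab <- ingest_fixtures(paths)
design <- load_design_table(paths$metadata, reference = "control")
tab <- filter_min_reads(tab, design, min_reads = 5)
res <- run_differential_length(tab, design, test_config("lmm"))
head(res)
```

On the command line the same pipeline is
`nanolen fixtures`, `nanolen ingest`, `nanolen test`; simulation studies
run with `nanolen simulate`, and the anatomy computations with
`nanolen metalen`, `nanolen tss` and `nanolen composition`.

## Known limitations

* Two-condition designs only; no paired or longitudinal structure.
* Library random effects are assumed homoscedastic across conditions
  (one $\sigma^2_{lib}$), matching the single random-intercept model.
* The Wilcoxon option cannot absorb library effects or covariates; with
  replicate-level variation present it should be interpreted as a
  descriptive, not inferential, tool.
* All coordinates are transcript-space; spliced genome-space alignments
  must be projected to transcripts upstream.
* Aligned span slightly underestimates molecule length when alignments
  are locally clipped; since clipping affects both conditions, the
  between-condition contrast is robust to it.
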