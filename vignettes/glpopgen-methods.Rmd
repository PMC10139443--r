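---
title: "Genotype-likelihood population genomics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-likelihood population genomics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glpopgen)
```

## Why genotype likelihoods

Low-coverage whole-genome resequencing (1-17x per individual) cannot support
confident hard genotype calls: at 4x, a true heterozygote shows both alleles
only about 87% of the time.  `glpopgen` therefore propagates per-genotype
likelihoods `P(reads | g)` through every downstream analysis - allele
frequencies, site frequency spectra, diversity statistics, Fst and the
population branch statistic, PCA, admixture, inbreeding, and linkage
disequilibrium - calling hard genotypes only where an analysis (the
Treemix-style allele-count tables behind the F-statistics) requires them.
The package is built around an invasive three-population system (Andes,
Central and North demes of a crop pest, plus an out-of-range colony), but
every component is generic.

## The coalescent generator

All statistical machinery is exercised against a built-in backward-time
coalescent simulator (`simulate_genotypes()`, `simulate_sfs()`), so the whole
pipeline is testable without external data.  The engine supports:

* piecewise population-size epochs, each constant or exponentially growing;
* population splits (backward merges) on the fixed rooted topology
  ((Andes, Central), North), with the joint Andes/Central lineage carrying
  the Andes branch's size between the two splits and the ancestral size
  `N_anc` beyond the older split;
* instantaneous resizes, continuous migration, and admixture pulses that
  found a fourth sampled deme as an alpha : (1 - alpha) mixture;
* infinite-sites mutation, and Hudson-style ancestral recombination in
  sequence mode (descendant sets are 64-bit masks, so sequence mode handles
  up to 64 haplotypes - ample for 4-8 diploids per deme as in the motivating
  study design).

The three model variants mirror a standard nested family: `constant`
(6 parameters), `growth` (9), and `resize` (12).  Counting conventions for
such models differ by whether the ancestral size is tied to the pre-split
lineage; `fix_anc = TRUE` provides the tied variant rather than guessing a
single convention.

Two tabulation modes exist.  *Sequence mode* returns haplotypes.  *SFS mode*
simulates independent single-site genealogies and accumulates the branch
length subtending every joint derived-allele-count class; by the
infinite-sites argument these lengths are proportional to the expected
unlinked-site SFS, with far less Monte-Carlo noise than counting simulated
mutations.  Mutation dropping (`theta_site > 0`) is still available to
generate finite observed SFS counts.

Default rates follow the motivating system: mutation 2.9e-9 per bp per
generation and recombination 2.97e-8 crossovers per bp per generation
(2.97 cM/Mb; the literature sometimes prints this figure with a
dimensionally inconsistent unit, and the crossovers-per-bp reading is the
one used here).  Recombination defaults to 0 because SFS-based statistics do
not require linkage; LD analyses switch it on.

Simulated reads use a single symmetric base-error parameter epsilon and
Poisson depth.  This emulates the uncertainty structure of low-coverage
data but none of its mapping artefacts: no reference bias, no indels, no
mapping-quality variation, no batch effects across lanes.  Tests passing on
these data demonstrate correctness of the estimators under the stated
noise model, not robustness to real-data artefacts.

## Genotype likelihoods and filters

`gl_from_pileup()` uses the standard symmetric-error model
(`P(base|allele) = 1 - eps` or `eps/3`; heterozygotes average the two
alleles).  Sites are oriented major/minor by an EM allele-frequency estimate
(`estimate_maf()`, monotone in likelihood), tested for polymorphism by a
likelihood-ratio test against the nearer monomorphic boundary referred to
chi-square(1) (the boundary one-half mixture would halve these p-values;
at the default threshold of 1e-6 the distinction never changes a decision),
and filtered in a fixed, documented order: SNP test, minimum minor allele
frequency, greedy 500-bp distance pruning anchored at the first SNP of each
contig, then missingness rules (a global 20% ceiling, and removal of sites
with no data in an entire sampling location).  Genotype calling combines the
GLs with a Hardy-Weinberg prior extended by per-individual inbreeding
coefficients, emitting a call only at 95% posterior confidence.

## SAF, SFS, and the EM machinery

`saf_site()` computes the likelihood of one population's data given each
possible allele count j by the usual dynamic programme (convolution of
per-individual triples weighted 1, 2, 1), normalised by `choose(2n, j)`.
Its correctness is pinned against brute-force enumeration over all genotype
configurations.  Sites with missing individuals are either dropped or
down-projected hypergeometrically to a common chromosome count; projection
uses a uniform count prior, the standard pragmatic choice.

`em_sfs_1d()` / `em_sfs_2d()` maximise the usual mixture likelihood over
frequency classes (cap 400 iterations, relative tolerance 1e-8 - the cap
follows common practice for genome-scale runs, the tolerance is our choice
since only the cap is conventionally quoted).  Folding is applied to the SAF
likelihoods before estimation.  For the joint spectrum two conventions are
implemented: the default pools the pair and folds cell (i, j) with
(2n1 - i, 2n2 - j) (ties broken to the lexicographically smaller cell), and
`"perpop"` folds each axis independently.  2D estimation accumulates
expected counts in site chunks so genome-scale inputs stream.

## Diversity, Fst, PBS

Per-site diversity uses the genome-wide SFS as an empirical prior:
`E[pi] = sum_j P(j|D) j(2n-j)/C(2n,2)`, and the per-site Watterson term is
the segregation probability over `a_2n`.  Both are folding-invariant.
Tajima's D uses the classic constants and is undefined (NA) at S = 0.

Fst uses the Hudson-type estimator (Bhatia et al.'s recommendation) on
posterior-expected sample frequencies, with the finite-sample corrections
`p(1-p)/(n-1)`; windows report the ratio of sums (weighted Fst), never the
mean of ratios, because rare population-specific variants otherwise bias
the estimate.  A Reynolds-type between-over-total variance ratio is
available behind a switch.  The population branch statistic transforms the
three pairwise window Fsts via `T = -log(1 - Fst)` and reports
`PBS_A = (T_AB + T_AC - T_BC)/2`; the identity `PBS_A + PBS_B = T_AB` holds
to machine precision and is asserted in tests.  Negative window Fst is
clamped to zero before the log; a window Fst of 1 (possible with few,
extreme sites) yields +Inf, which is reported with a warning and excluded
from the top-fraction ranking.  The 5-kb/500-bp sliding windows flag the
top 0.1% of retained windows per population.  Whether the data-sufficiency
threshold counts all covered sites or variable sites is configurable
(`min_sites`); with all-site SAF input the conventional 4-kb-of-data rule
corresponds to the default of 4000.

## Structure: inbreeding, PCA, admixture

Inbreeding coefficients are estimated per individual by EM on the
identity-by-descent mixture prior (monotone log-likelihood), with a direct
search on [-1, 0] when the EM hits the zero boundary, so negative
(outbred) values remain reachable.  PCA follows the iterative low-coverage
scheme: posterior mean dosages under current individual allele frequencies,
rank-K frequency reconstruction, and the standardised covariance
eigendecomposition; variance fractions are eigenvalues over the positive
trace.  Admixture proportions use plain EM on the binomial mixture
(NGSadmix-style updates) with 5 seeded restarts by default - plain EM is
slower than accelerated schemes but its monotonicity is a checkable
invariant at desk scale.  Cluster labels are ordered by total mass so
output is deterministic; seed counts are our defaults, declared rather
than inherited from any published configuration.

## F-statistics

Allele counts per sampling location come from called genotypes (the hard
calls mirror the count-table pathway of graph-based admixture tools);
GL-based frequencies remain available upstream.  `f3_hat()` uses the
per-site product estimator with the target-heterozygosity correction
(denominator `n-1` by default; `n` behind a switch, since published
implementations differ), a delete-one block jackknife over consecutive
500-SNP blocks (trailing partial block merged into the last full block to
avoid one high-variance fragment), and flags `Z <= -3` as significant
admixture - the usual reading of "|Z| >= 3 with negative f3".  The
identity `f3(A;B,C) = [f2(A,B) + f2(A,C) - f2(B,C)]/2` (corrections off)
is asserted in tests.

## Demographic inference

The fitted data are the three pairwise folded 2D spectra among Andes,
Central and North (the pairwise-joint composite is used rather than a 3D
spectrum, matching how 2D spectra are consumed by SFS-based ML tools).
The expected spectrum under a parameter vector is obtained by simulating
unlinked genealogies with common random numbers - a fixed seed makes the
likelihood surface deterministic and smooth enough for direct search.
The composite likelihood is multinomial over retained entries; observed
entries with fewer than 10 counts are excluded, and zero expected
probabilities are floored at 1e-12.

Because the normalised SFS shape is exactly invariant to rescaling all
sizes and times by a common factor, the fit is anchored by the mutation
scale: the total SNP count is modelled as Poisson with mean
`n_loci x theta_site x E[tree length]`, tying parameters to generations
via mu x L, and making the scale identifiable.

Optimisation is Nelder-Mead on transformed parameters: log sizes,
`log T_C` and `log(T_N - T_C)`, and resize times as logit fractions of the
founding time - every proposal is therefore a valid model and the split
ordering `T_N > T_C` is maintained by construction.  Each restart runs up
to three Nelder-Mead cycles (re-inflating the simplex at the previous
optimum, which guards against premature simplex collapse), and an optional
higher-precision polish stage re-optimises from the best restart with a
larger simulation budget to remove Monte-Carlo distortion of the optimum.
Restarts draw log-uniform start points within bounds.

The parametric bootstrap re-simulates at the MLE and refits each replicate.
Refits can start at the parent MLE (cheap, default) or re-draw random
restarts exactly as the original fit did (`refit_starts = "random"`), and
the reported 95% intervals are *basic* (reflected around the MLE) rather
than raw percentile by default: calibration on simulated truths showed the
refits carry a consistent first-order bias which percentile intervals
double and basic intervals cancel.  Even so, interval coverage at desk
scale falls short of nominal (the bundled
`experiment_bootstrap_coverage()` measures roughly two-thirds rather than
95%): with 8 diploids per deme and folded pairwise spectra the composite
likelihood has a long flat ridge between the ancestral size and the split
times, the Monte-Carlo surface displaces the optimiser along it, and
refits cheap enough for routine use under-disperse relative to the true
sampling spread of the estimator.  Genome-scale studies using this
estimator class report the same phenomenon (point estimates outside their
own bootstrap intervals for size parameters); treat the intervals as
optimistic, especially for `N_anc`.

Desk-scale defaults (10^4 genealogies per likelihood evaluation, 20
restarts, 100 bootstrap replicates) are configurable upward to the
10^6-simulation / 100-restart regime of genome-scale studies; the tests
and the acceptance experiments run reduced sizes (documented inline)
chosen to exercise the statistical properties at desk scale.

## LD and the post hoc model check

`r2_em()` estimates two-locus haplotype frequencies from GLs by EM under
random mating and reports `r2 = D^2 / (p1 q1 p2 q2)`; on certain genotypes
it reproduces the classic phase-unknown EM.  `collect_pairs()` enumerates
pairs within 10 kb (with seeded subsampling, as one would subsample a
genome-scale pair list), and `fit_decay()` fits
`r2(d) = r2_min + (r2_max - r2_min) exp(-lambda d)` to bin means by
weighted nonlinear least squares with pair-level bootstrap CIs.  The
three-parameter exponential with free asymptotes is our choice of
functional form - decay-fitting scripts in circulation do not document a
single canonical curve - and a fit whose effective amplitude across the
observed distance range falls below 0.01 is declared flat (lambda = 0)
rather than reporting an unidentifiable rate.  The `fit_level` setting of
such scripts has no documented semantics; it is carried as an opaque
verbosity key and does not alter estimates.  `model_fit_check()` then asks,
for each candidate demographic model, whether decay rates simulated under
the fitted model fall inside the observed 95% CI (closed interval at the
boundary), reporting the distance otherwise and flagging the closest model.

## Numerical conventions and degenerate inputs

* Internal coordinates are 0-based half-open; VCF emission is 1-based.
* All likelihood vectors are log-scaled and max-normalised; flat triples
  mark missing data.
* EM monotonicity is asserted in tests for every EM (MAF, SFS 1D/2D,
  inbreeding, admixture, haplotype frequencies).
* `S = 0` windows have undefined Tajima's D (NA); all-missing sites and
  empty SAF sets raise errors naming the violated precondition.
* Zero-read pileups give flat, missing triples; `mean_depth = 0` is legal
  and produces entirely missing data.
* Seeds: every stochastic entry point takes an explicit integer seed and
  restores the caller's RNG state; identical seeds give bit-identical
  output, which the pipeline's manifest checksums verify end to end.

## Known limitations

* The read model has no mapping/alignment stage, so base and mapping
  quality filters of real pipelines appear only as the single epsilon
  parameter (a real-data mode consumes BEAGLE-GL files produced by
  external callers).
* Sequence mode caps at 64 haplotypes; SFS mode has no such cap.
* No selection, gene conversion, or multi-allelic sites in the simulator;
  f4/D statistics and admixture-graph search are out of scope.
* The SAF inbreeding prior down-weights heterozygote multiplicity
  heuristically; the exact inbreeding-aware SAF of specialised callers is
  not reproduced.
* Parametric-bootstrap intervals at desk scale use few replicates and
  under-cover (roughly two-thirds measured vs 95% nominal; see the
  demographic-inference section for the mechanism).
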