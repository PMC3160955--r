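---
title: "Models and methods behind pedscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pedscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedscan)
```

pedscan maps quantitative trait loci (QTL) in populations where individuals
are unequally related — advanced intercross lines (AILs), heterogeneous
stocks, extended families. Ignoring that relatedness in an association scan
inflates the false-positive rate, because family membership correlates both
with genotype and with the polygenic part of the phenotype. This vignette
describes the statistical machinery, the choices we made where the design
was genuinely open, and what the synthetic-data calibrations do and do not
demonstrate.

## The statistical model

For phenotypes $y$ the working model is

$$
y = X\beta + Q\gamma + u + \varepsilon,
\qquad u \sim N(0, G), \qquad \varepsilon \sim N(0, I\sigma^2_e),
$$

where $X\beta$ are covariate effects, $Q\gamma$ the effect of the locus
under test, and $u$ a polygenic effect. The polygenic covariance is a sum of
up to five genetic terms,

$$
G = \sigma^2_a\,\mathrm{AA} + \sigma^2_d\,\mathrm{DD}
  + \sigma_{adh}\,\mathrm{AD} + \sigma^2_h\,\mathrm{HH}
  + \iota^2\,\mathrm{MH},
$$

plus any non-genetic random components (cage, litter) supplied as extra
matrices. Each incidence matrix is a deterministic function of the pedigree
through Jacquard's nine condensed identity coefficients
$\Delta_1,\dots,\Delta_9$ and the inbreeding coefficients $f_i$:

| matrix | entry $(i,j)$ | diagonal |
|---|---|---|
| AA (additive) | $2\varphi_{ij}$ | $1+f_i$ |
| DD (dominance) | $\Delta_7$ | $1-f_i$ |
| AD | $4\Delta_1+\Delta_3+\Delta_5$ | $4f_i$ |
| HH | $\Delta_1$ | $f_i$ |
| MH | $\Delta_1+\Delta_2-f_if_j$ | $f_i(1-f_i)$ |

with kinship $\varphi = \Delta_1 + (\Delta_3+\Delta_5+\Delta_7)/2 +
\Delta_8/4$. In a completely outbred pedigree the three inbreeding-related
matrices vanish, which is why analyses of outbred AILs typically keep only
AA, DD and the residual — the package's default component set, with the
rest opt-in.

## Exact identity coefficients from the pedigree

For a pair $(i, j)$ the nine $\Delta$s are recovered from nine linear
equations in generalized kinship coefficients — probabilities that
independently drawn alleles are jointly identical by descent:
$\varphi(i,j)$, $\varphi(i,i,j)$, $\varphi(i,j,j)$, $\varphi(i,i,j,j)$, the
paired coefficients $\varphi(ii|jj)$ and $\varphi(ij|ij)$, the two
inbreeding coefficients, and the total probability. Each generalized
coefficient satisfies a recursion that replaces the individual latest in a
topological order by its parents, with boundary rules that account for
independent draws landing on the same physical allele. Founders are taken
non-inbred and mutually unrelated; unknown parents act as unrelated phantom
founders.

We deliberately did not take the recursion transcriptions on faith.
`enumerate_ibd_oracle()` is an independent brute-force verifier: it labels
each founder's two alleles uniquely, enumerates all $4^m$ transmission
patterns of the $m$ relevant meioses, and classifies each pattern into one
of the nine condensed states, giving exact rational probabilities (integer
counts over $4^m$). The test suite requires the recursive engine to agree
with this oracle exactly (to $10^{-12}$ in floating point) on textbook
relationships and on batches of randomized pedigrees; the oracle itself is
pinned by hand-counted cases (e.g. the 16 transmission patterns of a
full-sib quartet split 4:8:4 over $\Delta_7:\Delta_8:\Delta_9$).

The recursion is memoized in compiled code with compact open-addressing
tables, because on deep intercross pedigrees it can visit on the order of
$10^8$ distinct ancestor tuples. Three evaluation schedules are exposed and
return identical values: `bottom_up` recurses lazily from the target pairs
(minimal storage, cost grows quickly with depth), `top_down` pre-fills the
pairwise-kinship cache over the whole pedigree in generation order before
answering queries, and `hybrid` fills that cache only up to a
`split_generation` (default `depth - 6`) and recurses above it — the
practical compromise for very deep pedigrees. The split-generation knob is
this package's concrete realization of a bottom-up/top-down trade-off;
other implementations choose the switch point differently.

One feasibility fact worth knowing: the cost of the exact recursion is
governed less by cohort size than by how many individuals *breed*. In a
hypothetical AIL where every one of 200 individuals per generation is
paired, the reachable ancestor-tuple space grows roughly sixteen-fold per
generation and exact computation at ten generations is out of reach on a
workstation for any evaluation order. Real AILs are maintained from a
limited breeder set, which keeps the space small; see the simulator design
below.

## Variance components by maximum likelihood

`fit_ml()` maximizes the Gaussian likelihood over the variance parameters
with the fixed effects profiled out by generalized least squares at every
parameter point, so the search space is just the component parameters.
Non-negative variances are searched on the log scale; the AD term is a
covariance and is searched unconstrained. If a proposed $\Sigma$ is not
positive definite the objective returns a large penalty
($10^{10}(1+\|\theta\|^2)$), which keeps derivative-free searches inside
the feasible region without projections. Defaults: Nelder–Mead (more
robust than gradient methods on these profiles; BFGS is available and the
two agree to $10^{-4}$ on well-conditioned problems), relative tolerance
$10^{-8}$ on the objective, at most 5000 iterations, and an initial value
that splits the phenotypic variance equally across components. ML rather
than REML is used throughout; at the sample sizes of interest the
difference is within Monte-Carlo noise, and the downstream scan treats
$\hat\Sigma$ as fixed either way.

Single-component significance tests sit on the boundary of the parameter
space under the null, so `lrt_component()` defaults to the 50:50
$\chi^2_0{:}\chi^2_1$ mixture p-value; the plain $\chi^2$ is available,
flagged as such. Model selection (`select_components()`) is greedy forward
inclusion by AIC (or a forward LRT), with ties broken by candidate order.
AIC-forward is this package's choice; nothing in the underlying methodology
prescribes a specific selection rule.

### Identifiability of dominance

Additive and dominance relatedness are nearly collinear in a single cohort
of full sibs: both matrices then differ from a constant background only on
sib pairs, and single-replicate ML routinely collapses to a boundary. Two
design features break the collinearity: half-sib families (additive ¼,
dominance 0) and parent–offspring pairs (additive ½, dominance 0 when
outbred). The calibration fixtures therefore use harem breeding (each sire
mated to about two dams) and phenotype two adjacent generations. Users
fitting DD on their own data should check that their pedigree carries such
contrasts; with only full-sib structure the DD estimate is unstable even
though the fit converges.

## Genome scans with the covariance held fixed

Re-estimating all variance components at every marker is unnecessary and
slow, and the scan deliberately does not do it: `scan_one()` treats the
fitted covariance as data. Users who want periodic re-estimation (e.g.
after conditioning on a detected QTL) refit with `fit_ml()` and rescan,
which keeps the estimation and testing modules cleanly separated. The scan
estimates $\hat\Sigma$ once under the no-QTL null, whitens
$y$, $X$ and the locus codings by its Cholesky factor, and tests each locus
by the likelihood ratio of ordinary regression in the whitened space:

$$
\mathrm{LRT} = n \log(\mathrm{RSS}_0/\mathrm{RSS}_1),
\qquad \mathrm{LOD} = \mathrm{LRT} / (2\ln 10),
$$

with locus codings $a = (\text{allele count}) - 1 \in \{-1,0,1\}$ and
$d = 1\{\text{heterozygote}\}$ (default; additive-only optional). P-values
use $\chi^2$ with the number of locus terms actually fitted — 2, or 1 when
the dominance column is collinear at a marker. The LRT (not an F statistic)
was chosen because it yields an additive LOD scale and is pinned exactly,
marker by marker, against an independent `lm()`-based ordinary-regression
oracle when $\Sigma = \sigma^2 I$; its invariance to rescaling of
$\hat\Sigma$ is also asserted. Markers with missing genotypes drop only the
affected individuals for that marker, with $\Sigma$ subset and re-factored
for that marker alone; monomorphic or all-missing markers are flagged
untestable rather than reported.

Interval mapping follows the Haley–Knott idea for biallelic markers: at a
query position the three genotype-class probabilities are computed from the
nearest non-missing flanking markers under a two-point Markov
approximation — ordered two-haplotype states with a uniform founder-origin
prior (F2-like), Haldane distances, no interference — and the scan uses
the expected codings $E[a]$ and $E[d]$. At a typed marker the probabilities
collapse onto the observed genotype; with no typed marker on the
chromosome the (¼, ½, ¼) prior is used with a warning. The default grid
step is 1 cM. Multi-allelic markers are out of scope.

Two-locus scans (`scan_two()`) test interaction terms (additive-by-additive
by default, all four products optionally) on top of both loci's marginal
terms, for all inter-chromosome pairs and intra-chromosome pairs at least
20 cM apart — closer pairs are too collinear to interpret. Forward
multiple-QTL mapping (`forward_multiple_qtl()`) repeatedly adds the
genome-wide best locus to the covariates while its LRT clears a threshold,
excluding already-selected loci from later scans.

## Empirical significance thresholds

Genome-wide thresholds come from the distribution of the genome-wide
maximum statistic under a null that preserves the structure of the data:

* **Permutation** (`permutation_threshold()`): whole genotype *rows* are
  permuted jointly across markers — preserving each genome's internal LD —
  while the phenotype, covariates and $\hat\Sigma$ stay fixed. Valid when
  the covariance model is correctly specified, because the whitened
  residuals are then exchangeable.
* **Gene dropping** (`gene_drop_threshold()`): null genotypes are simulated
  through the pedigree — founder alleles assigned (two-strain mode by
  default, or explicit founder haplotypes to condition on observed founder
  genomes; both modes exist because either convention is defensible),
  each meiosis recombining with probability `haldane(d)` between adjacent
  markers, no interference. Dropped genomes carry the same family
  structure as the real ones, so the threshold remains calibrated even
  when the scan ignores polygenic variation entirely.

Thresholds are empirical type-7 quantiles (default $q = 0.95$, 1000
replicates) of the per-replicate maxima; both methods are reproducible
bit-for-bit given a seed. The acceptance suite exercises the central
control property at reduced scale: on polygenic-null AIL simulations
(100 outer replicates, 200 null replicates each), the gene-dropping
threshold keeps the genome-wide type-I error inside the binomial 95%
interval of 0.05 both with a correct $\hat\Sigma$ and with $\Sigma$
misspecified as $\sigma^2 I$, while permutation is calibrated only in the
correct case and inflates significantly (one-sided binomial test) under
misspecification.

## The synthetic AIL factory

All tests and calibrations run on data from `sim_ail()` and
`sim_phenotypes()`; no external data are needed. The simulator crosses two
inbred strains (F0, coded 2 and 0 at every marker), produces an F1, and
breeds subsequent generations with no selfing. Its design choices emulate
real mouse AIL husbandry:

* **Breeder set**: one breeding couple per ~4 offspring (mouse-like litter
  size), rather than pairing every individual. This is how AILs are
  actually maintained, and it is also what keeps exact identity-coefficient
  computation tractable at depth (see above).
* **Harem mating**: each sire serves about two dams, producing both
  full-sib and half-sib families — the contrast that identifies dominance
  variance. A `sib_mating` scheme is available for rapid-inbreeding
  scenarios.
* **Phenotypes**: $y = X\beta + Q\gamma + u + \varepsilon$ with
  $u \sim N(0, \sigma^2_a \mathrm{AA} + \sigma^2_d \mathrm{DD})$ drawn by
  Cholesky factorization (symmetrized, with at most $10^{-8}$ jitter,
  logged, if a numerically semidefinite case arises), QTL effects applied
  through the $a$/$d$ codings, and the true polygenic values returned for
  diagnostics.

Default calibration scales, chosen so the whole suite runs in minutes on
one CPU: genome of 3–5 chromosomes × 50–60 cM with 13–60 markers each;
cohorts of 100–200; the variance-recovery study uses a five-generation AIL
phenotyping the last two generations ($n = 400$, truth
$\sigma^2_a = 1, \sigma^2_d = 0.5, \sigma^2_e = 1$, 20 replicates); the
threshold calibration uses $n = 128$ with strong polygenic signal
($\sigma^2_a = 3$); the strategy-invariance check uses a ten-generation,
200-per-generation pedigree with all pairs of 16 sampled targets.

What these simulations do *not* capture: genotyping error, missing-data
mechanisms that depend on genotype, selection and mutation during breeding,
crossover interference, X-linked loci, and phenotype non-normality. Passing
calibrations demonstrate internal consistency of the machinery under its
own model, not robustness to those violations.

## Numerical notes and limitations

* Symmetric matrices are enforced by averaging $(M + M^\top)/2$ after
  assembly from per-pair values; tiny negative solver noise (below
  $10^{-13}$) in structural zeros of $\Delta$ is clamped to 0.
* The 9×9 linear system mapping generalized kinship coefficients to
  $\Delta_1,\dots,\Delta_9$ has condition number ≈ 326, so no meaningful
  precision is lost in the solve.
* Scan ties at identical LRT values are resolved by marker order (first
  wins) in forward selection.
* Individuals missing a genotype at a *selected* marker in forward
  selection have that locus coding mean-imputed (0) so they are not lost
  to every later step.
* `fit_ml()` with a single parameter uses Brent line search rather than
  Nelder–Mead, which is unreliable in one dimension.
* Pedigree depth beyond ~10 generations with hundreds of *breeders* per
  generation will exhaust memory in any exact evaluation order; the hybrid
  schedule extends the reach but does not change the asymptotics.
* The X chromosome, founder inbreeding priors, REML, and multi-allelic
  Haley–Knott are out of scope.
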