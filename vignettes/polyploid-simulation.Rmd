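---
title: "Simulating genotypes, traits and genomic selection in polyploids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genotypes, traits and genomic selection in polyploids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysim)
set.seed(1)
```

polysim is a forward ("gene dropping") simulator of genotypes and complex
phenotypes for species of arbitrary even ploidy $h$, built to evaluate
genomic-selection (GS) strategies in crops such as tetraploid potato and
octoploid strawberry. This vignette is the package's own account of the
models it implements, the parameters that matter, and the design choices
made where more than one reasonable reading existed.

## Genome representation and gene dropping

Founder genotypes enter as phased haplotypes: per chromosome, a vector of
physical positions (bp, 1-based as in VCF) and an $h n_f \times m$ matrix
of 0/1 alleles, one row per *haplotype slot*. Slots $(1,2), (3,4), \dots,
(h-1,h)$ are the homologous pairs, in the same order as the alleles of the
VCF `GT` field. Unphased genotypes (and plain dosage tables) are expanded
to a random phase: the $c$ alternative alleles of a dosage-$c$ call are
placed into slots by a uniform random permutation, which preserves dosage
but destroys phase information — appropriate when the input phases are
unknown anyway and linkage disequilibrium (LD) is to be created afterwards
by base-population expansion.

Descendants of the pedigree never store allele vectors. Each chromosome
copy is a *mosaic*: an ordered list of (segment start, founder-haplotype
index) pairs, with segments half-open $[s_k, s_{k+1})$. A genotype query is
a binary search over breakpoints followed by a lookup in the founder
matrix, so simulation cost is independent of the number of loci and any
SNP panel can be re-queried after the fact (the restart file serialises
exactly these mosaics). Breakpoints live in continuous bp, aligned to
crossover positions rather than snapped to loci, for the same reason.

The test suite pins this machinery to an independent oracle: a dense
simulator that copies full allele vectors at every meiosis, replaying
identical random draws. Both engines consume their randomness exclusively
through `sample_meiosis_plan()`, so equality is required bit for bit, not
approximately.

## Meiosis across the autopolyploid–allopolyploid continuum

Within one homoeologous group the probability that copies $i \neq j$ pair
at meiosis is

$$R_{ij} = \frac{1}{h-1} + \theta_{ij},$$

with $R$ symmetric, zero-diagonal and row-stochastic. A scalar
*preferential pairing factor* $\theta$ is applied to the homologous pairs
and compensated by $-\theta/(h-2)$ elsewhere so rows still sum to one.
$\theta = 0$ gives random (polysomic) pairing; $\theta = 1 - 1/(h-1)$
forces homologues to pair (disomic inheritance). Intermediate values span
the continuum; an explicit $h \times h$ offset matrix is accepted verbatim
for asymmetric cases.

A pairing configuration is sampled by letting the lowest unpaired slot
draw its partner with probabilities proportional to $R$ restricted to the
slots still free. This is exact at both limits (uniform over the three
tetraploid matchings at $\theta = 0$; deterministic in the strict
allopolyploid) but for intermediate $\theta$ the realized marginal pairing
rates are not claimed to equal $R$ exactly — `pairing_frequencies()`
reports them empirically instead. Several conventions are deliberate
simplifications, stated here once:

* **Bivalents only.** The pairing model is pairwise, so multivalents and
  double reduction are out of scope.
* **Crossovers** are Poisson in the chromosome's genetic length with
  positions placed by the inverse genetic map (Haldane, no interference).
  The crossover model is not dictated by the pairing formulation; this is
  the standard minimal choice. When no map is supplied, 1 cM/Mb per
  chromosome is assumed — a documented, overridable convention.
* **Transmission** keeps one recombinant product per bivalent, starting
  from either strand with probability 1/2 (two-strand simplification).
  This yields correct Mendelian marginals without four-chromatid
  bookkeeping.
* $\theta$ affects **pairing only**, not the within-bivalent recombination
  rate, and pairing is resampled independently per chromosome and per
  meiosis. Both points are unstated in the formulation the package
  follows; these are this package's choices.

Offspring interleave the two parental gametes so that slot pairs keep one
product of each parent's $k$-th bivalent; under strict allopolyploid
pairing this keeps sub-genome identity attached to the slot pairs across
generations, which is what makes disomic inheritance checkable (and
checked) from founder-haplotype indices alone.

`expand_basepop()` creates additional founders by random crossing of the
available ones (monoecious, with replacement, selfing allowed — "random
crossing" is otherwise underspecified) and random breeding for a given
number of generations. Its purpose is to induce LD when founder phases
were generated at random; founder mosaics themselves carry no
recombination history.

## Phenotypes

A trait with $Q$ QTNs has genotypic value

$$g_i = \mu + \sum_{j=1}^{Q} \left(c_{ij} - \tfrac{h}{2}\right) a_j
      + \sum_{j=1}^{Q} \mathbf{1}[c_{ij} \ge \varphi_j]\, d_j,$$

where $c_{ij}$ is the allele dosage, $a_j$ the per-copy additive effect,
$d_j$ the dominance effect and $\varphi_j \in [1, h]$ the dominance
threshold: the minimum copy number at which $d_j$ is expressed
($\varphi = 1$ by default, i.e. classical complete-dominance behaviour).
Two readings of threshold dominance are defensible and the package exposes
both as `dominance_mode`:

* `"literal"` (default): the additive term always grows by $a_j$ per copy
  and $d_j$ is *added* once $c \ge \varphi$, exactly as the formula above.
* `"plateau"`: the additive dosage saturates at $\varphi$
  ($\min(c,\varphi) - h/2$), so all genotypes at or above the threshold
  share one expected phenotype. What happens *below* $\varphi$ in this
  mode (linear growth) is this package's choice; the plateau picture
  leaves it open.

At $h = 2$ the dominance indicator $\mathbf{1}[c \ge 1]$ would also fire
for the alternative homozygote ($c = 2$), which is not what the classical
diploid model's heterozygote indicator $\delta$ does. The diploid code
path therefore uses $\delta = \mathbf{1}[c = 1]$, recovering
$g = \mu + \gamma a + \delta d$ with $\gamma \in \{-1, 0, 1\}$ exactly;
the discrepancy only exists at $h = 2$ and is resolved in favour of the
classical model.

QTN effects can be supplied in a file or sampled from gamma, normal or
uniform distributions. Gamma uses the (shape, scale) parameterisation —
mean $= \alpha\beta$, the dominant convention in the quantitative-genetics
literature — with default $\Gamma(0.2, 5)$, a leptokurtic architecture of
many near-zero and few large effects. Gamma draws are positive, so each
receives a random sign with probability 1/2 (switchable), since QTN
effects must be bidirectional.

Residual variance is calibrated as
$\sigma_e^2 = \mathrm{Var}(g)\,(1 - h^2)/h^2$ against a reference
population — by default the full simulated pedigree, so that the realized
heritability in the analysed data matches the target; founders-only is
selectable. Per-QTN variance contributions are reported as the variance of
each QTN's own term divided by $\mathrm{Var}(g)$; they sum to one only
under linkage equilibrium, and the test suite asserts the sum on an LE
fixture only.

## Relationship matrices

The genomic relationship matrix generalises VanRaden's to ploidy $h$:

$$G = \frac{(M - h p')(M - h p')^{\!\top}}{h \sum_j p_j (1 - p_j)},$$

with $M$ the $n \times m$ dosage matrix and $p$ the allele frequencies
computed from $M$ itself (all genotyped individuals; an external frequency
vector is accepted). The denominator is the *summed* form: the per-marker
reading would not reduce to the standard diploid formula at $h = 2$, and
that reduction is asserted to $10^{-10}$ in the tests. Monomorphic markers
are undefined under either reading; they contribute nothing to the
numerator and are excluded from the denominator sum.

Two scorings model dosage-calling degradation. `MIMIC_DIPLOID` caps
dosages at 2 (only 0, 1, "2 or more" distinguishable) and sets the
effective ploidy to 2; `MIMIC_HAPLOID` keeps presence/absence only with
effective ploidy 1. Each mode's $G$ uses frequencies of its *own* recoded
matrix under its own effective ploidy — each mode mimics an observer who
only ever sees the recoded data.

The pedigree numerator matrix $A$ uses the diploid tabular method
(founders unrelated and non-inbred, $A_{ii} = 1 + A_{sd}/2$). Polysomic
kinship coefficients exist but are out of scope; the diploid convention is
what routine polyploid evaluations use, and it is documented as such.

## GBLUP evaluation

`solve_gblup()` solves the mixed-model equations with a GLS intercept:
$\hat g = K_{\cdot,t} (K_{tt} + \lambda I)^{-1} (y_t - \hat\mu)$, where
$\lambda = (1 - h^2)/h^2$ is fixed from the known simulated heritability
by default — the simulator knows the truth, and estimating what is known
adds only noise. A 1-D profile-likelihood grid (`estimate_lambda_ml()`)
is provided when realism is wanted. If $K_{tt} + \lambda I$ is numerically
singular a diagonal jitter of $10^{-8}$ is added, with a message.

Predictive ability is the Pearson correlation between observed and
predicted *phenotypes* over the test set (the convention in the GS
literature this package follows); the correlation with true genotypic
values is also reported (`pa_g`) as a diagnostic, since the simulator
knows them. `run_gs_experiment()` replicates the whole loop — simulate,
mask the final generation, predict with each requested kinship (true
dosage `GT`, diploid-SNPs-only `G2`, diploidized `G2star`, pedigree `A`,
or a random-marker `noise` floor) — and returns tidy per-replicate
results.

## Sequencing reads to dosages

For genotyping-by-sequencing data the genotype is inferred from the
alternative-read fraction $f$ as the nearest integer to $f h$, clipped to
$[0, h]$. Exact halves are rounded away from zero — "nearest integer"
leaves ties open, so the rule is documented and switchable to
nearest-even. Calls with fewer than 20 reads (default) are set missing,
sites missing in strictly more than 60% of samples are dropped (a site at
exactly the threshold is kept), and remaining gaps are imputed by i.i.d.
draws from the site's observed dosage distribution. Base/mapping quality
thresholds belong to the upstream alignment step and are metadata here.

## Synthetic founder generators and what tests can show

`make_founders()` draws linkage-equilibrium haplotypes (independent
Bernoulli per locus) or ancestral-haplotype mosaics (each founder
haplotype a recombinant of $K$ ancestors with exponential segment lengths)
when LD is wanted; LD strength is controlled by $K$ and the mean segment
length. A coalescent simulator would be more realistic but is not needed
for the properties tested here.

Two packaged scenarios mirror the sizes of published worked examples and
are used as study conditions throughout:

* **Potato-style** (`potato_scenario()`): 150 tetraploid founders at 407
  LE SNPs over 5 chromosomes, base population expanded by 100 individuals
  (2 generations of random breeding), a 100/100/100/150 pedigree on top of
  the 250 founders (700 rows in total), 140 QTNs with signed
  $\Gamma(0.2,5)$ effects, $h^2 = 0.5$, random pairing.
* **Strawberry-style** (`strawberry_scenario()`): 53 octoploid founders at
  1500 SNPs over 7 chromosomes, strict allopolyploid pairing, five
  generations of 100 lines and a terminal generation of 1000 crosses with
  masked phenotypes. 36% of loci are tagged as segregating in a single
  sub-genome pair by *random assignment* — their polymorphism is confined
  to one homologous slot pair so they behave as diploid markers — because
  the classification mechanism behind that observed proportion in real
  data is not described anywhere the package could follow. A further
  third of loci is tagged "pathway" for the candidate-gene architectures
  (`RQP`, `DQP`); `dominant` gene action sets $d = |a|$, $\varphi = 1$.

These generators emulate sample sizes, ploidy, architecture and the
LD-inducing expansion step. They do **not** emulate real potato or
strawberry LD maps, allele-frequency spectra shaped by selection, or true
sub-genome structure. Tests passing on them show the algorithms are
implemented correctly under controlled conditions, not that any particular
real-data accuracy will be attained.

Problem sizes in the test suite are the package's own choices: the
heritability-recovery check simulates 10,000 individuals (realized
$\mathrm{Var}(g)/\mathrm{Var}(y) = 0.50 \pm 0.02$); the oracle-equivalence
check uses 10 founders, 50 loci and 4 generations; the directional GS
comparison runs the strawberry-style scheme with 100 terminal crosses and
20 replicates and asserts the ordering
$\mathrm{PA}(GT) \ge \mathrm{PA}(G2^*) \ge \mathrm{PA}(\text{noise})$ —
an ordering, not a magnitude, because magnitudes depend on the real data
the surrogate does not reproduce.

## Numerical conventions and degenerate inputs

* Positions are 1-based bp; mosaic segments are half-open, so a breakpoint
  exactly on a locus assigns the locus to the new segment.
* Row-stochasticity of pairing matrices is enforced to $10^{-9}$;
  probabilities outside $[0,1]$ (e.g. $\theta$ too large for $h$) are an
  error, not a clamp.
* `h2 = 1` gives $\sigma_e^2 = 0$ exactly; `h2 = 0` requires an explicit
  residual variance, since the calibration ratio is undefined.
* All-monomorphic marker sets, all-missing sites, empty training sets and
  mixed phase separators are errors with actionable messages rather than
  silent degradations.
* Every stochastic routine uses R's global RNG: a single `set.seed()`
  makes entire simulations bit-reproducible, and this is asserted in the
  tests.

## Known limitations

Epistasis is not modelled (a faithful omission, not an oversight), nor are
multivalents, double reduction, mutation, sex chromosomes, copy-number
variation, or polysomic pedigree relationship coefficients. Multiallelic
VCF records are rejected rather than split, because the whole phenotype
model is biallelic. REML variance-component estimation is limited to the
1-D grid search; full Bayesian whole-genome regression is out of scope —
the package exports dosage matrices precisely so external methods can be
applied.
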