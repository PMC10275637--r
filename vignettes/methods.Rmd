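---
title: "Methods: models, parameters and design choices in discoloc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in discoloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discoloc)
```

# Scope and model overview

discoloc dissects pairs of GWAS for loci where both traits share a single
causal variant, with particular attention to *discordant* signals — the
shared allele raising one trait while lowering the other (the motivating
case: alleles that increase abdominal fat accumulation yet protect from
type 2 diabetes). The pipeline is: analysis-window construction →
two-trait colocalization → credible sets → discordance classification and
LD clumping → multi-signal fine-mapping → GWAS–QTL colocalization by two
reconciled routes → annotation-enrichment-based tissue-of-action scoring →
downstream expression statistics. Everything operates on summary
statistics; no individual-level data are touched.

# Colocalization

## Single-variant Bayes factor

For a variant with estimate $\hat\beta$, standard error $se$
($z = \hat\beta/se$) and normal effect prior $N(0, W)$, the approximate
Bayes factor against the point null is, with $V = se^2$ and
$r = W/(V+W)$,
$$\log \mathrm{ABF} = \tfrac12\left[\log(1-r) + r z^2\right].$$
Defaults for the prior standard deviation $\sqrt W$ follow the common
convention: 0.15 for quantitative traits and 0.2 on the log-odds scale for
case–control traits (which the simulators also generate on the log-odds
scale, so the same z machinery applies throughout). Both are
configurable; the package makes no attempt to estimate them.

## Hypothesis posteriors

Per-variant log-ABFs for the two traits are accumulated over the standard
causal configurations — H1: $\sum_i BF_{a,i}$; H2: $\sum_j BF_{b,j}$;
H3: $\sum_i\sum_{j\ne i} BF_{a,i}BF_{b,j}$ (computed as the product of the
H1 and H2 sums minus the diagonal); H4: $\sum_i BF_{a,i}BF_{b,i}$ —
weighted by priors $p_1 = p_2 = 10^{-4}$ and $p_{12} = 5\times10^{-6}$.
The reduced $p_{12}$ (versus the older $10^{-5}$ default) balances false
positives and negatives for well-powered GWAS. All accumulation is in log
space with log-sum-exp: a genome-wide lead variant's log-ABF routinely
exceeds 700, so linear-space arithmetic overflows.

A GWAS–GWAS locus is called colocalized when the *regional* probability
PPH3 + PPH4 exceeds 0.70. The GWAS–QTL stage instead uses PPH4 alone with
threshold 0.50 (strict inequality at the boundary). Both rules are
exposed via a flag because they answer different questions: regionally
shared architecture versus a single shared causal variant.

## Consensus rule and the visual-inspection stand-in

The consensus verdict requires 2 of 3 methods: (i) the ABF regional rule;
(ii) a simplified multi-trait shared-variant posterior,
$\mathrm{per\,variant} \propto \exp(\sum_t \mathrm{lABF}_t)$ with regional
posterior $\mathrm{plogis}(\log p_{12} + \mathrm{logsumexp})$ — a
deliberate simplification of branch-and-bound multi-trait clustering that
considers only the all-traits-share-one-variant hypothesis (for two traits
its per-variant posterior coincides exactly with the ABF route's
`snp_pp_h4`, which the tests assert); and (iii) an automated stand-in for
visual inspection of paired locus plots: the two traits' lead variants
must coincide or be in LD $r^2 > 0.8$. Visual inspection cannot be
formalized; this heuristic is the declared divergence, and its threshold
is configurable. In noisy replicates a moderately linked tag can take the
lead, so the heuristic alone is not expected to fire on every truly shared
locus — that is what the 2-of-3 rule absorbs.

# Credible sets, discordance, clumping

The 99% credible set is the smallest prefix of the descending-sorted
per-variant shared-causal posteriors reaching 0.99, with lexicographic
variant-id tie-breaks for reproducibility. A credible-set member is
discordant iff its harmonized z-scores disagree in sign *and* both traits
pass $p < 10^{-5}$; a z of exactly 0 leaves a variant unlabeled. (Where
source text wavers between $10^{-5}$ and $5\times10^{-5}$ for "nominal"
significance, $10^{-5}$ is taken as canonical and the threshold is a
flag.) Unlabeled members do not block a locus: the locus takes the label
of its lead signal. Signals are formed by greedy LD clumping — seed on the
smallest $\min(p_a, p_b)$, absorb everything with $r^2 > 0.50$ to the
lead, repeat — which matches standard clumping semantics rather than
connected components; the chain counter-example (a–b and b–c linked, a–c
not) is pinned in the tests.

# Fine-mapping

`susie_rss` implements sum-of-single-effects regression on $(z, R)$: the
model is $z \mid b \sim N(Rb, R)$ with $b = \sum_{l=1}^L b_l$, each
$b_l$ single-nonzero with a uniform location prior and effect prior
$N(0, \sigma_{0l}^2)$. Fitting is coordinate ascent: residualize the other
effects' contributions, compute per-variant single-effect Bayes factors,
set that effect's inclusion distribution to their softmax. The variational
objective (unit residual variance, sufficient-statistic parameterization
$X^TX = R$, $X^Ty = z$) is asserted non-decreasing at every iteration and
drives convergence (tolerance $10^{-3}$). Initialization is zeros and the
update order is 1..L, so fits are deterministic.

**Prior variance.** A candidate default of 0.04 on the z scale was
rejected during implementation: with $\hat b \approx z$ and unit sampling
variance it shrinks a $z = 6$ signal's log-BF to about 0.7, flattening the
inclusion distributions and demonstrably failing the coverage targets. The
shipped default is 50 — a weak prior appropriate for z-score
fine-mapping — with per-effect empirical-Bayes estimation of
$\sigma_{0l}^2$ enabled by default; an effect whose estimated prior
variance collapses to 0 carries no signal, flattens, and is subsequently
removed by the purity filter. A sensitivity scan over a prior-variance
grid reports lead-variant stability.

Credible sets are per-effect minimal-coverage sets (95%) filtered by
purity (minimum absolute pairwise LD ≥ 0.5) and deduplicated. Because the
sum-of-single-effects framework has no "PPH4", the upstream notion of a
high-confidence causal call is mapped to a flag: a set whose lead variant
has marginal PIP > 0.70. Raw inclusion matrices and PIPs are always
emitted so users can apply their own rule.

# QTL integration

For each gene within 1 Mb of a discordant window, two routes: (i) ABF
colocalization of the GWAS with the gene's QTL, pass iff PPH4 > 0.50;
(ii) the SMR statistic $T = z_g^2 z_q^2/(z_g^2+z_q^2) \sim \chi^2_1$ at
the top-QTL instrument (the smallest QTL p in the window), with
Benjamini–Hochberg control at 5% across the widest family — every
gene × tissue × kind test run for one GWAS trait — which is the most
conservative choice where the family is unstated, and is recorded in the
manifest. No heterogeneity (HEIDI-style) test is implemented. Route
agreement reconciles to: both → `candidate_causal`; ABF only →
`horizontal_pleiotropy`; SMR only → `locus_level`; neither → `none`. The
eGene catalog reports per-tissue directions with QTL betas aligned to the
trait-protective allele.

# Annotation enrichment and tissue of action

Enrichment is fit once across all colocalized loci under a
one-causal-variant-per-locus model: location prior
$\pi_i \propto \exp(\sum_k \gamma_k a_{ik})$, per-locus marginal
likelihood $\sum_i \pi_i(\gamma) BF_i$ over the per-variant
colocalization Bayes factors, maximized by bounded quasi-Newton
(L-BFGS-B, $|\gamma| \le 10$) from two starts ($\gamma = 0$ and the
empirical estimator), with standard errors from the observed-information
curvature. This is a declared simplification of segment-level hierarchical
enrichment models; for loci already selected for colocalization it targets
the same estimand, and the simulator makes that exact: planting labels
with probability $\mathrm{logistic}(\mathrm{logit}(b_0) + \gamma
\cdot \mathrm{causal})$ implies a posterior location prior
$\propto \exp(\gamma a_i)$, so $\gamma$ is recovered without asymptotic
bias. A closed-form posterior-weighted frequency-ratio estimator is
emitted alongside as a diagnostic. Annotations present at no variant are
reported missing rather than $\pm\infty$.

TOA scores allocate each credible-set variant's posterior mass across
tissues proportionally to $\sum_k e^{\gamma_k} a_{ik}$ over that tissue's
annotations; genome-level annotations (e.g. coding) take precedence and
route the variant's mass to the unclassified share, mirroring the
annotation hierarchy of tissue-of-action scoring tools (configurable).
Unannotated variants and residual credible-set mass are unclassified, so
scores always sum to 1. Classification: top tissue < 0.20 → unclassified;
top-two gap < 0.10 → shared; otherwise the top tissue.

# Expression statistics

Biweight midcorrelation uses the unscaled median absolute deviation:
$u_i = (x_i - \mathrm{med})/(9\,\mathrm{mad})$, Tukey weights
$(1-u_i^2)^2$ inside $|u_i| < 1$, correlation of the weighted deviations,
clamped to $[-1, 1]$ so the bound holds exactly in floating point. A zero
MAD is a hard error (no silent fallback). Significance uses the Student-t
transform on pairwise-complete samples with per-pair $n$ reported —
cohort tables have missingness and listwise deletion would discard
usable pairs. FDR is Benjamini–Hochberg by default; a Storey-type variant
($\hat\pi_0 = \min(1, 2\bar 1\{p>0.5\})$) is available by flag but is
unstable for the small families typical here, which is why it is not the
default. Phenotypes are not transformed by default; any transform is the
caller's responsibility.

The adipogenesis dynamics test is a Gaussian LRT of expression on time
against an intercept-only null, $2\Delta\ell \sim \chi^2_{df}$. Both a
per-timepoint-means ("factor") alternative and a linear-slope alternative
are implemented; the factor model is the default for small candidate-gene
panels because it captures non-monotone differentiation dynamics.
**Calibration caveat:** the chi-square reference is asymptotic; with 9
timepoints the factor alternative spends 8 df and is anti-conservative at
small $n$ (rejection ≈ 0.10 at $n = 45$ in our checks), while the linear
alternative (1 df) is near-nominal. The type-I acceptance check therefore
runs the linear model on the generator's default design (9 timepoints ×
10 replicates, $n = 90$), a choice fixed before measurement; users
wanting calibrated factor-model inference at small $n$ should prefer an
F-test, which is out of scope here.

# Synthetic data: what it emulates, what it does not

Summary statistics follow the RSS model $z \sim MVN(R\lambda, R)$ under an
explicit causal configuration (H0–H4, concordant or discordant signs),
with betas and standard errors reconstructed from z, allele frequency and
sample size. LD is AR(1) ($\rho^{|i-j|}$) or empirical from thresholded
latent-Gaussian haplotypes, ridge-repaired ($\varepsilon = 10^{-6}$ on the
diagonal, then renormalized) so Cholesky draws always work. Defaults are
the stated desk-scale world: $\lambda = 7$ (a strong but realistic
genome-wide signal), decay 0.9 (moderate local LD), $p = 60$–200 variants
per locus, GWAS $n = 5\times10^5$, 80-locus sets with 6 discordant-truth
loci mirroring the structure of the motivating analysis (79 colocalized
loci, 6 discordant signals) at reduced scale. H3 loci plant their two
causals at $r^2 < 0.1$ so the hypotheses are identifiable; on a locus too
small to offer such a pair, the least-linked pair is used. Expression
studies are Gaussian-copula draws hitting target correlations as $n$
grows; time courses are linear trends plus noise over a 16-day design
sampled every 2 days.

Deliberately *not* emulated: recombination maps and demography, allele
frequency spectra, sample overlap between GWAS, winner's curse, strand
errors beyond the ambiguous-variant mechanism, multi-allelic sites, and
count-distributed expression. A green test therefore establishes that the
statistical machinery is correct under its own assumptions — not that the
pipeline is robust to reference-panel mismatch or other real-data
pathologies.

# Numerical and policy choices

* BED intervals are 0-based half-open; variant positions 1-based; the
  conversion lives in one helper (`pos_in_bed_interval`): position $p$
  overlaps $[s, e)$ iff $s \le p-1 < e$, so the last covered 1-based
  position equals $e$.
* Analysis windows run $[pos - f + 1,\ pos + f]$ for flank $f$ and merge
  when the inter-window gap is below 250 kb or they overlap — the reading
  of "proximal windows were merged" that is monotone in flank size.
* Strand-ambiguous (A/T, C/G) variants are dropped by default during
  harmonization; frequency-based resolution is deliberately not attempted.
  Duplicate variant ids are dropped and counted.
* P-values are carried in natural-log space alongside the clamped linear
  value, so lead variants that underflow double precision stay ordered.
* Single global seed, expanded into per-stage and per-locus substreams
  (all below $2^{31}$); every simulator is a pure function of
  (parameters, seed), and the pipeline's outputs are byte-identical across
  reruns.

# Known limitations

One shared causal variant per locus in the colocalization model (no
conditional/iterative multi-signal colocalization, no SuSiE-coloc
hybrid); the multi-trait posterior does not search trait subsets; no
remote LD/annotation services — LD is always a local file; no VCF parsing
or liftover; sQTL inputs are treated as ordinary per-transcript summary
statistics; the enrichment model ignores LD between credible-set variants
when allocating causal-location probability (acceptable at the
desk-scale LD used, mildly attenuating at strong LD).
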