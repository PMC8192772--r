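---
title: "Methods and design notes for coihaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for coihaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coihaps)
```

This vignette documents the statistical machinery in `coihaps`, the
assumptions behind it, the tunable parameters that matter, and the design
choices made where more than one defensible option existed. It states no
empirical result that the package's tests do not themselves compute.

## The data model

The substrate of every analysis is a `coi_alignment`: equal-length DNA
sequences over `{A, C, G, T, N, -}` with unique sample ids, typically an
intraspecific alignment of a mitochondrial protein-coding fragment
(the default parameterizations assume a 595 bp *COI* barcode fragment).
Coordinates are 1-based and inclusive everywhere, so a "site 207" in a
report refers to the 207th alignment column. Characters outside the
alphabet are mapped to `N` on input (with a warning) rather than rejected;
`N` and `-` are treated as *missing* for all site-wise statistics but as
*ordinary characters* for haplotype identity.

**Haplotypes are exact string classes.** Two sequences belong to the same
haplotype iff they are identical strings — no similarity threshold, and `N`
does not wildcard-match. An `N` at a site therefore creates a new haplotype;
this is the conservative choice when no explicit mismatch-tolerance rule is
available, and it is invisible in practice for clean alignments with no
ambiguous calls. Haplotype ids (`H001`, `H002`, ...) are assigned in
descending carrier count with ties broken by first occurrence, making the
naming a pure function of the input; a `name_map` lets users impose
published labels.

## Diversity and neutrality statistics

For a sample of $N$ sequences with haplotype frequencies $p_i$:

* Haplotype diversity uses Nei's unbiased estimator
  $h = \frac{N}{N-1}\left(1 - \sum_i p_i^2\right)$, so $h = 1$ when all
  sequences are distinct and $h = 0$ for a monomorphic sample. Samples of
  size 1 report `NA` ("not determined"), as do all pair-based statistics.
* Nucleotide diversity is computed per pair as differences divided by
  compared sites, then averaged: `pi_raw`. Sites where either sequence of a
  pair carries `N`/`-` are excluded from that pair only (pairwise
  deletion). `pi_jc` applies the Jukes–Cantor transform
  $d = -\tfrac34\ln(1 - \tfrac43 p)$ to each pairwise proportion *before*
  averaging. Both are always reported because published tables are
  ambiguous about which convention they print; the raw value is the one
  that reproduces a table entry computed as (differences)/(length). A
  pairwise proportion $\ge 3/4$ (where the JC distance is undefined) yields
  `NA` for that pair with a warning — intraspecific data should never get
  there.
* $S$ counts columns with $\ge 2$ observed unambiguous states; $K$ is the
  mean pairwise difference count.

**Tajima's D** is implemented from the 1989 constants
($a_1, a_2, b_1, b_2, c_1, c_2, e_1, e_2$) exactly as defined, with
$D = (K - S/a_1)/\sqrt{e_1 S + e_2 S (S-1)}$. It requires $N \ge 4$ and
$S \ge 1$ (the variance is zero otherwise). A subtlety worth knowing: $D$
is *not* exactly mean-zero under neutrality — its neutral expectation is
slightly negative (about $-0.1$ at $N = 30$, $\theta = 5$, confirmed by the
package's own coalescent calibration test), which is why the calibration
invariant is a band ($|\bar D| \le 0.2$) rather than a point.

**Fu's Fs** asks how surprising the observed number of distinct haplotypes
$k_{obs}$ is under neutrality at $\hat\theta = K$. Under the Ewens sampling
distribution, $P(k) = |s(N,k)|\,\theta^k / \theta^{(N)}$ with unsigned
Stirling numbers of the first kind and the rising factorial
$\theta^{(N)}$. The Stirling row is built by the recurrence
$|s(n+1,k)| = |s(n,k-1)| + n\,|s(n,k)|$ evaluated entirely in log space
(log-sum-exp), which is exact to double precision for the $N \le$ a few
hundred relevant here and cannot overflow; the tests verify
$\sum_k P(k) = 1$ to $10^{-9}$ up to $N = 100$. With
$S' = P(k \ge k_{obs})$, $F_s = \ln\frac{S'}{1-S'}$. The estimator
$\hat\theta = K$ (mean pairwise differences) is used because the statistic
is conventionally defined on that scale; $k_{obs} = 1$ or $K = 0$ gives
`NA`. A true under/overflow of $S'$ (possible only for extreme inputs)
reports $\pm\infty$ with a warning rather than a fabricated finite value.

## Mismatch distributions

The mismatch histogram counts all $N(N-1)/2$ unordered pairs by their
difference count $d$. Two expectations are attached:

* **Constant size**: the equilibrium geometric
  $\hat F(d) = \theta^d/(1+\theta)^{d+1}$ at $\theta = K$.
* **Sudden expansion**: a population that jumped from scaled size
  $\theta_0$ to $\theta_1$ at scaled time $\tau$ before the present follows
  $$F_d = \hat F_d(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
    \sum_{j=0}^{d} \frac{\tau^j}{j!}
    \left[\hat F_{d-j}(\theta_0) - \hat F_{d-j}(\theta_1)\right].$$
  The two sanity anchors of this closed form are verified in the tests: at
  $\tau = 0$ it collapses to the $\theta_0$ equilibrium, and as
  $\theta_1 \to \infty$ it converges to a Poisson($\tau$) convolved with
  the $\theta_0$ geometric — the classic infinite-growth limit, which the
  test recomputes with an independent convolution oracle.

Both curves are truncated to the observed class range, renormalized, and
scaled to the pair count so observed and expected totals match.

**Fitting** $(\theta_0, \theta_1, \tau)$ is a deterministic grid search
minimizing the sum of squared deviations on relative frequencies — grids
$\tau \in \{0, 0.5, \dots, d_{max}+5\}$ (refined to a step of 0.05 around
the optimum), $\theta_0 \in \{0, 0.01, 0.1, 0.5, 1, 2, 5, 10\}$,
$\theta_1 \in \{10, 10^2, 10^3, 10^4\}$. A grid was chosen over a
quasi-Newton fit because the SSE surface is flat in $\theta_1$ and
multimodal in $\tau$ for ragged histograms; determinism matters more here
than the last decimal of an already weakly-identified parameter.

**Raggedness** is $r = \sum_i (f_{i+1} - f_i)^2$ over the observed relative
frequencies $f_0..f_{d_{max}}$ *including a closing class*
$f_{d_{max}+1} = 0$. The closing term makes $r$ well-defined for the
degenerate all-identical alignment ($r = 1$) and penalizes distributions
that end abruptly at their largest class; with or without it, smooth
unimodal (expansion-like) curves score far below ragged equilibrium curves,
which is the only use the package makes of $r$.

## AMOVA, Φ~ST~ and PCoA

The one-level AMOVA treats the raw pairwise difference count as the squared
inter-individual distance (the convention of standard haplotype-AMOVA
software). With populations $g$ of sizes $n_g$, $N = \sum n_g$:
$SSD_{total} = \frac1N \sum_{i<j} d^2_{ij}$,
$SSD_{within} = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d^2_{ij}$, and
$SSD_{among}$ is the difference. Mean squares over $P-1$ and $N-P$ degrees
of freedom and the coefficient $n_0 = (N - \sum_g n_g^2/N)/(P-1)$ give the
variance components; $\Phi_{ST} = \sigma^2_a/(\sigma^2_a + \sigma^2_w)$.
Negative $\sigma^2_a$ is *retained*, not truncated at zero — real tables
print "−1.05% among populations / 101.05% within", and truncation would
destroy the additivity invariant ($SSD$ additivity and percentages summing
to 100 are property-tested on fuzzed inputs).

The permutation test reassigns individuals to populations (sizes fixed)
and reports the observed-inclusive p-value
$p = (1 + \#\{\Phi^{perm} \ge \Phi^{obs}\})/(n_{perm}+1)$, which is bounded
below by $1/(n_{perm}+1)$ and can never report an impossible zero. The
default $n_{perm} = 1000$ balances resolution (p-granularity 1/1001)
against runtime; the seed is explicit and the caller's RNG state is left
untouched. At least two populations of size $\ge 2$ are required;
singleton populations are allowed alongside (they contribute no
within-group variance), and pairwise Φ~ST~ involving a singleton
population is reported `NA`.

PCoA is classical metric scaling (`stats::cmdscale`): double-center
$-\tfrac12 D^2$, eigendecompose, keep positive-eigenvalue axes, explained
fractions over positive eigenvalues only. Difference-count distances are
generally non-Euclidean, so negative eigenvalues are expected and silently
dropped.

## Hotspot keys, transition order and covariance

`classify_sites()` tallies states per column with one vote per haplotype
by default. Counting haplotypes rather than individuals makes the
classification invariant to sampling depth — a site is "parsimony
informative" because two *lineages* share a state, not because one common
haplotype was sampled often; per-individual weighting is available where
carrier frequencies are the point.

`assign_groups()` reduces each haplotype to its state string at the key
sites (default 207-282-354-420, spacings 75/72/66 bp). Key sites are
user-specified: the package deliberately does not guess hotspots by
default, because "the four covariate sites" of a study are a biological
claim, not a computable optimum. Non-biallelic key sites warn but are
retained.

`infer_transition_order()` picks the ancestral group as the one with the
highest within-group haplotype diversity (individual-weighted Nei's $h$):
the oldest group has had the longest time to accumulate internal variation.
This is a heuristic — outgroup states are the better evidence when
available, hence the explicit `ancestral` override. Exact diversity ties
are an error demanding the override rather than a silent arbitrary pick.
Remaining groups are ordered by Hamming distance of their key strings from
the ancestral key, ties by descending diversity and then alphabetically
(full determinism). The path is labelled `stepwise` only when every
consecutive pair differs at exactly one key site; note that a canonical
four-group system `A-A-A-A → A-A-G-A → G-A-G-A → G-G-G-G` is *not*
stepwise under this strict definition (the last step changes two sites),
and the flag reports exactly that.

**Covariance** between sites $i$ and $j$ is the number of haplotypes whose
states fall in the same polarity class at both sites — both
ancestral/major or both derived/minor. Polarity comes from
`infer_transition_order()` when supplied, otherwise each biallelic site is
split major/minor by haplotype counts (ties broken by base order
A<C<G<T). This concordance count is a deliberate, documented
interpretation of "covariate sites": it is symmetric, bounded by the
haplotype count, equals the haplotype count exactly under perfect linkage,
and equals $N/2$ for two independent 50/50 sites — all property-tested
against brute-force tallies. Haplotypes with a missing or third state at
either site never count as covariate. Multi-allelic sites in a
user-requested set are an error (naming the sites) because a two-class
polarity is undefined there.

`annotate_codon_synonymy()` translates under a selectable genetic code
(default: NCBI table 5, invertebrate mitochondrial — the right default for
a mollusc mitochondrial gene). Frame `"auto"` minimizes the internal-stop
fraction over the three forward frames; if the best frame still has stops
in more than 5% of codons the function refuses and suggests checking
strand or code, rather than annotating garbage. A polymorphic site is
synonymous iff *every* observed state yields the same amino acid in *every*
haplotype's own codon context — a site can therefore be nonsynonymous
purely through context, which per-state-pair definitions miss.

## The G-quadruplex scanner

`enumerate_g4()` finds maximal `G`-runs of length $\ge$ `g_min` and emits
every ordered choice of four whose three inter-tract gaps lie in
`[loop_min, loop_max]`. Enumeration is exhaustive and deterministic, and is
tested for exact equality against an independent brute-force oracle on
random sequences. Defaults: `g_min = 2` (canonical motifs), `loop_min = 0`,
`loop_max = 20`, `max_passes = 10`. `g_min = 1` admits the relaxed
"single-G tract" motifs of interest in weakly G-rich coding sequence, and
`loop_max` must be raised above 20 to admit motifs with longer connectors
(one of the motif geometries used in the tests has a 22 bp loop; the
package does not silently widen the cap — the caller opts in).

Since no public formula exists for the upstream tool's motif score, the
package defines a documented surrogate:
$w_t(t_{min}-1) - w_m \bar{l} - w_r(\max l - \min l)$ with defaults
$w_t = 20$, $w_m = w_r = 1$. It preserves the two orderings any
G4-plausibility score agrees on — more stacked tetrads beat fewer, and
short, even loops beat long, uneven ones — and the weights are exposed in
`g4_config()` for users who want to tune toward a published scorer.

`select_nonoverlapping()` runs greedy passes: within a pass, repeatedly
select the highest-scoring remaining candidate (ties: leftmost, then
shortest) and discard candidates overlapping it; candidates displaced by an
overlap become eligible again in the next pass, up to `max_passes`.
Within-pass selections are provably disjoint, the pass index is reported,
and the total selected count is non-decreasing in `max_passes`. This
iterated-selection semantic is the package's reading of "repeat the
non-overlapping calculation up to 10 times": pass 1 is the best
non-overlapping tiling; later passes rank the motifs that the tiling
suppressed.

## What the synthetic generator does and does not emulate

`simulate_expansion_alignment()` states a world and builds it exactly:

* a random stop-free coding ancestral sequence (frame 1, invertebrate
  mitochondrial code), 595 bp by default;
* hotspot groups as key-site state strings with *planted haplotype counts*
  (default `35/12/1/8` for the four canonical groups plus two singleton
  variant key-strings, 58 haplotypes total);
* exactly `n_shared_sites` parsimony-informative transitions (each carried
  by 2–6 haplotypes of one group) and `n_singleton_sites` singleton
  transitions, all at third codon positions, all transitions — so every
  planted mutation is synonymous and the site counts recovered by
  `classify_sites()` equal the budget (defaults 27 + 40, which with the 4
  informative key sites give 71 polymorphic / 31 informative);
* a skewed carrier-count law: one dominant haplotype (27 individuals by
  default, planted in the most derived group), a fixed decreasing
  multi-carrier tail, and singletons for the rest — 140 individuals over
  58 haplotypes with 43 singletons;
* populations assigned panmictically at `population_mixing = 1` (default),
  or with home-group bias below 1.

Distinctness of all planted haplotypes is guaranteed constructively
(duplicate shared-site profiles within a group are broken by assigning
singleton sites to the duplicates first), so haplotype recovery is exact by
construction, not with high probability. Everything is a pure function of
the seed.

What it does **not** emulate: recombination (none in mtDNA, none
simulated), back-mutation or multi-hit sites (infinite-sites within the
planted budget), transversions and nonsynonymous variation (all planted
mutations are third-position transitions), within-group phylogenetic
substructure beyond the shared-site carrier sets, and any geographic
signal at full mixing. A green planted-truth test therefore establishes
that the analysis operations invert the generator's construction — it does
not establish performance on data violating these assumptions (real data
with ambiguous bases, indels, or hypervariable sites).

`simulate_coalescent()` provides the calibration scaffold: a standard
Kingman coalescent (exponential waiting times at rate $k(k-1)/2$, time in
units of $2N$ generations, mutations as a Poisson process at rate
$\theta/2$ per unit branch length on an infinite-sites sequence) and a
star genealogy (all lineages meeting at depth $2(1-1/n)$, the expected
coalescent tree height, so every mutation is a singleton). The constant
model is validated in the tests against closed forms ($E[S] = \theta a_1$;
$S \sim$ Poisson($\theta$) at $n = 2$) and was cross-checked against an
independent coalescent simulator during development; the star model is the
caricature of a sudden expansion and drives Tajima's $D$ strongly negative.

## Numerical and degenerate-input policy

* Not-determined values are `NA`, never 0: $h$ and π for $N = 1$, $D$ for
  $S = 0$ or $N < 4$, $F_s$ for $k_{obs} = 1$, pairwise Φ~ST~ with a
  singleton population, synonymy for sites without a clean codon context.
* All tie-breaks are documented and deterministic: haplotype naming (first
  occurrence), candidate selection (score, then leftmost, then shortest),
  group ordering (Hamming, diversity, alphabetical), major-allele polarity
  (base order).
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; the pipeline derives its permutation seeds from
  the single run seed and stamps every output with the seed and a config
  hash, so a rerun is byte-identical.
* Tolerances in tests: exact identities are asserted to machine precision;
  probability normalizations to $10^{-9}$; Monte-Carlo means to bands whose
  width exceeds ~3 standard errors of the estimator at the stated
  replication.

## Known limitations

* AMOVA is single-level (populations within total); hierarchical designs
  (regions/populations) are out of scope.
* Φ~ST~ is the only differentiation estimator: no haplotype-frequency-only
  F~ST~, no genotypic (diploid) estimators.
* The ancestral-group heuristic can be misled when the truly derived group
  is old enough to have accumulated comparable diversity; use the override
  with outgroup evidence where possible.
* The G4 score is a surrogate for ranking within this package, not a
  thermodynamic stability prediction; no folding or ribosome-kinetics
  model is attached to the motifs.
* The expansion-model fit inherits the weak identifiability of
  $(\theta_0, \theta_1, \tau)$ from ragged histograms; treat fitted
  parameters as descriptive, not as demographic estimates with confidence
  intervals.
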