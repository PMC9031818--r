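---
title: "Functional load and its evolution on language phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional load and its evolution on language phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flphylo)
```

## The problem

The functional load (FL) of a phonological contrast quantifies how much that
contrast contributes to keeping the strings of a lexicon distinct. If the
phonemes /t/ and /d/ were merged, some previously distinct strings would
collapse together; FL measures, in bits, how much distinctiveness would be
lost. `flphylo` computes entropy-based FL from segmented wordlists and then
treats per-language FL values as continuous traits evolving on a language
family phylogeny: it measures *phylogenetic signal* (do related languages
have similar FL?) and *phylogenetic correlation* (do two FL variables trade
off against each other over the family's history?), propagating phylogenetic
uncertainty through a whole sample of candidate trees.

The motivating system is a family of ~90 related languages in which tonic
(first-syllable) vowel length and properties of the single consonant that
follows the tonic vowel interact both phonetically and diachronically:
historically, loss of vowel length contrasts has repeatedly been compensated
by new manner contrasts on the following consonant. The package's domain of
interest is therefore the string formed by the tonic vowel and a single
intervocalic post-tonic consonant, and the three contrasts studied are tonic
vowel length (FLV), post-tonic consonant manner (FLC), and post-tonic
consonant place (FLP), each in an unnormalized (`*u`, bits) and normalized
(`*n`, dimensionless) variant.

## The FL model

For a language's lexicon, every word contributes at most one instance of the
domain: its first vowel, provided the next segment is exactly one consonant
that is itself followed by a vowel (words with post-tonic clusters, hiatus,
or final consonants contribute nothing). The multiset of vowel–consonant
string types $s$ with type probabilities $\Pr(s)$ has entropy

$$H = -\sum_s \Pr(s)\log_2 \Pr(s).$$

A contrast $\phi$ is a collection of pairwise-disjoint phoneme sets; the
collapsed profile rewrites each set's members to a single fresh symbol. The
functional load of $\phi$ is

$$f = H - H_{\phi},\qquad f_{\mathrm{norm}} = f / H,$$

where $H_\phi$ is the entropy after collapse. By the grouping property of
entropy $0 \le f \le H$, so $f_{\mathrm{norm}} \in [0,1]$. Probabilities are
type counts over extracted instances: comparative wordlists are lexical
(type) lists, so no token-frequency weighting is available or attempted.

Lexicon preprocessing follows the conventions of the source descriptions:
greedy longest-match tokenization treats digraphs, geminates, and
pre-stopped sonorants as single segments; two adjacent identical short
vowels are rewritten as the long partner; and /uwu/, /iji/ are rewritten as
long /u:/, /i:/ (a common analysis of long high vowels as
vowel–glide–vowel). Languages enter the comparative analyses only with more
than 200 domain instances and with both members of at least one short/long
vowel pair attested among tonic vowels.

### Decisions where the design was open

* **Non-identical adjacent vowels** are left as hiatus. Long vowels are
  single qualities, so fusing unlike vowels has no length interpretation; a
  tonic vowel followed by another vowel then simply yields no instance.
* **The 200-instance filter is applied after** length normalization, since
  the instances being counted only exist post-normalization.
* **`fl_norm` at `H = 0`** is defined as 0 with a warning; such degenerate
  languages are excluded by the filters in any real run.
* **FLC/FLP feature grouping** uses the user-supplied place/manner labels of
  the segment table: FLC collapses within place groups (removing manner
  distinctions), FLP within manner groups. Published per-language feature
  assignments rarely accompany wordlists, so the table is configuration, not
  something the package infers.

## Phylogenetic signal: Blomberg's K

Let $C$ be the Brownian-motion (BM) covariance implied by a rooted, dated
tree ($C_{ij}$ = shared root-to-MRCA path length). With the GLS root
estimate $\hat a = (\mathbf 1^\top C^{-1}\mathbf 1)^{-1}\mathbf 1^\top
C^{-1} x$ and residuals $d = x - \hat a\mathbf 1$,

$$K \;=\; \frac{d^\top d / d^\top C^{-1} d}
              {\left[\operatorname{tr} C - n/(\mathbf 1^\top C^{-1}\mathbf 1)\right]/(n-1)}.$$

$K = 1$ when trait variation accords with BM on the tree (exactly 1 on a
star tree for any data), $K \to 0$ for data random with respect to the tree,
and $K > 1$ for data more clumped within clades than BM predicts. Before
interpreting K, a tip-randomization test asks whether the data beat
randomness at all: the observed GLS mean squared error is compared with
`n_perm` tip permutations, with $p = (1 + \#\{MSE_{perm} \le
MSE_{obs}\})/(n_{perm}+1)$. Ties count against the data and the add-one
smoothing means $p$ is never 0; the default `n_perm = 999` gives a p floor
of 0.001, matching significance reported to three digits. Both steps are run
on every tree of the sample and aggregated as mean/sd of K and the maximum
p. Per-tree permutation seeds are derived deterministically from the run
seed, so results are independent of iteration order.

## Phylogenetic correlation

For two traits on the same tree, GLS residuals give evolutionary
(co)variances $\sigma_{xy} = d_x^\top C^{-1} d_y/(n-1)$ and the
phylogenetic Pearson correlation $r = \sigma_{xy}/\sqrt{\sigma_{xx}
\sigma_{yy}}$, identical to the correlation through the origin of
phylogenetically independent contrasts (verified against an independent
pruning-algorithm implementation in the tests). The $n-1$ (REML-style)
denominator is shared with the K module so the two cannot silently diverge;
it cancels in $r$ itself.

Computed on each tree of a posterior sample, the per-tree $r$ values form a
posterior sample of the correlation. The package reports their mean, the
equal-tail 2.5%/97.5% quantile interval, and a p value from the Student-t
transform $t = r\sqrt{(n-2)/(1-r^2)}$ applied to the posterior mean with
$n-2$ degrees of freedom. The t transform applied to a posterior mean is a
pragmatic choice — the interval construction and the test form are both
package decisions where several defensible options exist (e.g. a per-tree
likelihood-ratio test); exact p values from other constructions will differ
slightly, though significance calls at conventional levels agree in all
cases we have examined.

## The synthetic-data generator

Because comparative lexical datasets are large, hard-won, and often
restricted, the package ships a generator that emulates the study
conditions end to end:

* `yule_tree(n, birth_rate, seed)` — dated pure-birth trees conditioned on
  tip count (via `ape::rphylo`), standing in for a posterior tree sample.
* `simulate_bm(tree, rate, ...)` — (bi)variate BM by accumulating
  independent Gaussian branch increments; tip values have covariance
  $R \otimes C$ exactly, which the tests confirm by Monte Carlo.
* `synth_lexicon(theta, n_words, ...)` — CVCV wordforms whose domain
  distribution is a $\theta$-mixture: with probability $1-\theta$ the
  instance is distinguished by vowel length (short/long equiprobable,
  voiceless stop fixed), with probability $\theta$ by consonant manner
  (stop/voiced equiprobable, short vowel fixed). Closed forms follow with
  $h$ the binary entropy function: $H(\theta) = 1 + h(\theta)/2$ (one place),
  $FLV_u(\theta) = 1 + h(\theta)/2 - h(\theta/2)$, and by symmetry
  $FLC_u(\theta) = FLV_u(1-\theta)$, so FLV falls from 1 bit to 0 and FLC
  rises from 0 to 1 bit as $\theta$ goes 0 to 1. Lexicon sizes default to
  uniform on [208, 3215] domain instances, the span typical of comparative
  wordlists of this kind.
* `evolve_tradeoff(tree, ...)` — a latent trait evolves by BM and maps
  through a logistic function to per-language $\theta$ (BM on the
  unconstrained scale avoids boundary reflection). A second, *independent*
  latent evolves the place-of-articulation proportion the same way. This
  second latent matters: if place were drawn iid per word with fixed
  probabilities, FLP would carry no phylogenetic signal at all, and the
  BM-based correlation test between a strongly tree-structured FLV and a
  tree-free FLP is anticonservative (we measured ~15% rejection at the
  nominal 5% level over 100 runs). Real FL variables all show strong
  signal, so the generator matches the study system by making every FL
  variable tree-structured while keeping place exactly independent of the
  trade-off. With both traits BM-governed the empirical FLV–FLP rejection
  rate is ~5%.

What the generator deliberately does **not** emulate: discrete sound-change
events (mergers, transphonologization as such), borrowing/contact between
non-sister languages, real segment inventories with many vowel qualities,
or token-frequency structure. Passing tests on synthetic data therefore
demonstrate the statistical machinery and the trade-off detection, not the
philological preprocessing of any particular real dataset.

When comparing FLV against FLP for independence, prefer the unnormalized
pair: the normalized variables share the denominator $H$, which induces a
mechanical correlation between them even when the underlying contrasts are
independent.

## Numerical choices and degenerate inputs

* Logarithms are base 2 throughout; FL is reported in bits.
* The GLS solve uses a Cholesky factorization; near-zero pivots (relative
  threshold $10^{-6}$, e.g. from zero-length terminal branches producing
  duplicate covariance rows) raise an error rather than returning garbage,
  with an opt-in SVD pseudo-inverse fallback (`pseudo = TRUE`).
* Tiny negative FL from floating-point cancellation (bounded by $10^{-9}$)
  is clamped to 0; anything larger is an error, as the grouping property
  guarantees $f \ge 0$.
* Tip-name matching between trait tables and trees is exact after
  whitespace trimming, and any mismatch is fatal: silently dropping tips
  corrupts comparative analyses.
* Permutation ties are counted as "at least as good as the data"
  (conservative).
* Basal polytomies are treated as unrooted by the underlying `ape`
  convention; set `root.edge` explicitly for genuinely rooted star trees.

## Problem sizes used in the shipped tests

The test suite exercises the pipeline at the scale of the study design:
64-tip trees with 500 BM replicates for the K calibration (mean K expected
in [0.95, 1.05]), 1000 iid trait vectors with 999 permutations each for the
test's type-I error (95% binomial band around 0.05), a 90-tip tree with 500
bivariate replicates for correlation recovery (±0.05 of the generating
−0.5), and 50 seeded end-to-end trade-off runs on 48-tip trees, of which at
least 45 must show the expected pattern (significant signal in FLVu and
FLCu, significant negative FLVu–FLCu, non-significant FLVu–FLPu). The whole
suite runs in about two minutes on one core.

## Known limitations

* FL is computed for one domain shape (tonic V + single intervocalic C);
  word-level FL, pairwise-phoneme FL matrices, and token-weighted FL are out
  of scope.
* The correlation p value is tied to the posterior-mean-plus-t construction
  described above; it is not a fully Bayesian posterior probability.
* No tree inference or dating: trees are inputs.
* Reproducing published per-language FL values from raw lexicons requires
  the same feature assignments (place/manner labels, length partnerships)
  the original analysts used; with only published FL values, the package's
  table-ingestion mode reproduces the downstream statistics instead.
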