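---
title: "Methods: detecting and testing S/T-Q cluster domains"
author: "scdscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and testing S/T-Q cluster domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdscan)
```

This vignette is the package's account of its models and the design
choices behind them: what is computed, under which conventions, which
approximations are involved, and what the validation on synthetic data
does and does not establish about real proteomes.

## The cluster definition and the scanner

An S/T-Q motif is a serine or threonine immediately followed by
glutamine — the phosphorylation consensus of the PIKK-family checkpoint
kinases (Tel1/Mec1, ATM/ATR). An S/T-Q cluster domain (SCD) under the
definition `(k, W)` is a region with at least `k` motifs whose *span* is
at most `W` residues. Throughout the package the span is measured from
the S/T of the first motif through the Q of the last, inclusive: motifs
at positions $p_1 < \dots < p_k$ qualify when
$(p_k + 1) - p_1 + 1 \le W$. The defaults `k = 3`, `W = 50` are the
field's working definition of the domain; `k` and `W` are plain counts
and residues, and both are sweepable (`sweep_definitions()`, grid
defaults `k` 3–5 and `W` 50–100 by 5, the historical refinement path of
the definition).

Three scanner choices matter:

- **Exhaustive enumeration.** Every start position is tested
  (`find_motifs()`), rather than letting a regex engine consume
  characters: greedy gap matching can skip occurrences, and an
  exhaustive scan is trivially checkable against a brute-force oracle.
  For the default motif, occurrences can never overlap (Q is not S/T),
  so consecutive hits differ by at least 2.
- **Consecutive-tuple windowing.** A cluster exists iff some `k`
  *consecutive* hits satisfy the span rule: if any `k`-subset of hits
  fits in a span, the `k` consecutive hits inside that span fit as well.
  Tests verify equality with an oracle that enumerates all `k`-subsets.
- **Transitive merging.** Qualifying tuples that share hits merge into
  maximal regions; a protein's region count is the number of maximal
  regions, and the census is the set of proteins with at least one. The
  merge is deterministic, so no tie-breaking is needed.

Coordinates are 1-based inclusive everywhere; only the optional BED
export converts to 0-based half-open. Ambiguity characters
(B, Z, X, U, O, `*`) never match the motif class. Splice variants and
other near-duplicate FASTA entries are counted as separate records;
deduplication is the caller's responsibility and is deliberately not
guessed at.

## The null model

Each protein $i$ is modeled as a Bernoulli trial: it contains an SCD by
chance with probability $p_i$, so the census size under the null is a
sum of independent, non-identical Bernoulli variables. Two quantities
follow: the expected census $\sum_i p_i$, and the exact significance of
an observed census as the Poisson-binomial upper tail
$P(X \ge \mathrm{obs})$, computed by iterative convolution
(`poisson_binomial_tail`, with a continuity-corrected normal refinement
as a cross-check). The convolution is exact to machine precision
(validated against $2^{12}$ enumeration).

### Per-protein cluster probability

The motif process along a protein is idealized as a Poisson process at
rate $\lambda$ per residue; discretely, each residue carries an
independent Bernoulli($\lambda$) motif indicator and the scanner's span
rule defines the event. `scd_probability()` offers:

- `monte_carlo` (default): simulate the indicators, apply the span rule,
  report the estimate with its standard error. Seeded, chunked, and
  deduplicated by `(L, λ)` class in `null_model()`.
- `exact_small`: sum over all $2^L$ indicator vectors (grouped by event
  count), supported for $L \le 22$; this is the oracle the other
  methods are tested against. (The bound is 22 rather than a few
  residues more because the subset enumeration is materialized in
  memory; every validation point uses $L \le 20$.)
- `exact_dp`: an exact dynamic program over the distances to the last
  $k - 1$ events (distances beyond $W - 3$ collapse into a "dead"
  state). One forward pass yields $p$ for *every* length up to
  $L_{\max}$ (`scd_prob_profile_bernoulli()`), which is what makes
  proteome-scale expectations cheap. It agrees with `exact_small` to
  machine precision and extends the same model to arbitrary lengths —
  Monte Carlo remains the reference method in validation.
- `approximation`: the product-type scan approximation
  $P(\text{no cluster}) \approx q_v\,(q_{v+1}/q_v)^{L-v}$ with
  $q_n = P(\mathrm{Binom}(n, \lambda) < k)$ and $v = W - 1$. At
  realistic rates it runs some 10–15% high; it is provided for quick
  estimates and is always validated against the exact methods, never
  authoritative.

Proteins shorter than $2k$ residues cannot hold $k$ dipeptides and get
$p = 0$ in all methods.

### The footprint correction

The Bernoulli idealization ignores that a motif occupies two residues:
real S/T-Q starts can never sit on adjacent positions, while the
idealized process happily counts such configurations. The error is not
negligible for clustering probabilities — the fraction of qualifying
$k$-tuples with an adjacent pair is of order $k/W$ (about 8–9% at
`k = 3`, `W = 50`) and does not vanish at small $\lambda$. The package
therefore also provides `scd_probability_composition(L, p_st, p_q, k,
W)`: an exact dynamic program over residue classes (S/T, Q, other) for
sequences of i.i.d. residues with known composition. It is exact for
the synthetic generator's sequence model (verified against $3^L$
enumeration) and is what the generative-consistency validation uses;
the Bernoulli idealization remains the default user-facing null because
it is the model the census-expectation methodology is stated in, and
its inflation is documented rather than silently corrected.

### The rate estimator

The published methodology estimates $\lambda$ "per protein, divided by
the protein's length", which admits three readings, all implemented in
`estimate_rates()`:

- `per_protein` (default): $\lambda_i = m_i / L_i$, each protein's own
  motif count over its length;
- `global_mean_per_protein`: $\lambda_i = \bar{m} / L_i$, the literal
  reading (proteome-mean count divided by each length);
- `global_per_residue`: $\lambda = \sum m / \sum L$, one pooled rate.

The choice is a logged configuration value, not a hidden constant. Note
that with `per_protein`, proteins with $m_i < k$ get $p_i$ near zero and
the expected census is driven by motif-rich proteins; with pooled modes
long proteins dominate. On a given snapshot the three can differ
substantially, which is one reason snapshot-dependent published counts
are treated as commands to re-run, not as test targets.

## Overlap tests and term enrichment

Overlaps with external protein lists use the hypergeometric
distribution: universe $N$, census $K$, list $n$, observed overlap $x$,
expected $nK/N$, and the *inclusive* upper tail $P(X \ge x)$ (the
standard over-representation convention; the inclusivity choice is
documented because published numbers do not state it, and the package
reports its own exact tail rather than tuning to match any published
p-value). The universe defaults to the scanned proteome's ids; ids
outside it are dropped with a logged count.

Term enrichment runs one such test per annotation term with at least
`min_term_size` universe members (default 2), corrects by Bonferroni
over the tested terms (significance flag at 0.01 by default) and
reports Benjamini–Hochberg FDR over the same tested terms. Annotation
maps come from GAF 2.x (NOT-qualified rows skipped) or two-column TSV;
no ontology-graph propagation is performed — annotations are used as
given.

One calibration subtlety: exact hypergeometric p-values are discrete
and conservative, so with small expected overlaps their null
distribution sits visibly above uniform. The calibration validation
therefore uses a configuration with large expected overlaps (universe
5000, census 1000, term rate 0.3), where the support is dense and a
Kolmogorov–Smirnov uniformity check is meaningful; with sparse counts a
"failed" uniformity check would reflect discreteness, not an
implementation error.

## Length goodness of fit

`lognormal_gof()` tests census lengths against a log-normal: maximum
likelihood on log lengths, equal-probability bins under the fitted
distribution (20 by default), adjacent bins merged until every expected
count is at least 5, Pearson chi-square with `df = bins - 3`. One
correction is applied to make that reference distribution exact: with
parameters estimated from the raw data, the binned statistic is
stochastically between $\chi^2_{m-3}$ and $\chi^2_{m-1}$
(Chernoff–Lehmann), which is enough to fail a 500-replicate uniformity
check. The parameters entering the statistic are therefore re-fit by
grouped (multinomial) maximum likelihood on the fixed bin edges, which
restores the textbook $\chi^2_{m-3}$ asymptotics; the raw MLE is still
reported as `mu_hat`/`sigma_hat`.

## Flank profiles

`build_profile()` pools counts per offset over all sites (offsets −5 to
+5 by default, S/T at offset 0). Conventions:

- Only sites that are genuinely S/T, and (by default) followed by Q,
  are profiled; others are excluded and counted. Offsets 0 and +1 are
  therefore structurally pure (S/T and Q), which doubles as an
  invariant check.
- Sites near a terminus keep their in-range offsets: denominators are
  per offset, rather than dropping whole sites or padding with gap
  symbols. This maximizes data use; frequencies at different offsets
  can then rest on slightly different totals.
- Frequencies are pooled per offset over sites (not averaged per site).

`compare_to_background()` reports per-cell
$\log_2((f+\varepsilon)/(g+\varepsilon))$ with
$\varepsilon = 1/(2\max(\text{totals}))$ and delta-method standard
errors; offsets with zero totals come back missing rather than zero.

## The synthetic generator

`generate_proteome()` draws lengths from a log-normal truncated to
`[min_len, max_len]` and fills sequences with i.i.d. residues. The
defaults — `meanlog = 6.0`, `sdlog = 0.55`, bounds 50–4000, and the
yeast-like composition preset (S 9.0%, T 5.9%, Q 3.9%, remainder
uniform) — give a median length near 400 residues and a background
motif-start rate of about 0.0058 per residue, realistic for a fungal
proteome. Planted clusters overwrite `k` S/T-Q dipeptides (pairwise
gaps ≥ 2, span ≤ `W`) rather than inserting them, keeping the length
model exact; plants are recorded as ground-truth intervals, at most one
per protein. Phosphosites are drawn from true motif positions;
offset-specific flank biases rewrite the flanking residue to the biased
one with probability $\pi$ and otherwise draw from the composition
*excluding* it, so the realized frequency equals $\pi$ exactly.
Annotation maps assign background terms independently of census
membership and one optional planted term with separate inside/outside
rates. Everything is a pure function of the seed; component seeds
derive from it by fixed offsets.

What the generator does *not* emulate: homology and domain structure,
compositional heterogeneity along sequences, splice-variant redundancy,
and any biological correlation between clusters, phosphosites and
annotations beyond what is explicitly planted. Validation on this
synthetic model therefore establishes algorithmic correctness
(oracle-equivalence, exact tails, calibrated tests, recovery of planted
signal) — it does not certify that any particular real proteome census
is biologically meaningful, nor reproduce counts tied to a specific
database snapshot (a yeast census of 436 with 147 expected, the
42-residue minimal span over known substrates, a length-fit p of 0.285:
all snapshot-dependent; the corresponding commands run on user-supplied
FASTA).

## Validation problem sizes

The shipped validation uses: 1,000 random sequences (lengths 10–2,000)
for scanner/oracle equivalence; one 10,000-protein proteome with 500
planted clusters for recall; 200 replicate proteomes of 200 proteins
for generative consistency of $\sum p_i$ (compared at 2 standard errors
of the replicate mean); a 54-point $(L \le 20, \lambda, k, W)$ lattice
with $10^5$ Monte Carlo draws per point against $2^L$ enumeration;
$2^{12}$ enumeration for the Poisson-binomial; 200 replicates each for
enrichment calibration and power; 500 + 200 replicates for
goodness-of-fit calibration and power; and 1,000 sites for flank-bias
recovery. These sizes are the package's own validation choices; all are
regenerated in code at run time from seeds.

## Known limitations

- The Bernoulli-model census expectation overstates $\sum p_i$ by
  roughly 5–10% at the default definition relative to the
  footprint-exact composition null; use
  `scd_probability_composition()` when the composition is known and the
  bias matters.
- `exact_small` is limited to $L \le 22$; beyond that, `exact_dp` is
  the exact method.
- The closed-form approximation is a convenience with a documented
  10–15% upward bias at realistic rates.
- Exact hypergeometric and Poisson-binomial tails are conservative for
  sparse, discrete data; that is a property of exact tests, not a bug.
- General PROSITE patterns, DNA/RNA scanning, GO-graph propagation and
  network inference are out of scope.
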