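---
title: "Correlation-weight QSAR models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-weight QSAR models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwqsar)
```

## The model

`cwqsar` implements the *optimal descriptor* approach to QSAR: rather
than computing a fixed vector of molecular descriptors, it attaches one
real-valued **correlation weight** to every structural attribute a
molecule exhibits, and uses the weighted attribute count

$$\mathrm{DCW}(T, N) \;=\; \sum_k \mathrm{CW}(A_k)$$

as the single descriptor of a one-variable linear model
$y = C_0 + C_1\,\mathrm{DCW}$.  The weights are free parameters tuned by
a Monte Carlo search that maximizes the correlation between DCW and the
endpoint on the training set; $C_0, C_1$ come from ordinary least
squares afterwards.  The approach trades mechanistic descriptors for a
transparent, fully data-driven weighting in which the *sign* of each
learned weight is interpretable: an attribute whose weight is positive
in every independent run of the search behaves as a promoter of
endpoint increase, a stably negative one as a promoter of decrease.

### Attributes

Two families of attributes are extracted from the SMILES string itself:

* **Local.** Each token (an atom symbol, bond symbol, digit, bracket,
  branch parenthesis, two-letter halogen, `@@`, or `%NN` ring closure)
  is one $S_k$ attribute; each adjacent token pair is one $SS_k$
  attribute.  Closing parentheses are canonicalized to `(` before
  extraction so that branch opening and closing count as the same
  attribute, and the two tokens of a pair are ordered by descending
  ASCII rank so that A–B and B–A collapse to one key.  Every attribute
  is rendered as a fixed 12-character key (`"Cl..(......."` is the
  Cl–branch pair), which keeps weight tables and reports alignable.
* **Global.** One `BOND` key flags the presence of `=`, `#`, and
  `@`/`@@` (in that flag order); one `NOSP` key flags N, O, S, P; one
  `HALO` key flags F, Cl, Br, I; and one `PAIR` key per unordered pair
  of co-present features from {F, Cl, Br, I, N, O, S, P, double bond,
  triple bond, stereo marker} records feature co-occurrence without any
  positional information.  Aromatic lowercase atoms count as their
  element for these presence flags; the SMILES dialect question of
  whether they should is invisible in practice because the weight of
  e.g. `c` vs `C` is learned separately at the local level anyway.

A third family comes from the hydrogen-suppressed molecular graph
(heavy atoms as vertices, every bond an edge, bond orders ignored):
vertex degrees (`EC0`), first-order Morgan extended connectivity — the
sum of neighbour degrees (`EC1`) — and counts of 5- and 6-membered rings
in a minimum cycle basis (`C5`/`C6`).  Ring perception uses a
Horton-style minimum cycle basis: molecular graphs are small, every
candidate cycle is built from shortest paths, and candidates are
accepted greedily under GF(2) independence, which resolves fused-ring
ambiguity deterministically.  A per-vertex nearest-neighbour code
(`NNC`) is also available; several conventions for it circulate in the
literature, so this package fixes one (counts of neighbours of degree
1, 2, and ≥3, each clipped at 9), documents it, disables it by default,
and never asserts reference values against it.

`descriptor_config()` gates the families.  The preset `"smiles"`
(default) uses the SMILES-only attributes; `"hybrid_ec"` replaces the
global indicators with EC0/EC1; `"hybrid_rings"` uses the ring codes.

### The threshold T and epochs N

`T` is a rarity threshold: an attribute must occur in at least `T`
distinct training molecules to receive a weight; rarer attributes are
*blocked* (weight exactly 0).  Blocking protects against attributes that
would act as molecule indicators and overfit.  `N` is the number of
optimization epochs.  The defaults `T = 1, N = 10` follow the common
usage of this method family.  At prediction time, attributes never seen
in training contribute 0 and are counted; the count is exposed per
molecule as a crude applicability-domain signal.

## The Monte Carlo search

The paper family behind this method states only that weights are
"calculated with the Monte Carlo method", so the concrete scheme is this
package's design, chosen for reproducibility and documented here:

* **Initialization**: all weights 1 (`init_mode = "ones"`), or
  Uniform(−1, 1) (`"uniform"`).
* **Visit order**: each epoch visits every active attribute once, in a
  freshly shuffled order.
* **Proposal**: draw $u \sim \mathrm{Uniform}(0, \texttt{step\_max}]$
  (default `step_max = 0.1`) and a random sign; try $CW \pm u$.  If the
  first direction does not improve the target, try the mirror move.
  After an accepted move the search keeps sliding in the accepted
  direction with geometrically doubled steps while the target strictly
  increases — a cheap line search.  Without it, fixed-size steps cannot
  traverse the weight space within a ten-epoch budget; with it the
  recovery harnesses below converge with a wide margin.
* **Acceptance**: strictly greedy — a move is kept only if the target
  increases.  Consequently the per-epoch trace is non-decreasing, which
  the tests assert.  There is no annealing temperature; greedy
  acceptance is the simplest scheme consistent with the method family.
* **Target**: Pearson r between DCW and the endpoint over the training
  molecules (`target = "r_train"`); a zero-variance descriptor scores a
  −1 sentinel.  With a calibration subset, `target = "balance"` scores
  $r_{sub} + r_{cal} - 0.1\,|r_{sub} - r_{cal}|$, rewarding agreement
  between the sub-training and calibration correlations.
* **Randomness**: every run owns a private RNG stream seeded from its
  seed; the caller's global RNG state is saved and restored, and
  identical inputs give bit-identical weight tables.  Ensembles derive
  nothing from each other: `run_ensemble()` differs across runs only in
  the seed.

Because a weight update changes the descriptor by `delta * count_column`,
the implementation keeps the molecule-by-attribute count matrix and the
current descriptor vector, making each proposal O(n).

## Validation criteria

`criteria_report()` assembles, for one (observed, predicted) pairing:
Pearson r and r²; Lin's CCC (whose location/scale penalty guarantees
|CCC| ≤ |r|); the through-origin slopes $k = \sum y\tilde y / \sum
\tilde y^2$, $k' = \sum y\tilde y / \sum y^2$ and determination
coefficients $r_0^2$, $r_0'^2$ in both regression directions; the Q²
family (Q² and Q²F2 scale the prediction error by the external variance
about the external mean, Q²F1 by deviations from the training mean,
Q²F3 by the per-molecule training variance); the rm² metrics; the IIC;
and Golbraikh–Tropsha acceptability flags (defaults $0.85 \le k \le
1.15$, $r^2 > 0.6$, $Q^2 > 0.5$, relative $r^2$–$r_0^2$ gap < 0.1, all
overridable).

Three deliberate choices:

* **rm² variant.**  Some printed sources state
  $r_m^2 = r^2(1 - |r^2 - r_0^2|)$ while the originating literature uses
  $r^2(1 - \sqrt{|r^2 - r_0^2|})$.  The square-root form is the default;
  `variant = "literal"` selects the other.  Similarly, the "average rm²"
  is implemented as the mean of the two directional values (a printed
  minus sign in some renditions notwithstanding), with their absolute
  difference reported alongside.
* **Q² flavours.**  The plain Q² symbol is ambiguous between
  leave-one-out and external prediction; both are provided.  External Q²
  is part of the report; `q2_loo()` computes exact LOO for the
  two-parameter calibration via the hat-matrix identity.
* **Degeneracy.**  Undefined statistics (zero variance, vanishing
  denominators) are reported as `NA`, never as silent zeros — with one
  documented exception: IIC is defined as 0 when either residual-sign
  class is empty, because the min/max MAE ratio is then meaningless.
  IIC equals the supplied correlation exactly when the two classes have
  equal mean absolute residuals.

## Endpoint similarity via promoter stability

For one endpoint, `classify_promoters()` inspects the weight tables of
several independent runs and labels each attribute +1 (positive weight
in every run), −1 (negative in every run) or 0 (sign-unstable, blocked
in any run, or exactly zero).  Strict sign is used with no epsilon band:
a weight of exactly 0 is unstable.  Two endpoints are compared by
counting attributes with equal non-zero labels (similarity) and opposite
labels (dissimilarity) over the union of their attribute universes;
`similarity_matrix()` assembles the pairwise counts, with each
endpoint's own stable-attribute count on the similarity diagonal.
`consistency_table()` generalizes the scheme to a splits-by-runs design
per cohort, marking each cell whose weight is positive and totalling
rows — the layout used to contrast, e.g., male-rat and female-rat
carcinogenicity models.

The package ships three transcribed promoter-sign blocks for the
endpoint triple mutagenicity / anticancer activity / blood–brain
barrier, and a split-by-run indicator table for the rat-carcinogenicity
cohorts, as plain TSV under `inst/extdata/`.  Reading them normalizes
key dialects (dot-filled PAIR fields, upper-case `CL`, 11-character
keys) to the canonical 12-character rendering.  The recomputed
similarity counts and row totals match the recorded tables exactly; the
cohort *grand* totals are reported as the sum of row totals by
construction (the source table prints grand totals that do not equal the
sum of its own rows, so only row-level values are treated as reference).

## The synthetic-data generator

`synth_dataset()` emulates the study conditions end to end: molecules
are drawn from a closed grammar (chains of 2–12 heavy atoms over
C/N/O/S/F/Cl/Br, branch probability 0.3, one 5- or 6-membered ring with
probability 0.3, double/triple bond probabilities 0.15/0.03), every
observed attribute receives a planted weight Uniform(−1, 1), and the
endpoint is `intercept + slope · DCW + ε` with Gaussian noise, by
default 5% of the signal standard deviation — the natural emulation for
log-scaled endpoints (lnR, pIC50) where noise is additive.  The grammar
is deliberately a subset of what the parsers accept, so
generator–parser compatibility is an invariant, not a hope.  Splits are
either seeded random shuffles or "striped": endpoint-sorted round-robin
dealing, which balances the endpoint distribution across sets and
emulates rational splitting.

What the generator does *not* emulate: chemically realistic molecule
distributions, aromatic systems in generated strings, correlated
attribute co-occurrence as found in congeneric series, or the specific
endpoint datasets of the literature.  Passing tests on synthetic data
therefore demonstrate that the machinery recovers a planted
linear-in-attributes signal under noise — not that any particular real
endpoint is predictable.

## Test harnesses and problem sizes

The suite runs at sizes chosen to finish quickly while exercising every
code path: tokenizer/oracle cross-checks on 1000 generated molecules;
graph identities on 80; a training harness of 60 molecules at `N = 10`
asserting training r² ≥ 0.8; a recovery harness of 250 noiseless
molecules at `N = 50` asserting validation r² ≥ 0.95 on three fixed
seeds; split-sensitivity over 10 random splits of one dataset asserting
a strictly positive spread of validation r²; and 100 random pairings
cross-checking every criterion against naive brute-force loops at
1e-12.  The end-to-end similarity smoke test gives each endpoint's run
ensemble its own seed set: with shared seeds the ensembles would share
initializations, and attributes the search never touches would keep
identical initial signs in both endpoints, manufacturing spurious
"stable similarity".

## Limitations

* The optimizer is greedy and coordinate-wise; it finds a good local
  optimum reproducibly, but no claim of global optimality is made, and
  collinear attribute columns make individual weights (not predictions)
  non-identifiable — which is exactly why promoter conclusions are drawn
  only from signs stable across independent runs.
* SMILES handling is syntactic: no valence checking, no aromaticity
  perception, no canonicalization, and stereochemistry enters only as a
  presence flag.  Bracket atoms are tokenized character-by-character.
* The one-variable model cannot express interactions between attributes
  beyond what co-occurrence already encodes in the descriptor sum.
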