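---
title: "Minimal Boolean formulas, network learning effort, and how lotlearn compares them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimal Boolean formulas, network learning effort, and how lotlearn compares them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lotlearn)
```

## The problem

Two broad accounts of how people acquire Boolean categories make
predictions about the same observable: how hard each category is to
learn.  A symbolic (language-of-thought, LOT) account says a category is
as hard as its shortest description in some mental logical language.  A
connectionist account says a category is as hard as it is for a generic
neural network to fit.  `lotlearn` computes both predictions exactly or
by simulation, and measures their agreement per candidate language with
Spearman rank correlations.

The domain is fixed by `n` binary properties.  An *object* is an
assignment of truth values to the properties; a *category* is a set of
objects, i.e. a Boolean function over `2^n` assignments.  With the study
default `n = 4` there are 16 objects and 65,536 categories.  Categories
are written as bit strings in a fixed assignment order — all-true first,
all-false last, `p1` most significant — so `"1100"` at `n = 2` is the
category "p".

## Languages of thought and functional completeness

A candidate LOT is a subset of nine connectives: and, or, the material
conditional and its negation, the biconditional and its negation (the
*parity* operators, XNOR/XOR), nand, nor, and negation.  Constants,
affirmations, projections and the left-pointing conditionals are
excluded from the universe because they never shorten a minimal formula
relative to this set.  There are `2^9 = 512` candidate LOTs.

Only LOTs that can express *every* category are usable.  `is_complete()`
decides this by Post's criterion: a set of connectives (with literals
available, constants not) is functionally complete iff it is not
contained in any of the five maximal clones — the 0-preserving,
1-preserving, monotone, self-dual and affine functions.  The criterion is
exact and independent of `n`; the test suite cross-checks it against a
brute-force closure over the sixteen two-property functions for all 512
subsets.

Both routes give **479** complete LOTs.  The number previously reported
for this operator universe, 468, was obtained by filtering the powerset
against a published list of minimal bases; that count can only be
reproduced by omitting some minimal bases that are valid here (the
parity-based triples such as `{and, bicond, nbicond}` and some
two-element bases involving the conditional operators; several omission
patterns leave exactly eleven complete sets undetected, and 479 − 11 =
468).  Because inclusion–exclusion over the five clone memberships
confirms 479 by hand, `lotlearn` reports the computed count and treats
the published 468 as an artifact of an incomplete filter list.

## Minimal formula length

For a complete LOT, `minimal_profile()` assigns every category the
length of its shortest formula.  The search is a size-ordered dynamic
program over truth tables: start from the literal tables, and for each
size in ascending order apply the unary operator to tables of the
previous size and the binary operators to ordered pairs of tables whose
sizes sum to one less.  The first size at which a truth table appears is
its minimal length — sizes are processed in ascending order, so no
relaxation step is needed.  Provenance of the first derivation yields a
deterministic witness formula (`minimal_formula()`): ties are broken by
a fixed iteration order (operators in canonical order, subformula sizes
ascending, left before right, truth tables ascending).

Two length metrics are supported:

* `metric = "nodes"` (default): parse-tree node count, operator
  applications plus literal occurrences.  `p1` has length 1,
  `nand(p1,p2)` length 3.  This is the metric used by all reference
  length fixtures in the package.
* `metric = "ops"`: operator applications only; a bare literal has
  length 0.

The two metrics are equivalent up to `nodes = 2*ops + 1` — identical
rankings — for LOTs without negation, and can differ with it.  The
reported maxima for the study domain (26 for the nand-only LOT over all
four-property categories, 15 for some four-operator LOTs) are reproduced
exactly by the operator-count metric; under node count the same witness
trees have 53 and 31 nodes.  We therefore read "formula length" in the
source analysis as the operator count, keep node count as the package
default because every printed two-property reference formula is
node-counted in the fixtures, and compute headline maxima under
`metric = "ops"`.  `scripts/acceptance.R` does exactly this.

Numerical safeguards: the DP has a hard size cap (default 64) that turns
a non-terminating search — only possible through a bug or an incomplete
LOT slipping past the completeness check — into an error; incomplete
LOTs are rejected before any search.  At `n = 4` the DP stores one
integer per truth table plus per-size table lists, a few megabytes; the
nand-only run takes a few seconds on one core.

LOTs with identical length vectors over all categories make identical
predictions; `profile_dedup()` counts distinct vectors under exact
equality.  The full four-property dedup over all complete LOTs is a
cluster-scale computation; the test suite runs the two-property version
against an independent relaxation oracle instead.

## Network learning effort

`train_once()` trains a feedforward network — `n` inputs, two ReLU
hidden layers of 16 units, one sigmoid output — on a category's full
truth table with binary cross entropy and Adam, and returns the *learning
effort*: the unweighted mean of all per-batch losses across all epochs,
i.e. the area under the learning curve.  Study conditions: batch size 8,
400 epochs, 25 replicates per category.

Choices the source analysis leaves open, fixed here once:

* Adam hyperparameters: lr 0.001, beta1 0.9, beta2 0.999, eps 1e-8 (the
  optimizer's canonical defaults).
* Initialisation: He-uniform for the rectifier layers, Xavier-uniform
  for the sigmoid output, biases zero, all drawn from a private
  xorshift generator so a fixed seed reproduces the loss trajectory
  bitwise.
* Inputs are encoded 0/1 in the package-wide assignment order; labels
  are the membership bits.  The encoding is isolated in
  `make_dataset()` so it can be swapped.
* Examples are reshuffled every epoch (seeded).

Replicate `r` of category `c` uses seed `base_seed XOR hash(c, r)`, a
pure function of its arguments, so categories can be trained in any
order — or resumed from a checkpoint CSV (`effort_table()`) — with
results identical to a serial run.

The exact correlation magnitudes depend on these unstated details
(learning rate, initialisation, input/output encoding), which is the
main replication caveat for reproducing the reported per-LOT rank
correlations of 0.22–0.77 at full scale.

## Comparing the accounts

`spearman()` is the Pearson correlation of average ranks — length
vectors are heavily tied, so tie handling matters — and is invariant
under strictly monotone transforms of either variable, which is why only
effort *ranks* carry meaning.  `lot_rho_table()` joins each LOT's
profile with per-category mean efforts (means over replicates; partial
effort tables are a hard join error unless `allow_subset = TRUE`) and
sorts by descending rho, ties broken by LOT id.
`cumulative_operator_counts()`, `parity_split()` and
`operators_per_lot_curve()` summarise the ordering at the operator
level: in the study conditions, LOTs containing a parity operator
correlate systematically worse (networks find nonlinearly separable
categories hard, while parity-bearing LOTs describe them compactly), and
more operators generally help.

## Surrogate data

`surrogate_efforts()` draws `transform(length) + N(0, noise_sd)`,
truncated at a small positive floor, from a generating LOT's profile.
This is the minimal generative model consistent with the assumption that
logical complexity drives learning effort: a strictly increasing
transform (identity, log or square root) plus additive Gaussian noise.
It makes rank recovery a meaningful end-to-end check
(`recovery_experiment()`): at zero noise the generating LOT attains
rho = 1 and ranks first; at noise far above the length range the
correlation is centred on zero.  What the surrogate deliberately does
*not* model: the skewed, heteroscedastic distribution of real
cross-entropy efforts, replicate-level variance structure, and any
category-level effects beyond minimal length (e.g. linear separability),
so passing surrogate tests validates the analysis plumbing, not the
training dynamics.

The two-property reference world (`small_world()`) pins the DP to
node-counted known minimal formulas for three LOTs — nand-only; the
English-like not/and/or/nor; and a parity LOT not/or/xor — across all 16
categories.

## Scale of the shipped checks

The full study grid (65,536 categories × 25 replicates × 400 epochs,
profiles for every complete LOT at `n = 4`) is a cluster computation.
The package's own checks run at desk scale, chosen once:

* all exactness checks (completeness, profiles, dedup, witnesses) are
  exhaustive at `n = 2`, where independent oracles are feasible;
* the nand-only `n = 4` profile is computed exactly (seconds);
* the learning experiment uses a seeded sample of 256 four-property
  categories, 3 replicates, 100 epochs, and eleven LOTs spanning one to
  nine operators with and without parity — enough to establish the sign
  and ordering claims (all rho > 0 for parity-free LOTs; parity LOTs
  correlate worse; XOR costs more effort than a literal), not the exact
  full-scale rho values.

## Known limitations

* Domains beyond `n = 4` are rejected: truth-table masks are machine
  integers and the DP's table space grows as `2^(2^n)`.
* Formula grammar is unrestricted; normal-form variants (DNF, CNF,
  algebraic) would lengthen some minima and are out of scope.
* Shared subexpressions are not counted once (formulas are trees, not
  circuits).
* The trainer is single-threaded and CPU-only by design; the seed
  policy makes concurrent schedules equivalent to serial ones, but no
  parallel executor is shipped.
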