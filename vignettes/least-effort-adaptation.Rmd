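---
title: "Measuring least-effort adaptation in phrase-prediction logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring least-effort adaptation in phrase-prediction logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the model

Users of an autocomplete tool for a closed terminology face a trade-off
every time they type: a shorter query costs fewer keystrokes but matches
more labels, pushing the intended one down the suggestion list; a longer
query is more distinctive but more effortful. Zipf's principle of least
effort predicts that experienced users settle near the optimal trade-off
between these two pressures.

`zipfadapt` operationalises this as a two-objective minimisation. For a
target label $t$ and the set $\mathbb{P}^*$ of queries empirically
observed in a log, each query $p$ that surfaces $t$ within the top $J$
suggestions contributes a point $(k, j)$: its character count and the rank
of $t$ under the completion function $F(p)$. The Pareto front of these
points is the empirical optimum for $t$; the Euclidean distance from an
interaction's $(k, j)$ to its nearest front member is the convergence
metric; and user-label seniority — the running count of selections of that
label by that user — is the time axis along which adaptation is read.

Three assumptions deserve emphasis:

* **The optimum is empirical.** Optimising over all strings up to the
  longest label (a space of $(|\Phi|^{L+1}-|\Phi|)/(|\Phi|-1)$ strings,
  `string_space_size()`) is both intractable and meaningless to users, who
  can only discover queries by typing plausible text. Fronts computed from
  $\mathbb{P}^*$ therefore improve as the log grows, which has analysis
  consequences discussed below.
* **The engine is a fixed, deterministic function.** Every downstream
  quantity depends on $F$ only through ranks, so any fixed engine
  semantics supports the analysis. The built-in engine scores exact
  matches with a canonical text or synonym above word-prefix matches
  (every query token a prefix of some word of the label text) above
  substring matches, breaking ties by shorter matched text then ascending
  label id. It is deterministic, never repeats a label, and extending the
  last token of a query never enlarges the candidate set.
* **Distances are in raw units** — characters on one axis, rank positions
  on the other — because no normalisation of the axes is assumed. A
  min-max variant (`normalize = TRUE`) is available for sensitivity
  analyses; absolute distance scales are therefore not comparable across
  datasets with different rank caps.

## Parameters that matter

| Parameter | Default | Role |
|---|---|---|
| alphabet | 37 symbols: a–z, 0–9, space | the query symbol space; accented label text is folded into it |
| `J` | 30 | suggestion-list cap; ranks beyond it are infeasible |
| `zipf_s` | 1 | exponent of label popularity in the simulator |
| `n_users`, `n_labels`, `n_events` | 200, 300, 50 000 | reference scale of the synthetic study |
| `epsilon0`, `decay` | 0.8, 0.85 | exploration probability $\varepsilon_0\,\mathrm{decay}^{s-1}$ at seniority $s$ |
| `idiom_start_prob` | 0.8 | chance a first selection uses the label's jargon idiom |
| `margin`, `confidence` | 0.03, 0.95 | representativeness cap of the seniority axis |
| SG `window`, `polyorder` | 11, 2 | Savitzky–Golay smoothing of seniority curves |

The 37-symbol alphabet is the enumerable set (26 letters, 10 digits,
space); both the alphabet and $J$ are configurable, and every
combinatorial quantity is computed generically from the alphabet actually
supplied. The exploration schedule makes naive behaviour fade over roughly
the first five selections, matching the qualitative stabilisation point of
idiom usage. The representativeness cap uses the Cochran margin of error
for a proportion at $p = 0.5$ with finite-population correction,
$e = z\sqrt{0.25/n}\,\sqrt{(N-n)/(N-1)}$, with the normal quantile $z$
exposed through `confidence`; the recommended cap is the largest seniority
level up to which $e$ stays within `margin` at every level.

## What the simulator emulates — and what it does not

The generator produces the statistical structure the analyses assume,
without modelling cognition:

* **Terminology.** Labels are built as a head noun (from a pool of 26
  pathology/finding words) plus one to three modifiers (from a pool of
  70), mirroring how problem-list entries cluster on head nouns
  ("Douleur …", "Infection …"). This structure is load-bearing: it makes
  short novice queries ambiguous (many labels share a head) and two-token
  queries distinctive (the modifier disambiguates), which is precisely the
  conciseness/distinctiveness tension being measured. A fraction (0.2) of
  labels register their word-initial acronym as a searchable synonym.
* **Idiom lexicon.** Jargon expressions are the registered acronyms plus
  3-character stems of head words for a fraction (0.4) of labels —
  abbreviations a clinician knows, which the engine resolves poorly
  because they are ambiguous.
* **Label popularity** is Zipfian with exponent `zipf_s`; users are drawn
  uniformly. Selected-label frequencies in large simulated logs recover
  the configured exponent in a log-log rank-frequency fit.
* **Agents.** A (user, label) pair's first query is the label's idiom
  (with probability `idiom_start_prob`, when feasible) or a short (3–5
  character) feasible prefix: novices minimise typing at the cost of poor
  ranks. At later selections the agent explores with the decaying
  probability above: it samples a few candidates from a per-label pool
  (canonical prefixes, the acronym, head-prefix + modifier-prefix
  two-token combinations, and modifier-word prefixes) and switches by
  Pareto dominance: a candidate that weakly dominates the incumbent is
  adopted (exact objective ties switch with probability one half). One
  extension proved necessary: an incumbent that is *dominated within the
  pool* may also be traded, with probability one half, for a sampled
  candidate that is Pareto-efficient in the pool even when the two are
  incomparable. Without this "sideways escape", agents whose naive start
  admits no same-length-or-shorter improvement stay stuck on dominated
  points forever and the population never converges; with it, convergence
  toward the front is structural, because efficient points are absorbing
  up to dominance improvements. The sideways move is also the empirically
  observed adaptation pattern: trading a short ambiguous abbreviation for
  a longer, much better-ranked term. A scalarized adoption rule
  (weighted sum of $k$ and $j$) is available behind
  `adoption_rule = "scalarized"` for sensitivity checks.

Agents only ever submit feasible queries, timestamps are integer ticks,
and the whole log is a deterministic function of the seed.

What the simulator does **not** emulate: typing errors and their
correction, visual scan time across the suggestion list, calendar
seasonality, label co-occurrence within patients, users abandoning
searches, or any real French lexical statistics beyond the bundled
vocabulary. Passing the pipeline's convergence checks on synthetic data
therefore shows that the *instruments* detect adaptation when it is
present and stay silent when it is absent — it does not by itself
establish how strong such adaptation is in any real hospital log.

## Analysis instruments and their pitfalls

`curve_by_seniority()` pools all records at each seniority level and
reports the mean and population standard deviation (each level is treated
as the complete set of occurrences at that level, not a sample from a
larger one). Because label popularity is heavy-tailed, the population of
pairs present at high levels differs from that at low levels; the
consistency filter (`consistency_filter()`) removes labels that never
reach the cap, which controls the label mix along the axis.

One pitfall survives the filter and is worth understanding: a label's
empirical front is the best of all queries observed for it, so popular
labels — sampled by more users — have stronger fronts, and their records
sit systematically farther from the front even when nobody adapts.
Pooled level means then drift upward with seniority purely through
composition. The trend instrument `trend_bootstrap_ci()` therefore works
on a balanced panel by default: only pairs that attain `S_max` enter, so
every level aggregates the same pairs, and the bootstrap resamples pairs
(the independent unit). On no-adaptation (null) simulations the balanced
slope is zero by construction and its interval covers zero; on adaptive
simulations it is reliably negative. The pooled mode remains available
(`balanced = FALSE`) for comparability with record-pooled figures.

## Numerical choices

* **Normalisation** lowercases, folds accented Latin-1 characters through
  an explicit table (no locale dependence), drops characters outside the
  alphabet, and collapses whitespace. Queries and label texts pass through
  the same function, so "AVC" and "avc" are one element of
  $\mathbb{P}^*$.
* **Front extraction** sorts by $k$, keeps the minimal $j$ per $k$
  (smallest query lexicographically among duplicates), then keeps points
  whose $j$ strictly beats every smaller-$k$ point. This equals the
  $O(n^2)$ dominance definition exactly; tests verify set equality on
  1 000 random point sets. Note that the distance to a front is not
  monotone under re-fronting: adding a point that dominates the front
  advances the optimum and can widen any fixed query's gap. That is a
  property of optimality gaps, not a defect.
* **Savitzky–Golay smoothing** fits a degree-`polyorder` polynomial by
  least squares in a sliding window and evaluates it at the centre. At
  the series ends the window is truncated to the available points rather
  than reusing the first full window off-centre, keeping the fit local;
  interior points agree with the `signal` package's filter, and
  polynomials up to the filter order are reproduced exactly.
* **Power-law fitting** is ordinary least squares on
  $(\log_{10} r, \log_{10} f)$ over a configurable rank window
  (default capped at rank 100) to avoid the flat discrete tail of
  frequency-1 items; tied frequencies get distinct consecutive ranks,
  lexicographically. OLS was chosen over maximum-likelihood exponent
  estimation for transparency; it recovers exact exponents to numerical
  precision and sampled exponents to within a documented tolerance.
* **Degenerate inputs.** Empty normalised queries, empty point sets,
  empty fronts, unknown labels, and a smoothing window exceeding the
  series are all errors, not silent results; infeasible records (label
  beyond rank $J$) are kept, flagged, and counted, never dropped.

## Problem sizes

The reference synthetic study used throughout tests and the acceptance
script is 200 users, 300 labels and 50 000 events at `zipf_s = 1`, with
seniority trajectories read up to level 20 (the level-20 pair panel still
holds several hundred pairs at this scale) and idiom proportions up to
level 15. Statistical signatures are checked across five independent
seeds, with per-seed assertions where the effect is large (distance
decline, idiom decline, null coverage) and seed-ensemble assertions for
the noisier contrasts (standard-deviation shrinkage, rank decline).

## Known limitations

* The completion engine is a documented stand-in; real engines with
  learned rankers or fuzzy matching will produce different rank
  geometries, though the analysis layer is agnostic to them.
* Absolute distance values depend on $J$ and on the unit convention and
  should not be compared across configurations.
* The agent policy is a convergence device, not a cognitive model; only
  its structural properties (convergence when enabled, stasis when
  disabled, idiom fade-out) are committed behaviour.
* Idiom tracking requires a supplied lexicon; extracting jargon
  expressions from raw logs is out of scope.
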