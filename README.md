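# zipfadapt

Measuring least-effort adaptation in phrase-prediction query logs.

## The problem

Clinicians in hospitals select standardised problem-list labels through an
autocomplete ("phrase prediction") tool: they type a partial query, the
engine returns a ranked list of candidate labels, and they pick one. Every
interaction leaves a record — who typed what, and which label was chosen.
Zipf's principle of least effort predicts that, with experience, users
should drift toward queries that are jointly **concise** (few keystrokes)
and **distinctive** (the intended label near the top of the suggestions).

`zipfadapt` implements that analysis end to end for anyone studying
human–machine linguistic adaptation in interaction logs, together with a
seeded synthetic-log simulator so the whole pipeline runs, and can be
validated, without access to any proprietary hospital data.

## The model

For a target label *t*, every query *p* observed in the log (the empirical
query space ℙ\*) through which *t* is reachable within the top *J*
suggestions becomes a point with two objectives, both minimised:

* *k* — the query length in characters (conciseness), and
* *j* — the rank of *t* in the suggestion list `F(p)` (distinctiveness).

The **Pareto front** of these points — the queries no other query beats on
both axes — is the empirical optimum for *t*. The Euclidean distance from
an interaction's *(k, j)* point to its nearest front member measures how
far from optimal that interaction was. Distances are then tracked against
**user-label seniority** (the number of times that user has selected that
label — the pseudo-time axis of adaptation), with a consistency filter, a
finite-population representativeness cap, and Savitzky–Golay smoothing.
Companion analyses track the two objectives separately, the usage of
medical-jargon idioms ("hta", "avc", …) across experience levels, and the
rank-frequency power laws of words, queries and selected labels.

## Worked example

A terminology with synonyms, and the deterministic completion engine:

```r
library(zipfadapt)
trm <- terminology(data.frame(
  label_id = c(2477, 4578, 847),
  canonical_text = c("Accident vasculaire cérébral ischémique",
                     "Diabète de Type 2",
                     "Infection des voies respiratoires supérieures"),
  synonyms = c("avc", "", "ivrs")))
complete_query(trm, "avc")
#> [1] 2477
rank_of_label(trm, 2477, "accident vasc")
#> [1] 1
```

The full synthetic study — simulate a log of 50,000 interactions by 200
users over 300 Zipf-popular labels, enrich it, and track the distance to
the per-label Pareto fronts:

```r
trm <- generate_terminology(300, seed = 1)
lex <- generate_idiom_lexicon(trm, seed = 1)
log <- simulate_log(simulation_config(seed = 1), trm, lex)
enr <- enrich_log(log, trm)
dst <- annotate_distance(enr, pareto_fronts(enr, trm))
flt <- consistency_filter(dst, 20)
smooth_curve(curve_by_seniority(flt, "distance", S_max = 20), 11, 2)
#>   level   n  mean  std mean_smoothed
#> 1     1 800 4.786 6.62         4.630
#> 2     2 800 2.967 5.34         3.282
#> 3     3 800 2.179 4.53         2.371
#> ...
#> 5    19 337 0.629 1.53         0.634
#> 6    20 318 0.638 1.56         0.639
```

The mean distance to the optimum falls from 4.79 at the first selection to
0.64 by the twentieth, and its standard deviation shrinks from 6.6 to 1.6:
simulated users converge toward the conciseness/distinctiveness optimum,
and do so increasingly consistently. Idiom usage over the same log:

```r
idiom_proportion_by_seniority(enr, lex, 15)[c(1, 5, 10), ]
#>   level     n n_idiom proportion
#> 1     1 19729   17116      0.868
#> 2     5  1934     614      0.317
#> 3    10   769     246      0.320
```

Jargon idioms dominate first selections (87%) and fall to about a third of
queries once users know a label well — experienced users trade familiar
abbreviations for queries the engine resolves better.

The same pipeline runs on real logs: read them with `read_log()` (CSV or
JSON-lines with columns `user,query,label_id,timestamp`), the terminology
with `read_terminology()`, and proceed identically. A stage-by-stage
command-line wrapper is included:

```sh
Rscript inst/cli/zipfadapt.R all --config config.yaml --seed 1 --out out/
```

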