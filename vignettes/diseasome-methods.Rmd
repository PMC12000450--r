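---
title: "Methods: co-occurrence networks, Louvain communities, and their robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, Louvain communities, and their robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diseasome)
```

`diseasome` turns long-format administrative encounter records into an
ICD-code co-occurrence network, detects communities in it, and — the part
that deserves the most care — quantifies how much those communities can be
trusted. This vignette explains each model and the design decisions behind
it.

## The case definition

A patient enters the cohort when their encounter stream satisfies a
validated administrative rule: within some 2-year window they must have at
least 2 hospitalizations, **or** 4 physician claims, **or** 2 ambulatory
care contacts carrying an IBD diagnostic code. Key reading choices:

- *Windowing.* "Within a 2-year period" is evaluated as a sliding 730-day
  closed interval anchored at each IBD-coded encounter, per clause. 730
  days (leap days ignored) keeps the rule deterministic. A clause is met if
  any window contains the required count of that clause's encounter type.
- *Clause independence.* Each clause alone suffices; encounter types are
  never pooled across clauses.
- *Code map.* Both ICD-10-CA (K50/K51) and ICD-9-CA (555/556) prefixes
  count by default; the prefix list is a parameter of
  `case_definition()` because source systems differ in coding era.
- *Subtype.* The registry's original CD/UC scoring system is proprietary to
  its derivation cohort; here subtype is a documented stand-in: strict
  majority of IBD-coded encounters by prefix (ties and non-majorities →
  IBDU). It is exposed via `assign_subtype()` and is deliberately simple —
  on synthetic data its accuracy is exact by construction, and on real data
  any calibrated rule can be substituted at the same interface.
- *Age strata* (`<18`, `18–64`, `>64`) are assigned after flooring
  fractional age at first encounter.

## Descriptive statistics

Percentages are `round(100 * n / d, 3)` — round-half-even at three
decimals, the convention of the descriptive tables this layer mirrors. The
CD-vs-UC comparison for binary outcomes is the Pearson chi-square on the
2×2 table **with Yates continuity correction**. The correction is on by
default because the package's regression fixtures of published p-values
reproduce only under it (0.0438 and 0.0029 for the digestive and
respiratory rows; without correction one obtains 0.0414 and 0.0027). It is
toggleable. **No multiple-testing adjustment is applied anywhere** —
mirroring the analysis this package reimplements; treat the p-values as
descriptive.

Medians and IQRs use linear interpolation between order statistics
(`quantile(..., type = 7)`), which reproduces the hand-computable examples
(e.g. `[1,2,3,4] → median 2.5, IQR 1.5`).

ICD codes are grouped into organ-system domains by an ordered range map
(`default_domain_map()`, shipped editable at
`inst/extdata/domain_map.csv`). Order matters: specific overrides precede
chapters and the first match wins. The cerebrovascular group pools I60–I69
with I80–I82 (phlebitis, embolism, thrombosis and stroke), and the IBD
index range K50–K51 is flagged non-EIM so the disease-defining codes never
count as manifestations. The exact published membership of every organ
system is not enumerated in the source material, so this map is a best
reconstruction — flagged as such, and user-replaceable.

## The co-occurrence graph

Nodes are ICD codes; a node's weight `n` is the number of **unique**
patients ever carrying the code, and its display size is
`sqrt(n) * 0.3 + 2.5`. An undirected edge joins two codes co-carried by
`m ≥ 1` unique patients; its display width is `m * 0.01`. Co-occurrence is
lifetime ("ever/ever") — no window is imposed between the two diagnoses.
Each co-carrying patient is classified by comparing the two
first-diagnosis dates (minimum encounter date per patient and code):
strictly earlier → `a_first`/`b_first`, equal → `same_day`; these
direction counts always sum to `m`. Edges are canonically oriented
`code_a < code_b` lexicographically, so rebuilding the graph from shuffled
input yields byte-identical tables.

`filter_graph()` reproduces the interactive display's controls: minimum
pair count, top-N heaviest edges (display default caps at 1000), domain
restriction, and code truncation. Truncation at, say, 3 characters merges
`K50.1` and `K50.9` into `K50` and **recomputes** unique-patient counts
from the raw incidence table — summing child counts would double-count
patients carrying several children.

## Louvain with an explicit edge order

Community detection is a native implementation of the two-phase Louvain
heuristic for weighted Newman–Girvan modularity,

$$Q = \sum_c \left[ \frac{w_{in}(c)}{W} - \left(\frac{s_c}{2W}\right)^2 \right],$$

with resolution fixed at 1 (exposed for exploration), edge weight `m`,
self-loops permitted (they arise from code aggregation; a loop counts once
in $w_{in}$ and twice in its node's strength — the same convention as the
igraph reference implementation, against which `modularity_q()` is
cross-checked to 1e-9 in the test suite).

Numerical choices:

- *Visit order.* Phase-1 local moving visits nodes in order of first
  appearance in the supplied edge sequence. This makes the edge input
  order the **single** source of run-to-run variability — exactly the
  property the shuffle robustness experiment manipulates — and makes every
  run deterministic given graph + order. The default order is the canonical
  alphabetical edge table.
- *Move acceptance* requires a modularity gain above `1e-12`, guarding
  against floating-point ping-pong; candidate communities are scanned in
  ascending id so ties keep the current community deterministically.
- *Termination* when a full level makes no move; aggregation then stops
  changing the graph. Q never decreases across levels.
- *Output ids* are dense, 0-based, ordered by descending community size
  with ties broken by the lexicographically smallest member code; the
  display palette (blue, yellow, green, red, purple, then overflow) is
  assigned in that order.

Greedy modularity optimization has no optimality guarantee: on sparse
graphs with near-zero optimal Q a single run can stall in a local optimum.
The test suite therefore asserts single-run optimality only on the
disconnected-cliques family (where enumeration proves the optimum is
unique) and asserts a 95%-of-optimum guarantee for random graphs over the
algorithm's own edge-order shuffles.

## Robustness of the communities

The Dice–Sørensen coefficient $2|A\cap B|/(|A|+|B|)$ scores the overlap of
two code sets (two empty sets score 1). To compare two partitions, the
full Dice matrix between their communities is built and communities are
paired by **exact maximum-total-Dice assignment** (a subset-DP; community
counts are small). "Corresponding communities" is not further specified in
the source analysis; optimal assignment is chosen because it is
deterministic and reproducible, where greedy matching depends on scan
order. When community counts differ, the smaller side is padded with empty
communities scoring 0 — disagreement in community count is penalized, and
those padded pairs **are** included in the reported mean.

Three experiments share this scoring:

- `shuffle_experiment()`: fixed graph, `n_runs` Louvain runs under
  independently shuffled edge orders, overlap of each consecutive pair
  (algorithmic variability).
- `split_sample_experiment()`: per trial, patients are split into two
  equal, mutually exclusive halves; a graph is built and Louvain run per
  half with edges in fixed alphabetical order (controlling algorithmic
  variability); the two partitions are compared (sampling variability).
  Trials with an edgeless half are skipped and logged.
- `random_null()`: two independent uniform assignments of the code set to
  `k` communities per trial. Uniform assignment (rather than preserving
  empirical community sizes) is the most literal reading of "random
  assignment"; with optimal matching the mean lands near `1/k` plus a
  positive matching bonus. The null's exactness is verified in the tests
  against complete enumeration of all assignment pairs at `n_codes = 4,
  k = 2`.

Each experiment reports the mean and SEM (sd/√trials) of its per-trial
scores; `welch_one_sided()` (Welch t, Satterthwaite df) compares real
scores against the null.

Overlap scoring is restricted to the EIM/AID codes: the IBD index codes
remain in the graph — they anchor the clusters — but a cohort defined by
those codes carries them near-universally, so including them in an EIM
community-stability score (or in the frequency quartiles) would be
circular. Quartile-restricted scoring (`quantile_subset()`) uses type-7
percentile boundaries with half-open intervals `Q0 = [min, 25th)` …
`Q3 = [75th, max]`; with all frequencies tied, every code lands in Q3.
Communities emptied by a subset restriction are dropped before matching —
keeping them would let empty-vs-empty pairs inflate restricted scores.

## The synthetic generator

Real registry data being non-public, `generate_cohort()` produces encounter
streams with known ground truth. What it emulates:

- A mixed cohort (defaults: 42% CD-like, 31% UC-like, 7% IBDU-like, 20%
  non-case, echoing the case mix of large IBD registries at a realistic
  case fraction).
- Index streams that satisfy exactly one case-definition clause (rotated
  per patient so all three arms are exercised), or — for a configurable
  `case_noise` fraction — streams below every clause, to exercise the
  classifier's reject path. IBDU-like patients receive balanced K50/K51
  streams so the majority rule ties.
- A planted block structure over 100 synthetic EIM codes (4 communities ×
  25 codes, spread across realistic ICD chapters so chapter grouping and
  community structure cut across each other). Each patient is assigned one
  block and carries each code with probability `p_within = 0.3` inside it,
  `p_between = 0.01` outside — a planted-partition regime in which
  community recovery is achievable but not trivial.
- Heavy-tailed code frequencies: per-code carriage propensities follow a
  geometric profile spanning `frequency_spread = 5` within each block
  (normalized so the block mean stays `p_within`). Real ICD code
  frequencies vary over orders of magnitude; homogeneous carriage would
  make frequency-quartile analyses pure noise. Set `frequency_spread = 1`
  to recover exact per-code marginals.
- First-diagnosis dates uniform over 2002–2019, adjusted so designated
  ordered code pairs respect `temporal_bias` (default 0.9; at 1.0 the
  ordering is strict for every co-carrier). Repeat encounters are generated
  with probability 0.1 to exercise first-date deduplication.

What it does **not** emulate: realistic registry demographics, medication
exposure streams, coding-practice drift over time, correlated comorbidity
beyond the planted blocks, or the empirical size distribution of real
communities. Passing tests on this generator therefore demonstrate the
*machinery* (construction, detection, scoring) is correct and that planted
structure of the stated strength is recovered — not that real EIM
communities have any particular stability.

Benchmark scale: the standard fixture is 2000 patients (~1600 cases),
100 EIM codes, ~110 graph nodes and ~5000 edges; robustness experiments in
the tests use 8–12 runs/trials and a 200–1000-trial null. These sizes give
sub-minute end-to-end runs while keeping binomial noise far below the
planted effect sizes.

## Known limitations

- The subtype rule and the domain map are documented stand-ins where the
  original analysis relied on unpublished internals; both are injectable.
- Louvain is a heuristic; stability claims should always be read through
  the robustness experiments, which is why they are first-class citizens
  here.
- The null model does not preserve empirical community sizes; with
  size-matched pairing the expected base overlap is 1/k either way, but
  heavy-tailed real partitions could shift the matching bonus slightly.
- p-values in the frequency layer are unadjusted for multiplicity by
  design.
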