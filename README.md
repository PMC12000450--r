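# diseasome

Disease co-occurrence networks and community robustness for administrative
health data.

## The problem

Inflammatory bowel disease (IBD — Crohn's disease, ulcerative colitis and
IBD-unclassified) is accompanied by a wide range of extraintestinal
manifestations (EIM) and associated immune disorders (AID): arthritis,
uveitis, skin disease, psychiatric comorbidity, and many more. Given
population-scale administrative encounter data (one dated ICD-10 diagnosis
per row), one can ask which conditions co-occur in the same patients, which
tends to come first, and whether groups of conditions cluster into
reproducible "diseasome" communities.

`diseasome` implements that analysis end to end for epidemiologists and
network-medicine researchers:

- **Cohort extraction** by a validated administrative case definition: a
  patient is an IBD case if, within some 730-day window, they have ≥2
  hospitalizations, or ≥4 physician claims, or ≥2 ambulatory contacts with
  an IBD diagnostic code (K50.x/K51.x, ICD-9 555/556 accepted). Subtype
  (CD/UC/IBDU) is assigned by a documented majority rule.
- **Descriptive tables**: per-group patient counts, 3-decimal percentages,
  Yates-corrected chi-square CD-vs-UC comparisons, medians/IQR, ICD chapter
  grouping, utilization rates.
- **Co-occurrence network**: nodes are ICD codes with display size
  √n × 0.3 + 2.5 (n = unique patients); undirected edges link codes
  co-carried by m patients with width m × 0.01, annotated with temporal
  direction counts from first-diagnosis dates.
- **Community detection**: a native weighted Louvain implementation
  maximizing Newman–Girvan modularity
  Q = Σ_c [ w_in(c)/W − (s_c/2W)² ], with the edge input order — the
  algorithm's only source of run-to-run variability — exposed as a
  parameter.
- **Robustness evaluation**: matched Dice–Sørensen overlap between
  partitions (optimal assignment over the community Dice matrix),
  edge-order shuffle and split-sample experiments, frequency-quartile
  restricted scoring, a uniform random-assignment null distribution
  (mean ± SEM over trials), and one-sided Welch tests against it.
- **A synthetic EHR generator** with planted block structure over the code
  set, so the whole pipeline is testable without access to restricted
  registry data.

## Worked example

```r
library(diseasome)

sim    <- generate_cohort(sim_config(n_patients = 500, seed = 1))
cohort <- build_cohort(sim$records, demographics = sim$truth$demographics)
table(cohort$label)
#>       CD excluded     IBDU       UC
#>      216       87       40      157

g <- build_graph(sim$records, cohort, cohort_tag = "IBD")
g
#> ICD co-occurrence graph [IBD]: 108 nodes, 3594 edges

p <- louvain(g)
p
#> Partition: 108 nodes in 4 communities, Q = 0.385025

# recovery of the generator's planted 4-block structure
partition_overlap(p, sim$truth$code_communities,
                  code_subset = names(sim$truth$code_communities))
#> [1] 1

# stability vs the random-assignment null
null <- random_null(nrow(g$nodes), p$n_communities, n_trials = 200, seed = 1)
null
#> Overlap [all]: mean 0.3286 +/- 0.0017 SEM over 200 trials
sh <- shuffle_experiment(g, n_runs = 10, seed = 1)
sh
#> Overlap [all]: mean 1.0000 +/- 0.0000 SEM over 9 trials
welch_one_sided(sh$per_trial_scores, null$per_trial_scores)
#> [1] 1.399576e-288
```

The cohort table shows the case definition at work: IBD-labelled synthetic
patients classify as CD/UC/IBDU, sub-threshold patients are excluded. The
Louvain partition recovers the generator's four planted code communities
exactly (matched Dice 1.0), and the shuffle experiment's overlap is far
above the ~0.33 expected when codes are assigned to four communities at
random.

`run_pipeline(list(n_patients = 2000, seed = 1), "out/")` executes the whole
chain (simulate → cohort → frequencies → graph → communities → robustness →
interactive network payload) and writes every artifact plus a manifest.

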