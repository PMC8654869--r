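# ecvnet

Network-based cancer subtyping from transcriptome data alone.

Multi-omics clustering methods often produce tumor subtypes with no
prognostic separation. `ecvnet` implements an alternative: estimate one
*basal* gene regulatory network for the whole cohort, quantify how strongly
each **patient** uses each **edge** of that network, and cluster patients on
those per-edge quantities. Patients whose tumors run the same regulatory
program end up together even when their raw expression profiles look alike.

## The model

The cohort network is a Bayesian network with B-spline nonparametric
regression. For gene *j* with parents pa₁…pa_q, expression is modeled as

    x_ij = m₁^(j)(pa_i1) + … + m_q^(j)(pa_iq) + ε,   ε ~ N(0, σ_j²)

where each m_k is a penalized cubic B-spline smooth. Structures are scored
by a decomposable Laplace-approximated marginal likelihood and searched by
greedy hill-climbing with restarts (with an exhaustive-search oracle for
networks of at most 5 genes).

The **Edge Contribution value** of edge (j_k → j) for patient *i* is

    ECv_(i)(j_k → j) = m_k^(j)(pa_ik)

— the fitted contribution of that edge to the patient's expression of gene
*j*. Collecting ECvs over all E edges gives each patient a "quantified
network" vector; the cohort forms a patients × edges ECv matrix.

Downstream analysis:

* **Subtyping** — rank edges by ECv variance across patients, keep the top
  N (default 250), and cluster patients hierarchically (Ward + Euclidean).
* **Subtype-specific edges** — for each subtype R_r, per edge,

      Δ̃ECv^{R_r} = | mean_{i∈R_r} ECv_i − mean_{i∉R_r} ECv_i |,

  select the top 1% of edges per subtype, and keep the edges selected by
  exactly one subtype (Venn exclusion). Their induced subnetworks
  characterize each subtype.
* **Survival** — Kaplan–Meier curves and M-sample / pairwise log-rank tests
  compare subtype prognoses.

A synthetic-cohort generator (`generate_cohort`) plants known subtypes that
differ only in regulatory edge usage — balanced so marginal per-gene
statistics carry no subtype signal — plus subtype-dependent survival, so the
whole pipeline is testable end to end without any data downloads.

## Worked example

```r
library(ecvnet)

coh <- generate_cohort(generator_config(seed = 4))     # 15 genes, 3 x 50 patients
surv <- generate_survival(coh$truth$labels, c(0.004, 0.002, 0.001),
                          censor_rate = 0.001, seed = 5)
res <- run_pipeline(coh$X,
                    pipeline_config(n_edges = 50, k = 3, seed = 4),
                    clinical = surv, out_dir = "run1")

res$network
#> bn_fit: 15 genes, 27 edges, score = -3542.882
res$assignment
#> subtype_assignment: 150 patients in 3 subtypes (sizes: 59/49/42 )
compare_assignments(res$assignment, coh$truth$labels)$ari
#> [1] 0.8299674
res$survival$overall
#> log-rank test: chi-square = 23.6 on 2 df, p = 7.516e-06
lengths(res$delta$exclusive_sets)
#> 1 2 3
#> 1 1 1
```

The estimated basal network has 27 edges; clustering the top-variance ECv
columns recovers the three planted subtypes well (adjusted Rand index 0.83
against ground truth), the subtypes differ sharply in survival (log-rank
p ≈ 8e-06, true hazards spanning 4×), and each subtype
gets its own exclusive high-Δ̃ECv edge. `run1/` contains the assignment,
ECv matrix, Δ̃ECv table, subnetwork SIF files, survival table, fitted-model
JSON, and a manifest of all parameters.

A command-line front end with subcommands `simulate`, `estimate`, `ecv`,
`subtype`, `edges`, `survival`, and `pipeline` is installed at
`inst/scripts/ecvnet.R` (run it with `Rscript`).

## Scope notes

The published full-scale analyses behind this method used ~20,000-gene
networks estimated on a supercomputer with a parallel structure-search
algorithm; that scale is out of reach here by design. This package treats
any pre-estimated network (edge list + model JSON) as input, replaces the
large-scale search with greedy hill-climbing bounded by an exhaustive oracle
on small instances, and validates all claims on synthetic cohorts.
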