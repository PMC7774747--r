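# evosubtype

Classifying tumors by *how they evolved*, not just which genes they
mutated. Given multi-region somatic mutation tables — several spatially
separated samples per tumor, each with per-region variant allele
frequencies — **evosubtype** reconstructs a per-patient mutation
phylogeny, encodes it as a comparable numeric vector, clusters patients
into evolutionary subtypes, and quantifies what those subtypes mean:
intra-tumor heterogeneity, the timing of driver mutations, and clinical
outcome. It is aimed at cancer-genomics analysts working with
multi-region cohorts (e.g. early-stage non-small-cell lung cancer).

## The method

1. **Phylogeny.** Per patient, mutations with VAF ≥ 0.1 in a region are
   scored present there; the binary regions × mutations matrix is fitted
   by **Dollo parsimony** (each mutation gained once, on the edge above
   the MRCA of its carriers, lost arbitrarily often below), with the
   matched normal as an all-zero outgroup. Branch lengths are mutation
   counts. Search is exhaustive over all rooted topologies for small
   region counts and seeded NNI hill-climbing above; co-optimal trees are
   resolved by canonical Newick order.
2. **Vectorization.** Each tree is mapped onto a complete binary
   reference tree of cohort-wide depth *D* by inserting zero-length
   virtual edges (largest subtrees grouped first), normalized so edge
   lengths sum to 1, and read off root-down, larger-subtree-first, into a
   vector z of length 2^(D+1) − 2.
3. **Subtyping.** Euclidean distances d(z_i, z_j) feed hierarchical
   clustering (complete linkage); the number of subtypes k ∈ {2, …, 10}
   maximizes the average silhouette S̄, with
   S_i = (b(i) − a(i)) / max{a(i), b(i)}.
4. **Heterogeneity.** Branched diversity (#private + #shared)/#ubiquitous;
   ITH index #subclonal/#clonal; copy-number ITH by interval arithmetic;
   subclonal-diversity AUC; sphere-corrected tumor size TS/∛SS.
5. **Driver timing.** Trunk < shared < private mutations define timing
   pairs (shared→private only along one root-to-leaf path); genes early
   in ≥ 3 patients are **EDF genes**; a Bradley–Terry model on the pair
   tournament yields a temporal ordering of driver genes.
6. **Association.** Fisher exact tests with Haldane-corrected log odds
   ratios for mutual exclusivity / co-occurrence; Kaplan–Meier/log-rank
   and Mann–Whitney U for clinical phenotypes.

A seeded synthetic-cohort generator with full ground truth (archetypal
tree shapes, noisy VAFs, CCFs, copy-number segments, survival) makes the
whole pipeline testable without any external data; see the vignette
`vignettes/evolutionary-subtyping.Rmd` for the models and design choices.

## Worked example

```r
library(evosubtype)

cfg  <- sim_config(n_patients = c(arch1 = 5L, arch2 = 5L, arch3 = 5L),
                   seed = 42L)
sim  <- simulate_cohort(cfg)          # mutations / CNA / clinical tables
pipe <- evo_subtype_pipeline(sim$mutations)
print(pipe)
#> <evo_pipeline> 15 patients, reference depth 6
#> <subtype_assignment> 15 patients, k = 3 (complete linkage)
#> subtype
#> 1 2 3
#> 5 5 5
#> average silhouette by k:
#>     2     3     4     5     6     7     8     9    10
#> 0.482 0.609 0.513 0.452 0.434 0.401 0.338 0.278 0.258
```

The silhouette scan peaks at k = 3 and the three evolutionary subtypes
are recovered 5/5/5. Heterogeneity profiles and outcome follow:

```r
prof <- heterogeneity_profile(sim$mutations, pipe$trees,
                              segments = sim$cna, clinical = sim$clinical)
head(round(prof[-1], 3), 4)
#>   branched_diversity ith_index cna_ith subclonal_diversity_auc corrected_tumor_size
#> 1             20.000    17.875   0.675                   0.787               39.155
#> 2              5.632     5.095   0.611                   0.635               34.018
#> 3             13.778    11.273   0.523                   0.743               24.256
#> 4             11.100     9.167   0.532                   0.704               48.208

km <- km_logrank(sim$clinical, pipe$assignment$labels)
#> log-rank chi-square: 9.735  p = 0.00769
```

Patients in subtype 1 (branched evolution, high branched diversity and
subclonal-diversity AUC) progress significantly faster. Early driver
feature genes are subtype-specific:

```r
early <- do.call(rbind, lapply(names(pipe$trees), function(p)
  early_driver_calls(pipe$trees[[p]], pipe$locations[[p]],
                     pipe$matrices[[p]]$drivers,
                     genes = pipe$matrices[[p]]$genes, patient_id = p)))
edf_genes(early, min_patients = 3, subtypes = pipe$assignment$labels)
#>     gene n_patients_early subtype_1 subtype_2 subtype_3 assigned_subtype
#> 1   KRAS                4         0         4         0                2
#> 2 COL5A2                3         0         3         0                2
#> 3 PIK3CA                3         3         0         0                1
```

All early KRAS/COL5A2 carriers sit in subtype 2 and all early PIK3CA
carriers in subtype 1 — the generator's planted driver placement,
recovered from the trees alone.

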