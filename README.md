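# dockcal

Similarity-calibrated hybrid docking scoring for virtual screening.

Docking scoring functions rank-order compound libraries cheaply, but their
absolute binding-energy estimates are noisy and carry systematic,
target-dependent error. When a set of *reference ligands* with experimentally
measured affinities (Ki/Kd) is available for the target — the routine
situation when screening against a well-studied receptor — that information
can be folded back into the docking score at essentially no computational
cost. `dockcal` implements such a hybrid scoring function together with the
evaluation machinery around it: 2D fingerprints and Tanimoto similarity,
affinity/energy conversion and activity labelling, scoring/ranking/screening
metrics, a repeated-split benchmark harness, and a synthetic clustered-library
generator for method validation.

It is written for computational chemists doing structure-based virtual
screening: data frames in, tibbles out, pipeable, with `tidy()`, `glance()`
and `autoplot()` methods on the result objects.

## The model

For query compound *j* with original docking score DS⁰ⱼ and reference ligands
*i* = 1…n with docking scores DSᵢ and experimental binding free energies ΔGᵢ,
the calibrated score is

```
DS_j = DS⁰_j · (1/ω) Σ_{i≠j} S_ij^p · (ΔG_i / DS_i),      ω = Σ_{i≠j} S_ij^p
```

where S₍ᵢⱼ₎ is the Tanimoto coefficient between the 2D fingerprints of query
and reference, Tc(X,Y) = z/(x+y−z), and p is an integer exponent (the
*compound similarity effect* function S^p; default p = 4). The correction is
a similarity-weighted convex combination of the reference ratios
experimental/docked, so a query surrounded by references whose docking scores
run systematically too strong (or weak) is pulled toward the experimentally
anchored scale. Reference ligands can be restricted to a Tanimoto window:
a lower bound alone models a *focus library* (lead optimisation); adding an
upper bound models a *diverse library* (lead identification, near-neighbour
references excluded).

Experimental affinities convert through ΔG = RT·ln Ki[M] at T = 298.15 K
(R = 8.314 J mol⁻¹ K⁻¹), so a 100 nM binder corresponds to −9.55 kcal/mol.

Fingerprints (FP2 1024-bit path-based, FP3/FP4 SMARTS sets, MACCS 166 keys)
are computed with OpenBabel via ChemmineR/ChemmineOB; precomputed bit vectors
from any other toolkit can be supplied as a hex table instead.

## Worked example

A query docked at −9.0 kcal/mol, two references docked at −8.0 and −10.0
kcal/mol with experimental energies −7.0 and −8.0, similarities 0.9 and 0.5
to the query, p = 4:

```r
library(dockcal)

refs <- data.frame(id = c("ref_i", "ref_j"),
                   docking_score = c(-8.0, -10.0),
                   delta_g_kcal  = c(-7.0, -8.0))
calibrate_one(list(id = "query", docking_score = -9.0), refs,
              calibration_config(p = 4), similarities = c(0.9, 0.5))
#> <dockcal_calibration> 1 query(ies), CSE = S^4, 0 fallback(s)
#> # A tibble: 1 × 6
#>   id    original_score calibrated_score omega n_contributing fallback
#> * <chr>          <dbl>            <dbl> <dbl>          <int> <lgl>
#> 1 query             -9            -7.82 0.719              2 FALSE
```

The highly similar reference (S = 0.9, weight 0.9⁴ = 0.656) dominates the
dissimilar one (0.5⁴ = 0.0625), so the calibrated score −7.82 sits close to
DS⁰·(−7/−8): the docking score is softened toward the similar reference's
experimental/docked ratio. `omega` is the total similarity weight; when no
reference survives the Tc window the query keeps its original score and is
flagged `fallback`.

End to end on a full library, the same computation runs from score tables and
structure files (`calibrate_scores()`, or the `calibrate` subcommand of the
CLI wrapper in `inst/cli/dockcal.R`).

## Benchmarking on synthetic clustered libraries

The generator builds chemical series (shared scaffold, enumerated
substituents) whose docking scores carry a shared per-cluster bias — the
regime the calibration is designed for:

```r
compounds <- generate_compounds(synthetic_spec(seed = 1))   # 5 clusters × 20
bench <- run_benchmark(compounds,
                       calibration_grid(fingerprint = "FP2", p = 4),
                       split_spec(n_repeats = 10, seed = 1))
glance(bench) |> dplyr::filter(metric %in% c("rmse", "pi", "auc"))
#>   fingerprint     p tc_lower tc_upper metric phase       mean    ci95
#> 1 FP2             4        0       NA rmse   original   0.942 0.0754
#> 2 FP2             4        0       NA pi     original   0.923 0.0174
#> 3 FP2             4        0       NA auc    original   0.967 0.0234
#> 4 FP2             4        0       NA rmse   calibrated 0.530 0.0793
#> 5 FP2             4        0       NA pi     calibrated 0.971 0.00896
#> 6 FP2             4        0       NA auc    calibrated 0.998 0.00320
```

Across ten 4:1 reference/validation splits, calibration cuts RMSE from 0.94
to 0.53 kcal/mol and raises the predictive index and ROC AUC; `ci95` is the
95% confidence half-width over the repeats, and `tidy(bench)` returns the
long per-repeat table the summary is computed from.

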