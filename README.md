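# piwikit

Quantitative analysis of PIWI-guided target binding and slicing.

PIWI-clade Argonaute proteins (mouse MILI and MIWI, sponge Piwi) use
piRNA guides to find and cleave transposon transcripts. Unlike AGO-clade
proteins, they tolerate extensive guide:target mismatches — they bind
without seed pairing and slice targets with as few as ~15 contiguous
base pairs. Establishing that quantitatively takes several coupled
measurements, and piwikit implements the full analysis chain for people
working with this kind of data:

- **Pairing and energetics** — guide:target duplex annotation in g/t
  coordinates (antiparallel; the scissile bond fixed between t10 and
  t11), nearest-neighbour duplex free energies
  (Turner 2004 stacks, WC + G:U), and K_d → ΔG⁰ conversion
  (ΔG⁰ = RT ln K_d, T = 306.15 K).
- **Bind-n-Seq** (`assign_sites`, `fit_kd_mle`) — reads are assigned to
  non-overlapping complementarity windows with flank rules, and per-site
  dissociation constants estimated by maximum likelihood under the
  equilibrium model θ_i = E/(E + K_d,i) with free-RISC conservation,
  across a six-point concentration series (0.003–1 nM), reporting the
  median of 49 optimizations from a 7×7 initial-guess grid.
- **Cleave-n-Seq** (`fit_burst`, `fold_change_summary`,
  `map_cut_sites`) — time-course depletion counts are converted to
  P_relative and fit to the burst-and-steady-state model
  P(t) = E·[(k2/(k2+k3))²(1 − e^−(k2+k3)t) + (k2k3/(k2+k3))t]
  with bounds 0.5 ≤ E ≤ 1, 0 ≤ k2 ≤ 100 min⁻¹, 0 ≤ k3 ≤ 1e-4 min⁻¹;
  k = k2 + k3 is the pre-steady-state cleavage rate.
- **Degradome analysis** (`group_pirnas`, `find_candidates`,
  `fraction_cleaved`) — 5′-monophosphorylated species explained by a
  piRNA placing t10 at their 5′ end are scored for ≥8-fold loss in
  piRNA-deficient mutants over all 16 single-animal replicate pairings;
  f_cleaved = f_decreased(targeted) − f_decreased(control piRNAs), with
  a 10,000-iteration bootstrap CI over candidate sites.
- **Cleavage decision function** (`build_features`,
  `fit_cleavage_ensemble`) — the 35-feature penalized logistic model of
  in vivo cleavage probability, fit as a 16 × 5 × 5 = 400-model
  ensemble with balanced class weights and λ = 1, evaluated by
  precision-recall AUC.
- **Escape simulation** (`simulate_escape`, `decay_rate`,
  `shared_kmer_fraction`) — iterated single-nucleotide substitutions
  (synonymous-only inside ORFs) with counting of cleavage-competent
  piRNAs (≤6 mismatches) and simulated siRNAs (≤5 total, ≤1 in seed,
  none at g9/g10/g11/g13).
- **Synthetic data** (`sim_rbns_counts`, `sim_cns`, `sim_degradome`,
  `sim_repertoire`, `sim_logit_cohort`) — seeded generators with known
  ground truth for every stage, so the whole pipeline is testable
  without downloads.

Everything takes and returns tibbles, composes with the pipe, and the
fitted objects have `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

Simulate a small Cleave-n-Seq library with known rates, fit the burst
model per variant, and summarize mismatch effects as fold changes
against the perfect site:

```r
library(piwikit)
library(dplyr)

truth <- tibble::tibble(variant_id = c("perfect", "mm_g10", "mm_g5_g15"),
                        k = c(2, 0.5, 0.05))
sim <- sim_cns(truth, depth = 2e5, n_normalizers = 10, seed = 42)

fits <- sim$counts |>
  normalize_library(sim$normalizer_ids) |>
  compute_p_relative() |>
  fit_burst_rates() |>
  filter(variant_id %in% truth$variant_id)

fits |> select(variant_id, e_relative, k, k_se, converged)
#> # A tibble: 3 × 5
#>   variant_id e_relative      k     k_se converged
#>   <chr>           <dbl>  <dbl>    <dbl> <lgl>
#> 1 mm_g10              1 0.501  0.00115  TRUE
#> 2 mm_g5_g15           1 0.0503 0.000471 TRUE
#> 3 perfect             1 1.99   0.00275  TRUE

fold_changes(fits, perfect_id = "perfect") |>
  select(variant_id, k, fold_change)
#> # A tibble: 3 × 3
#>   variant_id      k fold_change
#>   <chr>       <dbl>       <dbl>
#> 1 mm_g10     0.501         3.97
#> 2 mm_g5_g15  0.0503       39.6
#> 3 perfect    1.99          1
```

The fitted rates recover the planted 2, 0.5 and 0.05 min⁻¹ within
counting noise; the fold-change column reads directly as "this mismatch
slows cleavage ~4-fold". The same pattern — simulate with known truth,
run the estimator, compare — runs through the whole package:
`sim_degradome()` → `fraction_cleaved()` recovers a planted cleavage
fraction minus background with calibrated bootstrap intervals, and
`sim_rbns_counts()` → `fit_kd_mle()` recovers dissociation constants
within a few percent at 10⁶ reads/sample.

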