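---
title: "Models and methods behind piwikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind piwikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piwikit)
library(dplyr)
```

piwikit quantifies how PIWI-clade Argonaute proteins (MILI, MIWI and
their relatives) bind and slice RNA targets that are only partially
complementary to their piRNA guides. It covers five connected analyses —
equilibrium binding (Bind-n-Seq), pre-steady-state cleavage kinetics
(Cleave-n-Seq), in vivo cleavage detection from degradome sequencing, a
logistic decision function for cleavage probability, and a transposon
mutagenesis escape simulation — together with seeded generators that
produce synthetic inputs with known ground truth for every stage. This
vignette explains each model, its assumptions, the tunable parameters,
and the numerical and design choices where the methods left room for
judgement.

## Coordinates and pairing conventions

Guide positions are 1-based (g1 is the guide 5′ end); transcript
coordinates are 0-based and half-open. The target runs antiparallel to
the guide, so the nucleotide opposite g\_i sits at transcript index
`c + 10 - i`, where `c` is the index of t10. The scissile phosphodiester
bond always lies between t10 and t11: slicing leaves a 3′ product whose
first nucleotide is t10 and whose 5′ end carries the monophosphate that
degradome sequencing captures.

Pairing states are Watson–Crick, G:U wobble, mismatch, and the two indel
states (guide bulge = target deletion, target bulge = target insertion).
Whether a wobble counts as "paired" is a convention, not a fact: for
duplex energies and contiguity we count G:U as paired (wobbles stack,
and the binding data treat wobble-containing sites as bound), while
mismatch-geometry labelling in kinetic summaries can treat wobbles as
mismatches. `annotate_pairing(..., wobble =)` exposes the switch; the
default is `"paired"`.

## Duplex free energy

`predict_duplex_energy()` sums published Turner 2004 nearest-neighbour
stacking parameters (Watson–Crick and G:U pairs) over contiguous paired
blocks, adds a duplex-initiation term (+4.10 kcal/mol), a +0.50 kcal/mol
penalty per AU/GU helix end, and fixed affine penalties for the internal
loops and bulges that separate blocks (internal loop:
`1.6 + 1.1 ln(n/2)`; bulge: `3.8 + 1.1 ln(n)`, n = unpaired
nucleotides). Dangling ends, coaxial stacking and loop-sequence effects
are not modelled. The predictor is deterministic for a fixed table,
which is what the rest of the package needs: ranking configurations,
the x27 feature of the decision function, and the regression of
Kd-derived against predicted energies. An empty pairing has energy 0 by
convention. `kd_to_energy()` converts dissociation constants with
ΔG⁰ = RT ln(K_d/1 M) at a default temperature of 306.15 K (33 °C, the
binding-assay temperature).

A guarantee the package relies on, and tests assert on enumerated
cases: adding one Watson–Crick pair adjacent to an existing helix never
raises the predicted energy (every WC-containing stack in the table is
more favorable than the worst-case change in terminal penalties).

## Bind-n-Seq: site assignment and K_d estimation

Reads have the fixed layout `GATC + N20 + TGGA`; the whole 28-mer is
searched for site motifs because sites may extend into the constant
regions. To keep site types non-overlapping, windows of ≤10 nt must be
flanked on both sides by read nucleotides not Watson–Crick
complementary to the adjacent guide positions, 11-nt windows need the
non-complementary flank only beyond their highest guide position, and
≥12-nt windows carry no flank requirement. A read with exactly one
motif occurrence is assigned to that site type; reads with several
(including partially overlapping) occurrences are rejected; reads with
none are `no_site`. Flank positions outside the read are vacuously
satisfied.

The binding model is standard equilibrium competition. Site type *i*
with dissociation constant K_d,i and library concentration
S_i = f_i·L (f_i = input frequency, L = total library concentration,
default 100 nM) is occupied at free-RISC concentration E with
probability θ_i = E/(E + K_d,i). E solves total-RISC conservation
E_T = E + Σ_i S_i θ_i, by bisection to relative tolerance 1e-9. Bound
samples are multinomial with read probabilities ∝ f_i θ_i. The joint
likelihood over the six-point concentration series (0.003, 0.01, 0.032,
0.1, 0.316, 1 nM nominal) is maximized in log-parameter space
(L-BFGS-B with an analytic gradient obtained by implicit
differentiation of the conservation equation) over all site K_d values
— the no-site background is one site type with its own K_d — and a
stock-concentration scale. The optimization is repeated from the 7×7
grid of initial guesses for stock concentration and no-site K_d (0.1,
0.2, 0.5, 1, 2, 5, 10 nM), and the median of the 49 estimates is
reported per site. Starts that fail, hit a box bound, or do not
converge are dropped from the median; an estimate with fewer than half
its starts converged is flagged.

Two practical notes. First, the absolute K_d scale is identified by
ligand depletion: the fit is well-conditioned when the planted site
concentrations fall inside the RISC titration range so that sites
saturate nonlinearly across the series. The synthetic generator's
defaults (five sites at input frequency 1e-3 on a 100 nM library, weak
micromolar no-site background) put it in that regime, which also mirrors
the real experiment's design. Second, sites of ≥15 nt are excluded from
fitting by default: such sites are long enough to be sliced, and the
binding reactions rely on short sites rather than a cleavage
correction.

`fit_filter_binding()` implements the closed-form quadratic solution for
double-filter binding assays, f = ((E_T+S_T+K_d) −
√((E_T+S_T+K_d)² − 4 E_T S_T))/(2 S_T), fit by bounded
Levenberg–Marquardt; flat titrations (range of f below 0.1) are flagged
unidentifiable. `energy_regression()` reports OLS r² and a two-tailed
permutation P for Pearson's r with the `(1 + extreme)/(1 + N)`
convention.

## Cleave-n-Seq: burst-and-steady-state kinetics

Counts are normalized in two steps: ppm within each sample, then
division by the summed ppm of normalizer variants (targets with ≤7 nt
complementarity, which are not cleaved and so track the total library
through the reaction). The relative cleaved product is
P_relative = (a₀ − a_t)/a₀; negative values from counting noise are
retained, because clipping them would bias slow rates upward.

The kinetic scheme is E+S ⇌ ES → EP → E+P with burst amplitude
E_relative and rate constants k2 (chemistry) and k3 (product release):

P_relative(t) = E_relative·[(k2/(k2+k3))²·(1 − e^−(k2+k3)t) +
(k2·k3/(k2+k3))·t]

with the amplitude applied once (the single-turnover burst form; a
squared amplitude would allow P > E). Bounds are 0.5 ≤ E_relative ≤ 1,
0 ≤ k2 ≤ 100 min⁻¹ and 0 ≤ k3 ≤ 1e-4 min⁻¹ — the k3 bound asserts the
single-turnover regime. Fitting is bounded Levenberg–Marquardt
(`minpack.lm::nlsLM`, ≤10,000 function evaluations) from a small start
grid (a half-rise heuristic plus decade steps in k2); the best
residual-sum-of-squares solution wins. Trials are pooled as independent
observations; parameter standard deviations come from the fit
covariance (not across-trial spread) and are labelled as such. The
reported pre-steady-state cleavage rate is k = k2 + k3.

Degenerate inputs are flagged rather than fit: all-zero signal (k = 0,
amplitude unidentifiable), fewer than four distinct nonzero timepoints,
a fast phase saturated even at the earliest sample
(1 − e^−k·t_min > 0.99), or k2 pinned at its upper bound.

Fold-change summaries divide the matched perfect-site rate by each
variant's rate within the same guide/protein run and report medians and
IQRs over the requested grouping. Cut-site mapping locates each
sequenced 3′-product 5′ end in its barcode-matched library variant and
reports offsets relative to t10 (0 = canonical scissile bond); spiked
synthetic 5′-monophosphorylated oligos ride through the same path with
t10_index = 0, so trimming and non-templated addition show up as
nonzero offsets on the controls.

## Degradome analysis: the fraction-cleaved statistic

Small-RNA reads are grouped by their 25-nt 5′ prefix (3′ trimming makes
piRNA 3′ ends heterogeneous). A prefix group is retained when it maps
uniquely and is ≥1 ppm in all 12 control replicates; it belongs to the
targeted set when its mean mutant abundance is ≤0.1 ppm. All thresholds
here and below are inclusive, and the boundary cases are tested
explicitly. Spike-in oligonucleotides give a linear reads→molecules
calibration; molecules per cell divided by (Avogadro × cell volume,
default 1 pL) gives intracellular concentration — 10 molecules in 1 pL
is 16.6 pM.

Candidate 3′ cleavage products are 5′-monophosphorylated species whose
5′ end coincides with t10 of a retained piRNA laid antiparallel on the
transcript. A species belongs to configuration gA–gB when positions
A..B are all paired and the guide nucleotides immediately outside the
paired region are unpaired, so classes do not overlap. Sites explained
by several piRNAs are counted once; their abundances are summed for
concentration binning (bins <30, 30–50, 50–100, 100–500, >500 pM,
lower-inclusive).

For each configuration, f_decreased is the fraction of non-redundant
candidate sites whose abundance falls ≥8-fold in the mutant, computed
under each of the 16 single-animal pairings of 4 control × 4 mutant
replicates (the only reading of "16 permutations of 4 and 4" that
yields 16). A site absent from the mutant replicate always counts as
decreased; otherwise the mutant abundance is floored at one
read-equivalent ppm before the ratio is taken, to avoid division by
zero. The statistic is

f_cleaved = f_decreased(targeted piRNAs) − f_decreased(control piRNAs),

the control set estimating how often short-lived 5′P species drop
≥8-fold by sampling alone. Reported per configuration: the median over
the 16 pairings and a 95% bootstrap confidence interval from 10,000
resamples of candidate sites (targeted and control sets resampled
independently — the uncertainty is over sites, not reads).

## The 35-feature logistic decision function

Features x1–x24 are pairing presence at g2–g25; x25 the total paired
count over that window; x26 the piRNA abundance; x27 the negative
predicted pairing energy (so stronger binding is a positive feature);
x28–x31 one-hot t1 identity; x32–x34 region indicators (5′ UTR, ORF,
3′ UTR); x35 an lncRNA indicator. Inclusion requires ≥19 paired
nucleotides between g2 and g25, abundance ≥0.1 ppm and no indels. The
three continuous features are min–max rescaled to [0,1]; to avoid
leakage the ensemble fitter learns the rescaling on each training
portion and applies it clipped to the held-out fold — the methods that
inspired this do not specify the split, so the no-leakage choice is
ours.

The objective is written out rather than delegated: with class-balanced
weights w_i = n/(2·n_class(y_i)) (averaging 1) and ridge weight λ = 1,

minimize Σ_i w_i·logloss_i + (λ/2)·‖β‖², intercept unpenalized,

by L-BFGS-B with at most 1,000 iterations. The penalty is set against
the *summed* loss, the convention of the standard penalized-logistic
implementations in which λ = 1 is the default; putting λ = 1 against
the mean loss instead would shrink every coefficient towards zero by a
factor of n and no ordering of feature importance would survive. A unit
test cross-checks the optimizer against an independent ridge solver at
the equivalent penalty.

The ensemble is 16 permutations × 5 repeats × 5-fold stratified
cross-validation = 400 models, each scored by the area under the
precision–recall curve on its held-out fold; an independent cohort can
be scored by all 400 models (×16 permutations when the new cohort
carries per-permutation labels). PR-AUC is trapezoidal integration of
the (recall, precision) curve from the anchor (0, 1), with ties in
predicted score broken by stable ordering. Fold seeds are derived
deterministically per (permutation, repeat).

## Transposon escape simulation

One lineage applies 1,000 accepted single-nucleotide substitutions: a
position is drawn uniformly, the replacement base from a 12-entry
mutation spectrum (default transition:transversion weight 2:1 — the
published germline rate tables are external inputs, so the ratio is a
configurable stand-in), and proposals causing a non-synonymous codon
change in *any* overlapping ORF are rejected and redrawn. After every
step the simulator counts guides still predicted to cleave: a 26-nt
piRNA tolerates ≤6 total mismatches; its simulated 21-nt siRNA (the
piRNA 5′ prefix) tolerates ≤5 total, ≤1 in g2–g8, and none at g9, g10,
g11 or g13. G:U counts as a mismatch for these rules (the rules say
"mismatch" with no wobble carve-out; a switch exists). Guides are
evaluated at fixed anchors — only substitutions are simulated, so
coordinates never shift — with mismatch bookkeeping updated
incrementally at the mutated position and verified in tests against a
fresh full count.

Decay is summarized as percent of guides lost per substitution, both as
the slope of the across-simulation mean trajectory and as the median
and IQR of per-simulation slopes (the two readings of "slope" the
summary could mean; both are reported). Counts are not guaranteed
monotone — back-mutations can restore competence.

`shared_kmer_fraction()` supports the related transcriptome question:
for each k, the fraction of transcripts sharing at least one exact
k-mer with a transposon consensus set (sense strand by default,
ambiguity codes excluded), monotone non-increasing in k.

## Synthetic data: what it emulates and what it does not

All generators are deterministic given their seed. `sim_rbns_counts()`
inverts the binding model at the level of site counts; read-level
generation with planted motifs (`sim_rbns_reads`) exists for testing
site assignment. `sim_cns()` decays targets as 1 − P_relative(t) with
multinomial sampling at the configured depth (default 1e5
reads/sample, the fast (0–8 min) and slow (0–960 min) sampling subsets,
3 trials each) and includes uncleavable normalizer variants.

`sim_degradome()` plants the marginal decreased fractions directly: a
targeted-set site is reduced `drop_fold`-fold (default 100, i.e.
essentially absent) in mutants with probability φ — φ is the *total*
decreased fraction, background included — and a control-set site with
probability b, so the expected f_cleaved is exactly φ − b and the
estimator's calibration can be tested honestly. The exchangeable
no-signal null is φ = b. Abundances carry Poisson counting noise at the
configured depth. piRNA abundances are log-normal with defaults
(meanlog log 30, sdlog 1.5, pM scale) placing a few percent of guides
above 500 pM, qualitatively matching the observed repertoire shape.

What the generators do *not* emulate: alignment ambiguity, adapter and
UMI chemistry, sequencing error, overdispersion beyond multinomial or
Poisson counting (a negative-binomial switch is a possible extension),
transcript secondary structure, and any selection in the escape
simulation. Passing tests therefore demonstrate that the estimators
recover the truth under the stated statistical structure — not that
real libraries satisfy that structure.

## Problem sizes and numerical choices

The recovery studies run at: 500 CNS variants (rates log-uniform in
[1e-3, 10] min⁻¹; rates are called identifiable when the earliest
1-min sample retains ≥5% substrate, i.e. k ≤ −ln(0.05)/1 ≈ 3 min⁻¹ — a
property of the sampling design fixed before any fitting); RBNS with
five sites at K_d 5–1000 pM and 1e6 reads/sample; degradome cohorts of
150 targeted + 300 control sites with 10,000-iteration bootstraps; the
full 400-model ensemble on cohorts of ~1,500 piRNA–site pairs; and 100
escape lineages of 1,000 substitutions on a 3-kb consensus with 200
guides. Free-RISC bisection runs to relative tolerance 1e-9; optimizer
iteration caps are 500 (K_d MLE), 1,000 (logistic), and 10,000
function evaluations (burst fits).

## Known limitations

The energy model is a stacking sum with fixed loop penalties, not a
full secondary-structure calculation; accessibility of the target site
inside a folded transcript is ignored (energies are pure duplex
energies). The K_d MLE assumes input frequencies are measured without
error, which is why input-limited long sites are excluded rather than
modelled. The degradome statistic treats candidate sites as
exchangeable units in the bootstrap; correlated sites on one transcript
are not modelled. The logistic ensemble's λ is fixed at 1 by design —
no tuning, matching the referenced setup — and the escape simulator
models neither indels nor selection.
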