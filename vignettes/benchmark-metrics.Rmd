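---
title: "Evaluation metrics for macromolecular modeling and design benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluation metrics for macromolecular modeling and design benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrobench)
```

## Scope

macrobench scores the output of macromolecular modeling and design engines
against experimental reference data with a fixed, testable set of metrics.
It deliberately contains no sampling or scoring machinery of its own: the
structures, model ensembles, designed sequences and energy decompositions it
consumes are produced elsewhere (Rosetta or any other engine), and the
package's job is to make the *evaluation* uniform across engines. Five
benchmark families are covered: stability ΔΔG prediction, alanine-scanning
ΔΔG of binding, sequence design against natural protein families,
recognition-specificity prediction, and loop reconstruction. A sixth module
generates seeded synthetic inputs with known ground truth so every metric can
be exercised, and its estimators validated, without any external dataset.

## Stability ΔΔG evaluation

A ΔΔG benchmark compares predicted stability changes (unit-agnostic "score
units") against experimental values in kcal/mol, with positive values
destabilizing. Three complementary metrics are computed, because each has a
blind spot on its own:

* **Pearson correlation** — scale-free linear agreement;
* **mean absolute error (MAE)** — scale-sensitive accuracy, the quantity a
  designer ranking individual mutations actually cares about;
* **fraction correct** — agreement of three-way stability classes
  (stabilizing / neutral / destabilizing). This metric can look flattering
  for random predictors, so it is reported alongside the other two, never
  alone.

The neutral class is the closed interval |ΔΔG| ≤ 1 kcal/mol for experimental
values. For predictions the package defaults to the analogous symmetric
±1 score-unit band; some published protocols instead used an asymmetric
neutral range of [−3, 1.1] score units, which is available through the
`pred_bounds` argument of `classify_stability()` and `fraction_correct()`.
Both boundaries are inclusive: "within ±1" is read as a closed interval.

Ensemble predictions are aggregated by `aggregate_ensemble_ddg()` as the
*mean* of the `n_best = 3` lowest mutant model scores minus the mean of the
three lowest wild-type scores. The mean (rather than the sum) keeps the
aggregate on the per-model score scale, so MAE values remain comparable with
single-model predictions; a difference of sums would be three times larger.

Alanine-scanning predictions are derived from six total-energy terms,

ΔΔG_bind = (ΔG_complex^MUT − ΔG_A^MUT − ΔG_B^MUT) −
           (ΔG_complex^WT − ΔG_A^WT − ΔG_B^WT),

and then scored with the same three metrics.

### Dataset curation

`curate_dataset()` applies the three standard filters for thermostability
data: (i) no X-ray structure at 2.5 Å resolution or better (non-X-ray
methods and missing resolutions are rejected under the same reason code);
(ii) replicate experimental measurements of one mutation — keyed by PDB id,
chain, residue id, wild-type and mutant amino acid — spanning more than
2.5 kcal/mol; (iii) transmembrane proteins. For filter (ii) the spread is
measured as the max−min range over all replicates, the strictest reading
when more than two measurements exist, and *all* records of an
over-dispersed mutation are removed rather than averaged: replicates that
disagree by more than the typical mutation effect size cannot be reconciled
without taking sides. A consequence worth knowing: the range is evaluated on
the full input, so the filter is idempotent (re-curating the kept set
removes nothing).

## Sequence design metrics

Native **sequence recovery** is percent identity between a designed and the
native sequence; a gap never counts as a match. Column-level comparisons use
the amino-acid distribution of each alignment column, with gaps and unknown
residues excluded and the column renormalized.

**Profile similarity** between a natural column distribution p and a
designed one q is

PS(p, q) = ½ (1 − D_JS[p‖q]) (1 + D_JS[r‖P₀]),  r = (p + q)/2,

with Jensen–Shannon divergences in bits. The first factor rewards agreement
between the two distributions, the second rewards their joint departure from
the background P₀, so an uninformative design that simply reproduces the
background scores exactly 0.5. P₀ defaults to the uniform distribution
(1/20): the analysis that introduced the score did not publish its
background, and the uniform choice makes the self-similarity floor exactly
0.5 without importing assumptions about any particular sequence database; a
user-supplied composition can be passed instead. Because both factors are
JS divergences, the score is finite for every input including backgrounds
with restricted support (where the maximal score 1 is attainable).

**Covariation** is computed in three stages on an alignment:

1. `mutual_information()`: MI_ij = H_i + H_j − H_ij in bits, plug-in
   estimates. For each pair, only sequences carrying a standard amino acid
   at *both* columns enter the counts, so the marginals and joint share one
   sample space and MI ≥ 0 holds exactly. Entropies are in bits so a
   perfectly coupled uniform binary pair gives exactly 1 bit.
2. `mip_correction()`: the average-product correction
   MIp_ij = MI_ij − MĪ_i MĪ_j / MĪ removes the background component shared
   by high-entropy columns (random noise, common ancestry). Means exclude
   the diagonal. When the grand mean is zero the correction is a no-op.
3. `zpx_scores()`: each MIp entry is standardized against the off-diagonal
   mean and standard deviation of each of its two columns; the z-scores are
   multiplied and passed through a signed square root,
   Zpx = sign(z_i z_j) √|z_i z_j|. The second factor standardizes against
   column j's σ — the symmetric form, which is the only reading under which
   Zpx is a symmetric pairwise score.

Highly covarying pairs are those with Zpx above mean + 2 SD of the
off-diagonal upper triangle, and the similarity of natural and designed
covariation is the percentage of the *natural* high-covariation set
recovered in the designed set. "Percent overlap" is not otherwise
standardized; the recovery denominator was chosen because the scientific
question is whether the design method reproduces couplings that evolution
produced, and a Jaccard variant is available for symmetric comparisons. No
sequence weighting or pseudocounts are applied by default (options exist for
real family alignments, which carry phylogenetic redundancy the synthetic
fixtures do not).

**Burial** classification counts, for each residue, the other residues
whose Cβ atom (Cα for glycine, the standard stand-in since glycine has no
Cβ) lies within 8 Å of its own. More than 14 neighbors is buried — the
threshold is strict, so a count of exactly 14 is intermediate — and 0–8
neighbors is exposed. Composition breakdowns default to the polarity
partition nonpolar = CGAVLIMFWP, polar = STYNQ, charged = HRKDE.

## Recognition specificity

`boltzmann_pwm()` converts scored designed sequences into a predicted
position weight matrix, weighting each sequence by exp(−E/kT) with the
minimum energy subtracted before exponentiation (an overflow guard that also
makes the weights exactly invariant to any common energy shift). The
default kT of 1.0 score units is an analysis temperature, distinct from any
sampling temperature used to generate the sequences; it is exposed as an
argument because the appropriate flattening depends on the score scale of
the engine that produced the energies.

Predicted and experimental PWMs are compared with four metrics: AAD (mean
absolute deviation), Frobenius distance, AUC and rank-top. AAD and
Frobenius are computed per designed position and macro-averaged for matrix
inputs (flattened variants are available by passing vectors). For AUC the
amino acids with experimental frequency ≥ 0.1 at a position form the
positive class and predicted frequencies are the ranking scores, pooled
across positions into a single ranking (micro-averaged); ties contribute
0.5, i.e. the Wilcoxon/Mann–Whitney form. The 0.1 label threshold and the
pooling are implementation choices — the original analysis did not define
its label construction — and both are arguments, so they can be matched to
other conventions. Rank-top is the competition rank (ties share the best
rank) of the experimentally most frequent amino acid within the predicted
column, reported per position together with the mean.

## Loop reconstruction

For each model, `loop_rmsd()` superposes the model onto the native structure
with the Kabsch algorithm using the backbone atoms of all *non-loop*
residues, then measures RMSD over the loop backbone heavy atoms without
further fitting. Two choices deserve note:

* The frame excludes side chains, because side chains within 10 Å of the
  loop are typically repacked during reconstruction and would contaminate
  the reference frame.
* "Backbone heavy atoms" defaults to {N, CA, C, O}, carbonyl oxygen
  included; whether the original analyses included O is not recorded, so the
  atom set is an argument (`c("N","CA","C")` reproduces the other
  convention).

Per-case summaries are the RMSD of the lowest-energy model, the best RMSD
among the 5 lowest-energy models (less sensitive to stochastic fluctuations
in the energy minimum; undefined with fewer than 5 models), and the percent
of models strictly below 1 Å ("sub-angstrom", strict `<` matching "below
1 Å"). Benchmark-level values are medians over cases, with the even-length
median defined as the mean of the two central values. Energy ties are
broken by model input order, which is documented rather than hidden because
it affects reproducibility of the lowest-energy pick.

The long-loop curation rule is implemented by `crystal_contact_filter()`: a
case passes when at most 5 loop residues have any heavy atom within 6 Å
(inclusive) of any symmetry-mate heavy atom. All-atom distances are used
rather than Cβ-only — the more conservative reading — and symmetry-mate
generation itself is out of scope: mates are supplied as coordinates,
because full space-group expansion is a crystallographic concern orthogonal
to the metric.

## Synthetic fixtures: what they emulate and what they do not

Every generator is seeded, restores the caller's RNG state, and records its
ground truth so the corresponding metric can be checked against it.

* `simulate_ddg_dataset()` draws experimental values from N(1.0, 2.0²)
  kcal/mol — centered on mildly destabilizing, the empirical shape of point
  mutant panels — and constructs predictions with an exactly specified
  population correlation, so MAE has the closed form σ√(2/π) with
  σ² = 4[(1−r)² + (1−r²)] (`expected_simulated_mae()`). Planted curation
  violations occupy the last four records when requested.
* `simulate_msa()` plants identical-symbol couplings: column j copies
  column i with the coupling probability. At coupling 1 the planted MI
  equals the column entropy exactly; at coupling 0 the pair is null.
* `simulate_scored_sequences()` samples sequences from a balanced uniform
  proposal (each amino acid near-equally often per column, random row
  order) and sets E = −kT Σ log p under the target PWM. Boltzmann
  reweighting by exp(−E/kT) is then an unbiased importance-sampling
  estimator of the target, which is what makes PWM recovery a meaningful
  end-to-end test; sampling from the target itself with these energies
  would instead converge to p²/Σp². The balanced proposal removes the
  multinomial letter-count component of the estimator variance. The
  remaining variance grows with the number of positions and the sharpness
  of the target, which is why the bundled checks use a 4-position,
  0.2-peak profile — the 4–6 designable-position regime the specificity
  protocol targets.
* `simulate_loop_ensemble()` perturbs only loop atoms with i.i.d. Gaussian
  offsets (the frame stays exact, so recorded ground-truth RMSDs and the
  superposition-based measurement agree to numerical precision) and links
  pseudo-energies to true RMSD at a chosen correlation.
* `simulate_protein_backbone()` and `simulate_structure()` produce
  schematic geometry — non-collinear frames, analytically known neighbor
  counts — not stereochemically valid proteins.

These fixtures validate the *estimators*, not the biology: they contain no
phylogenetic structure, no alignment errors, no gap patterns, no correlated
experimental noise, and no realistic energy landscapes. Passing the bundled
checks therefore demonstrates that the metrics compute what they claim on
inputs with known truth; it says nothing about how any particular design
method performs on real families, which is exactly the question the metrics
are meant to be applied to.

## Numerical conventions and degenerate inputs

* Entropies and divergences in bits; 0·log 0 = 0.
* Undefined metrics (zero variance for Pearson, zero spread for the
  high-covariation threshold, degenerate AUC labels, best-of-5 with fewer
  than 5 models, empty natural covariation set) return an explicit marker
  (`is_undefined_metric()`) and serialize as null-with-reason in reports,
  never as silent omissions or NaN propagation.
* Matrices of pairwise scores carry an `NA` diagonal; all means and
  standard deviations exclude it.
* The Kabsch rotation is determinant-corrected, so reflections are never
  returned even for degenerate clouds; fewer than 3 points or collapsed
  geometry is an error.
* Reports serialize floats with 6 significant digits and stable
  (alphabetical) key order, so identical configurations give byte-identical
  files.

## Problem sizes in the bundled checks

The test suite validates the covariation stack against brute-force oracles
on fifty 10×8 alignments, the planted-coupling power analysis on twenty
500-sequence alignments with four couplings at strength 0.9, PWM recovery
at 10⁵ sequences, Kabsch optimality against 10⁴ random rotations on twenty
10-point clouds, and the loop summary statistics on a 45-case ensemble
fixture — sizes chosen so each check is statistically meaningful while the
whole suite stays interactive.

## Known limitations

* Readers cover the formats the benchmarks actually use (FASTA, PDB ATOM
  records, CSV/JSON tables); mmCIF and multi-model NMR statistics are out
  of scope, as is writing PDB files.
* `classify_burial()` assumes one conformer per residue (alternate
  locations are resolved at read time by keeping altloc ' '/'A').
* The covariation estimators are plug-in estimators; at natural-alignment
  depths they carry the usual finite-sample bias, and the optional
  weighting/pseudocount arguments are the intended mitigation for real
  Pfam-scale data.
* The CLI's `simulate` subcommand writes only text formats (ddG tables,
  FASTA alignments, scored-sequence tables); structure and loop-ensemble
  fixtures are available through the R API, since PDB writing is
  deliberately not implemented.
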