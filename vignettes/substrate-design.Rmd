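---
title: "Designing protease substrates from panel-wide cleavage screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing protease substrates from panel-wide cleavage screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

High-throughput display screens can profile tens of thousands of short
peptides against a panel of proteases at once, reporting for every
substrate--protease pair a normalised cleavage Z-score: the relative strength
with which protease *m* cleaves substrate *s*. Matrix metalloproteinases
(MMPs), the motivating enzyme family, share strongly overlapping substrate
preferences, so the two practical design questions — *find substrates that a
target protease cleaves efficiently* and *find substrates that only the
target cleaves* — cannot be answered by scanning motifs alone. cleavekit
implements a complete in-silico design loop over such screens:

1. a **multi-task predictor** mapping a 10-mer sequence to the full vector of
   panel Z-scores, with ensemble uncertainty;
2. a **conditional autoregressive generator** that samples new peptides,
   optionally steered by a target cleavage profile;
3. a **score calculus** (selectivity, screen-calibrated corrected efficiency
   and corrected selectivity, cleavage thresholds, activity quadrants);
4. **nomination workflows** (uncertainty-aware ranking, k-mer diversity
   filtering, site-independent baselines);
5. **sequence analytics** (IceLogo matrices, position-wise KL divergence,
   k-mer censuses, biophysical indices, activity-profile clustering);
6. a **synthetic protease-panel simulator** that gives every component a
   ground truth to be tested against.

# The synthetic panel: what it emulates and what it does not

`build_panel()` defines the ground truth the rest of the package is validated
on. Each protease scores a peptide additively: a position-weight matrix
(L × 20) plus *subsite-cooperativity* bonuses — position-anchored 3-mers that
contribute beyond their single-residue terms, mirroring the observation that
contiguous residue combinations (the canonical P-X-X-hydrophobic motifs and
their relatives) drive cleavage beyond position-wise composition. Proteases
come in families that share a base weight matrix (with small idiosyncratic
deviations, s.d. 0.15 around family weights of s.d. 0.5) and share all their
family motifs, the way MMP subclasses (gelatinases, collagenases,
membrane-type) share substrate space. Exactly one designated protease (the
first panel member) carries one **private motif** with a strong bonus (3.0)
shared with no other protease, so "design a selective substrate" has a known
correct answer: enrich that motif.

`simulate_library()` draws peptides as a mixture of uniform-random
backgrounds and motif-implanted sequences (`motif_fraction`, default 0.3),
adds i.i.d. Gaussian observation noise (`noise_sd`, default 0.5 raw units)
and standardises each protease column to mean 0, s.d. 1, mirroring
per-screen normalisation. The per-protease calibration (mean/s.d. of the
noisy raw scores) is stored so that *new* peptides — generated designs —
can be placed on the same Z scale via `true_zscores()`, noise-free; this is
the ground truth used by all steering and nomination checks.

What the simulator deliberately does **not** model: sequencing-count noise
and selection dynamics of display screens, enzyme kinetics, position-register
ambiguity, or non-additive epistasis beyond the implanted k-mers. Passing
tests therefore certify that the pipeline recovers additive-plus-motif
structure under Gaussian noise, not that it reproduces any particular wet
screen.

# The predictor

The default backbone is a 2-layer encoder-only transformer, model dimension
32, 6 attention heads, sinusoidal positional encodings, a CLS token whose
final-layer representation feeds a linear head with one output per protease,
trained with mean squared error (averaged over proteases) under Adam and the
classic inverse-square-root warmup schedule
`d^-0.5 * min(step^-0.5, step * warmup^-1.5)`. A bidirectional 2-layer LSTM
(hidden size 32, dropout 0.25 after each layer, constant learning rate 5e-3)
is provided as the alternative backbone. Both consume sequences tokenised
over the alphabetical 20-residue vocabulary with PAD at index 0.

Design points that were genuinely open:

* **Attention head width.** 32 dimensions do not divide into 6 heads; we run
  6 heads of width 5 (internal width 30) with a learned output projection
  back to 32. The same device gives the generator 6 heads of width 10 over
  64 dimensions.
* **Feed-forward width** is 4 × model dimension, the transformer default.
* **Loss** is mean squared error averaged over the panel outputs.
* **Ensembling.** `train_predictor_ensemble()` trains K = 5 members over
  independent 80/20 train/validation resplits (member seeds derived from the
  master seed), keeps each member's lowest-validation-loss epoch checkpoint,
  and reports the across-member mean as the prediction and the across-member
  standard deviation as the uncertainty σ (exactly 0 when K = 1).
* **Regularisation.** At the library sizes used here (thousands rather than
  tens of thousands of peptides) the unregularised transformer memorises its
  training split long before it has extracted the cooperativity structure,
  which caps held-out accuracy well above the observation-noise floor. The
  `dropout` configuration therefore applies to both backbones (inverted
  dropout on the two transformer sublayer outputs; default 0.25, the same
  rate the biLSTM uses, selected by internal validation loss), and the Adam
  trainer supports decoupled weight decay (default 1e-3). Both are trainer
  properties, not per-experiment knobs.
* **Warmup length.** The 4000-step default warmup matches screen-scale
  training runs (hundreds of steps per epoch). Desk-scale runs in the tests
  and acceptance script use a warmup of roughly 10% of their total step
  count (e.g. 400), the usual proportional rule; leaving 4000 steps of
  warmup on a 3000-step run would never exit the warmup ramp.

The networks are implemented directly in RcppArmadillo (forward and backward
passes, ~200 lines per backbone); they are small enough (tens of thousands
of parameters) that a deep-learning framework would add nothing but
deployment weight. The analytic gradients of all three backbones
(encoder, decoder, biLSTM) are checked against central finite differences in
the test suite.

# The generator

`train_generator()` fits a decoder-only transformer (3 layers, dimension 64,
6 heads, batch 128) with next-token cross-entropy over sequences wrapped in
START/STOP. Conditioning follows the tag-in-place-of-START reading: the
vector of panel Z-scores, rounded to the nearest tenth, passes through a
learned linear map into the model dimension and occupies the first sequence
position; each training sample is conditioned with probability
`conditional_fraction = 0.5`, drawn per sample and per epoch, so a single
model supports both unconditional and conditional sampling. Tags used in
training are the peptides' own (true) library scores; tags used to *seed
designs* are predicted profiles of top-ranked library peptides
(`conditional_seed_profiles()`), ranked by predicted target score
(efficiency) or predicted selectivity.

Sampling (`sample_peptides()`) is ancestral with temperature (1 for
unconditional runs, 1.2 for conditional design runs) and a repeat penalty of
1.2 applied only to the immediately previous residue, sign-aware (positive
logits divided, negative multiplied). Generation stops at STOP or at
`max_generated_length` (20), where STOP is forced and flagged.
`filter_generations()` then removes off-register lengths and exact train-set
matches, reporting both counts. A 10% held-out split of the training library
(never the evaluation set, to avoid leakage) selects the checkpoint.

# The score calculus

* **Selectivity** `S = Z_target − mean(Z_others)`; translation-covariant in
  the target entry.
* **Screen efficiencies** reduce kinetics to replicate-averaged endpoint
  fold changes (or linear rates), call cleavage against no-enzyme controls
  (mean + 3 s.d.) or a fold-change floor of 1.2 when no controls exist, and
  map to [0, 1] with 1 for the most active substrate, 0 for non-cleaved, and
  `FC_x / (FC_max − FC_minbar)` between, where `FC_minbar` is the mean
  readout of non-cleaved substrates (configurable to 0 for the plain
  `FC/FC_max` reading). The call rule and `FC_minbar` reading are
  configuration points, not claims.
* **Cleavage thresholds.** "The score cut under which ROC classification is
  maximised" is not well-posed as stated (AUC is threshold-free); we
  interpret it as the ROC operating point maximising Youden's J, with ties
  broken at the midpoint of the optimal score interval. Proteases that
  cannot be fitted (no commercial enzyme, single-class labels) receive the
  mean of the fitted thresholds, flagged `imputed` — reproducing the
  mean-imputation construction exactly.
* **Corrected efficiency** `(Ẑ − T) / max(Ẑ − T)` for `Ẑ > T`, else 0 —
  strict inequality at the boundary; columnwise max is exactly 1 whenever
  any substrate clears the threshold. **Corrected selectivity** applies the
  selectivity form to corrected efficiencies and is bounded in [−1, 1].
* **Quadrants** split substrates at efficiency > 0.4 and selectivity > 2.4
  (strict).

# Nomination

Efficiency designs are ranked by the uncertainty-aware score `Ẑ − σ`;
selectivity designs by predicted selectivity without uncertainty filtering.
The k-mer diversity filter is a greedy pass in descending score order (ties
broken lexicographically for determinism): a peptide is kept only if none of
its overlapping 5-mers has been claimed, and claims all of them when kept —
so the output has globally unique 5-mers and the filter is idempotent. The
site-independent baseline samples each position independently from the
source set's empirical position-wise residue frequencies.

# Problem sizes used in tests and the acceptance script

Everything statistical runs on the simulator at desk scale, chosen once:

* predictor recovery: panel M = 4 (2 families), n = 4000 training
  peptides, noise s.d. 0.5, K = 5 ensemble, 130 epochs, warmup 400,
  evaluated on a separately simulated 2000-peptide batch standardised on
  the training screen's calibration. Accuracy is summarised per protease
  (Pearson r) and as the panel-mean MAE relative to the panel-mean
  observation-noise floor; the uncertainty's rank correlation with the
  absolute error is measured against the noise-free ground truth, because
  correlating a small uncertainty signal against noisy observations
  attenuates it towards zero;
* steering: the generator trains on the same library (40 epochs, warmup
  300); 1000 conditional generations seeded by the top-50 predicted
  selectivity profiles at temperature 1.2 versus 1000 unconditional at
  temperature 1; selectivity evaluated on simulator ground truth for the
  private-motif protease;
* nomination-versus-baseline: 20 repetitions, each nominating 24 substrates
  from a fresh 400-sample unconditional (efficiency route) or conditional
  (selectivity route) pool against an equal-size site-independent baseline;
* analytics and score-calculus oracles: closed-form cases and random inputs
  at n of tens to thousands, compared to brute-force recomputation at 1e-12.

These sizes are the package's validation conditions; larger runs only
sharpen the same comparisons.

# Known limitations

* The simulator's additive ground truth makes recovery easier than real
  screens with epistasis, register shifts and heavy-tailed noise; treat
  passing bounds as necessary, not sufficient, evidence for real data.
* Parameter counts of the printed reference architectures depend on
  unstated feed-forward and projection details; ours are logged (via
  `glance()`), not asserted.
* The uncertainty σ is an ensemble-spread heuristic; it is only coarsely
  related to absolute error (rank correlation ~0.05 against ground-truth
  error on the simulator) and is not a calibrated predictive interval.
* Conditional tags cover the full panel; partial-panel conditioning and
  multi-protease AND/OR objectives are out of scope.
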