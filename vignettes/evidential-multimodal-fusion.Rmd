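---
title: "Evidential multimodal fusion: model, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidential multimodal fusion: model, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`evidfuse` predicts a binary clinical outcome from two heterogeneous
modalities — a structured patient table and free-text notes — by reasoning in
the space of Dempster–Shafer mass functions rather than probabilities. The
chain is:

1. **Per-modality encoding.** A tabular encoder (MLP or ResNet, 3 layers or
   blocks of 32 hidden units, dropout 0.1, 32-dimensional output) embeds the
   preprocessed structured row; a frozen text-embedding provider followed by
   one trainable 128-unit projection embeds the patient's concatenated notes.
   An `external` encoder slot accepts any drop-in feature extractor
   (e.g. an FT-Transformer-class model) satisfying the same contract.
2. **Evidence mapping.** An evidential layer with H = 20 learned prototypes
   treats each prototype as a piece of evidence discounted by squared
   Euclidean distance: `s_h = beta_h * exp(-gamma_h * d_h^2)`, mass
   `u_h^(c) * s_h` on each singleton class and `1 - s_h` on the whole frame.
   The H masses are pooled with Dempster's rule into one modality mass.
3. **Evidence fusion.** The K modality masses are pooled with Dempster's rule
   again; the pignistic transform `p(c) = m({c}) + m(Omega)/M` produces the
   decision probability, and the fused `m(Omega)` is reported as per-patient
   uncertainty.
4. **Augmented objective.** Training minimises the class-weighted
   cross-entropy of the pignistic output plus two auxiliary class-weighted
   softmax cross-entropies computed from single affine heads on the encoder
   features, `L = L_main + alpha * L_aux_structured + beta * L_aux_notes`
   with defaults alpha = 2, beta = 1. The auxiliary heads only shape the
   encoder representations; they play no role at inference.

The underlying assumptions are those of Dempster's rule: the modalities are
treated as independent items of evidence on a shared, exhaustive frame. The
restricted mass family (singletons plus ignorance) is closed under
combination, which is what makes the layer tractable.

# Key parameters

| Parameter | Default | Units / range | Why |
|---|---|---|---|
| `n_prototypes` (H) | 20 | count | enough prototypes to tile a 32–128-dim feature space without starving each of gradient signal |
| encoder width / depth | 32 units, 3 layers | — | standard tabular deep-learning baseline size |
| text projection | 128 units | — | single trainable layer on top of a frozen provider |
| `alpha`, `beta` | 2, 1 | ≥ 0 | weights of the structured / notes auxiliary losses |
| `batch_size` | 32 | samples | mini-batch SGD granularity |
| `max_epochs`, `patience` | 150, 10 | epochs | early stopping on validation overall loss |
| `lr` | 1e-3 | — | Adam step size |
| `weight_decay` | 1 | decoupled λ; per-step factor `1 − lr·λ` | see below |
| decision threshold | 0.5 | probability | symmetric treatment of the two classes; config-exposed |
| class weights | `N/(M·N_c)` | — | balanced inverse frequency for the rare positive outcome |

# Choices the design left open

Several pieces are not pinned down by the framework itself; the package fixes
them as follows.

**Parameterisation of the evidential layer.** The constraints
`gamma_h > 0`, `beta_h in [0,1]`, `u_h` on the simplex are enforced through
smooth bijections (softplus, logistic, row softmax) so optimisation is
unconstrained, and *all* layer parameters — prototypes included — are learned
jointly with the encoders.

**Prototype initialisation.** Prototypes start at k-means centroids of the
encoded training features (`random_sample` draws feature rows instead);
memberships start near-uniform with small seeded noise and beta at 0.5. The
scale gamma starts at the inverse *mean squared distance from the training
features to their nearest prototype*. An alternative that seems natural —
scaling by the mean pairwise distance *between* prototypes — fails in
high-dimensional feature spaces: within-cluster spread dwarfs the
between-centroid spread there, activations start around `exp(-20)` and the
layer receives no gradient (we observed exactly this collapse for the
128-dimensional text branch, whose evidential output froze at total ignorance
while its auxiliary head was clearly discriminative). Anchoring the scale to
feature-to-prototype distances keeps initial activations responsive in any
dimension.

**Orthogonal-sum evaluation.** Dempster combination of restricted masses is
associative and its normalisation commutes with combination, so the H-fold
(and K-fold) orthogonal sum can be computed either as a pairwise
left fold or in closed product form,
`mu({c}) ∝ prod_h (m_h({c}) + m_h(Omega)) − prod_h m_h(Omega)`,
`mu(Omega) ∝ prod_h m_h(Omega)`, normalised once. The eager reference path
(`combine_masses`, `enn_forward`) uses the fold; the training graph uses the
product form in log space, which costs an order of magnitude fewer graph
nodes. The two are tested to agree within 1e-10, and both are cross-checked
against an exact power-set implementation of Dempster's rule.

**Optimizer and regularisation.** Adam (lr 1e-3) with decoupled weight decay,
per-step factor `1 - lr * lambda`, `lambda = 1`. The decay is not cosmetic:
evidence fusion multiplies per-modality masses, so a modality whose evidential
branch memorises noise injects confident random masses into every fused
prediction. Decay pulls raw memberships toward uniform and evidence strengths
toward their neutral range unless the data support them, which is what lets
the fused model shed an uninformative modality. We selected lambda jointly on
the informative-signal, single-modality and noise-modality conditions of the
synthetic benchmark (0.3/1/3 compared; 1 best or tied on all three) before
freezing it as the default.

**Early stopping.** Monitors the *overall* validation loss (main plus
auxiliary terms, symmetric with training), patience 10 epochs, with a minimum
improvement of 1e-4 so plateau drift does not stretch runs indefinitely. The
best-validation checkpoint is returned.

**Numerical guards.** Logs are clamped at 1e-12 in every cross-entropy;
`log(1-s)` terms are clamped at 1e-30; the Dempster denominator `1 - kappa`
is clamped at 1e-12 inside the differentiable graph (eager use raises a
total-conflict error instead, naming kappa). Masses with `beta_h < 1` can
never reach total conflict, so the clamp is a safety net, not a modelling
device.

**Other fixed readings.** "Normalisation" of numeric features is z-scoring;
missingness is injected completely at random in the generator (the minimal
mechanism, keeping the imputation comparison interpretable); notes are
concatenated in the fixed order Nursing, Nursing/Other, Physician, Radiology;
all note types share one embedding provider but get separate evidential
layers under the `data_sources` partition; the auxiliary heads are single
affine maps; prediction is positive at pignistic probability ≥ 0.5.

# The synthetic cohort generator

Real credentialed ICU datasets cannot ship with the package, so the generator
produces cohorts with their statistical *shape*: ~12% positive prevalence;
20 numeric features (6 informative, class-conditional Gaussian shifts of
1.2 SD) and 10 binary features (4 informative, rate shift 0.25) tagged by
source (demographics, vitals/labs, treatments, comorbidities); 10% MCAR
missingness; four note types built from a background vocabulary plus
class-informative tokens appearing at rate 0.25 per note for
signal-expressing positives versus 0.02 for everyone else.

Signal placement is the interesting part. Half of the positives express
signal in both modalities (`modality_correlation = 0.5`); the remainder split
evenly between structured-only and notes-only expression, making the
modalities genuinely complementary: either modality alone can rank at most
~75% of positives above the negatives, while the fused model can see them
all. A further 15% of positives express only attenuated (0.4×) signal so the
cohort contains borderline patients — without them, near-separable classes
would let weighted and unweighted training both saturate recall and the
effect of class weighting on the decision boundary would be invisible. A
"separable" configuration (effects 2.5 SD / 0.4 / token rate 0.5, no weak
positives) is used as a positive control in which every positive is strongly
expressed in at least one modality.

What the generator does *not* emulate: real clinical language (tokens are
synthetic), informative missingness, temporal structure, inter-feature
correlation beyond the shared latent label, or the semantics of specific
labs. Passing tests therefore demonstrate that the machinery recovers signal
with the right qualitative behaviour under controlled conditions — not that
any particular clinical performance level would be reached on real EHR data.

# Problem sizes and test design

The test suite validates the algebra exhaustively (1,000 random mass pairs
per frame size M ∈ {2,3,4} against the power-set oracle; commutativity,
associativity, neutrality, normalisation and pignistic bounds on random
draws) and checks every gradient against central finite differences. The
end-to-end benchmark uses 5,000-patient cohorts with a 60/20/20 stratified
split — large enough for stable AUROC estimates on a 12%-prevalence test set
(~120 positive test patients) while keeping the full suite in the minutes
range on one CPU. Cross-validation and the fusion-strategy comparison are
exercised at smaller scale (hundreds of patients, 2 folds) since they test
protocol plumbing, not statistical power.

One property stated naively turns out to be false and is tested in corrected
form: fusing two masses that merely both *favor* a class can lower that
class's pignistic probability below the more confident input's (a nearly
vacuous mass dilutes a confident mixed one). The guarantee that does hold,
and is asserted, is for one-sided simple-support masses: fusing
`({c}: a, Omega: 1-a)` with `({c}: b, Omega: 1-b)` gives
`p(c) = 1 - (1-a)(1-b)/2 >= max(p1(c), p2(c))`.

# Known limitations

- Binary outcomes only; the restricted mass family would extend to M > 2,
  but the losses, metrics and generator assume two classes.
- No missing-modality handling at inference: absent inputs fail fast.
- The hashing text provider is a deterministic bag-of-tokens stub; it makes
  the pipeline self-contained and reproducible but ignores word order and
  context. Pre-trained language models plug in through the provider contract
  when available locally.
- Training runs on a purpose-built reverse-mode tape over dense base-R
  matrices; it is exact (finite-difference-verified) and adequate for the
  model sizes here, but it is not a general deep-learning runtime.
- Dempster's rule with per-sample normalisation is the only combination rule
  implemented; unnormalised conjunctive pooling, discounting and other rules
  are out of scope.
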