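---
title: "Multi-view TSK fuzzy classification: model, training and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view TSK fuzzy classification: model, training and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzyview)
```

## The model

`fuzzyview` fits a Takagi–Sugeno–Kang (TSK) fuzzy classifier to samples that
are observed through several feature *views* (modalities) at once — for
example wavelet-feature and spectral-feature representations of the same EEG
recording, or histopathological and clinical descriptors of the same
dermatology patient. A TSK system partitions the input space with fuzzy
IF-parts and combines linear THEN-parts, so every decision can be read back
as a weighted set of human-readable rules.

Three mechanisms extend the classic system.

**Deformable Gaussian memberships.** For view $v$, rule $r$ and feature $d$,
the membership degree is

$$\mu_{d,r}(x_d) = \exp\!\left(-\frac{\bigl(x_d - (c_{d,r} + \Delta c_{d,r})\bigr)^2}{2\sigma_{d,r}^2}\right),$$

where the center $c_{d,r}$, the *offset* $\Delta c_{d,r}$ and the width
$\sigma_{d,r}$ are all trainable. The offset lets a rule's region drift
during training without abandoning the Gaussian form, which keeps the rule
interpretable while adapting to heterogeneous view distributions. With all
offsets frozen at zero the system is exactly the standard-membership TSK
model — that reduction is tested bit-for-bit.

A rule's firing strength is the product of its per-feature memberships. In
high dimension that product underflows, so the package only ever computes
the *log-firing*

$$\ln a_r(x) = \sum_{d=1}^{D} -\frac{\bigl(x_d - (c_{d,r}+\Delta c_{d,r})\bigr)^2}{2\sigma_{d,r}^2} \le 0,$$

and raw products are never materialized.

**Rule-level attention.** A multi-head self-attention block treats the
sample's feature vector as a sequence of length one, projects it per head
($Q$, $K$, $V$), applies scaled dot-product attention, concatenates the
heads and projects back to $\mathbb{R}^D$. A linear head then scores every
rule and a softmax turns the scores into per-sample rule weights
$\alpha \in \Delta^{R-1}$. Because the sequence has one token, the attention
softmax is degenerate and the whole block is analytically a linear map
$x \mapsto \mathrm{Concat}_i(xW_i^V)\,W^O$; the package keeps the full
attention structure anyway (and verifies the closed form in tests), so the
code generalizes directly if rules are later treated as tokens.

**Learnable view fusion.** Each view's activation vector is
$f^{(v)} = \mathrm{softmax}(\alpha^{(v)} \odot \ln a^{(v)})$, and the views
are fused by a convex combination $f = \sum_v \beta^{(v)} f^{(v)}$ whose
weights $\beta$ are the softmax of trainable logits. The fused activation
weights first-order linear consequents over the concatenation of all view
features; the resulting class scores are trained as logits under
cross-entropy.

## Interpretation choices that were genuinely open

* *What the attention weights modulate.* The element-wise product
  $\alpha \odot s$ needs a definition of the "raw rule activation" $s$. We
  take $s$ to be the log-firing vector, because
  $\mathrm{softmax}(\ln a) = a_r / \sum_j a_j$: with attention disabled
  (the all-ones path used by the `no_attention` and `basic` variants) the
  activation collapses *exactly* to the classic normalized firing of a
  standard TSK system, giving a clean, testable reduction. The linear-domain
  alternative $\mathrm{softmax}(\alpha \odot a)$ is available via
  `fusion_domain = "linear"`.
* *Scope of the consequents.* Consequents consume the concatenation of all
  scaled view features (one consequent bank after fusion) rather than
  per-view banks; the fused activation is the only place rule responsibility
  is decided, which matches a single post-fusion inference stage and keeps
  rule extraction global.
* *Trainability.* Centers, offsets and widths are all trained (the
  parameterization is redundant — $c$ and $\Delta c$ only enter as a sum —
  but keeping both preserves the "initial partition + learned deformation"
  reading, and the `no_deform`/`basic` variants freeze exactly the offsets).
  The multi-class consequent is the natural vectorization of the scalar
  first-order rule over $C$ class columns.
* *Softmax over rules, not views,* in the per-view activation: it is the
  only reading under which $f^{(v)}$ is a simplex vector in $\mathbb{R}^R$
  and fusion is a convex combination of rule distributions.

## Training protocol

`mvtsk_control()` defaults encode the protocol the model is built around:
AdamW (decoupled weight decay) with learning rate $5\times10^{-4}$ and
weight decay $10^{-8}$, batch size 8, at most 256 epochs, early stopping
with patience 50, 51 rules, 80/20 stratified splits, and 20 seeded runs in
`run_protocol()` (run $k$ uses seed $\mathrm{base}+k-1$ for both split and
initialization). Accuracy across runs is summarized as mean ± sample
standard deviation ($n-1$ denominator) and can be compared against a fixed
benchmark accuracy with a two-sided one-sample t-test
(`protocol_ttest()`); when a published baseline reports only a mean, that
mean is the natural fixed benchmark.

Choices the protocol leaves open, and what this package does:

* **Early-stopping monitor.** No validation split is part of the protocol,
  and the test set must never be touched, so by default the training loss
  is monitored; `validation_fraction > 0` holds out a stratified slice of
  the training data instead. Best-loss parameters are restored on stop.
* **Initialization.** Rule centers are drawn from training rows
  (`init = "sample"`) or k-means centroids (`init = "kmeans"`); offsets
  start at exactly 0, so the untrained model *is* the standard-membership
  model; widths start at 1, the scale they typically remain near on
  standardized features. Attention projections use small-variance Gaussian
  init, but the rule-score head starts at zero, so initial attention is
  exactly uniform and early training is close to the no-attention ablation.
  Consequents start at zero: the untrained model emits uniform class
  scores, a testable start state.
* **Batch order** is reshuffled each epoch from the run seed, so a full fit
  is a deterministic function of (data, configuration, seed).

## Preprocessing

Exact zeros are shifted to $10^{-8}$ first (structural zeros are common in
these feature matrices and destabilize min-max ranges); each view is then
scaled — min-max to $[0,1]$ by default, or standardization using the
population ($1/N$) standard deviation — with statistics fitted **only** on
training rows. `predict()` re-applies the stored training statistics, so
test rows may legitimately fall outside $[0,1]$ and no test-set statistic
can leak into the scaler state (this is asserted by a dedicated leakage
test). Constant columns map to zero with a warning.

## Numerical choices

* All antecedent math is in log space; `exp` is applied only inside
  softmaxes that follow a max-subtraction.
* Softmax exponentials are floored at $10^{-300}$, so rule and view weights
  remain strictly positive even for score gaps beyond `exp`'s underflow
  point; entropy diagnostics therefore never meet an exact zero.
* Widths are kept positive by clamping at $10^{-4}$ after each optimizer
  step — simpler than a reparameterization and inert in practice, since
  trained widths stay near 1.
* If a view's dimension is not divisible by the requested head count, the
  head count is reduced to the largest divisor (with a message), so head
  width is always integral.
* Tiny positive round-off in the log-firing at a rule's exact center is
  clipped to 0, preserving the "log-firing $\le 0$" invariant.

## Diagnostics

Rule usage is summarized from the *sample-averaged* attention weights of a
view (averaging weights first, then computing statistics — the same
pipeline used for per-view weight-distribution figures; averaging
per-sample entropies instead is the flagged alternative). From the average
weight vector $\bar w$: Shannon entropy $H$ in nats, normalized entropy
$H/\ln R$, **effective rules** $e^H$ (the perplexity of $\bar w$ — the
published tables' effective-rule counts are reproduced by this definition
to their printed precision, which is how the formula was pinned down),
proportion of active rules $e^H/R$, and the top-$k$ contribution (sum of
the $k$ largest average weights, $k=5$ by default). Antecedent parameter
stability uses the population mean and $1/N$ standard deviation per family
(centers, widths, offsets), plus quartiles for box-plot export.

## The synthetic generator

`generate_multiview()` emulates exactly the structure the classifier
assumes: a latent class signal observed through heterogeneous views.
Labels are round-robin (balanced to within one sample, so stratified
splitting is always valid); latent vectors are spherical Gaussians whose
class centers sit at mutual distance `separation` (in latent standard
deviations, via scaled basis vectors); each view is an independent random
linear map of the latent vector plus Gaussian noise (`noise_sd`); optional
*redundant views* are corrupted copies of an existing view, modeling
cross-view redundancy; an optional `tanh` squashing gives a nonlinear
variant. Defaults (400 samples, 2 views of 8 and 6 features, 3 classes,
separation 4, noise 0.1) are a moderately separable problem a fuzzy
classifier should solve nearly perfectly.

What it does **not** emulate: the heavy-tailed, highly collinear,
block-structured feature distributions of real image/EEG feature
extractors, class imbalance, label noise, or view-specific missingness.
Passing the synthetic-recovery tests therefore demonstrates that the
implementation optimizes what it claims to optimize — not that the model
will reach any particular accuracy on real benchmark data.

## Problem sizes used by the shipped tests

The test suite runs the full protocol at reduced scale — 10 rules instead
of 51, a few hundred samples, 2–3 seeds instead of 20 — chosen so each
end-to-end check isolates one claim (recovery of separated structure,
chance-level behavior without signal, ablation comparisons) at sizes where
the expected behavior is unambiguous. The ablation comparison is *soft*:
means per variant are reported, and only their validity is asserted,
because at synthetic scale the variant ordering is a stochastic tendency,
not a theorem.

## Known limitations

* Training is plain R; it is comfortable at test scale (hundreds of
  samples, tens of rules) but not tuned for the 51-rule, 254-dimension
  regime of the largest public benchmarks.
* MAT containers are not read directly; convert to the delimited layout
  (`view_1.csv … labels.csv`) documented in `read_multiview()`.
* View weights $\beta$ are one vector per model (sample-independent);
  per-sample view attention is out of scope.
* Rules are neither pruned nor merged; all $R$ rules are kept, and the
  diagnostics quantify how uniformly they are used.
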