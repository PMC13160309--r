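# fuzzyview

Multi-view Takagi–Sugeno–Kang (TSK) fuzzy classification with deformable
Gaussian membership functions, rule-level self-attention, and learnable
view fusion — for tabular data observed through several feature views of
the same samples (multi-modal biomedical features, multi-descriptor image
features, wavelet-band EEG features, …), aimed at users who want
competitive classification **and** a rule base they can read.

## The model

Each view $v$ has its own antecedent network of $R$ fuzzy rules. Rule $r$
judges feature $d$ with a *deformable* Gaussian membership

$$\mu_{d,r}(x_d) = \exp\!\left(-\frac{\bigl(x_d - (c_{d,r} + \Delta c_{d,r})\bigr)^2}{2\sigma_{d,r}^2}\right),$$

whose center $c$, trainable offset $\Delta c$ and width $\sigma$ all adapt
during training. Firing strengths are computed in log space
($\ln a_r = \sum_d -\tfrac{(x_d - (c+\Delta c))^2}{2\sigma^2}$) to avoid
underflow in high dimension. A rule-level multi-head self-attention block
maps the sample to weights $\alpha \in \Delta^{R-1}$ over the rules, the
view's activation is $f^{(v)} = \mathrm{softmax}(\alpha \odot \ln a)$, and
views are fused convexly, $f = \sum_v \beta^{(v)} f^{(v)}$, with trainable
softmax-normalized view weights $\beta$. First-order linear consequents
over the concatenated features, weighted by $f$, give class scores trained
with cross-entropy via AdamW with early stopping. With attention disabled
and offsets frozen the system reduces exactly to the classic TSK form
$y(x) = \sum_k \frac{a_k(x)}{\sum_j a_j(x)}\, y_k(x)$ — a reduction the
test suite verifies against independent oracles.

Everything is exposed in the classic R modelling idiom: `mvtsk()` fits and
returns an object with `print`, `summary`, `coef`, `predict` and `plot`
methods; `run_protocol()` repeats stratified splits over seeded runs and
reports mean ± sd with a one-sample t-test against a fixed benchmark;
`extract_rule()` renders any rule as IF–THEN text; `rule_usage()` and
friends quantify how uniformly the rule base is used (attention entropy,
effective rules $e^H$, top-k contribution); `generate_multiview()` creates
controllable synthetic multi-view data; `read_multiview()` /
`write_multiview()` handle a delimited on-disk layout; `write_mvtsk()` /
`read_mvtsk()` round-trip fitted models through JSON checkpoints. A thin
command-line front end lives at `inst/scripts/fuzzyview.R`
(`simulate | train | evaluate | ablate | diagnose`).

## Worked example

```r
library(fuzzyview)
d <- worked_example()                       # 12 samples, 2 views, 2 classes
fit <- mvtsk(d$views, d$labels, n_rules = 4, seed = 1)
print(fit)
#> Multi-view TSK fuzzy classifier
#>   variant: full | rules: 4 | views: 2 (dims 2, 3) | classes: 2
#>   trained 256 epochs (best epoch 256, monitored loss 0.309594)
#>   view weights beta: 0.2596 0.7404

table(predicted = predict(fit, d$views), truth = d$labels)
#>          truth
#> predicted 0 1
#>         0 6 0
#>         1 0 6
```

The fitted view weights say the second (3-feature) view carries most of
the decision (β ≈ 0.74 vs 0.26). Rule-usage diagnostics for view 1:

```r
rule_usage(mean_attention_over_samples(fit, d$views, view = 1), k = 2)
#> Rule usage over 4 rules: H = 1.2297 nats (normalized 0.8870)
#>   effective rules 3.42 (85.50% active); top-2 contribution 72.96%
```

Entropy H is near its maximum ln 4 ≈ 1.386, so all four rules participate
(3.42 "effective" rules), while the two most-used rules still carry ~73% of
the average attention. Any rule can be read back as text:

```r
cat(extract_rule(fit, view = 1, r = 1))
#> IF x1 is A_1,1 (centered at -0.266533, width 0.589848) AND x2 is A_2,1 (centered at -0.356039, width 0.638787)
#> THEN y_1[class 1] = -0.017403*x1 + 0.0113583*x2 + 0.226579; y_1[class 2] = 0.017403*x1 + ...
```

Ablation variants (`variant = "no_attention"`, `"no_deform"`, `"basic"`)
disable the attention branch, freeze the offsets, or both, letting you
measure each mechanism's contribution with `run_protocol()` on your data.

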