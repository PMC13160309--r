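Package: fuzzyview
Title: Multi-View TSK Fuzzy Classification with Deformable Memberships and Rule-Level Attention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits multi-view Takagi-Sugeno-Kang (TSK) fuzzy classifiers whose
    Gaussian membership functions carry trainable center offsets (deformable
    memberships), whose rule activations are re-weighted per sample by a
    rule-level multi-head self-attention block, and whose views are fused with
    learnable softmax-normalized weights. Includes gradient training with the
    AdamW optimizer, early stopping, stratified multi-run evaluation with
    one-sample t-tests, ablation variants, rule-usage diagnostics (attention
    entropy, effective-rule counts, top-k contributions), explicit rule
    extraction, a synthetic multi-view data generator, and delimited
    multi-view data input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml, optparse, knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
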