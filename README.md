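# sadln

Adversarial multi-omics integration for cancer subtype discovery.

Molecular subtyping asks whether the patients of one cancer fall into
molecularly coherent subgroups with distinct prognosis. Each omics layer —
copy number, mRNA, miRNA, DNA methylation — has its own scale, noise and
information content, so naive concatenation treats them poorly, and none of
the layers alone sees the whole picture. `sadln` is for computational
biologists who have several aligned sample-by-feature matrices (plus,
ideally, survival and clinical annotations) and want integrated subtype
calls with a defensible statistical evaluation.

## The method

The core is a self-attention adversarial autoencoder. Each omics block
`x^m` is mapped by its own affine sub-network `y^m = x^m w_m + b_m` to a
common width `d = 25`; the blocks are concatenated to `Y` (width
`d_k = M·d`, 100 for four omics), batch-normalized, passed through the
exact GELU `x·Φ(x)`, and then through *sample-wise* scaled dot-product
self-attention with `K = Y′W^K`, `Q = Y′W^Q`, `V = Y′W^V`:

    ω_ij = softmax_j( q_i·k_j / √d_k ),   z_i = Σ_j ω_ij v_j

so each sample's code borrows from the samples it resembles. Affine heads
produce `μ` and `log σ²`; training draws `Z = μ + σ·ε`
(reparameterization), inference uses `Z = μ`. A decoder reconstructs every
block from `Z` (squared-Frobenius loss, averaged over blocks and samples),
while a discriminator — trained to tell latent codes from `N(0, I)` draws —
adversarially regularizes the encoder. The total generator objective is
`λ₁·L_Decoder + λ₂·L_adv` (defaults 1 and 1e-4). A Gaussian mixture model
with full covariances, fitted to `Z` by EM, assigns each sample to its
maximum-posterior component: the subtype.

Subtype solutions are evaluated the way the subtyping literature does:
a K-group log-rank chi-square calibrated by label permutation (initial
batch `min(max(10/p, 1e4), 1e6)`, then batches of 1e5 until the 95% CI is
within 10% of the estimate and clear of 0.05), and a clinical-enrichment
count (Kruskal–Wallis for numeric labels; permutation-calibrated Pearson
chi-square for categorical ones).

## Worked example

The package ships a seeded generator whose defaults are the built-in
benchmark: 400 samples, four omics blocks (widths 200/200/50/200), four
clusters with mean shifts of three noise standard deviations on 20% of
features, and cluster-linked exponential survival.

```r
library(sadln)

sim <- simulate_multiomics(simulation_config())   # n = 400, 4 blocks, K = 4
sim$data
#> omics_dataset: 400 samples, 4 blocks
#>   cnv: 200 features
#>   mrna: 200 features
#>   mirna: 50 features
#>   meth: 200 features

res <- sadln_subtype(sim$data, K = 4, epochs = 200, seed = 2)
ari(res$assignment$cluster, sim$labels)
#> [1] 1

ev <- sadln_evaluate(res$assignment, sim$clinical, seed = 3)
ev
#> survival: -log10(p) = 6.0 (permutation p = 1e-06, 1000000 permutations)
#> clinical enrichment: 1 of 2 labels significant at alpha = 0.05
#>   age              kruskal_wallis p = 3.135e-16
#>   gender           chi_square     p = 0.7662
```

The pipeline recovers the generating clusters exactly (adjusted Rand
index 1). The permutation log-rank p-value hits the resolution floor of
one million permutations — the four clusters differ strongly in survival,
as simulated — and of the two clinical labels, the cluster-linked `age`
is flagged while the null covariate `gender` is (correctly) not.

`model_summary(res$model)` prints the 19-layer architecture
(10 encoder / 5 decoder / 4 discriminator layers, 100-dimensional
integrated representation). Ablations are one flag away:
`use_attention = FALSE`, `lambda1 = 0`, or `lambda2 = 0`.

A command-line front end wrapping the same functions lives at
`inst/cli/sadln.R` (`simulate`, `subtype`, `evaluate` subcommands; YAML
config with flag overrides).

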